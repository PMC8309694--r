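# Dataset bookkeeping: stage-1 filtering of the raw sequence pool, class
# balancing, the validation reserve, replication of dead sequences, and
# mixed-dataset assembly.

#' Pool counts for dataset assembly
#'
#' @param alive_total,dead_total raw labelled pool sizes per class.
#' @param alive_to_nn,dead_to_nn sequences per class routed to the network
#'   by the stage-1 prefilter (the remainder were settled as trivially
#'   alive, or misrouted).
#' @param val_per_class validation reserve per class (drawn from the
#'   original post-stage-1 sequences only).
#' @param simulated_per_class simulator sequences added per class.
#' @return list of class `pool_counts`.
#' @export
pool_counts <- function(alive_total, dead_total, alive_to_nn, dead_to_nn,
                        val_per_class, simulated_per_class = 0L) {
  stopifnot(alive_to_nn <= alive_total, dead_to_nn <= dead_total,
            val_per_class <= min(alive_to_nn, dead_to_nn),
            val_per_class >= 0, simulated_per_class >= 0)
  structure(list(alive_total = alive_total, dead_total = dead_total,
                 alive_to_nn = alive_to_nn, dead_to_nn = dead_to_nn,
                 val_per_class = val_per_class,
                 simulated_per_class = simulated_per_class),
            class = "pool_counts")
}

#' Stage-1 routing rates from pool counts
#'
#' Percentages of each class the rule-based prefilter routed to the network
#' versus settled as trivially alive. For dead worms, an "alive" verdict is
#' a stage-1 error.
#'
#' @param alive_total,alive_to_nn live pool size and live sequences routed
#'   to the network.
#' @param dead_total,dead_to_nn dead pool size and dead sequences routed to
#'   the network.
#' @return list: `alive_trivial_pct` (live settled by the rules),
#'   `alive_to_nn_pct`, `dead_error_pct` (dead misrouted as alive).
#' @export
stage1_rates <- function(alive_total, alive_to_nn, dead_total, dead_to_nn) {
  stopifnot(alive_to_nn <= alive_total, dead_to_nn <= dead_total)
  list(alive_trivial_pct = 100 * (alive_total - alive_to_nn) / alive_total,
       alive_to_nn_pct = 100 * alive_to_nn / alive_total,
       dead_error_pct = 100 * (dead_total - dead_to_nn) / dead_total)
}

#' Plan the balanced mixed training dataset
#'
#' Balancing logic: only `min(alive_to_nn, dead_to_nn)` sequences per class
#' are usable as a balanced original set; after reserving the validation
#' sample, the leftover live sequences (the excess of the larger class) are
#' not wasted -- they join the training set, matched by an equal number of
#' replicated dead sequences, and simulator sequences top up both classes.
#'
#' @param counts a [pool_counts()].
#' @return list of class `assembly_plan`: `train_original_alive`,
#'   `train_original_dead`, `replicated_dead`, `val_per_class`,
#'   `simulated_per_class`, `total_per_class`, `total`.
#' @export
plan_mixed_dataset <- function(counts) {
  stopifnot(inherits(counts, "pool_counts"))
  balanced <- min(counts$alive_to_nn, counts$dead_to_nn)
  if (counts$val_per_class > balanced)
    stop("validation reserve exceeds the balanced usable pool")
  unused_live <- counts$alive_to_nn - balanced
  train_dead <- balanced - counts$val_per_class
  train_alive <- train_dead + unused_live
  total_per_class <- train_alive + counts$simulated_per_class
  stopifnot(total_per_class ==
              train_dead + unused_live + counts$simulated_per_class)
  structure(list(train_original_alive = train_alive,
                 train_original_dead = train_dead,
                 replicated_dead = unused_live,
                 val_per_class = counts$val_per_class,
                 simulated_per_class = counts$simulated_per_class,
                 total_per_class = total_per_class,
                 total = 2L * total_per_class),
            class = "assembly_plan")
}

#' @export
print.assembly_plan <- function(x, ...) {
  cat("assembly_plan:\n",
      "  original  ", x$train_original_alive, "alive /",
      x$train_original_dead, "dead\n",
      "  simulated ", x$simulated_per_class, "per class\n",
      "  replicated", x$replicated_dead, "dead\n",
      "  total     ", x$total_per_class, "per class (", x$total, ")\n")
  invisible(x)
}

#' Materialise the train/validation split from triplet pools
#'
#' Draws the validation reserve from the original post-stage-1 pool only
#' (simulated data never enters validation), fills the training strata to
#' the plan's counts exactly, and produces the replicated dead sequences
#' from seeded uniformly-chosen live originals via
#' [replicate_dead_from_live()].
#'
#' @param plan an [plan_mixed_dataset()] result.
#' @param original list of labelled original triplets (`$label`,
#'   `$triplet`).
#' @param simulated list of labelled simulator triplets.
#' @param seed selection seed.
#' @return list with `train` (shuffled), `val`, and `plan`.
#' @export
materialize <- function(plan, original, simulated, seed = 1L) {
  stopifnot(inherits(plan, "assembly_plan"))
  lab_o <- vapply(original, `[[`, character(1), "label")
  lab_s <- vapply(simulated, `[[`, character(1), "label")
  oa <- which(lab_o == "alive"); od <- which(lab_o == "dead")
  sa <- which(lab_s == "alive"); sd_ <- which(lab_s == "dead")
  need <- c(alive_original = plan$val_per_class + plan$train_original_alive,
            dead_original = plan$val_per_class + plan$train_original_dead,
            alive_simulated = plan$simulated_per_class,
            dead_simulated = plan$simulated_per_class)
  have <- c(length(oa), length(od), length(sa), length(sd_))
  short <- which(have < need)
  if (length(short))
    stop("pool shortfall in stratum: ",
         paste(names(need)[short], collapse = ", "))
  with_seed(derive_seed(seed, 17), {
    val_a <- sample(oa, plan$val_per_class)
    val_d <- sample(od, plan$val_per_class)
    tr_a <- sample(setdiff(oa, val_a), plan$train_original_alive)
    tr_d <- sample(setdiff(od, val_d), plan$train_original_dead)
    sim_a <- sample(sa, plan$simulated_per_class)
    sim_d <- sample(sd_, plan$simulated_per_class)
    reps <- list()
    if (plan$replicated_dead > 0) {
      src <- sample(tr_a, plan$replicated_dead, replace = plan$replicated_dead > length(tr_a))
      reps <- lapply(seq_along(src), function(i)
        replicate_dead_from_live(original[[src[i]]]$triplet,
                                 seed = derive_seed(seed, 18, i)))
    }
    train <- c(original[tr_a], original[tr_d],
               simulated[c(sim_a, sim_d)], reps)
    train <- train[sample.int(length(train))]
    val <- c(original[val_a], original[val_d])
    n_alive <- sum(vapply(train, `[[`, character(1), "label") == "alive")
    stopifnot(n_alive == plan$total_per_class,
              length(train) == plan$total)
    list(train = train, val = val, plan = plan)
  })
}

#' Apply the stage-1 prefilter to a labelled triplet pool
#'
#' Routes each triplet with [stage1_classify()]; returns the post-stage-1
#' pool (UNDETERMINED sequences, the network's material) and the routing
#' summary per class.
#'
#' @param triplets list of labelled triplets.
#' @param config a [cascade_config()].
#' @return list: `to_nn` (labelled triplets routed to the network),
#'   `trivial_alive` (settled by the rules), and `counts` (a table of
#'   label x verdict).
#' @export
filter_pool_stage1 <- function(triplets, config = cascade_config()) {
  verdicts <- vapply(triplets, function(it)
    stage1_classify(triplet_of(it), config)$verdict, character(1))
  labels <- vapply(triplets, `[[`, character(1), "label")
  list(to_nn = triplets[verdicts == "UNDETERMINED"],
       trivial_alive = triplets[verdicts == "ALIVE"],
       counts = table(label = labels, verdict = verdicts))
}
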