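# End-to-end orchestration: simulate -> train -> classify -> postprocess ->
# evaluate, with a run manifest for reproducibility.

#' Demo-scale pipeline configuration
#'
#' Study conditions for a desk-scale synthetic assay: a handful of plates
#' with 10 worms each on 360 px images, worms moving 30 px/day in mid life
#' and decelerating near death, placement shifts up to 15 px. The classifier
#' is the small backbone trained on simulator triplets drawn under the same
#' motion model.
#'
#' @param n_plates plates simulated.
#' @param worms_per_plate,days,image_size_px,speed,n_noise_blobs plate
#'   conditions, see [sim_config()].
#' @param n_train,n_val simulator triplets for training/validation.
#' @param train_speed,train_speed_jitter triplet pose-change magnitude and
#'   per-sample range for the training set; the range covers the slow
#'   near-death movers the network must separate from dead worms.
#' @param epochs_phase1,epochs_phase2,lr_phase1,lr_phase2,batch_size
#'   training schedule (desk scale: fewer, larger steps than the
#'   full-scale 120+10 epoch recipe).
#' @param input_size,feature_dim,lstm_hidden small-backbone dimensions.
#' @param split_day monotone-correction boundary day (the strain's mean
#'   life); `NULL` uses the simulated death distribution's mean,
#'   `floor((days + 7) / 2)`.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_plates = 5L, worms_per_plate = 6L, days = 10L,
                            image_size_px = 600L, speed = 30, n_noise_blobs = 2L,
                            n_train = 1200L, n_val = 200L, train_speed = 10,
                            train_speed_jitter = c(0.5, 1.5),
                            epochs_phase1 = 24L, epochs_phase2 = 3L,
                            lr_phase1 = 3e-3, lr_phase2 = 3e-4,
                            batch_size = 32L,
                            input_size = 32L, feature_dim = 64L,
                            lstm_hidden = 32L, split_day = NULL, seed = 1L) {
  if (is.null(split_day)) split_day <- (as.integer(days) + 7L) %/% 2L
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full lifespan pipeline on synthetic plates
#'
#' Stages: (1) generate a balanced simulator triplet set and train the
#' CNN-LSTM classifier; (2) simulate labelled plates; (3) run the two-stage
#' cascade to get daily live/dead counts; (4) build survival curves and
#' apply the two-period monotone correction; (5) compare automatic against
#' ground-truth curves with [plate_error()] and [condition_error()]. All
#' stages derive their randomness from `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, writes counts.csv,
#'   curves.csv, report.json and manifest.json.
#' @param model optional pre-trained model (skips stage 1).
#' @param verbose print stage progress.
#' @return list of class `pipeline_report`: per-plate errors, condition
#'   error, curves, counts, the trained model, and the manifest.
#' @export
pipeline_end_to_end <- function(config = pipeline_config(), out_dir = NULL,
                                model = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()
  if (is.null(model)) {
    say("stage 1: training classifier on simulator triplets")
    tripcfg <- sim_config(n_sequences = config$n_train + config$n_val,
                          speed = config$train_speed,
                          speed_jitter = config$train_speed_jitter,
                          noise_frac = 0.3,
                          seed = derive_seed(config$seed, 21))
    pool <- generate_dataset(tripcfg)
    train_set <- pool[seq_len(config$n_train)]
    val_set <- pool[config$n_train + seq_len(config$n_val)]
    ncfg <- net_config(backbone = "small_cnn", feature_dim = config$feature_dim,
                       lstm_hidden = config$lstm_hidden,
                       input_size = config$input_size)
    model <- build_model(ncfg, seed = derive_seed(config$seed, 22))
    model <- train(model, train_set,
                   train_config(epochs_phase1 = config$epochs_phase1,
                                epochs_phase2 = config$epochs_phase2,
                                lr_phase1 = config$lr_phase1,
                                lr_phase2 = config$lr_phase2,
                                batch_size = config$batch_size,
                                seed = derive_seed(config$seed, 23)))
    cm <- evaluate(model, val_set)
    val_acc <- (cm$TD + cm$TA) / (cm$TD + cm$FA + cm$FD + cm$TA)
    say(sprintf("  validation accuracy: %.3f", val_acc))
  } else {
    cm <- NULL; val_acc <- NA_real_
  }
  say("stage 2-3: simulating plates and running the cascade")
  platecfg <- sim_config(worms_per_plate = config$worms_per_plate,
                         speed = config$speed, days = config$days,
                         image_size_px = config$image_size_px,
                         n_noise_blobs = config$n_noise_blobs,
                         worm_min_sep = 80,
                         seed = derive_seed(config$seed, 24))
  plates <- lapply(seq_len(config$n_plates), function(p)
    simulate_plate(platecfg, plate_id = p))
  counts <- do.call(rbind, lapply(plates, function(pl) {
    say("  plate ", pl$plate_id)
    run_cascade(pl, model)
  }))
  say("stage 4-5: curves, monotone correction, metrics")
  manual <- lapply(plates, truth_curve)
  auto <- lapply(plates, function(pl) {
    cc <- counts[counts$plate == pl$plate_id, ]
    monotone_correct(build_curve(cc$live[order(cc$day)],
                                 initial_live = length(pl$worms),
                                 plate_id = pl$plate_id),
                     split_day = config$split_day)
  })
  per_plate <- vapply(seq_along(plates), function(i)
    plate_error(manual[[i]], auto[[i]]), numeric(1))
  cond <- condition_error(manual, auto)
  curves <- do.call(rbind, lapply(seq_along(plates), function(i) {
    data.frame(plate = plates[[i]]$plate_id,
               day = seq_len(config$days),
               live_manual = manual[[i]]$counts,
               live_auto = counts$live[counts$plate == plates[[i]]$plate_id],
               live_auto_corrected = auto[[i]]$counts)
  }))
  manifest <- list(command = "pipeline_end_to_end",
                   seed = config$seed,
                   config = unclass(config),
                   version = as.character(utils::packageVersion("wormlifespan")),
                   started = format(t0), finished = format(Sys.time()))
  report <- structure(list(per_plate_error = per_plate,
                           mean_plate_error = mean(per_plate),
                           sd_plate_error = stats::sd(per_plate),
                           condition_error = cond,
                           val_accuracy = val_acc,
                           val_confusion = cm,
                           curves = curves, counts = counts,
                           model = model, manifest = manifest),
                      class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(counts, file.path(out_dir, "counts.csv"), row.names = FALSE)
    utils::write.csv(curves, file.path(out_dir, "curves.csv"), row.names = FALSE)
    jsonlite::write_json(list(per_plate_error = per_plate,
                              mean_plate_error = mean(per_plate),
                              condition_error = cond,
                              val_accuracy = val_acc),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  if (!is.na(x$val_accuracy))
    cat(sprintf("  classifier validation accuracy: %.1f%%\n",
                100 * x$val_accuracy))
  cat(sprintf("  plate error: %.2f%% +/- %.2f%% (n = %d plates)\n",
              x$mean_plate_error, x$sd_plate_error,
              length(x$per_plate_error)))
  cat(sprintf("  condition error: %.2f%%\n", x$condition_error))
  invisible(x)
}
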