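# Survival curves, monotone correction, hit rates, curve errors.

test_that("percent_live and curve construction behave", {
  cv <- build_curve(c(111, 90, 0), initial_live = 111)
  expect_equal(percent_live(cv, 1), 100)
  expect_equal(percent_live(cv, 3), 0)
  expect_equal(percent_live(build_curve(c(55), 110), 1), 50)
  expect_error(percent_live(build_curve(c(1), 0), 1), "positive")
  expect_error(percent_live(cv, 4), "range")
  expect_error(build_curve(numeric(0), 10), "non-empty")
  expect_error(build_curve(c(3, -1), 10), "non-negative")
  expect_warning(percent_live(build_curve(c(12), 10), 1), "exceeds")
})

test_that("daily and plate errors follow the stated arithmetic", {
  a <- build_curve(c(10, 5, 0), 10)
  b <- build_curve(c(10, 6, 1), 10)
  expect_equal(daily_error(a, a, 2), 0)
  expect_equal(daily_error(a, b, 2), 10)
  expect_equal(daily_error(a, b, 2), daily_error(b, a, 2))
  expect_equal(plate_error(a, a), 0)
  # manual % = [100, 50, 0], automatic % = [100, 60, 10] -> mean 20/3
  expect_equal(plate_error(a, b), 20 / 3)
  const_gap <- plate_error(build_curve(rep(100, 20), 100),
                           build_curve(rep(95, 20), 100))
  expect_equal(const_gap, 5)
  expect_error(plate_error(a, build_curve(c(1, 1), 10)), "same days")
})

test_that("condition error pools counts and differs from mean plate error", {
  a <- build_curve(c(10, 5, 0), 10)
  b <- build_curve(c(10, 6, 1), 10)
  expect_equal(condition_error(list(a), list(b)), plate_error(a, b))
  expect_equal(condition_error(list(a, a), list(a, a)), 0)
  # constructed counterexample: pooling is not averaging
  m1 <- build_curve(c(10, 8), 10); m2 <- build_curve(c(40, 10), 40)
  a1 <- build_curve(c(10, 10), 10); a2 <- build_curve(c(40, 8), 40)
  pooled <- condition_error(list(m1, m2), list(a1, a2))
  avg <- mean(c(plate_error(m1, a1), plate_error(m2, a2)))
  expect_false(isTRUE(all.equal(pooled, avg)))
  # direct recomputation of the pooled definition
  pm <- 100 * (m1$counts + m2$counts) / 50
  pa <- 100 * (a1$counts + a2$counts) / 50
  expect_equal(pooled, mean(abs(pm - pa)))
})

test_that("monotone correction applies the two-period rules", {
  up <- monotone_correct(build_curve(c(10, 12, 9), 10), split_day = 2)
  expect_equal(up$counts, c(12, 12, 9))
  down <- monotone_correct(build_curve(c(10, 10, 8, 9), 10), split_day = 2)
  expect_equal(down$counts, c(10, 10, 8, 8))
  flat <- build_curve(c(9, 7, 7, 4), 10)
  expect_equal(monotone_correct(flat, 2)$counts, flat$counts)
})

test_that("monotone correction matches a fixed-point oracle on random curves", {
  # oracle: apply the stated single-step rules anywhere until nothing changes
  oracle <- function(x, split) {
    repeat {
      changed <- FALSE
      for (d in 2:length(x)) {
        if (x[d] > x[d - 1]) {
          if (d <= split) { x[d - 1] <- x[d] } else { x[d] <- x[d - 1] }
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    x
  }
  set.seed(31)
  for (i in 1:60) {
    n <- sample(3:15, 1)
    split <- sample(1:n, 1)
    x <- sample(0:12, n, replace = TRUE)
    got <- monotone_correct(build_curve(x, 12), split_day = split)
    expect_equal(got$counts, as.numeric(oracle(x, split)),
                 info = paste("counts", paste(x, collapse = ","),
                              "split", split))
    # non-increasing and idempotent
    expect_true(all(diff(got$counts) <= 0))
    expect_equal(monotone_correct(got, split_day = split)$counts, got$counts)
    # direction discipline: early days never lowered, late days never raised
    early <- seq_len(min(split, n))
    expect_true(all(got$counts[early] >= x[early]))
    if (split < n)
      expect_true(all(got$counts[(split + 1):n] <= x[(split + 1):n]))
  }
})

test_that("hit rates reproduce the printed validation arithmetic", {
  # full cascade confusion: dead 430/84, alive 74/5050
  m <- confusion_matrix(TD = 430, FA = 84, FD = 74, TA = 5050)
  expect_equal(round(true_dead_rate(m), 2), 83.66)
  expect_equal(round(true_live_rate(m), 2), 98.56)
  expect_equal(round(mean_hit_rate(m), 2), 91.11)
  # network-only validation: 430/70, 74/426
  m2 <- confusion_matrix(TD = 430, FA = 70, FD = 74, TA = 426)
  expect_equal(true_dead_rate(m2), 86)
  expect_equal(true_live_rate(m2), 85.2)
  expect_equal(mean_hit_rate(m2), 85.6)
  m3 <- confusion_matrix(7, 0, 0, 7)
  expect_equal(mean_hit_rate(m3), 100)
  expect_error(true_dead_rate(confusion_matrix(0, 0, 1, 1)), "undefined")
  expect_error(true_live_rate(confusion_matrix(1, 1, 0, 0)), "undefined")
})

test_that("hit rates agree with brute-force counting on prediction lists", {
  set.seed(8)
  truth <- sample(c("alive", "dead"), 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.8, truth,
                 ifelse(truth == "alive", "dead", "alive"))
  m <- confusion_matrix(TD = sum(truth == "dead" & pred == "dead"),
                        FA = sum(truth == "dead" & pred == "alive"),
                        FD = sum(truth == "alive" & pred == "dead"),
                        TA = sum(truth == "alive" & pred == "alive"))
  expect_equal(true_dead_rate(m),
               100 * mean(pred[truth == "dead"] == "dead"))
  expect_equal(true_live_rate(m),
               100 * mean(pred[truth == "alive"] == "alive"))
})
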