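# CNN-LSTM sequence classifier: construction, preprocessing, training
# mechanics, prediction, evaluation.

test_that("model outputs normalized probabilities and honours batch order", {
  m <- build_model(tiny_net_config(), seed = 2)
  ds <- generate_dataset(easy_sim_config(6, seed = 14))
  pr <- predict(m, ds)
  expect_equal(pr$p_alive + pr$p_dead, rep(1, 6), tolerance = 1e-12)
  expect_true(all(pr$p_alive >= 0 & pr$p_dead >= 0))
  # permuting samples permutes outputs identically
  pr2 <- predict(m, ds[c(3, 1, 2, 6, 5, 4)])
  expect_equal(pr2$p_alive, pr$p_alive[c(3, 1, 2, 6, 5, 4)], tolerance = 1e-10)
  # single-triplet interface
  one <- predict(m, ds[[1]])
  expect_named(one$probs, c("alive", "dead"))
  expect_equal(sum(one$probs), 1, tolerance = 1e-12)
})

test_that("the residual backbone emits 512-dim per-frame features", {
  cfg <- net_config(backbone = "residual18", input_size = 224L)
  m <- build_model(cfg, seed = 1)
  trip <- make_triplet(worm_scene())
  x <- wormlifespan:::preprocess_batch(list(trip), cfg)
  feats <- wormlifespan:::stack_forward(m$backbone, x, train = FALSE)
  expect_equal(dim(feats), c(3L, 512L))
  logits <- wormlifespan:::model_forward(m, x, train = FALSE)
  expect_equal(dim(logits), c(1L, 2L))
})

test_that("net_config validates its invariants", {
  expect_error(net_config(backbone = "residual18", feature_dim = 256),
               "512")
  expect_error(net_config(backbone = "small_cnn", input_size = 50),
               "multiple of 8")
  expect_error(net_config(lstm_layers = 2), "single")
})

test_that("preprocess_input resizes bilinearly and keeps frame order", {
  mk <- function(v) matrix(v, 80, 80)
  trip <- sub_image_triplet(mk(0.2), mk(0.5), mk(0.8),
                            anchor_centroid = c(40.5, 40.5))
  cfg <- tiny_net_config(input_size = 32L)
  x <- preprocess_input(trip, config = cfg)
  expect_equal(dim(x), c(32, 32, 3, 3))
  # constants are preserved by bilinear resize, then normalised
  expect_equal(as.vector(x[, , 1, 1]), rep((0.2 - 0.5) / 0.5, 32 * 32))
  expect_equal(as.vector(x[, , 1, 2]), rep((0.5 - 0.5) / 0.5, 32 * 32))
  expect_equal(as.vector(x[, , 1, 3]), rep((0.8 - 0.5) / 0.5, 32 * 32))
  # mean intensity is preserved through resize within 1%
  img <- matrix(runif(80 * 80), 80, 80)
  rs <- wormlifespan:::resize_bilinear(img, 224)
  expect_lt(abs(mean(rs) - mean(img)) / mean(img), 0.01)
  # non-square input is rejected
  bad <- sub_image_triplet(mk(0.2), mk(0.5), mk(0.8), c(40, 40))
  bad$cur <- matrix(0.5, 80, 60)
  expect_error(preprocess_input(bad, config = cfg), "square")
})

test_that("backprop matches numerical gradients", {
  cfg <- net_config(backbone = "small_cnn", feature_dim = 8, lstm_hidden = 6,
                    input_size = 8)
  m <- build_model(cfg, seed = 2)
  set.seed(4)
  x <- array(rnorm(8 * 8 * 3 * 2 * 3), c(8, 8, 3, 6))
  y <- c(1L, 2L)
  loss_at <- function() {
    lo <- wormlifespan:::model_forward(m, x, train = TRUE)
    wormlifespan:::softmax_ce(lo, y)$loss
  }
  lo <- wormlifespan:::model_forward(m, x, train = TRUE)
  ce <- wormlifespan:::softmax_ce(lo, y)
  invisible(wormlifespan:::model_backward(m, ce$dlogits))
  params <- c(wormlifespan:::collect_params(m$backbone),
              wormlifespan:::collect_params(m$lstm),
              wormlifespan:::collect_params(m$head))
  for (k in c(1, 4, 7, 9, 10, 11, 12, 13)) {
    p <- params[[k]]
    W <- p$env[[p$par]]; G <- p$env[[p$grad]]
    i <- sample(length(W), 1)
    eps <- 1e-5
    p$env[[p$par]][i] <- W[i] + eps; lp <- loss_at()
    p$env[[p$par]][i] <- W[i] - eps; lm <- loss_at()
    p$env[[p$par]][i] <- W[i]
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - G[i]) / max(abs(num), abs(G[i]), 1e-8), 1e-4)
  }
})

test_that("training runs the two-phase schedule reproducibly", {
  ds <- generate_dataset(easy_sim_config(40, seed = 15))
  tc <- train_config(epochs_phase1 = 2, epochs_phase2 = 1,
                     lr_phase1 = 1e-3, lr_phase2 = 1e-4,
                     batch_size = 8, seed = 6)
  m1 <- train(build_model(tiny_net_config(), seed = 3), ds, tc)
  expect_equal(m1$history$lr, c(1e-3, 1e-3, 1e-4))
  expect_equal(nrow(m1$history), 3)
  expect_true(m1$trained)
  m2 <- train(build_model(tiny_net_config(), seed = 3), ds, tc)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(predict(m1, ds[1:4])$p_alive, predict(m2, ds[1:4])$p_alive)
})

test_that("training warns on unbalanced sets and errors on empty ones", {
  ds <- generate_dataset(easy_sim_config(20, seed = 16))
  labs <- vapply(ds, `[[`, character(1), "label")
  unbal <- c(ds[labs == "alive"], ds[labs == "dead"][1:3])
  tc <- train_config(epochs_phase1 = 1, epochs_phase2 = 0, batch_size = 8,
                     seed = 1, auto_balance = TRUE)
  expect_warning(train(build_model(tiny_net_config(), seed = 1), unbal, tc),
                 "unbalanced")
  expect_error(train(build_model(tiny_net_config(), seed = 1), list(),
                     train_config()),
               "empty")
})

test_that("quarter-turn rotation of a batch is exact", {
  x <- array(seq_len(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  r4 <- wormlifespan:::rot90_batch(x, 4)
  expect_identical(r4, x)
  r1 <- wormlifespan:::rot90_batch(x, 1)
  expect_equal(dim(r1), dim(x))
  expect_equal(r1[1, 1, 1, 1], x[1, 4, 1, 1])
  expect_equal(r1[4, 1, 1, 1], x[1, 1, 1, 1])
})

test_that("evaluate fills the confusion matrix in table orientation", {
  ds <- generate_dataset(easy_sim_config(20, seed = 18))
  perfect <- function(triplet) {
    # oracle: any real frame-to-frame change means alive
    if (mean(abs(triplet$prev - triplet$cur)) > 0.01) "alive" else "dead"
  }
  cm <- evaluate(perfect, ds)
  expect_equal(cm$TD, 10); expect_equal(cm$TA, 10)
  expect_equal(cm$FA, 0); expect_equal(cm$FD, 0)
  always_alive <- function(triplet) "alive"
  cm2 <- evaluate(always_alive, ds)
  expect_equal(cm2$TD, 0); expect_equal(cm2$FA, 10)
  expect_equal(cm2$FD, 0); expect_equal(cm2$TA, 10)
  expect_equal(cm2$TD + cm2$FA + cm2$FD + cm2$TA, 20)
})
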