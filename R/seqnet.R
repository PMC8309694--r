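# Stage-2 sequence classifier: per-frame convolutional feature extractor,
# single-layer unidirectional LSTM over the 3-frame sequence, linear head
# with softmax. Two backbones: "residual18" (18-layer residual network,
# 512-dim features, faithful to the architecture the full-scale pipeline
# uses) and "small_cnn" (4 conv blocks + global pool) for desk-scale work.

seqnet_classes <- c("alive", "dead")

#' Network configuration
#'
#' @param backbone `"residual18"` or `"small_cnn"`.
#' @param feature_dim per-frame feature length; 512 for residual18 (fixed by
#'   the architecture); small_cnn accepts any multiple of 8.
#' @param lstm_hidden LSTM hidden size (256 in the full-scale model).
#' @param lstm_layers LSTM layers; only 1 is supported (unidirectional).
#' @param n_classes output classes (2: alive/dead).
#' @param input_size square input side after bilinear resize; 224 for
#'   residual18; small_cnn needs a multiple of 8.
#' @param seq_length frames per sequence (3: previous/current/next day).
#' @param in_channels backbone input channels; grayscale frames are
#'   replicated across channels.
#' @param norm_mean,norm_sd per-channel normalisation applied after resize
#'   (defaults: ImageNet statistics for residual18, 0.5/0.5 otherwise).
#' @param seq_center centre the pooled per-frame features across the three
#'   frames of each sequence before the LSTM, removing scene-specific
#'   appearance so the recurrent unit sees temporal change directly;
#'   defaults to TRUE for the small backbone (which lacks the capacity and
#'   data budget to learn this invariance) and FALSE for residual18.
#' @param center_mask radii `c(inner, outer)` in crop pixels of a soft
#'   radial mask applied to each frame before resizing: content beyond
#'   `outer` px from the crop centre is blended into the background so
#'   bystander worms near the crop edge cannot masquerade as motion of the
#'   anchored worm. `NULL` disables; defaults to `c(26, 38)` for the small
#'   backbone and disabled for residual18.
#' @return list of class `net_config`.
#' @export
net_config <- function(backbone = c("residual18", "small_cnn"),
                       feature_dim = 512L, lstm_hidden = 256L,
                       lstm_layers = 1L, n_classes = 2L,
                       input_size = 224L, seq_length = 3L,
                       in_channels = 3L,
                       norm_mean = NULL, norm_sd = NULL,
                       seq_center = NULL, center_mask = c(-1)) {
  backbone <- match.arg(backbone)
  if (backbone == "residual18" && feature_dim != 512L)
    stop("residual18 produces 512-dim features; feature_dim must be 512")
  if (feature_dim %% 8 != 0) stop("feature_dim must be a multiple of 8")
  if (input_size %% 8 != 0) stop("input_size must be a multiple of 8")
  if (lstm_layers != 1L) stop("only a single unidirectional LSTM layer is supported")
  if (seq_length != 3L) stop("this pipeline uses 3-frame sequences")
  if (is.null(norm_mean))
    norm_mean <- if (backbone == "residual18") c(0.485, 0.456, 0.406) else rep(0.5, in_channels)
  if (is.null(norm_sd))
    norm_sd <- if (backbone == "residual18") c(0.229, 0.224, 0.225) else rep(0.5, in_channels)
  if (is.null(seq_center)) seq_center <- backbone == "small_cnn"
  if (identical(center_mask, c(-1)))
    center_mask <- if (backbone == "small_cnn") c(26, 38) else NULL
  structure(list(backbone = backbone, feature_dim = as.integer(feature_dim),
                 lstm_hidden = as.integer(lstm_hidden),
                 lstm_layers = 1L, n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size), seq_length = 3L,
                 in_channels = as.integer(in_channels),
                 norm_mean = norm_mean, norm_sd = norm_sd,
                 seq_center = seq_center, center_mask = center_mask),
            class = "net_config")
}

#' Training configuration
#'
#' Two-phase schedule: `lr_phase1` for `epochs_phase1` epochs then
#' `lr_phase2` for `epochs_phase2` epochs, Adam on cross-entropy, batch 64,
#' and rotation augmentation (0/90/180/270 degrees, one rotation drawn per
#' sample per epoch and applied to all three frames of the triplet).
#'
#' @param epochs_phase1,lr_phase1,epochs_phase2,lr_phase2 schedule.
#' @param batch_size samples per gradient step.
#' @param augment enable rotation augmentation.
#' @param augment_time_flip also reverse the frame order of half the
#'   samples each epoch; a reversed sequence keeps its label (motion is
#'   motion in either direction). Off by default: the cascade instead
#'   reverses assay-boundary triplets at prediction time, which keeps the
#'   training distribution focused.
#' @param auto_balance subsample the majority class when the training set is
#'   unbalanced (otherwise only a warning is issued).
#' @param seed seed for init, shuffling, and augmentation draws.
#' @param verbose print per-epoch loss/accuracy.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs_phase1 = 120L, lr_phase1 = 1e-4,
                         epochs_phase2 = 10L, lr_phase2 = 1e-5,
                         batch_size = 64L, augment = TRUE,
                         augment_time_flip = FALSE,
                         auto_balance = FALSE, seed = 1L, verbose = FALSE) {
  stopifnot(epochs_phase1 >= 1, epochs_phase2 >= 0, batch_size >= 1)
  structure(as.list(environment()), class = "train_config")
}

backbone_small_cnn <- function(cfg) {
  w <- cfg$feature_dim %/% 8 * c(1L, 2L, 4L, 8L)
  list(nn_conv(cfg$in_channels, w[1], 3L), nn_relu(), nn_maxpool2(),
       nn_conv(w[1], w[2], 3L), nn_relu(), nn_maxpool2(),
       nn_conv(w[2], w[3], 3L), nn_relu(), nn_maxpool2(),
       nn_conv(w[3], w[4], 3L), nn_relu(),
       nn_gap(), nn_featnorm())
}

backbone_residual18 <- function(cfg) {
  list(nn_conv(cfg$in_channels, 64L, 7L, stride = 2L, pad = 3L), nn_relu(),
       nn_maxpool2(),
       nn_resblock(64L, 64L), nn_resblock(64L, 64L),
       nn_resblock(64L, 128L, stride = 2L), nn_resblock(128L, 128L),
       nn_resblock(128L, 256L, stride = 2L), nn_resblock(256L, 256L),
       nn_resblock(256L, 512L, stride = 2L), nn_resblock(512L, 512L),
       nn_gap(), nn_featnorm())
}

#' Build the CNN-LSTM sequence classifier
#'
#' Each frame of a 3-frame sequence passes independently through the
#' convolutional backbone (frames folded into the batch dimension), yielding
#' one feature vector per frame; the LSTM consumes the 3-step feature
#' sequence; its final hidden state feeds a linear layer to 2 classes whose
#' softmax output is the alive/dead probability.
#'
#' @param config a [net_config()].
#' @param seed seed for weight initialisation.
#' @return object of class `seqnet_model`.
#' @export
build_model <- function(config = net_config(), seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  with_seed(seed, {
    backbone <- switch(config$backbone,
                       small_cnn = backbone_small_cnn(config),
                       residual18 = backbone_residual18(config))
    model <- structure(list(config = config,
                            backbone = backbone,
                            lstm = nn_lstm(config$feature_dim, config$lstm_hidden),
                            head = nn_linear(config$lstm_hidden, config$n_classes),
                            trained = FALSE,
                            history = NULL),
                       class = "seqnet_model")
    model
  })
}

#' @export
print.seqnet_model <- function(x, ...) {
  cat("seqnet_model:", x$config$backbone, "->", x$config$feature_dim,
      "features -> LSTM(", x$config$lstm_hidden, ") ->",
      x$config$n_classes, "classes;",
      if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

resize_bilinear <- function(m, size) {
  if (nrow(m) == size && ncol(m) == size) return(m)
  as_image_matrix(EBImage::resize(EBImage::Image(m), w = size, h = size,
                                  filter = "bilinear"))
}

#' Preprocess a sub-image triplet for the network
#'
#' Each frame is resized to `input_size` x `input_size` by bilinear
#' interpolation, replicated across the backbone's input channels, and
#' normalised per channel; frame order previous, current, next is preserved.
#'
#' @param triplet a [sub_image_triplet()] with square grayscale frames.
#' @param input_size target side in px.
#' @param config a [net_config()] supplying channel count and normalisation.
#' @return array of dim (input_size, input_size, in_channels, 3), frames
#'   along the last axis.
#' @export
preprocess_input <- function(triplet, input_size = NULL,
                             config = net_config()) {
  stopifnot(inherits(triplet, "sub_image_triplet"))
  if (nrow(triplet$cur) != ncol(triplet$cur))
    stop("frames must be square")
  input_size <- input_size %||% config$input_size
  C <- config$in_channels
  out <- array(0, c(input_size, input_size, C, 3))
  frames <- list(triplet$prev, triplet$cur, triplet$nxt)
  w <- NULL
  if (!is.null(config$center_mask)) {
    n0 <- nrow(triplet$cur)
    g <- coord_grid(n0, n0)
    r <- sqrt((g$r - (n0 + 1) / 2)^2 + (g$c - (n0 + 1) / 2)^2)
    w <- clamp((config$center_mask[2] - r) /
                 (config$center_mask[2] - config$center_mask[1]), 0, 1)
  }
  for (t in 1:3) {
    fr <- frames[[t]]
    if (!is.null(w)) fr <- w * fr + (1 - w) * stats::median(fr)
    rs <- resize_bilinear(fr, input_size)
    for (ch in seq_len(C))
      out[, , ch, t] <- (rs - config$norm_mean[ch]) / config$norm_sd[ch]
  }
  out
}

# Stack preprocessed triplets into a batch array (S,S,C,N*3), frame-major
# within sample: 4th index (n-1)*3 + t.
preprocess_batch <- function(triplets, config) {
  S <- config$input_size; C <- config$in_channels
  n <- length(triplets)
  x <- array(0, c(S, S, C, n * 3))
  for (i in seq_len(n))
    x[, , , (i - 1) * 3 + 1:3] <- preprocess_input(triplets[[i]], S, config)
  x
}

model_forward <- function(model, x, train = TRUE) {
  feats <- stack_forward(model$backbone, x, train)       # (N*3) x D
  NT <- nrow(feats)
  xs <- lapply(1:3, function(t) feats[seq(t, NT, by = 3), , drop = FALSE])
  if (model$config$seq_center) {
    mu <- (xs[[1]] + xs[[2]] + xs[[3]]) / 3
    xs <- lapply(xs, function(f) f - mu)
  }
  h <- lstm_forward(model$lstm, xs, train)
  linear_forward(model$head, h, train)
}

model_backward <- function(model, dlogits) {
  dh <- linear_backward(model$head, dlogits)
  dxs <- lstm_backward(model$lstm, dh)
  if (model$config$seq_center) {
    dmu <- (dxs[[1]] + dxs[[2]] + dxs[[3]]) / 3
    dxs <- lapply(dxs, function(d) d - dmu)
  }
  NT <- nrow(dxs[[1]]) * 3
  dF <- matrix(0, NT, ncol(dxs[[1]]))
  for (t in 1:3) dF[seq(t, NT, by = 3), ] <- dxs[[t]]
  stack_backward(model$backbone, dF)
}

rot90_batch <- function(x, k) {
  k <- k %% 4
  while (k > 0) {
    x <- aperm(x[, dim(x)[2]:1, , , drop = FALSE], c(2, 1, 3, 4))
    k <- k - 1
  }
  x
}

label_to_class <- function(labels) match(labels, seqnet_classes)

triplet_of <- function(item) {
  if (inherits(item, "sub_image_triplet")) item else item$triplet
}

#' Train the sequence classifier
#'
#' Runs the two-phase Adam schedule on cross-entropy with rotation
#' augmentation. The training set must be class-balanced (a warning is
#' issued otherwise; `config$auto_balance` subsamples the majority class).
#' Seeded and reproducible: the same seed yields the same trained weights.
#'
#' @param model a [build_model()] result (trained in place and returned).
#' @param train_set list of labelled triplets: each element has `$triplet`
#'   (a [sub_image_triplet()]) and `$label` ("alive"/"dead").
#' @param config a [train_config()].
#' @return the trained model; `$history` holds a data.frame (epoch, lr,
#'   loss, acc).
#' @export
train <- function(model, train_set, config = train_config()) {
  stopifnot(inherits(model, "seqnet_model"), inherits(config, "train_config"))
  if (length(train_set) == 0) stop("empty training set")
  labels <- vapply(train_set, `[[`, character(1), "label")
  tab <- table(factor(labels, levels = seqnet_classes))
  if (tab[1] != tab[2]) {
    warning("training set is unbalanced (", tab[1], " alive / ", tab[2], " dead)")
    if (config$auto_balance) {
      k <- min(tab)
      keep <- with_seed(derive_seed(config$seed, 1), unlist(lapply(
        seqnet_classes, function(cl) sample(which(labels == cl), k))))
      train_set <- train_set[keep]
      labels <- labels[keep]
    }
  }
  y <- label_to_class(labels)
  n <- length(train_set)
  X <- preprocess_batch(lapply(train_set, triplet_of), model$config)
  params <- c(collect_params(model$backbone),
              collect_params(model$lstm),
              collect_params(model$head))
  opt <- adam_init(params)
  schedule <- c(rep(config$lr_phase1, config$epochs_phase1),
                rep(config$lr_phase2, config$epochs_phase2))
  history <- data.frame(epoch = seq_along(schedule), lr = schedule,
                        loss = NA_real_, acc = NA_real_)
  for (e in seq_along(schedule)) {
    lr <- schedule[e]
    ep <- with_seed(derive_seed(config$seed, 2, e), {
      list(perm = sample.int(n),
           rots = if (config$augment) sample(0:3, n, replace = TRUE)
                  else integer(n),
           flips = if (config$augment_time_flip)
             sample(c(TRUE, FALSE), n, replace = TRUE) else logical(n))
    })
    losses <- c(); hits <- 0L
    for (b in seq(1, n, by = config$batch_size)) {
      sel <- ep$perm[b:min(b + config$batch_size - 1, n)]
      fidx <- as.vector(vapply(seq_along(sel), function(k) {
        o <- (sel[k] - 1L) * 3L
        if (ep$flips[sel[k]]) o + 3:1 else o + 1:3
      }, integer(3)))
      xb <- X[, , , fidx, drop = FALSE]
      rots <- ep$rots[sel]
      for (k in 1:3) {
        grp <- which(rots == k)
        if (length(grp)) {
          gi <- as.vector(vapply(grp, function(i) (i - 1L) * 3L + 1:3, integer(3)))
          xb[, , , gi] <- rot90_batch(xb[, , , gi, drop = FALSE], k)
        }
      }
      yb <- y[sel]
      logits <- model_forward(model, xb, train = TRUE)
      ce <- softmax_ce(logits, yb)
      model_backward(model, ce$dlogits)
      adam_step(opt, params, lr)
      losses <- c(losses, ce$loss)
      hits <- hits + sum(max.col(ce$probs) == yb)
    }
    history$loss[e] <- mean(losses)
    history$acc[e] <- hits / n
    if (config$verbose)
      message(sprintf("epoch %3d  lr %.0e  loss %.4f  acc %.3f",
                      e, lr, history$loss[e], history$acc[e]))
  }
  model$history <- history
  model$trained <- TRUE
  model
}

#' Classify triplets with the trained network
#'
#' @param object a `seqnet_model`.
#' @param newdata a [sub_image_triplet()], a labelled-triplet list element,
#'   or a list of either.
#' @param ... unused.
#' @return for a single triplet, a list with `label` ("alive"/"dead") and
#'   `probs` (named, sums to 1); for a list, a data.frame with columns
#'   `label`, `p_alive`, `p_dead`.
#' @export
predict.seqnet_model <- function(object, newdata, ...) {
  single <- inherits(newdata, "sub_image_triplet") ||
    (!is.null(newdata$triplet) && inherits(newdata$triplet, "sub_image_triplet"))
  items <- if (single) list(newdata) else newdata
  x <- preprocess_batch(lapply(items, triplet_of), object$config)
  logits <- model_forward(object, x, train = FALSE)
  probs <- softmax_rows(logits)
  labels <- seqnet_classes[max.col(probs)]
  if (single)
    return(list(label = labels[1],
                probs = stats::setNames(probs[1, ], seqnet_classes)))
  data.frame(label = labels, p_alive = probs[, 1], p_dead = probs[, 2])
}

#' Evaluate the classifier on a labelled set
#'
#' @param model a trained `seqnet_model` (or a `function(triplet) -> label`).
#' @param val_set list of labelled triplets.
#' @return a [confusion_matrix()] with TD/FA/FD/TA counts (rows = true
#'   label, columns = prediction).
#' @export
evaluate <- function(model, val_set) {
  truth <- vapply(val_set, `[[`, character(1), "label")
  pred <- if (is.function(model)) {
    vapply(val_set, function(it) model(triplet_of(it)), character(1))
  } else {
    predict(model, val_set)$label
  }
  confusion_matrix(TD = sum(truth == "dead" & pred == "dead"),
                   FA = sum(truth == "dead" & pred == "alive"),
                   FD = sum(truth == "alive" & pred == "dead"),
                   TA = sum(truth == "alive" & pred == "alive"))
}
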