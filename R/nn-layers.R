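# Minimal neural-network engine: convolution (im2col + BLAS), ReLU, max
# pooling, global average pooling, a single-layer LSTM, a linear head,
# softmax cross-entropy, and Adam. Layers are environments holding
# parameters, gradients, and forward caches; tensors are arrays laid out
# (H, W, C, N).

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

nn_conv <- function(in_ch, out_ch, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "conv"
  ly$k <- k; ly$stride <- stride; ly$pad <- pad
  ly$in_ch <- in_ch; ly$out_ch <- out_ch
  ly$W <- he_init(k * k * in_ch, out_ch, k * k * in_ch)
  ly$b <- numeric(out_ch)
  ly$idx_cache <- list()
  ly
}

conv_geometry <- function(ly, H, W, C, N) {
  key <- paste(H, W, C, N, sep = "x")
  g <- ly$idx_cache[[key]]
  if (!is.null(g)) return(g)
  k <- ly$k; s <- ly$stride; p <- ly$pad
  Hp <- H + 2 * p; Wp <- W + 2 * p
  oh <- (Hp - k) %/% s + 1L; ow <- (Wp - k) %/% s + 1L
  r0 <- 1L + (seq_len(oh) - 1L) * s
  c0 <- 1L + (seq_len(ow) - 1L) * s
  posbase <- as.vector(outer(r0 - 1L, (c0 - 1L) * Hp, `+`))      # length P
  offs <- as.vector(outer(as.vector(outer(0:(k - 1L), (0:(k - 1L)) * Hp, `+`)),
                          (seq_len(C) - 1L) * Hp * Wp, `+`))      # length K
  idx1 <- outer(posbase, offs, `+`) + 1L                          # P x K
  S <- Hp * Wp * C
  P <- oh * ow
  bigidx <- idx1[rep(seq_len(P), N), , drop = FALSE] +
    rep((seq_len(N) - 1L) * S, each = P)
  g <- list(oh = oh, ow = ow, Hp = Hp, Wp = Wp, P = P, S = S, bigidx = bigidx)
  ly$idx_cache[[key]] <- g
  g
}

conv_forward <- function(ly, x, train) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  g <- conv_geometry(ly, H, W, C, N)
  p <- ly$pad
  if (p > 0) {
    xp <- array(0, c(g$Hp, g$Wp, C, N))
    xp[(p + 1):(p + H), (p + 1):(p + W), , ] <- x
  } else xp <- x
  col <- matrix(xp[g$bigidx], nrow(g$bigidx), ncol(g$bigidx))
  out <- col %*% ly$W
  out <- out + rep(ly$b, each = nrow(out))
  if (train) { ly$cache_col <- col; ly$cache_dims <- c(H, W, C, N) }
  aperm(array(out, c(g$oh, g$ow, N, ly$out_ch)), c(1, 2, 4, 3))
}

conv_backward <- function(ly, dy) {
  d <- ly$cache_dims; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  g <- conv_geometry(ly, H, W, C, N)
  dm <- matrix(aperm(dy, c(1, 2, 4, 3)), g$P * N, ly$out_ch)
  ly$gW <- crossprod(ly$cache_col, dm)
  ly$gb <- colSums(dm)
  dcol <- dm %*% t(ly$W)
  dxp <- numeric(g$S * N)
  # for a fixed patch offset, output positions map to distinct input pixels,
  # so each column can be scattered with a plain vectorized add
  for (k in seq_len(ncol(dcol))) {
    ii <- g$bigidx[, k]
    dxp[ii] <- dxp[ii] + dcol[, k]
  }
  dxp <- array(dxp, c(g$Hp, g$Wp, C, N))
  p <- ly$pad
  ly$cache_col <- NULL
  if (p > 0) dxp[(p + 1):(p + H), (p + 1):(p + W), , , drop = FALSE] else dxp
}

nn_relu <- function() {
  ly <- new.env(parent = emptyenv()); ly$type <- "relu"; ly
}

nn_maxpool2 <- function() {
  ly <- new.env(parent = emptyenv()); ly$type <- "maxpool2"; ly
}

maxpool_forward <- function(ly, x, train) {
  d <- dim(x)
  if (d[1] %% 2 || d[2] %% 2) stop("maxpool2 needs even spatial dims, got ",
                                   d[1], "x", d[2])
  ri <- seq(1, d[1], 2); ci <- seq(1, d[2], 2)
  a <- x[ri, ci, , , drop = FALSE];      b <- x[ri + 1, ci, , , drop = FALSE]
  cc <- x[ri, ci + 1, , , drop = FALSE]; e <- x[ri + 1, ci + 1, , , drop = FALSE]
  m <- pmax(a, b, cc, e)
  if (train) ly$cache <- list(a = a, b = b, cc = cc, e = e, m = m, d = d)
  m
}

maxpool_backward <- function(ly, dy) {
  cc <- ly$cache; d <- cc$d
  ma <- cc$a == cc$m
  mb <- (cc$b == cc$m) & !ma
  mc <- (cc$cc == cc$m) & !ma & !mb
  me <- !(ma | mb | mc)
  dx <- array(0, d)
  ri <- seq(1, d[1], 2); ci <- seq(1, d[2], 2)
  dx[ri, ci, , ] <- dy * ma
  dx[ri + 1, ci, , ] <- dy * mb
  dx[ri, ci + 1, , ] <- dy * mc
  dx[ri + 1, ci + 1, , ] <- dy * me
  ly$cache <- NULL
  dx
}

nn_gap <- function() {
  ly <- new.env(parent = emptyenv()); ly$type <- "gap"; ly
}

gap_forward <- function(ly, x, train) {
  d <- dim(x)
  if (train) ly$d <- d
  m <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4]))    # C*N
  t(matrix(m, d[3], d[4]))                              # N x C
}

gap_backward <- function(ly, dy) {
  d <- ly$d
  array(rep(t(dy) / (d[1] * d[2]), each = d[1] * d[2]), d)
}

# Parameter-free per-sample feature standardisation (layer norm without
# learnables). Conditions the pooled feature scale for the recurrent unit,
# standing in for the batch normalisation a full-scale backbone carries.
nn_featnorm <- function() {
  ly <- new.env(parent = emptyenv()); ly$type <- "featnorm"; ly
}

featnorm_forward <- function(ly, x, train) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd_ <- sqrt(rowMeans(xc^2) + 1e-6)
  y <- xc / sd_
  if (train) { ly$y <- y; ly$sd <- sd_ }
  y
}

featnorm_backward <- function(ly, dy) {
  y <- ly$y; sd_ <- ly$sd
  dx <- (dy - rowMeans(dy) - y * rowMeans(dy * y)) / sd_
  ly$y <- NULL; ly$sd <- NULL
  dx
}

nn_linear <- function(in_dim, out_dim) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "linear"
  ly$W <- he_init(in_dim, out_dim, in_dim)
  ly$b <- numeric(out_dim)
  ly
}

linear_forward <- function(ly, x, train) {
  if (train) ly$cache_x <- x
  x %*% ly$W + rep(ly$b, each = nrow(x))
}

linear_backward <- function(ly, dy) {
  ly$gW <- crossprod(ly$cache_x, dy)
  ly$gb <- colSums(dy)
  ly$cache_x <- NULL
  dy %*% t(ly$W)
}

nn_resblock <- function(in_ch, out_ch, stride = 1L) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "resblock"
  ly$conv1 <- nn_conv(in_ch, out_ch, 3L, stride = stride)
  ly$conv2 <- nn_conv(out_ch, out_ch, 3L)
  ly$proj <- if (stride != 1L || in_ch != out_ch)
    nn_conv(in_ch, out_ch, 1L, stride = stride, pad = 0L) else NULL
  ly
}

resblock_forward <- function(ly, x, train) {
  y1 <- conv_forward(ly$conv1, x, train)
  m1 <- y1 > 0
  y1 <- y1 * m1
  y2 <- conv_forward(ly$conv2, y1, train)
  s <- if (is.null(ly$proj)) x else conv_forward(ly$proj, x, train)
  out <- y2 + s
  m2 <- out > 0
  if (train) { ly$m1 <- m1; ly$m2 <- m2 }
  out * m2
}

resblock_backward <- function(ly, dy) {
  dout <- dy * ly$m2
  dy1 <- conv_backward(ly$conv2, dout) * ly$m1
  dx <- conv_backward(ly$conv1, dy1)
  ds <- if (is.null(ly$proj)) dout else conv_backward(ly$proj, dout)
  ly$m1 <- NULL; ly$m2 <- NULL
  dx + ds
}

sigm <- function(x) 1 / (1 + exp(-x))

nn_lstm <- function(input_dim, hidden) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "lstm"
  ly$H <- hidden
  sc <- 1 / sqrt(hidden)
  ly$Wx <- matrix(stats::runif(input_dim * 4 * hidden, -sc, sc), input_dim, 4 * hidden)
  ly$Wh <- matrix(stats::runif(hidden * 4 * hidden, -sc, sc), hidden, 4 * hidden)
  # forget-gate bias 1 (standard); small random biases elsewhere break the
  # odd symmetry of the zero-state cell so variance-type signals in the
  # input sequence are visible to the linear head from the start
  ly$b <- c(stats::runif(hidden, -0.5, 0.5), rep(1, hidden),
            stats::runif(2 * hidden, -0.5, 0.5))
  ly
}

# xs: list of T matrices (N x D); returns the last hidden state (N x H).
lstm_forward <- function(ly, xs, train) {
  H <- ly$H; N <- nrow(xs[[1]])
  h <- matrix(0, N, H); cst <- matrix(0, N, H)
  caches <- vector("list", length(xs))
  ii <- 1:H; ff <- (H + 1):(2 * H); gg <- (2 * H + 1):(3 * H); oo <- (3 * H + 1):(4 * H)
  for (t in seq_along(xs)) {
    z <- xs[[t]] %*% ly$Wx + h %*% ly$Wh + rep(ly$b, each = N)
    i <- sigm(z[, ii, drop = FALSE]); f <- sigm(z[, ff, drop = FALSE])
    g <- tanh(z[, gg, drop = FALSE]); o <- sigm(z[, oo, drop = FALSE])
    c_new <- f * cst + i * g
    tc <- tanh(c_new)
    if (train) caches[[t]] <- list(x = xs[[t]], hprev = h, cprev = cst,
                                   i = i, f = f, g = g, o = o, tc = tc)
    cst <- c_new
    h <- o * tc
  }
  if (train) ly$caches <- caches
  h
}

# dh: gradient at the last hidden state; returns list of per-step dx.
lstm_backward <- function(ly, dh) {
  caches <- ly$caches
  T_ <- length(caches); H <- ly$H
  gWx <- 0 * ly$Wx; gWh <- 0 * ly$Wh; gb <- 0 * ly$b
  dc <- matrix(0, nrow(dh), H)
  dxs <- vector("list", T_)
  for (t in rev(seq_len(T_))) {
    cc <- caches[[t]]
    do <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g; dg <- dc * cc$i; df <- dc * cc$cprev
    dc_prev <- dc * cc$f
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    gWx <- gWx + crossprod(cc$x, dz)
    gWh <- gWh + crossprod(cc$hprev, dz)
    gb <- gb + colSums(dz)
    dxs[[t]] <- dz %*% t(ly$Wx)
    dh <- dz %*% t(ly$Wh)
    dc <- dc_prev
  }
  ly$gWx <- gWx; ly$gWh <- gWh; ly$gb <- gb
  ly$caches <- NULL
  dxs
}

layer_forward <- function(ly, x, train = TRUE) {
  switch(ly$type,
         conv = conv_forward(ly, x, train),
         relu = { if (train) ly$mask <- x > 0; x * (x > 0) },
         maxpool2 = maxpool_forward(ly, x, train),
         gap = gap_forward(ly, x, train),
         featnorm = featnorm_forward(ly, x, train),
         linear = linear_forward(ly, x, train),
         resblock = resblock_forward(ly, x, train),
         stop("unknown layer type ", ly$type))
}

layer_backward <- function(ly, dy) {
  switch(ly$type,
         conv = conv_backward(ly, dy),
         relu = { m <- ly$mask; ly$mask <- NULL; dy * m },
         maxpool2 = maxpool_backward(ly, dy),
         gap = gap_backward(ly, dy),
         featnorm = featnorm_backward(ly, dy),
         linear = linear_backward(ly, dy),
         resblock = resblock_backward(ly, dy),
         stop("unknown layer type ", ly$type))
}

stack_forward <- function(layers, x, train = TRUE) {
  for (ly in layers) x <- layer_forward(ly, x, train)
  x
}

stack_backward <- function(layers, dy) {
  for (ly in rev(layers)) dy <- layer_backward(ly, dy)
  dy
}

# named parameter slots for the optimizer: list of list(env, par, grad)
collect_params <- function(obj) {
  out <- list()
  add <- function(env, par, grad) out[[length(out) + 1]] <<- list(env = env, par = par, grad = grad)
  walk <- function(ly) {
    if (is.list(ly) && !is.environment(ly)) { lapply(ly, walk); return(invisible()) }
    switch(ly$type,
           conv = { add(ly, "W", "gW"); add(ly, "b", "gb") },
           linear = { add(ly, "W", "gW"); add(ly, "b", "gb") },
           lstm = { add(ly, "Wx", "gWx"); add(ly, "Wh", "gWh"); add(ly, "b", "gb") },
           resblock = { walk(ly$conv1); walk(ly$conv2)
                        if (!is.null(ly$proj)) walk(ly$proj) },
           NULL)
    invisible()
  }
  walk(obj)
  out
}

adam_init <- function(params) {
  opt <- new.env(parent = emptyenv())
  opt$m <- lapply(params, function(p) 0 * p$env[[p$par]])
  opt$v <- lapply(params, function(p) 0 * p$env[[p$par]])
  opt$t <- 0L
  opt
}

adam_step <- function(opt, params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (k in seq_along(params)) {
    p <- params[[k]]
    g <- p$env[[p$grad]]
    if (is.null(g)) next
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * g
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * g^2
    p$env[[p$par]] <- p$env[[p$par]] -
      lr * (opt$m[[k]] / bc1) / (sqrt(opt$v[[k]] / bc2) + eps)
  }
  invisible(opt)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy loss; y: integer class indices. Returns loss, dlogits, probs.
softmax_ce <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(n), y)] + eps))
  dl <- p
  dl[cbind(seq_len(n), y)] <- dl[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = dl / n, probs = p)
}
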