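# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's RNG stream. `seed = NULL` evaluates the expression as-is.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed from a base seed and integer tags,
# kept well inside 32-bit range.
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  s <- 0
  for (t in tags) s <- (s * 69069 + as.numeric(t) + 1) %% 2147483629
  as.integer(s)
}

# Pixel-centre coordinate grids for an nr x nc image (1-based row/col).
coord_grid <- function(nr, nc) {
  list(r = matrix(rep(seq_len(nr), nc), nr, nc),
       c = matrix(rep(seq_len(nc), each = nr), nr, nc))
}

disk_mask <- function(nr, nc, center, radius) {
  g <- coord_grid(nr, nc)
  (g$r - center[1])^2 + (g$c - center[2])^2 <= radius^2
}

#' Rigid plate transform
#'
#' A rotation by `theta_deg` about `center` followed by a translation of
#' `(dr, dc)` pixels, in 1-based (row, col) coordinates.
#'
#' @param dr,dc translation in pixels (rows, cols).
#' @param theta_deg rotation in degrees (counter-clockwise in (row,col)).
#' @param center 2-vector, rotation centre.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(dr = 0, dc = 0, theta_deg = 0, center = c(0, 0)) {
  structure(list(dr = dr, dc = dc, theta_deg = theta_deg, center = center),
            class = "rigid_transform")
}

#' Map points through a rigid transform
#'
#' @param tf a [rigid_transform()].
#' @param pts n x 2 matrix of (row, col) points (a 2-vector is accepted).
#' @return n x 2 matrix of transformed points.
#' @export
transform_points <- function(tf, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  th <- tf$theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  centered <- sweep(pts, 2, tf$center)
  out <- centered %*% t(R)
  sweep(out, 2, c(tf$center[1] + tf$dr, tf$center[2] + tf$dc), `+`)
}

invert_transform <- function(tf) {
  th <- -tf$theta_deg * pi / 180
  # inverse maps p to R^-1 (p - t - center) + center
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  structure(list(R = R, tf = tf), class = "rigid_transform_inv")
}

# Bilinear sampling of img at float (row, col) positions; out-of-range
# positions take `fill`.
bilinear_sample <- function(img, r, c, fill) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  ok <- r0 >= 1 & c0 >= 1 & (r0 + 1) <= nr & (c0 + 1) <= nc
  r0k <- pmin(pmax(r0, 1), nr - 1); c0k <- pmin(pmax(c0, 1), nc - 1)
  i00 <- r0k + (c0k - 1) * nr
  v <- (img[i00] * (1 - fr) + img[i00 + 1] * fr) * (1 - fc) +
    (img[i00 + nr] * (1 - fr) + img[i00 + nr + 1] * fr) * fc
  v[!ok] <- fill
  v
}

# Apply a rigid transform to an image: output pixel (r,c) is sampled from the
# input at the inverse-transformed position.
warp_rigid <- function(img, tf, fill = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(fill)) fill <- stats::median(img[c(1:nr, (nc - 1) * nr + 1:nr)])
  if (tf$dr == 0 && tf$dc == 0 && tf$theta_deg == 0) return(img)
  g <- coord_grid(nr, nc)
  th <- -tf$theta_deg * pi / 180
  pr <- g$r - tf$center[1] - tf$dr
  pc <- g$c - tf$center[2] - tf$dc
  sr <- cos(th) * pr - sin(th) * pc + tf$center[1]
  sc <- sin(th) * pr + cos(th) * pc + tf$center[2]
  matrix(bilinear_sample(img, sr, sc, fill), nr, nc)
}

as_image_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}
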