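# Plate image processing: segmentation, zone partition, daily centroid
# tracking, and 80x80 sub-image triplet extraction.

#' Segmentation configuration
#'
#' Dark-foreground segmentation by background difference: the background is
#' estimated with a large-kernel median filter and the difference is
#' thresholded at `threshold`. An optional morphological opening is
#' available for speckly imagery but disabled by default: at 2-4 px body
#' widths an opening fragments worms into multiple blobs, and the minimum
#' blob area already rejects speckle. All values are config-exposed
#' stand-ins (the acquisition pipeline's exact segmentation is not
#' prescribed).
#'
#' @param median_radius half-size of the median background filter (px).
#' @param threshold minimum background-minus-pixel difference for foreground.
#' @param opening_size side of the box opening element (0 disables).
#' @return list of class `segment_config`.
#' @export
segment_config <- function(median_radius = 9L, threshold = 0.15,
                           opening_size = 0L) {
  stopifnot(median_radius >= 1, threshold > 0)
  structure(list(median_radius = as.integer(median_radius),
                 threshold = threshold,
                 opening_size = as.integer(opening_size)),
            class = "segment_config")
}

#' Segment dark foreground (worms, opaque noise) in a plate image
#'
#' @param image numeric matrix with intensities in \[0, 1\].
#' @param geometry optional [plate_geometry()]; when given, the mask is
#'   restricted to the central zone of the plate disk (the wall zone is
#'   handled separately by motion detection).
#' @param config a [segment_config()].
#' @return logical matrix: TRUE on foreground.
#' @export
segment <- function(image, geometry = NULL, config = segment_config()) {
  img <- clamp(as_image_matrix(image), 0, 1)
  bg <- EBImage::medianFilter(EBImage::Image(img), config$median_radius)
  mask <- (as_image_matrix(bg) - img) > config$threshold
  if (config$opening_size > 1) {
    brush <- EBImage::makeBrush(config$opening_size, shape = "box")
    mask <- as_image_matrix(EBImage::opening(EBImage::Image(mask * 1), brush)) > 0.5
  }
  if (!is.null(geometry)) {
    mask <- mask & disk_mask(nrow(img), ncol(img), geometry$center,
                             geometry$central_zone_radius)
  }
  mask
}

#' Partition a plate into central and wall zone masks
#'
#' @param geometry a [plate_geometry()].
#' @param image_size side of the (square) image in px.
#' @return list with logical matrices `central` (disk of
#'   `central_zone_radius`) and `wall` (annulus out to `outer_radius`);
#'   disjoint, union = plate disk.
#' @export
partition_zones <- function(geometry, image_size) {
  plate <- disk_mask(image_size, image_size, geometry$center,
                     geometry$outer_radius)
  central <- disk_mask(image_size, image_size, geometry$center,
                       geometry$central_zone_radius)
  list(central = central, wall = plate & !central)
}

#' Find connected dark blobs in a binary mask
#'
#' 8-connected components with at least `min_area` pixels; 20 px is the
#' minimum area a worm can project at the nominal scale. Components are
#' labelled over foreground pixels via graph connectivity.
#'
#' @param mask logical matrix.
#' @param min_area minimum blob area in px (>= 1).
#' @return list of blobs sorted by area (decreasing); each is a list with
#'   `pixels` (n x 2 matrix of (row, col)), `area`, and `centroid`
#'   (float (row, col), the arithmetic mean of the pixel coordinates).
#' @export
find_blobs <- function(mask, min_area = 20L) {
  stopifnot(min_area >= 1)
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  nr <- nrow(mask)
  pos <- match(idx, idx)  # identity; vertex ids = seq_along(idx)
  rows <- ((idx - 1) %% nr) + 1
  cols <- ((idx - 1) %/% nr) + 1
  edges <- NULL
  for (off in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    nrow2 <- rows + off[1]; ncol2 <- cols + off[2]
    valid <- nrow2 >= 1 & nrow2 <= nr & ncol2 >= 1 & ncol2 <= ncol(mask)
    nidx <- (ncol2 - 1) * nr + nrow2
    j <- match(nidx, idx)
    keep <- valid & !is.na(j)
    if (any(keep)) edges <- rbind(edges, cbind(which(keep), j[keep]))
  }
  memb <- if (is.null(edges)) seq_along(idx) else {
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    igraph::components(g)$membership
  }
  blobs <- lapply(split(seq_along(idx), memb), function(ii) {
    if (length(ii) < min_area) return(NULL)
    px <- cbind(row = rows[ii], col = cols[ii])
    list(pixels = px, area = length(ii),
         centroid = c(mean(px[, 1]), mean(px[, 2])))
  })
  blobs <- Filter(Negate(is.null), blobs)
  blobs[order(vapply(blobs, `[[`, numeric(1), "area"), decreasing = TRUE)]
}

#' Centroids of candidate worms on one assay day
#'
#' Segments the last of the day's 30 frames (the frame in which daily
#' centroids are defined) restricted to the central zone, and returns the
#' centroids of all blobs of at least `min_area` px.
#'
#' @param day_frames list of exactly 30 image matrices.
#' @param geometry a [plate_geometry()].
#' @param min_area minimum blob area (px).
#' @param config a [segment_config()].
#' @return n x 2 matrix of (row, col) centroids (0 rows when none).
#' @export
track_daily_centroids <- function(day_frames, geometry, min_area = 20L,
                                  config = segment_config()) {
  if (length(day_frames) != 30L)
    stop("expected exactly 30 frames per day, got ", length(day_frames))
  mask <- segment(day_frames[[30]], geometry, config)
  blobs <- find_blobs(mask, min_area)
  if (length(blobs) == 0) return(matrix(numeric(0), 0, 2,
                                        dimnames = list(NULL, c("row", "col"))))
  out <- t(vapply(blobs, `[[`, numeric(2), "centroid"))
  colnames(out) <- c("row", "col")
  out
}

crop_pad <- function(img, r0, c0, size) {
  nr <- nrow(img); nc <- ncol(img)
  rows <- (r0 + 1):(r0 + size); cols <- (c0 + 1):(c0 + size)
  rin <- rows >= 1 & rows <= nr; cin <- cols >= 1 & cols <= nc
  out <- matrix(NA_real_, size, size)
  out[rin, cin] <- img[rows[rin], cols[cin]]
  padded <- any(!rin) || any(!cin)
  if (padded) out[is.na(out)] <- stats::median(out, na.rm = TRUE)
  list(crop = out, padded = padded)
}

#' Construct a sub-image triplet
#'
#' Three crops of identical size taken at identical image coordinates from
#' the previous, current, and next day's images, centred on a current-day
#' worm centroid.
#'
#' @param prev,cur,nxt square image matrices of equal size.
#' @param anchor_centroid (row, col) the crops are centred on, in the source
#'   image's coordinates.
#' @param plate_id,day optional identifiers.
#' @param padded logical: TRUE when out-of-bounds regions were padded.
#' @return object of class `sub_image_triplet`.
#' @export
sub_image_triplet <- function(prev, cur, nxt, anchor_centroid,
                              plate_id = NA, day = NA, padded = FALSE) {
  stopifnot(all(dim(prev) == dim(cur)), all(dim(nxt) == dim(cur)),
            nrow(cur) == ncol(cur))
  structure(list(prev = prev, cur = cur, nxt = nxt,
                 anchor_centroid = anchor_centroid,
                 plate_id = plate_id, day = day, padded = padded),
            class = "sub_image_triplet")
}

#' @export
print.sub_image_triplet <- function(x, ...) {
  cat("sub_image_triplet:", nrow(x$cur), "x", ncol(x$cur),
      "crops at (", round(x$anchor_centroid[1], 1), ",",
      round(x$anchor_centroid[2], 1), ")",
      if (x$padded) "[padded]" else "", "\n")
  invisible(x)
}

#' Crop a three-day sub-image triplet around a worm centroid
#'
#' Crops `size` x `size` windows at identical image coordinates from the
#' previous, current, and next day's images -- no alignment is performed; the
#' window is sized so a stationary worm stays inside all three crops despite
#' plate placement shifts (55 px worm + 15 px shift + 10 px margin = 80).
#' Out-of-bounds regions are padded with the local background median.
#'
#' @param prev_img,cur_img,next_img full-plate images (equal size).
#' @param centroid (row, col) of the current-day worm.
#' @param size crop side in px; even, default 80.
#' @param plate_id,day optional identifiers carried on the triplet.
#' @return a [sub_image_triplet()].
#' @export
crop_triplet <- function(prev_img, cur_img, next_img, centroid, size = 80L,
                         plate_id = NA, day = NA) {
  stopifnot(size > 0, size %% 2 == 0)
  if (centroid[1] < 1 || centroid[1] > nrow(cur_img) ||
      centroid[2] < 1 || centroid[2] > ncol(cur_img))
    stop("centroid lies outside the image")
  r0 <- round(centroid[1]) - size %/% 2
  c0 <- round(centroid[2]) - size %/% 2
  p <- crop_pad(prev_img, r0, c0, size)
  ci <- crop_pad(cur_img, r0, c0, size)
  nx <- crop_pad(next_img, r0, c0, size)
  sub_image_triplet(p$crop, ci$crop, nx$crop, anchor_centroid = centroid,
                    plate_id = plate_id, day = day,
                    padded = p$padded || ci$padded || nx$padded)
}
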