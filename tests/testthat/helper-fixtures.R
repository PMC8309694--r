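# Shared fixtures, built in code at test time.

# tiny network configuration used throughout the tests
tiny_net_config <- function(input_size = 32L) {
  net_config(backbone = "small_cnn", feature_dim = 64L, lstm_hidden = 32L,
             input_size = input_size)
}

# an "easy" triplet set: clear pose change for live worms, identical frames
# for dead, no noise blobs, no plate displacement
easy_sim_config <- function(n, seed = 1L, speed = 8) {
  sim_config(n_sequences = n, speed = speed, noise_frac = 0,
             anchor_noise_frac = 0, neighbor_frac = 0,
             displacement_max_px = 0, rotation_max_deg = 0, seed = seed)
}

# a small plate for cascade tests
small_plate_config <- function(speed = 35, days = 4L, seed = 1L, ...) {
  sim_config(image_size_px = 240L, worms_per_plate = 3L, days = days,
             n_noise_blobs = 0L, speed = speed, worm_min_sep = 40,
             seed = seed, ...)
}

# uniform background canvas at central-zone brightness
blank_canvas <- function(n = 120L, value = 0.85) matrix(value, n, n)

# triplet whose three frames are given images (defaults: all equal)
make_triplet <- function(cur, prev = cur, nxt = cur) {
  sub_image_triplet(prev, cur, nxt,
                    anchor_centroid = (dim(cur) + 1) / 2)
}

# read a PNG back as a plain numeric matrix
as_image_matrix_for_test <- function(path) {
  m <- EBImage::readImage(path)
  m <- EBImage::imageData(m)
  if (length(dim(m)) > 2) m <- m[, , 1]
  matrix(as.numeric(m), nrow(m), ncol(m))
}

# render one worm centred in an 80x80 scene
worm_scene <- function(center = c(40.5, 40.5), heading = 0.7, size = 80L,
                       intensity = 0.25, bg = 0.85) {
  canvas <- matrix(bg, size, size)
  p <- worm_pose(center = center, heading = heading, intensity = intensity)
  img <- render_worm(p, canvas)
  attributes(img) <- list(dim = dim(img))
  img
}
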