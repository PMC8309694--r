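# Segmentation, zones, blob detection, centroid tracking, triplet crops.

test_that("segment finds nothing on a blank background", {
  g <- plate_geometry(c(100.5, 100.5), 96)
  bg <- render_plate_background(200, g, seed = 3)
  mask <- segment(bg, g)
  expect_equal(sum(mask), 0)
})

test_that("segment recovers a rendered worm as one blob", {
  g <- plate_geometry(c(100.5, 100.5), 96)
  bg <- render_plate_background(200, g, seed = 3)
  img <- render_worm(worm_pose(center = c(100, 100), intensity = 0.25), bg)
  truth_idx <- attr(img, "stamped")
  attributes(img) <- list(dim = dim(img))
  mask <- segment(img, g)
  blobs <- find_blobs(mask, 20)
  expect_length(blobs, 1)
  expect_gte(blobs[[1]]$area, 100)
  expect_lte(blobs[[1]]$area, 250)
  # overlap with the renderer's stamped-pixel truth
  truth <- matrix(FALSE, 200, 200); truth[truth_idx] <- TRUE
  dice <- 2 * sum(mask & truth) / (sum(mask) + sum(truth))
  expect_gte(dice, 0.8)
  # mask confined to the plate disk
  disk <- wormlifespan:::disk_mask(200, 200, g$center, g$outer_radius)
  expect_true(all(disk[mask]))
})

test_that("partition_zones produces disjoint covering masks", {
  g <- plate_geometry(c(50.5, 50.5), 45, 30)
  z <- partition_zones(g, 100)
  expect_equal(sum(z$central & z$wall), 0)
  disk <- wormlifespan:::disk_mask(100, 100, g$center, g$outer_radius)
  expect_equal(sum(z$central) + sum(z$wall), sum(disk))
  # membership at characteristic radii
  expect_true(z$central[51, 51])
  mid <- round(50.5 + (30 + 45) / 2)
  expect_true(z$wall[mid, 51])
})

test_that("find_blobs filters by area and computes centroids", {
  m <- matrix(FALSE, 40, 40)
  expect_length(find_blobs(m, 20), 0)
  m[10:14, 20:24] <- TRUE            # 5x5 square, area 25
  blobs <- find_blobs(m, 20)
  expect_length(blobs, 1)
  expect_equal(blobs[[1]]$area, 25)
  expect_equal(blobs[[1]]$centroid, c(12, 22))
  m2 <- matrix(FALSE, 40, 40)
  m2[10:13, 20:23] <- TRUE           # 4x4, area 16 < 20
  expect_length(find_blobs(m2, 20), 0)
})

test_that("find_blobs uses 8-connectivity", {
  m <- matrix(FALSE, 10, 10)
  m[cbind(1:6, 1:6)] <- TRUE  # pure diagonal
  expect_length(find_blobs(m, 1), 1)
  blobs <- find_blobs(m, 1)
  expect_equal(blobs[[1]]$area, 6)
})

test_that("track_daily_centroids finds stationary worms in the last frame", {
  cfg <- sim_config(image_size_px = 240L, worms_per_plate = 3L, days = 3L,
                    n_noise_blobs = 0L, speed = 0, displacement_max_px = 0,
                    rotation_max_deg = 0, seed = 9)
  plate <- simulate_plate(cfg)
  frames <- plate_day_frames(plate, 2)
  cents <- track_daily_centroids(frames, plate$geometry)
  expect_equal(nrow(cents), 3)
  truth <- plate$truth[plate$truth$day == 2, ]
  for (k in seq_len(nrow(truth))) {
    err <- min(sqrt((cents[, 1] - truth$row[k])^2 +
                      (cents[, 2] - truth$col[k])^2))
    expect_lte(err, 3)
  }
  expect_error(track_daily_centroids(frames[1:29], plate$geometry), "30")
})

test_that("track_daily_centroids ignores the wall zone and empty plates", {
  g <- plate_geometry(c(80.5, 80.5), 76, 55)
  bg <- render_plate_background(160, g, seed = 2)
  frames <- replicate(30, bg, simplify = FALSE)
  expect_equal(nrow(track_daily_centroids(frames, g)), 0)
  # worm in the wall annulus only (body oriented tangentially)
  wall_img <- render_worm(worm_pose(center = c(80.5, 80.5 + 65),
                                    heading = pi / 2, intensity = 0.2), bg)
  attributes(wall_img) <- list(dim = dim(wall_img))
  frames[[30]] <- wall_img
  expect_equal(nrow(track_daily_centroids(frames, g)), 0)
})

test_that("crop_triplet crops at identical coordinates with padding", {
  img <- matrix(seq(0, 1, length.out = 200 * 200), 200, 200)
  trip <- crop_triplet(img, img, img, centroid = c(100, 100), size = 80)
  expect_equal(dim(trip$cur), c(80, 80))
  expect_equal(trip$cur, img[61:140, 61:140])
  expect_identical(trip$prev, trip$cur)
  expect_false(trip$padded)
  # near-edge crop: a padded band appears
  tripe <- crop_triplet(img, img, img, centroid = c(10, 100), size = 80)
  expect_true(tripe$padded)
  expect_equal(dim(tripe$cur), c(80, 80))
  # padded band width 30: rows 1..30 of the crop are synthetic
  expect_true(all(tripe$cur[1:30, ] == stats::median(tripe$cur[31:80, ])))
  expect_error(crop_triplet(img, img, img, centroid = c(-5, 100)), "outside")
  # idempotence
  expect_identical(crop_triplet(img, img, img, c(100, 100)),
                   crop_triplet(img, img, img, c(100, 100)))
})

test_that("a stationary worm stays inside all three crops", {
  plate <- simulate_plate(sim_config(image_size_px = 240L, worms_per_plate = 1L,
                                     days = 3L, n_noise_blobs = 0L, speed = 0,
                                     seed = 12))
  lasts <- lapply(1:3, function(d) render_plate_frame(plate, d, 30))
  truth <- plate$truth[plate$truth$day == 2, ]
  trip <- crop_triplet(lasts[[1]], lasts[[2]], lasts[[3]],
                       c(truth$row, truth$col), size = 80)
  for (fr in list(trip$prev, trip$cur, trip$nxt)) {
    blobs <- find_blobs(segment(fr), 20)
    expect_gte(length(blobs), 1)
    # the anchored worm sits at the crop centre in every frame, whole
    # (area comparable to a full body), even though the dark wall annulus
    # may intrude at the crop corner
    d <- vapply(blobs, function(b) sqrt(sum((b$centroid - c(40.5, 40.5))^2)),
                numeric(1))
    worm <- blobs[[which.min(d)]]
    expect_lt(min(d), 6)
    expect_gt(worm$area, 80)
  }
})
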