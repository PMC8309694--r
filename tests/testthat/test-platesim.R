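# Plate and triplet simulator.

test_that("render_worm stamps a 55x3 body with the expected area", {
  canvas <- blank_canvas()
  # straight horizontal skeleton on an integer row
  pose <- worm_pose(center = c(60, 60), heading = 0, length_px = 55,
                    width_px = 3, amplitude = 0)
  out <- render_worm(pose, canvas)
  stamped <- attr(out, "stamped")

  # independent brute-force oracle: pixel centres within the anti-aliased
  # half-width of the skeleton polyline
  pts <- pose$skeleton
  hits <- 0L
  for (r in 1:120) for (cl in 1:120) {
    d2 <- Inf
    for (i in seq_len(nrow(pts) - 1)) {
      a <- pts[i, ]; b <- pts[i + 1, ]
      t <- sum((c(r, cl) - a) * (b - a)) / sum((b - a)^2)
      t <- min(max(t, 0), 1)
      q <- a + t * (b - a)
      d2 <- min(d2, sum((c(r, cl) - q)^2))
    }
    if (sqrt(d2) < 3 / 2 + 0.5) hits <- hits + 1L
  }
  expect_equal(length(stamped), hits)
  expect_gte(length(stamped), 120)
  expect_lte(length(stamped), 220)
  # untouched outside the stamped envelope
  expect_equal(out[setdiff(seq_along(canvas), stamped)],
               canvas[setdiff(seq_along(canvas), stamped)])
})

test_that("render_worm rejects degenerate skeletons and is deterministic", {
  canvas <- blank_canvas()
  pose <- worm_pose(center = c(60, 60))
  degenerate <- pose
  degenerate$skeleton <- matrix(rep(c(60, 60), 5), 5, 2, byrow = TRUE)
  expect_error(render_worm(degenerate, canvas), "degenerate")
  a <- render_worm(pose, canvas)
  b <- render_worm(pose, canvas)
  expect_identical(a, b)
})

test_that("render_worm flags worms clipped at the canvas boundary", {
  canvas <- blank_canvas(60)
  pose <- worm_pose(center = c(5, 5), heading = pi / 4)
  out <- render_worm(pose, canvas)
  expect_true(attr(out, "clipped"))
})

test_that("perturb_pose hits the requested displacement and keeps arc length", {
  pose <- worm_pose(center = c(100, 100), heading = 1.2)
  expect_identical(perturb_pose(pose, 0), pose)
  for (i in 1:20) {
    p2 <- perturb_pose(pose, 2, seed = i)
    disp <- mean(sqrt(rowSums((p2$skeleton - pose$skeleton)^2)))
    expect_gte(disp, 1.6)
    expect_lte(disp, 2.4)
    arc0 <- sum(sqrt(rowSums(diff(pose$skeleton)^2)))
    arc2 <- sum(sqrt(rowSums(diff(p2$skeleton)^2)))
    expect_lt(abs(arc2 - arc0) / arc0, 0.1)
  }
  expect_identical(perturb_pose(pose, 5, seed = 9),
                   perturb_pose(pose, 5, seed = 9))
})

test_that("apply_plate_displacement bounds the transform and maps truth", {
  img <- blank_canvas(80)
  res0 <- apply_plate_displacement(img, 0, 0, seed = 1)
  expect_identical(res0$image, img)
  # empirical bound over many draws
  mags <- vapply(1:1000, function(i) {
    tf <- apply_plate_displacement(img, 15, 2, seed = i)$transform
    sqrt(tf$dr^2 + tf$dc^2)
  }, numeric(1))
  expect_lte(max(mags), 15)
  expect_gt(max(mags), 12)  # the bound is actually approached
  # a rendered worm's centroid, mapped through the transform, lands on the
  # worm body in the transformed image
  scene <- worm_scene()
  res <- apply_plate_displacement(scene, 10, 2, seed = 42)
  ctr <- transform_points(res$transform, c(40.5, 40.5))
  mask <- segment(res$image)
  blobs <- find_blobs(mask, 20)
  expect_length(blobs, 1)
  expect_lt(sqrt(sum((blobs[[1]]$centroid - ctr)^2)), 3)
})

test_that("generate_dataset balances classes exactly and is reproducible", {
  cfg <- easy_sim_config(24, seed = 5)
  ds <- generate_dataset(cfg)
  labs <- vapply(ds, `[[`, character(1), "label")
  expect_equal(sum(labs == "alive"), 12L)
  expect_equal(sum(labs == "dead"), 12L)
  ds2 <- generate_dataset(easy_sim_config(24, seed = 5))
  expect_identical(ds, ds2)
  expect_false(identical(ds, generate_dataset(easy_sim_config(24, seed = 6))))
})

test_that("generated live triplets move, dead triplets are static", {
  ds <- generate_dataset(easy_sim_config(30, seed = 8))
  for (it in ds) {
    resid <- mean(abs(it$triplet$prev - it$triplet$cur))
    if (it$label == "dead") {
      # identical poses: residual is sensor noise only
      expect_lt(resid, 0.01)
      expect_identical(it$truth$prev_pose, it$truth$cur_pose)
    } else {
      expect_gt(resid, 0.01)
    }
    # the next day's pose always equals the current day's
    expect_identical(it$truth$next_pose, it$truth$cur_pose)
  }
})

test_that("dead triplets are static up to the recorded plate transform", {
  cfg <- sim_config(n_sequences = 20, speed = 8, noise_frac = 0,
                    anchor_noise_frac = 0, neighbor_frac = 0,
                    displacement_max_px = 10, rotation_max_deg = 1, seed = 3)
  ds <- generate_dataset(cfg)
  for (it in ds[vapply(ds, `[[`, character(1), "label") == "dead"]) {
    # align prev back to cur through the inverse of the applied transform
    tf <- it$truth$prev_transform
    nr <- nrow(it$triplet$prev)
    g <- wormlifespan:::coord_grid(nr, nr)
    pos <- transform_points(tf, cbind(as.vector(g$r), as.vector(g$c)))
    aligned <- matrix(wormlifespan:::bilinear_sample(it$triplet$prev,
                                                     pos[, 1], pos[, 2], NA),
                      nr, nr)
    interior <- !is.na(aligned)
    interior[c(1:8, (nr - 7):nr), ] <- FALSE
    interior[, c(1:8, (nr - 7):nr)] <- FALSE
    resid <- mean(abs(aligned[interior] - it$triplet$cur[interior]))
    expect_lt(resid, 0.02)
  }
})

test_that("replicate_dead_from_live copies the current frame three times", {
  scene <- worm_scene()
  trip <- make_triplet(scene)
  rep0 <- replicate_dead_from_live(trip, seed = 1, max_shift_px = 0,
                                   max_rot_deg = 0)
  expect_identical(rep0$triplet$prev, rep0$triplet$cur)
  expect_identical(rep0$triplet$nxt, rep0$triplet$cur)
  expect_equal(rep0$label, "dead")
  expect_equal(rep0$provenance, "replicated")
  # a zero-transform replicated sequence is stationary: stage 1 must route
  # it to the network
  v <- stage1_classify(rep0$triplet)
  expect_equal(v$verdict, "UNDETERMINED")
  # with jitter, frames differ but only by a rigid transform
  repj <- replicate_dead_from_live(trip, seed = 2)
  expect_false(identical(repj$triplet$prev, repj$triplet$cur))
})

test_that("simulated plates respect geometry and truth invariants", {
  plate <- simulate_plate(small_plate_config(seed = 2))
  expect_s3_class(plate, "plate_sequence")
  # all truth centroids inside the plate disk
  d <- sqrt((plate$truth$row - plate$geometry$center[1])^2 +
              (plate$truth$col - plate$geometry$center[2])^2)
  expect_true(all(d <= plate$geometry$outer_radius))
  # dead worms keep an identical pose across days
  for (w in plate$worms) {
    dead_days <- which(seq_len(plate$days) >= w$death_day)
    if (length(dead_days) > 1) {
      for (d2 in dead_days[-1])
        expect_identical(w$poses[[d2]], w$poses[[dead_days[1]]])
    }
  }
  # frames render deterministically
  expect_identical(render_plate_frame(plate, 1, 5),
                   render_plate_frame(plate, 1, 5))
  expect_equal(length(plate_day_frames(plate, 1)), 30L)
})

test_that("truth_curve counts survivors per day", {
  plate <- simulate_plate(small_plate_config(seed = 4))
  tc <- truth_curve(plate)
  expect_equal(tc$initial_live, 3)
  manual <- vapply(seq_len(plate$days), function(d)
    sum(vapply(plate$worms, function(w) d < w$death_day, logical(1))),
    integer(1))
  expect_equal(tc$counts, as.numeric(manual))
  expect_true(all(diff(tc$counts) <= 0))
})

test_that("plate sequences round-trip through PNG output", {
  cfg <- sim_config(image_size_px = 160L, worms_per_plate = 2L, days = 3L,
                    frames_per_day = 2L, n_noise_blobs = 0L, seed = 6)
  plate <- simulate_plate(cfg)
  dir <- withr::local_tempdir()
  pdir <- write_plate_sequence(plate, dir)
  expect_true(file.exists(file.path(pdir, "truth.csv")))
  f <- file.path(pdir, "day_01", "frame_01.png")
  expect_true(file.exists(f))
  img <- as_image_matrix_for_test(f)
  orig <- render_plate_frame(plate, 1, 1)
  expect_equal(dim(img), dim(orig))
  expect_lt(mean(abs(img - orig)), 0.005)  # 8-bit quantisation
})
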