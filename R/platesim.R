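# Synthetic plate simulator: renders labelled C. elegans plate image
# sequences and classifier-ready sub-image triplets with per-worm truth.

#' Simulator configuration
#'
#' Study conditions for the synthetic data generator. Defaults describe the
#' acquisition geometry the pipeline targets: 55 x 3 px worms on a bright
#' central agar zone surrounded by a darker wall annulus, 30 frames per plate
#' per day, inter-day plate placement shifts of at most 15 px and small
#' rotations.
#'
#' @param n_sequences number of sub-image triplets [generate_dataset()] emits.
#' @param worms_per_plate worms seeded per simulated plate.
#' @param worm_min_sep minimum initial distance between worm centroids (px);
#'   keeps the seeded density comparable to a real plate so 80 px crops
#'   rarely contain bystander worms.
#' @param speed mean skeleton-point displacement between consecutive daily
#'   poses of a live worm, in pixels per day.
#' @param n_noise_blobs static opaque blobs stamped per plate.
#' @param noise_area_range min/max area (px) of a noise blob.
#' @param displacement_max_px bound on the rigid plate translation applied
#'   when a plate is (re)placed in the rig; 15 px is the measured maximum.
#' @param rotation_max_deg bound on the plate rotation (degrees).
#' @param image_size_px side of the square plate image; the acquisition rig
#'   captures 1944 px, desk-scale simulations use smaller plates.
#' @param central_zone_radius_frac central (homogeneously lit) zone radius as
#'   a fraction of the plate's outer radius.
#' @param days assay days simulated per plate.
#' @param death_day_range inclusive integer range worm death days are drawn
#'   from (uniform); a worm is alive on days strictly before its death day,
#'   and death days beyond `days` mean the worm outlives the assay window.
#'   `NULL` uses `c(3, days + 4)`, spreading deaths across the assay.
#' @param frames_per_day frames captured per plate per day (1 fps).
#' @param noise_frac fraction of generated triplets that receive a static
#'   noise blob.
#' @param anchor_noise_frac fraction of dead triplets whose anchored object
#'   is a static noise blob instead of a worm (the segmentation-error cases
#'   the rule stage forwards to the network; counting them dead is the safe
#'   outcome).
#' @param neighbor_frac fraction of triplets that also contain a bystander
#'   worm near the crop edge, usually moving; teaches the classifier that
#'   off-centre motion says nothing about the anchored worm.
#' @param speed_jitter per-sample multiplicative range on `speed` in
#'   [generate_dataset()] (diversifies training motion magnitudes).
#' @param texture_amp,texture_scale amplitude (intensity sd) and spatial
#'   scale (px) of the static low-frequency agar/illumination texture; the
#'   texture is a plate property and moves with the plate, making relative
#'   worm motion observable.
#' @param worm_length_px,worm_width_range nominal worm scale in pixels.
#' @param worm_intensity_range worm body intensity (darker than the ~0.85
#'   background).
#' @param balanced emit exactly equal numbers of alive and dead triplets.
#' @param seed integer seed; every simulator draw derives from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_sequences = 22440L,
                       worms_per_plate = 10L,
                       worm_min_sep = 60,
                       speed = 30,
                       n_noise_blobs = 4L,
                       noise_area_range = c(30, 200),
                       displacement_max_px = 15,
                       rotation_max_deg = 2,
                       image_size_px = 1944L,
                       central_zone_radius_frac = 0.72,
                       days = 12L,
                       death_day_range = NULL,
                       frames_per_day = 30L,
                       noise_frac = 0.3,
                       anchor_noise_frac = 0.1,
                       neighbor_frac = 0.3,
                       speed_jitter = c(0.8, 1.2),
                       texture_amp = 0.035, texture_scale = 6,
                       worm_length_px = 55,
                       worm_width_range = c(2, 4),
                       worm_intensity_range = c(0.1, 0.35),
                       balanced = TRUE,
                       seed = 1L) {
  stopifnot(n_sequences >= 1, worms_per_plate >= 1, speed >= 0,
            displacement_max_px >= 0, rotation_max_deg >= 0,
            image_size_px >= 100, central_zone_radius_frac > 0,
            central_zone_radius_frac < 1, days >= 1, frames_per_day >= 1,
            noise_area_range[2] > noise_area_range[1],
            worm_width_range[2] >= worm_width_range[1])
  structure(as.list(environment()), class = "sim_config")
}

#' Construct a worm pose
#'
#' A pose is a smooth sinusoidal polyline skeleton with a body width and
#' intensity; the sinusoid is the locomotion signature used when labelling
#' worms in plate images. Arc length is normalised to `length_px`.
#'
#' @param center 2-vector (row, col): skeleton centroid position.
#' @param heading direction of the body axis, radians.
#' @param length_px body arc length in pixels (<= 60).
#' @param width_px body width in pixels (>= 1).
#' @param intensity body intensity in \[0, 1\] (darker than background).
#' @param amplitude,periods,phase sinusoid shape parameters.
#' @param n_points skeleton sample points (>= 5).
#' @return object of class `worm_pose` with fields `skeleton` (n x 2 matrix of
#'   (row, col) points), `width_px`, `intensity`.
#' @export
worm_pose <- function(center, heading = 0, length_px = 55, width_px = 3,
                      intensity = 0.25, amplitude = 4, periods = 1.5,
                      phase = 0, n_points = 13L) {
  stopifnot(n_points >= 5, length_px <= 60, length_px > 0, width_px >= 1)
  s <- seq(0, 1, length.out = n_points)
  x <- s * length_px
  y <- amplitude * sin(2 * pi * periods * s + phase)
  # normalise arc length to length_px
  arc <- sum(sqrt(diff(x)^2 + diff(y)^2))
  x <- x * length_px / arc; y <- y * length_px / arc
  rot <- matrix(c(cos(heading), sin(heading), -sin(heading), cos(heading)), 2, 2)
  pts <- cbind(y, x) %*% t(rot)        # (row, col)
  pts <- sweep(pts, 2, colMeans(pts))
  pts <- sweep(pts, 2, center, `+`)
  structure(list(skeleton = pts, width_px = width_px, intensity = intensity),
            class = "worm_pose")
}

pose_arc_length <- function(pose) {
  d <- diff(pose$skeleton)
  sum(sqrt(rowSums(d^2)))
}

pose_centroid <- function(pose) colMeans(pose$skeleton)

# Distance from each point (r, c) to a polyline (minimum over segments).
dist_to_polyline <- function(r, c, pts) {
  d2 <- rep(Inf, length(r))
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((r - a[1]) * ab[1] + (c - a[2]) * ab[2]) / max(len2, 1e-12)
    t <- clamp(t, 0, 1)
    d2 <- pmin(d2, (r - (a[1] + t * ab[1]))^2 + (c - (a[2] + t * ab[2]))^2)
  }
  sqrt(d2)
}

#' Render a worm pose onto a canvas
#'
#' Stamps a smooth dark curve of the pose's width along its skeleton with
#' anti-aliased edges; pixels outside the dilated skeleton envelope are left
#' untouched. Rendering is deterministic.
#'
#' @param pose a [worm_pose()].
#' @param canvas numeric image matrix with background brighter than
#'   `pose$intensity`.
#' @param position optional 2-vector; if given, the skeleton centroid is
#'   translated there before stamping.
#' @return the canvas with the worm stamped; attributes `stamped` (linear
#'   indices of altered pixels) and `clipped` (TRUE when the skeleton exits
#'   the canvas and the body was clipped at the boundary).
#' @export
render_worm <- function(pose, canvas, position = NULL) {
  stopifnot(inherits(pose, "worm_pose"))
  pts <- pose$skeleton
  if (nrow(pts) < 2 || pose_arc_length(pose) <= 0)
    stop("degenerate pose: skeleton has no extent")
  if (!is.null(position))
    pts <- sweep(pts, 2, position - pose_centroid(pose), `+`)
  nr <- nrow(canvas); nc <- ncol(canvas)
  half <- pose$width_px / 2 + 0.5
  clipped <- any(pts[, 1] < 1 | pts[, 1] > nr | pts[, 2] < 1 | pts[, 2] > nc)
  r0 <- max(1L, floor(min(pts[, 1]) - half - 1)); r1 <- min(nr, ceiling(max(pts[, 1]) + half + 1))
  c0 <- max(1L, floor(min(pts[, 2]) - half - 1)); c1 <- min(nc, ceiling(max(pts[, 2]) + half + 1))
  if (r0 > r1 || c0 > c1) {
    attr(canvas, "stamped") <- integer(0); attr(canvas, "clipped") <- TRUE
    return(canvas)
  }
  rows <- r0:r1; cols <- c0:c1
  g <- coord_grid(length(rows), length(cols))
  rr <- g$r + r0 - 1; cc <- g$c + c0 - 1
  d <- dist_to_polyline(as.vector(rr), as.vector(cc), pts)
  alpha <- clamp(pose$width_px / 2 + 0.5 - d, 0, 1)
  idx <- which(alpha > 0)
  lin <- (as.vector(cc) - 1) * nr + as.vector(rr)
  sel <- lin[idx]
  canvas[sel] <- (1 - alpha[idx]) * canvas[sel] + alpha[idx] * pose$intensity
  attr(canvas, "stamped") <- sel
  attr(canvas, "clipped") <- clipped
  canvas
}

#' Perturb a worm pose by a given motion magnitude
#'
#' Produces the next day's pose: a seeded random rigid drift (translation and
#' small body rotation) plus a smooth bending perturbation, rescaled so the
#' mean skeleton-point displacement equals `speed` (within a few percent) and
#' the arc length is preserved.
#'
#' @param pose a [worm_pose()].
#' @param speed target mean per-point displacement in px; `0` returns the
#'   pose unchanged.
#' @param seed integer seed for the draw (`NULL` uses the current RNG).
#' @return a new `worm_pose`.
#' @export
perturb_pose <- function(pose, speed, seed = NULL) {
  stopifnot(speed >= 0)
  if (speed == 0) return(pose)
  with_seed(seed, {
    pts <- pose$skeleton
    n <- nrow(pts)
    L <- pose_arc_length(pose)
    seg_len <- sqrt(rowSums(diff(pts)^2))
    ctr <- pose_centroid(pose)
    # the day-scale move combines translation (dominant, so the centroid
    # displacement tracks `speed` and the move-out rule fires for fast
    # worms), re-orientation about the centroid (worms turn constantly;
    # this is the posture cue that survives plate shifts), and a
    # perpendicular bend of the body
    s <- seq(0, 1, length.out = n)
    wig <- sin(2 * pi * s + stats::runif(1, 0, 2 * pi)) *
      min(0.3 * speed, 4)
    d <- diff(pts)
    tang <- rbind(d, d[n - 1, , drop = FALSE])
    tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-9)
    normal <- cbind(-tang[, 2], tang[, 1])
    theta <- stats::runif(1, -1, 1) * clamp(0.045 * speed, 0.03, 0.5)
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    ang <- stats::runif(1, 0, 2 * pi)
    trans <- speed * c(sin(ang), cos(ang))
    cand <- sweep(sweep(pts, 2, ctr) %*% t(R), 2, ctr + trans, `+`) +
      normal * wig
    for (it in 1:4) {
      disp <- cand - pts
      m <- mean(sqrt(rowSums(disp^2)))
      cand <- pts + disp * (speed / max(m, 1e-9))
      # restore original segment lengths along the new directions
      dirs <- diff(cand)
      dirs <- dirs / pmax(sqrt(rowSums(dirs^2)), 1e-9)
      rebuilt <- matrix(0, n, 2)
      rebuilt[1, ] <- cand[1, ]
      for (i in 2:n) rebuilt[i, ] <- rebuilt[i - 1, ] + dirs[i - 1, ] * seg_len[i - 1]
      cand <- rebuilt
    }
    out <- pose
    out$skeleton <- cand
    out
  })
}

#' Apply a random rigid plate displacement to an image
#'
#' Emulates the shift and small rotation a plate undergoes when placed in the
#' acquisition rig. The translation magnitude is uniform in
#' \[0, `max_shift_px`\] with uniform direction; the rotation is uniform in
#' +/- `max_rot_deg` about the plate centre. The applied transform is
#' returned so truth centroids can be mapped through it.
#'
#' @param image numeric image matrix.
#' @param max_shift_px,max_rot_deg transform bounds.
#' @param seed integer seed (`NULL` uses the current RNG).
#' @param center rotation centre; defaults to the image centre.
#' @return list with `image` (warped) and `transform` (a [rigid_transform()]).
#' @export
apply_plate_displacement <- function(image, max_shift_px = 15,
                                     max_rot_deg = 2, seed = NULL,
                                     center = NULL) {
  stopifnot(max_shift_px >= 0, max_rot_deg >= 0)
  if (is.null(center)) center <- (dim(image) + 1) / 2
  tf <- with_seed(seed, {
    mag <- stats::runif(1, 0, max_shift_px)
    ang <- stats::runif(1, 0, 2 * pi)
    rigid_transform(dr = mag * sin(ang), dc = mag * cos(ang),
                    theta_deg = stats::runif(1, -1, 1) * max_rot_deg,
                    center = center)
  })
  list(image = warp_rigid(image, tf), transform = tf)
}

# Static low-frequency texture field (agar granularity, uneven backlight):
# Gaussian-smoothed white noise rescaled to the requested amplitude.
smooth_texture <- function(nr, nc, amp, scale, seed) {
  if (amp <= 0) return(matrix(0, nr, nc))
  with_seed(seed, {
    z <- matrix(stats::rnorm(nr * nc), nr, nc)
    z <- as_image_matrix(EBImage::gblur(EBImage::Image(z), sigma = scale))
    z * (amp / stats::sd(z))
  })
}

# ---- plate-level simulation -------------------------------------------------

render_noise_blob <- function(canvas, center, area, intensity, seed) {
  with_seed(seed, {
    a <- sqrt(area / pi) * stats::runif(1, 0.7, 1.4)
    b <- area / pi / a
    th <- stats::runif(1, 0, pi)
    nr <- nrow(canvas); nc <- ncol(canvas)
    half <- ceiling(max(a, b)) + 2
    rows <- max(1, floor(center[1] - half)):min(nr, ceiling(center[1] + half))
    cols <- max(1, floor(center[2] - half)):min(nc, ceiling(center[2] + half))
    g <- coord_grid(length(rows), length(cols))
    rr <- g$r + rows[1] - 1; cc <- g$c + cols[1] - 1
    u <- (rr - center[1]) * cos(th) + (cc - center[2]) * sin(th)
    v <- -(rr - center[1]) * sin(th) + (cc - center[2]) * cos(th)
    # irregular edge via angular ripple
    ripple <- 1 + 0.25 * sin(3 * atan2(v, u) + stats::runif(1, 0, 2 * pi))
    d <- sqrt((u / a)^2 + (v / b)^2) / ripple
    alpha <- clamp((1.15 - d) / 0.3, 0, 1)
    lin <- (as.vector(cc) - 1) * nr + as.vector(rr)
    sel <- which(alpha > 0)
    canvas[lin[sel]] <- (1 - alpha[sel]) * canvas[lin[sel]] +
      alpha[sel] * intensity
    canvas
  })
}

#' Plate geometry
#'
#' @param center 2-vector (row, col) of the plate centre.
#' @param outer_radius plate disk radius in px.
#' @param central_zone_radius radius of the homogeneously lit central zone.
#' @return object of class `plate_geometry`.
#' @export
plate_geometry <- function(center, outer_radius,
                           central_zone_radius = 0.72 * outer_radius) {
  stopifnot(central_zone_radius > 0, central_zone_radius < outer_radius)
  structure(list(center = center, outer_radius = outer_radius,
                 central_zone_radius = central_zone_radius),
            class = "plate_geometry")
}

#' Render a synthetic empty-plate background
#'
#' Bright uniform central disk (~0.85) with a mild radial vignette, darker
#' wall annulus (~0.35) crossed by bright illumination ring arcs, dark
#' exterior. Deterministic given the seed.
#'
#' @param n image side in px.
#' @param geometry a [plate_geometry()].
#' @param seed integer seed for the arc layout.
#' @return numeric n x n matrix in \[0, 1\].
#' @export
render_plate_background <- function(n, geometry, seed = 1L) {
  with_seed(seed, {
    g <- coord_grid(n, n)
    r <- sqrt((g$r - geometry$center[1])^2 + (g$c - geometry$center[2])^2)
    img <- matrix(0.06, n, n)
    wall <- r <= geometry$outer_radius & r > geometry$central_zone_radius
    img[wall] <- 0.35
    central <- r <= geometry$central_zone_radius
    img[central] <- 0.85 * (1 - 0.05 * (r[central] / geometry$central_zone_radius)^2)
    for (k in 1:3) {
      ring_r <- stats::runif(1, geometry$central_zone_radius + 4,
                             geometry$outer_radius - 4)
      width <- stats::runif(1, 2, 5)
      a0 <- stats::runif(1, 0, 2 * pi); a1 <- a0 + stats::runif(1, 1, 4)
      ang <- atan2(g$r - geometry$center[1], g$c - geometry$center[2]) %% (2 * pi)
      in_arc <- ((ang - a0) %% (2 * pi)) < (a1 - a0)
      prof <- exp(-((r - ring_r)^2) / (2 * width^2)) * 0.4
      sel <- wall & in_arc
      img[sel] <- clamp(img[sel] + prof[sel], 0, 1)
    }
    img
  })
}

place_worm_centers <- function(n_worms, geometry, seed, min_sep = 40,
                               margin_frac = 0.75, max_tries = 200L) {
  with_seed(seed, {
    centers <- matrix(NA_real_, n_worms, 2)
    rmax <- geometry$central_zone_radius * margin_frac
    for (w in seq_len(n_worms)) {
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        rad <- rmax * sqrt(stats::runif(1))
        ang <- stats::runif(1, 0, 2 * pi)
        p <- geometry$center + rad * c(sin(ang), cos(ang))
        if (w == 1 || all(sqrt(rowSums(sweep(centers[seq_len(w - 1), , drop = FALSE],
                                             2, p)^2)) >= min_sep)) {
          centers[w, ] <- p; ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place ", n_worms,
                    " worms on the plate: too crowded after bounded retries")
    }
    centers
  })
}

#' Simulate one labelled plate sequence
#'
#' Seeds `worms_per_plate` worms in the central zone, draws each worm's death
#' day, evolves daily poses by [perturb_pose()] with a senescence slowdown
#' (worms move at `speed` px/day in mid life and decelerate over their last
#' days), freezes the pose at death, and draws one rigid placement transform
#' per day. Frames are rendered lazily by [render_plate_frame()].
#'
#' @param config a [sim_config()].
#' @param plate_id identifier stored in truth records.
#' @param seed integer; defaults to `config$seed`.
#' @return object of class `plate_sequence` with fields `geometry`, `days`,
#'   `worms` (per-worm death day and per-day poses), `transforms`,
#'   `background`, and `truth` (data.frame: plate, day, worm_id, row, col,
#'   state).
#' @export
simulate_plate <- function(config, plate_id = 1L, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  n <- config$image_size_px
  center <- c((n + 1) / 2, (n + 1) / 2)
  geometry <- plate_geometry(center, outer_radius = 0.48 * n,
                             central_zone_radius =
                               config$central_zone_radius_frac * 0.48 * n)
  background <- render_plate_background(n, geometry,
                                        seed = derive_seed(seed, plate_id, 1))
  background <- clamp(background +
                        smooth_texture(n, n, config$texture_amp,
                                       config$texture_scale,
                                       derive_seed(seed, plate_id, 10)), 0, 1)
  # static opaque noise blobs, part of the plate itself
  noise <- list()
  if (config$n_noise_blobs > 0) {
    noise <- with_seed(derive_seed(seed, plate_id, 2), {
      lapply(seq_len(config$n_noise_blobs), function(i) {
        rad <- geometry$central_zone_radius * sqrt(stats::runif(1))
        ang <- stats::runif(1, 0, 2 * pi)
        list(center = geometry$center + rad * c(sin(ang), cos(ang)),
             area = stats::runif(1, config$noise_area_range[1],
                                 config$noise_area_range[2]),
             intensity = stats::runif(1, 0.15, 0.3))
      })
    })
    for (i in seq_along(noise))
      background <- render_noise_blob(background, noise[[i]]$center,
                                      noise[[i]]$area, noise[[i]]$intensity,
                                      seed = derive_seed(seed, plate_id, 2, i))
  }
  centers <- place_worm_centers(config$worms_per_plate, geometry,
                                seed = derive_seed(seed, plate_id, 3),
                                min_sep = config$worm_min_sep)
  worms <- with_seed(derive_seed(seed, plate_id, 4), {
    lapply(seq_len(config$worms_per_plate), function(w) {
      pose <- worm_pose(center = centers[w, ],
                        heading = stats::runif(1, 0, 2 * pi),
                        length_px = stats::runif(1, 45, 58),
                        width_px = stats::runif(1, config$worm_width_range[1],
                                                config$worm_width_range[2]),
                        intensity = stats::runif(1, config$worm_intensity_range[1],
                                                 config$worm_intensity_range[2]),
                        amplitude = stats::runif(1, 2.5, 5),
                        periods = stats::runif(1, 1, 2),
                        phase = stats::runif(1, 0, 2 * pi))
      # death day: worm is alive on days < death_day; > days means survivor
      rng <- config$death_day_range %||% c(3L, config$days + 4L)
      span <- seq(as.integer(rng[1]), as.integer(rng[2]))
      death <- span[sample.int(length(span), 1)]
      list(id = w, death_day = death, pose0 = pose)
    })
  })
  rmax <- geometry$central_zone_radius * 0.85
  for (w in seq_along(worms)) {
    poses <- vector("list", config$days)
    prev <- worms[[w]]$pose0
    for (d in seq_len(config$days)) {
      if (d >= worms[[w]]$death_day) {
        poses[[d]] <- prev        # frozen at death
      } else {
        slow <- clamp((worms[[w]]$death_day - d) / 5, 0.1, 1)
        sp <- config$speed * slow
        cand <- prev
        for (t in 1:10) {
          cand <- perturb_pose(prev, sp, seed = derive_seed(seed, plate_id, 5, w, d, t))
          if (sqrt(sum((pose_centroid(cand) - geometry$center)^2)) <= rmax) break
        }
        poses[[d]] <- cand
        prev <- cand
      }
    }
    worms[[w]]$poses <- poses
  }
  transforms <- lapply(seq_len(config$days), function(d) {
    if (d == 1) return(rigid_transform(center = geometry$center))
    with_seed(derive_seed(seed, plate_id, 6, d), {
      mag <- stats::runif(1, 0, config$displacement_max_px / 2)
      ang <- stats::runif(1, 0, 2 * pi)
      rigid_transform(dr = mag * sin(ang), dc = mag * cos(ang),
                      theta_deg = stats::runif(1, -1, 1) * config$rotation_max_deg / 2,
                      center = geometry$center)
    })
  })
  truth <- do.call(rbind, lapply(seq_len(config$days), function(d) {
    do.call(rbind, lapply(worms, function(wm) {
      ctr <- transform_points(transforms[[d]], pose_centroid(wm$poses[[d]]))
      data.frame(plate = plate_id, day = d, worm_id = wm$id,
                 row = ctr[1], col = ctr[2],
                 state = if (d >= wm$death_day) "dead" else "alive",
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(config = config, plate_id = plate_id, seed = seed,
                 geometry = geometry, background = background, noise = noise,
                 worms = worms, transforms = transforms, days = config$days,
                 truth = truth),
            class = "plate_sequence")
}

#' @export
print.plate_sequence <- function(x, ...) {
  cat("plate_sequence: plate", x$plate_id, "-", length(x$worms), "worms,",
      x$days, "days,", x$config$frames_per_day, "frames/day,",
      nrow(x$background), "px\n")
  invisible(x)
}

# within-day skeleton for worm w on day d at frame f (pre-transform):
# live worms interpolate from yesterday's pose to today's, dead are static.
worm_frame_pose <- function(plate, w, d, f) {
  wm <- plate$worms[[w]]
  cur <- wm$poses[[d]]
  if (d >= wm$death_day) return(cur)
  prev <- if (d == 1) wm$pose0 else wm$poses[[d - 1]]
  a <- f / plate$config$frames_per_day
  out <- cur
  out$skeleton <- (1 - a) * prev$skeleton + a * cur$skeleton
  out
}

#' Render one frame of a simulated plate
#'
#' Deterministic: the same (day, frame) always renders the same image. Live
#' worms move within the day (poses interpolate from the previous day's pose
#' to the current day's, reaching it at the last frame); dead worms are
#' static; the whole image then receives the day's placement transform plus
#' faint per-frame sensor noise.
#'
#' @param plate a [simulate_plate()] result.
#' @param day,frame indices (frame in 1..frames_per_day).
#' @return numeric image matrix.
#' @export
render_plate_frame <- function(plate, day, frame) {
  stopifnot(day >= 1, day <= plate$days,
            frame >= 1, frame <= plate$config$frames_per_day)
  img <- plate$background
  for (w in seq_along(plate$worms))
    img <- render_worm(worm_frame_pose(plate, w, day, frame), img)
  attributes(img) <- list(dim = dim(img))
  img <- warp_rigid(img, plate$transforms[[day]], fill = 0.06)
  ns <- with_seed(derive_seed(plate$seed, plate$plate_id, 7, day, frame),
                  stats::rnorm(length(img), 0, 0.004))
  clamp(img + ns, 0, 1)
}

#' All frames of one plate-day
#' @param plate a `plate_sequence`; @param day day index.
#' @return list of `frames_per_day` image matrices.
#' @export
plate_day_frames <- function(plate, day) {
  lapply(seq_len(plate$config$frames_per_day),
         function(f) render_plate_frame(plate, day, f))
}

#' Ground-truth survival curve of a simulated plate
#' @param plate a `plate_sequence`.
#' @return a [build_curve()] survival curve of per-day live counts.
#' @export
truth_curve <- function(plate) {
  counts <- vapply(seq_len(plate$days), function(d)
    sum(vapply(plate$worms, function(w) d < w$death_day, logical(1))),
    integer(1))
  build_curve(counts, initial_live = length(plate$worms),
              plate_id = plate$plate_id)
}

# ---- triplet-level simulation ----------------------------------------------

render_triplet_scene <- function(poses, size, base, grad, noise_blob, tex) {
  g <- coord_grid(size, size)
  img <- base + grad[1] * (g$r - size / 2) / size + grad[2] * (g$c - size / 2) / size
  img <- img + tex
  if (!is.null(noise_blob))
    img <- render_noise_blob(img, noise_blob$center, noise_blob$area,
                             noise_blob$intensity, seed = noise_blob$seed)
  for (pose in poses) if (!is.null(pose)) img <- render_worm(pose, img)
  attributes(img) <- list(dim = dim(img))
  img
}

#' Generate a labelled triplet dataset
#'
#' Emits classifier-ready 80x80 sub-image triplets with truth labels,
#' emulating triplets extracted from real plates. Live triplets have the
#' previous day's pose perturbed by `config$speed` while the next day's pose
#' equals the current one; dead triplets have identical poses in all three
#' frames. A configurable fraction receives a static noise blob, and the
#' previous/next frames receive independent rigid placement transforms
#' bounded by `displacement_max_px` / `rotation_max_deg`. With
#' `balanced = TRUE` the alive/dead split is exactly 50/50. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param size crop side in px (80, the classifier's input crop).
#' @return list of labelled triplets: each has `triplet` (a
#'   [sub_image_triplet()]), `label` ("alive"/"dead"), `provenance`
#'   ("simulated"), and `truth` (the poses used).
#' @export
generate_dataset <- function(config, size = 80L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_sequences
  labels <- if (config$balanced) {
    if (n %% 2 != 0) stop("balanced output requires an even n_sequences")
    rep(c("alive", "dead"), n / 2)
  } else {
    with_seed(derive_seed(config$seed, 101),
              sample(c("alive", "dead"), n, replace = TRUE))
  }
  out <- vector("list", n)
  ctr <- c((size + 1) / 2, (size + 1) / 2)
  for (i in seq_len(n)) {
    si <- derive_seed(config$seed, 8, i)
    sc <- with_seed(si, {
      list(base = stats::runif(1, 0.8, 0.88),
           grad = stats::runif(2, -0.04, 0.04),
           jitter = stats::runif(2, -3, 3),
           heading = stats::runif(1, 0, 2 * pi),
           length = stats::runif(1, 45, 58),
           width = stats::runif(1, config$worm_width_range[1],
                                config$worm_width_range[2]),
           intensity = stats::runif(1, config$worm_intensity_range[1],
                                    config$worm_intensity_range[2]),
           amplitude = stats::runif(1, 2.5, 5),
           periods = stats::runif(1, 1, 2),
           phase = stats::runif(1, 0, 2 * pi),
           speed = config$speed * stats::runif(1, config$speed_jitter[1],
                                              config$speed_jitter[2]),
           anchor_is_noise = stats::runif(1) < config$anchor_noise_frac,
           has_neighbor = stats::runif(1) < config$neighbor_frac,
           neighbor_moves = stats::runif(1) < 0.75,
           neighbor_off = stats::runif(1, 30, 46) *
             c(sin(a <- stats::runif(1, 0, 2 * pi)), cos(a)),
           has_noise = stats::runif(1) < config$noise_frac,
           noise_off = stats::runif(2, -1, 1) * size * 0.35,
           noise_area = stats::runif(1, config$noise_area_range[1],
                                     min(config$noise_area_range[2], 120)),
           noise_int = stats::runif(1, 0.15, 0.3))
    })
    alive <- labels[i] == "alive"
    anchor_noise <- !alive && sc$anchor_is_noise
    cur_pose <- if (anchor_noise) NULL else
      worm_pose(center = ctr + sc$jitter, heading = sc$heading,
                length_px = sc$length, width_px = sc$width,
                intensity = sc$intensity, amplitude = sc$amplitude,
                periods = sc$periods, phase = sc$phase)
    prev_pose <- if (alive) perturb_pose(cur_pose, sc$speed,
                                         seed = derive_seed(si, 1)) else cur_pose
    next_pose <- cur_pose
    nb <- NULL
    if (anchor_noise) {
      # the anchored object is itself a static opaque blob (a
      # segmentation-error case), not a worm
      nb <- list(center = ctr + sc$jitter, area = max(sc$noise_area, 40),
                 intensity = sc$noise_int, seed = derive_seed(si, 2))
    } else if (sc$has_noise) {
      nctr <- ctr + sc$noise_off
      if (sqrt(sum(sc$noise_off^2)) < 18) nctr <- ctr + c(20, 20)
      nb <- list(center = nctr, area = sc$noise_area,
                 intensity = sc$noise_int, seed = derive_seed(si, 2))
    }
    tex <- smooth_texture(size, size, config$texture_amp, config$texture_scale,
                          derive_seed(si, 6))
    # bystander worm near the crop edge, moving independently of the anchor
    nbr <- list(prev = NULL, cur = NULL, nxt = NULL)
    if (sc$has_neighbor) {
      base_pose <- with_seed(derive_seed(si, 7), worm_pose(
        center = ctr + sc$neighbor_off, heading = stats::runif(1, 0, 2 * pi),
        length_px = stats::runif(1, 45, 58),
        width_px = stats::runif(1, config$worm_width_range[1],
                                config$worm_width_range[2]),
        intensity = stats::runif(1, config$worm_intensity_range[1],
                                 config$worm_intensity_range[2]),
        amplitude = stats::runif(1, 2.5, 5), periods = stats::runif(1, 1, 2),
        phase = stats::runif(1, 0, 2 * pi)))
      nbr$cur <- base_pose
      if (sc$neighbor_moves) {
        nbr$prev <- perturb_pose(base_pose, sc$speed, seed = derive_seed(si, 8))
        nbr$nxt <- perturb_pose(base_pose, sc$speed, seed = derive_seed(si, 9))
      } else {
        nbr$prev <- base_pose; nbr$nxt <- base_pose
      }
    }
    mk <- function(pose, nb_pose) render_triplet_scene(list(pose, nb_pose),
                                                       size, sc$base, sc$grad,
                                                       nb, tex)
    cur <- mk(cur_pose, nbr$cur)
    prevf <- apply_plate_displacement(mk(prev_pose, nbr$prev),
                                      config$displacement_max_px,
                                      config$rotation_max_deg,
                                      seed = derive_seed(si, 3))
    nextf <- apply_plate_displacement(mk(next_pose, nbr$nxt),
                                      config$displacement_max_px,
                                      config$rotation_max_deg,
                                      seed = derive_seed(si, 4))
    ns <- function(img, tag) clamp(img + with_seed(derive_seed(si, 5, tag),
      stats::rnorm(length(img), 0, 0.004)), 0, 1)
    trip <- sub_image_triplet(ns(prevf$image, 1), ns(cur, 2), ns(nextf$image, 3),
                              anchor_centroid = ctr)
    out[[i]] <- list(triplet = trip, label = labels[i], provenance = "simulated",
                     truth = list(cur_pose = cur_pose, prev_pose = prev_pose,
                                  next_pose = next_pose,
                                  prev_transform = prevf$transform,
                                  next_transform = nextf$transform))
  }
  ord <- with_seed(derive_seed(config$seed, 9), sample.int(n))
  out[ord]
}

#' Replicate a dead triplet from a live worm image
#'
#' Copies the current-day frame to all three slots of a new triplet, applying
#' an independent small rigid transform to each copy, yielding a sequence
#' with no worm movement -- a synthetic dead sequence.
#'
#' @param triplet a [sub_image_triplet()] whose current frame contains a worm.
#' @param seed integer seed.
#' @param max_shift_px,max_rot_deg per-copy transform bounds.
#' @return a labelled triplet (`label = "dead"`, `provenance = "replicated"`).
#' @export
replicate_dead_from_live <- function(triplet, seed = NULL, max_shift_px = 15,
                                     max_rot_deg = 2) {
  stopifnot(inherits(triplet, "sub_image_triplet"))
  frames <- lapply(1:3, function(k)
    apply_plate_displacement(triplet$cur, max_shift_px, max_rot_deg,
                             seed = if (is.null(seed)) NULL
                                    else derive_seed(seed, k))$image)
  trip <- sub_image_triplet(frames[[1]], frames[[2]], frames[[3]],
                            anchor_centroid = triplet$anchor_centroid,
                            plate_id = triplet$plate_id, day = triplet$day)
  list(triplet = trip, label = "dead", provenance = "replicated")
}

#' Write a simulated plate sequence to disk
#'
#' PNG frames under `plate_<id>/day_<d>/frame_<f>.png` plus a `truth.csv`
#' with columns plate, day, worm_id, row, col, state.
#'
#' @param plate a `plate_sequence`; @param dir output directory.
#' @return invisibly, the plate directory.
#' @export
write_plate_sequence <- function(plate, dir) {
  pdir <- file.path(dir, sprintf("plate_%03d", plate$plate_id))
  for (d in seq_len(plate$days)) {
    ddir <- file.path(pdir, sprintf("day_%02d", d))
    dir.create(ddir, recursive = TRUE, showWarnings = FALSE)
    for (f in seq_len(plate$config$frames_per_day)) {
      img <- render_plate_frame(plate, d, f)
      EBImage::writeImage(EBImage::Image(img),
                          file.path(ddir, sprintf("frame_%02d.png", f)))
    }
  }
  utils::write.csv(plate$truth, file.path(pdir, "truth.csv"),
                   row.names = FALSE)
  invisible(pdir)
}
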