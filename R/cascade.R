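# Two-stage cascade classifier: rule-based initial detection of trivially
# live worms, wall-zone motion detection, and cascade orchestration.

#' Cascade classifier configuration
#'
#' @param min_blob_area minimum blob area accepted as a candidate worm (px).
#' @param distance_threshold maximum centroid distance (px) for a
#'   previous/next-day blob to count as "the same worm": 15 px of possible
#'   plate displacement plus a 5 px safety margin.
#' @param wall_area_threshold minimum connected changed-pixel area for a
#'   wall-zone motion region (px).
#' @param wall_change_range inclusive range of per-pixel change counts over
#'   the 30-frame stack that counts as low-frequency motion; changes at
#'   nearly every frame are flicker noise, not a worm.
#' @param wall_intensity_delta per-pixel |intensity change| between
#'   consecutive frames that counts as a change.
#' @param seg a [segment_config()] used on sub-image crops.
#' @return list of class `cascade_config`.
#' @export
cascade_config <- function(min_blob_area = 20L, distance_threshold = 20,
                           wall_area_threshold = 20L,
                           wall_change_range = c(2L, 10L),
                           wall_intensity_delta = 0.15,
                           seg = segment_config()) {
  stopifnot(distance_threshold > 0, min_blob_area >= 1,
            wall_change_range[1] >= 1,
            wall_change_range[2] >= wall_change_range[1])
  structure(list(min_blob_area = as.integer(min_blob_area),
                 distance_threshold = distance_threshold,
                 wall_area_threshold = as.integer(wall_area_threshold),
                 wall_change_range = as.integer(wall_change_range),
                 wall_intensity_delta = wall_intensity_delta,
                 seg = seg),
            class = "cascade_config")
}

stage1_verdict <- function(verdict, reason, anchor = NULL) {
  structure(list(verdict = verdict, reason = reason, anchor = anchor),
            class = "stage1_verdict")
}

# the anchored worm in the central frame: blob nearest the crop centre;
# ties broken by larger area, then lexicographic centroid.
pick_central_blob <- function(blobs, center) {
  if (length(blobs) == 0) return(NULL)
  d <- vapply(blobs, function(b)
    sqrt(sum((b$centroid - center)^2)), numeric(1))
  areas <- vapply(blobs, `[[`, numeric(1), "area")
  rs <- vapply(blobs, function(b) b$centroid[1], numeric(1))
  cs <- vapply(blobs, function(b) b$centroid[2], numeric(1))
  blobs[[order(d, -areas, rs, cs)[1]]]
}

#' Stage-1 rule-based classification of a sub-image triplet
#'
#' Segments the three frames, identifies the anchored worm (blob nearest the
#' crop centre in the current-day frame), and checks the previous and next
#' frames for any blob of at least `min_blob_area` px whose centroid lies
#' within `distance_threshold` px of the anchor. If either neighbouring
#' frame has no qualifying blob, the worm moved farther than a plate shift
#' can explain (or left the window entirely), so the sequence is assuredly a
#' live worm; otherwise it is UNDETERMINED and routed to the network.
#'
#' @param triplet a [sub_image_triplet()].
#' @param config a [cascade_config()].
#' @return a `stage1_verdict`: `verdict` in {"ALIVE", "UNDETERMINED"} and
#'   `reason` in {"no_blob_prev", "no_blob_next", "moved_out",
#'   "stationary_or_noisy"}.
#' @export
stage1_classify <- function(triplet, config = cascade_config()) {
  stopifnot(inherits(triplet, "sub_image_triplet"))
  center <- (dim(triplet$cur) + 1) / 2
  segs <- lapply(list(triplet$prev, triplet$cur, triplet$nxt),
                 function(f) find_blobs(segment(f, config = config$seg),
                                        config$min_blob_area))
  anchor_blob <- pick_central_blob(segs[[2]], center)
  if (is.null(anchor_blob))
    return(stage1_verdict("UNDETERMINED", "stationary_or_noisy"))
  anchor <- anchor_blob$centroid
  qualifies <- function(blobs) {
    length(blobs) > 0 && any(vapply(blobs, function(b)
      sqrt(sum((b$centroid - anchor)^2)) < config$distance_threshold,
      logical(1)))
  }
  if (length(segs[[1]]) == 0)
    return(stage1_verdict("ALIVE", "no_blob_prev", anchor))
  if (length(segs[[3]]) == 0)
    return(stage1_verdict("ALIVE", "no_blob_next", anchor))
  if (!qualifies(segs[[1]]) || !qualifies(segs[[3]]))
    return(stage1_verdict("ALIVE", "moved_out", anchor))
  stage1_verdict("UNDETERMINED", "stationary_or_noisy", anchor)
}

#' Count live worms in the wall zone by low-frequency motion
#'
#' The wall annulus cannot be segmented reliably, so worms there are found
#' by temporal analysis: a pixel "changes" when its intensity differs by
#' more than `wall_intensity_delta` between consecutive frames; pixels whose
#' change count over the daily stack falls in `wall_change_range`
#' (low-frequency -- a worm body passing, not flicker) are grouped into
#' 8-connected regions, and regions of at least `wall_area_threshold` px are
#' counted as live worms.
#'
#' @param wall_frames list of exactly 30 image matrices.
#' @param config a [cascade_config()].
#' @param wall_mask optional logical matrix restricting analysis to the wall
#'   annulus.
#' @return integer: number of distinct motion regions (live count).
#' @export
wall_motion_detect <- function(wall_frames, config = cascade_config(),
                               wall_mask = NULL) {
  if (length(wall_frames) != 30L)
    stop("expected exactly 30 frames, got ", length(wall_frames))
  changes <- matrix(0L, nrow(wall_frames[[1]]), ncol(wall_frames[[1]]))
  for (i in 1:29) {
    d <- abs(wall_frames[[i + 1]] - wall_frames[[i]]) > config$wall_intensity_delta
    changes <- changes + d
  }
  qualify <- changes >= config$wall_change_range[1] &
    changes <= config$wall_change_range[2]
  if (!is.null(wall_mask)) qualify <- qualify & wall_mask
  length(find_blobs(qualify, config$wall_area_threshold))
}

#' Run the two-stage cascade over a plate sequence
#'
#' For each day: counts wall-zone live worms by motion, extracts central-zone
#' triplets around the day's centroids, settles trivially live cases with
#' [stage1_classify()], and routes the UNDETERMINED remainder to the network
#' model. Day 1 reuses the current day's image as "previous" and the final
#' day reuses it as "next" (`boundary = "reuse"`, the conservative choice
#' that never fabricates motion); `boundary = "skip"` restricts output to
#' interior days.
#'
#' @param plate a [simulate_plate()] `plate_sequence`.
#' @param model a trained [build_model()] network, or any function
#'   `function(triplet) -> "alive"/"dead"`; `NULL` counts every
#'   UNDETERMINED triplet as dead.
#' @param config a [cascade_config()].
#' @param boundary `"reuse"` (default) or `"skip"`.
#' @param crop_size triplet crop side (px).
#' @return data.frame with columns plate, day, live, dead, wall,
#'   stage1_alive, nn_alive, nn_dead, nn_calls.
#' @export
run_cascade <- function(plate, model, config = cascade_config(),
                        boundary = c("reuse", "skip"), crop_size = 80L) {
  boundary <- match.arg(boundary)
  if (plate$days < 3)
    stop("cascade needs at least 3 consecutive days (triplets need prev and next)")
  zones <- partition_zones(plate$geometry, nrow(plate$background))
  n_frames <- plate$config$frames_per_day
  last_frame <- lapply(seq_len(plate$days), function(d)
    render_plate_frame(plate, d, n_frames))
  days <- if (boundary == "skip") 2:(plate$days - 1) else seq_len(plate$days)
  rows <- lapply(days, function(d) {
    frames <- plate_day_frames(plate, d)
    wall <- wall_motion_detect(frames, config, wall_mask = zones$wall)
    cents <- track_daily_centroids(frames, plate$geometry,
                                   min_area = config$min_blob_area,
                                   config = config$seg)
    s1_alive <- 0L; nn_alive <- 0L; nn_dead <- 0L; nn_calls <- 0L
    prev_img <- last_frame[[max(d - 1, 1)]]
    next_img <- last_frame[[min(d + 1, plate$days)]]
    for (k in seq_len(nrow(cents))) {
      trip <- crop_triplet(prev_img, last_frame[[d]], next_img,
                           cents[k, ], size = crop_size,
                           plate_id = plate$plate_id, day = d)
      v <- stage1_classify(trip, config)
      if (v$verdict == "ALIVE") {
        s1_alive <- s1_alive + 1L
      } else {
        nn_calls <- nn_calls + 1L
        # day 1 reuses the current frame as "previous", so any motion sits
        # in the next-day slot; present the network the time-reversed
        # sequence it was trained on (motion in the previous-day slot)
        if (d == 1 && boundary == "reuse") {
          trip <- sub_image_triplet(trip$nxt, trip$cur, trip$prev,
                                    anchor_centroid = trip$anchor_centroid,
                                    plate_id = trip$plate_id, day = trip$day,
                                    padded = trip$padded)
        }
        lab <- if (is.null(model)) "dead"
          else if (is.function(model)) model(trip)
          else predict(model, trip)$label
        if (identical(lab, "alive")) nn_alive <- nn_alive + 1L
        else nn_dead <- nn_dead + 1L
      }
    }
    data.frame(plate = plate$plate_id, day = d,
               live = wall + s1_alive + nn_alive, dead = nn_dead,
               wall = wall, stage1_alive = s1_alive,
               nn_alive = nn_alive, nn_dead = nn_dead, nn_calls = nn_calls)
  })
  do.call(rbind, rows)
}
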