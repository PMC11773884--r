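#' @title Swim kinematics
#' @description
#' Turns per-frame keypoints into behavioral readouts: instantaneous speed,
#' the signed rostral-caudal body-bend angle, high-amplitude bend events
#' (peak magnitude at or above 110 degrees by default), swim bouts (maximal
#' runs with speed above 2 mm/s), and stimulus-window summaries for
#' light/dark visuomotor assays.
#' @name kinematics
NULL

#' Per-animal trajectory container
#'
#' @param keypoints Numeric array `(n_frames, K, 2)` of (x, y) pixel
#'   coordinates, keypoints ordered rostral to caudal, or an `n x 2` matrix
#'   for a single keypoint.
#' @param framerate Hz; the time base is uniform at `1/framerate`.
#' @param mm_per_px Spatial calibration (mm per pixel), required -- typically
#'   derived from the known well diameter. No default is assumed.
#' @param stimulus_marks Optional named numeric vector of stimulus times (s),
#'   e.g. `c(light_on = 30, dark_on = 60)`.
#' @param confidence Optional `(n_frames, K)` matrix of detection confidences.
#' @return List of class `fp_trajectory`.
#' @export
trajectory_series <- function(keypoints, framerate, mm_per_px,
                              stimulus_marks = NULL, confidence = NULL) {
  if (length(dim(keypoints)) == 2) {
    keypoints <- array(keypoints, dim = c(nrow(keypoints), 1, 2))
  }
  stopifnot(length(dim(keypoints)) == 3, dim(keypoints)[3] == 2,
            framerate > 0, mm_per_px > 0)
  n <- dim(keypoints)[1]
  structure(list(keypoints = keypoints,
                 times = (seq_len(n) - 1) / framerate,
                 framerate = framerate, mm_per_px = mm_per_px,
                 stimulus_marks = stimulus_marks, confidence = confidence),
            class = "fp_trajectory")
}

#' Kinematic analysis configuration
#'
#' @param bend_threshold Degrees; bend peaks at or above this magnitude count
#'   as high-amplitude body bends. Default 110.
#' @param bout_threshold mm/s; a swim bout begins when speed exceeds this
#'   value (strictly) and ends when it drops below it. Default 2.
#' @param stim_window Seconds of the post-stimulus analysis window. Default 5.
#' @param smooth_window Seconds of the mean-filter window used for
#'   presentation speed traces. Default 1.
#' @param reference_keypoint 1-based index of the keypoint used for position
#'   and speed; default 1, the most rostral point (for single-keypoint
#'   visuomotor tracking this is the between-the-eyes point).
#' @return List of class `fp_kinematic_config`.
#' @export
kinematic_config <- function(bend_threshold = 110, bout_threshold = 2,
                             stim_window = 5, smooth_window = 1,
                             reference_keypoint = 1L) {
  stopifnot(bend_threshold > 0, bout_threshold > 0, stim_window > 0,
            smooth_window > 0, reference_keypoint >= 1)
  structure(list(bend_threshold = bend_threshold,
                 bout_threshold = bout_threshold, stim_window = stim_window,
                 smooth_window = smooth_window,
                 reference_keypoint = as.integer(reference_keypoint)),
            class = "fp_kinematic_config")
}

#' Instantaneous speed series
#'
#' `speed[t] = ||pos[t] - pos[t-1]|| * mm_per_px * framerate` at the reference
#' keypoint; the first frame has speed 0. Speeds are computed from raw
#' positions; smoothing ([smooth_series()]) is for presentation traces only.
#'
#' @param traj An [trajectory_series()].
#' @param cfg An [kinematic_config()].
#' @return Numeric vector (mm/s), one value per frame.
#' @export
compute_speed <- function(traj, cfg = kinematic_config()) {
  p <- traj$keypoints[, cfg$reference_keypoint, , drop = FALSE]
  n <- dim(traj$keypoints)[1]
  if (n < 2) stop("compute_speed needs at least 2 frames")
  d <- sqrt(diff(p[, 1, 1])^2 + diff(p[, 1, 2])^2)
  c(0, d) * traj$mm_per_px * traj$framerate
}

#' Centered moving-mean filter
#'
#' Mean filter with a centered sliding window of `window_s` seconds
#' (`2*round(window_s*framerate/2) + 1` frames); the window shrinks at the
#' series edges.
#'
#' @param x Numeric series.
#' @param window_s Window length in seconds.
#' @param framerate Hz.
#' @return Smoothed series of the same length.
#' @export
smooth_series <- function(x, window_s, framerate) {
  h <- round(window_s * framerate / 2)
  if (h < 1) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Signed rostral-caudal bend angle
#'
#' Sum over consecutive keypoint-segment pairs of the signed turning angle
#' between segment direction vectors (counterclockwise positive in image
#' coordinates). A straight body gives 0; a mirrored pose negates the angle;
#' the angle is invariant under rotation and translation.
#'
#' @param kp `K x 2` matrix (`K >= 3`) of keypoints ordered rostral to caudal.
#' @return Signed angle in degrees.
#' @export
rostral_caudal_angle <- function(kp) {
  kp <- as_keypoint_matrix(kp)
  K <- nrow(kp)
  if (K < 3) stop("rostral_caudal_angle needs at least 3 keypoints")
  seg <- diff(kp)
  len2 <- rowSums(seg^2)
  if (any(len2 < 1e-20)) stop("coincident consecutive keypoints")
  a <- seg[-nrow(seg), , drop = FALSE]
  b <- seg[-1, , drop = FALSE]
  turn <- atan2(a[, 1] * b[, 2] - a[, 2] * b[, 1], rowSums(a * b))
  sum(turn) * 180 / pi
}

# angle series for a whole trajectory (NA when K < 3)
angle_series <- function(traj) {
  K <- dim(traj$keypoints)[2]
  if (K < 3) return(rep(NA_real_, dim(traj$keypoints)[1]))
  vapply(seq_len(dim(traj$keypoints)[1]),
         function(t) rostral_caudal_angle(traj$keypoints[t, , ]),
         numeric(1))
}

#' Detect body-bend events
#'
#' The angle series is segmented at zero crossings (zeros act as boundaries);
#' within each constant-sign segment the frame of maximum magnitude (earliest
#' frame on ties) is one bend peak. Peaks with `|peak_angle| >=
#' bend_threshold` are high-amplitude bends.
#'
#' @param angle Numeric series of signed bend angles (degrees).
#' @param framerate Hz.
#' @param cfg An [kinematic_config()].
#' @return List with `events` (data frame: `peak_time`, `peak_angle`,
#'   `is_high_amplitude`) and `summary` (list: `first_peak_angle`,
#'   `first_peak_time`, `max_angle` magnitude, `max_angle_time`,
#'   `n_high_amplitude`, `any_high_amplitude`). Empty event lists are allowed.
#' @export
detect_bends <- function(angle, framerate, cfg = kinematic_config()) {
  stopifnot(length(angle) >= 3)
  s <- sign(angle)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  events <- data.frame(peak_time = numeric(0), peak_angle = numeric(0),
                       is_high_amplitude = logical(0))
  for (g in which(keep)) {
    idx <- starts[g]:ends[g]
    j <- idx[which.max(abs(angle[idx]))] # which.max: earliest tie
    events <- rbind(events, data.frame(
      peak_time = (j - 1) / framerate, peak_angle = angle[j],
      is_high_amplitude = abs(angle[j]) >= cfg$bend_threshold))
  }
  mags <- abs(angle)
  jmax <- which.max(mags)
  summary <- list(
    first_peak_angle = if (nrow(events)) events$peak_angle[1] else NA_real_,
    first_peak_time = if (nrow(events)) events$peak_time[1] else NA_real_,
    max_angle = if (all(!is.finite(mags))) NA_real_ else mags[jmax],
    max_angle_time = (jmax - 1) / framerate,
    n_high_amplitude = sum(events$is_high_amplitude),
    any_high_amplitude = any(events$is_high_amplitude))
  list(events = events, summary = summary)
}

#' Detect swim bouts
#'
#' Maximal runs of frames with speed strictly above `bout_threshold`; a bout
#' ends when speed drops below (or to) the threshold, and a run still open at
#' the end of the series closes at the last frame. Single-frame bouts are
#' allowed. Duration is `run length / framerate`.
#'
#' @param speed Numeric speed series (mm/s).
#' @param framerate Hz.
#' @param cfg An [kinematic_config()].
#' @return Data frame: `start_time`, `end_time`, `duration`, `peak_speed`
#'   (one row per bout; zero rows when no bout).
#' @export
detect_bouts <- function(speed, framerate, cfg = kinematic_config()) {
  above <- speed > cfg$bout_threshold
  if (!length(above) || !any(above)) {
    return(data.frame(start_time = numeric(0), end_time = numeric(0),
                      duration = numeric(0), peak_speed = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  w <- which(r$values)
  data.frame(
    start_time = (starts[w] - 1) / framerate,
    end_time = (starts[w] - 1) / framerate + r$lengths[w] / framerate,
    duration = r$lengths[w] / framerate,
    peak_speed = vapply(w, function(g) max(speed[starts[g]:ends[g]]),
                        numeric(1)))
}

#' Post-stimulus summary
#'
#' Statistics over the window `[mark, mark + stim_window)` following one
#' stimulus: maximum raw (unsmoothed) speed, swim-bout count, mean bout
#' duration and mean bout peak speed (both `NA` when there is no bout). The
#' window is truncated with a warning when it exceeds the recording.
#'
#' @param traj An [trajectory_series()].
#' @param mark Stimulus time (s), within the recording.
#' @param cfg An [kinematic_config()].
#' @return List: `max_speed`, `n_bouts`, `mean_bout_duration`,
#'   `mean_bout_peak_speed`, `window` (start/end s).
#' @export
stimulus_summary <- function(traj, mark, cfg = kinematic_config()) {
  n <- dim(traj$keypoints)[1]
  if (mark < 0 || mark > traj$times[n]) stop("stimulus mark outside recording")
  end <- mark + cfg$stim_window
  if (end > traj$times[n] + 1 / traj$framerate) {
    warning("post-stimulus window exceeds the recording; truncated")
    end <- traj$times[n] + 1 / traj$framerate
  }
  speed <- compute_speed(traj, cfg)
  sel <- traj$times >= mark & traj$times < end
  sp <- speed[sel]
  bouts <- detect_bouts(sp, traj$framerate, cfg)
  list(max_speed = max(sp),
       n_bouts = nrow(bouts),
       mean_bout_duration = if (nrow(bouts)) mean(bouts$duration) else NA_real_,
       mean_bout_peak_speed = if (nrow(bouts)) mean(bouts$peak_speed) else NA_real_,
       window = c(start = mark, end = end))
}

#' Whole-response summary for a trimmed escape response
#'
#' For a recording trimmed to a single response: duration
#' (`n_frames/framerate`), distance travelled (path length of the reference
#' keypoint times `mm_per_px`), bend summaries, and the response-progress
#' series `t/duration` in `[0, 1]` (1 at the final frame).
#'
#' @param traj An [trajectory_series()].
#' @param cfg An [kinematic_config()].
#' @return List: `duration`, `distance`, `bends` (as [detect_bends()]),
#'   `progress`.
#' @export
response_summary <- function(traj, cfg = kinematic_config()) {
  n <- dim(traj$keypoints)[1]
  p <- traj$keypoints[, cfg$reference_keypoint, ]
  dist <- sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)) * traj$mm_per_px
  ang <- angle_series(traj)
  bends <- if (all(is.na(ang))) NULL else detect_bends(ang, traj$framerate, cfg)
  list(duration = n / traj$framerate, distance = dist, bends = bends,
       progress = seq_len(n) / n)
}

#' Export a per-animal kinematics table
#'
#' One row per frame: `frame`, `time_s`, `x_i`/`y_i` per keypoint,
#' `speed_mm_s`, `rostral_caudal_angle_deg` (NA when K < 3), and the absolute
#' orientation of each consecutive inter-keypoint segment
#' (`segment_angle_i_deg`).
#'
#' @param traj An [trajectory_series()].
#' @param cfg An [kinematic_config()].
#' @return A data frame.
#' @export
kinematics_table <- function(traj, cfg = kinematic_config()) {
  n <- dim(traj$keypoints)[1]
  K <- dim(traj$keypoints)[2]
  tab <- data.frame(frame = seq_len(n) - 1L, time_s = traj$times)
  for (k in seq_len(K)) {
    tab[[paste0("x_", k - 1L)]] <- traj$keypoints[, k, 1]
    tab[[paste0("y_", k - 1L)]] <- traj$keypoints[, k, 2]
  }
  tab$speed_mm_s <- compute_speed(traj, cfg)
  tab$rostral_caudal_angle_deg <- angle_series(traj)
  if (K >= 2) {
    for (k in seq_len(K - 1)) {
      dx <- traj$keypoints[, k + 1, 1] - traj$keypoints[, k, 1]
      dy <- traj$keypoints[, k + 1, 2] - traj$keypoints[, k, 2]
      tab[[paste0("segment_angle_", k - 1L, "_deg")]] <- atan2(dy, dx) * 180 / pi
    }
  }
  tab
}
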