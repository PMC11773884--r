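#' @title Synthetic larval-fish scenes
#' @description
#' Seeded generator of synthetic larval zebrafish frames, labeled pose
#' datasets, and scripted trajectory movies. Larvae are rendered as dark,
#' curved, tapered bodies on a bright well background -- the appearance of an
#' embryonic/larval fish imaged from above with transillumination -- with
#' optional well edges, probe-like occluders, illumination gradients, blur and
#' sensor noise. Every output is a pure function of its inputs and a seed, and
#' carries exact ground-truth keypoints, so all downstream modules (codec,
#' augmentation, network training, kinematics) are testable without recordings.
#' @name synthetic
NULL

#' Pose parameters of a single fish
#'
#' The body midline is a constant-curvature circular arc of length
#' `body_length`; `arc_curvature` is the total signed turning angle of the
#' midline from head to tail (degrees, counterclockwise positive in image
#' coordinates). The body is a linearly interpolated taper of half-widths
#' (fractions of body length) from head to tail.
#'
#' @param centroid Numeric (x, y), pixels: mean position of the midline
#'   (or the head keypoint when `anchor = "head"`).
#' @param heading Degrees; direction of the head-to-tail axis at the body
#'   midpoint.
#' @param arc_curvature Total signed turning angle of the midline, degrees;
#'   must satisfy `|arc_curvature| < 360`.
#' @param body_length Pixels, > 0.
#' @param body_width_profile Half-width fractions of `body_length`, head to
#'   tail. The default tapers from a wide head/yolk region to a thin tail.
#' @param anchor `"centroid"` (default) or `"head"`: which point `centroid`
#'   pins.
#' @return List of class `fp_pose`.
#' @export
pose_params <- function(centroid, heading = 0, arc_curvature = 0,
                        body_length = 100,
                        body_width_profile = c(0.050, 0.058, 0.046, 0.032,
                                               0.022, 0.016, 0.012),
                        anchor = c("centroid", "head")) {
  anchor <- match.arg(anchor)
  stopifnot(length(centroid) == 2, is.finite(centroid), body_length > 0,
            abs(arc_curvature) < 360, all(body_width_profile > 0))
  structure(list(centroid = as.numeric(centroid), heading = heading,
                 arc_curvature = arc_curvature, body_length = body_length,
                 body_width_profile = body_width_profile, anchor = anchor),
            class = "fp_pose")
}

#' Scene specification
#'
#' @param frame_size Frame side length in pixels (square frames).
#' @param background_level,fish_level Intensity fractions in `[0, 1]`; the
#'   fish is darker than the background under transillumination.
#' @param well_edge Optional list `(center = c(x, y), radius, darkness)`
#'   drawing a dark circular well rim.
#' @param probe Optional bar occluder, list `(position = c(x, y), angle,
#'   width, level)`: a dark bar with its tip at `position`, extending away
#'   along `angle` (degrees), emulating a touch probe entering the field.
#' @param illumination_gradient Corner-to-corner additive intensity slope
#'   (fraction); 0 disables.
#' @param noise_sd Gaussian sensor-noise SD (intensity fraction), >= 0.
#' @param blur_sigma Optical blur SD in pixels.
#' @return List of class `fp_scene`.
#' @export
scene_spec <- function(frame_size = 256, background_level = 0.85,
                       fish_level = 0.12, well_edge = NULL, probe = NULL,
                       illumination_gradient = 0, noise_sd = 0.01,
                       blur_sigma = 0.7) {
  stopifnot(frame_size >= 32,
            background_level >= 0, background_level <= 1,
            fish_level >= 0, fish_level <= 1, noise_sd >= 0, blur_sigma >= 0)
  structure(list(frame_size = as.integer(frame_size),
                 background_level = background_level, fish_level = fish_level,
                 well_edge = well_edge, probe = probe,
                 illumination_gradient = illumination_gradient,
                 noise_sd = noise_sd, blur_sigma = blur_sigma),
            class = "fp_scene")
}

# closed-form constant-curvature midline; returns function of arc fraction
# u in [0,1] -> (x, y) relative to the arc's own centroid (or head)
midline_xy <- function(pose, u) {
  L <- pose$body_length
  th0 <- pose$heading * pi / 180
  kap <- pose$arc_curvature * pi / 180
  if (abs(kap) < 1e-12) {
    return(unname(cbind(L * u * cos(th0), L * u * sin(th0))))
  } else {
    R <- L / kap
    th <- th0 + kap * (u - 0.5)
    thh <- th0 - kap * 0.5 # heading at head (u = 0)
    x <- R * (sin(th) - sin(thh))
    y <- -R * (cos(th) - cos(thh))
    unname(cbind(x, y))
  }
}

# exact arc centroid (mean of the continuous midline) relative to the head
arc_centroid <- function(pose) {
  L <- pose$body_length
  th0 <- pose$heading * pi / 180
  kap <- pose$arc_curvature * pi / 180
  if (abs(kap) < 1e-12) {
    return(c(L / 2 * cos(th0), L / 2 * sin(th0)))
  }
  R <- L / kap
  thh <- th0 - kap * 0.5
  tht <- th0 + kap * 0.5
  mx <- R * ((cos(thh) - cos(tht)) / kap - sin(thh))
  my <- -R * ((sin(tht) - sin(thh)) / kap - cos(thh))
  c(mx, my)
}

# translation pinning the pose anchor at pose$centroid
anchor_shift <- function(pose) {
  if (pose$anchor == "head") pose$centroid
  else pose$centroid - arc_centroid(pose)
}

# dense midline samples translated to the pose anchor; ns points
midline_points <- function(pose, ns) {
  u <- seq(0, 1, length.out = ns)
  sweep(midline_xy(pose, u), 2, anchor_shift(pose), `+`)
}

# half-width (px) at arc fractions u
midline_halfwidth <- function(pose, u) {
  prof <- pose$body_width_profile
  stats::approx(seq(0, 1, length.out = length(prof)), prof, xout = u,
                rule = 2)$y * pose$body_length
}

#' Evenly spaced midline keypoints
#'
#' K keypoints at arc-length fractions `i/(K-1)`, `i = 0..K-1`, rostral to
#' caudal; `K = 1` returns the head end of the midline (the point between the
#' eyes of a real larva).
#'
#' @param pose An [pose_params()] object.
#' @param n_keypoints Integer in `[1, 10]`.
#' @return `n_keypoints x 2` matrix of (x, y) pixel coordinates.
#' @export
pose_keypoints <- function(pose, n_keypoints) {
  check_n_keypoints(n_keypoints)
  u <- if (n_keypoints == 1L) 0 else seq(0, 1, length.out = n_keypoints)
  sweep(midline_xy(pose, u), 2, anchor_shift(pose), `+`)
}

check_n_keypoints <- function(k) {
  if (length(k) != 1 || is.na(k) || k != as.integer(k) || k < 1 || k > 10) {
    stop("n_keypoints must be an integer in [1, 10], got ", k)
  }
  invisible(as.integer(k))
}

#' Render one labeled frame
#'
#' Draws the background (with optional illumination gradient and well rim),
#' the fish body (anti-aliased union of disks along the midline with a linear
#' taper), an optional probe occluder on top, then applies Gaussian blur and
#' seeded sensor noise. Deterministic for fixed inputs.
#'
#' @param pose An [pose_params()].
#' @param scene An [scene_spec()].
#' @param rng_seed Integer seed for the noise draw.
#' @param n_keypoints Number of ground-truth keypoints (default 7).
#' @return List of class `fp_labeled_frame`: `image` (H x W matrix in
#'   `[0, 1]`) and `keypoints` (K x 2, 0-based pixel-center coordinates).
#' @export
render_frame <- function(pose, scene, rng_seed = 1L, n_keypoints = 7L) {
  check_n_keypoints(n_keypoints)
  sz <- scene$frame_size
  ns <- max(129L, as.integer(ceiling(pose$body_length)) + 1L)
  pts <- midline_points(pose, ns)
  u <- seq(0, 1, length.out = ns)
  hw <- midline_halfwidth(pose, u)
  margin <- max(hw)
  if (any(pts[, 1] < margin) || any(pts[, 1] > sz - 1 - margin) ||
      any(pts[, 2] < margin) || any(pts[, 2] > sz - 1 - margin)) {
    stop("pose outside frame: the fish body does not fit inside the ",
         sz, "x", sz, " frame")
  }

  xs <- 0:(sz - 1)
  # background with corner-to-corner gradient
  if (scene$illumination_gradient != 0) {
    g <- (outer(xs, xs, `+`) / (2 * (sz - 1))) - 0.5 # (y + x)/2 normalized
    img <- scene$background_level + scene$illumination_gradient * g
  } else {
    img <- matrix(scene$background_level, sz, sz)
  }

  if (!is.null(scene$well_edge)) {
    we <- scene$well_edge
    d <- sqrt(outer((xs - we$center[2])^2, (xs - we$center[1])^2, `+`))
    ring <- clamp01(1.5 - abs(d - we$radius)) * we$darkness
    img <- img * (1 - ring)
  }

  # fish: signed coverage = clamp(halfwidth - dist + 0.5, 0, 1), max over samples
  lo <- pmax(0L, floor(apply(pts, 2, min) - margin - 1))
  hi <- pmin(sz - 1L, ceiling(apply(pts, 2, max) + margin + 1))
  bx <- lo[1]:hi[1]; by <- lo[2]:hi[2]
  cov <- matrix(0, length(by), length(bx))
  for (j in seq_len(ns)) {
    d <- sqrt(outer((by - pts[j, 2])^2, (bx - pts[j, 1])^2, `+`))
    cov <- pmax(cov, clamp01(hw[j] - d + 0.5))
  }
  sub <- img[by + 1L, bx + 1L]
  img[by + 1L, bx + 1L] <- sub * (1 - cov) + scene$fish_level * cov

  if (!is.null(scene$probe)) {
    pr <- scene$probe
    th <- pr$angle * pi / 180
    dxm <- outer(rep(1, sz), xs - pr$position[1])
    dym <- outer(xs - pr$position[2], rep(1, sz))
    along <- dxm * cos(th) + dym * sin(th)
    across <- abs(-dxm * sin(th) + dym * cos(th))
    mask <- clamp01(pr$width / 2 - across + 0.5) * clamp01(along + 0.5)
    lvl <- if (is.null(pr$level)) 0.25 else pr$level
    img <- img * (1 - mask) + lvl * mask
  }

  img <- gaussian_blur(img, scene$blur_sigma)
  if (scene$noise_sd > 0) {
    noise <- with_seed(rng_seed, function() {
      matrix(stats::rnorm(sz * sz, 0, scene$noise_sd), sz, sz)
    })
    img <- img + noise
  }
  img <- clamp01(img)

  structure(list(image = img, keypoints = pose_keypoints(pose, n_keypoints)),
            class = "fp_labeled_frame")
}

#' Default randomization ranges for dataset generation
#'
#' Ranges emulate the variability of real recordings: varying lighting,
#' magnification (body length relative to the frame), focus (blur), pose and
#' body curvature, optional well rims and probe occluders (which may overlap
#' the fish; labels remain valid behind occluders).
#'
#' @param frame_size Frame side length, px.
#' @param body_length_frac Range of body length as a fraction of `frame_size`.
#' @param curvature Range of total midline turning angle, degrees.
#' @param background_level,fish_level,illumination_gradient,noise_sd,blur_sigma
#'   Ranges of the corresponding [scene_spec()] fields.
#' @param well_edge_prob,probe_prob Per-frame probabilities of a well rim /
#'   probe occluder.
#' @return List of class `fp_scene_ranges`.
#' @export
scene_ranges <- function(frame_size = 256,
                         body_length_frac = c(0.30, 0.42),
                         curvature = c(-300, 300),
                         background_level = c(0.70, 0.95),
                         fish_level = c(0.05, 0.25),
                         illumination_gradient = c(-0.15, 0.15),
                         noise_sd = c(0.003, 0.03),
                         blur_sigma = c(0.5, 1.2),
                         well_edge_prob = 0.5, probe_prob = 0.25) {
  structure(as.list(environment()), class = "fp_scene_ranges")
}

runif1 <- function(r) stats::runif(1, r[1], r[2])

#' Generate a randomized labeled dataset
#'
#' Draws `n_frames` poses and scenes from `ranges` and renders each frame with
#' exact keypoint labels. Reproducible: one root seed is split into per-frame
#' seeds via a fixed counter scheme.
#'
#' @param n_frames Number of frames, >= 1.
#' @param n_keypoints Keypoints per frame, in `[1, 10]` (7 for touch-evoked
#'   style data, 1 for visuomotor style data).
#' @param ranges A [scene_ranges()].
#' @param seed Integer root seed.
#' @return List of class `fp_dataset`: `frames` (list of matrices),
#'   `keypoints` (list of K x 2 matrices), plus `n_keypoints`, `frame_size`,
#'   `seed`.
#' @export
generate_dataset <- function(n_frames, n_keypoints = 7L,
                             ranges = scene_ranges(), seed = 1L) {
  stopifnot(n_frames >= 1)
  check_n_keypoints(n_keypoints)
  seeds <- derive_seeds(seed, 2L * n_frames)
  sz <- ranges$frame_size
  frames <- vector("list", n_frames)
  kps <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    drawn <- with_seed(seeds[i], function() {
      L <- runif1(ranges$body_length_frac) * sz
      pose <- NULL
      for (try in 1:50) { # rejection-sample a pose that fits
        pose_try <- pose_params(
          centroid = c(stats::runif(1, 0.3, 0.7) * (sz - 1),
                       stats::runif(1, 0.3, 0.7) * (sz - 1)),
          heading = stats::runif(1, 0, 360),
          arc_curvature = runif1(ranges$curvature),
          body_length = L)
        ext <- midline_points(pose_try, 65L)
        m <- max(midline_halfwidth(pose_try, c(0, 1)))
        if (all(ext > m + 1) && all(ext < sz - 2 - m)) { pose <- pose_try; break }
      }
      if (is.null(pose)) stop("could not place a fish inside the frame")
      bg <- runif1(ranges$background_level)
      fg <- runif1(ranges$fish_level)
      well <- if (stats::runif(1) < ranges$well_edge_prob) {
        list(center = c(sz / 2, sz / 2) + stats::runif(2, -0.05, 0.05) * sz,
             radius = stats::runif(1, 0.40, 0.48) * sz,
             darkness = stats::runif(1, 0.3, 0.8))
      } else NULL
      probe <- if (stats::runif(1) < ranges$probe_prob) {
        list(position = pose$centroid + stats::runif(2, -0.1, 0.1) * sz,
             angle = stats::runif(1, 0, 360),
             width = stats::runif(1, 0.02, 0.05) * sz,
             level = stats::runif(1, 0.1, 0.35))
      } else NULL
      scene <- scene_spec(frame_size = sz, background_level = bg,
                          fish_level = fg, well_edge = well, probe = probe,
                          illumination_gradient = runif1(ranges$illumination_gradient),
                          noise_sd = runif1(ranges$noise_sd),
                          blur_sigma = runif1(ranges$blur_sigma))
      list(pose = pose, scene = scene)
    })
    lf <- render_frame(drawn$pose, drawn$scene, rng_seed = seeds[n_frames + i],
                       n_keypoints = n_keypoints)
    frames[[i]] <- lf$image
    kps[[i]] <- lf$keypoints
  }
  structure(list(frames = frames, keypoints = kps,
                 n_keypoints = as.integer(n_keypoints),
                 frame_size = as.integer(sz), seed = as.integer(seed)),
            class = "fp_dataset")
}

#' Write / read a labeled dataset directory
#'
#' Layout: `frames/NNNNNN.tiff` (16-bit grayscale TIFF), `labels.csv` with
#' columns `frame, keypoint_index, x, y` (0-based indices, pixel-center
#' coordinates), and `manifest.yaml` (frame size, keypoint count, seed,
#' generator version).
#'
#' @param ds An `fp_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly (`write_dataset`); an `fp_dataset`
#'   (`read_dataset`).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ds$frames)) {
    tiff::writeTIFF(ds$frames[[i]],
                    file.path(dir, "frames", sprintf("%06d.tiff", i - 1L)),
                    bits.per.sample = 16L)
  }
  labs <- do.call(rbind, lapply(seq_along(ds$keypoints), function(i) {
    kp <- ds$keypoints[[i]]
    data.frame(frame = i - 1L, keypoint_index = seq_len(nrow(kp)) - 1L,
               x = kp[, 1], y = kp[, 2])
  }))
  utils::write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE)
  yaml::write_yaml(list(frame_size = ds$frame_size,
                        n_keypoints = ds$n_keypoints,
                        n_frames = length(ds$frames), seed = ds$seed,
                        generator = "finpose", format_version = 1L),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  labs <- utils::read.csv(file.path(dir, "labels.csv"))
  frames <- load_frames(file.path(dir, "frames"))
  kps <- lapply(seq_len(man$n_frames) - 1L, function(f) {
    sub <- labs[labs$frame == f, ]
    sub <- sub[order(sub$keypoint_index), ]
    unname(cbind(sub$x, sub$y))
  })
  structure(list(frames = frames, keypoints = kps,
                 n_keypoints = as.integer(man$n_keypoints),
                 frame_size = as.integer(man$frame_size),
                 seed = as.integer(man$seed)),
            class = "fp_dataset")
}

#' Trajectory script for a scripted movie
#'
#' Describes a fish that translates head-first during scheduled swim bouts and
#' performs scheduled body bends, on a fixed time base. Bout speed profiles
#' are half-sine pulses reaching the stated peak; bends are triangular pulses
#' of the rostral-caudal angle (the chord-based bend angle computed by
#' [rostral_caudal_angle()]), reaching the stated peak exactly at the stated
#' (frame-snapped) time. Bout and bend times are snapped to the frame grid so
#' the ground truth is exact.
#'
#' @param framerate Hz, > 0.
#' @param duration Seconds.
#' @param bout_schedule Data frame (or list of length-3 vectors) with columns
#'   `start` (s), `duration` (s), `peak_speed` (mm/s).
#' @param bend_schedule Data frame (or list of length-2 vectors) with columns
#'   `peak_time` (s), `peak_angle` (signed degrees, chord-based).
#' @param mm_per_px Spatial calibration, mm per pixel.
#' @param n_keypoints Keypoints of the ground truth (>= 3 when bends are
#'   scheduled, so the bend angle is defined).
#' @param body_length Pixels.
#' @param heading Travel direction, degrees.
#' @param start_xy Optional head start position (x, y) px; default centers the
#'   full path in the frame.
#' @param bend_duration_s Full width of each triangular bend pulse, seconds.
#' @return List of class `fp_script`.
#' @export
trajectory_script <- function(framerate, duration, bout_schedule = NULL,
                              bend_schedule = NULL, mm_per_px = 0.1,
                              n_keypoints = 7L, body_length = 80,
                              heading = 0, start_xy = NULL,
                              bend_duration_s = 0.08) {
  stopifnot(framerate > 0, duration > 0, mm_per_px > 0)
  check_n_keypoints(n_keypoints)
  bouts <- normalize_schedule(bout_schedule, c("start", "duration", "peak_speed"))
  bends <- normalize_schedule(bend_schedule, c("peak_time", "peak_angle"))
  if (nrow(bouts) && any(bouts$start < 0 | bouts$start + bouts$duration > duration)) {
    stop("bout_schedule events must lie within [0, duration]")
  }
  if (nrow(bends)) {
    if (any(bends$peak_time < 0 | bends$peak_time > duration)) {
      stop("bend_schedule events must lie within [0, duration]")
    }
    if (n_keypoints < 3) stop("bends require n_keypoints >= 3")
  }
  structure(list(framerate = framerate, duration = duration,
                 bout_schedule = bouts, bend_schedule = bends,
                 mm_per_px = mm_per_px, n_keypoints = as.integer(n_keypoints),
                 body_length = body_length, heading = heading,
                 start_xy = start_xy, bend_duration_s = bend_duration_s),
            class = "fp_script")
}

normalize_schedule <- function(x, cols) {
  if (is.null(x)) {
    return(stats::setNames(as.data.frame(matrix(numeric(0), 0, length(cols))), cols))
  }
  if (!is.data.frame(x)) x <- as.data.frame(do.call(rbind, x))
  names(x) <- cols
  x
}

#' Generate a scripted trajectory movie with exact ground truth
#'
#' The fish is anchored at its head (rostral) keypoint, which integrates the
#' scripted bout speed along `heading`; body bends swing the body around the
#' head without moving it, so the scripted speed is exactly the frame-to-frame
#' displacement of the reference keypoint. The returned ground truth contains
#' the per-frame keypoints, speeds and chord-based rostral-caudal angles
#' implied by the script.
#'
#' @param script A [trajectory_script()].
#' @param scene An [scene_spec()].
#' @param seed Integer seed (per-frame noise).
#' @param render If `FALSE`, skip image rendering and return `frames = NULL`
#'   (ground truth only).
#' @return List of class `fp_movie`: `frames` (list of matrices or NULL),
#'   `truth` (an [trajectory_series()]), `truth_table` (data frame: frame,
#'   time_s, x_i/y_i per keypoint, speed_mm_s, angle_deg).
#' @export
generate_trajectory_movie <- function(script, scene, seed = 1L, render = TRUE) {
  fr <- script$framerate
  n <- round(fr * script$duration)
  dt <- 1 / fr
  K <- script$n_keypoints
  sz <- scene$frame_size

  # scripted speed series (mm/s), frame-snapped half-sine bouts
  v <- numeric(n)
  bout_id <- rep(NA_integer_, n)
  bts <- script$bout_schedule
  for (b in seq_len(nrow(bts))) {
    i0 <- max(1L, round(bts$start[b] * fr)) # never frame 0: speed[1] is 0 by definition
    nb <- max(2L, round(bts$duration[b] * fr))
    idx <- i0:(min(n - 1L, i0 + nb - 1L))
    v[idx + 1L] <- bts$peak_speed[b] * sin(pi * (seq_along(idx) - 0.5) / nb)
    bout_id[idx + 1L] <- b
  }

  # scripted chord-based bend angle series (deg), frame-snapped triangles
  ang <- numeric(n)
  bds <- script$bend_schedule
  for (b in seq_len(nrow(bds))) {
    ip <- round(bds$peak_time[b] * fr)
    h <- max(1L, round(script$bend_duration_s * fr / 2))
    idx <- max(0L, ip - h):min(n - 1L, ip + h)
    pulse <- bds$peak_angle[b] * (1 - abs(idx - ip) / h)
    ang[idx + 1L] <- ang[idx + 1L] + pulse
  }

  # underlying arc curvature reproducing the chord angle for K keypoints
  chord_factor <- if (K >= 3) (K - 2) / (K - 1) else 1
  kappa <- ang / chord_factor

  # head path
  dir <- c(cos(script$heading * pi / 180), sin(script$heading * pi / 180))
  step_px <- v * dt / script$mm_per_px
  disp <- c(0, cumsum(step_px[-1]))
  start <- script$start_xy
  if (is.null(start)) {
    start <- c((sz - 1) / 2, (sz - 1) / 2) - dir * max(disp) / 2
  }
  heads <- cbind(start[1] + dir[1] * disp, start[2] + dir[2] * disp)

  # upfront feasibility: the swept path plus the body extent must fit
  body_margin <- script$body_length + 4
  if (max(disp) - min(disp) + 2 * body_margin > sz && nrow(bts)) {
    contrib <- vapply(seq_len(nrow(bts)), function(b) {
      sum(step_px[which(bout_id == b)])
    }, numeric(1))
    off <- which.max(contrib)
    stop(sprintf(
      "bout %d (start %.3f s, peak %.2f mm/s) drives the fish outside the frame (path span %.0f px exceeds the %d px frame)",
      off, bts$start[off], bts$peak_speed[off], max(disp) - min(disp), sz))
  }

  kps <- array(0, dim = c(n, K, 2))
  frames <- if (render) vector("list", n) else NULL
  seeds <- derive_seeds(seed, n)
  for (t in seq_len(n)) {
    pose <- pose_params(centroid = heads[t, ], heading = script$heading,
                        arc_curvature = kappa[t],
                        body_length = script$body_length, anchor = "head")
    ext <- midline_points(pose, 65L)
    m <- max(midline_halfwidth(pose, c(0, 1)))
    if (any(ext < m + 1) || any(ext > sz - 2 - m)) {
      off <- bout_id[t]
      if (!is.na(off)) {
        stop(sprintf(
          "bout %d (start %.3f s, peak %.2f mm/s) drives the fish outside the frame at t = %.3f s",
          off, bts$start[off], bts$peak_speed[off], (t - 1) * dt))
      }
      stop(sprintf("fish outside the frame at t = %.3f s", (t - 1) * dt))
    }
    kps[t, , ] <- pose_keypoints(pose, K)
    if (render) {
      frames[[t]] <- render_frame(pose, scene, rng_seed = seeds[t],
                                  n_keypoints = K)$image
    }
  }

  truth <- trajectory_series(keypoints = kps, framerate = fr,
                             mm_per_px = script$mm_per_px)
  tab <- data.frame(frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1L) * dt)
  for (k in seq_len(K)) {
    tab[[paste0("x_", k - 1L)]] <- kps[, k, 1]
    tab[[paste0("y_", k - 1L)]] <- kps[, k, 2]
  }
  tab$speed_mm_s <- v
  tab$angle_deg <- ang
  structure(list(frames = frames, truth = truth, truth_table = tab,
                 script = script, seed = as.integer(seed)),
            class = "fp_movie")
}

#' Write a scripted movie to disk
#'
#' Layout: `frames/NNNNNN.tiff` + `truth.csv`.
#'
#' @param movie An `fp_movie` with rendered frames.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_movie <- function(movie, dir) {
  if (is.null(movie$frames)) stop("movie has no rendered frames")
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(movie$frames)) {
    tiff::writeTIFF(movie$frames[[i]],
                    file.path(dir, "frames", sprintf("%06d.tiff", i - 1L)),
                    bits.per.sample = 16L)
  }
  utils::write.csv(movie$truth_table, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
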