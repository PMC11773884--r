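#' @title Workbench: I/O, multiwell ROIs, tracking, export
#' @description
#' Frame-sequence loading, regular ROI grids for multiwell plates (one animal
#' per ROI), movie tracking through a heatmap predictor with exact coordinate
#' mapping back to plate pixels, and export of per-animal kinematics tables,
#' event tables, trajectory plots and a machine-readable run summary.
#'
#' Coordinates are 0-based pixel centers, x right / y down, everywhere.
#' @name workbench
NULL

#' Load a frame sequence
#'
#' Reads a directory of lexicographically ordered PNG/TIFF frames into a list
#' of `H x W` matrices with values in `[0, 1]` (16-bit images scale to 1 at
#' full range). RGB frames are converted by luminance average with a warning.
#' Mixed frame sizes or unreadable files raise an error listing the offenders.
#' Video files are not decoded; extract frames to an image sequence first.
#'
#' @param path Directory of `.png` / `.tif(f)` files.
#' @return List of matrices.
#' @export
load_frames <- function(path) {
  if (!dir.exists(path)) {
    if (file.exists(path)) {
      stop("'", path, "' is a file; video decoding is not supported -- ",
           "provide a directory of PNG/TIFF frames")
    }
    stop("no such directory: ", path)
  }
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop("no PNG/TIFF frames found in ", path)
  bad <- character(0)
  frames <- vector("list", length(files))
  rgb_seen <- FALSE
  for (i in seq_along(files)) {
    img <- tryCatch({
      if (grepl("\\.png$", files[i], ignore.case = TRUE)) {
        png::readPNG(files[i])
      } else {
        tiff::readTIFF(files[i])
      }
    }, error = function(e) NULL)
    if (is.null(img)) { bad <- c(bad, files[i]); next }
    if (length(dim(img)) == 3) {
      rgb_seen <- TRUE
      img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
    }
    frames[[i]] <- img
  }
  if (length(bad)) stop("unreadable frames: ", paste(basename(bad), collapse = ", "))
  sizes <- vapply(frames, function(f) paste(dim(f), collapse = "x"), "")
  if (length(unique(sizes)) > 1) {
    off <- basename(files[sizes != sizes[1]])
    stop("mixed frame sizes: ", paste(off, collapse = ", "))
  }
  if (rgb_seen) warning("RGB frames converted to grayscale by luminance average")
  frames
}

#' Regular ROI grid for multiwell plates
#'
#' `rows * cols` equal, non-overlapping ROIs tiling `bounds` (the outer
#' rectangle of the well array), e.g. 4 x 6 for a 24-well plate. ROIs are
#' ordered row-major (left-to-right, top-to-bottom).
#'
#' @param rows,cols Grid dimensions.
#' @param bounds `c(x, y, width, height)` in plate pixels (0-based corner of
#'   the outer rectangle).
#' @param shape `"circle"` (wells) or `"square"`; metadata for plotting, the
#'   crop is always the bounding square/rectangle.
#' @return List of class `fp_roi_grid`.
#' @export
make_roi_grid <- function(rows, cols, bounds, shape = c("circle", "square")) {
  shape <- match.arg(shape)
  stopifnot(rows >= 1, cols >= 1, length(bounds) == 4, bounds[3] > 0, bounds[4] > 0)
  cw <- bounds[3] / cols
  ch <- bounds[4] / rows
  if (floor(cw) < 2 || floor(ch) < 2) stop("ROIs would be degenerate (overlap or < 2 px)")
  n <- rows * cols
  centers <- matrix(0, n, 2)
  offsets <- matrix(0L, n, 2)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    i <- (r - 1) * cols + c
    offsets[i, ] <- c(round(bounds[1] + (c - 1) * cw), round(bounds[2] + (r - 1) * ch))
    centers[i, ] <- offsets[i, ] + c(floor(cw), floor(ch)) / 2
  }
  structure(list(rows = rows, cols = cols, bounds = bounds, shape = shape,
                 roi_w = as.integer(floor(cw)), roi_h = as.integer(floor(ch)),
                 offsets = offsets, centers = centers, n = n),
            class = "fp_roi_grid")
}

#' Crop one ROI from a frame
#'
#' @param frame `H x W` matrix.
#' @param grid An [make_roi_grid()].
#' @param i ROI index (row-major).
#' @return List: `image` (the subframe) and `offset` (`c(x0, y0)` to add to
#'   ROI-local keypoints to obtain plate coordinates).
#' @export
crop_roi <- function(frame, grid, i) {
  stopifnot(i >= 1, i <= grid$n)
  off <- grid$offsets[i, ]
  if (off[1] + grid$roi_w > ncol(frame) || off[2] + grid$roi_h > nrow(frame)) {
    stop("ROI ", i, " exceeds the frame")
  }
  list(image = frame[off[2] + seq_len(grid$roi_h), off[1] + seq_len(grid$roi_w)],
       offset = off)
}

# letterbox an image into (h, w): isotropic resize + centered padding.
# returns image, scale s and integer pads; coordinate map is
# x_net = s*x + (s-1)/2 + px (same for y)
letterbox <- function(img, h, w, fill = stats::median(img)) {
  s <- min(h / nrow(img), w / ncol(img))
  ho <- round(s * nrow(img)); wo <- round(s * ncol(img))
  py <- (h - ho) %/% 2L; px <- (w - wo) %/% 2L
  A <- aff_translate((s - 1) / 2, (s - 1) / 2) %*% aff_scale(s)
  resized <- warp_bilinear(img, solve(A), out_dim = c(ho, wo), fill = fill)
  out <- matrix(fill, h, w)
  out[py + seq_len(ho), px + seq_len(wo)] <- resized
  list(image = out, scale = s, pad = c(px, py))
}

letterbox_to_plate <- function(coords, lb, offset) {
  xy <- sweep(coords, 2, lb$pad)
  xy <- (xy - (lb$scale - 1) / 2) / lb$scale
  sweep(xy, 2, offset, `+`)
}

#' Track a movie through a heatmap predictor
#'
#' For every frame and ROI: crop, letterbox to the predictor's input size
#' (aspect preserved, median fill), optionally standardize, run
#' [predict_heatmaps()], decode, and map the keypoints back through the
#' letterbox and ROI offset to plate pixel coordinates. Confidences (channel
#' peak values) are retained.
#'
#' @param frames List of plate-sized matrices.
#' @param net A predictor with a [predict_heatmaps()] method and a `cfg`
#'   holding `H`, `W`, `O`.
#' @param grid An [make_roi_grid()]; use `rows = 1, cols = 1` with bounds
#'   covering the frame for single-well recordings.
#' @param framerate,mm_per_px Time base and spatial calibration for the
#'   returned trajectories.
#' @param stats Optional `fp_split_stats` used to standardize inputs (use the
#'   statistics the network was trained with; omit for predictors that expect
#'   raw intensities).
#' @param n_keypoints Expected keypoint count; must match the predictor's
#'   output channels.
#' @param batch_size Frames per forward pass.
#' @return List of `n` [trajectory_series()] (one per ROI), each with a
#'   `confidence` matrix.
#' @export
track_movie <- function(frames, net, grid, framerate, mm_per_px,
                        stats = NULL, n_keypoints = net$cfg$O,
                        batch_size = 8L) {
  cfg <- net$cfg
  if (n_keypoints != cfg$O) {
    stop("predictor outputs ", cfg$O, " keypoints but ", n_keypoints,
         " were requested")
  }
  nf <- length(frames)
  out <- vector("list", grid$n)
  for (roi in seq_len(grid$n)) {
    kps <- array(0, c(nf, cfg$O, 2))
    conf <- matrix(0, nf, cfg$O)
    for (start in seq(1L, nf, by = batch_size)) {
      idx <- start:min(nf, start + batch_size - 1L)
      lbs <- vector("list", length(idx))
      x <- array(0, c(cfg$I, cfg$H, cfg$W, length(idx)))
      for (b in seq_along(idx)) {
        cr <- crop_roi(frames[[idx[b]]], grid, roi)
        lb <- letterbox(cr$image, cfg$H, cfg$W)
        img <- lb$image
        if (!is.null(stats)) img <- standardize(img, stats)
        x[1, , , b] <- img
        lbs[[b]] <- list(lb = lb, offset = cr$offset)
      }
      y <- predict_heatmaps(net, x)
      for (b in seq_along(idx)) {
        dec <- decode_heatmaps(output_to_heatmaps(y, b))
        kps[idx[b], , ] <- letterbox_to_plate(dec$coords, lbs[[b]]$lb,
                                              lbs[[b]]$offset)
        conf[idx[b], ] <- dec$confidence
      }
    }
    out[[roi]] <- trajectory_series(kps, framerate, mm_per_px,
                                    confidence = conf)
  }
  out
}

#' Bundle an analysis run
#'
#' @param trajectories List of [trajectory_series()] (one per ROI).
#' @param kcfg An [kinematic_config()].
#' @param seed Seed used for the run.
#' @param config Arbitrary configuration echo for the run summary.
#' @return List of class `fp_analysis_run`.
#' @export
analysis_run <- function(trajectories, kcfg = kinematic_config(), seed = NA,
                         config = list()) {
  structure(list(trajectories = trajectories, kcfg = kcfg, seed = seed,
                 config = config),
            class = "fp_analysis_run")
}

#' Export per-animal outputs
#'
#' Writes, per ROI: the kinematics table (`roi_NN_trajectory.csv`), bout and
#' bend event tables (`roi_NN_bouts.csv`, `roi_NN_bends.csv`), a trajectory
#' plot (`roi_NN_trajectory.png`), and one machine-readable run summary
#' (`run_summary.json`) echoing the configuration, seed, config hash and
#' package version. Floats are written at full precision.
#'
#' @param run An [analysis_run()].
#' @param outdir Output directory (created if missing).
#' @return Invisible character vector of written files.
#' @export
export_outputs <- function(run, outdir) {
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  written <- character(0)
  wcsv <- function(d, f) {
    p <- file.path(outdir, f)
    utils::write.csv(d, p, row.names = FALSE)
    written <<- c(written, p)
  }
  for (i in seq_along(run$trajectories)) {
    tr <- run$trajectories[[i]]
    tag <- sprintf("roi_%02d", i)
    tab <- kinematics_table(tr, run$kcfg)
    wcsv(tab, paste0(tag, "_trajectory.csv"))
    speed <- compute_speed(tr, run$kcfg)
    wcsv(detect_bouts(speed, tr$framerate, run$kcfg), paste0(tag, "_bouts.csv"))
    ang <- tab$rostral_caudal_angle_deg
    if (!all(is.na(ang))) {
      wcsv(detect_bends(ang, tr$framerate, run$kcfg)$events,
           paste0(tag, "_bends.csv"))
    }
    p <- file.path(outdir, paste0(tag, "_trajectory.png"))
    grDevices::png(p, width = 600, height = 600)
    plot_trajectory(tr, run$kcfg, main = tag)
    grDevices::dev.off()
    written <- c(written, p)
  }
  summary_path <- file.path(outdir, "run_summary.json")
  jsonlite::write_json(list(
    seed = run$seed,
    config = run$config,
    kinematic_config = unclass(run$kcfg),
    config_hash = config_hash(list(run$config, unclass(run$kcfg))),
    package = "finpose",
    version = as.character(utils::packageVersion("finpose")),
    n_rois = length(run$trajectories)),
    summary_path, auto_unbox = TRUE, digits = NA, null = "null")
  written <- c(written, summary_path)
  invisible(written)
}

#' Trajectory plot
#'
#' Path of the reference keypoint colored by time.
#'
#' @param traj An [trajectory_series()].
#' @param kcfg An [kinematic_config()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_trajectory <- function(traj, kcfg = kinematic_config(), ...) {
  p <- traj$keypoints[, kcfg$reference_keypoint, ]
  n <- nrow(p)
  cols <- grDevices::hcl.colors(max(n - 1, 1), "viridis")
  graphics::plot(p[, 1], p[, 2], type = "n", asp = 1, xlab = "x (px)",
                 ylab = "y (px)", ylim = rev(range(p[, 2])), ...)
  if (n > 1) {
    graphics::segments(p[-n, 1], p[-n, 2], p[-1, 1], p[-1, 2], col = cols)
  } else {
    graphics::points(p[, 1], p[, 2])
  }
  invisible(traj)
}
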