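#' @title Keypoint/heatmap codec
#' @description
#' Conversion between keypoint coordinates and per-keypoint Gaussian target
#' heatmaps, plus prediction scoring (PCK and relative accuracy).
#'
#' Coordinate conventions used throughout the package: coordinates are 0-based
#' pixel centers with x increasing rightwards (columns) and y increasing
#' downwards (rows). Images are `H x W` matrices indexed `[row, col]`, i.e.
#' `img[y + 1, x + 1]`. Heatmaps live at half the input resolution; the input
#' pixel `x` maps to heatmap coordinate `x/2 - 0.25` (the center of a heatmap
#' pixel is the mean of the centers of the two input pixels it covers), and the
#' inverse map is `2*h + 0.5`.
#' @name codec
NULL

#' Codec configuration
#'
#' @param sigma Gaussian standard deviation of the target blobs, in heatmap
#'   pixels. Default 2.
#' @param wiggle_sd Standard deviation of the label jitter ("wiggle") applied
#'   to the target center during training-target generation, in input pixels.
#'   The image itself is never touched. Default 0.5.
#' @param correctness_radius Radius (input pixels) within which a prediction
#'   counts as correct for [pck()]. The radii used for the reference datasets
#'   are 3 px (7-keypoint touch-evoked data) and 1.5 px (single-keypoint
#'   visuomotor data); both are interpreted as input-image pixels.
#' @return A list of class `fp_codec_config`.
#' @export
codec_config <- function(sigma = 2, wiggle_sd = 0.5, correctness_radius = 3) {
  stopifnot(sigma > 0, wiggle_sd >= 0, correctness_radius > 0)
  structure(list(sigma = sigma, wiggle_sd = wiggle_sd,
                 correctness_radius = correctness_radius),
            class = "fp_codec_config")
}

# input-pixel coordinate -> heatmap coordinate (0-based pixel centers, 2x scale)
input_to_heatmap <- function(z) z / 2 - 0.25

# heatmap coordinate -> input-pixel coordinate
heatmap_to_input <- function(z) 2 * z + 0.5

#' Encode keypoints as Gaussian target heatmaps
#'
#' Each channel holds `exp(-d^2 / (2 * sigma^2))` where `d` is the distance (in
#' heatmap pixels) from the pixel center to the keypoint mapped into heatmap
#' coordinates. When the keypoint center coincides with a heatmap pixel center
#' the channel maximum is exactly 1.
#'
#' @param kp K x 2 matrix of (x, y) keypoint coordinates in input pixels.
#' @param heatmap_shape Integer `c(Hh, Wh)`: heatmap grid size (half the input
#'   resolution).
#' @param cfg A [codec_config()].
#' @param rng Optional function `function(n)` returning `n` standard-normal
#'   draws; when supplied, isotropic Gaussian wiggle of SD `cfg$wiggle_sd`
#'   (input px) is added to the target centers before encoding. With
#'   `wiggle_sd = 0` the output is identical to the rng-free call.
#' @return Array `(Hh, Wh, K)` of class `fp_heatmaps` with attribute
#'   `scale = 2`.
#' @export
encode_targets <- function(kp, heatmap_shape, cfg = codec_config(), rng = NULL) {
  kp <- as_keypoint_matrix(kp)
  stopifnot(length(heatmap_shape) == 2, all(heatmap_shape >= 1))
  K <- nrow(kp)
  hh <- heatmap_shape[1]; wh <- heatmap_shape[2]
  if (!is.null(rng) && cfg$wiggle_sd > 0) {
    kp <- kp + matrix(rng(2L * K), ncol = 2) * cfg$wiggle_sd
  }
  hx <- input_to_heatmap(kp[, 1])
  hy <- input_to_heatmap(kp[, 2])
  xs <- seq_len(wh) - 1
  ys <- seq_len(hh) - 1
  hm <- array(0, dim = c(hh, wh, K))
  inv2s2 <- 1 / (2 * cfg$sigma^2)
  for (k in seq_len(K)) {
    dy2 <- (ys - hy[k])^2
    dx2 <- (xs - hx[k])^2
    hm[, , k] <- exp(-outer(dy2, dx2, `+`) * inv2s2)
  }
  structure(hm, scale = 2, class = c("fp_heatmaps", "array"))
}

#' Decode heatmaps to keypoints
#'
#' Per channel, the global maximum is located (ties broken by the lowest
#' row-major index, rows scanned first) and refined to subpixel precision by an
#' intensity-weighted centroid over the 3x3 neighborhood (clipped at borders)
#' after subtracting the neighborhood minimum as a local baseline -- without
#' baseline removal the flat shoulders of wide Gaussians bias the centroid
#' toward the peak pixel by more than half an input pixel. The refined
#' position is mapped back to input-pixel coordinates. The channel peak value is
#' returned as the confidence. An all-zero channel is flagged undetected:
#' confidence 0 and coordinates at heatmap pixel (0, 0).
#'
#' @param hm Array `(Hh, Wh, K)` of finite values (negative values are treated
#'   as 0 for the centroid weights).
#' @return List with `coords` (K x 2 input-pixel matrix) and `confidence`
#'   (length-K numeric).
#' @export
decode_heatmaps <- function(hm) {
  stopifnot(is.array(hm), length(dim(hm)) == 3, all(is.finite(hm)))
  hh <- dim(hm)[1]; wh <- dim(hm)[2]; K <- dim(hm)[3]
  coords <- matrix(0, K, 2)
  conf <- numeric(K)
  for (k in seq_len(K)) {
    ch <- hm[, , k]
    peak <- max(ch)
    if (peak <= 0) { # undetected
      coords[k, ] <- heatmap_to_input(c(0, 0))
      conf[k] <- 0
      next
    }
    hits <- which(ch == peak, arr.ind = TRUE) # (row, col), 1-based
    rowmajor <- (hits[, 1] - 1) * wh + (hits[, 2] - 1)
    best <- hits[which.min(rowmajor), , drop = TRUE]
    r0 <- best[1]; c0 <- best[2]
    rs <- max(1, r0 - 1):min(hh, r0 + 1)
    cs <- max(1, c0 - 1):min(wh, c0 + 1)
    w <- pmax(ch[rs, cs, drop = FALSE], 0)
    w <- w - min(w) # local baseline removal; see Description
    sw <- sum(w)
    if (sw <= 0) { # perfectly flat neighborhood: keep the argmax pixel
      coords[k, ] <- heatmap_to_input(c(c0 - 1, r0 - 1))
      conf[k] <- peak
      next
    }
    cy <- sum(w * (rs - 1)) / sw
    cx <- sum(t(w) * (cs - 1)) / sw
    coords[k, ] <- heatmap_to_input(c(cx, cy))
    conf[k] <- peak
  }
  list(coords = coords, confidence = conf)
}

#' Percentage of correct keypoints (PCK)
#'
#' Fraction of keypoints whose Euclidean error is strictly below `radius`
#' (input pixels). Predictions and ground truth are given as lists of K x 2
#' matrices (one per frame) or single matrices.
#'
#' @param pred,truth Keypoints: a K x 2 matrix or a list of them.
#' @param radius Correctness radius in input pixels.
#' @return Fraction in `[0, 1]`.
#' @export
pck <- function(pred, truth, radius) {
  pred <- as_keypoint_list(pred)
  truth <- as_keypoint_list(truth)
  if (length(pred) != length(truth)) {
    stop("pck: prediction and truth sequences differ in length (",
         length(pred), " vs ", length(truth), ")")
  }
  err <- unlist(Map(function(p, t) {
    p <- as_keypoint_matrix(p); t <- as_keypoint_matrix(t)
    if (nrow(p) != nrow(t)) stop("pck: keypoint count mismatch within a frame")
    sqrt(rowSums((p - t)^2))
  }, pred, truth))
  mean(err < radius)
}

#' Relative accuracy of an ablated model
#'
#' Ratio of correctly predicted keypoints for a model trained on an ablated
#' training split to the number correct when all training data is available.
#'
#' @param correct_ablated,correct_full Counts of correct keypoints.
#' @return `correct_ablated / correct_full`.
#' @export
relative_accuracy <- function(correct_ablated, correct_full) {
  if (correct_full <= 0) {
    stop("relative_accuracy: undefined when the full-data model has 0 correct keypoints")
  }
  correct_ablated / correct_full
}

# ---- internal keypoint coercion helpers ----

as_keypoint_matrix <- function(kp) {
  if (is.data.frame(kp)) kp <- as.matrix(kp[, c("x", "y")])
  if (is.null(dim(kp))) kp <- matrix(kp, ncol = 2)
  stopifnot(ncol(kp) == 2, all(is.finite(kp)))
  kp
}

as_keypoint_list <- function(kp) {
  if (is.list(kp) && !is.data.frame(kp)) kp else list(kp)
}
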