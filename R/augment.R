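#' @title Label-consistent augmentation and dataset standardization
#' @description
#' On-the-fly training augmentation: photometric jitter (gamma, brightness),
#' a single composed geometric affine (resize, flips, rotation, pad/crop
#' translation) applied identically to the image (bilinear) and the keypoints
#' (exact), then standardization with training-split statistics and finally
#' Gaussian pixel noise. Validation frames receive standardization only.
#' @name augmentation
NULL

#' Augmentation configuration
#'
#' All ranges contain the identity. Magnitudes default to values plausible for
#' well-plate recordings: fish orientation in a well is unconstrained, so
#' rotation spans the full circle.
#'
#' @param gamma_range Gamma exponent range (log-uniform draw).
#' @param brightness_range Additive brightness range (intensity fraction).
#' @param resize_range Isotropic scale-factor range.
#' @param rotate_range Rotation range, degrees.
#' @param pad_crop_max Maximum pad/crop translation, fraction of the side.
#' @param flip_prob Per-axis flip probability.
#' @param noise_sd Gaussian noise SD added after standardization (in
#'   standardized units).
#' @param enabled Master switch; when `FALSE`, [augment_pair()] applies
#'   standardization only.
#' @return List of class `fp_augment_config`.
#' @export
augment_config <- function(gamma_range = c(0.75, 1.33),
                           brightness_range = c(-0.1, 0.1),
                           resize_range = c(0.9, 1.1),
                           rotate_range = c(0, 360),
                           pad_crop_max = 0.05,
                           flip_prob = 0.5,
                           noise_sd = 0.05,
                           enabled = TRUE) {
  stopifnot(gamma_range[1] <= 1, gamma_range[2] >= 1,
            brightness_range[1] <= 0, brightness_range[2] >= 0,
            resize_range[1] <= 1, resize_range[2] >= 1,
            flip_prob >= 0, flip_prob <= 1, pad_crop_max >= 0, noise_sd >= 0)
  structure(as.list(environment()), class = "fp_augment_config")
}

#' Split a dataset into training and validation
#'
#' Seeded shuffle, then the first `round(n * train_fraction)` frames form the
#' training split and the remainder the validation split (disjoint and
#' exhaustive).
#'
#' @param ds An `fp_dataset`.
#' @param train_fraction Fraction in (0, 1); default 0.75 (a 75/25 split).
#' @param seed Integer seed.
#' @return List with `train` and `val`, both `fp_dataset`s.
#' @export
split_dataset <- function(ds, train_fraction = 0.75, seed = 1L) {
  n <- length(ds$frames)
  stopifnot(n >= 1)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  perm <- with_seed(seed, function() sample.int(n))
  ntr <- round(n * train_fraction)
  take <- function(idx) {
    out <- ds
    out$frames <- ds$frames[idx]
    out$keypoints <- ds$keypoints[idx]
    out
  }
  list(train = take(perm[seq_len(ntr)]),
       val = take(perm[setdiff(seq_len(n), seq_len(ntr))]))
}

#' Pooled pixel statistics of the training split
#'
#' Mean and SD pooled over every pixel of every training image (the
#' validation split is excluded by construction: pass only the training
#' split). SD uses the population (1/n) convention so that a standardized
#' stack has SD exactly 1.
#'
#' @param train An `fp_dataset` (training split).
#' @return List of class `fp_split_stats` with `mean` and `sd`.
#' @export
compute_split_stats <- function(train) {
  stopifnot(length(train$frames) >= 1)
  px <- unlist(train$frames, use.names = FALSE)
  m <- mean(px)
  s <- sqrt(mean((px - m)^2))
  if (s <= 0) stop("training split has zero pixel variance (constant images)")
  structure(list(mean = m, sd = s), class = "fp_split_stats")
}

#' Standardize an image with training-split statistics
#'
#' @param img Matrix.
#' @param stats An `fp_split_stats`.
#' @return `(img - mean) / sd`.
#' @export
standardize <- function(img, stats) (img - stats$mean) / stats$sd

# 3x3 affine helpers (0-based pixel-center coordinates)
aff_identity <- function() diag(3)
aff_translate <- function(tx, ty) matrix(c(1, 0, 0, 0, 1, 0, tx, ty, 1), 3)
aff_scale <- function(s) diag(c(s, s, 1))
aff_rotate <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
}
aff_flip <- function(fx, fy) diag(c(if (fx) -1 else 1, if (fy) -1 else 1, 1))

# apply a 3x3 affine to an n x 2 coordinate matrix
apply_affine <- function(A, xy) {
  out <- cbind(xy, 1) %*% t(A)
  out[, 1:2, drop = FALSE]
}

# memoized output-pixel grids for the bilinear warp
.warp_grids <- new.env(parent = emptyenv())

warp_grid <- function(ho, wo) {
  key <- paste0(ho, "x", wo)
  g <- .warp_grids[[key]]
  if (is.null(g)) {
    g <- cbind(rep(0:(wo - 1), each = ho), rep(0:(ho - 1), times = wo))
    .warp_grids[[key]] <- g
  }
  g
}

# bilinear warp: output pixel (x, y) sampled at Ainv %*% (x, y);
# out-of-range samples take `fill`
warp_bilinear <- function(img, Ainv, out_dim = dim(img), fill = stats::median(img)) {
  ho <- out_dim[1]; wo <- out_dim[2]
  h <- nrow(img); w <- ncol(img)
  src <- apply_affine(Ainv, warp_grid(ho, wo))
  x <- src[, 1]; y <- src[, 2]
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  inside <- x0 >= -1 & x0 <= w - 1 & y0 >= -1 & y0 <= h - 1
  gx0 <- pmin(pmax(x0, 0), w - 1); gx1 <- pmin(pmax(x0 + 1, 0), w - 1)
  gy0 <- pmin(pmax(y0, 0), h - 1); gy1 <- pmin(pmax(y0 + 1, 0), h - 1)
  # weights of clamped taps: taps outside the frame get weight on the fill
  in0x <- (x0 >= 0); in1x <- (x0 < w - 1)
  in0y <- (y0 >= 0); in1y <- (y0 < h - 1)
  wx0 <- (1 - fx) * in0x + fx * (1 - in0x)
  wx1 <- fx * in0x * in1x
  wy0 <- (1 - fy) * in0y + fy * (1 - in0y)
  wy1 <- fy * in0y * in1y
  at <- function(gy, gx) img[gy + gx * h + 1L]
  val <- wy0 * (wx0 * at(gy0, gx0) + wx1 * at(gy0, gx1)) +
         wy1 * (wx0 * at(gy1, gx0) + wx1 * at(gy1, gx1))
  wsum <- (wx0 + wx1) * (wy0 + wy1)
  val <- val + (1 - wsum) * fill
  val[!inside] <- fill
  matrix(val, ho, wo)
}

#' Augment one labeled frame
#'
#' Composition order is fixed: photometric (gamma, brightness) -> geometric
#' (one composed affine: resize, flips, rotation, pad/crop translation) ->
#' standardization -> Gaussian noise. Photometric operations leave keypoints
#' untouched; the geometric affine transforms keypoints exactly. If a drawn
#' transform pushes every keypoint outside the frame it is resampled (up to 20
#' retries), then an error is raised. With `cfg$enabled = FALSE` the frame is
#' standardized only (the validation path).
#'
#' @param frame List with `image` (H x W matrix) and `keypoints` (K x 2).
#' @param cfg An [augment_config()].
#' @param stats An `fp_split_stats` from [compute_split_stats()].
#' @return List with `image` (standardized, same size) and `keypoints`.
#' @export
augment_pair <- function(frame, cfg, stats) {
  img <- frame$image
  kp <- as_keypoint_matrix(frame$keypoints)
  h <- nrow(img); w <- ncol(img)

  if (cfg$enabled) {
    gam <- exp(stats::runif(1, log(cfg$gamma_range[1]), log(cfg$gamma_range[2])))
    bri <- stats::runif(1, cfg$brightness_range[1], cfg$brightness_range[2])
    img <- clamp01(pmax(img, 0)^gam + bri)

    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    for (try in 1:20) {
      s <- stats::runif(1, cfg$resize_range[1], cfg$resize_range[2])
      th <- stats::runif(1, cfg$rotate_range[1], cfg$rotate_range[2])
      fx <- stats::runif(1) < cfg$flip_prob
      fy <- stats::runif(1) < cfg$flip_prob
      tx <- stats::runif(1, -1, 1) * cfg$pad_crop_max * w
      ty <- stats::runif(1, -1, 1) * cfg$pad_crop_max * h
      A <- aff_translate(cx + tx, cy + ty) %*% aff_rotate(th) %*%
        aff_flip(fx, fy) %*% aff_scale(s) %*% aff_translate(-cx, -cy)
      kp2 <- apply_affine(A, kp)
      ok <- kp2[, 1] >= 0 & kp2[, 1] <= w - 1 & kp2[, 2] >= 0 & kp2[, 2] <= h - 1
      if (any(ok)) {
        img <- warp_bilinear(img, solve(A))
        kp <- kp2
        break
      }
      if (try == 20) stop("augmentation failed: no transform kept a keypoint in frame")
    }
  }

  img <- standardize(img, stats)
  if (cfg$enabled && cfg$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(h * w, 0, cfg$noise_sd), h, w)
  }
  list(image = img, keypoints = kp)
}
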