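#' @title Pose network architectures
#' @description
#' Two macro-architectures for heatmap keypoint regression. The isotropic
#' network patchifies the input with an 8x8 pixel unshuffle and processes it at
#' a single internal resolution with N inverted-bottleneck residual blocks; the
#' outro expands channels 2x, applies hard swish and spatial dropout, projects
#' to 16x the keypoint count and restores resolution with a 4x4 pixel shuffle,
#' yielding heatmaps at half the input resolution. The hierarchical variant is
#' a conventional strided encoder-decoder with the residual blocks at its
#' smallest (1/8) resolution. The residual block comes in two flavors: the
#' MobileNetV3 inverted bottleneck (three normalizations, two hard swishes,
#' squeeze-and-excitation) and a slimmed variant keeping exactly one
#' normalization and one hard swish.
#' @name network
NULL

#' Network configuration
#'
#' @param H,W Input height/width, px; must be divisible by `patch` (isotropic)
#'   or 8 (hierarchical).
#' @param I Input channels (1 for grayscale).
#' @param M Middle channels (channel count at the smallest internal
#'   resolution).
#' @param O Output channels = number of keypoints.
#' @param N Number of residual blocks.
#' @param E Channel expansion ratio inside the residual block. Default 2.
#' @param patch Intro patch size of the isotropic network. Default 8.
#' @param kernel Depthwise kernel size, one of 3, 5, 7. Default 3.
#' @param norm Normalization: `"instance"` (default), `"batch"`, `"layer"`,
#'   or `"group"`.
#' @param variant Residual block flavor: `"slim"` (default) or `"mnv3"`.
#' @param macro `"isotropic"` (default) or `"hierarchical"`.
#' @param drop_prob Spatial dropout probability in the outro. Default 0.05.
#' @param norm_eps Normalization epsilon. Default 1e-3.
#' @param bn_momentum Batch-norm running-stat momentum (decay of the running
#'   value). Default 0.9.
#' @param slim_norm Which normalization the slim block keeps: after the
#'   `"expand"`, `"dw"` (default) or `"project"` convolution.
#' @param slim_act Which hard swish the slim block keeps: after `"expand"`
#'   (default) or `"dw"`.
#' @param se_reduction Squeeze-excitation channel reduction. Default 4.
#' @param groups Group count for group normalization. Default 8.
#' @return List of class `fp_network_config`.
#' @export
network_config <- function(H = 512, W = H, I = 1, M = 32, O = 7, N = 10,
                           E = 2, patch = 8, kernel = 3,
                           norm = c("instance", "batch", "layer", "group"),
                           variant = c("slim", "mnv3"),
                           macro = c("isotropic", "hierarchical"),
                           drop_prob = 0.05, norm_eps = 1e-3,
                           bn_momentum = 0.9,
                           slim_norm = c("dw", "expand", "project"),
                           slim_act = c("expand", "dw"),
                           se_reduction = 4, groups = 8) {
  norm <- match.arg(norm)
  variant <- match.arg(variant)
  macro <- match.arg(macro)
  slim_norm <- match.arg(slim_norm)
  slim_act <- match.arg(slim_act)
  stopifnot(kernel %in% c(3, 5, 7), N >= 1, M >= 1, O >= 1, I >= 1, E >= 1)
  if (macro == "isotropic" && (H %% patch != 0 || W %% patch != 0)) {
    stop("input size must be divisible by the patch size (", patch, ")")
  }
  if (macro == "isotropic" && patch %% 2 != 0) {
    stop("isotropic patch size must be even (the outro upsamples by patch/2)")
  }
  if (macro == "hierarchical" && (H %% 8 != 0 || W %% 8 != 0 || M %% 4 != 0)) {
    stop("hierarchical networks need H, W divisible by 8 and M divisible by 4")
  }
  structure(list(H = as.integer(H), W = as.integer(W), I = as.integer(I),
                 M = as.integer(M), O = as.integer(O), N = as.integer(N),
                 E = as.numeric(E), patch = as.integer(patch),
                 kernel = as.integer(kernel),
                 norm = norm, variant = variant, macro = macro,
                 drop_prob = drop_prob, norm_eps = norm_eps,
                 bn_momentum = bn_momentum, slim_norm = slim_norm,
                 slim_act = slim_act, se_reduction = as.numeric(se_reduction),
                 groups = as.numeric(groups)),
            class = "fp_network_config")
}

#' Reference presets
#'
#' `preset_touch()`: 512x512 input, 32 middle channels, 7 keypoints, 10
#' blocks -- the high-resolution, many-keypoint configuration for
#' touch-evoked escape recordings. `preset_visuomotor()`: 256x256 input, 16
#' middle channels, 1 keypoint, 10 blocks -- the multiwell visuomotor
#' configuration.
#'
#' @param ... Overrides forwarded to [network_config()].
#' @return An `fp_network_config`.
#' @export
preset_touch <- function(...) {
  network_config(H = 512, W = 512, I = 1, M = 32, O = 7, N = 10, ...)
}

#' @rdname preset_touch
#' @export
preset_visuomotor <- function(...) {
  network_config(H = 256, W = 256, I = 1, M = 16, O = 1, N = 10, ...)
}

# one residual block per the configured flavor
build_block <- function(cfg) {
  M <- cfg$M; EM <- as.integer(round(cfg$E * cfg$M))
  nrm <- function(ch) l_norm(ch, cfg$norm, cfg$norm_eps, cfg$bn_momentum, cfg$groups)
  body <- list()
  add <- function(b, x) c(b, list(x))
  if (cfg$variant == "mnv3") {
    body <- add(body, l_conv1x1(M, EM, gain = sqrt(2)))
    body <- add(body, nrm(EM))
    body <- add(body, l_act("hswish"))
    body <- add(body, l_dwconv(EM, cfg$kernel, gain = sqrt(2)))
    body <- add(body, nrm(EM))
    body <- add(body, l_act("hswish"))
    body <- add(body, l_se(EM, cfg$se_reduction))
    body <- add(body, l_conv1x1(EM, M, gain = 1, scale = 1 / sqrt(cfg$N)))
    body <- add(body, nrm(M))
  } else {
    expand_gain <- if (cfg$slim_act == "expand") sqrt(2) else 1
    dw_gain <- if (cfg$slim_act == "dw") sqrt(2) else 1
    body <- add(body, l_conv1x1(M, EM, gain = expand_gain))
    if (cfg$slim_norm == "expand") body <- add(body, nrm(EM))
    if (cfg$slim_act == "expand") body <- add(body, l_act("hswish"))
    body <- add(body, l_dwconv(EM, cfg$kernel, gain = dw_gain))
    if (cfg$slim_norm == "dw") body <- add(body, nrm(EM))
    if (cfg$slim_act == "dw") body <- add(body, l_act("hswish"))
    body <- add(body, l_se(EM, cfg$se_reduction))
    body <- add(body, l_conv1x1(EM, M, gain = 1, scale = 1 / sqrt(cfg$N)))
    if (cfg$slim_norm == "project") body <- add(body, nrm(M))
  }
  l_residual(body)
}

#' Build a pose network
#'
#' Composable forward map from `(batch, I, H, W)` inputs to
#' `(batch, O, H/2, W/2)` heatmap stacks. Weights are allocated but not
#' initialized; call [init_weights()].
#'
#' @param cfg An [network_config()].
#' @return List of class `fp_network` with elements `cfg` and `layers`.
#' @export
build_network <- function(cfg) {
  nrm <- function(ch) l_norm(ch, cfg$norm, cfg$norm_eps, cfg$bn_momentum, cfg$groups)
  layers <- list()
  add <- function(x) layers[[length(layers) + 1L]] <<- x
  if (cfg$macro == "isotropic") {
    p <- cfg$patch
    add(l_pixel_unshuffle(p))
    add(l_conv1x1(cfg$I * p * p, cfg$M, gain = 1))
    add(nrm(cfg$M))
    for (i in seq_len(cfg$N)) add(build_block(cfg))
    EM <- as.integer(round(cfg$E * cfg$M))
    add(l_conv1x1(cfg$M, EM, gain = sqrt(2)))
    add(l_act("hswish"))
    add(l_dropout(cfg$drop_prob))
    up <- cfg$patch %/% 2L # 4 for the reference 8x8 patches
    add(l_conv1x1(EM, up * up * cfg$O, zero = TRUE))
    add(l_pixel_shuffle(up))
  } else {
    M <- cfg$M; M2 <- M %/% 2L; M4 <- M %/% 4L
    add(l_conv(cfg$I, M4, k = 4, stride = 2, pad = 1, gain = 1))
    add(nrm(M4))
    add(l_conv(M4, M2, k = 2, stride = 2, pad = 0, gain = 1))
    add(nrm(M2))
    add(l_conv(M2, M, k = 2, stride = 2, pad = 0, gain = 1))
    add(nrm(M))
    for (i in seq_len(cfg$N)) add(build_block(cfg))
    add(l_tconv2(M, M2, gain = 1))
    add(nrm(M2))
    add(l_tconv2(M2, M4, gain = 1))
    add(nrm(M4))
    add(l_conv1x1(M4, M2, gain = sqrt(2)))
    add(l_act("hswish"))
    add(l_dropout(cfg$drop_prob))
    add(l_conv1x1(M2, cfg$O, zero = TRUE))
  }
  structure(list(cfg = cfg, layers = layers), class = "fp_network")
}

#' @export
print.fp_network <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<fp_network> %s/%s: %dx%dx%d -> %dx%dx%d, M=%d, N=%d, norm=%s\n",
              cfg$macro, cfg$variant, cfg$I, cfg$H, cfg$W,
              cfg$O, cfg$H %/% 2L, cfg$W %/% 2L, cfg$M, cfg$N, cfg$norm))
  cat(sprintf("  trainable parameters: %d\n", count_parameters(x)))
  invisible(x)
}

# coerce frames (matrix / list of matrices / array) to a (I, H, W, N) batch
as_input_batch <- function(x, I = 1L) {
  if (is.matrix(x)) x <- list(x)
  if (is.list(x)) {
    h <- nrow(x[[1]]); w <- ncol(x[[1]])
    out <- array(0, c(I, h, w, length(x)))
    for (i in seq_along(x)) out[1, , , i] <- x[[i]]
    return(out)
  }
  stopifnot(is.array(x), length(dim(x)) == 4)
  x
}

#' Forward pass
#'
#' @param net An initialized `fp_network`.
#' @param x Input batch: `(I, H, W, N)` array, an `H x W` matrix, or a list of
#'   matrices.
#' @param training Logical: training mode (dropout active, batch statistics
#'   used and updated by batch normalization).
#' @return For `net_forward`: list with `y` (`(O, H/2, W/2, N)` array),
#'   `caches`, and `net` (updated running statistics). For
#'   `predict_heatmaps`: the output array only (evaluation mode).
#' @export
net_forward <- function(net, x, training = FALSE) {
  x <- as_input_batch(x, net$cfg$I)
  r <- forward_layers(net$layers, x, training)
  net$layers <- r$layers
  list(y = r$y, caches = r$caches, net = net)
}

#' Predict heatmaps (generic)
#'
#' Evaluation-mode forward pass mapping an input batch to per-keypoint
#' heatmaps. Methods exist for `fp_network`; tracking code ([track_movie()])
#' accepts any object with a `predict_heatmaps` method, which lets tests
#' substitute an oracle predictor.
#'
#' @param object A predictor.
#' @param x Input batch as in [net_forward()].
#' @param ... Method arguments.
#' @return `(O, H/2, W/2, N)` array.
#' @export
predict_heatmaps <- function(object, x, ...) UseMethod("predict_heatmaps")

#' @rdname predict_heatmaps
#' @export
predict_heatmaps.fp_network <- function(object, x, ...) {
  net_forward(object, x, training = FALSE)$y
}

# output array (O, Hh, Wh, N), one sample -> codec heatmap stack (Hh, Wh, O)
output_to_heatmaps <- function(y, n = 1L) {
  hm <- aperm(y[, , , n, drop = FALSE], c(2, 3, 1, 4))
  dim(hm) <- dim(hm)[1:3]
  structure(hm, scale = 2, class = c("fp_heatmaps", "array"))
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (convolution and squeeze-excitation
#' weights and biases, normalization scales and offsets; running statistics
#' are buffers, not parameters).
#'
#' @param net An `fp_network` or an [network_config()].
#' @return Integer count.
#' @export
count_parameters <- function(net) {
  if (inherits(net, "fp_network_config")) net <- build_network(net)
  sum(vapply(param_paths(net$layers), function(p) {
    length(pluck(net$layers, p$path))
  }, numeric(1)))
}

#' Save / load network weights
#'
#' Single-file archive: an 8-byte ASCII header length, a JSON header echoing
#' the configuration, format version and parameter manifest, then the raw
#' parameter and buffer arrays as little-endian doubles. The loader validates
#' the configuration echo against the requested one.
#'
#' @param net An `fp_network`.
#' @param path File path.
#' @return `path` invisibly (`save_network`); an `fp_network`
#'   (`load_network`).
#' @export
save_network <- function(net, path) {
  paths <- all_array_paths(net$layers)
  manifest <- lapply(paths, function(p) {
    v <- pluck(net$layers, p)
    list(path = unlist(lapply(p, as.character)), length = length(v))
  })
  header <- jsonlite::toJSON(list(format = "finpose-net", version = 1L,
                                  cfg = unclass(net$cfg), manifest = manifest),
                             auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  hraw <- charToRaw(as.character(header))
  writeBin(sprintf("%08d", length(hraw)), con, useBytes = TRUE)
  writeBin(hraw, con)
  for (p in paths) {
    writeBin(as.numeric(pluck(net$layers, p)), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' @rdname save_network
#' @param cfg Optional [network_config()] the archive must match.
#' @export
load_network <- function(path, cfg = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hlen <- as.integer(readBin(con, "character"))
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                               simplifyVector = FALSE)
  if (!identical(header$format, "finpose-net")) stop("not a finpose network archive")
  stored <- do.call(network_config, header$cfg[setdiff(names(header$cfg), NULL)])
  if (!is.null(cfg) && !identical(unclass(stored), unclass(cfg))) {
    stop("archive configuration does not match the requested configuration")
  }
  net <- build_network(stored)
  paths <- all_array_paths(net$layers)
  for (i in seq_along(paths)) {
    expect_len <- header$manifest[[i]]$length
    v <- readBin(con, "numeric", expect_len, size = 8, endian = "little")
    old <- pluck(net$layers, paths[[i]])
    attributes(v) <- attributes(old)
    net$layers <- poke(net$layers, paths[[i]], v)
  }
  net
}

# parameter plus buffer arrays (running statistics), in traversal order
all_array_paths <- function(layers, prefix = list()) {
  out <- list()
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$kind == "residual") {
      out <- c(out, all_array_paths(ly$body, c(prefix, list(i, "body"))))
    } else {
      for (nm in intersect(c("w", "b", "w1", "b1", "w2", "b2",
                             "gamma", "beta", "run_mean", "run_var"),
                           names(ly))) {
        out[[length(out) + 1L]] <- c(prefix, list(i, nm))
      }
    }
  }
  out
}
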