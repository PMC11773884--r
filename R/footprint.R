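#' @title Theoretical minimum training memory footprint
#' @description
#' Accounting of the smallest buffer set a training implementation must hold
#' under these rules: every required buffer is allocated before training
#' starts and never freed or repurposed; individual computations use the
#' minimum possible number and size of buffers (depthwise convolutions use
#' implicit padding, so padded copies are not charged); and gradient
#' accumulation is used to the fullest extent possible wherever it does not
#' change the results -- i.e. the micro-batch can be reduced to a single
#' sample whenever no batch normalization couples samples, so the retained
#' activations are charged for one sample only. With batch normalization the
#' whole batch must be processed jointly and activations are charged for the
#' full batch. All scalars are 4 bytes (32-bit training arithmetic).
#' @name footprint
NULL

# per-layer accounting: output shape, retained-activation scalars (per
# micro-sample), and the transient workspace scalars of the layer
fp_shape_step <- function(layer, s) {
  C <- s[1]; H <- s[2]; W <- s[3]
  switch(layer$kind,
    conv1x1 = list(out = c(layer$cout, H, W), act = C * H * W),
    conv = {
      ho <- (H + 2 * layer$pad - layer$k) %/% layer$stride + 1L
      wo <- (W + 2 * layer$pad - layer$k) %/% layer$stride + 1L
      list(out = c(layer$cout, ho, wo), act = C * H * W)
    },
    dwconv = list(out = c(C, H, W), act = C * H * W), # implicit padding
    tconv2 = list(out = c(layer$cout, 2 * H, 2 * W), act = C * H * W),
    norm = list(out = c(C, H, W), act = C * H * W + 2 * norm_group_count(layer, s)),
    act = list(out = c(C, H, W), act = C * H * W),
    se = list(out = c(C, H, W), act = C * H * W + 3 * C + layer$cr),
    dropout = list(out = c(C, H, W), act = C),
    unshuffle = list(out = c(C * layer$p^2, H %/% layer$p, W %/% layer$p), act = 0),
    shuffle = list(out = c(C %/% layer$p^2, H * layer$p, W * layer$p), act = 0),
    residual = NULL, # handled by the walker
    stop("unknown layer kind: ", layer$kind))
}

norm_group_count <- function(layer, s) {
  switch(layer$type,
         instance = s[1], batch = s[1], layer = 1, group = layer$groups)
}

walk_footprint <- function(layers, s) {
  act <- 0; biggest <- prod(s)
  for (ly in layers) {
    if (ly$kind == "residual") {
      r <- walk_footprint(ly$body, s)
      act <- act + r$act
      biggest <- max(biggest, r$biggest)
      # output shape unchanged by a residual block
    } else {
      st <- fp_shape_step(ly, s)
      act <- act + st$act
      s <- st$out
      biggest <- max(biggest, prod(s))
    }
  }
  list(act = act, out = s, biggest = biggest)
}

#' Theoretical minimum memory footprint of a training run
#'
#' @param cfg An [network_config()].
#' @param batch Micro-batch size the implementation would use (the requested
#'   batch size); with batch normalization the retained activations scale
#'   with this value, otherwise gradient accumulation reduces the retained
#'   activations to a single sample.
#' @param effective_batch Effective batch size reached by gradient
#'   accumulation; must be a multiple of `batch`. It does not change the
#'   footprint (the accumulated gradient buffer is the gradient buffer).
#' @return List of class `fp_footprint`: `total_bytes` and `breakdown` with
#'   `parameters`, `gradients`, `optimizer_state` (two AdamW moments),
#'   `activations`, `input_target`, `workspace` (all bytes).
#' @export
theoretical_min_footprint <- function(cfg, batch = 16L, effective_batch = batch) {
  if (effective_batch %% batch != 0) {
    stop("effective_batch must be a multiple of batch")
  }
  net <- build_network(cfg)
  n_par <- count_parameters(net)
  micro <- if (cfg$norm == "batch") batch else 1L
  w <- walk_footprint(net$layers, c(cfg$I, cfg$H, cfg$W))
  bytes <- 4
  breakdown <- c(
    parameters = n_par * bytes,
    gradients = n_par * bytes,
    optimizer_state = 2 * n_par * bytes,
    activations = w$act * micro * bytes,
    input_target = (cfg$I * cfg$H * cfg$W +
                    cfg$O * (cfg$H %/% 2) * (cfg$W %/% 2)) * micro * bytes,
    workspace = w$biggest * micro * bytes)
  structure(list(total_bytes = sum(breakdown),
                 breakdown = as.list(breakdown)),
            class = "fp_footprint")
}

#' @export
print.fp_footprint <- function(x, ...) {
  cat(sprintf("<fp_footprint> total %.2f MiB\n", x$total_bytes / 2^20))
  for (nm in names(x$breakdown)) {
    cat(sprintf("  %-16s %12.0f bytes\n", nm, x$breakdown[[nm]]))
  }
  invisible(x)
}
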