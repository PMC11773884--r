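# shared fixtures and independent oracles, all generated in code

# tiny network used by training tests: 64x64 input, 8 middle channels,
# 4 blocks, 1 keypoint, 4x4 patches (16x16 internal grid)
tiny_net_cfg <- function(...) {
  args <- utils::modifyList(
    list(H = 64L, W = 64L, M = 8L, O = 1L, N = 4L, patch = 4L), list(...))
  do.call(network_config, args)
}

# the training recipe used with the tiny configuration
tiny_train_cfg <- function(n_updates = 600L, seed = 1L, ...) {
  train_config(learning_rate = 6e-3, n_updates = n_updates, seed = seed,
               eval_interval = max(100L, n_updates), ...)
}

tiny_dataset <- function(n_frames = 32L, seed = 2L, n_keypoints = 1L) {
  generate_dataset(n_frames, n_keypoints = n_keypoints,
                   ranges = scene_ranges(frame_size = 64), seed = seed)
}

# brute-force swim-bout oracle: explicit frame-by-frame state machine
oracle_bouts <- function(speed, framerate, threshold) {
  out <- NULL
  open <- FALSE
  start <- NA
  for (i in seq_along(speed)) {
    if (!open && speed[i] > threshold) { open <- TRUE; start <- i }
    closing <- open && (i == length(speed) || speed[i + 1] <= threshold)
    if (closing) {
      run <- start:i
      out <- rbind(out, data.frame(
        start_time = (start - 1) / framerate,
        end_time = (start - 1) / framerate + length(run) / framerate,
        duration = length(run) / framerate,
        peak_speed = max(speed[run])))
      open <- FALSE
    }
  }
  if (is.null(out)) {
    out <- data.frame(start_time = numeric(0), end_time = numeric(0),
                      duration = numeric(0), peak_speed = numeric(0))
  }
  out
}

# brute-force bend-peak oracle: scan constant-sign segments between zeros
oracle_bends <- function(angle, framerate, threshold) {
  out <- NULL
  i <- 1
  n <- length(angle)
  while (i <= n) {
    if (angle[i] == 0) { i <- i + 1; next }
    j <- i
    while (j < n && sign(angle[j + 1]) == sign(angle[i])) j <- j + 1
    seg <- i:j
    k <- seg[which.max(abs(angle[seg]))]
    out <- rbind(out, data.frame(
      peak_time = (k - 1) / framerate, peak_angle = angle[k],
      is_high_amplitude = abs(angle[k]) >= threshold))
    i <- j + 1
  }
  if (is.null(out)) {
    out <- data.frame(peak_time = numeric(0), peak_angle = numeric(0),
                      is_high_amplitude = logical(0))
  }
  out
}

# stub predictor: replays pre-computed network-input-space keypoints as
# encoded heatmaps, bypassing any real network (one call per sample, in order)
oracle_predictor <- function(kp_list, H, W, sigma = 2) {
  env <- new.env()
  env$i <- 0L
  structure(list(cfg = list(H = H, W = W, I = 1L, O = nrow(kp_list[[1]])),
                 kp = kp_list, sigma = sigma, env = env),
            class = "fp_oracle_predictor")
}

predict_heatmaps.fp_oracle_predictor <- function(object, x, ...) {
  n <- dim(x)[4]
  hh <- object$cfg$H %/% 2L
  wh <- object$cfg$W %/% 2L
  y <- array(0, c(object$cfg$O, hh, wh, n))
  for (b in seq_len(n)) {
    object$env$i <- object$env$i + 1L
    hm <- encode_targets(object$kp[[object$env$i]], c(hh, wh),
                         codec_config(sigma = object$sigma))
    y[, , , b] <- aperm(hm, c(3, 1, 2))
  }
  y
}

# registered so S3 dispatch works from inside the package
.S3method("predict_heatmaps", "fp_oracle_predictor",
          predict_heatmaps.fp_oracle_predictor)

# the scaled-down training study shared by the trainability and ablation
# checks: one 128-frame dataset, 3 split/init seeds, 25% and 100% training
# fractions, 600 updates each; computed once per test run
.tiny_study <- new.env(parent = emptyenv())

tiny_ablation_study <- function() {
  if (is.null(.tiny_study$tab)) {
    ds <- generate_dataset(128, n_keypoints = 1,
                           ranges = scene_ranges(frame_size = 64), seed = 1)
    .tiny_study$tab <- ablation_experiment(
      ds, tiny_net_cfg(), fractions = 0.25, n_seeds = 3L,
      tcfg = tiny_train_cfg(n_updates = 600L),
      ccfg = codec_config(correctness_radius = 2))
  }
  .tiny_study$tab
}
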