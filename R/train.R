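#' @title Training loop
#' @description
#' Mean-squared-error heatmap regression with AdamW, Xavier initialization
#' with a zeroed final layer, gradient accumulation to the configured
#' effective batch, on-the-fly augmentation of the training split, periodic
#' validation, and the data-ablation experiment driver.
#' @name training
NULL

#' Training configuration
#'
#' Defaults follow the reference recipe: AdamW with beta1 = 0.9, beta2 = 0.95,
#' eps = 1e-6; decoupled weight decay 1e-5 on convolution weights only; batch
#' size 16; 6000 parameter updates. The reference learning rates are 5e-4
#' (touch-evoked configuration) and 1e-4 (visuomotor configuration).
#'
#' @param learning_rate AdamW learning rate.
#' @param beta1,beta2,adam_eps AdamW moment decays and epsilon.
#' @param weight_decay Decoupled weight decay, applied to convolution weights
#'   only (never biases or normalization parameters).
#' @param batch_size Micro-batch size per forward/backward pass.
#' @param effective_batch Effective batch reached by gradient accumulation;
#'   multiple of `batch_size`.
#' @param n_updates Number of optimizer steps.
#' @param seed Integer seed controlling initialization, batch sampling,
#'   augmentation and dropout (single-threaded runs are bit-reproducible).
#' @param eval_interval Updates between validation evaluations.
#' @return List of class `fp_train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, beta1 = 0.9, beta2 = 0.95,
                         adam_eps = 1e-6, weight_decay = 1e-5,
                         batch_size = 16L, effective_batch = batch_size,
                         n_updates = 6000L, seed = 1L, eval_interval = 100L) {
  stopifnot(learning_rate > 0, batch_size >= 1,
            effective_batch %% batch_size == 0, n_updates >= 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 effective_batch = as.integer(effective_batch),
                 n_updates = as.integer(n_updates), seed = as.integer(seed),
                 eval_interval = as.integer(eval_interval)),
            class = "fp_train_config")
}

#' Initialize network weights
#'
#' Xavier (Glorot) normal initialization of all convolution and
#' squeeze-excitation weights with per-layer gains: sqrt(2) when the
#' convolution is followed by a nonlinearity (directly or through a
#' normalization), 1 otherwise; the gain of the last convolution in each
#' residual block is additionally scaled by `1/sqrt(N)`; the final convolution
#' layer is initialized to zeros (so the freshly initialized network outputs
#' exactly zero for any input); all biases are zeros; normalization scales are
#' 1 and offsets 0. Deterministic given `seed`.
#'
#' @param net An `fp_network`.
#' @param seed Integer seed.
#' @return The initialized `fp_network`.
#' @export
init_weights <- function(net, seed = 1L) {
  with_seed(seed, function() {
    net$layers <- init_layers(net$layers)
    net
  })
}

init_layers <- function(layers) {
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$kind == "residual") {
      layers[[i]]$body <- init_layers(ly$body)
    } else if (ly$kind == "norm") {
      layers[[i]]$gamma <- rep(1, ly$ch)
      layers[[i]]$beta <- numeric(ly$ch)
      layers[[i]]$run_mean <- numeric(ly$ch)
      layers[[i]]$run_var <- rep(1, ly$ch)
    } else if (ly$kind == "se") {
      sd1 <- sqrt(2) * sqrt(2 / (ly$ch + ly$cr))
      sd2 <- sqrt(2) * sqrt(2 / (ly$cr + ly$ch))
      layers[[i]]$w1 <- matrix(stats::rnorm(length(ly$w1), 0, sd1), nrow(ly$w1))
      layers[[i]]$w2 <- matrix(stats::rnorm(length(ly$w2), 0, sd2), nrow(ly$w2))
      layers[[i]]$b1 <- numeric(length(ly$b1))
      layers[[i]]$b2 <- numeric(length(ly$b2))
    } else if (!is.null(ly$init)) {
      if (ly$init$zero) {
        layers[[i]]$w[] <- 0
      } else {
        sd <- ly$init$gain * ly$init$scale *
          sqrt(2 / (ly$init$fan_in + ly$init$fan_out))
        layers[[i]]$w[] <- stats::rnorm(length(ly$w), 0, sd)
      }
      layers[[i]]$b[] <- 0
    }
  }
  layers
}

#' Mean squared error over heatmap batches
#'
#' @param pred,target Arrays of identical shape.
#' @return Mean of squared differences over all elements.
#' @export
loss_mse <- function(pred, target) {
  if (!identical(dim(pred), dim(target))) {
    stop("loss_mse: shape mismatch (", paste(dim(pred), collapse = "x"),
         " vs ", paste(dim(target), collapse = "x"), ")")
  }
  mean((pred - target)^2)
}

#' Loss gradients with respect to all parameters
#'
#' One forward/backward pass in training mode. Exposed so that gradient
#' properties (accumulation equivalence, finite-difference checks) can be
#' tested directly.
#'
#' @param net An initialized `fp_network`.
#' @param x Input batch `(I, H, W, N)`.
#' @param target Target batch `(O, H/2, W/2, N)`.
#' @param training Forward-pass mode (default TRUE).
#' @return List: `loss`, `grads` (tree parallel to `net$layers`), `net`.
#' @export
net_gradients <- function(net, x, target, training = TRUE) {
  fw <- net_forward(net, x, training = training)
  loss <- loss_mse(fw$y, target)
  dy <- 2 * (fw$y - target) / length(target)
  bw <- backward_layers(fw$net$layers, dy, fw$caches)
  list(loss = loss, grads = bw$grads, net = fw$net)
}

# elementwise combination of two gradient trees
grad_tree_combine <- function(a, b, f) {
  if (is.null(a)) return(b)
  if (is.list(a)) {
    for (i in seq_along(a)) {
      a[i] <- list(grad_tree_combine(a[[i]], b[[i]], f)) # keep NULL slots
    }
    return(a)
  }
  f(a, b)
}

grad_tree_scale <- function(a, s) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) return(lapply(a, grad_tree_scale, s = s))
  a * s
}

# AdamW state: list of m/v arrays parallel to param paths
adamw_init <- function(paths, layers) {
  lapply(paths, function(p) {
    v <- pluck(layers, p$path)
    list(m = v * 0, v = v * 0)
  })
}

adamw_step <- function(net, grads, state, t, tcfg, paths) {
  lr <- tcfg$learning_rate
  b1 <- tcfg$beta1; b2 <- tcfg$beta2
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    g <- pluck_grad(grads, p$path)
    st <- state[[i]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    state[[i]] <- st
    w <- pluck(net$layers, p$path)
    w <- w - lr * (st$m / c1) / (sqrt(st$v / c2) + tcfg$adam_eps)
    if (p$decay && tcfg$weight_decay > 0) w <- w - lr * tcfg$weight_decay * w
    net$layers <- poke(net$layers, p$path, w)
  }
  list(net = net, state = state)
}

# assemble an augmented (x, target) pair batch from dataset indices
assemble_batch <- function(ds, idx, stats, acfg, ccfg, cfg, augment = TRUE) {
  nb <- length(idx)
  x <- array(0, c(cfg$I, cfg$H, cfg$W, nb))
  tg <- array(0, c(cfg$O, cfg$H %/% 2L, cfg$W %/% 2L, nb))
  use_cfg <- acfg
  if (!augment) use_cfg$enabled <- FALSE
  for (b in seq_len(nb)) {
    fr <- list(image = ds$frames[[idx[b]]], keypoints = ds$keypoints[[idx[b]]])
    aug <- augment_pair(fr, use_cfg, stats)
    x[1, , , b] <- aug$image
    rng <- if (augment && use_cfg$enabled) function(n) stats::rnorm(n) else NULL
    hm <- encode_targets(aug$keypoints, c(cfg$H %/% 2L, cfg$W %/% 2L), ccfg, rng)
    tg[, , , b] <- aperm(hm, c(3, 1, 2))
  }
  list(x = x, target = tg)
}

#' Evaluate a network on a labeled dataset
#'
#' Evaluation mode (no augmentation, no dropout; batch normalization uses
#' running statistics). Frames are standardized with the training-split
#' statistics, predictions decoded, and scored.
#'
#' @param net An `fp_network`.
#' @param ds An `fp_dataset`.
#' @param stats Training-split `fp_split_stats`.
#' @param ccfg An [codec_config()] (provides the correctness radius).
#' @param batch_size Evaluation micro-batch.
#' @return List: `loss`, `pck`, `n_correct`, `n_keypoints`.
#' @export
evaluate_network <- function(net, ds, stats, ccfg = codec_config(),
                             batch_size = 16L) {
  cfg <- net$cfg
  n <- length(ds$frames)
  total_se <- 0; total_el <- 0; correct <- 0; total_kp <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    ba <- assemble_batch(ds, idx, stats, augment_config(enabled = FALSE),
                         ccfg, cfg, augment = FALSE)
    y <- predict_heatmaps(net, ba$x)
    total_se <- total_se + sum((y - ba$target)^2)
    total_el <- total_el + length(y)
    for (b in seq_along(idx)) {
      dec <- decode_heatmaps(output_to_heatmaps(y, b))
      truth <- ds$keypoints[[idx[b]]]
      err <- sqrt(rowSums((dec$coords - truth)^2))
      correct <- correct + sum(err < ccfg$correctness_radius)
      total_kp <- total_kp + nrow(truth)
    }
  }
  list(loss = total_se / total_el, pck = correct / total_kp,
       n_correct = correct, n_keypoints = total_kp)
}

#' Train a pose network
#'
#' Re-initializes the weights from `tcfg$seed`, then runs `n_updates` AdamW
#' steps. Each update samples `effective_batch` training frames uniformly with
#' replacement, augments them on the fly, and accumulates gradients over
#' micro-batches of `batch_size` before one optimizer step (the mean-loss
#' gradient over the effective batch is the mean of micro-batch gradients, so
#' accumulation is exact in the absence of batch normalization). Augmentation
#' and label wiggle apply to the training split only; validation uses
#' standardization alone. Aborts with a diagnostic on a non-finite loss.
#'
#' @param net An `fp_network`.
#' @param train_split,val_split `fp_dataset`s.
#' @param tcfg An [train_config()].
#' @param acfg An [augment_config()].
#' @param ccfg An [codec_config()].
#' @param verbose Print progress.
#' @return List of class `fp_train_result`: `net` (trained), `history` (data
#'   frame: update, train_loss, val_loss, wall_time_s), `stats` (split
#'   statistics used for standardization).
#' @export
train <- function(net, train_split, val_split, tcfg = train_config(),
                  acfg = augment_config(), ccfg = codec_config(),
                  verbose = FALSE) {
  stopifnot(length(train_split$frames) >= 1, length(val_split$frames) >= 1)
  cfg <- net$cfg
  stats <- compute_split_stats(train_split)
  net <- init_weights(net, tcfg$seed)
  paths <- param_paths(net$layers)
  state <- adamw_init(paths, net$layers)
  n_micro <- tcfg$effective_batch %/% tcfg$batch_size
  history <- data.frame(update = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), wall_time_s = numeric(0))
  t0 <- proc.time()[["elapsed"]]

  run <- with_seed(tcfg$seed + 1L, function() {
    for (u in seq_len(tcfg$n_updates)) {
      idx <- sample.int(length(train_split$frames), tcfg$effective_batch,
                        replace = TRUE)
      acc <- NULL
      loss_u <- 0
      for (mb in seq_len(n_micro)) {
        sub <- idx[((mb - 1) * tcfg$batch_size + 1):(mb * tcfg$batch_size)]
        ba <- assemble_batch(train_split, sub, stats, acfg, ccfg, cfg)
        g <- net_gradients(net, ba$x, ba$target)
        net <<- g$net
        loss_u <- loss_u + g$loss / n_micro
        acc <- if (is.null(acc)) grad_tree_scale(g$grads, 1 / n_micro) else
          grad_tree_combine(acc, grad_tree_scale(g$grads, 1 / n_micro), `+`)
      }
      if (!is.finite(loss_u) || loss_u > 1e12) {
        stop("training aborted: non-finite or diverged loss at update ", u,
             " (learning rate too high or degenerate inputs)")
      }
      stepped <- adamw_step(net, acc, state, u, tcfg, paths)
      net <<- stepped$net
      state <<- stepped$state
      if (u %% tcfg$eval_interval == 0 || u == tcfg$n_updates) {
        ev <- evaluate_network(net, val_split, stats, ccfg, tcfg$batch_size)
        history[nrow(history) + 1L, ] <<- list(
          u, loss_u, ev$loss, proc.time()[["elapsed"]] - t0)
        if (verbose) {
          message(sprintf("update %5d  train %.3e  val %.3e", u, loss_u, ev$loss))
        }
      }
    }
    NULL
  })

  structure(list(net = net, history = history, stats = stats),
            class = "fp_train_result")
}

#' Training-data ablation experiment
#'
#' For each seed: one fixed train/validation split, then training runs on
#' nested ablations of the training split (the validation split is held
#' constant) while the number of parameter updates is controlled (identical
#' across fractions). Reports the final validation loss, PCK at the
#' configured correctness radius, and the relative accuracy (correct
#' keypoints relative to the same seed's full-data run).
#'
#' @param dataset An `fp_dataset`.
#' @param net_cfg An [network_config()].
#' @param fractions Training-data fractions in (0, 1]; 1.0 is added if absent
#'   (it anchors relative accuracy).
#' @param n_seeds Number of independent split/initialization seeds.
#' @param tcfg An [train_config()].
#' @param acfg,ccfg Augmentation and codec configurations.
#' @param train_fraction Train share of the initial split. Default 0.75.
#' @param verbose Print progress.
#' @return Data frame: `fraction`, `seed`, `n_train`, `final_val_loss`,
#'   `pck`, `relative_accuracy` (one row per fraction x seed).
#' @export
ablation_experiment <- function(dataset, net_cfg, fractions, n_seeds = 3L,
                                tcfg = train_config(), acfg = augment_config(),
                                ccfg = codec_config(), train_fraction = 0.75,
                                verbose = FALSE) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  fractions <- sort(unique(c(fractions, 1)), decreasing = TRUE)
  out <- NULL
  for (s in seq_len(n_seeds)) {
    sp <- split_dataset(dataset, train_fraction, seed = s)
    ntr <- length(sp$train$frames)
    order_idx <- with_seed(s + 10000L, function() sample.int(ntr))
    full_correct <- NA_real_
    for (f in fractions) {
      keep <- order_idx[seq_len(max(1L, round(f * ntr)))]
      if (length(keep) == 0) stop("fraction ", f, " leaves no training images")
      tr <- sp$train
      tr$frames <- tr$frames[keep]
      tr$keypoints <- tr$keypoints[keep]
      tc <- tcfg
      tc$seed <- s
      res <- train(build_network(net_cfg), tr, sp$val, tc, acfg, ccfg)
      ev <- evaluate_network(res$net, sp$val, res$stats, ccfg, tcfg$batch_size)
      if (f == 1) full_correct <- ev$n_correct
      ra <- if (is.na(full_correct) || full_correct == 0) NA_real_ else
        relative_accuracy(ev$n_correct, full_correct)
      out <- rbind(out, data.frame(
        fraction = f, seed = s, n_train = length(keep),
        final_val_loss = ev$loss, pck = ev$pck, relative_accuracy = ra))
      if (verbose) {
        message(sprintf("seed %d fraction %.2f: val loss %.3e pck %.3f",
                        s, f, ev$loss, ev$pck))
      }
    }
  }
  out[order(out$seed, -out$fraction), , drop = FALSE]
}
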