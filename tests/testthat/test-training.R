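# loss, initialization-driven invariants, optimizer behavior, training loop

test_that("MSE loss matches its definition and rejects shape mismatches", {
  a <- array(0.5, c(2, 4, 4, 3))
  expect_equal(loss_mse(a, a), 0)
  expect_equal(loss_mse(a + 0.3, a), 0.3^2, tolerance = 1e-12)
  expect_error(loss_mse(a, array(0, c(2, 4, 5, 3))), "shape mismatch")
})

test_that("gradients agree with central finite differences for sampled parameters", {
  for (cfg in list(tiny_net_cfg(H = 16L, N = 1L, drop_prob = 0),
                   network_config(H = 16, M = 8, O = 1, N = 1, variant = "mnv3",
                                  norm = "batch", drop_prob = 0))) {
    net <- init_weights(build_network(cfg), 3)
    set.seed(3)
    x <- array(rnorm(16 * 16 * 2), c(1, 16, 16, 2))
    tg <- array(rnorm(8 * 8 * 2, 0, 0.3), c(1, 8, 8, 2))
    pp <- finpose:::param_paths(net$layers)
    # perturb the zero-initialized final layer so every path carries signal
    for (p in pp) {
      v <- finpose:::pluck(net$layers, p$path)
      if (all(v == 0) && !p$is_bias) {
        v[] <- rnorm(length(v), 0, 0.1)
        net$layers <- finpose:::poke(net$layers, p$path, v)
      }
    }
    g <- net_gradients(net, x, tg, training = TRUE)
    lossat <- function(nn) loss_mse(net_forward(nn, x, training = TRUE)$y, tg)
    set.seed(4)
    for (p in pp[sample(length(pp), 12)]) {
      v <- finpose:::pluck(net$layers, p$path)
      j <- sample(length(v), 1)
      eps <- 1e-5
      for (sgn in c(1, -1)) {
        vv <- v; vv[j] <- v[j] + sgn * eps
        nn <- net; nn$layers <- finpose:::poke(nn$layers, p$path, vv)
        if (sgn > 0) lp <- lossat(nn) else lm <- lossat(nn)
      }
      fd <- (lp - lm) / (2 * eps)
      ga <- finpose:::pluck_grad(g$grads, p$path)[j]
      expect_lt(abs(fd - ga) / max(1e-6, abs(fd), abs(ga)), 1e-4)
    }
  }
})

test_that("decoupled weight decay touches convolution weights only", {
  cfg <- tiny_net_cfg(N = 1L)
  net <- init_weights(build_network(cfg), 7)
  paths <- finpose:::param_paths(net$layers)
  state <- finpose:::adamw_init(paths, net$layers)
  zero_grads <- finpose:::grad_tree_scale(
    net_gradients(net, array(0, c(1, 64, 64, 1)),
                  array(0, c(1, 32, 32, 1)))$grads, 0)
  tcfg <- train_config(learning_rate = 0.1, weight_decay = 0.5, n_updates = 1)
  stepped <- finpose:::adamw_step(net, zero_grads, state, 1, tcfg, paths)
  for (p in paths) {
    before <- finpose:::pluck(net$layers, p$path)
    after <- finpose:::pluck(stepped$net$layers, p$path)
    if (p$decay) {
      expect_equal(after, before * (1 - 0.1 * 0.5), tolerance = 1e-12)
    } else {
      expect_identical(after, before)
    }
  }
})

test_that("gradient accumulation is exact without batch coupling and fails with it", {
  tree_norm <- function(a) {
    sqrt(sum(unlist(lapply(a, function(x) {
      if (is.list(x)) tree_norm(x)^2 else if (is.null(x)) 0 else sum(x^2)
    }))))
  }
  rel_acc_diff <- function(norm) {
    cfg <- network_config(H = 32, M = 8, O = 1, N = 2, patch = 4,
                          norm = norm, drop_prob = 0)
    net <- init_weights(build_network(cfg), 5)
    set.seed(9)
    x <- array(rnorm(32 * 32 * 16), c(1, 32, 32, 16))
    tg <- array(rnorm(16 * 16 * 16, 0, 0.3), c(1, 16, 16, 16))
    gfull <- net_gradients(net, x, tg)$grads
    acc <- NULL
    for (b in 1:16) {
      gb <- net_gradients(net, x[, , , b, drop = FALSE],
                          tg[, , , b, drop = FALSE])$grads
      gb <- finpose:::grad_tree_scale(gb, 1 / 16)
      acc <- if (is.null(acc)) gb else finpose:::grad_tree_combine(acc, gb, `+`)
    }
    diff <- finpose:::grad_tree_combine(acc, finpose:::grad_tree_scale(gfull, -1), `+`)
    tree_norm(diff) / tree_norm(gfull)
  }
  expect_lt(rel_acc_diff("instance"), 1e-5)
  expect_lt(rel_acc_diff("layer"), 1e-5)
  expect_lt(rel_acc_diff("group"), 1e-5)
  expect_gt(rel_acc_diff("batch"), 1e-3)
})

test_that("short training lowers validation loss, reproducibly, with train-only augmentation", {
  ds <- tiny_dataset(32, seed = 2)
  sp <- split_dataset(ds, 0.75, seed = 1)
  tcfg <- tiny_train_cfg(n_updates = 150L, seed = 1L)
  tcfg$eval_interval <- 50L
  res <- train(build_network(tiny_net_cfg()), sp$train, sp$val, tcfg,
               ccfg = codec_config(correctness_radius = 2))
  h <- res$history
  # zero-output init forces the initial loss to the mean squared target,
  # computed independently from the codec
  ms <- mean(vapply(seq_along(sp$val$frames), function(i) {
    mean(encode_targets(sp$val$keypoints[[i]], c(32, 32), codec_config())^2)
  }, numeric(1)))
  net0 <- init_weights(build_network(tiny_net_cfg()), 1)
  ev0 <- evaluate_network(net0, sp$val, res$stats, codec_config())
  expect_equal(ev0$loss, ms, tolerance = 1e-6)
  expect_lt(h$val_loss[nrow(h)], ev0$loss)
  # bitwise reproducibility of a run given (seed, config)
  short <- tiny_train_cfg(n_updates = 30L, seed = 4L)
  ra <- train(build_network(tiny_net_cfg()), sp$train, sp$val, short)
  rb <- train(build_network(tiny_net_cfg()), sp$train, sp$val, short)
  expect_identical(ra$net$layers, rb$net$layers)
  expect_equal(ra$history$val_loss, rb$history$val_loss)
})

test_that("the ablation driver holds the validation split constant and reports per-run rows", {
  ds <- tiny_dataset(24, seed = 8)
  tab <- ablation_experiment(ds, tiny_net_cfg(N = 1L), fractions = c(0.5, 1),
                             n_seeds = 2L, tcfg = tiny_train_cfg(n_updates = 20L))
  expect_equal(nrow(tab), 4L)
  expect_equal(sort(unique(tab$fraction)), c(0.5, 1))
  # fraction 1.0 has relative accuracy 1 by definition (when anything is correct)
  full <- tab[tab$fraction == 1, ]
  expect_true(all(is.na(full$relative_accuracy) | full$relative_accuracy == 1))
  # ablated training split is a subset: n_train at 0.5 is half of the split
  expect_true(all(tab$n_train[tab$fraction == 0.5] == 9L))
  expect_error(ablation_experiment(ds, tiny_net_cfg(), fractions = c(0, 1)),
               "fractions")
})

test_that("training aborts with a diagnostic on divergence", {
  ds <- tiny_dataset(8, seed = 3)
  sp <- split_dataset(ds, 0.75, seed = 1)
  tcfg <- tiny_train_cfg(n_updates = 40L)
  tcfg$learning_rate <- 1e6
  expect_error(
    train(build_network(tiny_net_cfg(N = 1L)), sp$train, sp$val, tcfg),
    "training aborted")
})
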