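# layers, architectures, counting, footprints

test_that("pixel unshuffle/shuffle rearrange losslessly and invert each other", {
  set.seed(1)
  x <- array(rnorm(1 * 256 * 256), c(1, 256, 256, 1))
  u <- finpose:::pixel_unshuffle(x, 8)
  expect_equal(dim(u), c(64, 32, 32, 1))
  expect_equal(sort(as.vector(u)), sort(as.vector(x))) # multiset preserved
  expect_identical(finpose:::pixel_shuffle(u, 8), x)
  expect_error(finpose:::pixel_unshuffle(x, 7), "divisible")
  expect_error(finpose:::pixel_shuffle(x, 2), "divisible")
})

test_that("the compiled depthwise kernels match a plain R loop oracle", {
  set.seed(8)
  C <- 5L; H <- 7L; W <- 6L; N <- 3L; k <- 3L; pad <- 1L
  x <- array(rnorm(C * H * W * N), c(C, H, W, N))
  w <- array(rnorm(C * k * k), c(C, k, k))
  b <- rnorm(C)
  y <- finpose:::dwconv_fwd_cpp(x, c(C, H, W, N), w, b, k, pad)
  dim(y) <- dim(x)
  ref <- array(0, dim(x))
  for (n in 1:N) for (c in 1:C) for (h in 1:H) for (wo in 1:W) {
    acc <- b[c]
    for (ki in 1:k) for (kj in 1:k) {
      hi <- h + ki - 1 - pad; wi <- wo + kj - 1 - pad
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        acc <- acc + x[c, hi, wi, n] * w[c, ki, kj]
      }
    }
    ref[c, h, wo, n] <- acc
  }
  expect_equal(y, ref, tolerance = 1e-12)
  # backward: dx equals the correlation with the flipped kernel; dw, db by sums
  dy <- array(rnorm(length(x)), dim(x))
  r <- finpose:::dwconv_bwd_cpp(x, dy, c(C, H, W, N), w, k, pad)
  dxr <- array(0, dim(x)); dwr <- array(0, c(C, k, k)); dbr <- numeric(C)
  for (n in 1:N) for (c in 1:C) for (h in 1:H) for (wo in 1:W) {
    g <- dy[c, h, wo, n]
    dbr[c] <- dbr[c] + g
    for (ki in 1:k) for (kj in 1:k) {
      hi <- h + ki - 1 - pad; wi <- wo + kj - 1 - pad
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        dwr[c, ki, kj] <- dwr[c, ki, kj] + g * x[c, hi, wi, n]
        dxr[c, hi, wi, n] <- dxr[c, hi, wi, n] + g * w[c, ki, kj]
      }
    }
  }
  dx <- r$dx; dim(dx) <- dim(x)
  dw2 <- r$dw; dim(dw2) <- c(C, k, k)
  expect_equal(dx, dxr, tolerance = 1e-12)
  expect_equal(dw2, dwr, tolerance = 1e-12)
  expect_equal(r$db, dbr, tolerance = 1e-12)
})

test_that("the transposed 2x2/stride-2 convolution matches a direct scatter oracle", {
  set.seed(2)
  ly <- finpose:::l_tconv2(3, 2)
  ly$w <- array(rnorm(2 * 3 * 2 * 2), c(2, 3, 2, 2))
  ly$b <- rnorm(2)
  x <- array(rnorm(3 * 4 * 4), c(3, 4, 4, 1))
  y <- finpose:::layer_forward(ly, x)$y
  # oracle: out[co, 2h+i, 2w+j] = b[co] + sum_ci w[co, ci, i, j] x[ci, h, w]
  ref <- array(0, c(2, 8, 8, 1))
  for (co in 1:2) for (h in 1:4) for (w in 1:4) for (i in 1:2) for (j in 1:2) {
    ref[co, 2 * (h - 1) + i, 2 * (w - 1) + j, 1] <-
      ly$b[co] + sum(ly$w[co, , i, j] * x[, h, w, 1])
  }
  expect_equal(y, ref, tolerance = 1e-12)
})

test_that("both presets reproduce the reference input/output geometry", {
  touch <- preset_touch()
  net <- init_weights(build_network(touch), 1)
  y <- predict_heatmaps(net, matrix(0.5, 512, 512))
  expect_equal(dim(y), c(7L, 256L, 256L, 1L))
  vis <- preset_visuomotor()
  nv <- init_weights(build_network(vis), 1)
  yv <- predict_heatmaps(nv, matrix(0.5, 256, 256))
  expect_equal(dim(yv), c(1L, 128L, 128L, 1L))
  # hierarchical macro: same output contract (checked at a smaller size)
  hcfg <- network_config(H = 64, M = 8, O = 2, N = 1, macro = "hierarchical")
  nh <- init_weights(build_network(hcfg), 1)
  yh <- predict_heatmaps(nh, matrix(0.5, 64, 64))
  expect_equal(dim(yh), c(2L, 32L, 32L, 1L))
})

test_that("outro shape algebra is consistent: 16*O channels through a 4x4 shuffle", {
  # internal 64x64 grid with 16*O channels -> O channels at 256 = H/2
  O <- 7L
  x <- array(rnorm(16 * O * 64 * 64), c(16 * O, 64, 64, 1))
  y <- finpose:::pixel_shuffle(x, 4)
  expect_equal(dim(y), c(O, 256L, 256L, 1L))
})

test_that("a residual block with a zeroed projection is the identity", {
  cfg <- tiny_net_cfg()
  blk <- finpose:::build_block(cfg)
  blk$body <- finpose:::init_layers(blk$body)
  i_last <- max(which(vapply(blk$body, function(l) l$kind == "conv1x1", TRUE)))
  blk$body[[i_last]]$w[] <- 0
  blk$body[[i_last]]$b[] <- 0
  set.seed(3)
  x <- array(rnorm(8 * 16 * 16 * 2), c(8, 16, 16, 2))
  y <- finpose:::layer_forward(blk, x, training = FALSE)$y
  expect_equal(y, x, tolerance = 1e-12)
})

test_that("hard swish and instance normalization match their definitions", {
  hs <- finpose:::hswish_f
  expect_equal(hs(0), 0)
  expect_equal(hs(3), 3)
  expect_equal(hs(-3), 0)
  expect_equal(hs(1), 1 * 4 / 6)
  ly <- finpose:::l_norm(4, "instance", eps = 1e-3)
  set.seed(4)
  x <- array(rnorm(4 * 12 * 12, 5, 3), c(4, 12, 12, 1))
  y <- finpose:::layer_forward(ly, x, training = TRUE)$y
  for (c in 1:4) {
    ch <- y[c, , , 1]
    expect_lt(abs(mean(ch)), 1e-9)
    expect_equal(stats::var(as.vector(ch)) * (length(ch) - 1) / length(ch), 1,
                 tolerance = 2e-3) # within the eps correction
  }
})

# independent layer-by-layer parameter enumeration
enumerate_params <- function(cfg) {
  EM <- round(cfg$E * cfg$M)
  cr <- max(1, EM %/% cfg$se_reduction)
  se <- EM * cr + cr + cr * EM + EM
  block <- cfg$M * EM + EM +                      # expand conv
    EM * cfg$kernel^2 + EM +                      # depthwise conv
    se +
    EM * cfg$M + cfg$M                            # project conv
  nnorm2 <- function(ch) 2 * ch
  if (cfg$variant == "mnv3") {
    block <- block + nnorm2(EM) + nnorm2(EM) + nnorm2(cfg$M)
  } else {
    block <- block + nnorm2(if (cfg$slim_norm == "project") cfg$M else EM)
  }
  if (cfg$macro == "isotropic") {
    up <- cfg$patch %/% 2
    intro <- cfg$I * cfg$patch^2 * cfg$M + cfg$M + nnorm2(cfg$M)
    outro <- cfg$M * EM + EM + EM * up^2 * cfg$O + up^2 * cfg$O
    intro + cfg$N * block + outro
  } else {
    M <- cfg$M; M2 <- M %/% 2; M4 <- M %/% 4
    intro <- cfg$I * 16 * M4 + M4 + nnorm2(M4)
    down <- (M4 * 4 * M2 + M2 + nnorm2(M2)) + (M2 * 4 * M + M + nnorm2(M))
    up <- (M * M2 * 4 + M2 + nnorm2(M2)) + (M2 * M4 * 4 + M4 + nnorm2(M4))
    outro <- M4 * M2 + M2 + M2 * cfg$O + cfg$O
    intro + down + cfg$N * block + up + outro
  }
}

test_that("parameter counts equal brute-force enumeration across varied configs", {
  # primitive examples: 1x1 conv 16->32 with bias; depthwise 3x3 over 32
  c1 <- finpose:::l_conv1x1(16, 32)
  expect_equal(length(c1$w) + length(c1$b), 544)
  dw <- finpose:::l_dwconv(32, 3)
  expect_equal(length(dw$w) + length(dw$b), 320)
  cfgs <- list(
    network_config(H = 64, M = 8, O = 1, N = 2, patch = 4),
    network_config(H = 64, M = 16, O = 3, N = 5, kernel = 5, variant = "mnv3"),
    network_config(H = 64, M = 8, O = 2, N = 3, slim_norm = "project"),
    network_config(H = 64, M = 8, O = 2, N = 3, macro = "hierarchical"),
    network_config(H = 64, M = 16, O = 7, N = 4, macro = "hierarchical",
                   variant = "mnv3"),
    preset_touch(), preset_visuomotor())
  for (cfg in cfgs) {
    expect_equal(count_parameters(cfg), enumerate_params(cfg))
  }
})

test_that("the initialized network outputs exactly zero and honors the init recipe", {
  for (macro in c("isotropic", "hierarchical")) {
    cfg <- network_config(H = 32, M = 8, O = 2, N = 2, patch = 4, macro = macro)
    net <- init_weights(build_network(cfg), 11)
    set.seed(12)
    y <- predict_heatmaps(net, matrix(runif(32 * 32), 32, 32))
    expect_true(all(y == 0))
    for (p in finpose:::param_paths(net$layers)) {
      if (p$is_bias) expect_true(all(finpose:::pluck(net$layers, p$path) == 0))
    }
  }
  # residual-block project conv SD = Xavier SD * gain / sqrt(N) within 10%
  cfg <- network_config(H = 64, M = 32, O = 1, N = 10, patch = 8)
  net <- init_weights(build_network(cfg), 21)
  blk <- net$layers[[4]]
  i_last <- max(which(vapply(blk$body, function(l) l$kind == "conv1x1", TRUE)))
  w <- blk$body[[i_last]]$w
  expected_sd <- (1 / sqrt(10)) * sqrt(2 / (64 + 32))
  expect_equal(stats::sd(as.vector(w)), expected_sd, tolerance = 0.1)
  # weights are deterministic given the seed
  net2 <- init_weights(build_network(cfg), 21)
  expect_identical(net$layers, net2$layers)
})

test_that("footprints: batch-size independence, batch-norm penalty, macro ordering, monotonicity", {
  cfg_in <- network_config(H = 128, M = 8, O = 1, N = 2)
  f16 <- theoretical_min_footprint(cfg_in, batch = 1, effective_batch = 16)
  f64 <- theoretical_min_footprint(cfg_in, batch = 1, effective_batch = 64)
  expect_identical(f16, f64) # constant footprint under accumulation
  cfg_bn <- network_config(H = 128, M = 8, O = 1, N = 2, norm = "batch")
  expect_gt(theoretical_min_footprint(cfg_bn, 16, 16)$total_bytes,
            theoretical_min_footprint(cfg_in, 16, 16)$total_bytes)
  # breakdown sums to the total and is non-negative
  expect_equal(sum(unlist(f16$breakdown)), f16$total_bytes)
  expect_true(all(unlist(f16$breakdown) >= 0))
  # monotone non-decreasing in H, M and N
  base <- theoretical_min_footprint(network_config(H = 64, M = 8, O = 1, N = 2), 16, 16)
  for (cfg2 in list(network_config(H = 128, M = 8, O = 1, N = 2),
                    network_config(H = 64, M = 16, O = 1, N = 2),
                    network_config(H = 64, M = 8, O = 1, N = 6))) {
    expect_gte(theoretical_min_footprint(cfg2, 16, 16)$total_bytes,
               base$total_bytes)
  }
  expect_error(theoretical_min_footprint(cfg_in, 16, 24), "multiple")
})

test_that("network archives round-trip and reject mismatched configurations", {
  cfg <- tiny_net_cfg(N = 1L)
  net <- init_weights(build_network(cfg), 31)
  path <- withr::local_tempfile(fileext = ".fpnet")
  save_network(net, path)
  back <- load_network(path, cfg)
  set.seed(5)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_identical(predict_heatmaps(back, x), predict_heatmaps(net, x))
  expect_error(load_network(path, tiny_net_cfg(N = 2L)), "does not match")
})
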