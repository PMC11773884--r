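#' @title Network layers
#' @description
#' Minimal layer zoo with hand-written forward and backward passes, sufficient
#' for the inverted-bottleneck pose networks: pointwise and general strided
#' convolutions, depthwise convolutions (implicit padding), 2x2/stride-2
#' transposed convolutions, pixel shuffle/unshuffle, batch/layer/group/instance
#' normalization, hard swish / ReLU / hard sigmoid, squeeze-and-excitation,
#' spatial (channel) dropout, and residual/sequential containers.
#'
#' Activations are arrays of shape `(C, H, W, N)` (channels fastest, batch
#' slowest) so that pointwise convolutions reduce to one BLAS matrix product.
#' All computation is in double precision; the memory-footprint accounting
#' assumes 4-byte scalars (the reference 32-bit training arithmetic).
#' @name layers
#' @keywords internal
NULL

# ---- constructors -------------------------------------------------------
# each param-bearing layer carries `init` (gain/zero/scale for Xavier) and
# `decay` flags naming the params subject to weight decay (conv weights only)

l_conv1x1 <- function(cin, cout, gain = 1, zero = FALSE, scale = 1) {
  list(kind = "conv1x1", cin = cin, cout = cout,
       w = matrix(0, cout, cin), b = numeric(cout),
       init = list(gain = gain, zero = zero, scale = scale,
                   fan_in = cin, fan_out = cout),
       decay = "w")
}

l_conv <- function(cin, cout, k, stride, pad, gain = 1, zero = FALSE, scale = 1) {
  list(kind = "conv", cin = cin, cout = cout, k = k, stride = stride, pad = pad,
       w = array(0, c(cout, cin, k, k)), b = numeric(cout),
       init = list(gain = gain, zero = zero, scale = scale,
                   fan_in = cin * k * k, fan_out = cout * k * k),
       decay = "w")
}

l_dwconv <- function(ch, k, gain = 1) {
  stopifnot(k %% 2 == 1)
  list(kind = "dwconv", ch = ch, k = k, pad = (k - 1) %/% 2,
       w = array(0, c(ch, k, k)), b = numeric(ch),
       init = list(gain = gain, zero = FALSE, scale = 1,
                   fan_in = k * k, fan_out = k * k),
       decay = "w")
}

l_tconv2 <- function(cin, cout, gain = 1) {
  list(kind = "tconv2", cin = cin, cout = cout,
       w = array(0, c(cout, cin, 2, 2)), b = numeric(cout),
       init = list(gain = gain, zero = FALSE, scale = 1,
                   fan_in = cin, fan_out = cout * 4),
       decay = "w")
}

l_norm <- function(ch, type = "instance", eps = 1e-3, momentum = 0.9, groups = 8) {
  if (type == "group") {
    groups <- min(groups, ch)
    if (ch %% groups != 0) stop("channel count not divisible by group count")
  }
  list(kind = "norm", ch = ch, type = type, eps = eps, momentum = momentum,
       groups = groups, gamma = rep(1, ch), beta = numeric(ch),
       run_mean = numeric(ch), run_var = rep(1, ch), decay = character(0))
}

l_act <- function(fun) list(kind = "act", fun = fun)

l_pixel_unshuffle <- function(p) list(kind = "unshuffle", p = p)
l_pixel_shuffle <- function(p) list(kind = "shuffle", p = p)

l_se <- function(ch, reduction = 4) {
  cr <- max(1L, ch %/% reduction)
  list(kind = "se", ch = ch, cr = cr,
       w1 = matrix(0, cr, ch), b1 = numeric(cr),
       w2 = matrix(0, ch, cr), b2 = numeric(ch),
       init = list(gain = sqrt(2), zero = FALSE, scale = 1,
                   fan_in = ch, fan_out = cr),
       decay = c("w1", "w2"))
}

l_dropout <- function(p) list(kind = "dropout", p = p)

l_residual <- function(body) list(kind = "residual", body = body)

# ---- pixel shuffle / unshuffle ------------------------------------------
# unshuffle: (C, H, W, N) -> (C*p^2, H/p, W/p, N); the output channel index is
# c*p^2 + i*p + j (0-based) for input pixel offsets (row i, col j)

pixel_unshuffle <- function(x, p) {
  d <- dim(x)
  if (d[2] %% p != 0 || d[3] %% p != 0) {
    stop("pixel_unshuffle: spatial dims not divisible by ", p)
  }
  dim(x) <- c(d[1], p, d[2] %/% p, p, d[3] %/% p, d[4])
  x <- aperm(x, c(4, 2, 1, 3, 5, 6)) # (j, i, C, H/p, W/p, N)
  dim(x) <- c(d[1] * p * p, d[2] %/% p, d[3] %/% p, d[4])
  x
}

pixel_shuffle <- function(x, p) {
  d <- dim(x)
  if (d[1] %% (p * p) != 0) {
    stop("pixel_shuffle: channel count not divisible by ", p * p)
  }
  dim(x) <- c(p, p, d[1] %/% (p * p), d[2], d[3], d[4]) # (j, i, C, H, W, N)
  x <- aperm(x, c(3, 2, 4, 1, 5, 6)) # (C, i, H, j, W, N)
  dim(x) <- c(d[1] %/% (p * p), d[2] * p, d[3] * p, d[4])
  x
}

# ---- helpers -------------------------------------------------------------

pad_spatial <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  out[, p + seq_len(d[2]), p + seq_len(d[3]), ] <- x
  out
}

unpad_spatial <- function(x, p, h, w) {
  if (p == 0) return(x)
  x[, p + seq_len(h), p + seq_len(w), , drop = FALSE]
}

as_cmat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], prod(d[-1]))
  x
}

# normalization grouping: returns permutation and group layout for a type
norm_layout <- function(type, d, groups) {
  switch(type,
    instance = list(perm = c(2, 3, 1, 4), m = d[2] * d[3], g = d[1] * d[4]),
    batch    = list(perm = c(2, 3, 4, 1), m = d[2] * d[3] * d[4], g = d[1]),
    layer    = list(perm = NULL, m = d[1] * d[2] * d[3], g = d[4]),
    group    = list(perm = NA, m = (d[1] %/% groups) * d[2] * d[3],
                    g = groups * d[4]),
    stop("unknown normalization type: ", type))
}

to_groups <- function(x, type, groups) {
  d <- dim(x)
  lay <- norm_layout(type, d, groups)
  if (type == "group") {
    dim(x) <- c(d[1] %/% groups, groups, d[2], d[3], d[4])
    x <- aperm(x, c(1, 3, 4, 2, 5))
  } else if (!is.null(lay$perm)) {
    x <- aperm(x, lay$perm)
  }
  dim(x) <- c(lay$m, lay$g)
  x
}

from_groups <- function(xg, type, d, groups) {
  if (type == "group") {
    dim(xg) <- c(d[1] %/% groups, d[2], d[3], groups, d[4])
    xg <- aperm(xg, c(1, 4, 2, 3, 5))
  } else {
    lay <- norm_layout(type, d, groups)
    if (!is.null(lay$perm)) {
      pd <- d[lay$perm]
      dim(xg) <- pd
      xg <- aperm(xg, order(lay$perm))
    }
  }
  dim(xg) <- d
  xg
}

# per-(channel, sample) sums over HW-column blocks of a (C, HW*N) matrix
channel_sums_blocks <- function(xm, hw, n) {
  m <- matrix(0, nrow(xm), n)
  for (i in seq_len(n)) {
    m[, i] <- .rowSums(xm[, (i - 1) * hw + seq_len(hw), drop = FALSE],
                       nrow(xm), hw)
  }
  m
}

# per-(channel, sample) means: (C, N) matrix
channel_means <- function(x) {
  d <- dim(x)
  hw <- d[2] * d[3]
  xm <- matrix(x, d[1])
  m <- matrix(0, d[1], d[4])
  for (n in seq_len(d[4])) {
    m[, n] <- .rowMeans(xm[, (n - 1) * hw + seq_len(hw), drop = FALSE],
                        d[1], hw)
  }
  m
}

# expand per-(channel, sample) values g (C, N) to a (C, HW*N) factor matrix
cs_expand <- function(g, hw) g[, rep(seq_len(ncol(g)), each = hw), drop = FALSE]

# multiply x (C,H,W,N) by per-(channel,sample) factors g (C,N)
scale_by_channel_sample <- function(x, g) {
  d <- dim(x)
  y <- matrix(x, d[1]) * cs_expand(g, d[2] * d[3])
  dim(y) <- d
  y
}

hswish_f <- function(x) x * pmin(pmax(x + 3, 0), 6) / 6
hswish_g <- function(x) ((x > -3) & (x < 3)) * (2 * x + 3) / 6 + (x >= 3)
hsigmoid_f <- function(x) pmin(pmax(x + 3, 0), 6) / 6
hsigmoid_g <- function(x) ((x > -3) & (x < 3)) / 6

# ---- forward -------------------------------------------------------------
# layer_forward returns list(y, cache, layer); containers recurse

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$kind,
    conv1x1 = {
      d <- dim(x)
      xm <- as_cmat(x)
      y <- layer$w %*% xm + layer$b
      dim(y) <- c(layer$cout, d[2], d[3], d[4])
      list(y = y, cache = list(xm = xm, d = d), layer = layer)
    },
    conv = {
      d <- dim(x)
      s <- layer$stride; k <- layer$k; p <- layer$pad
      xp <- pad_spatial(x, p)
      ho <- (d[2] + 2 * p - k) %/% s + 1L
      wo <- (d[3] + 2 * p - k) %/% s + 1L
      y <- array(rep(layer$b, ho * wo * d[4]), c(layer$cout, ho, wo, d[4]))
      ym <- as_cmat(y)
      for (ki in seq_len(k)) for (kj in seq_len(k)) {
        rows <- ki + s * (seq_len(ho) - 1L)
        cols <- kj + s * (seq_len(wo) - 1L)
        xs <- xp[, rows, cols, , drop = FALSE]
        ym <- ym + layer$w[, , ki, kj] %*% as_cmat(xs)
      }
      dim(ym) <- c(layer$cout, ho, wo, d[4])
      list(y = ym, cache = list(xp = xp, d = d), layer = layer)
    },
    dwconv = {
      d <- dim(x)
      y <- dwconv_fwd_cpp(x, as.integer(d), layer$w, layer$b,
                          layer$k, layer$pad)
      dim(y) <- d
      list(y = y, cache = list(x = x, d = d), layer = layer)
    },
    tconv2 = {
      d <- dim(x)
      wm <- aperm(layer$w, c(4, 3, 1, 2)) # (j, i, cout, cin)
      dim(wm) <- c(4 * layer$cout, layer$cin)
      xm <- as_cmat(x)
      y <- wm %*% xm + rep(layer$b, each = 4)
      dim(y) <- c(4 * layer$cout, d[2], d[3], d[4])
      y <- pixel_shuffle(y, 2)
      list(y = y, cache = list(xm = xm, d = d), layer = layer)
    },
    norm = {
      d <- dim(x)
      if (layer$type == "batch" && !training) {
        invstd <- 1 / sqrt(layer$run_var + layer$eps)
        xhat <- (x - layer$run_mean) * invstd
        y <- xhat * layer$gamma + layer$beta
        return(list(y = y, cache = list(eval_bn = TRUE), layer = layer))
      }
      if (layer$type == "instance") { # fast path: no transposes
        hw <- d[2] * d[3]
        mu <- channel_means(x)
        va <- channel_means(x * x) - mu^2
        invstd <- 1 / sqrt(pmax(va, 0) + layer$eps)
        xhat <- (matrix(x, d[1]) - cs_expand(mu, hw)) * cs_expand(invstd, hw)
        y <- xhat * layer$gamma + layer$beta
        dim(y) <- d
        return(list(y = y,
                    cache = list(in_xhat = xhat, in_invstd = invstd, d = d),
                    layer = layer))
      }
      xg <- to_groups(x, layer$type, layer$groups)
      m <- nrow(xg)
      mu <- colMeans(xg)
      va <- colMeans(xg^2) - mu^2
      invstd <- 1 / sqrt(pmax(va, 0) + layer$eps)
      xhatg <- (xg - rep(mu, each = m)) * rep(invstd, each = m)
      xhat <- from_groups(xhatg, layer$type, d, layer$groups)
      y <- xhat * layer$gamma + layer$beta
      if (layer$type == "batch" && training) {
        mom <- layer$momentum
        layer$run_mean <- mom * layer$run_mean + (1 - mom) * mu
        layer$run_var <- mom * layer$run_var + (1 - mom) * va
      }
      list(y = y, cache = list(xhatg = xhatg, invstd = invstd, d = d),
           layer = layer)
    },
    act = {
      y <- switch(layer$fun,
                  hswish = hswish_f(x),
                  relu = pmax(x, 0),
                  hsigmoid = hsigmoid_f(x))
      list(y = y, cache = list(x = x), layer = layer)
    },
    unshuffle = list(y = pixel_unshuffle(x, layer$p), cache = NULL, layer = layer),
    shuffle = list(y = pixel_shuffle(x, layer$p), cache = NULL, layer = layer),
    se = {
      d <- dim(x)
      s <- channel_means(x) # (C, N)
      z1 <- pmax(layer$w1 %*% s + layer$b1, 0)
      a <- layer$w2 %*% z1 + layer$b2
      g <- hsigmoid_f(a)
      y <- scale_by_channel_sample(x, g)
      list(y = y, cache = list(x = x, s = s, z1 = z1, a = a, g = g, d = d),
           layer = layer)
    },
    dropout = {
      if (!training || layer$p <= 0) {
        return(list(y = x, cache = list(mask = NULL), layer = layer))
      }
      d <- dim(x)
      keep <- matrix(stats::runif(d[1] * d[4]) >= layer$p, d[1], d[4])
      mask <- keep / (1 - layer$p)
      y <- scale_by_channel_sample(x, mask)
      list(y = y, cache = list(mask = mask), layer = layer)
    },
    residual = {
      r <- forward_layers(layer$body, x, training)
      layer$body <- r$layers
      list(y = x + r$y, cache = r$caches, layer = layer)
    },
    stop("unknown layer kind: ", layer$kind))
}

forward_layers <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, training)
    x <- r$y
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(y = x, caches = caches, layers = layers)
}

# ---- backward ------------------------------------------------------------
# layer_backward returns list(dx, grads); grads is a named list matching the
# layer's param names (NULL for parameter-free layers)

layer_backward <- function(layer, dy, cache) {
  switch(layer$kind,
    conv1x1 = {
      dym <- as_cmat(dy)
      dw <- dym %*% t(cache$xm)
      db <- rowSums(dym)
      dx <- t(layer$w) %*% dym
      dim(dx) <- cache$d
      list(dx = dx, grads = list(w = dw, b = db))
    },
    conv = {
      d <- cache$d
      s <- layer$stride; k <- layer$k; p <- layer$pad
      do <- dim(dy)
      dym <- as_cmat(dy)
      dw <- array(0, dim(layer$w))
      dxp <- array(0, dim(cache$xp))
      for (ki in seq_len(k)) for (kj in seq_len(k)) {
        rows <- ki + s * (seq_len(do[2]) - 1L)
        cols <- kj + s * (seq_len(do[3]) - 1L)
        xs <- cache$xp[, rows, cols, , drop = FALSE]
        dw[, , ki, kj] <- dym %*% t(as_cmat(xs))
        dxs <- t(layer$w[, , ki, kj]) %*% dym
        dim(dxs) <- c(layer$cin, do[2], do[3], do[4])
        dxp[, rows, cols, ] <- dxp[, rows, cols, , drop = FALSE] + dxs
      }
      dx <- unpad_spatial(dxp, p, d[2], d[3])
      dim(dx) <- d
      list(dx = dx, grads = list(w = dw, b = rowSums(dym)))
    },
    dwconv = {
      d <- cache$d
      r <- dwconv_bwd_cpp(cache$x, dy, as.integer(d), layer$w,
                          layer$k, layer$pad)
      dx <- r$dx
      dim(dx) <- d
      dw <- r$dw
      dim(dw) <- dim(layer$w)
      list(dx = dx, grads = list(w = dw, b = r$db))
    },
    tconv2 = {
      d <- cache$d
      dyu <- pixel_unshuffle(dy, 2)
      dym <- as_cmat(dyu)
      wm <- aperm(layer$w, c(4, 3, 1, 2))
      dim(wm) <- c(4 * layer$cout, layer$cin)
      dwm <- dym %*% t(cache$xm)
      dim(dwm) <- c(2, 2, layer$cout, layer$cin) # (j, i, cout, cin)
      dw <- aperm(dwm, c(3, 4, 2, 1))
      db <- colSums(matrix(rowSums(dym), 4, layer$cout))
      dx <- t(wm) %*% dym
      dim(dx) <- d
      list(dx = dx, grads = list(w = dw, b = db))
    },
    norm = {
      if (isTRUE(cache$eval_bn)) {
        stop("backward through batch norm in evaluation mode is not supported")
      }
      d <- cache$d
      if (layer$type == "instance") {
        hw <- d[2] * d[3]
        xhat <- cache$in_xhat # (C, HW*N) matrix
        dym <- matrix(dy, d[1])
        dgamma <- rowSums(dym * xhat)
        dbeta <- rowSums(dym)
        dxhat <- dym * layer$gamma
        mu1 <- channel_sums_blocks(dxhat, hw, d[4]) / hw
        mu2 <- channel_sums_blocks(dxhat * xhat, hw, d[4]) / hw
        dx <- (dxhat - cs_expand(mu1, hw) - xhat * cs_expand(mu2, hw)) *
          cs_expand(cache$in_invstd, hw)
        dim(dx) <- d
        return(list(dx = dx, grads = list(gamma = dgamma, beta = dbeta)))
      }
      xhat <- from_groups(cache$xhatg, layer$type, d, layer$groups)
      dgamma <- rowSums(matrix(dy * xhat, d[1]))
      dbeta <- rowSums(matrix(dy, d[1]))
      dxhat <- dy * layer$gamma
      dxg <- to_groups(dxhat, layer$type, layer$groups)
      m <- nrow(dxg)
      mu1 <- colMeans(dxg)
      mu2 <- colMeans(dxg * cache$xhatg)
      dxg <- (dxg - rep(mu1, each = m) - cache$xhatg * rep(mu2, each = m)) *
        rep(cache$invstd, each = m)
      dx <- from_groups(dxg, layer$type, d, layer$groups)
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    act = {
      g <- switch(layer$fun,
                  hswish = hswish_g(cache$x),
                  relu = (cache$x > 0) * 1,
                  hsigmoid = hsigmoid_g(cache$x))
      list(dx = dy * g, grads = NULL)
    },
    unshuffle = list(dx = pixel_shuffle(dy, layer$p), grads = NULL),
    shuffle = list(dx = pixel_unshuffle(dy, layer$p), grads = NULL),
    se = {
      d <- cache$d
      hw <- d[2] * d[3]
      dx <- scale_by_channel_sample(dy, cache$g)
      dg <- channel_sums_blocks(matrix(dy, d[1]) * matrix(cache$x, d[1]),
                                hw, d[4])
      da <- dg * hsigmoid_g(cache$a)
      db2 <- rowSums(da)
      dw2 <- da %*% t(cache$z1)
      dz1 <- t(layer$w2) %*% da
      dz1[cache$z1 <= 0] <- 0
      db1 <- rowSums(dz1)
      dw1 <- dz1 %*% t(cache$s)
      ds <- t(layer$w1) %*% dz1 / hw
      dx <- matrix(dx, d[1]) + cs_expand(ds, hw)
      dim(dx) <- d
      list(dx = dx, grads = list(w1 = dw1, b1 = db1, w2 = dw2, b2 = db2))
    },
    dropout = {
      if (is.null(cache$mask)) return(list(dx = dy, grads = NULL))
      list(dx = scale_by_channel_sample(dy, cache$mask), grads = NULL)
    },
    residual = {
      r <- backward_layers(layer$body, dy, cache)
      list(dx = dy + r$dx, grads = list(body = r$grads))
    },
    stop("unknown layer kind: ", layer$kind))
}

backward_layers <- function(layers, dy, caches) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], dy, caches[[i]])
    dy <- r$dx
    grads[i] <- list(r$grads) # keep NULL placeholders for param-free layers
  }
  list(dx = dy, grads = grads)
}

# ---- parameter traversal -------------------------------------------------
# flat list of parameter paths; each path indexes both the layer tree and the
# parallel gradient tree (residual grads live under $body)

param_paths <- function(layers, prefix = list()) {
  out <- list()
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$kind == "residual") {
      out <- c(out, param_paths(ly$body, c(prefix, list(i, "body"))))
    } else {
      for (nm in intersect(c("w", "b", "w1", "b1", "w2", "b2", "gamma", "beta"),
                           names(ly))) {
        out[[length(out) + 1L]] <- list(
          path = c(prefix, list(i, nm)),
          decay = nm %in% ly$decay,
          is_bias = nm %in% c("b", "b1", "b2"))
      }
    }
  }
  out
}

pluck <- function(x, path) {
  for (k in path) x <- x[[k]]
  x
}

poke <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path[[1L]]]] <- value
    return(x)
  }
  x[[path[[1L]]]] <- poke(x[[path[[1L]]]], path[-1L], value)
  x
}

# gradient tree: same shape as the layer path space; grads from
# backward_layers use $grads nesting under residual$body already matching
pluck_grad <- function(grads, path) {
  for (k in path) grads <- grads[[k]]
  grads
}
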