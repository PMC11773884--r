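# small shared internals

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# evaluate fn() under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# split one root seed into n per-item seeds via a fixed counter scheme
derive_seeds <- function(seed, n) {
  with_seed(seed, function() sample.int(2147483646L, n, replace = FALSE))
}

# separable Gaussian blur with reflected borders; sigma in pixels
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(m) { # along rows (dimension 1)
    n <- nrow(m)
    if (n == 1L) return(m)
    idx <- outer(seq_len(n), (-r):r, `+`)
    idx <- abs(idx - 1) %% (2L * (n - 1L)) # reflect
    idx <- pmin(idx, 2L * (n - 1L) - idx) + 1L
    out <- matrix(0, n, ncol(m))
    for (j in seq_len(2L * r + 1L)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(blur_1d(t(blur_1d(img))))
}

# cheap FNV-1a style hash of an R object for provenance stamps
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2)[-(1:14)]) # skip header
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^32
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
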