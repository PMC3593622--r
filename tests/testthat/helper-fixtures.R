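# shared fixtures, cached across test files (generation is deterministic)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fix_subject <- function(noise_sd = 1, seed = 1, ...) {
  key <- paste0("subj_", noise_sd, "_", seed, "_", length(list(...)))
  cached(key, simulate_subject(synthetic_spec(noise_sd = noise_sd, seed = seed, ...)))
}

# independent Laplacian spatial maps mixed by the identity: the classical
# exactly-identifiable ICA test bed
laplacian_mix <- function(n = 5L, v = 2000L, seed = 7L) {
  key <- paste0("lap_", n, "_", v, "_", seed)
  cached(key, {
    set.seed(seed)
    maps <- t(vapply(seq_len(n), function(i) {
      x <- sample(c(-1, 1), v, replace = TRUE) * stats::rexp(v)
      as.numeric(scale(x)) * sqrt((v - 1) / v)
    }, numeric(v)))
    list(maps = maps, data = maps) # identity mixing: Y = I %*% X
  })
}

tiny_series <- function(t = 20L, grid = c(4L, 4L, 2L), seed = 3L) {
  set.seed(seed)
  v <- prod(grid)
  volume_series(matrix(rnorm(t * v), t, v), array(TRUE, grid), tr = 1)
}

standardize_test <- function(x) {
  x <- x - mean(x)
  x / sqrt(mean(x^2))
}

expect_no_ica <- function(expr) {
  before <- ica_call_count()
  force(expr)
  expect_identical(ica_call_count(), before)
}
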