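#' Build a block paradigm and its boxcar regressors
#'
#' The default design mirrors a lateralized visuo-motor block experiment:
#' 15 s of right-hemifield stimulation, 5 s fixation, 15 s left-hemifield
#' stimulation, 20 s fixation — a 55 s cycle repeated 4 times at TR = 1 s,
#' giving 220 volumes.
#'
#' @param segments data frame with columns `condition` and `duration`
#'   (seconds), one row per segment in presentation order.
#' @param n_cycles number of repetitions of the segment cycle.
#' @param tr repetition time in seconds. Durations that are not multiples
#'   of `tr` are rounded to the nearest TR with a warning.
#' @return list with `design` (segments, n_cycles, tr, cycle_seconds) and
#'   `boxcars`, a 0/1 matrix of `n_cycles * cycle TRs` rows with one column
#'   per distinct condition label.
#' @export
build_paradigm <- function(segments = default_segments(), n_cycles = 4L, tr = 1) {
  segments <- as.data.frame(segments)
  if (nrow(segments) == 0L) abort("`segments` must contain at least one segment")
  if (any(segments$duration <= 0)) abort("segment durations must be > 0")
  n_trs <- segments$duration / tr
  if (any(abs(n_trs - round(n_trs)) > 1e-8)) {
    warn("segment durations are not multiples of the TR; rounding to nearest TR")
  }
  n_trs <- as.integer(round(n_trs))
  conds <- unique(segments$condition)
  cycle <- rep(segments$condition, times = n_trs)
  full <- rep(cycle, times = n_cycles)
  boxcars <- matrix(vapply(conds, function(cn) as.numeric(full == cn),
                           numeric(length(full))),
                    ncol = length(conds), dimnames = list(NULL, conds))
  list(
    design = list(segments = segments, n_cycles = as.integer(n_cycles),
                  tr = tr, cycle_seconds = sum(n_trs) * tr),
    boxcars = boxcars
  )
}

default_segments <- function() {
  data.frame(condition = c("right", "fix", "left", "fix2"),
             duration = c(15, 5, 15, 20))
}

#' Convolve a boxcar with a canonical double-gamma HRF
#'
#' The impulse response peaks at 6 s, with an undershoot peaking at 16 s and
#' a peak-to-undershoot ratio of 6. The convolved regressor is truncated to
#' the input length and normalized to peak 1 (when non-zero).
#'
#' @param boxcar numeric 0/1 stimulus indicator sampled at TR resolution.
#' @param tr repetition time in seconds (> 0).
#' @return numeric vector of the same length as `boxcar`.
#' @export
hrf_regressor <- function(boxcar, tr = 1) {
  if (tr <= 0) abort("`tr` must be > 0")
  tt <- seq(0, 32, by = tr)
  h <- dgamma(tt, shape = 6, rate = 1) - dgamma(tt, shape = 16, rate = 1) / 6
  out <- convolve(boxcar, rev(h), type = "open")[seq_along(boxcar)]
  pk <- max(abs(out))
  if (pk > 0) out <- out / pk
  out
}

#' Specification of a synthetic BOLD subject
#'
#' Defines the grid, paradigm, the five network blobs (right and left
#' task-related, a midline DMN-like pair, and two smooth nuisance fields),
#' the noise level, and an optional spatial-drift schedule. The defaults
#' emulate a 220-volume lateralized visuo-motor session at TR = 1 s on a
#' desk-scale 12 x 12 x 6 grid; `noise_sd` is expressed relative to the
#' unit-variance network signals and `noise_sd = 1` is the reference level
#' at which the package's recovery guarantees are stated.
#'
#' @param grid_dims integer length-3 voxel grid.
#' @param segments,n_cycles,tr paradigm, as in [build_paradigm()].
#' @param noise_sd standard deviation of additive white Gaussian noise.
#' @param seed RNG seed; the whole dataset is a pure function of the spec.
#' @param drift optional list(network =, axis =, step =, every =): translate
#'   the named network's blob centers by `step` voxels along `axis` every
#'   `every` TRs (a scripted slow spatial drift; instantaneous true maps are
#'   retained in the ground truth).
#' @param smooth_noise also spatially smooth the additive noise (default
#'   `FALSE`).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(grid_dims = c(12L, 12L, 6L),
                           segments = default_segments(), n_cycles = 4L,
                           tr = 1, noise_sd = 1, seed = 1L, drift = NULL,
                           smooth_noise = FALSE) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  structure(
    list(grid_dims = as.integer(grid_dims), segments = segments,
         n_cycles = as.integer(n_cycles), tr = tr, noise_sd = noise_sd,
         seed = seed, drift = drift, smooth_noise = smooth_noise,
         networks = c("RVMT", "LVMT", "DMN", "N1", "N2")),
    class = "synthetic_spec"
  )
}

gaussian_blob <- function(grid, centers, radius) {
  co <- as.matrix(expand.grid(x = seq_len(grid[1]), y = seq_len(grid[2]),
                              z = seq_len(grid[3])))
  val <- numeric(nrow(co))
  for (k in seq_len(nrow(centers))) {
    d2 <- rowSums(sweep(co, 2L, centers[k, ])^2)
    val <- val + exp(-d2 / (2 * radius^2))
  }
  val
}

network_geometry <- function(grid) {
  gx <- grid[1]; gy <- grid[2]; gz <- grid[3]
  radius <- max(1.2, min(grid) / 4)
  list(
    RVMT = list(centers = rbind(c(gx * 0.8, gy * 0.5, gz * 0.55)),
                radius = radius),
    LVMT = list(centers = rbind(c(gx * 0.2, gy * 0.5, gz * 0.55)),
                radius = radius),
    # the DMN analogue is deliberately distributed: broad midline blobs give
    # a near-Gaussian (low-kurtosis) map, which together with its slow time
    # course makes it the hardest network for windowed ICA to pin down
    DMN = list(centers = rbind(c(gx * 0.5, gy * 0.2, gz * 0.7),
                               c(gx * 0.5, gy * 0.85, gz * 0.7)),
               radius = radius * 1.7)
  )
}

# standardized blob map of one structured network, optionally translated
network_blob_map <- function(grid, network, shift = c(0, 0, 0)) {
  geo <- network_geometry(grid)[[network]]
  if (is.null(geo)) abort(sprintf("no blob geometry for network '%s'", network))
  ctr <- sweep(geo$centers, 2L, shift, `+`)
  standardize(gaussian_blob(grid, ctr, geo$radius))
}

#' Generate the synthetic network spatial maps
#'
#' Builds five standardized maps on the spec's grid: mirrored lateral
#' Gaussian blobs for the right/left task networks, a midline blob pair for
#' the DMN analogue, and two smooth seeded random fields for nuisance
#' sources. Nuisance fields are redrawn (up to 100 times) until every
#' pairwise absolute correlation between maps is at most 0.3.
#'
#' @param spec a [synthetic_spec()].
#' @return numeric matrix `5 x v` with rownames
#'   `RVMT, LVMT, DMN, N1, N2`; each row has zero mean and unit variance.
#' @export
generate_network_maps <- function(spec) {
  grid <- spec$grid_dims
  v <- prod(grid)
  radius <- max(1.2, min(grid) / 4)
  fixed <- rbind(
    RVMT = network_blob_map(grid, "RVMT"),
    LVMT = network_blob_map(grid, "LVMT"),
    DMN = network_blob_map(grid, "DMN")
  )
  maps <- with_seed(spec$seed, {
    ok <- FALSE
    m <- NULL
    for (attempt in seq_len(100L)) {
      # nuisance sources live in the inferior slices (vascular/CSF-like),
      # clear of the task plane and the superior midline DMN
      nuis <- t(vapply(1:2, function(i) {
        co <- cbind(0.15 + 0.7 * runif(2), 0.15 + 0.7 * runif(2),
                    0.1 + 0.3 * runif(2))
        co <- sweep(co, 2L, grid, `*`)
        standardize(gaussian_blob(grid, co, radius * 0.8))
      }, numeric(v)))
      rownames(nuis) <- c("N1", "N2")
      m <- rbind(fixed, nuis)
      cm <- abs(cor(t(m)))
      diag(cm) <- 0
      if (max(cm) <= 0.3) {
        ok <- TRUE
        break
      }
    }
    if (!ok) abort("could not draw network maps with pairwise |r| <= 0.3")
    m
  })
  maps
}

# slow oscillation anti-correlated with the combined task regressor
dmn_course <- function(task_sum, tr, period) {
  n <- length(task_sum)
  tt <- seq(0, by = tr, length.out = n)
  phases <- seq(0, 2 * pi, length.out = 33L)[-33L]
  best <- NULL
  best_r <- Inf
  for (ph in phases) {
    s <- sin(2 * pi * tt / period + ph)
    r <- cor(s, task_sum)
    if (r < best_r) {
      best_r <- r
      best <- s
    }
  }
  best
}

#' Simulate a synthetic BOLD subject with retained ground truth
#'
#' Generates data under the linear mixing model `Y = A X + E`: task-network
#' time courses are HRF-convolved boxcars of their conditions, the DMN
#' analogue is a slow (cycle-period) oscillation phase-picked to
#' anti-correlate with the task, nuisance courses are smoothed white noise,
#' and all courses are standardized before mixing with the standardized
#' network maps of [generate_network_maps()]. Additive voxelwise white
#' Gaussian noise is scaled by `spec$noise_sd`; at `noise_sd = 0` the series
#' equals `A X` exactly. With a drift schedule, the drifting network's map
#' is regenerated per epoch and the instantaneous maps are retained.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_subject` with `series` (a
#'   [volume_series()]) and `truth` (true maps `5 x v`, true courses
#'   `t x 5`, the paradigm, the task regressors used, the DMN reference
#'   course, and per-epoch drift maps when drifting).
#' @export
simulate_subject <- function(spec = synthetic_spec()) {
  par <- build_paradigm(spec$segments, spec$n_cycles, spec$tr)
  n_t <- nrow(par$boxcars)
  task_conditions <- c("right", "left")
  missing_cond <- setdiff(task_conditions, colnames(par$boxcars))
  if (length(missing_cond)) {
    abort(sprintf("paradigm lacks condition(s): %s",
                  paste(missing_cond, collapse = ", ")))
  }
  reg <- cbind(
    RVMT = hrf_regressor(par$boxcars[, "right"], spec$tr),
    LVMT = hrf_regressor(par$boxcars[, "left"], spec$tr)
  )
  dmn_ref <- dmn_course(reg[, "RVMT"] + reg[, "LVMT"], spec$tr,
                        max(40, par$design$cycle_seconds))

  courses <- with_seed(spec$seed, {
    nuis <- vapply(1:2, function(i) {
      as.numeric(stats::filter(rnorm(n_t + 8L), rep(1 / 5, 5), sides = 2L))[5:(n_t + 4L)]
    }, numeric(n_t))
    cbind(RVMT = standardize(reg[, "RVMT"]),
          LVMT = standardize(reg[, "LVMT"]),
          DMN = standardize(dmn_ref),
          N1 = standardize(nuis[, 1]),
          N2 = standardize(nuis[, 2]))
  })

  maps <- generate_network_maps(spec)
  v <- ncol(maps)

  if (is.null(spec$drift)) {
    y <- courses %*% maps
    drift_maps <- NULL
    epochs <- NULL
  } else {
    dr <- spec$drift
    epochs <- floor((seq_len(n_t) - 1L) / dr$every)
    drift_maps <- lapply(sort(unique(epochs)), function(ep) {
      shift <- c(0, 0, 0)
      shift[dr$axis] <- ep * dr$step
      network_blob_map(spec$grid_dims, dr$network, shift = shift)
    })
    names(drift_maps) <- as.character(sort(unique(epochs)))
    y <- matrix(0, n_t, v)
    for (ep in sort(unique(epochs))) {
      rows <- which(epochs == ep)
      m_ep <- maps
      m_ep[dr$network, ] <- drift_maps[[as.character(ep)]]
      y[rows, ] <- courses[rows, , drop = FALSE] %*% m_ep
    }
  }

  if (spec$noise_sd > 0) {
    noise <- with_seed(derive_seed(spec$seed, 7919L),
                       matrix(rnorm(n_t * v, sd = spec$noise_sd), n_t, v))
    if (isTRUE(spec$smooth_noise)) {
      for (i in seq_len(n_t)) {
        noise[i, ] <- as.numeric(smooth_array3(array(noise[i, ], spec$grid_dims)))
      }
      noise <- noise * (spec$noise_sd / sd(as.numeric(noise)))
    }
    y <- y + noise
  }

  mask <- array(TRUE, dim = spec$grid_dims)
  series <- volume_series(y, mask, voxel_size = c(3, 3, 5), tr = spec$tr,
                          subject_id = sprintf("synthetic-seed%s", spec$seed))
  truth <- structure(
    list(true_maps = maps, true_courses = courses, paradigm = par,
         regressors = reg, dmn_reference = dmn_ref, drift = spec$drift,
         drift_maps = drift_maps, drift_epochs = epochs, spec = spec),
    class = "synthetic_truth"
  )
  structure(list(series = series, truth = truth), class = "synthetic_subject")
}

# light 3D box smoothing used for the optional smooth-noise regime
smooth_array3 <- function(arr) {
  d <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    idx_lo <- pmax(seq_len(d[ax]) - 1L, 1L)
    idx_hi <- pmin(seq_len(d[ax]) + 1L, d[ax])
    if (ax == 1L) out <- (out[idx_lo, , , drop = FALSE] + 2 * out + out[idx_hi, , , drop = FALSE]) / 4
    if (ax == 2L) out <- (out[, idx_lo, , drop = FALSE] + 2 * out + out[, idx_hi, , drop = FALSE]) / 4
    if (ax == 3L) out <- (out[, , idx_lo, drop = FALSE] + 2 * out + out[, , idx_hi, drop = FALSE]) / 4
  }
  out
}

#' Instantaneous true map of a network at a given TR
#'
#' For drifting subjects, returns the map active during the epoch containing
#' `tr`; otherwise the static true map.
#'
#' @param truth the `truth` element of [simulate_subject()].
#' @param network network name.
#' @param tr 0-based TR index.
#' @return numeric map vector.
#' @export
true_map_at <- function(truth, network, tr) {
  if (is.null(truth$drift) || truth$drift$network != network) {
    return(truth$true_maps[network, ])
  }
  ep <- as.character(floor(tr / truth$drift$every))
  truth$drift_maps[[ep]]
}

#' @export
print.synthetic_subject <- function(x, ...) {
  print(x$series)
  cat(sprintf("  networks: %s; noise_sd = %g%s\n",
              paste(rownames(x$truth$true_maps), collapse = ", "),
              x$truth$spec$noise_sd,
              if (is.null(x$truth$drift)) "" else "; drifting"))
  invisible(x)
}
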