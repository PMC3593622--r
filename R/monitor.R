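#' Monitoring configuration
#'
#' @param method one of `"bp"` (static back-projection), `"rtc"` (recursive
#'   temporally constrained), `"rsc"` (recursive spatially constrained),
#'   `"rstc"` (recursive spatio-temporal).
#' @param window_length sliding-window length in TRs (default 15, roughly
#'   the period of the behavior being monitored). Must be at least the ICA
#'   model order for the window-ICA methods.
#' @param ica an [ica_config()] used by the window decompositions.
#' @param time_budget optional wall-clock seconds allowed per update; when
#'   exceeded the update is skipped: the previous spatial map is carried and
#'   the amplitude falls back to back-projection onto it.
#' @return list of class `monitor_config`.
#' @export
monitor_config <- function(method = c("bp", "rtc", "rsc", "rstc"),
                           window_length = 15L, ica = ica_config(),
                           time_budget = NULL) {
  method <- match.arg(method)
  if (method != "bp" && window_length < ica$model_order) {
    abort("`window_length` must be at least the ICA model order")
  }
  structure(
    list(method = method, window_length = as.integer(window_length),
         ica = ica, time_budget = time_budget),
    class = "monitor_config"
  )
}

#' Stream volumes from a series as in a real-time acquisition
#'
#' @param series a [volume_series()].
#' @param start 0-based index of the first streamed volume (default 60, the
#'   functional-localizer length).
#' @return list of volumes (as from [get_volume()]), in acquisition order.
#' @export
stream_volumes <- function(series, start = 60L) {
  if (start < 0L || start > n_volumes(series) - 1L) abort("`start` out of range")
  lapply(seq.int(start, n_volumes(series) - 1L), get_volume, series = series)
}

monitor_row <- function(tr_index, amplitude, dynamic_map, fl_amplitude = NA_real_,
                        converged = NA, skipped = FALSE, warmup = FALSE,
                        compute_seconds = NA_real_, amplitudes = NULL) {
  tibble(
    tr_index = as.integer(tr_index),
    amplitude = amplitude,
    fl_amplitude = fl_amplitude,
    converged = converged,
    skipped = skipped,
    warmup = warmup,
    compute_seconds = compute_seconds,
    amplitudes = list(amplitudes %||% amplitude),
    dynamic_map = list(dynamic_map)
  )
}

stack_target_maps <- function(targets) {
  if (inherits(targets, "target_ic")) targets <- list(targets)
  do.call(rbind, lapply(targets, function(t) t$spatial_map))
}

#' Static back-projection update
#'
#' Projects one newly acquired volume onto the fixed localizer map(s) via
#' the pseudo-inverse; no ICA is executed. With several targets the stacked
#' pseudo-inverse yields all amplitudes jointly.
#'
#' @param volume a volume from [get_volume()] or a plain value vector.
#' @param targets a [target_ic()] or list of them.
#' @return one-row tibble (tr_index, amplitude, dynamic_map, ...); with
#'   multiple targets `amplitudes` holds the joint vector and `amplitude`
#'   its first entry. `dynamic_map` is the (static) first target map.
#' @export
bp_update <- function(volume, targets) {
  maps <- stack_target_maps(targets)
  t0 <- proc.time()[["elapsed"]]
  amps <- pseudo_project(volume, maps)
  monitor_row(
    tr_index = if (is.list(volume)) volume$index else NA_integer_,
    amplitude = amps[1], dynamic_map = maps[1, ],
    converged = TRUE, compute_seconds = proc.time()[["elapsed"]] - t0,
    amplitudes = amps
  )
}

# shared temporally-constrained window decomposition: back-project the
# window onto the static FL map to get the prior course a_n, seed the first
# whitened-space unmixing row from it (the prior's direction is also kept
# inside the whitened subspace), run window FastICA, and return the
# monitored component. Symmetric updates do not preserve row order, so the
# component is re-identified by maximal spatial correlation with the
# localizer map (the framework's real-time selection rule).
tc_window_fit <- function(window, fl_map, ica,
                          select = c("spatial", "temporal", "combined")) {
  select <- match.arg(select)
  a_n <- drop(window %*% fl_map) / sum(fl_map^2)
  dec <- fastica(window, ica, init_courses = matrix(a_n, ncol = 1L))
  sp_scores <- apply(dec$sources, 1L, cor, y = fl_map)
  tc_scores <- if (sd(a_n) > 0) apply(dec$mixing, 2L, cor, y = a_n) else sp_scores
  strength <- switch(select,
    spatial = abs(sp_scores),
    temporal = abs(tc_scores),
    combined = abs(sp_scores) + abs(tc_scores)
  )
  sel <- which.max(strength)
  map <- dec$sources[sel, ]
  course <- dec$mixing[, sel]
  # sign: follow the reference where the spatial match is meaningful;
  # otherwise keep the decomposition's non-negative-skewness convention
  # (a weakly overlapping reference would assign an arbitrary, often
  # inverted, sign to a genuinely displaced component)
  if (sp_scores[sel] < -0.2) {
    map <- -map
    course <- -course
  }
  # the decomposition is fitted on centered data, so the component's window
  # course is mean-free; restore the window's DC level from the prior
  course <- course + mean(a_n)
  list(map = map, course = course, prior_course = a_n,
       converged = dec$converged)
}

#' Recursive temporally constrained update
#'
#' Back-projects the current window onto the static localizer map to obtain
#' the prior time course, runs window FastICA seeded with that course
#' (first unmixing row), and reads the amplitude off the seeded component's
#' window time course. The spatial map is therefore updated every TR while
#' the temporal prior stays anchored to the localizer.
#'
#' @param window numeric `Delta x v` window matrix (see [extract_window()]).
#' @param fl_target the [target_ic()] from the localizer.
#' @param config a [monitor_config()].
#' @param tr_index 0-based index of the window's last volume.
#' @return one-row tibble; `dynamic_map` is the updated map, `amplitude`
#'   the last entry of the component's window course.
#' @export
rtc_update <- function(window, fl_target, config, tr_index = NA_integer_) {
  if (nrow(window) < config$window_length) abort("window is not full")
  t0 <- proc.time()[["elapsed"]]
  fit <- tc_window_fit(window, fl_target$spatial_map, config$ica)
  monitor_row(tr_index, amplitude = fit$course[length(fit$course)],
              dynamic_map = fit$map, converged = fit$converged,
              compute_seconds = proc.time()[["elapsed"]] - t0)
}

#' Recursive spatially constrained update
#'
#' Extracts one component from the window with [constrained_extract()],
#' anchored to the localizer map, then back-projects the newly acquired
#' volume onto the updated map for the amplitude.
#'
#' @inheritParams rtc_update
#' @param volume the newly acquired volume (vector or [get_volume()] item).
#' @return one-row tibble.
#' @export
rsc_update <- function(window, volume, fl_target, config,
                       tr_index = NA_integer_) {
  if (nrow(window) < config$window_length) abort("window is not full")
  t0 <- proc.time()[["elapsed"]]
  ce <- constrained_extract(window, fl_target$spatial_map, config$ica)
  amp <- pseudo_project(volume, ce$map)
  monitor_row(tr_index, amplitude = amp, dynamic_map = ce$map,
              converged = ce$converged,
              compute_seconds = proc.time()[["elapsed"]] - t0)
}

#' Recursive spatio-temporal update
#'
#' Three concatenated steps: (1) back-project the new volume onto the static
#' localizer map (`fl_amplitude`); (2) run the temporally constrained window
#' decomposition and shrink the resulting component halfway toward the
#' localizer map — the subject-space map adapts to the new data while
#' keeping the localizer-defined characteristics as its target; (3)
#' back-project the new volume onto that subject-space map for the final
#' amplitude.
#'
#' @inheritParams rsc_update
#' @return one-row tibble with both `fl_amplitude` (localizer space) and
#'   `amplitude` (subject space).
#' @export
rstc_update <- function(window, volume, fl_target, config,
                        tr_index = NA_integer_) {
  if (nrow(window) < config$window_length) abort("window is not full")
  t0 <- proc.time()[["elapsed"]]
  a_fl <- pseudo_project(volume, fl_target$spatial_map)
  fit <- tc_window_fit(window, fl_target$spatial_map, config$ica)
  x_sub <- standardize(0.5 * fit$map + 0.5 * fl_target$spatial_map)
  a_sub <- pseudo_project(volume, x_sub)
  monitor_row(tr_index, amplitude = a_sub, fl_amplitude = a_fl,
              dynamic_map = x_sub, converged = fit$converged,
              compute_seconds = proc.time()[["elapsed"]] - t0)
}

#' Run a full simulated real-time monitoring session
#'
#' Streams the series volume by volume from `start` (the end of the
#' functional localizer) and applies the configured method at every TR.
#' Window methods warm up on back-projection until `window_length` post-FL
#' volumes exist; thereafter the causal window of the most recent volumes
#' advances one TR per step. Individual step failures or per-update time
#' budget overruns never raise: the step is recorded with `skipped = TRUE`,
#' the previous spatial map is carried and the amplitude falls back to
#' back-projection onto it. Deterministic given the ICA seed (per-step
#' seeds are derived from it).
#'
#' @param series a [volume_series()].
#' @param config a [monitor_config()].
#' @param fl_target the [target_ic()] selected from the localizer.
#' @param start 0-based first monitored TR (default 60).
#' @return a tibble of class `rtica_session`, one row per monitored TR with
#'   columns `tr_index`, `amplitude`, `fl_amplitude`, `converged`,
#'   `skipped`, `warmup`, `compute_seconds` and list-column `dynamic_map`.
#' @export
run_session <- function(series, config, fl_target, start = 60L) {
  t_total <- n_volumes(series)
  if (start < 0L || start > t_total - 1L) abort("series too short for the requested start")
  method <- config$method
  delta <- config$window_length
  budget <- config$time_budget
  fl_map <- fl_target$spatial_map
  base_seed <- config$ica$seed
  prev_map <- fl_map

  rows <- vector("list", t_total - start)
  for (tr in seq.int(start, t_total - 1L)) {
    y <- series$data[tr + 1L, ]
    n_post <- tr - start + 1L
    t0 <- proc.time()[["elapsed"]]

    if (method == "bp" || n_post < delta) {
      row <- bp_update(list(values = y, index = tr), fl_target)
      row$warmup <- method != "bp"
      prev_map <- row$dynamic_map[[1L]]
      rows[[tr - start + 1L]] <- row
      next
    }

    window <- series$data[(tr - delta + 2L):(tr + 1L), , drop = FALSE]
    step_ica <- config$ica
    step_ica$seed <- derive_seed(base_seed, tr)
    step_cfg <- config
    step_cfg$ica <- step_ica

    skip_row <- function(a_fl = NA_real_) {
      amp <- pseudo_project(y, prev_map)
      monitor_row(tr, amplitude = amp, dynamic_map = prev_map,
                  fl_amplitude = a_fl, converged = FALSE, skipped = TRUE,
                  compute_seconds = proc.time()[["elapsed"]] - t0)
    }

    row <- if (!is.null(budget) && budget <= 0) {
      skip_row(if (method == "rstc") pseudo_project(y, fl_map) else NA_real_)
    } else {
      tryCatch({
        r <- switch(method,
          rtc = rtc_update(window, fl_target, step_cfg, tr),
          rsc = rsc_update(window, y, fl_target, step_cfg, tr),
          rstc = rstc_update(window, y, fl_target, step_cfg, tr)
        )
        if (!is.null(budget) &&
            proc.time()[["elapsed"]] - t0 > budget) {
          skip_row(r$fl_amplitude)
        } else r
      }, error = function(e) skip_row())
    }
    prev_map <- row$dynamic_map[[1L]]
    rows[[tr - start + 1L]] <- row
  }

  out <- dplyr::bind_rows(rows)
  attr(out, "method") <- method
  attr(out, "window_length") <- delta
  attr(out, "start") <- as.integer(start)
  attr(out, "fl_label") <- fl_target$label
  class(out) <- c("rtica_session", class(out))
  out
}
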