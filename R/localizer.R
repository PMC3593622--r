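#' Construct a target independent component
#'
#' The object monitored in real time: a standardized spatial map plus the
#' time course it had in the decomposition it was selected from.
#'
#' @param spatial_map standardized numeric vector over in-mask voxels.
#' @param time_course numeric vector over the fitted TRs.
#' @param source_index 1-based component ordinal in its decomposition.
#' @param selection_score the correlation that drove the selection.
#' @param label network name (e.g. `"DMN"`, `"RVMT"`, `"LVMT"`).
#' @return object of class `target_ic`.
#' @export
target_ic <- function(spatial_map, time_course = NULL, source_index = NA_integer_,
                      selection_score = NA_real_, label = NA_character_) {
  if (!is.na(selection_score) && abs(selection_score) > 1 + 1e-8) {
    abort("`selection_score` must lie in [-1, 1]")
  }
  structure(
    list(spatial_map = as.numeric(spatial_map), time_course = time_course,
         source_index = as.integer(source_index),
         selection_score = selection_score, label = label),
    class = "target_ic"
  )
}

#' @export
print.target_ic <- function(x, ...) {
  cat(sprintf("<target_ic> %s: component %s, selection score %.3f, %d voxels\n",
              x$label, x$source_index, x$selection_score,
              length(x$spatial_map)))
  invisible(x)
}

#' Build gold-standard network templates from the full series
#'
#' Fits FastICA on all time points, then labels components greedily: each
#' task regressor claims the unused component whose time course has maximal
#' absolute temporal correlation with it; additional reference courses (for
#' networks without a task regressor, e.g. a slow DMN-like oscillation) and
#' reference maps (matched by spatial correlation) claim components the same
#' way. No component receives two labels. Each template is sign-aligned so
#' its course correlates positively with its regressor (or its map with the
#' reference map).
#'
#' @param series a [volume_series()].
#' @param config an [ica_config()]; `model_order` must be at least the
#'   number of requested labels.
#' @param regressors numeric matrix `t x k` of task regressors with column
#'   names used as labels.
#' @param reference_courses optional `t x m` matrix of non-task reference
#'   time courses (named columns).
#' @param reference_maps optional `m x v` matrix of reference spatial maps
#'   (named rows).
#' @param min_score below this absolute correlation a label is still
#'   assigned but a warning is emitted (default 0.3).
#' @param restarts seeded FastICA restarts, keeping the highest-negentropy
#'   fit (default 3; identification-phase fits are worth protecting from
#'   local optima).
#' @return object of class `template_set`: the full-series decomposition
#'   plus a named list of [target_ic()] templates.
#' @export
build_templates <- function(series, config = ica_config(), regressors,
                            reference_courses = NULL, reference_maps = NULL,
                            min_score = 0.3, restarts = 3L) {
  regressors <- as.matrix(regressors)
  n_labels <- ncol(regressors) +
    (if (is.null(reference_courses)) 0L else ncol(as.matrix(reference_courses))) +
    (if (is.null(reference_maps)) 0L else nrow(reference_maps))
  if (config$model_order < n_labels) {
    abort("model order is smaller than the number of requested labels")
  }
  dec <- fastica(series$data, config, restarts = restarts)
  if (!dec$converged) {
    warn("full-series decomposition did not converge within the iteration cap")
  }

  used <- integer(0)
  templates <- list()
  claim <- function(scores, label) {
    strength <- abs(scores)
    strength[used] <- -Inf
    idx <- which.max(strength - 1e-12 * seq_along(scores)) # ties -> lowest index
    used <<- c(used, idx)
    if (abs(scores[idx]) < min_score) {
      warn(sprintf("label '%s': best match only |r| = %.2f", label,
                   abs(scores[idx])))
    }
    flip <- if (scores[idx] < 0) -1 else 1
    templates[[label]] <<- target_ic(
      spatial_map = flip * dec$sources[idx, ],
      time_course = flip * dec$mixing[, idx],
      source_index = idx,
      selection_score = abs(scores[idx]),
      label = label
    )
  }

  for (j in seq_len(ncol(regressors))) {
    lab <- colnames(regressors)[j] %||% paste0("task", j)
    claim(apply(dec$mixing, 2L, cor, y = regressors[, j]), lab)
  }
  if (!is.null(reference_courses)) {
    rc <- as.matrix(reference_courses)
    for (j in seq_len(ncol(rc))) {
      lab <- colnames(rc)[j] %||% paste0("ref", j)
      claim(apply(dec$mixing, 2L, cor, y = rc[, j]), lab)
    }
  }
  if (!is.null(reference_maps)) {
    for (j in seq_len(nrow(reference_maps))) {
      lab <- rownames(reference_maps)[j] %||% paste0("map", j)
      claim(apply(dec$sources, 1L, cor, y = reference_maps[j, ]), lab)
    }
  }

  structure(list(decomposition = dec, templates = templates), class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d components, labeled: %s\n",
              x$decomposition$n_components,
              paste(names(x$templates), collapse = ", ")))
  invisible(x)
}

#' Run the ICA functional localizer on the initial block
#'
#' Fits FastICA on the first `fl_length` TRs only — the simulated
#' functional-localizer session from which the target component is selected
#' before monitoring begins.
#'
#' @param series a [volume_series()].
#' @param fl_length number of initial TRs (default 60).
#' @param config an [ica_config()].
#' @param restarts seeded FastICA restarts (default 3), as in
#'   [build_templates()].
#' @return an `ica_decomposition` fitted on rows `0..fl_length-1`.
#' @export
run_localizer <- function(series, fl_length = 60L, config = ica_config(),
                          restarts = 3L) {
  if (fl_length > n_volumes(series)) abort("`fl_length` exceeds the series length")
  if (fl_length < config$model_order) abort("`fl_length` is below the model order")
  fastica(series$data[seq_len(fl_length), , drop = FALSE], config,
          restarts = restarts)
}

#' Select the localizer component matching a template
#'
#' Picks the functional-localizer component whose spatial map has maximal
#' absolute Pearson correlation with the template map (ties broken by lowest
#' component index), sign-aligns it to the template, and records the
#' selection score.
#'
#' @param fl an `ica_decomposition` from [run_localizer()].
#' @param template a [target_ic()] or a plain map vector.
#' @return a [target_ic()] holding the selected map and its localizer time
#'   course.
#' @export
select_target <- function(fl, template) {
  tmap <- if (inherits(template, "target_ic")) template$spatial_map else as.numeric(template)
  if (fl$n_components < 1L) abort("empty decomposition")
  scores <- apply(fl$sources, 1L, cor, y = tmap)
  idx <- which.max(abs(scores) - 1e-12 * seq_along(scores))
  flip <- if (scores[idx] < 0) -1 else 1
  target_ic(
    spatial_map = flip * fl$sources[idx, ],
    time_course = flip * fl$mixing[, idx],
    source_index = idx,
    selection_score = abs(scores[idx]),
    label = if (inherits(template, "target_ic")) template$label else "target"
  )
}
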