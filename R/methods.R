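#' Tidy an ICA decomposition into per-component statistics
#'
#' @param x an `ica_decomposition`.
#' @param ... unused.
#' @return tibble with one row per component: map skewness and kurtosis and
#'   the course variance (the energy the component carries).
#' @method tidy ica_decomposition
#' @export
tidy.ica_decomposition <- function(x, ...) {
  mc <- x$sources - rowMeans(x$sources)
  s2 <- rowMeans(mc^2)
  tibble(
    component = seq_len(x$n_components),
    map_skewness = rowMeans(mc^3) / s2^1.5,
    map_kurtosis = rowMeans(mc^4) / s2^2 - 3,
    course_variance = apply(x$mixing, 2L, var)
  )
}

#' @method glance ica_decomposition
#' @export
glance.ica_decomposition <- function(x, ...) {
  tibble(
    n_components = x$n_components,
    n_time_points = nrow(x$mixing),
    n_voxels = ncol(x$sources),
    converged = x$converged,
    n_iterations = x$n_iterations
  )
}

#' Plot the component time courses of a decomposition
#'
#' @param object an `ica_decomposition`.
#' @param ... unused.
#' @return a ggplot: one facet per component, course over TRs.
#' @method autoplot ica_decomposition
#' @export
autoplot.ica_decomposition <- function(object, ...) {
  df <- as_tibble(object$mixing, .name_repair = ~ paste0("IC", seq_along(.x))) |>
    dplyr::mutate(tr = dplyr::row_number() - 1L) |>
    tidyr::pivot_longer(-"tr", names_to = "component", values_to = "amplitude")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tr, y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "TR", y = "course amplitude")
}

#' @method glance rtica_session
#' @export
glance.rtica_session <- function(x, ...) {
  tibble(
    method = attr(x, "method"),
    n_trs = nrow(x),
    n_skipped = sum(x$skipped),
    n_warmup = sum(x$warmup),
    mean_compute_s = mean(x$compute_seconds, na.rm = TRUE)
  )
}

#' Plot the monitored amplitude trace of a session
#'
#' @param object an `rtica_session` from [run_session()].
#' @param reference optional reference course (full series or monitored TRs
#'   only) overlaid after least-squares scaling to the estimate.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot rtica_session
#' @export
autoplot.rtica_session <- function(object, reference = NULL, ...) {
  df <- tibble(tr = object$tr_index, amplitude = object$amplitude,
               series = "estimate")
  if (!is.null(reference)) {
    ref <- if (length(reference) > nrow(object)) reference[object$tr_index + 1L] else reference
    b <- drop(crossprod(ref, object$amplitude) / crossprod(ref))
    df <- dplyr::bind_rows(df, tibble(tr = object$tr_index,
                                      amplitude = ref * b,
                                      series = "reference (scaled)"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tr, y = .data$amplitude,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "TR", y = "amplitude",
                  title = sprintf("%s monitoring (%s)",
                                  toupper(attr(object, "method") %||% ""),
                                  attr(object, "fl_label") %||% ""))
}

#' Plot evaluation results by method and network
#'
#' @param object an `rtica_evaluation` from [evaluate_all()].
#' @param metric `"temporal_r"` or `"spatial_r"`.
#' @param ... unused.
#' @return a ggplot of trial-level scores, one panel per network.
#' @method autoplot rtica_evaluation
#' @export
autoplot.rtica_evaluation <- function(object, metric = c("temporal_r", "spatial_r"),
                                      ...) {
  metric <- match.arg(metric)
  df <- dplyr::filter(object, !.data$failed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~network) +
    ggplot2::labs(x = NULL, y = metric)
}

#' Export a session's per-TR results as CSV
#'
#' Writes tr_index, amplitude, fl_amplitude, converged, skipped,
#' compute_seconds (and, when a template map is given, the per-TR spatial
#' correlation of the dynamic map to it).
#'
#' @param session an `rtica_session`.
#' @param path output CSV path.
#' @param template_map optional reference map for the per-TR spatial
#'   correlation column.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(session, path, template_map = NULL) {
  df <- dplyr::select(as_tibble(session), -"dynamic_map", -"amplitudes")
  if (!is.null(template_map)) {
    df$spatial_corr_to_template <- vapply(
      session$dynamic_map, spatial_correlation, numeric(1),
      map_b = template_map
    )
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
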