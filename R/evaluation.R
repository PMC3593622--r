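#' Temporal correlation between an amplitude series and a reference course
#'
#' @param estimate numeric amplitude series.
#' @param reference reference time course of the same length (a template
#'   course restricted to the monitored TRs, or a true mixing column).
#' @return Pearson correlation.
#' @export
temporal_correlation <- function(estimate, reference) {
  if (length(estimate) != length(reference)) abort("series lengths differ")
  if (length(estimate) < 3L) abort("need at least 3 time points")
  if (!all(is.finite(estimate)) || !all(is.finite(reference))) {
    abort("non-finite values in input series")
  }
  if (sd(estimate) == 0 || sd(reference) == 0) abort("zero-variance input series")
  cor(estimate, reference)
}

#' Spatial correlation between two maps over in-mask voxels
#'
#' @param map_a,map_b numeric map vectors of equal length.
#' @param absolute return `|r|` (sign-agnostic matching) instead of `r`.
#' @return Pearson correlation (or its absolute value).
#' @export
spatial_correlation <- function(map_a, map_b, absolute = FALSE) {
  if (length(map_a) != length(map_b)) abort("map lengths differ")
  if (sd(map_a) == 0 || sd(map_b) == 0) abort("zero-variance map")
  r <- cor(map_a, map_b)
  if (absolute) abs(r) else r
}

#' Dice overlap of supra-threshold voxels
#'
#' Alternative sign-agnostic spatial-overlap metric: both maps are
#' z-thresholded at `|z| > threshold` and the Dice coefficient of the
#' binarized supports is returned.
#'
#' @param map_a,map_b numeric map vectors (standardized or standardizable).
#' @param threshold absolute z threshold (default 1.5).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_overlap <- function(map_a, map_b, threshold = 1.5) {
  a <- abs(standardize(map_a)) > threshold
  b <- abs(standardize(map_b)) > threshold
  if (sum(a) + sum(b) == 0) return(0)
  2 * sum(a & b) / (sum(a) + sum(b))
}

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

#' Match estimated components to ground-truth maps
#'
#' ICA recovers sources up to permutation and sign; this finds the
#' assignment of estimated components to truth maps maximizing the total
#' absolute spatial correlation (exhaustive over permutations up to 8
#' components, greedy beyond).
#'
#' @param estimated an `ica_decomposition` or a `k x v` matrix of maps.
#' @param truth_maps `m x v` matrix of reference maps (`m <= k`).
#' @return tibble with columns `truth` (rowname or index), `component`
#'   (matched estimated row), `r` (signed) and `abs_r`.
#' @export
match_components <- function(estimated, truth_maps) {
  est <- if (inherits(estimated, "ica_decomposition")) estimated$sources else as.matrix(estimated)
  truth_maps <- as.matrix(truth_maps)
  k <- nrow(est); m <- nrow(truth_maps)
  if (m > k) abort("more truth maps than estimated components")
  rmat <- cor(t(truth_maps), t(est)) # m x k signed correlations
  amat <- abs(rmat)

  if (k <= 8L) {
    best <- NULL; best_sum <- -Inf
    for (p in all_perms(k)) {
      sel <- p[seq_len(m)]
      s <- sum(amat[cbind(seq_len(m), sel)])
      if (s > best_sum) {
        best_sum <- s
        best <- sel
      }
    }
    assign <- best
  } else {
    assign <- integer(m)
    avail <- rep(TRUE, k)
    for (i in order(-apply(amat, 1L, max))) {
      j <- which.max(ifelse(avail, amat[i, ], -Inf))
      assign[i] <- j
      avail[j] <- FALSE
    }
  }

  tibble(
    truth = rownames(truth_maps) %||% as.character(seq_len(m)),
    component = assign,
    r = rmat[cbind(seq_len(m), assign)],
    abs_r = amat[cbind(seq_len(m), assign)]
  )
}

#' Score a monitoring session against a reference map and course
#'
#' The two headline metrics: `spatial_r`, the mean over monitored TRs of the
#' spatial correlation between the per-TR dynamic map and the reference map;
#' and `temporal_r`, the single Pearson correlation of the full amplitude
#' series with the reference course restricted to the monitored TRs.
#'
#' @param session an `rtica_session` from [run_session()].
#' @param reference_map template (or true) spatial map.
#' @param reference_course template (or true) time course over all TRs, or
#'   already restricted to the monitored TRs.
#' @param absolute use `|r|` for the per-TR spatial correlations.
#' @return one-row tibble: `spatial_r`, `temporal_r`, `mean_compute_s`,
#'   `prop_skipped`.
#' @export
score_session <- function(session, reference_map, reference_course,
                          absolute = FALSE) {
  ref_course <- reference_course
  if (length(ref_course) > nrow(session)) {
    ref_course <- ref_course[session$tr_index + 1L]
  }
  sp <- vapply(session$dynamic_map, spatial_correlation, numeric(1),
               map_b = reference_map, absolute = absolute)
  tibble(
    spatial_r = mean(sp),
    temporal_r = temporal_correlation(session$amplitude, ref_course),
    mean_compute_s = mean(session$compute_seconds, na.rm = TRUE),
    prop_skipped = mean(session$skipped)
  )
}

#' Run-to-run stability of a stochastic monitoring method
#'
#' Repeats the full monitoring session on the *same* data with different
#' algorithm seeds and summarizes the spread (standard deviation across
#' trials) of the run-level mean spatial and temporal correlations — the
#' stochastic-variability protocol. Runs that fail are recorded, not raised.
#'
#' @param session_factory function(seed) returning an `rtica_session`.
#' @param seeds integer vector of algorithm seeds, one per run (>= 2).
#' @param reference_map,reference_course scoring references as in
#'   [score_session()].
#' @return tibble of class `stability_runs` with one row per run
#'   (`run`, `seed`, `spatial_r`, `temporal_r`, `failed`); [glance()] it for
#'   the mean/sd summary.
#' @export
stability_across_runs <- function(session_factory, seeds, reference_map,
                                  reference_course) {
  if (length(seeds) < 2L) abort("need at least 2 runs")
  rows <- purrr::imap(seeds, function(seed, i) {
    res <- tryCatch({
      s <- session_factory(seed)
      sc <- score_session(s, reference_map, reference_course)
      tibble(run = i, seed = seed, spatial_r = sc$spatial_r,
             temporal_r = sc$temporal_r, failed = FALSE)
    }, error = function(e) {
      tibble(run = i, seed = seed, spatial_r = NA_real_,
             temporal_r = NA_real_, failed = TRUE)
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stability_runs", class(out))
  out
}

#' @method glance stability_runs
#' @export
glance.stability_runs <- function(x, ...) {
  tibble(
    n_runs = nrow(x),
    n_failed = sum(x$failed),
    mean_spatial_r = mean(x$spatial_r, na.rm = TRUE),
    sd_spatial_r = sd(x$spatial_r, na.rm = TRUE),
    mean_temporal_r = mean(x$temporal_r, na.rm = TRUE),
    sd_temporal_r = sd(x$temporal_r, na.rm = TRUE)
  )
}

#' Full factorial evaluation of monitoring methods
#'
#' For each synthetic subject: builds full-series templates, runs the
#' functional localizer, selects each requested network's target, and runs
#' every method `n_runs` times with varying algorithm seeds. Scores each
#' session against the subject's template map and course. Cell failures are
#' recorded (`failed = TRUE`), never raised.
#'
#' @param subjects list of `synthetic_subject` objects (see
#'   [simulate_subject()]).
#' @param methods character vector among `"bp","rtc","rsc","rstc"`.
#' @param networks character vector among the template labels (default
#'   `c("RVMT","LVMT","DMN")`).
#' @param n_runs repetitions per cell with different algorithm seeds.
#' @param fl_length functional-localizer length in TRs (default 60).
#' @param window_length,model_order monitoring parameters (defaults 15, 5).
#' @param base_seed seed stream root for the per-run algorithm seeds.
#' @param reference score sessions against the full-series `"template"`
#'   (the observable gold standard, as in real data) or against the
#'   generator's `"truth"` (maps and courses the data were built from).
#' @return tibble of class `rtica_evaluation`: one row per
#'   (subject, method, network, run) with `spatial_r`, `temporal_r`,
#'   `mean_compute_s`, `failed`. Summarize with [summarize_evaluation()].
#' @export
evaluate_all <- function(subjects, methods = c("bp", "rtc", "rsc", "rstc"),
                         networks = c("RVMT", "LVMT", "DMN"), n_runs = 10L,
                         fl_length = 60L, window_length = 15L,
                         model_order = 5L, base_seed = 1L,
                         reference = c("template", "truth")) {
  reference = match.arg(reference)
  if (length(subjects) < 1L || length(methods) < 1L) {
    abort("need at least one subject and one method")
  }
  if (inherits(subjects, "synthetic_subject")) subjects <- list(subjects)
  rows <- list()
  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    tset <- suppressWarnings(build_templates(
      sub$series, ica_config(model_order, seed = derive_seed(base_seed, si)),
      regressors = sub$truth$regressors,
      reference_courses = cbind(DMN = sub$truth$dmn_reference)
    ))
    fl <- run_localizer(sub$series, fl_length,
                        ica_config(model_order, seed = derive_seed(base_seed, 100L + si)))
    for (net in networks) {
      tpl <- tset$templates[[net]]
      if (is.null(tpl)) abort(sprintf("no template labeled '%s'", net))
      tgt <- select_target(fl, tpl)
      if (reference == "template") {
        ref_map <- tpl$spatial_map
        ref_course <- tpl$time_course
      } else {
        ref_map <- sub$truth$true_maps[net, ]
        ref_course <- sub$truth$true_courses[, net]
      }
      for (method in methods) {
        for (run in seq_len(n_runs)) {
          seed <- derive_seed(base_seed, si * 100000L + run * 1000L + match(method, c("bp", "rtc", "rsc", "rstc")))
          cell <- tryCatch({
            cfg <- monitor_config(method, window_length,
                                  ica_config(model_order, seed = seed))
            ses <- run_session(sub$series, cfg, tgt, start = fl_length)
            sc <- score_session(ses, ref_map, ref_course)
            tibble(subject = si, method = method, network = net, run = run,
                   seed = seed, spatial_r = sc$spatial_r,
                   temporal_r = sc$temporal_r,
                   mean_compute_s = sc$mean_compute_s,
                   prop_skipped = sc$prop_skipped, failed = FALSE)
          }, error = function(e) {
            tibble(subject = si, method = method, network = net, run = run,
                   seed = seed, spatial_r = NA_real_, temporal_r = NA_real_,
                   mean_compute_s = NA_real_, prop_skipped = NA_real_,
                   failed = TRUE)
          })
          rows[[length(rows) + 1L]] <- cell
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rtica_evaluation", class(out))
  out
}

#' Summarize an evaluation into the three variability tiers
#'
#' Produces per-(subject, method, network) cell means with the standard
#' deviation across repeated trials (stochastic variability), and
#' per-(method, network) means with the standard deviation across subjects.
#'
#' @param results an `rtica_evaluation` from [evaluate_all()].
#' @return list of two tibbles: `by_cell` (trial-level summaries) and
#'   `by_method_network` (across-subject summaries).
#' @export
summarize_evaluation <- function(results) {
  by_cell <- results |>
    dplyr::filter(!.data$failed) |>
    dplyr::group_by(.data$subject, .data$method, .data$network) |>
    dplyr::summarise(
      mean_spatial_r = mean(.data$spatial_r),
      sd_spatial_r = sd(.data$spatial_r),
      mean_temporal_r = mean(.data$temporal_r),
      sd_temporal_r = sd(.data$temporal_r),
      mean_compute_s = mean(.data$mean_compute_s),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  by_mn <- by_cell |>
    dplyr::group_by(.data$method, .data$network) |>
    dplyr::summarise(
      mean_spatial_r = mean(.data$mean_spatial_r),
      sd_across_subjects_spatial = sd(.data$mean_spatial_r),
      mean_temporal_r = mean(.data$mean_temporal_r),
      sd_across_subjects_temporal = sd(.data$mean_temporal_r),
      .groups = "drop"
    )
  list(by_cell = by_cell, by_method_network = by_mn)
}
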