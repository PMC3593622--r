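#' Construct a run configuration
#'
#' Flat, serializable description of an end-to-end run: either paths to an
#' acquired series (+ mask) or a synthetic-subject seed, plus the analysis
#' settings. Defaults follow the monitoring pipeline's standard settings
#' (localizer 60 TRs, window 15 TRs, model order 5, TR 1 s).
#'
#' @param input path to a 4D NIfTI series, or `NULL` to simulate.
#' @param mask optional mask path.
#' @param fl_length,window_length,model_order,tr analysis settings.
#' @param methods methods to run.
#' @param networks networks to monitor/evaluate.
#' @param n_runs repetitions for the evaluation factorial.
#' @param noise_sd synthetic noise level (simulation only).
#' @param seed RNG seed for everything downstream.
#' @param output_dir where command-style helpers write their files.
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL, mask = NULL, fl_length = 60L,
                       window_length = 15L, model_order = 5L, tr = 1,
                       methods = c("bp", "rtc", "rsc", "rstc"),
                       networks = c("RVMT", "LVMT", "DMN"), n_runs = 10L,
                       noise_sd = 1, seed = 1L, output_dir = ".") {
  structure(
    list(input = input, mask = mask, fl_length = as.integer(fl_length),
         window_length = as.integer(window_length),
         model_order = as.integer(model_order), tr = tr,
         methods = methods, networks = networks, n_runs = as.integer(n_runs),
         noise_sd = noise_sd, seed = as.integer(seed),
         output_dir = output_dir),
    class = "run_config"
  )
}

#' Write / read a run configuration as YAML
#'
#' Round-trip stable: `read_run_config(write_run_config(cfg, p))` equals
#' `cfg`.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return the path (write) or the `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, raw)
}
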