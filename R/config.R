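#' Default run configuration
#'
#' All pipeline parameters with their defaults, organized by stage. A
#' fully-defaulted configuration runs the easy-case demo end-to-end. A
#' YAML file with the same nesting overrides any subset of fields
#' ([load_config()]); command-line flags override the file.
#'
#' @return nested list of class `"run_config"` with sections `io`,
#'   `meanshift`, `drift`, `frc`, `simulate`, plus `seed` and `log_level`.
#' @export
default_config <- function() {
  structure(list(
    io = list(column_map = NULL, unit_scale = 1, default_precision = NULL),
    meanshift = list(r_initial = 150, r_window = NULL, tol = 0.1,
                     max_iter = 50, min_pairs = 10, z_scale = NULL),
    drift = list(bin_frames = 1000, bin_seconds = NULL, fps = NULL,
                 exclude_adjacent = FALSE, chisq_rescale = FALSE,
                 max_rms_err = NULL, two_pass = FALSE),
    frc = list(pixel_nm = 5, replicates = 20, threshold = 1 / 7,
               block_frames = 50),
    simulate = list(preset = "easy"),
    seed = 1,
    log_level = "info"
  ), class = "run_config")
}

#' Load a YAML run configuration
#'
#' Reads a YAML file with sections `io` / `meanshift` / `drift` / `frc` /
#' `simulate` and merges it over [default_config()]; unknown keys are an
#' error.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a `"run_config"` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_into <- function(base, upd, where = "") {
    for (nm in names(upd)) {
      if (!nm %in% names(base))
        stop("unknown config key '", where, nm, "'")
      if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        base[[nm]] <- merge_into(base[[nm]], upd[[nm]],
                                 paste0(where, nm, "/"))
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  structure(merge_into(unclass(cfg), user), class = "run_config")
}

.ms_params_from_config <- function(config) {
  m <- config$meanshift
  ms_params(r_initial = m$r_initial,
            r_window = if (is.null(m$r_window)) m$r_initial else m$r_window,
            tol = m$tol, max_iter = m$max_iter, min_pairs = m$min_pairs,
            scale = if (!is.null(m$z_scale)) c(1, 1, m$z_scale))
}
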