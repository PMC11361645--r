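#' Run configuration
#'
#' Default configuration for the pipeline and CLI: simulation seeds, the
#' stopped-flow protein-concentration ladder, noise levels, nucleotide pools
#' and analysis thresholds. The accepted fields and their constraints are
#' documented in the JSON schema shipped at
#' `system.file("extdata", "config-schema.json", package = "gtpasekin")`;
#' [read_run_config()] validates against the same rules.
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seeds = 1:20,
    ladder_uM = c(1, 2, 4, 6, 8, 10),
    reporter_conc_uM = 0.2,
    noise_sd_frac = 0.01,
    hydrolysis_noise_sd = 0.02,
    pools = list(gtp_uM = 500, gdp_uM = 50),
    thresholds = list(r1 = 5, f_gtp = 0.5, rel_threshold = 2,
                      min_area = 4L, max_dist = 3),
    out_dir = "."
  ), class = "run_config")
}

#' @rdname default_run_config
#' @param path A JSON or YAML file whose fields override the defaults.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("No such config file: %s", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- default_run_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown) > 0) {
    abort_format(sprintf("Unknown config field(s): %s.",
                         paste(unknown, collapse = ", ")))
  }
  for (nm in names(raw)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      modifyList(cfg[[nm]], raw[[nm]])
    } else raw[[nm]]
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  pos <- function(x, nm, strict = FALSE) {
    if (!is.numeric(x) || any(!is.finite(x)) ||
        any(if (strict) x <= 0 else x < 0)) {
      abort_format(sprintf("Config field `%s` must be %s numeric.",
                           nm, if (strict) "positive" else "nonnegative"))
    }
  }
  pos(cfg$seeds, "seeds")
  pos(cfg$ladder_uM, "ladder_uM", strict = TRUE)
  if (length(cfg$ladder_uM) < 3 || anyDuplicated(cfg$ladder_uM)) {
    abort_format("Config field `ladder_uM` needs >= 3 distinct values.")
  }
  pos(cfg$reporter_conc_uM, "reporter_conc_uM", strict = TRUE)
  pos(cfg$noise_sd_frac, "noise_sd_frac")
  pos(cfg$hydrolysis_noise_sd, "hydrolysis_noise_sd")
  pos(cfg$pools$gtp_uM, "pools$gtp_uM")
  pos(cfg$pools$gdp_uM, "pools$gdp_uM")
  pos(cfg$thresholds$r1, "thresholds$r1", strict = TRUE)
  pos(cfg$thresholds$max_dist, "thresholds$max_dist")
  if (cfg$thresholds$f_gtp < 0 || cfg$thresholds$f_gtp > 1) {
    abort_format("Config field `thresholds$f_gtp` must lie in [0, 1].")
  }
  class(cfg) <- "run_config"
  cfg
}
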