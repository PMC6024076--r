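#' Load a run configuration
#'
#' Reads the YAML configuration holding the footprint geometry table, the
#' enzyme rulesets, the Pab1 dissociation calibration and the analysis
#' thresholds. The package ships a versioned default; every numeric default
#' used by the model comes from this file, so alternative calibrations can
#' be supplied without touching code.
#'
#' @param path Path to a YAML config. `NULL` (default) loads the shipped
#'   default configuration.
#' @return A list of class `"run_config"`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml",
                        package = "deadenylate", mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop("config file not found: ", path)
  }
  cfg <- yaml::read_yaml(path)
  required <- c("geometry", "rulesets", "koff", "thresholds", "bins")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("config is missing sections: ", paste(missing, collapse = ", "))
  }
  cfg$source_path <- path
  class(cfg) <- "run_config"
  cfg
}

#' Write a configuration next to run outputs
#'
#' @param config A `run_config` list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$source_path <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Deadenylation run configuration (version ",
      x$config_version, ")\n", sep = "")
  cat("  rulesets: ", paste(names(x$rulesets), collapse = ", "), "\n",
      sep = "")
  cat("  binding modes: ", paste(names(x$geometry)[
    names(x$geometry) %in% c("utr_anchored", "all_polyA")],
    collapse = ", "), "\n", sep = "")
  invisible(x)
}

# default config, cached per session
the <- new.env(parent = emptyenv())

default_config <- function() {
  if (is.null(the$config)) the$config <- load_config()
  the$config
}
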