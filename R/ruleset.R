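#' Enzyme rulesets
#'
#' A ruleset gives the context-dependent per-nucleotide removal rates for a
#' named nuclease configuration: the intact Ccr4-Not complex, complexes
#' with one or both nuclease active sites mutated, the isolated enzymes and
#' the Caf1-Ccr4 heterodimer. `k_naked` applies outside any Pab1 footprint,
#' `k_engaged` inside a protected region (zero for Caf1-only
#' configurations: only Ccr4 cuts adenosines bound by Pab1), and
#' `stimulation_factor` multiplies cutting when a C-terminal-region-bearing
#' Pab1 is on the RNA and the configuration has catalytically active Ccr4.
#'
#' @param name One of `ccr4not_wt`, `ccr4not_ccr4_inactive`,
#'   `ccr4not_caf1_inactive`, `ccr4not_double_inactive`, `isolated_ccr4`,
#'   `isolated_caf1`, `caf1_ccr4_heterodimer`.
#' @param config A [load_config()] result.
#' @param ... Named overrides of individual ruleset fields (rates, dwell).
#' @return An object of class `"enzyme_ruleset"`.
#' @examples
#' enzyme_ruleset("ccr4not_wt")
#' enzyme_ruleset("ccr4not_ccr4_inactive")
#' @export
enzyme_ruleset <- function(name, config = default_config(), ...) {
  rs <- config$rulesets[[name]]
  if (is.null(rs)) {
    stop("unknown enzyme ruleset '", name, "'; available: ",
         paste(names(config$rulesets), collapse = ", "))
  }
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(rs))
  if (length(bad)) stop("unknown ruleset fields: ", paste(bad, collapse = ", "))
  rs[names(overrides)] <- overrides
  if (rs$k_naked < 0 || rs$k_engaged < 0 || rs$stimulation_factor < 0 ||
      rs$pause_dwell_mean < 0) {
    stop("ruleset rates must be non-negative")
  }
  structure(c(list(name = name), rs), class = "enzyme_ruleset")
}

#' @export
print.enzyme_ruleset <- function(x, ...) {
  cat(sprintf(
    "enzyme ruleset %s: k_naked %.3g nt/min, k_engaged %.3g nt/min,\n",
    x$name, x$k_naked, x$k_engaged))
  cat(sprintf("  stimulation x%.3g (Ccr4 %s), pause dwell %.3g min\n",
              x$stimulation_factor,
              if (x$ccr4_active) "active" else "inactive",
              x$pause_dwell_mean))
  invisible(x)
}

#' Kinetic parameters for a simulation
#'
#' Bundles the enzyme ruleset with the Pab1 dissociation calibration, the
#' simulation horizon and the sampling grid. Dissociation is a
#' non-increasing step function of the remaining engaged adenosines:
#' fast (half-life ~2 min) at five or fewer, slow (half-life ~40 min) at
#' six to ten, and negligible above; molecules bound in all-poly(A) mode
#' additionally release at the fast rate once their engagement drops below
#' the mode's release threshold (~20 nt).
#'
#' @param enzyme An [enzyme_ruleset()].
#' @param t_end Simulation horizon in minutes.
#' @param record_times Sampling grid (minutes), sorted.
#' @param excess_pab1 Declare excess free Pab1: on UTR-containing
#'   substrates the naked-region rate is divided by the configured
#'   obstruction factor (~2-fold); UTR-less substrates are unaffected.
#' @param config A [load_config()] result.
#' @return An object of class `"kinetic_params"`.
#' @export
kinetic_params <- function(enzyme, t_end, record_times = NULL,
                           excess_pab1 = FALSE,
                           config = default_config()) {
  stopifnot(inherits(enzyme, "enzyme_ruleset"), t_end > 0)
  if (is.null(record_times)) record_times <- seq(0, t_end, length.out = 7L)
  record_times <- sort(unique(as.numeric(record_times)))
  if (any(record_times < 0) || any(record_times > t_end)) {
    stop("record_times must lie in [0, t_end]")
  }
  ko <- config$koff
  structure(list(enzyme = enzyme, t_end = t_end,
                 record_times = record_times, koff = ko,
                 excess_pab1 = isTRUE(excess_pab1),
                 obstruction = config$options$excess_pab1_obstruction),
            class = "kinetic_params")
}

# dissociation rate (1/min) given engaged adenosines, mode and geometry
koff_rate <- function(engaged, mode, release_threshold, koff) {
  if (engaged <= koff$fast_max_engagement) return(koff$fast)
  if (mode == "all_polyA" && engaged < release_threshold) return(koff$fast)
  if (engaged <= koff$slow_max_engagement) return(koff$slow)
  0
}

#' Context-dependent removal rate at the current terminal adenosine
#'
#' Pure function of the engagement status of the terminal position, the
#' enzyme ruleset and the presence of a C-terminal-region-bearing Pab1.
#' Stimulation only applies to rulesets with catalytically active Ccr4.
#'
#' @param state An [assemble_mrnp()] state.
#' @param enzyme An [enzyme_ruleset()].
#' @param position Current terminal adenosine (defaults to the remaining
#'   tail length).
#' @return Rate in cuts per minute.
#' @export
context_rate <- function(state, enzyme, position = state$tail_remaining) {
  stopifnot(inherits(state, "mrnp_state"), inherits(enzyme, "enzyme_ruleset"))
  if (position <= 0L) return(0)
  base <- if (position <= protected_boundary(state)) {
    enzyme$k_engaged
  } else {
    enzyme$k_naked
  }
  stim <- if (enzyme$ccr4_active &&
              any(vapply(state$bound,
                         function(b) b$variant$has_c_terminal_region,
                         logical(1)))) {
    enzyme$stimulation_factor
  } else 1
  base * stim
}
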