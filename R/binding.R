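#' One-site equilibrium binding fit
#'
#' Nonlinear least-squares fit of a polarization-style titration to the
#' hyperbolic one-site model
#' `signal = S_free + (S_bound - S_free) * C / (Kd + C)`.
#' The hyperbolic (ligand-depletion-free) form is the default; a quadratic
#' tight-binding variant that accounts for probe depletion at sub-nM Kd is
#' available with `tight_binding = TRUE` (requires `probe_nM`). Fits that
#' fail to converge, or whose Kd pins at the concentration range boundary,
#' are flagged rather than returned silently.
#'
#' @param concentrations Protein concentrations (nM).
#' @param signals Measured signals (same length).
#' @param tight_binding Use the quadratic depletion-corrected model.
#' @param probe_nM Labeled probe concentration (nM), tight-binding only.
#' @return An object of class `"binding_fit"`: `kd`, `signal_free`,
#'   `signal_bound`, `se_kd`, `n`, `flagged` (+ `flag_reason`).
#' @examples
#' conc <- 0.05 * 2^(0:11)
#' sig <- 40 + 160 * conc / (2 + conc)
#' fit_one_site(conc, sig)
#' @export
fit_one_site <- function(concentrations, signals, tight_binding = FALSE,
                         probe_nM = NULL) {
  stopifnot(length(concentrations) == length(signals))
  ok <- is.finite(concentrations) & is.finite(signals)
  conc <- concentrations[ok]; sig <- signals[ok]
  if (length(conc) < 5L) {
    stop("need at least 5 concentrations spanning the transition, got ",
         length(conc))
  }
  flagged <- function(reason) {
    structure(list(kd = NA_real_, signal_free = NA_real_,
                   signal_bound = NA_real_, se_kd = NA_real_,
                   n = length(conc), flagged = TRUE, flag_reason = reason),
              class = "binding_fit")
  }
  if (stats::sd(sig) == 0) return(flagged("constant signal"))
  start <- list(sf = min(sig), sb = max(sig),
                kd = exp(mean(log(range(conc[conc > 0])))))
  model <- if (tight_binding) {
    if (is.null(probe_nM)) stop("tight_binding = TRUE requires probe_nM")
    r <- probe_nM
    sig ~ sf + (sb - sf) *
      ((kd + conc + r) - sqrt((kd + conc + r)^2 - 4 * conc * r)) / (2 * r)
  } else {
    sig ~ sf + (sb - sf) * conc / (kd + conc)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(model, data = data.frame(conc = conc, sig = sig),
                      start = start,
                      lower = c(sf = -Inf, sb = -Inf, kd = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(flagged("non-convergent"))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["kd", "Std. Error"],
                 error = function(e) NA_real_)
  out <- structure(list(kd = unname(cf["kd"]),
                        signal_free = unname(cf["sf"]),
                        signal_bound = unname(cf["sb"]),
                        se_kd = unname(se), n = length(conc),
                        flagged = FALSE, flag_reason = NULL),
                   class = "binding_fit")
  rng <- range(conc[conc > 0])
  if (out$kd <= rng[1] * 1e-3 || out$kd >= rng[2] * 1e3) {
    out$flagged <- TRUE
    out$flag_reason <- "Kd at concentration-range boundary"
  }
  if (isTRUE(all.equal(out$signal_bound, out$signal_free))) {
    out$flagged <- TRUE
    out$flag_reason <- "no signal amplitude"
  }
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  if (x$flagged) {
    cat("one-site binding fit: FLAGGED (", x$flag_reason, ")\n", sep = "")
  } else {
    cat(sprintf("one-site binding fit: Kd = %.3g +/- %.3g nM (n = %d)\n",
                x$kd, x$se_kd, x$n))
  }
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(kd = object$kd, signal_free = object$signal_free,
    signal_bound = object$signal_bound)
}

#' Exponential dissociation fit
#'
#' Fits `signal = baseline + A * exp(-koff * t)` to a dissociation trace
#' (e.g. a biosensor sensogram), with optional pre-averaging of the raw
#' points in fixed time intervals (default 10 s) to improve
#' signal-to-noise. The half-life is `ln(2)/koff`.
#'
#' @param times Times in minutes.
#' @param signal Trace values.
#' @param average_interval Pre-averaging window in seconds (0 disables).
#' @return An object of class `"kinetic_fit"`: `koff` (1/min),
#'   `half_life` (min), `amplitude`, `baseline`, `se`, `flagged`.
#' @export
fit_dissociation <- function(times, signal,
                             average_interval =
                               default_config()$thresholds$dissociation_average_interval) {
  stopifnot(length(times) == length(signal))
  if (length(times) < 10L) {
    stop("need at least 10 time points for a dissociation fit, got ",
         length(times))
  }
  if (average_interval > 0) {
    win <- average_interval / 60  # minutes
    bin <- floor(times / win)
    times <- tapply(times, bin, mean)
    signal <- tapply(signal, bin, mean)
    times <- as.numeric(times); signal <- as.numeric(signal)
  }
  amp0 <- signal[1] - signal[length(signal)]
  if (amp0 == 0) amp0 <- stats::sd(signal) + 1e-12
  # crude initial rate from the time to lose half the amplitude
  below <- which(abs(signal - signal[length(signal)]) < abs(amp0) / 2)
  t_half0 <- if (length(below)) max(times[below[1]], min(diff(times))) else
    max(times) / 2
  start <- list(b = signal[length(signal)], a = amp0, k = log(2) / t_half0)
  fit <- tryCatch(
    minpack.lm::nlsLM(signal ~ b + a * exp(-k * times),
                      data = data.frame(times = times, signal = signal),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  flagged <- FALSE; reason <- NULL
  if (is.null(fit)) {
    return(structure(list(koff = NA_real_, half_life = NA_real_,
                          amplitude = NA_real_, baseline = NA_real_,
                          se = NA_real_, n = length(times), flagged = TRUE,
                          flag_reason = "non-convergent"),
                     class = "kinetic_fit"))
  }
  cf <- stats::coef(fit)
  k <- unname(cf["k"])
  if (k <= 0) { flagged <- TRUE; reason <- "non-positive rate constant" }
  se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(koff = k, half_life = if (k > 0) log(2) / k else NA_real_,
                 amplitude = unname(cf["a"]), baseline = unname(cf["b"]),
                 se = unname(se), n = length(times),
                 flagged = flagged, flag_reason = reason),
            class = "kinetic_fit")
}

#' Association rate from observed-rate concentration dependence
#'
#' Under pseudo-first-order binding, the observed relaxation rate is
#' `kobs = koff + kon * C`; ordinary least-squares regression of `kobs`
#' against concentration yields `kon` as the slope (with standard error)
#' and the intercept as an estimate of `koff`.
#'
#' @param concentrations Protein concentrations (nM).
#' @param kobs Observed rates (1/min), one per concentration (replicates
#'   allowed as repeated concentrations).
#' @return An object of class `"kinetic_fit"` with `kon` (1/(nM min)),
#'   `intercept` (~koff), and `se` of the slope.
#' @export
fit_association <- function(concentrations, kobs) {
  stopifnot(length(concentrations) == length(kobs))
  if (length(unique(concentrations)) < 3L) {
    stop("need at least 3 distinct concentrations, got ",
         length(unique(concentrations)))
  }
  fit <- stats::lm(kobs ~ concentrations)
  cf <- stats::coef(fit)
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  structure(list(kon = unname(cf[2]), intercept = unname(cf[1]),
                 se = unname(se), n = length(kobs),
                 flagged = unname(cf[2]) <= 0,
                 flag_reason = if (cf[2] <= 0) "non-positive kon" else NULL),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (!is.null(x$kon)) {
    cat(sprintf("association fit: kon = %.3g +/- %.3g /(nM min), intercept (~koff) %.3g /min\n",
                x$kon, x$se, x$intercept))
  } else if (isTRUE(x$flagged)) {
    cat("dissociation fit: FLAGGED (", x$flag_reason, ")\n", sep = "")
  } else {
    cat(sprintf("dissociation fit: koff = %.3g /min (half-life %.3g min)\n",
                x$koff, x$half_life))
  }
  invisible(x)
}
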