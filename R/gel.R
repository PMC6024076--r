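#' Virtual gel lane from an ensemble
#'
#' Histogram of tail lengths at one recorded time, optionally convolved
#' with a Gaussian band blur, mimicking a densitometric profile of one
#' lane of a denaturing gel. Total intensity before blurring equals the
#' number of molecules; blurring conserves total intensity.
#'
#' @param ensemble A [simulate_ensemble()] result.
#' @param time A recorded time (must be in `record_times`).
#' @param blur_sigma Gaussian blur in nt (0 for the exact histogram).
#' @return An object of class `"lane_profile"`: `tail_length` (0..L0),
#'   `intensity`, `time`, `blur_sigma`.
#' @export
lane_profile <- function(ensemble, time,
                         blur_sigma = default_config()$thresholds$blur_sigma) {
  stopifnot(inherits(ensemble, "deadenylation_ensemble"))
  idx <- match(time, ensemble$record_times)
  if (is.na(idx)) {
    stop("time ", time, " was not sampled; available times: ",
         paste(signif(ensemble$record_times, 4), collapse = ", "))
  }
  l0 <- ensemble$provenance$substrate$tail_length
  counts <- tabulate(ensemble$tails[idx, ] + 1L, nbins = l0 + 1L)
  intensity <- as.numeric(counts)
  if (blur_sigma > 0) {
    half <- max(1L, ceiling(4 * blur_sigma))
    kern <- stats::dnorm(-half:half, sd = blur_sigma)
    kern <- kern / sum(kern)
    padded <- c(numeric(half), intensity, numeric(half))
    sm <- stats::filter(padded, kern, sides = 2)
    sm <- as.numeric(sm)[(half + 1L):(half + l0 + 1L)]
    # renormalize so mass blurred past the lane edges is not lost
    intensity <- sm * (sum(intensity) / sum(sm))
  }
  structure(list(tail_length = 0:l0, intensity = intensity,
                 time = time, blur_sigma = blur_sigma),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat(sprintf("gel lane at t = %.3g min: %d bins, total intensity %.4g\n",
              x$time, length(x$intensity), sum(x$intensity)))
  cat(sprintf("  modal tail length %d nt\n", modal_tail_length(x)))
  invisible(x)
}

#' Modal tail length of a lane
#'
#' Tail length of maximum intensity; ties are broken toward the smaller
#' length (the more-deadenylated species).
#'
#' @param profile A [lane_profile()].
#' @return Tail length in nt.
#' @export
modal_tail_length <- function(profile) {
  stopifnot(inherits(profile, "lane_profile"))
  if (all(profile$intensity == 0)) {
    stop("all-zero lane profile has no modal tail length")
  }
  profile$tail_length[which.max(profile$intensity)]
}

#' Average deadenylation rate by linear regression of modal tail lengths
#'
#' Ordinary least-squares fit of modal tail length against time; the rate
#' is reported as the positive loss in nt/min with a 95% confidence
#' interval from the t distribution on the slope standard error. Trailing
#' points after absorption (a constant terminal plateau) are excluded
#' before fitting, since regressing over the plateau biases the slope.
#'
#' @param modal_series Data frame or list with `time` (min) and
#'   `modal_tail` (nt) — e.g. from [modal_series()].
#' @return An object of class `"rate_fit"`: `rate`, `intercept`,
#'   `ci95_halfwidth`, `n_points`.
#' @export
deadenylation_rate <- function(modal_series) {
  time <- modal_series$time
  tail <- modal_series$modal_tail
  stopifnot(length(time) == length(tail))
  # drop trailing constant plateau (absorbed endpoint), keep its first point
  n <- length(tail)
  keep <- n
  while (keep > 1L && tail[keep - 1L] == tail[n]) keep <- keep - 1L
  if (keep < n) {
    time <- time[seq_len(keep)]
    tail <- tail[seq_len(keep)]
  }
  if (length(time) < 3L) {
    stop("need at least 3 pre-absorption points for a rate fit, got ",
         length(time))
  }
  fit <- stats::lm(tail ~ time)
  slope <- unname(stats::coef(fit)[2])
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  ci <- stats::qt(0.975, df = length(time) - 2L) * se
  if (!is.finite(ci)) ci <- 0
  structure(list(rate = -slope, intercept = unname(stats::coef(fit)[1]),
                 ci95_halfwidth = ci, n_points = length(time)),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("deadenylation rate: %.3g +/- %.3g nt/min (95%% CI, n = %d)\n",
              x$rate, x$ci95_halfwidth, x$n_points))
  invisible(x)
}

#' @export
coef.rate_fit <- function(object, ...) {
  c(rate = object$rate, intercept = object$intercept)
}

#' Modal tail length series over recorded times
#'
#' @param ensemble A [simulate_ensemble()] result.
#' @param blur_sigma Band blur passed to [lane_profile()].
#' @return Data frame with `time` and `modal_tail`.
#' @export
modal_series <- function(ensemble, blur_sigma = 0) {
  data.frame(
    time = ensemble$record_times,
    modal_tail = vapply(ensemble$record_times, function(t) {
      modal_tail_length(lane_profile(ensemble, t, blur_sigma))
    }, numeric(1)))
}

#' Detect persistent pause bands across lanes
#'
#' A pause band is a tail length that is a local intensity maximum of a
#' lane — above a prominence threshold relative to that lane's median
#' nonzero intensity — in at least `min_lanes` consecutive lanes. A
#' population that merely drifts through a tail length peaks there in a
#' single lane only, so this persistence rule separates genuine stalling
#' intermediates from a moving front. The initial substrate band and the
#' terminal absorbed band are excluded, leaving the transient
#' intermediates that mark RRM footprint edges.
#'
#' @param profiles List of [lane_profile()]s, in time order.
#' @param prominence Multiplier of the per-lane median nonzero intensity.
#' @param min_lanes Consecutive-lane persistence requirement.
#' @return List with `positions` (nt, ascending) and `spacings`
#'   (successive differences); both may be empty.
#' @export
detect_pause_bands <- function(profiles,
                               prominence =
                                 default_config()$thresholds$band_prominence,
                               min_lanes =
                                 default_config()$thresholds$band_min_lanes) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "lane_profile")))
  empty <- list(positions = integer(0), spacings = integer(0))
  if (length(profiles) < 3L) return(empty)
  lens <- profiles[[1]]$tail_length
  mat <- vapply(profiles, function(p) p$intensity, numeric(length(lens)))
  n <- length(lens)
  local_max <- function(v) {
    vapply(seq_len(n), function(i) {
      left <- if (i > 1L) v[i - 1L] else -Inf
      right <- if (i < n) v[i + 1L] else -Inf
      v[i] > 0 && v[i] >= left && v[i] > right
    }, logical(1))
  }
  # per lane: prominent, sharp local maxima; a discrete band rises well
  # above its immediate neighbours (band blur is sub-nucleotide), whereas
  # a diffuse moving population does not
  hit <- vapply(seq_len(ncol(mat)), function(j) {
    v <- mat[, j]
    nz <- v[v > 0]
    thr <- if (length(nz)) prominence * stats::median(nz) else Inf
    flank <- (c(0, v[-n]) + c(v[-1], 0)) / 2
    local_max(v) & v >= thr & v >= prominence * flank
  }, logical(n))
  # persistence across >= min_lanes consecutive lanes
  persistent <- vapply(seq_len(n), function(i) {
    r <- rle(hit[i, ])
    any(r$values & r$lengths >= min_lanes)
  }, logical(1))
  cand <- lens[persistent]
  # exclude the unreacted substrate band and the terminal absorbed band
  l0 <- max(lens)
  terminal <- min(vapply(profiles, function(p) {
    min(p$tail_length[p$intensity > 0])
  }, numeric(1)))
  cand <- setdiff(cand, c(l0, terminal))
  positions <- sort(as.integer(cand))
  list(positions = positions,
       spacings = if (length(positions) > 1L) diff(positions) else integer(0))
}

#' Bound fraction over time
#'
#' Fraction of molecules with at least one Pab1 bound at each recorded
#' time — the virtual analogue of the native-gel bound/unbound readout.
#'
#' @param ensemble A [simulate_ensemble()] result.
#' @return Data frame with `time` and `fraction_bound`.
#' @export
bound_fraction_series <- function(ensemble) {
  stopifnot(inherits(ensemble, "deadenylation_ensemble"))
  data.frame(time = ensemble$record_times,
             fraction_bound = rowMeans(ensemble$bound >= 1L))
}

#' Robust shortest tail length per lane
#'
#' The in vivo pulse-chase rate statistic tracks the shortest poly(A)
#' species per time point; a low percentile (default 5th) is used instead
#' of the literal minimum to be robust to single-molecule outliers.
#'
#' @param ensemble A [simulate_ensemble()] result.
#' @param percentile Percentile (0-100) of the tail-length distribution.
#' @return Data frame with `time` and `shortest_tail`.
#' @export
shortest_tail_series <- function(ensemble,
                                 percentile =
                                   default_config()$thresholds$shortest_tail_percentile) {
  stopifnot(inherits(ensemble, "deadenylation_ensemble"))
  data.frame(
    time = ensemble$record_times,
    shortest_tail = apply(ensemble$tails, 1L, stats::quantile,
                          probs = percentile / 100, names = FALSE))
}

#' Export lanes to TSV
#'
#' Single-lane format: `tail_length`, `intensity`. Multi-lane matrix
#' format: `tail_length` plus one `t<time>` column per lane.
#'
#' @param profiles A [lane_profile()] or list of them.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_lanes_tsv <- function(profiles, path) {
  if (inherits(profiles, "lane_profile")) profiles <- list(profiles)
  df <- data.frame(tail_length = profiles[[1]]$tail_length)
  for (p in profiles) {
    df[[sprintf("t%g", p$time)]] <- p$intensity
  }
  if (length(profiles) == 1L) names(df)[2] <- "intensity"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
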