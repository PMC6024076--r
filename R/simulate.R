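#' Simulate deadenylation of a single molecule
#'
#' Event-driven (Gillespie) simulation of one Pab1-loaded RNA. Exponential
#' waiting times are drawn at the context rate of the current terminal
#' adenosine; each cut removes one adenosine. On first arrival at a pause
#' site the complex dwells for an extra exponential time (mean
#' `pause_dwell_mean`, scaled down for RRM1/RRM2 mutants). Crossing an RRM
#' footprint edge irreversibly disengages that RRM because the shortened
#' tail cannot be rebound, so engagement is a function of the remaining
#' tail. A Pab1 molecule dissociates at the rate given by its remaining
#' engagement (see [kinetic_params()]). The trajectory ends at `t_end`, or
#' earlier when no event can occur: with all rates zero and tail remaining,
#' the final state is flagged stalled (e.g. a Caf1-class activity at the
#' hard stop).
#'
#' @param state An [assemble_mrnp()] state.
#' @param params A [kinetic_params()] object.
#' @return A data.frame of class `"deadenylation_trajectory"` with columns
#'   `time`, `event` (`start`, `cut`, `pause_exit`, `pab1_release`),
#'   `tail_remaining`, `bound_count`; attribute `stalled` flags absorption
#'   with tail remaining.
#' @export
simulate_molecule <- function(state, params) {
  stopifnot(inherits(state, "mrnp_state"), inherits(params, "kinetic_params"))
  enzyme <- params$enzyme
  koff <- params$koff
  nb <- length(state$bound)
  offset <- vapply(state$bound, function(b) b$five_prime_offset, integer(1))
  span <- vapply(state$bound, function(b) b$geometry$span, integer(1))
  hstop_abs <- vapply(state$bound, function(b) {
    b$five_prime_offset - 1L + b$geometry$hard_stop
  }, integer(1))
  mode <- vapply(state$bound, function(b) b$binding_mode, character(1))
  rel_thr <- vapply(state$bound, function(b) b$geometry$release_threshold,
                    integer(1))
  ctd <- vapply(state$bound, function(b) b$variant$has_c_terminal_region,
                logical(1))
  dwell_factor <- vapply(state$bound, function(b) b$geometry$dwell_factor,
                         numeric(1))
  # absolute pause sites with owning molecule
  p_site <- integer(0); p_owner <- integer(0)
  for (i in seq_len(nb)) {
    s <- offset[i] - 1L + state$bound[[i]]$geometry$pause_sites
    p_site <- c(p_site, s)
    p_owner <- c(p_owner, rep(i, length(s)))
  }
  p_visited <- rep(FALSE, length(p_site))

  k_naked <- enzyme$k_naked
  if (isTRUE(params$excess_pab1) && state$substrate$utr_length > 0L) {
    k_naked <- k_naked / params$obstruction
  }
  tail <- state$tail_remaining
  active <- rep(TRUE, nb)
  t_now <- 0
  dwell_until <- 0
  cap <- 16L
  ev_time <- numeric(cap); ev_kind <- character(cap)
  ev_tail <- integer(cap); ev_bound <- integer(cap)
  n_ev <- 0L
  push <- function(tm, kind) {
    n_ev <<- n_ev + 1L
    if (n_ev > cap) {
      cap <<- cap * 2L
      length(ev_time) <<- cap; length(ev_kind) <<- cap
      length(ev_tail) <<- cap; length(ev_bound) <<- cap
    }
    ev_time[n_ev] <<- tm; ev_kind[n_ev] <<- kind
    ev_tail[n_ev] <<- tail; ev_bound[n_ev] <<- sum(active)
  }
  push(0, "start")
  stalled <- FALSE

  repeat {
    boundary <- if (any(active)) max(hstop_abs[active]) else 0L
    stim <- if (enzyme$ccr4_active && any(active & ctd)) {
      enzyme$stimulation_factor
    } else 1
    rate_cut <- if (tail <= 0L) 0 else {
      (if (tail <= boundary) enzyme$k_engaged else k_naked) * stim
    }
    engaged <- pmax(0L, pmin(tail, offset - 1L + span) - (offset - 1L))
    rate_rel <- numeric(nb)
    for (i in seq_len(nb)) {
      rate_rel[i] <- if (active[i]) {
        koff_rate(engaged[i], mode[i], rel_thr[i], koff)
      } else 0
    }
    if (rate_cut == 0 && all(rate_rel == 0)) {
      stalled <- tail > 0L
      break
    }
    t_cut <- if (rate_cut > 0) {
      max(t_now, dwell_until) + stats::rexp(1L, rate_cut)
    } else Inf
    t_rel <- rep(Inf, nb)
    pos <- which(rate_rel > 0)
    if (length(pos)) {
      t_rel[pos] <- t_now + stats::rexp(length(pos), rate_rel[pos])
    }
    t_rel_min <- if (nb) min(t_rel) else Inf
    if (t_cut <= t_rel_min) {
      if (t_cut > params$t_end) break
      if (dwell_until > t_now) {
        t_exit <- min(dwell_until, t_cut)
        push(t_exit, "pause_exit")
      }
      t_now <- t_cut
      tail <- tail - 1L
      push(t_now, "cut")
      hit <- which(!p_visited & p_site == tail & active[p_owner])
      if (length(hit)) {
        p_visited[hit] <- TRUE
        d <- enzyme$pause_dwell_mean * min(dwell_factor[p_owner[hit]])
        dwell_until <- if (d > 0) t_now + stats::rexp(1L, 1 / d) else t_now
      }
    } else {
      if (t_rel_min > params$t_end) break
      j <- which.min(t_rel)
      t_now <- t_rel_min
      active[j] <- FALSE
      push(t_now, "pab1_release")
    }
  }

  traj <- data.frame(time = ev_time[seq_len(n_ev)],
                     event = ev_kind[seq_len(n_ev)],
                     tail_remaining = ev_tail[seq_len(n_ev)],
                     bound_count = ev_bound[seq_len(n_ev)],
                     stringsAsFactors = FALSE)
  attr(traj, "stalled") <- stalled
  class(traj) <- c("deadenylation_trajectory", "data.frame")
  traj
}

# step-function snapshot of a trajectory at given times
snapshot_trajectory <- function(traj, times) {
  idx <- findInterval(times, traj$time)
  idx[idx < 1L] <- 1L
  list(tail = traj$tail_remaining[idx], bound = traj$bound_count[idx])
}

#' Simulate an ensemble of molecules
#'
#' Vectorizes [simulate_molecule()] over a population. Each molecule runs
#' on an independent RNG substream derived from the master seed, so results
#' are reproducible and independent of evaluation order.
#'
#' @param substrate A [substrate_spec()].
#' @param variant A [pab1_variant()].
#' @param n_pab1 Pab1 molecules loaded per RNA.
#' @param params A [kinetic_params()] object.
#' @param n_molecules Population size.
#' @param seed Master RNG seed.
#' @param config A [load_config()] result.
#' @return An object of class `"deadenylation_ensemble"`: matrices `tails`
#'   and `bound` (record times x molecules), `record_times`, and
#'   provenance (substrate, variant, enzyme name, seed).
#' @examples
#' en <- simulate_ensemble(parse_substrate_label("23-mer-A30"), pab1_wt(), 1,
#'   kinetic_params(enzyme_ruleset("ccr4not_ccr4_inactive"), t_end = 60),
#'   n_molecules = 20, seed = 1)
#' en
#' @export
simulate_ensemble <- function(substrate, variant, n_pab1, params,
                              n_molecules, seed,
                              config = default_config()) {
  stopifnot(n_molecules >= 1L)
  state0 <- assemble_mrnp(substrate, variant, n_pab1, config)
  times <- params$record_times
  nt <- length(times)
  tails <- matrix(NA_integer_, nt, n_molecules)
  bound <- matrix(NA_integer_, nt, n_molecules)
  stalled <- logical(n_molecules)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_molecules)
  for (m in seq_len(n_molecules)) {
    set.seed(sub_seeds[m])
    traj <- simulate_molecule(state0, params)
    snap <- snapshot_trajectory(traj, times)
    tails[, m] <- snap$tail
    bound[, m] <- snap$bound
    stalled[m] <- attr(traj, "stalled")
  }
  structure(list(tails = tails, bound = bound, record_times = times,
                 n_molecules = n_molecules, stalled = stalled,
                 provenance = list(substrate = substrate, variant = variant,
                                   n_pab1 = n_pab1,
                                   enzyme = params$enzyme$name,
                                   seed = seed)),
            class = "deadenylation_ensemble")
}

#' @export
print.deadenylation_ensemble <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "deadenylation ensemble: %d molecules of %s + %d Pab1, enzyme %s\n",
    x$n_molecules, p$substrate$label, p$n_pab1, p$enzyme))
  cat(sprintf("  %d record times in [%.3g, %.3g] min; seed %d\n",
              length(x$record_times), min(x$record_times),
              max(x$record_times), p$seed))
  final <- x$tails[nrow(x$tails), ]
  cat(sprintf("  final tails: median %.0f nt (range %d-%d), %.0f%% stalled\n",
              stats::median(final), min(final), max(final),
              100 * mean(x$stalled)))
  invisible(x)
}

#' Serialize an ensemble to tidy TSV and back
#'
#' Long format: one row per (time, molecule), columns `time`,
#' `molecule_id`, `tail_remaining`, `bound_count`. Provenance is kept in
#' `#`-prefixed header lines so the round-trip is lossless.
#'
#' @param ensemble A [simulate_ensemble()] result.
#' @param path Output TSV path.
#' @return `path` invisibly (writer); the ensemble (reader).
#' @export
write_ensemble_tsv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "deadenylation_ensemble"))
  p <- ensemble$provenance
  hdr <- c(
    sprintf("# substrate\t%s\t%d\t%d", p$substrate$label,
            p$substrate$utr_length, p$substrate$tail_length),
    sprintf("# variant\t%s\t%d",
            paste(as.integer(p$variant$rrm_functional), collapse = ""),
            as.integer(p$variant$has_c_terminal_region)),
    sprintf("# run\t%s\t%d\t%d", p$enzyme, p$n_pab1, p$seed),
    sprintf("# stalled\t%s",
            paste(as.integer(ensemble$stalled), collapse = "")))
  nt <- length(ensemble$record_times)
  df <- data.frame(
    time = rep(ensemble$record_times, times = ensemble$n_molecules),
    molecule_id = rep(seq_len(ensemble$n_molecules), each = nt),
    tail_remaining = as.vector(ensemble$tails),
    bound_count = as.vector(ensemble$bound))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_tsv
#' @export
read_ensemble_tsv <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr <- lines[startsWith(lines, "# ")]
  parse_hdr <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key))]
    if (!length(ln)) stop("ensemble TSV missing '", key, "' header: ", path)
    strsplit(sub(paste0("^# ", key, "\t"), "", ln), "\t")[[1]]
  }
  sub_f <- parse_hdr("substrate")
  var_f <- parse_hdr("variant")
  run_f <- parse_hdr("run")
  stall_f <- parse_hdr("stalled")
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("time", "molecule_id", "tail_remaining", "bound_count")
  if (!all(need %in% names(df))) {
    stop("ensemble TSV has unknown columns; expected ",
         paste(need, collapse = ", "))
  }
  times <- sort(unique(df$time))
  n_mol <- max(df$molecule_id)
  df <- df[order(df$molecule_id, df$time), ]
  substrate <- substrate_spec(as.integer(sub_f[2]), as.integer(sub_f[3]),
                              label = sub_f[1])
  variant <- pab1_variant(
    as.integer(strsplit(var_f[1], "")[[1]]) == 1L,
    var_f[2] == "1")
  structure(list(
    tails = matrix(as.integer(df$tail_remaining), length(times), n_mol),
    bound = matrix(as.integer(df$bound_count), length(times), n_mol),
    record_times = times, n_molecules = n_mol,
    stalled = as.integer(strsplit(stall_f[1], "")[[1]]) == 1L,
    provenance = list(substrate = substrate, variant = variant,
                      n_pab1 = as.integer(run_f[2]), enzyme = run_f[1],
                      seed = as.integer(run_f[3]))),
    class = "deadenylation_ensemble")
}
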