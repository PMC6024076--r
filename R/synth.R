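#' Generate a synthetic shut-off expression table
#'
#' Emulates a spike-in-controlled transcriptional shut-off time course:
#' per-gene expression decays exponentially from a lognormal baseline with
#' multiplicative lognormal measurement noise; spike-in rows are constant
#' up to a declared global drift (e.g. progressive RNA loss), which the
#' spike-in normalization must undo. Ground truth (per-gene half-life,
#' noise model, seed) is recorded so downstream recovery can be checked
#' without rerunning the generator.
#'
#' @param n_genes Number of genes.
#' @param half_life Either a single half-life (min), a vector of length
#'   `n_genes`, or a function `n -> half-lives` (e.g. a sampler).
#' @param times Time points in minutes; must include 0.
#' @param noise_sd Lognormal noise sd (log scale), e.g. 0.05 for ~5%.
#' @param n_spikeins Number of spike-in rows.
#' @param seed RNG seed.
#' @param global_drift Per-time multiplicative drift applied to all rows
#'   (length of `times`, 1 at t = 0); defaults to no drift.
#' @return List with `table` (expression data.frame, TSV schema of
#'   [read_expression_tsv()]) and `truth` (per-gene half-lives, seed,
#'   noise descriptor).
#' @export
gen_decay_table <- function(n_genes, half_life, times, noise_sd = 0.05,
                            n_spikeins = 5, seed = 1,
                            global_drift = NULL) {
  if (!0 %in% times) stop("times must include 0")
  times <- sort(unique(times))
  if (is.function(half_life)) half_life <- half_life(n_genes)
  if (length(half_life) == 1L) half_life <- rep(half_life, n_genes)
  if (length(half_life) != n_genes || any(half_life <= 0)) {
    stop("invalid half-life specification")
  }
  if (is.null(global_drift)) global_drift <- rep(1, length(times))
  if (length(global_drift) != length(times) || global_drift[1] != 1) {
    stop("global_drift must match times and equal 1 at t = 0")
  }
  set.seed(seed)
  baseline <- stats::rlnorm(n_genes, meanlog = log(100), sdlog = 1)
  k <- log(2) / half_life
  mat <- outer(k, times, function(kk, tt) exp(-kk * tt)) * baseline
  if (noise_sd > 0) {
    mat <- mat * matrix(stats::rlnorm(length(mat), 0, noise_sd), nrow(mat))
  }
  mat <- sweep(mat, 2L, global_drift, "*")
  spike <- matrix(rep(stats::rlnorm(n_spikeins, log(500), 0.3),
                      length(times)), n_spikeins)
  spike <- sweep(spike, 2L, global_drift, "*")
  genes <- sprintf("gene%04d", seq_len(n_genes))
  spikes <- sprintf("spike%02d", seq_len(n_spikeins))
  tab <- data.frame(gene = c(genes, spikes),
                    is_spikein = rep(c(0L, 1L), c(n_genes, n_spikeins)))
  tcols <- paste0("t", times)
  tab[tcols] <- rbind(mat, spike)
  list(table = tab,
       truth = list(gene = genes, half_life = half_life, times = times,
                    noise = sprintf("lognormal(sd=%g)", noise_sd),
                    global_drift = global_drift, seed = seed))
}

#' Generate a synthetic fluorescence-polarization titration
#'
#' Two-fold (or arbitrary) dilution series sampled from the one-site
#' binding model with additive Gaussian noise proportional to the signal
#' amplitude — the same model [fit_one_site()] fits.
#'
#' @param kd_nM True dissociation constant (nM).
#' @param concentrations Protein concentrations (nM).
#' @param noise_sd Noise sd as a fraction of the bound-free amplitude.
#' @param replicates Number of replicate series.
#' @param seed RNG seed.
#' @param signal_free,signal_bound Anisotropy-like endpoints.
#' @return List with `data` (data.frame: `concentration_nM`, `replicate`,
#'   `signal`) and `truth`.
#' @export
gen_fp_titration <- function(kd_nM, concentrations = 0.05 * 2^(0:11),
                             noise_sd = 0.02, replicates = 5, seed = 1,
                             signal_free = 40, signal_bound = 200) {
  stopifnot(kd_nM > 0, all(concentrations >= 0))
  set.seed(seed)
  amp <- signal_bound - signal_free
  out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    mu <- signal_free + amp * concentrations / (kd_nM + concentrations)
    data.frame(concentration_nM = concentrations, replicate = r,
               signal = mu + stats::rnorm(length(mu), 0, noise_sd * amp))
  }))
  list(data = out,
       truth = list(kd_nM = kd_nM, signal_free = signal_free,
                    signal_bound = signal_bound,
                    noise = sprintf("gaussian(sd=%g x amplitude)", noise_sd),
                    seed = seed))
}

#' Generate a synthetic dissociation trace
#'
#' Single-exponential decay sampled on a regular grid with additive
#' Gaussian noise proportional to the amplitude, emulating a biosensor
#' dissociation sensogram.
#'
#' @param koff Dissociation rate (1/min).
#' @param duration Trace length (min).
#' @param dt Sampling interval (min).
#' @param noise_sd Noise sd as a fraction of the amplitude.
#' @param seed RNG seed.
#' @param amplitude,baseline Signal scale.
#' @return List with `data` (data.frame: `time_min`, `signal`) and `truth`.
#' @export
gen_dissociation_trace <- function(koff, duration = 120, dt = 1 / 6,
                                   noise_sd = 0.02, seed = 1,
                                   amplitude = 1, baseline = 0.1) {
  stopifnot(koff > 0, duration > 0, dt > 0)
  set.seed(seed)
  t <- seq(0, duration, by = dt)
  mu <- baseline + amplitude * exp(-koff * t)
  sig <- mu + stats::rnorm(length(t), 0, noise_sd * amplitude)
  list(data = data.frame(time_min = t, signal = sig),
       truth = list(koff = koff, half_life = log(2) / koff,
                    amplitude = amplitude, baseline = baseline,
                    noise = sprintf("gaussian(sd=%g x amplitude)", noise_sd),
                    seed = seed))
}

#' Generate a coding sequence with controlled codon optimality
#'
#' Builds a CDS of `length_codons` sense codons in which a target fraction
#' is drawn from the optimal class and the rest from the non-optimal class
#' of the supplied codon table (stop codons are never used). The realized
#' fraction is the exact count `round(target * length_codons) /
#' length_codons`.
#'
#' @param length_codons Number of sense codons.
#' @param target_optimal_fraction Desired optimal-codon fraction in [0, 1].
#' @param codon_table Classification table (see [read_codon_table()]).
#' @param seed RNG seed.
#' @return List with `cds` (character string), `truth` (realized fraction,
#'   seed).
#' @export
gen_cds <- function(length_codons, target_optimal_fraction,
                    codon_table = read_codon_table(), seed = 1) {
  stopifnot(length_codons >= 1,
            target_optimal_fraction >= 0, target_optimal_fraction <= 1)
  set.seed(seed)
  opt <- codon_table$codon[codon_table$class == "optimal"]
  non <- codon_table$codon[codon_table$class == "non-optimal"]
  n_opt <- round(target_optimal_fraction * length_codons)
  codons <- c(sample(opt, n_opt, replace = TRUE),
              sample(non, length_codons - n_opt, replace = TRUE))
  codons <- sample(codons)  # shuffle positions
  list(cds = paste(codons, collapse = ""),
       truth = list(length_codons = length_codons,
                    optimal_fraction = n_opt / length_codons, seed = seed))
}

#' Write CDS sequences to FASTA
#'
#' @param cds Named character vector of sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  x <- Biostrings::DNAStringSet(cds)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read CDS sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_cds_fasta <- function(path) {
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("malformed FASTA: ", path))
  stats::setNames(as.character(x), names(x))
}

#' Generate matched occupancy and tail-length tables
#'
#' Per-transcript log2 RIP enrichment with an optimality-dependent effect
#' (high-optimality transcripts gain `optimality_effect` log2 units at
#' optimality 1 relative to optimality 0) and lognormal mean poly(A) tail
#' lengths, emulating the RIP-seq + PAL-seq input pair.
#'
#' @param n_transcripts Number of transcripts.
#' @param optimality_effect Log2 enrichment gained across the full
#'   optimality range (0 for no effect).
#' @param tail_meanlog,tail_sdlog Lognormal tail-length parameters
#'   (defaults give a ~40-70 nt interquartile range).
#' @param noise_sd Gaussian sd of the log2 enrichment around its mean.
#' @param seed RNG seed.
#' @return List with `occupancy` (transcript, logfc), `tails` (transcript,
#'   mean_tail_nt), `optimality` (transcript, fraction) and `truth`.
#' @export
gen_occupancy_tables <- function(n_transcripts, optimality_effect = 1,
                                 tail_meanlog = log(50), tail_sdlog = 0.25,
                                 noise_sd = 0.3, seed = 1) {
  stopifnot(n_transcripts >= 2)
  set.seed(seed)
  ids <- sprintf("txp%04d", seq_len(n_transcripts))
  frac <- stats::runif(n_transcripts)
  logfc <- optimality_effect * frac +
    stats::rnorm(n_transcripts, 0, noise_sd)
  tails <- stats::rlnorm(n_transcripts, tail_meanlog, tail_sdlog)
  list(occupancy = data.frame(transcript = ids, logfc = logfc),
       tails = data.frame(transcript = ids, mean_tail_nt = tails),
       optimality = data.frame(transcript = ids, fraction = frac),
       truth = list(optimality_effect = optimality_effect,
                    noise = sprintf("gaussian(sd=%g)", noise_sd),
                    seed = seed))
}

#' Write generator ground truth as a JSON sidecar
#'
#' @param truth A generator's `truth` list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
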