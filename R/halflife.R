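#' Read and validate an expression time-course table
#'
#' Expected TSV schema: `gene`, `is_spikein` (0/1), then one column per
#' time point named `t<minutes>` (a `t0` column is mandatory). Values are
#' FPKM-like non-negative expression levels.
#'
#' @param path TSV path.
#' @return The validated data.frame.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene", "is_spikein") %in% names(df))) {
    stop("expression table must have 'gene' and 'is_spikein' columns: ", path)
  }
  tc <- grep("^t[0-9.]+$", names(df), value = TRUE)
  if (!"t0" %in% tc) {
    stop("expression table is missing the mandatory 0-min column 't0': ", path)
  }
  df
}

expr_time_cols <- function(table) {
  tc <- grep("^t[0-9.]+$", names(table), value = TRUE)
  tc[order(as.numeric(sub("^t", "", tc)))]
}

expr_times <- function(table) as.numeric(sub("^t", "", expr_time_cols(table)))

#' Spike-in normalization of an expression table
#'
#' Divides each time point's column by the ratio of summed spike-in signal
#' at that time point to the summed spike-in signal at 0 min, removing
#' global RNA loss from the per-gene time courses. Idempotent: spike-in
#' totals are constant after one application.
#'
#' @param table Expression data.frame (see [read_expression_tsv()]).
#' @return The normalized table.
#' @export
normalize_spikein <- function(table) {
  tc <- expr_time_cols(table)
  sp <- table$is_spikein == 1
  if (!any(sp)) stop("no spike-in rows in expression table")
  totals <- colSums(table[sp, tc, drop = FALSE])
  if (any(totals <= 0)) {
    stop("zero spike-in total at time point(s): ",
         paste(tc[totals <= 0], collapse = ", "))
  }
  factors <- totals / totals[["t0"]]
  table[tc] <- sweep(table[tc], 2L, factors, "/")
  table
}

#' Normalize each gene to its 0-min level
#'
#' Returns relative abundances `R_g(t) = E_g(t) / E_g(0)` for non-spike-in
#' genes; genes with zero 0-min expression cannot be normalized and are
#' returned in the `excluded` attribute with status
#' `"excluded_annotation"`.
#'
#' @param table Expression data.frame.
#' @return Data.frame of relative abundances (gene + time columns);
#'   attribute `excluded` lists dropped genes.
#' @export
relative_to_t0 <- function(table) {
  tc <- expr_time_cols(table)
  genes <- table[table$is_spikein != 1, , drop = FALSE]
  zero <- genes$t0 <= 0
  dropped <- genes$gene[zero]
  genes <- genes[!zero, , drop = FALSE]
  genes[tc] <- genes[tc] / genes$t0
  out <- genes[c("gene", tc)]
  attr(out, "excluded") <- data.frame(
    gene = dropped,
    status = rep("excluded_annotation", length(dropped)))
  out
}

#' Exponential decay fit of one relative time course
#'
#' Least-squares fit of `R(t) = exp(-k t)` on the linear scale, with the
#' two exclusion rules applied on the fit: genes whose mean absolute
#' residual (linear scale) exceeds `residual_max` are excluded, as are
#' genes whose fitted half-life exceeds the measured time-course span.
#'
#' @param times Times in minutes (must include 0).
#' @param R Relative abundances (R(0) = 1 by construction).
#' @param span Time-course span in minutes (defaults to `max(times)`).
#' @param residual_max Exclusion threshold on the mean absolute residual.
#' @param log_linear Fit `log(R) ~ t` by OLS instead (residual rule is
#'   still evaluated on the linear scale).
#' @return An object of class `"decay_fit"`: `k`, `half_life`,
#'   `avg_abs_residual`, `status` in `kept`, `excluded_residual`,
#'   `excluded_range`.
#' @export
fit_decay <- function(times, R, span = max(times),
                      residual_max = default_config()$thresholds$residual_max,
                      log_linear = FALSE) {
  stopifnot(length(times) == length(R))
  if (length(times) < 3L) {
    stop("need at least 3 time points for a decay fit, got ", length(times))
  }
  if (log_linear) {
    usable <- R > 0
    k <- if (sum(usable) >= 2L) {
      max(0, -unname(stats::coef(stats::lm(log(R[usable]) ~ times[usable]))[2]))
    } else 0
  } else {
    sse <- function(k) sum((R - exp(-k * times))^2)
    # seed the 1-D search from a log-linear fit so the bracket is tight;
    # a wide bracket can strand golden-section search on the flat tail
    usable <- R > 0 & times > 0
    k0 <- if (sum(usable) >= 2L) {
      -unname(stats::coef(stats::lm(log(R[usable]) ~ times[usable]))[2])
    } else 0
    k0 <- max(k0, 1e-6)
    opt <- stats::optimize(sse, interval = c(0, 10 * k0), tol = 1e-10)
    k <- opt$minimum
    # optimize never returns exactly 0; snap to the boundary when flat
    if (sse(0) <= opt$objective + 1e-12) k <- 0
  }
  resid <- mean(abs(R - exp(-k * times)))
  half_life <- if (k > 0) log(2) / k else Inf
  status <- if (k <= 0 || half_life > span) {
    "excluded_range"
  } else if (resid > residual_max) {
    "excluded_residual"
  } else "kept"
  structure(list(k = k, half_life = half_life, avg_abs_residual = resid,
                 status = status, span = span),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay fit: k = %.4g /min, half-life %.4g min, |resid| %.3g [%s]\n",
              x$k, x$half_life, x$avg_abs_residual, x$status))
  invisible(x)
}

#' Fit decay for every gene of an expression table
#'
#' Runs [normalize_spikein()], [relative_to_t0()] and [fit_decay()] for
#' each gene.
#'
#' @param table Expression data.frame.
#' @param normalize Apply spike-in normalization first.
#' @param ... Passed to [fit_decay()].
#' @return Data.frame with `gene`, `k`, `half_life`, `avg_abs_residual`,
#'   `status` (including 0-min exclusions).
#' @export
fit_decay_table <- function(table, normalize = TRUE, ...) {
  if (normalize) table <- normalize_spikein(table)
  rel <- relative_to_t0(table)
  times <- expr_times(rel)
  tc <- expr_time_cols(rel)
  fits <- lapply(seq_len(nrow(rel)), function(i) {
    fit_decay(times, as.numeric(rel[i, tc]), ...)
  })
  out <- data.frame(
    gene = rel$gene,
    k = vapply(fits, `[[`, numeric(1), "k"),
    half_life = vapply(fits, `[[`, numeric(1), "half_life"),
    avg_abs_residual = vapply(fits, `[[`, numeric(1), "avg_abs_residual"),
    status = vapply(fits, `[[`, character(1), "status"),
    stringsAsFactors = FALSE)
  excl <- attr(rel, "excluded")
  if (nrow(excl)) {
    out <- rbind(out, data.frame(gene = excl$gene, k = NA_real_,
                                 half_life = NA_real_,
                                 avg_abs_residual = NA_real_,
                                 status = excl$status))
  }
  out
}

#' Fraction of optimal codons of a coding sequence
#'
#' @param cds A coding sequence (character string of A/C/G/T, length a
#'   multiple of 3) or a `Biostrings::DNAString`.
#' @param codon_table Data.frame with `codon` and `class`
#'   (`optimal`/`non-optimal`); default is the bundled synthetic
#'   classification (see [read_codon_table()]).
#' @return Fraction in [0, 1] of non-stop codons classified optimal.
#' @export
codon_optimality <- function(cds, codon_table = read_codon_table()) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) == 0L) stop("empty coding sequence")
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length ", nchar(cds), " is not divisible by 3")
  }
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  bad <- grep("[^ACGT]", codons)
  if (length(bad)) {
    stop("ambiguous base in codon ", bad[1], " ('", codons[bad[1]], "')")
  }
  stops <- c("TAA", "TAG", "TGA")
  codons <- codons[!codons %in% stops]
  if (!length(codons)) stop("CDS contains only stop codons")
  cls <- codon_table$class[match(codons, codon_table$codon)]
  if (anyNA(cls)) {
    stop("codon missing from optimality table: ",
         codons[which(is.na(cls))[1]])
  }
  mean(cls == "optimal")
}

#' Read a codon optimality classification table
#'
#' @param path TSV with columns `codon`, `class`; `NULL` loads the bundled
#'   synthetic default classification.
#' @return Data.frame with `codon` and `class`.
#' @export
read_codon_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "codon_optimality_synthetic.tsv",
                        package = "deadenylate", mustWork = TRUE)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("codon", "class") %in% names(df))) {
    stop("codon table must have 'codon' and 'class' columns: ", path)
  }
  df
}

#' Pab1 occupancy per nucleotide of poly(A) tail
#'
#' Converts RIP-seq style log2 fold-change enrichment to linear fold
#' change and divides by the transcript's mean poly(A) tail length,
#' yielding an occupancy-per-nucleotide statistic. Transcripts present in
#' only one input are dropped (count reported via message and the
#' `n_unmatched` attribute).
#'
#' @param logfc Data.frame with `transcript`, `logfc` (log2).
#' @param tail_lengths Data.frame with `transcript`, `mean_tail_nt`.
#' @return Data.frame with `transcript`, `logfc`, `fold_change`,
#'   `mean_tail_nt`, `occupancy_per_nt`.
#' @export
occupancy_statistic <- function(logfc, tail_lengths) {
  stopifnot(all(c("transcript", "logfc") %in% names(logfc)),
            all(c("transcript", "mean_tail_nt") %in% names(tail_lengths)))
  merged <- merge(logfc, tail_lengths, by = "transcript")
  n_unmatched <- nrow(logfc) + nrow(tail_lengths) - 2L * nrow(merged)
  if (n_unmatched > 0L) {
    message(n_unmatched, " unmatched transcript record(s) dropped")
  }
  bad <- merged$mean_tail_nt <= 0
  if (any(bad)) {
    stop("non-positive mean tail length for transcript ",
         merged$transcript[which(bad)[1]])
  }
  merged$fold_change <- 2^merged$logfc
  merged$occupancy_per_nt <- merged$fold_change / merged$mean_tail_nt
  out <- merged[c("transcript", "logfc", "fold_change", "mean_tail_nt",
                  "occupancy_per_nt")]
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Assign codon-optimality bins
#'
#' @param fractions Optimality fractions in [0, 1].
#' @param edges Bin edges in percent (default from config:
#'   `<40`, `40-50`, `50-60`, `>=60`).
#' @return Factor of bin labels; the lowest bin (`"<40%"` by default) is
#'   the first level and serves as the comparison reference.
#' @export
optimality_bin <- function(fractions, edges = default_config()$bins$edges) {
  edges <- sort(edges)
  pct <- fractions * 100
  brk <- c(-Inf, edges, Inf)
  labels <- c(sprintf("<%g%%", edges[1]),
              if (length(edges) > 1) {
                sprintf("%g-%g%%", edges[-length(edges)], edges[-1])
              },
              sprintf(">=%g%%", edges[length(edges)]))
  cut(pct, breaks = brk, labels = labels, right = FALSE)
}

#' One-way ANOVA and Tukey comparisons across optimality bins
#'
#' Bins per-transcript values by codon optimality and tests for
#' between-bin differences with a one-way ANOVA followed by Tukey's
#' Honest Significant Difference test; each bin is compared with the
#' lowest-optimality reference bin (`"<40%"` with default edges).
#'
#' @param values Numeric per-transcript statistic (e.g. occupancy per nt,
#'   half-life ratio).
#' @param fractions Matching optimality fractions in [0, 1].
#' @param edges Bin edges in percent.
#' @param small_bins `"error"` (default) to fail on bins with fewer than 2
#'   members, or `"merge"` to merge such bins into the adjacent lower bin.
#' @return An object of class `"bin_comparison"`: `counts`, `anova_f`,
#'   `anova_p`, `tukey` (data.frame of comparisons vs the reference:
#'   `bin`, `difference`, `p_adj`), `reference`.
#' @export
bin_and_compare <- function(values, fractions,
                            edges = default_config()$bins$edges,
                            small_bins = c("error", "merge")) {
  small_bins <- match.arg(small_bins)
  stopifnot(length(values) == length(fractions))
  bins <- optimality_bin(fractions, edges)
  counts <- table(bins)
  small <- names(counts)[counts > 0 & counts < 2]
  if (length(small)) {
    if (small_bins == "error") {
      stop("bin(s) with fewer than 2 members: ",
           paste(small, collapse = ", "))
    }
    lv <- levels(bins)
    for (s in small) {
      i <- match(s, lv)
      target <- lv[max(1L, i - 1L)]
      bins[bins == s] <- target
    }
  }
  bins <- droplevels(bins)
  counts <- table(bins)
  if (nlevels(bins) < 2L) stop("need at least 2 non-empty bins")
  reference <- levels(bins)[1]
  df <- data.frame(value = values, bin = bins)
  if (stats::var(values) == 0) {
    tk <- data.frame(bin = setdiff(levels(bins), reference),
                     difference = 0, p_adj = NA_real_)
    return(structure(list(counts = counts, anova_f = NA_real_,
                          anova_p = NA_real_, tukey = tk,
                          reference = reference, flagged = TRUE,
                          flag_reason = "zero within- and between-group variance"),
                     class = "bin_comparison"))
  }
  fit <- stats::aov(value ~ bin, data = df)
  an <- summary(fit)[[1]]
  tk_all <- stats::TukeyHSD(fit)$bin
  vs_ref <- grepl(paste0("-", reference, "$"), rownames(tk_all), fixed = FALSE)
  tk <- data.frame(
    bin = sub(paste0("-", reference, "$"), "", rownames(tk_all)[vs_ref]),
    difference = tk_all[vs_ref, "diff"],
    p_adj = tk_all[vs_ref, "p adj"],
    row.names = NULL)
  structure(list(counts = counts, anova_f = an[["F value"]][1],
                 anova_p = an[["Pr(>F)"]][1], tukey = tk,
                 reference = reference, flagged = FALSE, flag_reason = NULL),
            class = "bin_comparison")
}

#' @export
print.bin_comparison <- function(x, ...) {
  cat("bin comparison vs reference '", x$reference, "'\n", sep = "")
  cat("  counts:", paste(sprintf("%s=%d", names(x$counts), x$counts),
                         collapse = ", "), "\n")
  if (isTRUE(x$flagged)) {
    cat("  FLAGGED:", x$flag_reason, "\n")
  } else {
    cat(sprintf("  ANOVA F = %.4g, p = %.3g\n", x$anova_f, x$anova_p))
    for (i in seq_len(nrow(x$tukey))) {
      cat(sprintf("  %s: diff %.4g, p_adj %.3g\n", x$tukey$bin[i],
                  x$tukey$difference[i], x$tukey$p_adj[i]))
    }
  }
  invisible(x)
}

#' Per-gene half-life ratios between conditions
#'
#' Joins two [fit_decay_table()] outputs on gene, keeping genes whose fits
#' were kept in both conditions, and reports the mutant/wild-type
#' half-life ratio. Genes missing or excluded in either condition are
#' dropped and counted.
#'
#' @param fits_mutant,fits_wt Data.frames from [fit_decay_table()].
#' @return Data.frame with `gene`, `half_life_mutant`, `half_life_wt`,
#'   `ratio`; attribute `n_dropped` counts genes not kept in both.
#' @export
halflife_ratio <- function(fits_mutant, fits_wt) {
  km <- fits_mutant[fits_mutant$status == "kept", c("gene", "half_life")]
  kw <- fits_wt[fits_wt$status == "kept", c("gene", "half_life")]
  names(km)[2] <- "half_life_mutant"
  names(kw)[2] <- "half_life_wt"
  merged <- merge(km, kw, by = "gene")
  merged$ratio <- merged$half_life_mutant / merged$half_life_wt
  n_dropped <- length(union(fits_mutant$gene, fits_wt$gene)) - nrow(merged)
  attr(merged, "n_dropped") <- n_dropped
  merged
}
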