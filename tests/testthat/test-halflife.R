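times7 <- seq(0, 60, 10)

test_that("spike-in normalization undoes global drift and is idempotent", {
  g <- gen_decay_table(10, 20, times7, noise_sd = 0, seed = 1)
  expect_equal(normalize_spikein(g$table), g$table)  # constant spike-ins

  drift <- c(1, 1, 1, 0.5, 0.5, 0.5, 0.5)
  gd <- gen_decay_table(10, 20, times7, noise_sd = 0, seed = 1,
                        global_drift = drift)
  norm <- normalize_spikein(gd$table)
  # a halved spike-in total doubles that column
  expect_equal(norm$t30, gd$table$t30 * 2)
  expect_equal(norm$t10, gd$table$t10)
})

test_that("normalization is idempotent and errors on dead spike-ins", {
  drift <- c(1, 0.8, 0.7, 0.5, 0.4, 0.3, 0.2)
  gd <- gen_decay_table(8, 15, times7, noise_sd = 0.05, seed = 2,
                        global_drift = drift)
  once <- normalize_spikein(gd$table)
  expect_equal(normalize_spikein(once), once)
  broken <- gd$table
  broken[broken$is_spikein == 1, "t30"] <- 0
  expect_error(normalize_spikein(broken), "zero spike-in total.*t30")
  no_spikes <- gd$table[gd$table$is_spikein == 0, ]
  expect_error(normalize_spikein(no_spikes), "no spike-in rows")
})

test_that("relative abundances start at 1 and flag zero-baseline genes", {
  g <- gen_decay_table(6, 20, times7, noise_sd = 0, seed = 3)
  tab <- g$table
  tab$t0[2] <- 0
  rel <- relative_to_t0(tab)
  expect_true(all(rel$t0 == 1))
  expect_equal(attr(rel, "excluded")$gene, "gene0002")
  # one half-life later the relative level is one half
  expect_equal(rel$t20[rel$gene == "gene0001"], 0.5, tolerance = 1e-9)
})

test_that("decay fits recover exact series and apply both exclusion rules", {
  R <- exp(-times7 * log(2) / 20)
  f <- fit_decay(times7, R)
  expect_equal(f$half_life, 20, tolerance = 1e-4)
  expect_equal(f$avg_abs_residual, 0, tolerance = 1e-6)
  expect_equal(f$status, "kept")

  # flat series: infinite half-life, outside the measured span
  expect_equal(fit_decay(times7, rep(1, 7))$status, "excluded_range")
  # half-life longer than the time course
  expect_equal(fit_decay(times7, exp(-times7 * log(2) / 200))$status,
               "excluded_range")

  # noise with mean absolute deviation ~0.2 breaches the residual rule;
  # oracle: best achievable |resid| over a dense rate grid stays > 0.14
  bump <- rep(c(0.2, -0.2), length.out = 7)
  Rn <- pmax(exp(-times7 * log(2) / 20) + bump, 0)
  grid <- seq(0, 1, by = 1e-3)
  best <- min(vapply(grid, function(k) mean(abs(Rn - exp(-k * times7))),
                     numeric(1)))
  expect_gt(best, 0.14)
  expect_equal(fit_decay(times7, Rn)$status, "excluded_residual")

  expect_error(fit_decay(c(0, 10), c(1, 0.5)), "at least 3")
})

test_that("no kept gene ever violates an exclusion rule", {
  for (seed in 1:5) {
    g <- gen_decay_table(40, function(n) runif(n, 2, 120), times7,
                         noise_sd = 0.15, seed = seed)
    fits <- fit_decay_table(g$table)
    kept <- fits[fits$status == "kept", ]
    expect_true(all(kept$avg_abs_residual <= 0.14))
    expect_true(all(kept$half_life <= max(times7)))
  }
})

test_that("half-lives are recovered accurately at realistic noise", {
  g <- gen_decay_table(60, function(n) runif(n, 5, 50), times7,
                       noise_sd = 0.05, seed = 7)
  fits <- fit_decay_table(g$table)
  truth <- g$truth$half_life[match(fits$gene, g$truth$gene)]
  kept <- fits$status == "kept"
  rel_err <- abs(fits$half_life[kept] - truth[kept]) / truth[kept]
  expect_lt(median(rel_err), 0.10)
})

test_that("codon optimality counts optimal sense codons", {
  for (target in c(0, 0.5, 1)) {
    g <- gen_cds(200, target, seed = 5)
    expect_equal(codon_optimality(g$cds), target)
    expect_equal(g$truth$optimal_fraction, target)
  }
  expect_error(codon_optimality("ATGC"), "not divisible by 3")
  expect_error(codon_optimality("ATGNNN"), "ambiguous base in codon 2")
  expect_error(codon_optimality(""), "empty")
  # stop codons are ignored in the denominator
  tbl <- read_codon_table()
  expect_equal(codon_optimality("GCTTAA", tbl), 1)  # GCT optimal + stop
})

test_that("occupancy statistic divides fold change by tail length", {
  occ <- occupancy_statistic(
    data.frame(transcript = c("a", "b"), logfc = c(0, 1)),
    data.frame(transcript = c("a", "b"), mean_tail_nt = c(50, 40)))
  expect_equal(occ$occupancy_per_nt, c(0.02, 0.05))

  # scale equivariance: doubling tails halves occupancy
  g <- gen_occupancy_tables(50, seed = 11)
  o1 <- occupancy_statistic(g$occupancy, g$tails)
  t2 <- g$tails; t2$mean_tail_nt <- t2$mean_tail_nt * 2
  o2 <- occupancy_statistic(g$occupancy, t2)
  expect_equal(o2$occupancy_per_nt, o1$occupancy_per_nt / 2)

  expect_message(
    occupancy_statistic(
      data.frame(transcript = c("a", "b"), logfc = c(0, 1)),
      data.frame(transcript = "a", mean_tail_nt = 50)),
    "1 unmatched")
  expect_error(
    occupancy_statistic(
      data.frame(transcript = "a", logfc = 0),
      data.frame(transcript = "a", mean_tail_nt = 0)),
    "non-positive mean tail length")
})

test_that("occupancy rises with optimality when the generator says so", {
  g <- gen_occupancy_tables(400, optimality_effect = 1, seed = 13)
  occ <- occupancy_statistic(g$occupancy, g$tails)
  bins <- optimality_bin(g$optimality$fraction)
  med <- tapply(occ$occupancy_per_nt, bins, median)
  expect_gt(med[[">=60%"]], med[["<40%"]])
  bc <- bin_and_compare(occ$occupancy_per_nt, g$optimality$fraction)
  expect_lt(bc$anova_p, 0.001)
  expect_true(all(bc$tukey$difference[bc$tukey$bin == ">=60%"] > 0))
})

test_that("bin comparison handles constants and matches the t-test identity", {
  # all groups identical constants: flagged, zero differences
  bc0 <- bin_and_compare(rep(1, 40), runif(40))
  expect_true(bc0$flagged)
  expect_true(all(bc0$tukey$difference == 0))

  # two balanced groups: ANOVA F equals the squared pooled t statistic
  set.seed(21)
  x <- c(rnorm(30, 0), rnorm(30, 0.8))
  frac <- c(runif(30, 0, 0.39), runif(30, 0.61, 1))
  bc <- bin_and_compare(x, frac, edges = c(40))
  g1 <- x[1:30]; g2 <- x[31:60]
  sp2 <- (29 * var(g1) + 29 * var(g2)) / 58
  t_stat <- (mean(g2) - mean(g1)) / sqrt(sp2 * (1 / 30 + 1 / 30))
  expect_equal(bc$anova_f, t_stat^2, tolerance = 1e-10)

  # small bins: error by default, merged on request
  frac_small <- c(runif(20, 0, 0.39), 0.45, runif(20, 0.61, 1))
  vals <- rnorm(41)
  expect_error(bin_and_compare(vals, frac_small, edges = c(40, 50, 60)),
               "fewer than 2")
  bc2 <- bin_and_compare(vals, frac_small, edges = c(40, 50, 60),
                         small_bins = "merge")
  expect_false("40-50%" %in% names(bc2$counts))
})

test_that("between-bin shifts are detected reliably at moderate size", {
  hits <- 0L
  for (run in 1:20) {
    set.seed(300 + run)
    n <- 60
    frac <- c(runif(n, 0, 0.39), runif(n, 0.61, 1))
    vals <- c(rnorm(n, 0, 1), rnorm(n, 1, 1))   # shift of one SD
    bc <- bin_and_compare(vals, frac, edges = c(40))
    if (bc$tukey$p_adj[1] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("half-life ratios join kept genes and count the dropped", {
  fits <- data.frame(gene = c("a", "b", "c"),
                     k = 1, half_life = c(10, 20, 30),
                     avg_abs_residual = 0,
                     status = c("kept", "kept", "excluded_residual"))
  r_same <- halflife_ratio(fits, fits)
  expect_true(all(r_same$ratio == 1))
  expect_equal(attr(r_same, "n_dropped"), 1L)  # the excluded gene

  fits2 <- fits
  fits2$half_life <- c(27, 54, 81)
  r <- halflife_ratio(fits2, fits)
  expect_equal(r$ratio, c(2.7, 2.7))
})
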