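test_that("context rate reflects engagement, ruleset and stimulation", {
  cfg <- load_config()
  st <- assemble_mrnp(sub_a30u, pab1_wt(), 1)
  wt <- enzyme_ruleset("ccr4not_wt")
  # outside all footprints with a CTD-bearing Pab1: stimulated naked rate
  expect_equal(context_rate(st, wt, position = 30),
               wt$k_naked * wt$stimulation_factor)
  # inside the footprint, Ccr4-inactive: Caf1 cannot cut
  expect_equal(context_rate(st, enzyme_ruleset("ccr4not_ccr4_inactive"),
                            position = 20), 0)
  # isolated Caf1 penetrates the footprint slowly, unstimulated
  caf1 <- enzyme_ruleset("isolated_caf1")
  expect_gt(context_rate(st, caf1, position = 20), 0)
  expect_equal(context_rate(st, caf1, position = 30), caf1$k_naked)
  # no C-terminal region: no stimulation even with active Ccr4
  st_dpc <- assemble_mrnp(sub_a30u,
                          pab1_variant(has_c_terminal_region = FALSE), 1)
  expect_equal(context_rate(st_dpc, wt, position = 30), wt$k_naked)
  expect_equal(context_rate(st, wt, position = 0), 0)
})

test_that("Ccr4-inactive trajectories absorb at the hard stop, Pab1 bound", {
  st <- assemble_mrnp(sub_a30u, pab1_wt(), 1)
  params <- params_for("ccr4not_ccr4_inactive", t_end = 180)
  set.seed(101)
  for (i in 1:25) {
    traj <- simulate_molecule(st, params)
    expect_true(attr(traj, "stalled"))
    expect_equal(traj$tail_remaining[nrow(traj)], 22L)
    expect_equal(traj$bound_count[nrow(traj)], 1L)
  }
})

test_that("a double-inactive complex produces no cut events", {
  st <- assemble_mrnp(sub_a30u, pab1_wt(), 1)
  set.seed(5)
  traj <- simulate_molecule(st, params_for("ccr4not_double_inactive", 60))
  expect_false("cut" %in% traj$event)
  expect_equal(traj$tail_remaining[nrow(traj)], 30L)
})

test_that("naked-tail kinetics match the pure-death closed form", {
  # oracle: cuts in [0, t] ~ Poisson(r t), so before absorption the tail
  # has mean L0 - r t and variance r t
  st <- assemble_mrnp(sub_a60u, n_pab1 = 0)
  r <- enzyme_ruleset("ccr4not_wt")$k_naked
  t_obs <- 4
  en <- simulate_ensemble(sub_a60u, pab1_wt(), 0,
                          params_for("ccr4not_wt", t_obs,
                                     record_times = c(0, t_obs)),
                          n_molecules = 2000, seed = 31)
  tails <- en$tails[2, ]
  mu <- 60 - r * t_obs
  expect_lt(abs(mean(tails) - mu), 4 * sqrt(r * t_obs / 2000))
  expect_lt(abs(var(tails) / (r * t_obs) - 1), 0.15)
})

test_that("ensembles are reproducible for a fixed seed", {
  run <- function() {
    simulate_ensemble(sub_a30u, pab1_wt(), 1,
                      params_for("ccr4not_wt", 3), 40, seed = 99)
  }
  e1 <- run(); e2 <- run()
  expect_identical(e1$tails, e2$tails)
  expect_identical(e1$bound, e2$bound)
  e3 <- simulate_ensemble(sub_a30u, pab1_wt(), 1,
                          params_for("ccr4not_wt", 3), 40, seed = 100)
  expect_false(identical(e1$tails, e3$tails))
})

test_that("trajectories never gain adenosines or rebind Pab1", {
  set.seed(17)
  st <- assemble_mrnp(sub_a60u, pab1_wt(), 2)
  for (i in 1:10) {
    traj <- simulate_molecule(st, params_for("ccr4not_wt", 30))
    expect_true(all(diff(traj$time) >= 0))
    expect_true(all(diff(traj$tail_remaining) <= 0))
    bc <- traj$bound_count
    after_max <- bc[seq(which.max(bc), length(bc))]
    expect_true(all(diff(after_max) <= 0))
  }
})

test_that("with zero koff and zero engaged rate, absorption equals the protected limit", {
  caf1_only <- enzyme_ruleset("ccr4not_ccr4_inactive")
  cases <- list(list(sub_a30u, pab1_wt(), 1), list(sub_a30, pab1_wt(), 1),
                list(sub_a30, pab1_rrm_mutant(4), 1),
                list(sub_a30u, pab1_rrm_mutant(3), 1),
                list(sub_a60u, pab1_wt(), 2))
  set.seed(23)
  for (cs in cases) {
    st <- assemble_mrnp(cs[[1]], cs[[2]], cs[[3]])
    lim <- protected_limit(st, caf1_only)
    # engagement stays above the mobile thresholds here, so koff is 0
    for (i in 1:5) {
      traj <- simulate_molecule(st, params_for("ccr4not_ccr4_inactive", 600))
      expect_equal(traj$tail_remaining[nrow(traj)], lim)
    }
  }
})

test_that("Pab1 is not released while engagement keeps koff at zero", {
  set.seed(41)
  st <- assemble_mrnp(sub_a30u, pab1_wt(), 1)
  for (i in 1:10) {
    traj <- simulate_molecule(st, params_for("ccr4not_wt", 60))
    rel <- which(traj$event == "pab1_release")
    for (j in rel) {
      # engagement when released must be within the dissociating range
      expect_lte(traj$tail_remaining[j],
                 load_config()$koff$slow_max_engagement)
    }
  }
})

test_that("Pab1 slows isolated Caf1 about 3-fold", {
  p <- params_for("isolated_caf1", 400, record_times = seq(0, 400, 25))
  e_free <- simulate_ensemble(sub_a30u, pab1_wt(), 0, p, 80, seed = 61)
  e_bound <- simulate_ensemble(sub_a30u, pab1_wt(), 1, p, 80, seed = 62)
  r_free <- deadenylation_rate(modal_series(e_free))$rate
  r_bound <- deadenylation_rate(modal_series(e_bound))$rate
  expect_gt(r_free / r_bound, 2)
  expect_lt(r_free / r_bound, 4.5)
})

test_that("declared excess Pab1 slows naked cutting only on UTR substrates", {
  p <- function(sub, excess) {
    en <- simulate_ensemble(sub, pab1_wt(), 0,
                            kinetic_params(enzyme_ruleset("ccr4not_wt"),
                                           t_end = 3, record_times = c(0, 3),
                                           excess_pab1 = excess),
                            300, seed = 55)
    mean(en$tails[2, ])
  }
  removed_free <- 30 - p(sub_a30u, FALSE)
  removed_excess <- 30 - p(sub_a30u, TRUE)
  expect_equal(removed_free / removed_excess, 2, tolerance = 0.15)
  # no UTR: excess Pab1 has nothing to obstruct
  expect_equal(p(sub_a30, TRUE), p(sub_a30, FALSE))
})

test_that("ensemble TSV serialization round-trips losslessly", {
  en <- simulate_ensemble(sub_a30u, pab1_rrm_mutant(2), 1,
                          params_for("ccr4not_wt", 3), 15, seed = 8)
  path <- tempfile(fileext = ".tsv")
  write_ensemble_tsv(en, path)
  back <- read_ensemble_tsv(path)
  expect_equal(back$tails, en$tails)
  expect_equal(back$bound, en$bound)
  expect_equal(back$record_times, en$record_times)
  expect_equal(back$stalled, en$stalled)
  expect_equal(back$provenance$substrate$label, "23-mer-A30")
  expect_equal(back$provenance$variant$rrm_functional,
               c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(back$provenance$enzyme, "ccr4not_wt")
})
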