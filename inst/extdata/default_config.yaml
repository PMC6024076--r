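# Default geometry, kinetic calibration and analysis thresholds.
# All numeric model defaults live here; code contains no magic constants.
config_version: 1

geometry:
  # Footprint geometry per binding mode. Pause edges are the 3' edges of the
  # engaged RRM footprints, in adenosines from the UTR/tail junction
  # (1-based tail coordinates). Hard stops are the smallest tail length a
  # Caf1-class (engaged-rate-zero) activity can reach when the listed RRM is
  # the 3'-most *5'-ward-protecting* domain still engaged on the tail.
  utr_anchored:                 # RRM4 sits on the 3' UTR, RRMs 1-3 on poly(A)
    pause_edges: {rrm1: 8, rrm2: 16, rrm3: 24}
    hard_stops:  {rrm1: 8, rrm2: 16, rrm3: 22}
    release_threshold: 8        # engaged nt below which dissociation speeds up
  all_polyA:                    # all four RRMs engage poly(A)
    pause_edges: {rrm1: 8, rrm2: 16, rrm3: 24, rrm4: 28}
    hard_stops:  {rrm1: 8, rrm2: 16, rrm3: 22, rrm4: 28}
    release_threshold: 20       # loses grip once < 20 engaged adenosines
  # Loading capacity: proximal (UTR-anchored) molecule covers proximal_span
  # tail nt; each additional molecule needs a further distal_span nt.
  capacity:
    proximal_span: 22
    distal_span: 28
  # RRM1/RRM2 mutants: pause site removed, remaining pause dwell halved
  # (qualitative gel statement only; heuristic).
  mutant_dwell_factor: 0.5

rulesets:
  # Rates in nt/min. k_naked: outside any footprint; k_engaged: within a
  # protected region. stimulation_factor multiplies cutting when a
  # C-terminal-region-bearing Pab1 is on the RNA and the ruleset has active
  # Ccr4. pause_dwell_mean: extra exponential dwell (min) on first arrival
  # at each pause site. Calibration: naked A60 removed in ~12 min;
  # stimulation and dwell jointly reproduce the ~3-fold modal-rate increase
  # by Pab1 on 20-mer-A60; isolated enzymes are 10-fold slower.
  ccr4not_wt:
    {k_naked: 5.0, k_engaged: 5.0, stimulation_factor: 7.5,
     pause_dwell_mean: 0.35, ccr4_active: true}
  ccr4not_caf1_inactive:
    {k_naked: 5.0, k_engaged: 5.0, stimulation_factor: 7.5,
     pause_dwell_mean: 0.35, ccr4_active: true}
  ccr4not_ccr4_inactive:
    {k_naked: 5.0, k_engaged: 0.0, stimulation_factor: 1.0,
     pause_dwell_mean: 0.35, ccr4_active: false}
  ccr4not_double_inactive:
    {k_naked: 0.0, k_engaged: 0.0, stimulation_factor: 1.0,
     pause_dwell_mean: 0.0, ccr4_active: false}
  isolated_ccr4:
    {k_naked: 0.5, k_engaged: 0.5, stimulation_factor: 7.5,
     pause_dwell_mean: 0.35, ccr4_active: true}
  isolated_caf1:
    {k_naked: 0.5, k_engaged: 0.15, stimulation_factor: 1.0,
     pause_dwell_mean: 6.0, ccr4_active: false}
  caf1_ccr4_heterodimer:
    {k_naked: 0.5, k_engaged: 0.5, stimulation_factor: 7.5,
     pause_dwell_mean: 0.35, ccr4_active: true}

koff:
  # Pab1 dissociation rate (1/min) as a step function of remaining engaged
  # adenosines: half-life ~2 min at <= 5 nt, ~40 min at 6-10 nt, stable
  # above. all_polyA molecules additionally release (fast rate) once
  # engagement drops below the mode's release_threshold.
  fast: 0.34657          # ln(2)/2
  slow: 0.017329         # ln(2)/40
  fast_max_engagement: 5
  slow_max_engagement: 10

thresholds:
  residual_max: 0.14            # mean |R_obs - R_fit| exclusion cutoff
  blur_sigma: 0.5               # nt, virtual gel band blur
  band_prominence: 2.0          # x median lane intensity
  band_min_lanes: 2             # persistence requirement, consecutive lanes
  shortest_tail_percentile: 5   # "shortest tail" robust percentile
  dissociation_average_interval: 10  # s, trace pre-averaging window

options:
  # Fold slowing of naked-region cutting when excess free Pab1 is declared
  # on a UTR-containing substrate (excess Pab1 occupies the UTR and
  # obstructs the nuclease); applied only when a simulation opts in.
  excess_pab1_obstruction: 2.0

bins:
  # Codon-optimality bin edges (percent optimal codons); "<40%" is always
  # the reference bin for Tukey comparisons.
  edges: [40, 50, 60]
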