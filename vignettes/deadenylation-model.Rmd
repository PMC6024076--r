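---
title: "A mechanistic model of Pab1-coupled mRNA deadenylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic model of Pab1-coupled mRNA deadenylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deadenylate)
```

## The biological problem

Eukaryotic mRNA decay begins with removal of the 3' poly(A) tail by the
Ccr4-Not complex, whose two exonucleases, Ccr4 and Caf1, must work on a
tail that is tightly coated by the poly(A)-binding protein Pab1. `deadenylate`
implements a mechanistic, single-molecule model of this process: how Pab1's
four RNA-recognition motifs (RRMs) occupy the tail, where the complex pauses
and where a Caf1-only activity stalls outright, how Pab1 is released as the
tail shrinks, and what the resulting populations look like on a virtual
denaturing or native gel. Around the simulator sit the standard quantitative
procedures used with such data: one-site equilibrium binding fits,
exponential dissociation and linear association kinetics, and a
transcriptional shut-off half-life pipeline with spike-in normalization,
codon-optimality binning and ANOVA/Tukey comparisons.

## Footprint geometry

An mRNP state is a substrate (UTR length plus tail length) with an ordered
set of bound Pab1 molecules. Two binding modes exist:

* **UTR-anchored** — the 5'-most molecule on a substrate with a 3' UTR
  places RRM4 on the UTR and RRMs 1–3 on the tail. Its pause sites (3' RRM
  footprint edges) default to 8, 16 and 24 adenosines and its hard stop —
  the smallest tail a Caf1-class activity can generate — to 22.
* **all-poly(A)** — with no UTR available (or RRM4 impaired on a UTR-less
  substrate), all functional RRMs engage the tail; the full footprint and
  hard stop default to 28 nt, with pause edges at 8, 16, 24 and 28.

These numbers are deliberately independent entries of a geometry table
(`inst/extdata/default_config.yaml`) rather than multiples of a single
per-RRM span: the measured pause ladder (8/16/24), the Caf1 stall at 22,
and the all-poly(A) footprint of 28 are not mutually consistent with one
fixed span, and the table reproduces every measured endpoint as printed.
Impairing an RRM removes its pause edge and, if it was the 5'-most engaged
domain, lowers the hard stop (22 to 16 for RRM3 on a UTR substrate; 28 to
22 for RRM4 on a tail-only substrate). RRM1/RRM2 impairments are reported
to blur the ladder without a printed endpoint; we model them heuristically
as loss of the corresponding pause edge plus halved pause dwell.

Loading capacity is also a table entry (22 nt for the proximal molecule,
28 nt for each additional one), giving two molecules on an A60-class tail
and one on A30- or A10-class tails. Binding modes are assigned statically
at assembly; whether the distal molecule re-anchors during deadenylation is
not resolvable from gel data, so we do not model it.

```{r}
st <- assemble_mrnp(parse_substrate_label("23-mer-A30"), pab1_wt(), 1)
st
pause_sites(st)
protected_limit(st, enzyme_ruleset("ccr4not_ccr4_inactive"))
```

## Stochastic kinetics

`simulate_molecule()` runs an exact event-driven (Gillespie) simulation.
The cut rate at the terminal adenosine depends on context: `k_naked`
outside any footprint, `k_engaged` inside one (zero for Caf1-class
configurations — only Ccr4 cuts Pab1-bound poly(A)), both multiplied by a
stimulation factor when a Pab1 with its C-terminal region is on the RNA
and the ruleset has active Ccr4. On first arrival at a pause site the
complex dwells for an extra exponential time. RRM "breathing" — the
transient disengagement that lets the nuclease advance into a footprint —
is folded into these effective rates rather than modeled as explicit
engage/disengage events: no breathing rate is measurable from gel
patterns, while effective rates are identifiable from them. Because a
shortened tail cannot be rebound, crossing a footprint edge disengages
that RRM irreversibly, and Pab1 dissociation is a step function of its
remaining engagement: half-life about 2 min at five or fewer engaged
adenosines, about 40 min at six to ten, effectively stable above. An
all-poly(A) molecule additionally loses grip once fewer than ~20
adenosines remain engaged, reproducing the earlier release seen on
UTR-less substrates in native gels.

### Calibration

All rate constants live in the shipped config and were fixed analytically
from the measured end-to-end observables, not fitted to simulations:

* `k_naked = 5` nt/min — a naked A60 tail is removed in about 12 min at
  the reference enzyme concentration.
* `stimulation_factor = 7.5` with `pause_dwell_mean = 0.35` min — chosen
  jointly so that on 20-mer-A60 with two Pab1 the expected removal time is
  `60/(5 x 7.5) + 7 pauses x 0.35 min ~ 4 min`, i.e. the measured ~3-fold
  modal-rate increase over the naked substrate, while keeping the pause
  dwell long enough relative to inter-pause transit for discrete bands.
* isolated enzymes run at `k_naked/10` (they are >10-fold less active than
  the complex); isolated Caf1 penetrates footprints slowly
  (`k_engaged = 0.15` nt/min) with a long dwell, reproducing the ~3-fold
  slowing by Pab1 without a hard stall at 22.

## Virtual gels

`lane_profile()` histograms an ensemble's tail lengths at one time and
convolves them with a sub-nucleotide Gaussian blur (0.5 nt default),
conserving total intensity. The modal tail length (ties broken toward the
shorter species) regressed on time gives the average deadenylation rate,
with its uncertainty reported as the 95% confidence interval of the slope;
trailing plateau points after absorption are excluded because regressing
over a plateau biases the slope toward zero. `detect_pause_bands()` calls
a tail length a band when it is a sharp, prominent local maximum of a lane
in at least two consecutive lanes: a population drifting through a length
peaks there in one lane only, so persistence plus sharpness (both relative
to a configurable prominence factor, default 2x) separates genuine
stalling intermediates from a moving front. The prominence factor is not
derivable from first principles and is exposed in the config. For in vivo
style readouts, the "shortest tail" statistic is the 5th percentile of the
lane rather than the literal minimum, for robustness to single-molecule
outliers.

## Binding and kinetic fits

`fit_one_site()` fits the hyperbolic one-site curve
`S = S_free + (S_bound - S_free) C / (Kd + C)` by Levenberg-Marquardt
least squares, matching the conventional treatment of polarization
titrations. At sub-nanomolar Kd the probe concentration (0.2 nM in the
emulated assay) is comparable to Kd and the hyperbola overestimates it; a
quadratic tight-binding variant is available via `tight_binding = TRUE`,
with the hyperbolic form kept as the default to match standard practice.
The baseline is left free rather than floored at the free-probe signal;
both behaviors are supported. `fit_dissociation()` fits a single
exponential after optional 10-s pre-averaging, and `fit_association()`
regresses observed rates on concentration (`kobs = koff + kon C`), so
`intercept/slope` provides a kinetic Kd consistent with the equilibrium
fit by detailed balance.

## The half-life pipeline

Shut-off time courses are normalized to summed spike-in signal per time
point (per-spike-in regression would be an alternative; the summed form is
the config default), then to each gene's 0-min level, and fitted with
`R(t) = exp(-k t)` by nonlinear least squares *on the linear scale*. Two
exclusion rules are hard: mean absolute residual above 0.14, and fitted
half-life longer than the measured span. The 0.14 threshold is applied on
the linear relative-abundance scale, consistent with an absolute-residual
criterion on values in [0, 1]; whether the original analysis fitted
log-linearly is not documented, so a `log_linear` flag is provided. The
one-dimensional rate search is seeded from a log-linear regression and
bracketed around that seed — a wide fixed bracket can strand golden-section
search on the flat large-rate tail of the objective.

Codon optimality is the fraction of non-stop codons classified optimal by
a two-class codon table. The bundled table
(`codon_optimality_synthetic.tsv`) is a synthetic default classification
(25 optimal, 36 non-optimal codons, roughly following yeast usage
preferences); analyses of real data should supply a published
classification with the same two-column schema. Per-transcript Pab1
occupancy is RIP enrichment fold change (log base 2 assumed, the standard
output of the upstream differential-enrichment tooling) divided by mean
tail length. Bin comparisons use base R `aov()` and `TukeyHSD()` with the
`<40%` bin as the fixed reference; bin edges default to 40/50/60% and are
configurable. Bins with fewer than two members either error or merge into
the adjacent lower bin, per the `small_bins` argument.

## What the generators emulate — and what they do not

Each `gen_*()` function is a pure function of its arguments and seed and
records its ground truth, so every downstream stage has a recovery test
that does not rerun the generator. Expression noise is multiplicative
lognormal (5% default) — appropriate for sequencing-derived abundances —
with optional global drift that only spike-in normalization can undo;
optical signals get additive Gaussian noise at 2% of amplitude, typical of
plate-reader and biosensor data. The generators deliberately omit
features of real data: counting noise at low expression, gene-specific
deviations from single-exponential decay, correlated replicate structure,
RIP background binding, and sequence effects beyond codon classes.
Passing recovery tests therefore demonstrates correctness of the
estimators under the stated noise models, not robustness to everything
real libraries contain.

## Numerical choices and degenerate inputs

* Tail coordinates are 1-based adenosine indices from the UTR/tail
  junction; "tail length L" means adenosines 1..L remain, matching gel
  ladder labels (A8, A16, ...).
* Modal ties break toward the smaller tail; pause dwell is placed exactly
  at the pause site (whether the complex stalls 1–2 nt 3' of the edge is
  not resolvable from the data).
* Degenerate fits are flagged, not silently returned: constant titrations,
  non-positive rate constants, Kd pinned at the concentration range
  boundary, all-zero lanes, fewer than three usable rate points.
* Per-molecule RNG substreams are drawn from the master seed, so ensembles
  are reproducible and independent of evaluation order.

## Problem sizes

The test suite and the reproduction script use ensemble sizes of 300–1,000
molecules (10,000 for the pure-death distributional check), 50–200
replicate fits, and 40–60-gene expression tables — sizes at which the
stochastic checks are stable across seeds while the whole suite runs in
well under a minute on a laptop-class core.

## Known limitations

Enzyme concentration is absorbed into rates (no binding-site competition),
there is no distributive-vs-processive distinction beyond the dwell
parameters, the UTR is a featureless anchor, and the alternative
"sliding/ratcheting" model of Pab1 persistence is out of scope. The
excess-Pab1 inhibition seen on UTR-containing substrates is available as
an optional obstruction multiplier in the config, off by default.
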