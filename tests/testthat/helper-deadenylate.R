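# shared fixtures: substrates and short-hand constructors

sub_a30u <- parse_substrate_label("23-mer-A30")   # UTR + A30
sub_a30 <- parse_substrate_label("A30")           # tail only
sub_a60u <- parse_substrate_label("20-mer-A60")   # UTR + A60
sub_a10u <- parse_substrate_label("20-mer-A10")

params_for <- function(ruleset, t_end, record_times = NULL, ...) {
  kinetic_params(enzyme_ruleset(ruleset, ...), t_end = t_end,
                 record_times = record_times)
}

# analytic pure-death tail distribution: tail = L0 - min(L0, Poisson(r t))
pure_death_probs <- function(l0, r, t) {
  cuts <- 0:(l0 - 1)
  p <- stats::dpois(cuts, r * t)
  c(1 - sum(p), rev(p))  # tails 0, 1, ..., l0
}
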