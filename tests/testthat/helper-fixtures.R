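# Shared small fixtures, generated in code. Built once per test run.

small_cfg <- function(...) {
  defaults <- list(n_cell_lines = 60, n_tumors = 120, n_lncRNAs = 100,
                   n_pcgs = 200, n_agents = 4, n_cancer_types = 4,
                   n_pathways = 2, k_true_per_agent = 5, effect_size = 0.8,
                   noise_sd = 0.5, type_shift = 1, lineage_effect_sd = 0.3,
                   seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# One panel reused across read-only tests.
.fixture_panel <- simulate_cell_line_panel(small_cfg())
.fixture_cohort <- simulate_tumor_cohort(small_cfg(), .fixture_panel$truth)

fixture_panel <- function() .fixture_panel
fixture_cohort <- function() .fixture_cohort

# A matrix and response with planted sparse signal, used by the elastic-net
# modules.
planted_xy <- function(panel = fixture_panel(), agent = 1) {
  list(X = panel$expression,
       y = panel$response$ln_ic50[, agent],
       truth_idx = which(panel$truth$true_coefficients[agent, ] != 0))
}

# Independent oracle for the one-sided Fisher enrichment p: exhaustive
# hypergeometric enumeration over all outcomes at the observed margins.
enumerate_fisher_greater <- function(n11, n10, n01, n00) {
  m <- n11 + n10          # size of set A
  k <- n11 + n01          # size of set B
  N <- n11 + n10 + n01 + n00
  ks <- max(0, m + k - N):min(m, k)
  probs <- stats::dhyper(ks, k, N - k, m)
  sum(probs[ks >= n11])
}

# Brute-force Shannon entropy from first principles (explicit frequency
# loop, no table()).
entropy_oracle <- function(v) {
  u <- unique(v)
  h <- 0
  for (lab in u) {
    p <- sum(v == lab) / length(v)
    h <- h - p * log2(p)
  }
  h
}
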