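# Small fixtures built in code, shared across test files.

# A compact two-group cohort spec with scalar covariate parameters so the
# group labels can be anything.
small_cohort <- function(n_control = 20, n_case = 20) {
  cohort_spec(n_per_group = c(control = n_control, case = n_case),
              age_mean = 47, age_sd = 12,
              pmi_mean = 28, pmi_sd = 13,
              ph_mean = 6.6, ph_sd = 0.28,
              prop_male = 0.7, prop_left = 0.5,
              prop_smoker = c(control = 0.45, case = 0.8),
              prop_suicide = c(control = 0, case = 0.2))
}

# One clean gene with no subpopulation and no pH coupling.
plain_gene <- function(name = "G1", core_mean = 0, core_sd = 0.5) {
  gene_spec(name, core_mean = core_mean, core_sd = core_sd,
            subpop_prevalence = 0, ph_coupling = 0)
}

noiseless <- function() ct_noise_spec(replicate_sd = 0, aberrant_rate = 0)

# Brute-force Mann-Whitney U: count of (x_i, y_j) pairs with y_j < x_i,
# plus half-ties — the direct definition, independent of rank algebra.
brute_u_pairs <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exact two-sided Mann-Whitney p by enumeration of all assignments of the
# pooled values to the two groups (no-ties case).
brute_u_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(i) brute_u_pairs(pooled[i], pooled[-i]))
  u_obs <- brute_u_pairs(x, y)
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
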