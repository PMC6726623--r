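# Independent oracles used across the suite. These deliberately take a
# different computational route from the package implementation.

# Exact HWE heterozygote distribution by the upward recurrence relation
# (ratio of successive terms), independent of the log-gamma closed form.
oracle_hwe_probs <- function(n, n_a) {
  n_a <- min(n_a, 2 * n - n_a)
  h_vals <- seq(n_a %% 2, n_a, by = 2)
  probs <- numeric(length(h_vals))
  probs[1] <- 1
  if (length(h_vals) > 1) {
    for (i in seq_len(length(h_vals) - 1)) {
      h <- h_vals[i]
      hom_minor <- (n_a - h) / 2
      hom_major <- n - h - hom_minor
      # P(h+2)/P(h) = 4 * hom_minor * hom_major / ((h+1)(h+2))
      probs[i + 1] <- probs[i] * 4 * hom_minor * hom_major / ((h + 1) * (h + 2))
      # rescale to avoid overflow on long ranges
      if (probs[i + 1] > 1e280) probs <- probs / probs[i + 1]
    }
  }
  list(n_het = h_vals, prob = probs / sum(probs))
}

# naive tail aggregation: sum of probabilities no larger than the observed
oracle_hwe_pvalue <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  d <- oracle_hwe_probs(n, 2 * n_hom_alt + n_het)
  p_obs <- d$prob[d$n_het == n_het]
  min(1, sum(d$prob[d$prob <= p_obs * (1 + 1e-10)]))
}

# Clopper-Pearson bounds by inverting the binomial tail conditions with
# root bisection on stats::pbinom (independent of the qbeta route).
oracle_cp_ci <- function(x, n, alpha = 0.05) {
  low <- if (x == 0) 0 else {
    stats::uniroot(function(p) 1 - stats::pbinom(x - 1, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-10)$root
  }
  high <- if (x == n) 1 else {
    stats::uniroot(function(p) stats::pbinom(x, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-10)$root
  }
  c(low, high)
}

# Truth-table oracle for the bi-allelic screen: count pathogenic allele
# copies directly from a dose vector and a pathogenic indicator.
oracle_screen_status <- function(doses, is_pathogenic) {
  total <- sum(doses[is_pathogenic])
  if (total >= 2) "BIALLELIC_POSITIVE" else if (total == 1) "CARRIER" else "NEGATIVE"
}
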