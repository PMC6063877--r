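# Shared fixtures: small panels built in code.

# A labeled panel of p independent standard-normal variables with an
# optional mean shift on `informative` variables for the ASD class.
random_panel <- function(n_asd, n_td, p, seed, effect = 0,
                         informative = seq_len(min(2, p))) {
  with_seed(seed, {
    vals <- matrix(rnorm((n_asd + n_td) * p), n_asd + n_td, p)
    if (effect != 0) {
      vals[seq_len(n_asd), informative] <-
        vals[seq_len(n_asd), informative] + effect
    }
    colnames(vals) <- paste0("x", seq_len(p))
    metabolite_panel(vals, rep(c("ASD", "TD"), c(n_asd, n_td)))
  })
}

# A panel linearly separable on x1 with a wide margin.
separable_panel <- function(n_asd, n_td, p = 3, seed = 1, margin = 4) {
  pan <- random_panel(n_asd, n_td, p, seed)
  pan$values[, 1] <- pan$values[, 1] +
    ifelse(pan$labels == "ASD", margin, -margin)
  pan
}

# Empirical rank AUC by brute-force pair counting (ties count 1/2);
# the independent oracle for the KDE C-statistic.
rank_auc <- function(asd, td) {
  cmp <- outer(asd, td, "-")
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / length(cmp)
}
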