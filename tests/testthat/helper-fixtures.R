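# Fixture builders and independent brute-force oracles shared across tests.

# Small labeled log2-scale matrix with `n_signal` separated features.
toy_norm_matrix <- function(n_tumor = 5, n_normal = 5, n_mirna = 40,
                            n_signal = 8, shift = 3, sd = 0.5, seed = 1) {
  set.seed(seed)
  samples <- c(sprintf("T%02d", seq_len(n_tumor)),
               sprintf("N%02d", seq_len(n_normal)))
  labels <- setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)), samples)
  v <- matrix(rnorm(n_mirna * length(samples), 8, sd), n_mirna,
              dimnames = list(sprintf("mir-%03d", seq_len(n_mirna)), samples))
  if (n_signal > 0) {
    v[seq_len(n_signal), labels == "tumor"] <-
      v[seq_len(n_signal), labels == "tumor"] + shift
  }
  structure(list(values = v, platform = "counts", labels = labels),
            class = "normalized_matrix")
}

# AUC as the normalized count of concordant (tumor > normal) score pairs,
# ties counted one half.
bf_auc <- function(scores, labels) {
  s_t <- scores[labels == "tumor"]
  s_n <- scores[labels == "normal"]
  conc <- 0
  for (a in s_t) for (b in s_n) {
    conc <- conc + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  conc / (length(s_t) * length(s_n))
}

# Upper-tail hypergeometric P(X >= k) by direct summation of choose() ratios.
bf_hyper_upper <- function(k, K, n, N) {
  if (k <= 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Pooled-variance two-sample t-test from the textbook formula.
bf_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

# Run the standard count-platform preprocessing used across tests.
preprocess_counts <- function(sim, panel_size = 30) {
  em <- suppressMessages(exclude_markers(sim$matrix))
  normalize_to_reference(detection_filter(em), panel_size = panel_size)
}
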