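# Independent oracles, coded separately from the package implementations.

# Brute-force single-sample enrichment score: explicit loops, no shared code
# with ssgsea_scores().
oracle_ssgsea_one <- function(values, genes, set, alpha) {
  n <- length(values)
  ord <- order(-values, genes, method = "radix")
  g_sorted <- genes[ord]
  in_set <- g_sorted %in% set
  w_total <- 0
  for (i in seq_len(n)) if (in_set[i]) w_total <- w_total + (n - i + 1)^alpha
  es <- 0; p_in <- 0; p_out <- 0
  n_out <- n - sum(in_set)
  for (i in seq_len(n)) {
    if (in_set[i]) p_in <- p_in + (n - i + 1)^alpha / w_total
    else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  es
}

# Hand product-limit table
oracle_km <- function(times, events) {
  ut <- sort(unique(times))
  s <- 1
  out <- numeric(0)
  for (t in ut) {
    n_i <- sum(times >= t)
    d_i <- sum(times == t & events == 1)
    s <- s * (1 - d_i / n_i)
    out <- c(out, s)
  }
  data.frame(time = ut, surv = out)
}

# Breslow partial log-likelihood (valid for tie-free data) and grid maximiser
oracle_cox_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
oracle_cox_grid <- function(x, times, events, lo = -5, hi = 5) {
  f <- function(b) -oracle_cox_loglik(b, x, times, events)
  stats::optimize(f, c(lo, hi), tol = 1e-10)$minimum
}

# ARI from the contingency-table formula, written independently
oracle_ari <- function(a, b) {
  ct <- table(a, b)
  n <- sum(ct)
  sij <- sum(choose(ct, 2))
  sa <- sum(choose(rowSums(ct), 2))
  sb <- sum(choose(colSums(ct), 2))
  exp_ <- sa * sb / choose(n, 2)
  (sij - exp_) / ((sa + sb) / 2 - exp_)
}

# Hypergeometric upper tail by direct summation
oracle_hyper_tail <- function(k, set_size, n_hits, n_universe) {
  tot <- 0
  for (i in k:min(set_size, n_hits)) {
    tot <- tot + choose(set_size, i) *
      choose(n_universe - set_size, n_hits - i) / choose(n_universe, n_hits)
  }
  tot
}

# Small LOG2 expression matrix with labelled groups, used across tests
toy_log2_matrix <- function(n_genes = 20, n_samples = 12, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = 5),
              n_genes, n_samples,
              dimnames = list(sprintf("g%02d", 1:n_genes),
                              sprintf("s%02d", 1:n_samples)))
  expression_matrix(m, "LOG2")
}
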