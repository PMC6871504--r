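# Shared fixture builders; everything is generated in code at test time.

# small labeled dataset with an optional perfectly separating first probe
make_beta_dataset <- function(n_per_class = c(A = 6L, B = 6L), p = 8L,
                              seed = 1L, separate = FALSE) {
  set.seed(seed)
  n <- sum(n_per_class)
  x <- matrix(stats::runif(n * p, 0.05, 0.95), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("cg%03d", seq_len(p))))
  labels <- rep(names(n_per_class), times = n_per_class)
  if (separate) {
    centers <- seq(0.15, 0.85, length.out = length(n_per_class))
    x[, 1] <- centers[match(labels, names(n_per_class))] +
      stats::runif(n, -0.03, 0.03)
  }
  methyl_dataset(x, labels = labels)
}

# a small synthetic world that every downstream stage can chew quickly
tiny_world <- function(seed = 1L, n_informative = 8L, effect = 0.3,
                       n_probes = 120L,
                       n_per_class = c(A = 15L, B = 12L, C = 15L)) {
  generate_dataset(synthetic_spec(
    n_per_class = n_per_class, n_probes = n_probes,
    n_informative = n_informative, effect = effect, seed = seed))
}

# independent step-up BH oracle (naive arithmetic, no p.adjust)
naive_bh <- function(p) {
  M <- length(p)
  o <- order(p)
  q <- p[o] * M / seq_len(M)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(M)
  out[o] <- q
  out
}

# independent hypergeometric upper tail by explicit binomial coefficients
naive_hyper_tail <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# literal evaluation of the relative-importance formula over recorded trees
ri_by_hand <- function(trees, probe_ids, u = 1, v = 1) {
  ri <- stats::setNames(numeric(length(probe_ids)), probe_ids)
  for (tr in trees) {
    nd <- tr$nodes
    if (nrow(nd) == 0) next
    for (r in seq_len(nrow(nd))) {
      f <- nd$feature[r]
      ri[f] <- ri[f] + tr$wacc^u * nd$ig[r] * nd$node_fraction[r]^v
    }
  }
  ri
}
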