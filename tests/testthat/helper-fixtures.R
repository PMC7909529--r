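# Shared fixtures: small random matrices, toy cohorts and feature tables
# built in code.

random_two_class <- function(n_per_class, n_features, seed) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * n_features), 2 * n_per_class, n_features)
  colnames(X) <- sprintf("f%02d", seq_len(n_features))
  y <- factor(rep(c("control", "case"), each = n_per_class),
              levels = c("control", "case"))
  list(X = X, y = y)
}

toy_feature_table <- function(values, group = NULL) {
  if (is.null(group))
    group <- rep(c("control", "case"), length.out = nrow(values))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("f%02d", seq_len(ncol(values)))
  feature_table(values, factor(group, levels = c("control", "case")))
}

# Exact upper-tail hypergeometric probability by direct binomial-coefficient
# sums; all terms stay below 2^53 for N <= 30, so the arithmetic is exact.
hyper_tail_oracle <- function(k, K, N, n) {
  ks <- k:min(K, n)
  ks <- ks[ks >= max(0, n - (N - K))]
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
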