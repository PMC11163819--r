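# Independent oracles shared by unit and acceptance tests. Each re-derives
# the quantity by brute force, never through the package's code path.

# LRT p-value by numerical maximization of the binomial log-likelihood
# (golden-section search through optimize), not the analytic MLE.
lrt_oracle <- function(edited, unedited, is_case) {
  ll <- function(p, e, u) sum(e * log(p) + u * log(1 - p))
  opt <- function(e, u) stats::optimize(ll, c(1e-9, 1 - 1e-9), e = e, u = u,
                                        maximum = TRUE, tol = 1e-12)$objective
  ll1 <- opt(edited[is_case], unedited[is_case]) +
    opt(edited[!is_case], unedited[!is_case])
  ll0 <- opt(edited, unedited)
  stats::pchisq(max(2 * (ll1 - ll0), 0), 1, lower.tail = FALSE)
}

# Topological overlap by explicit triple loop with u != i, j.
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - 1
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# AUC by counting all case/control pairs with half credit for ties.
auc_pair_oracle <- function(x, y) {
  mean(outer(x[y], x[!y], function(a, b) (a > b) + 0.5 * (a == b)))
}

# Two-block latent-factor level matrix for network tests.
modular_levels <- function(n_per_block = 30, n_bg = 0, n_samp = 22,
                           loading = 0.9, seed = 31) {
  set.seed(seed)
  f1 <- rnorm(n_samp); f2 <- rnorm(n_samp)
  mk <- function(f, tag, k) {
    m <- t(sapply(seq_len(k), function(i)
      loading * f + sqrt(1 - loading^2) * rnorm(n_samp)))
    rownames(m) <- paste0(tag, seq_len(k))
    m
  }
  out <- rbind(mk(f1, "a", n_per_block), mk(f2, "b", n_per_block))
  if (n_bg > 0) {
    bg <- matrix(rnorm(n_bg * n_samp), n_bg, n_samp,
                 dimnames = list(paste0("n", seq_len(n_bg)), NULL))
    out <- rbind(out, bg)
  }
  colnames(out) <- paste0("s", seq_len(n_samp))
  0.2 + 0.05 * out
}
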