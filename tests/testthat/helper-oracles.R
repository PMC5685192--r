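# Independent brute-force oracles used to freeze expected values.

# two-sided binomial by full outcome enumeration (minimum-likelihood
# convention: sum of probabilities of outcomes no more likely than observed)
enum_binom_two_sided <- function(k, n, p0) {
  d <- stats::dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# signed-rank p by enumerating all 2^n sign vectors
enum_signed_rank <- function(diffs, sided = "two_sided") {
  diffs <- diffs[diffs != 0]
  n <- length(diffs)
  r <- rank(abs(diffs))
  v_obs <- sum(r[diffs > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_ge <- mean(vs >= v_obs - 1e-9)
  p_le <- mean(vs <= v_obs + 1e-9)
  switch(sided,
         greater = p_ge, less = p_le,
         two_sided = min(1, 2 * min(p_ge, p_le)))
}

# exact conditional permutation p over all choose(n, k) two-class
# relabelings, counting stat >= observed
enum_permutation <- function(values, labels, stat_fn) {
  classes <- unique(labels)
  idx <- utils::combn(seq_along(labels), sum(labels == classes[1]))
  obs <- stat_fn(labels)
  stats <- apply(idx, 2, function(i) {
    lab <- rep(classes[2], length(labels))
    lab[i] <- classes[1]
    stat_fn(lab)
  })
  mean(stats >= obs - 1e-12)
}

# Beta quantile by numeric inversion of pbeta (independent of qbeta)
invert_beta_quantile <- function(p, a, b) {
  stats::uniroot(function(x) stats::pbeta(x, a, b) - p, c(0, 1),
                 tol = 1e-12)$root
}
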