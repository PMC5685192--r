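#' Exact binomial test
#'
#' Exact binomial tail / two-sided probability for `k` successes in `n`
#' trials against null probability `p0`. The two-sided p-value uses the
#' minimum-likelihood convention (sum of probabilities of all outcomes no
#' more likely than the observed one, as in [stats::binom.test()]); for
#' `p0 = 0.5` this coincides with doubling the smaller tail.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param p0 null success probability, strictly inside (0, 1).
#' @param sided one of `"greater"`, `"less"`, `"two_sided"`.
#' @return A `TestResult` list: `statistic` (k), `p_value`, `sided`, `n`.
#' @examples
#' binom_test_exact(52, 67, 0.5, "two_sided")$p_value  # 6.459e-06
#' @export
binom_test_exact <- function(k, n, p0 = 0.5, sided = c("two_sided", "greater", "less")) {
  sided <- match.arg(sided)
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n))
    stop("k and n must be single non-missing integers")
  if (n < 1L) stop("n must be >= 1")
  if (k < 0L || k > n) stop("k must satisfy 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly within (0, 1)")
  p <- switch(sided,
    greater   = stats::pbinom(k - 1, n, p0, lower.tail = FALSE),
    less      = stats::pbinom(k, n, p0),
    two_sided = stats::binom.test(k, n, p0, alternative = "two.sided")$p.value
  )
  test_result(statistic = k, p_value = min(1, p), sided = sided, n = n)
}

#' Exact Wilcoxon signed-rank test
#'
#' Signed-rank test on paired differences under the sign-flip null: each
#' non-zero difference keeps its (mid)rank magnitude and receives a random
#' sign with probability 1/2. Zero differences are dropped. For `n <= 30`
#' after zero removal the null distribution of the positive-rank sum is
#' computed exactly by convolution over the realized rank values (ties
#' allowed via midranks); above that a normal approximation with continuity
#' correction is used. Two-sided p is twice the smaller tail, capped at 1.
#'
#' @param diffs numeric vector of paired differences.
#' @param sided `"two_sided"`, `"greater"` or `"less"`.
#' @param exact_max maximum n for which the exact null is enumerated.
#' @return A `TestResult` list; `statistic` is the positive-rank sum V.
#' @export
wilcoxon_signed_rank_exact <- function(diffs, sided = c("two_sided", "greater", "less"),
                                       exact_max = 30L) {
  sided <- match.arg(sided)
  diffs <- diffs[!is.na(diffs)]
  diffs <- diffs[diffs != 0]
  n <- length(diffs)
  if (n < 1L) stop("no information: all differences are zero or missing")
  r <- rank(abs(diffs))
  v <- sum(r[diffs > 0])
  if (n <= exact_max) {
    # exact distribution of V = sum of a random subset of the realized ranks;
    # double ranks so midranks (x.5) become integers for the convolution
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- c(1, rep(0, tot))      # f[s+1] = #sign vectors with doubled V = s
    for (w in r2) {
      g <- f
      g[(w + 1L):(tot + 1L)] <- g[(w + 1L):(tot + 1L)] + f[1L:(tot - w + 1L)]
      f <- g
    }
    pr <- f / 2^n
    v2 <- as.integer(round(2 * v))
    p_ge <- sum(pr[(v2 + 1L):(tot + 1L)])
    p_le <- sum(pr[1L:(v2 + 1L)])
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    p_ge <- stats::pnorm(v - 0.5, mu, sqrt(sig2), lower.tail = FALSE)
    p_le <- stats::pnorm(v + 0.5, mu, sqrt(sig2))
  }
  p <- switch(sided,
    greater = p_ge, less = p_le,
    two_sided = min(1, 2 * min(p_ge, p_le))
  )
  test_result(statistic = v, p_value = p, sided = sided, n = n)
}

#' FDR q-values
#'
#' Benjamini-Hochberg step-up q-values, optionally rescaled by Storey's
#' estimate of the null proportion pi0 (lambda grid 0.05..0.95 with
#' smoothing-spline extrapolation, the estimator popularized by the qvalue
#' package). BH is the default: deterministic and conservative.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` or `"storey"`.
#' @return list with `q_values` (aligned to input order), `method`, and
#'   `pi0` (1 for BH).
#' @export
fdr_qvalues <- function(pvals, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (length(pvals) == 0L) return(list(q_values = numeric(0), method = method, pi0 = 1))
  if (anyNA(pvals)) stop("p-values must not contain NA/NaN")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(pvals, method = "BH")
  pi0 <- 1
  if (method == "storey") {
    pi0 <- estimate_pi0(pvals)
    q <- pmin(1, q * pi0)
  }
  list(q_values = q, method = method, pi0 = pi0)
}

# Storey's smoother estimate of the proportion of true nulls.
estimate_pi0 <- function(pvals, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(pvals)
  pi0_l <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), numeric(1))
  if (m < 100 || all(pi0_l == 0)) return(1)  # too few p-values to smooth
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, 1 / m), 1)
}

#' Jeffreys interval for a binomial proportion
#'
#' Central quantile interval of the Beta(k + 1/2, n - k + 1/2) posterior
#' (Jeffreys prior). By convention the lower limit is 0 when `k = 0` and the
#' upper limit is 1 when `k = n`.
#'
#' @param k successes, `n` trials, `level` coverage in (0, 1).
#' @param n number of trials.
#' @param level interval coverage.
#' @return numeric `c(lo, hi)`.
#' @export
jeffreys_interval <- function(k, n, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must lie strictly within (0, 1)")
  if (any(n < 1) || any(k < 0) || any(k > n)) stop("require 0 <= k <= n, n >= 1")
  a <- (1 - level) / 2
  lo <- ifelse(k == 0, 0, stats::qbeta(a, k + 0.5, n - k + 0.5))
  hi <- ifelse(k == n, 1, stats::qbeta(1 - a, k + 0.5, n - k + 0.5))
  c(lo = unname(lo), hi = unname(hi))
}

#' Label-permutation p-value
#'
#' Generic two-class label-shuffling engine. Each permutation redraws the
#' assignment of the two labels while preserving class sizes; the p-value
#' uses the add-one estimator p = (1 + #extreme) / (1 + n_perm), which never
#' returns 0.
#'
#' @param observed_stat statistic on the real labels.
#' @param stat_fn function(labels) -> numeric statistic.
#' @param labels two-class label vector.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer RNG seed (mandatory: resampling must be reproducible).
#' @param extreme `"greater"` counts permuted statistics >= observed as
#'   extreme; `"less"` counts <= observed (for statistics where small is
#'   extreme, e.g. a p-value used as the statistic).
#' @return permutation p-value.
#' @export
permutation_pvalue <- function(observed_stat, stat_fn, labels, n_perm, seed,
                               extreme = c("greater", "less")) {
  extreme <- match.arg(extreme)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (length(unique(labels)) != 2L)
    stop("labels must contain exactly two classes")
  set.seed(as.integer(seed))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    s <- stat_fn(sample(labels))
    if (extreme == "greater") {
      if (s >= observed_stat) hits <- hits + 1L
    } else if (s <= observed_stat) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

test_result <- function(statistic, p_value, sided, n) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(statistic = statistic, p_value = min(1, p_value),
                 sided = sided, n = n),
            class = "xci_test_result")
}

#' @export
print.xci_test_result <- function(x, ...) {
  cat(sprintf("statistic = %g, n = %d, %s p = %.4g\n",
              x$statistic, x$n, x$sided, x$p_value))
  invisible(x)
}
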