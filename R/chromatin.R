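#' Chromatin-state enrichment between escape and inactive genes
#'
#' For each chromatin state (columns of a genes x states coverage matrix of
#' gene-body fractions, averaged across epigenomes) and each direction,
#' a one-sided Wilcoxon rank-sum test compares per-gene coverage between
#' the escape and inactive gene sets (normal approximation with continuity
#' and tie correction, as in [stats::wilcox.test()] with `exact = FALSE`).
#' Constant columns yield p = 1 with a flag.
#'
#' @param coverage genes x states numeric matrix; fractions in \[0, 1\],
#'   rows summing to at most 1 (plus tolerance).
#' @param labels per-gene labels, `"escape"` / `"inactive"`.
#' @return data.frame `state, direction, statistic, p_value, constant`
#'   (2 rows per state).
#' @export
state_enrichment <- function(coverage, labels) {
  stopifnot(nrow(coverage) == length(labels))
  if (!all(labels %in% c("escape", "inactive")))
    stop("labels must be 'escape' or 'inactive'")
  if (length(unique(labels)) < 2L) stop("both label classes must be non-empty")
  if (any(coverage < 0 | coverage > 1)) stop("coverage fractions must lie in [0, 1]")
  if (any(rowSums(coverage) > 1 + 1e-6)) stop("row coverage exceeds 1")
  r <- rank_sum_tests(coverage, labels == "escape")
  const <- apply(coverage, 2, function(x) length(unique(x)) == 1L)
  out <- data.frame(
    state = rep(colnames(coverage), each = 2),
    direction = rep(c("escape_enriched", "inactive_enriched"),
                    ncol(coverage)),
    statistic = as.vector(rbind(r$w, r$w)),
    p_value = as.vector(rbind(r$p_greater, r$p_less)),
    constant = rep(const, each = 2), stringsAsFactors = FALSE)
  out$p_value[out$constant] <- 1
  out$statistic[out$constant] <- NA_real_
  rownames(out) <- NULL
  out
}

# vectorized one-sided Mann-Whitney tests of escape vs inactive for every
# column: normal approximation with tie correction and continuity
# correction, matching wilcox.test(exact = FALSE, correct = TRUE);
# ranks and tie variances do not depend on the labels, so they can be
# precomputed once and reused across label permutations
rank_precompute <- function(coverage) {
  rk <- apply(coverage, 2, rank)
  n <- nrow(coverage)
  tie_term <- apply(rk, 2, function(r) {
    t <- table(r); sum(t^3 - t) / (n * (n - 1))
  })
  list(rk = rk, n = n, tie_term = tie_term)
}

rank_sum_tests <- function(coverage, esc, pre = NULL) {
  if (is.null(pre)) pre <- rank_precompute(coverage)
  n1 <- sum(esc); n2 <- pre$n - n1
  w <- colSums(pre$rk[esc, , drop = FALSE]) - n1 * (n1 + 1) / 2
  sig <- sqrt(n1 * n2 / 12 * ((pre$n + 1) - pre$tie_term))
  mu <- n1 * n2 / 2
  pg <- ifelse(sig == 0, 1, stats::pnorm((w - mu - 0.5) / sig, lower.tail = FALSE))
  pl <- ifelse(sig == 0, 1, stats::pnorm((w - mu + 0.5) / sig))
  list(w = unname(w), p_greater = pmin(1, pg), p_less = pmin(1, pl))
}

#' Permutation calibration of state enrichment
#'
#' Wraps [state_enrichment()] in a label-permutation scheme: the
#' escape/inactive labels are shuffled (class sizes preserved by
#' construction) and the one-sided Wilcoxon p-value itself is the
#' permutation statistic, smaller being more extreme. The permutation
#' p-value uses the add-one estimator. Bonferroni significance is assessed
#' at `alpha / 30` (15 states x 2 directions) for both the analytic and
#' the permutation p-values, since it is ambiguous which one should carry
#' the correction; both are emitted.
#'
#' @inheritParams state_enrichment
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @param alpha family-wise level before Bonferroni division.
#' @return [state_enrichment()] output plus `perm_p`,
#'   `significant_bonferroni` (analytic) and `perm_significant_bonferroni`.
#' @export
permutation_calibration <- function(coverage, labels, n_perm = 10000, seed = 1L,
                                    alpha = 0.05) {
  obs <- state_enrichment(coverage, labels)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  set.seed(as.integer(seed))
  hits <- numeric(nrow(obs))
  pre <- rank_precompute(coverage)
  for (i in seq_len(n_perm)) {
    perm <- sample(labels) == "escape"
    r <- rank_sum_tests(coverage, perm, pre)
    pp <- as.vector(rbind(r$p_greater, r$p_less))
    hits <- hits + (pp <= obs$p_value)
  }
  n_tests <- nrow(obs)
  obs$perm_p <- (1 + hits) / (1 + n_perm)
  obs$significant_bonferroni <- obs$p_value < alpha / n_tests
  obs$perm_significant_bonferroni <- obs$perm_p < alpha / n_tests
  obs
}

#' Read / write chromatin coverage TSV
#'
#' Genes x states matrix with gene ids in the first column.
#' @param path TSV file.
#' @export
read_state_coverage <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_state_coverage
#' @param coverage matrix to write.
#' @export
write_state_coverage <- function(coverage, path) {
  df <- data.frame(gene_id = rownames(coverage), coverage, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
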