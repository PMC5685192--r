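#' Expression filter rule
#'
#' Genes enter the per-tissue differential-expression analysis only when
#' expressed: median RPKM above `min_median_rpkm` across the tissue's
#' samples (applied when an RPKM matrix is supplied) and more than
#' `min_individuals` samples above `min_cpm` counts per million.
#'
#' @param min_median_rpkm,min_individuals,min_cpm thresholds (>= 0).
#' @export
expression_filter_rule <- function(min_median_rpkm = 0.1, min_individuals = 10,
                                   min_cpm = 1) {
  if (min_median_rpkm < 0 || min_individuals < 0 || min_cpm < 0)
    stop("thresholds must be >= 0")
  list(min_median_rpkm = min_median_rpkm, min_individuals = min_individuals,
       min_cpm = min_cpm)
}

cpm_matrix <- function(counts) sweep(counts, 2, colSums(counts), "/") * 1e6

#' Per-tissue male-female differential expression
#'
#' Pluggable default backend for the sex-bias statistics: per tissue, an
#' ordinary linear model on log2-CPM with sex plus any supplied covariate
#' columns, fitted gene-wise with limma (`lmFit` + `eBayes(trend = TRUE)`).
#' Effect sizes are log2 female-minus-male; q-values are computed within
#' each tissue separately. Externally computed summaries in the same layout
#' can be substituted anywhere downstream.
#'
#' @param counts genes x samples count matrix.
#' @param samples data.frame with `sample`, `sex` ("male"/"female"),
#'   `tissue` and any covariate columns.
#' @param covariates character vector naming covariate columns in
#'   `samples`.
#' @param filter an [expression_filter_rule()].
#' @param rpkm optional genes x samples RPKM matrix for the median-RPKM
#'   filter.
#' @param fdr_method passed to [fdr_qvalues()].
#' @return data.frame `gene_id, tissue, effect_size, effect_direction,
#'   p_value, q_value, expressed`.
#' @export
run_differential_expression <- function(counts, samples, covariates = NULL,
                                        filter = expression_filter_rule(),
                                        rpkm = NULL, fdr_method = "BH") {
  stopifnot(all(samples$sample %in% colnames(counts)))
  out <- NULL
  for (t in unique(samples$tissue)) {
    sm <- samples[samples$tissue == t, , drop = FALSE]
    if (length(unique(sm$sex)) < 2L)
      stop("tissue ", t, " has samples of one sex only")
    if (any(table(sm$sex) < 2L))
      stop("tissue ", t, " needs >= 2 samples per sex")
    x <- counts[, sm$sample, drop = FALSE]
    cpm <- cpm_matrix(x)
    keep <- rowSums(cpm > filter$min_cpm) > filter$min_individuals
    if (!is.null(rpkm))
      keep <- keep & apply(rpkm[, sm$sample, drop = FALSE], 1, stats::median) >
        filter$min_median_rpkm
    if (!any(keep)) next
    logcpm <- log2(cpm[keep, , drop = FALSE] + 0.5)
    sm$sex <- factor(sm$sex, levels = c("male", "female"))
    form <- if (length(covariates))
      stats::as.formula(paste("~ sex +", paste(covariates, collapse = " + ")))
    else ~ sex
    design <- stats::model.matrix(form, data = sm)
    fit <- limma::eBayes(limma::lmFit(logcpm, design), trend = TRUE)
    eff <- fit$coefficients[, "sexfemale"]
    p <- fit$p.value[, "sexfemale"]
    out <- rbind(out, data.frame(
      gene_id = rownames(logcpm), tissue = t, effect_size = unname(eff),
      effect_direction = ifelse(eff > 0, "female_higher", "male_higher"),
      p_value = unname(p),
      q_value = fdr_qvalues(unname(p), method = fdr_method)$q_values,
      expressed = TRUE, stringsAsFactors = FALSE))
  }
  if (is.null(out)) stop("no gene passed the expression filter in any tissue")
  rownames(out) <- NULL
  out
}

#' Proportion of sex-biased genes by XCI category
#'
#' Per tissue and per catalogued XCI status, the fraction of assessed genes
#' with significant (q below threshold) sex bias. Statuses with zero
#' assessed genes in a tissue yield NA (undefined), never 0.
#'
#' @param de differential-expression summary (see
#'   [run_differential_expression()]).
#' @param catalog catalogue data.frame (`gene_id`, `status`).
#' @param q_thresh significance cutoff.
#' @return data.frame `tissue, status, n_assessed, n_significant,
#'   proportion`.
#' @export
proportion_sexbiased_by_category <- function(de, catalog, q_thresh = 0.01) {
  st <- stats::setNames(catalog$status, catalog$gene_id)
  de$status <- unname(st[de$gene_id])
  de <- de[!is.na(de$status) & de$status != "absent", , drop = FALSE]
  grid <- expand.grid(tissue = unique(de$tissue),
                      status = unique(de$status),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$n_assessed <- 0L; grid$n_significant <- 0L
  for (i in seq_len(nrow(grid))) {
    d <- de[de$tissue == grid$tissue[i] & de$status == grid$status[i], ]
    grid$n_assessed[i] <- nrow(d)
    grid$n_significant[i] <- sum(d$q_value < q_thresh)
  }
  grid$proportion <- ifelse(grid$n_assessed > 0,
                            grid$n_significant / grid$n_assessed, NA_real_)
  grid
}

#' Paired comparison of sex-bias proportions between categories
#'
#' Two-sided exact Wilcoxon signed-rank test on the per-tissue differences
#' in sex-biased proportion between two XCI categories (tissues are the
#' pairs). With one category uniformly above the other in all 29 tissues
#' this attains the extreme of the sign-flip null, 2/2^29 = 3.73e-9.
#'
#' @param prop_table output of [proportion_sexbiased_by_category()].
#' @param status_a,status_b categories to compare (a minus b).
#' @return a `TestResult`.
#' @export
paired_category_comparison <- function(prop_table, status_a, status_b) {
  a <- prop_table[prop_table$status == status_a, ]
  b <- prop_table[prop_table$status == status_b, ]
  tiss <- intersect(a$tissue[!is.na(a$proportion)], b$tissue[!is.na(b$proportion)])
  if (length(tiss) < 1L) stop("no tissue with both categories defined")
  d <- a$proportion[match(tiss, a$tissue)] - b$proportion[match(tiss, b$tissue)]
  wilcoxon_signed_rank_exact(d, sided = "two_sided")
}

# one direction per gene: majority over significant tissues, falling back
# to majority over expressed tissues; exact ties give NA
gene_directions <- function(de, q_thresh = 0.01) {
  vapply(split(de, de$gene_id), function(d) {
    sig <- d[d$q_value < q_thresh, , drop = FALSE]
    use <- if (nrow(sig)) sig else d
    nf <- sum(use$effect_direction == "female_higher")
    nm <- nrow(use) - nf
    if (nf > nm) "female_higher" else if (nm > nf) "male_higher" else NA_character_
  }, character(1))
}

#' Direction-bias binomial test
#'
#' Reduces each gene in `gene_subset` to a single sex-bias direction
#' (majority over its significant tissues, falling back to all expressed
#' tissues; exact ties are excluded) and tests the count of female-higher
#' genes against 0.5 with the exact two-sided binomial test. 52
#' female-biased of 67 genes gives p = 6.46e-6.
#'
#' @param de differential-expression summary.
#' @param gene_subset genes to assess (e.g. nonPAR escape genes).
#' @param q_thresh significance cutoff for the per-tissue reduction.
#' @return a `TestResult` plus attribute `n_female_higher`.
#' @export
direction_bias_test <- function(de, gene_subset, q_thresh = 0.01) {
  d <- de[de$gene_id %in% gene_subset, , drop = FALSE]
  if (nrow(d) == 0L) stop("no assessed genes in subset")
  dir <- gene_directions(d, q_thresh)
  dir <- dir[!is.na(dir)]
  k <- sum(dir == "female_higher")
  res <- binom_test_exact(k, length(dir), 0.5, "two_sided")
  attr(res, "n_female_higher") <- k
  res
}

#' Per-gene direction concordance across tissues
#'
#' For genes expressed in at least `min_tissues` tissues: the fraction of
#' expressed tissues whose sex-bias direction matches the gene's majority
#' direction; an exact tie scores 0.5.
#'
#' @param de differential-expression summary.
#' @param min_tissues minimum expressed tissues; genes below are omitted.
#' @return data.frame `gene_id, n_tissues, concordance`.
#' @export
direction_consistency <- function(de, min_tissues = 5) {
  res <- lapply(split(de, de$gene_id), function(d) {
    if (nrow(d) < min_tissues) return(NULL)
    nf <- sum(d$effect_direction == "female_higher")
    nm <- nrow(d) - nf
    data.frame(gene_id = d$gene_id[1], n_tissues = nrow(d),
               concordance = if (nf == nm) 0.5 else max(nf, nm) / nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Flag escape-like genes outside the escape catalogue
#'
#' Genes not catalogued as escape whose sex-bias behaviour looks like
#' escape: direction concordance above `concordance_thresh` across
#' expressed tissues and significant sex bias (q below threshold) in at
#' least one tissue.
#'
#' @param de differential-expression summary.
#' @param catalog catalogue data.frame; genes missing from it count as
#'   status "absent" and are eligible for flagging.
#' @param concordance_thresh concordance cutoff (exclusive).
#' @param q_thresh significance cutoff.
#' @param min_tissues concordance support requirement.
#' @return data.frame `gene_id, status, concordance, n_significant,
#'   flagged`.
#' @export
flag_escape_like <- function(de, catalog, concordance_thresh = 0.9,
                             q_thresh = 0.01, min_tissues = 5) {
  st <- stats::setNames(catalog$status, catalog$gene_id)
  conc <- direction_consistency(de, min_tissues)
  if (is.null(conc)) return(NULL)
  nsig <- tapply(de$q_value < q_thresh, de$gene_id, sum)
  conc$status <- unname(st[conc$gene_id])
  conc$status[is.na(conc$status)] <- "absent"
  conc$n_significant <- as.integer(nsig[conc$gene_id])
  conc$flagged <- conc$status != "escape" &
    conc$concordance > concordance_thresh & conc$n_significant >= 1L
  conc
}

#' Re-test sex bias with combined X+Y homolog expression
#'
#' For X-Y homologous gene pairs, replaces the X gene's expression with the
#' sum of the X and Y homolog counts and re-runs the differential
#' expression fit, asking whether apparent female bias at the X member
#' persists once the male-specific Y output is accounted for. Y expression
#' is zero in females, so with a silent Y homolog the result reduces to the
#' X-only test.
#'
#' @param counts genes x samples count matrix containing both pair members.
#' @param samples sample sheet as in [run_differential_expression()].
#' @param pair_map data.frame `x_gene, y_gene` (the retained homolog
#'   pairs).
#' @param ... passed to [run_differential_expression()].
#' @return differential-expression summary restricted to the X members
#'   (computed on combined X+Y counts).
#' @export
xy_combined_retest <- function(counts, samples, pair_map, ...) {
  miss <- setdiff(c(pair_map$x_gene, pair_map$y_gene), rownames(counts))
  if (length(miss))
    stop("unmatched pair member(s): ", paste(miss, collapse = ", "))
  combined <- counts
  combined[pair_map$x_gene, ] <- counts[pair_map$x_gene, , drop = FALSE] +
    counts[pair_map$y_gene, , drop = FALSE]
  combined <- combined[setdiff(rownames(combined), pair_map$y_gene), , drop = FALSE]
  de <- run_differential_expression(combined, samples, ...)
  de[de$gene_id %in% pair_map$x_gene, , drop = FALSE]
}
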