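#' Calling configuration for ASE-based XCI inference
#'
#' `p0 = 0.025` is the empirical upper bound on the allele-miscall rate
#' (derived from the proportion of wrong-allele calls at XIST in fully
#' skewed samples): Xi expression is declared only when the Xi read
#' fraction is significantly greater than this bound. `q_thresh` is the FDR
#' cutoff applied within each tissue (or sample) separately.
#'
#' @param p0 null Xi-read probability (error bound), in (0, 0.5).
#' @param q_thresh FDR significance cutoff.
#' @param min_tissue_coverage site-selection coverage rule: a tissue counts
#'   for a site when its total reads exceed `min_tissue_coverage - 1`
#'   (i.e. > 7 reads at the default of 8).
#' @param heterogeneity_ratio H: an incompletely inactivated gene is
#'   "shared" when max/min significant Xi fraction <= H, else heterogeneous.
#' @param power_target,detect_fraction a tissue is "powered" when its
#'   coverage yields at least `power_target` power to detect an Xi fraction
#'   of `detect_fraction` at nominal level `q_thresh`.
#' @export
calling_config <- function(p0 = 0.025, q_thresh = 0.01, min_tissue_coverage = 8,
                           heterogeneity_ratio = 3, power_target = 0.8,
                           detect_fraction = 0.10) {
  if (p0 <= 0 || p0 >= 0.5) stop("p0 must lie in (0, 0.5)")
  if (q_thresh <= 0 || q_thresh >= 1) stop("q_thresh must lie in (0, 1)")
  list(p0 = p0, q_thresh = q_thresh, min_tissue_coverage = min_tissue_coverage,
       heterogeneity_ratio = heterogeneity_ratio, power_target = power_target,
       detect_fraction = detect_fraction)
}

#' Select one ASE site per gene
#'
#' Keeps, for each gene, the single site covered by more than
#' `min_tissue_coverage - 1` reads in the largest number of tissues, so
#' every gene is represented once downstream. Ties break to the smallest
#' genomic position, making the choice invariant to row order. Genes whose
#' sites never reach the coverage rule keep their best site (tissue count
#' 0 ties resolved by position); genes with no sites at all are omitted.
#'
#' @param table an [allele_count_table()] carrying a `gene_id` column (see
#'   [map_sites_to_genes()]).
#' @param config a [calling_config()].
#' @return data.frame `gene_id, site_id, n_tissues_covered`.
#' @export
select_site_per_gene <- function(table, config = calling_config()) {
  if (is.null(table$gene_id)) stop("table must carry gene_id; run map_sites_to_genes()")
  tab <- table[!is.na(table$gene_id), , drop = FALSE]
  dropped <- setdiff(unique(table$gene_id), tab$gene_id)
  if (length(dropped)) message(length(dropped), " gene(s) without sites omitted")
  cov <- tab$ref_count + tab$alt_count > config$min_tissue_coverage - 1
  agg <- stats::aggregate(cov, by = list(gene_id = tab$gene_id,
                                         site_id = tab$site_id,
                                         position = tab$position), FUN = sum)
  names(agg)[4] <- "n_tissues_covered"
  agg <- agg[order(agg$gene_id, -agg$n_tissues_covered, agg$position), ]
  sel <- agg[!duplicated(agg$gene_id), c("gene_id", "site_id", "n_tissues_covered")]
  rownames(sel) <- NULL
  sel
}

#' Assign the Xi allele at a site
#'
#' In a fully skewed donor the inactive-X allele is the one with the lower
#' combined relative expression across tissues (mean per-tissue allele
#' fraction, so deep tissues do not dominate). At XIST — expressed from Xi
#' only — the orientation is inverted: the higher-expressed allele is Xi.
#' Exactly balanced pooled expression is unresolvable and the site is
#' flagged for exclusion.
#'
#' @param site_rows rows of one site across tissues (ref_count, alt_count).
#' @param is_xist TRUE for the XIST gene.
#' @return list `xi_allele` ("ref", "alt", or NA), `mean_ref_fraction`.
#' @export
assign_xi_allele <- function(site_rows, is_xist = FALSE) {
  tot <- site_rows$ref_count + site_rows$alt_count
  use <- tot > 0
  if (!any(use)) stop("no reads at site across tissues")
  fr <- mean(site_rows$ref_count[use] / tot[use])
  xi <- if (fr == 0.5) NA_character_ else if (fr < 0.5) "ref" else "alt"
  if (is_xist && !is.na(xi)) xi <- if (xi == "ref") "alt" else "ref"
  list(xi_allele = xi, mean_ref_fraction = fr)
}

#' Per-tissue Xi-expression test
#'
#' One-sided exact binomial test per (gene, tissue): is the Xi read
#' fraction significantly greater than the error bound `p0`? FDR correction
#' is applied within each tissue separately; observations with
#' `q < q_thresh` indicate incomplete XCI at that site and tissue.
#' Zero-coverage observations are skipped.
#'
#' @param ase data.frame `gene_id, tissue, xi_count, xa_count`.
#' @param config a [calling_config()].
#' @param fdr_method passed to [fdr_qvalues()].
#' @return input with `total, xi_fraction, p, q, significant` columns.
#' @export
call_xi_per_tissue <- function(ase, config = calling_config(), fdr_method = "BH") {
  ase$total <- ase$xi_count + ase$xa_count
  ase <- ase[ase$total > 0, , drop = FALSE]
  ase$xi_fraction <- ase$xi_count / ase$total
  ase$p <- stats::pbinom(ase$xi_count - 1, ase$total, config$p0, lower.tail = FALSE)
  ase$q <- NA_real_
  for (t in unique(ase$tissue)) {
    i <- ase$tissue == t
    ase$q[i] <- fdr_qvalues(ase$p[i], method = fdr_method)$q_values
  }
  ase$significant <- ase$q < config$q_thresh
  rownames(ase) <- NULL
  ase
}

# smallest significant Xi count at nominal level alpha, and the power to
# detect Xi fraction f at coverage n
binom_power <- function(n, p0, alpha, f) {
  k_crit <- stats::qbinom(alpha, n, p0, lower.tail = FALSE) + 1
  stats::pbinom(k_crit - 1, n, f, lower.tail = FALSE)
}

#' Cross-tissue XCI classification
#'
#' Reduces one gene's per-tissue calls to an XCI status:
#' `full` — no tissue significant; `incomplete_single_context` — exactly
#' one significant tissue among at least two powered tissues (escape
#' restricted to one tissue, and the other tissues had the coverage to see
#' it); `incomplete_shared` — two or more significant tissues whose Xi
#' fractions differ by at most the heterogeneity ratio H (max/min <= H);
#' `incomplete_heterogeneous` — otherwise. A tissue is "powered" when its
#' coverage gives at least 80% power to detect an Xi fraction of 0.10 at
#' the nominal q threshold. With one significant tissue but fewer than two
#' powered tissues the single-context claim is not falsifiable and the gene
#' falls back to `incomplete_shared`.
#'
#' @param gene_calls one gene's rows from [call_xi_per_tissue()].
#' @param config a [calling_config()].
#' @return list `status`, `n_significant`, `n_powered`.
#' @export
classify_xci <- function(gene_calls, config = calling_config()) {
  if (nrow(gene_calls) < 1L) stop("need at least one tissue observation")
  sig <- gene_calls$significant
  n_sig <- sum(sig)
  powered <- binom_power(gene_calls$total, config$p0, config$q_thresh,
                         config$detect_fraction) >= config$power_target
  status <- if (n_sig == 0L) {
    "full"
  } else if (n_sig == 1L && sum(powered) >= 2L) {
    "incomplete_single_context"
  } else {
    fr <- gene_calls$xi_fraction[sig]
    fr <- fr[fr > 0]
    if (length(fr) >= 2L && max(fr) / min(fr) > config$heterogeneity_ratio)
      "incomplete_heterogeneous" else "incomplete_shared"
  }
  list(status = status, n_significant = n_sig, n_powered = sum(powered))
}

#' Multi-tissue XCI calling for a skewed donor
#'
#' End-to-end driver: map sites to genes, keep one site per gene, orient
#' alleles to Xa/Xi (pooled minor allele = Xi; inverted at XIST), test Xi
#' expression per tissue, and classify each gene across tissues. Genes with
#' unresolvable allele orientation (exactly balanced pooled expression) are
#' excluded and listed.
#'
#' @param counts an [allele_count_table()] over tissues.
#' @param genes a [gene_model_table()].
#' @param config a [calling_config()].
#' @param xist_gene_id gene treated with inverted Xi orientation.
#' @param fdr_method passed to [fdr_qvalues()].
#' @return list: `calls` (per-gene status with Jeffreys CI on the pooled Xi
#'   fraction), `per_tissue` (gene x tissue tests), `excluded`.
#' @export
donor_call_xci <- function(counts, genes, config = calling_config(),
                           xist_gene_id = "XIST", fdr_method = "BH") {
  tab <- map_sites_to_genes(counts, genes)
  sel <- select_site_per_gene(tab, config)
  tab <- tab[paste(tab$gene_id, tab$site_id) %in%
               paste(sel$gene_id, sel$site_id), , drop = FALSE]
  excluded <- character(0)
  ase <- NULL
  for (g in unique(tab$gene_id)) {
    rows <- tab[tab$gene_id == g, , drop = FALSE]
    ori <- assign_xi_allele(rows, is_xist = identical(g, xist_gene_id))
    if (is.na(ori$xi_allele)) { excluded <- c(excluded, g); next }
    xi <- if (ori$xi_allele == "ref") rows$ref_count else rows$alt_count
    ase <- rbind(ase, data.frame(gene_id = g, tissue = rows$unit_id,
                                 site_id = rows$site_id,
                                 xi_count = xi,
                                 xa_count = rows$ref_count + rows$alt_count - xi,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(ase)) stop("no usable genes")
  per_tissue <- call_xi_per_tissue(ase, config, fdr_method)
  calls <- do.call(rbind, lapply(split(per_tissue, per_tissue$gene_id), function(gc) {
    cl <- classify_xci(gc, config)
    k <- sum(gc$xi_count); n <- sum(gc$xi_count + gc$xa_count)
    ci <- jeffreys_interval(k, n)
    data.frame(gene_id = gc$gene_id[1], status = cl$status,
               n_tissues = nrow(gc), n_significant = cl$n_significant,
               n_powered = cl$n_powered,
               pooled_xi_fraction = k / n, ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
               stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  list(calls = calls, per_tissue = per_tissue, excluded = excluded)
}

#' Estimate XCI skew from bulk ASE
#'
#' Screens a donor for skewed XCI using sites in genes catalogued as
#' inactive (nonPAR): in a skewed individual such sites are close to
#' monoallelic in bulk tissue. The estimator is the read-weighted mean
#' major-allele fraction across informative sites, folded to \[0.5, 1\]
#' (parental labels are unknown without phasing). 1.0 means fully skewed;
#' 0.5 means balanced (random) XCI.
#'
#' @param counts an [allele_count_table()].
#' @param genes a [gene_model_table()].
#' @param catalog catalogue data.frame (`gene_id`, `status`); only genes
#'   with status `inactive` inform the estimate.
#' @param min_sites minimum informative site-tissue observations per
#'   tissue; below it the tissue's estimate is NA with a reason.
#' @param min_reads minimum reads per observation.
#' @return list: `per_tissue` (tissue, skew, n_sites), `donor` (pooled
#'   estimate), `reason` (NULL or why undefined).
#' @export
estimate_skew <- function(counts, genes, catalog, min_sites = 5, min_reads = 10) {
  inact <- catalog$gene_id[catalog$status == "inactive"]
  tab <- map_sites_to_genes(counts, genes)
  keep_genes <- genes$gene_id[genes$region_class %in% c("nonPAR_Xp", "nonPAR_Xq")]
  tab <- tab[!is.na(tab$gene_id) & tab$gene_id %in% intersect(inact, keep_genes), ,
             drop = FALSE]
  tab$total <- tab$ref_count + tab$alt_count
  tab <- tab[tab$total >= min_reads, , drop = FALSE]
  if (nrow(tab) == 0L)
    return(list(per_tissue = NULL, donor = NA_real_,
                reason = "no informative inactive-gene sites"))
  tab$major_frac <- pmax(tab$ref_count, tab$alt_count) / tab$total
  per_tissue <- do.call(rbind, lapply(split(tab, tab$unit_id), function(d) {
    data.frame(tissue = d$unit_id[1],
               skew = if (nrow(d) >= min_sites)
                 stats::weighted.mean(d$major_frac, d$total) else NA_real_,
               n_sites = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(per_tissue) <- NULL
  donor <- stats::weighted.mean(tab$major_frac, tab$total)
  reason <- if (nrow(tab) < min_sites) "fewer informative sites than min_sites" else NULL
  if (!is.null(reason)) donor <- NA_real_
  list(per_tissue = per_tissue, donor = donor, reason = reason)
}
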