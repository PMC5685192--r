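#' Single-cell calling configuration
#'
#' Thresholds for the single-cell XCI workflow. Defaults follow the
#' empirically motivated values used throughout the package: sites are
#' assessed in a cell only at >= 8 reads; a cell-site is biallelic when the
#' minor-allele fraction exceeds 0.05 and is nominally (p < 0.05,
#' one-sided) above the 2.5% miscall bound; a gene needs >= 5 contributing
#' cells and >= 2 biallelic cell observations to be claimed biallelic;
#' gene-level escape requires q < 0.01 against p0 = 0.025.
#'
#' @param min_reads_per_site minimum reads for a cell-site observation.
#' @param biallelic_ae_thresh minor-allele fraction floor for biallelic
#'   flags.
#' @param p0 miscall error bound (null Xi-read probability).
#' @param min_cells_per_gene cells required for a gene to be assayed.
#' @param min_biallelic_cells biallelic observations required for a
#'   gene-level biallelic flag.
#' @param q_thresh FDR cutoff for escape calls.
#' @param frequently_biallelic_cell_fraction sites biallelic in more than
#'   this fraction of their covered cells are excluded from phasing.
#' @param nominal_alpha nominal level for the per-cell biallelic test.
#' @param min_agreement cells with lower haplotype-agreement score after
#'   partition refinement are demoted to uninformative (doublet guard).
#' @export
sc_calling_config <- function(min_reads_per_site = 8, biallelic_ae_thresh = 0.05,
                              p0 = 0.025, min_cells_per_gene = 5,
                              min_biallelic_cells = 2, q_thresh = 0.01,
                              frequently_biallelic_cell_fraction = 0.10,
                              nominal_alpha = 0.05, min_agreement = 0.8) {
  stopifnot(min_reads_per_site > 0, min_cells_per_gene > 0,
            p0 > 0, p0 < 0.5, q_thresh > 0, q_thresh < 1)
  as.list(environment())
}

#' Detect biallelic expression in single cells
#'
#' Flags each (cell, site) observation with at least `min_reads_per_site`
#' reads as biallelic when (1) the minor-allele fraction exceeds
#' `biallelic_ae_thresh` and (2) a one-sided binomial test shows it
#' nominally significantly greater than the error bound `p0`. A gene is
#' flagged biallelic when at least `min_biallelic_cells` of its cell
#' observations are biallelic.
#'
#' @param counts an [allele_count_table()], optionally with `gene_id`.
#' @param config an [sc_calling_config()].
#' @return list: `cell_site` (assessed observations with `biallelic`
#'   flag), `gene` (per-gene biallelic flag; NULL without gene_id).
#' @export
detect_biallelic_cells <- function(counts, config = sc_calling_config()) {
  tot <- counts$ref_count + counts$alt_count
  d <- counts[tot >= config$min_reads_per_site, , drop = FALSE]
  tot <- d$ref_count + d$alt_count
  minor <- pmin(d$ref_count, d$alt_count)
  d$minor_fraction <- minor / tot
  d$p_biallelic <- stats::pbinom(minor - 1, tot, config$p0, lower.tail = FALSE)
  d$biallelic <- d$minor_fraction > config$biallelic_ae_thresh &
    d$p_biallelic < config$nominal_alpha
  gene <- NULL
  if (!is.null(d$gene_id)) {
    n_bi <- tapply(d$biallelic, d$gene_id, sum)
    gene <- data.frame(gene_id = names(n_bi),
                       n_biallelic_cells = as.integer(n_bi),
                       biallelic = as.integer(n_bi) >= config$min_biallelic_cells,
                       stringsAsFactors = FALSE, row.names = NULL)
  }
  rownames(d) <- NULL
  list(cell_site = d, gene = gene)
}

#' Sites excluded from phase inference
#'
#' Escape genes blur the monoallelic pattern the phasing relies on, so all
#' PAR1 sites plus any site that is biallelic in more than
#' `frequently_biallelic_cell_fraction` of its covered cells are excluded
#' from phasing (they are still aggregated and called afterwards).
#'
#' @param counts an [allele_count_table()].
#' @param genes a [gene_model_table()] used to find PAR1 sites.
#' @param config an [sc_calling_config()].
#' @return character vector of excluded `site_id`s.
#' @export
identify_frequently_biallelic_sites <- function(counts, genes,
                                                config = sc_calling_config()) {
  bi <- detect_biallelic_cells(counts, config)$cell_site
  frac <- tapply(bi$biallelic, bi$site_id, mean)
  freq <- names(frac)[frac > config$frequently_biallelic_cell_fraction]
  tab <- map_sites_to_genes(unique(counts[c("site_id", "chrom", "position",
                                            "ref_allele", "alt_allele")]),
                            genes[genes$region_class == "PAR1", , drop = FALSE])
  par1 <- tab$site_id[!is.na(tab$gene_id)]
  union(freq, par1)
}

# cells x sites majority-allele matrix: +1 ref-major, -1 alt-major, 0 no
# reads or tie; weighted = ref minus alt read counts instead of signs
majority_matrix <- function(counts, exclusions = character(0), weighted = FALSE) {
  d <- counts[!(counts$site_id %in% exclusions), , drop = FALSE]
  cells <- sort(unique(d$unit_id)); sites <- sort(unique(d$site_id))
  m <- matrix(0, length(cells), length(sites), dimnames = list(cells, sites))
  v <- d$ref_count - d$alt_count
  if (!weighted) v <- sign(v)
  m[cbind(match(d$unit_id, cells), match(d$site_id, sites))] <- v
  m
}

#' Assign cells to parental populations using trio phase
#'
#' With parental genotypes the maternal/paternal origin of every allele is
#' known, so each cell is assigned to the parental cell population whose
#' haplotype matches the majority of the expressed alleles at non-excluded
#' sites (each site votes by its within-cell majority allele). `P1` is the
#' population with haplotype a (maternal) active. Cells with no informative
#' sites, or with exactly tied support, are `uninformative`.
#'
#' @param counts an [allele_count_table()].
#' @param phased phased genotypes (see [read_phased_vcf()]).
#' @param exclusions site_ids excluded from assignment (PAR1 and frequently
#'   biallelic sites).
#' @return data.frame `cell_id, population, n_supporting_sites,
#'   agreement_score`.
#' @export
assign_cells_with_parental_phase <- function(counts, phased,
                                             exclusions = character(0)) {
  m <- majority_matrix(counts, exclusions)
  keep <- intersect(colnames(m), phased$site_id)
  m <- m[, keep, drop = FALSE]
  ph <- phased[match(keep, phased$site_id), ]
  s <- ifelse(ph$hap_a == ph$ref_allele, 1L, -1L)  # +1: ref on maternal hap
  score_mat <- sweep(m, 2, s, `*`)                 # +1 vote = maternal-active
  add_missing_cells(assignments_from_scores(score_mat), counts)
}

# cells whose every observation sits at an excluded or unphased site never
# enter the score matrix; report them as uninformative rather than dropping
add_missing_cells <- function(asn, counts) {
  missing <- setdiff(unique(counts$unit_id), asn$cell_id)
  if (length(missing))
    asn <- rbind(asn, data.frame(cell_id = missing, population = "uninformative",
                                 n_supporting_sites = 0L,
                                 agreement_score = NA_real_))
  rownames(asn) <- NULL
  asn
}

assignments_from_scores <- function(score_mat) {
  votes_for <- rowSums(score_mat > 0)
  votes_against <- rowSums(score_mat < 0)
  pop <- ifelse(votes_for + votes_against == 0, "uninformative",
                ifelse(votes_for > votes_against, "P1",
                       ifelse(votes_against > votes_for, "P2", "uninformative")))
  win <- pmax(votes_for, votes_against)
  agr <- ifelse(votes_for + votes_against > 0,
                win / (votes_for + votes_against), NA_real_)
  data.frame(cell_id = rownames(score_mat), population = pop,
             n_supporting_sites = as.integer(win), agreement_score = agr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Reference-free inference of the two X-active cell populations
#'
#' Without parental genotypes the two populations and the site haplotypes
#' are inferred jointly from the monoallelic expression structure: cells
#' with the same X active express the same allele at fully inactivated
#' sites. The algorithm builds a cell-cell agreement matrix (matches minus
#' mismatches of within-cell majority alleles over shared non-excluded
#' sites), splits cells by the sign of the leading eigenvector of the
#' centered matrix, then iteratively refines: re-estimate each site's
#' population-1 allele by weighted majority, re-assign each cell to the
#' population its expressed alleles agree with, until a fixpoint. The
#' partition is identifiable only up to a global label swap. Cells whose
#' agreement score stays below `min_agreement` are demoted to
#' uninformative.
#'
#' @param counts an [allele_count_table()].
#' @param exclusions site_ids excluded from phasing.
#' @param seed RNG seed (used only to break exact ties deterministically).
#' @param config an [sc_calling_config()].
#' @param max_iter refinement iteration cap.
#' @return list: `assignments` (as in
#'   [assign_cells_with_parental_phase()]), `phase` (site_id, `p1_allele`:
#'   the base expressed by population-1 cells at inactivated sites, i.e.
#'   the allele on P1's active haplotype).
#' @export
infer_partition_unphased <- function(counts, exclusions = character(0), seed = 1L,
                                     config = sc_calling_config(), max_iter = 100L) {
  set.seed(as.integer(seed))
  m <- majority_matrix(counts, exclusions)
  if (ncol(m) == 0L || nrow(m) < 2L) stop("too few cells or sites to partition")
  w <- majority_matrix(counts, exclusions, weighted = TRUE)
  a <- m %*% t(m)
  diag(a) <- 0
  if (all(a == 0)) stop("no overlapping sites between any two cells: unconnectable")
  ev <- eigen(a - mean(a), symmetric = TRUE)$vectors[, 1]
  ev[ev == 0] <- sample(c(-1, 1), sum(ev == 0), replace = TRUE)
  g <- ifelse(ev > 0, 1, -1)  # +1 ~ population 1
  for (it in seq_len(max_iter)) {
    # site orientation from read-weighted sums: unbiased toward the active
    # haplotype even at partially escaping sites (Xi fraction < 0.5)
    s <- sign(colSums(w * g))
    s[s == 0] <- 1                        # arbitrary, revisited next pass
    score <- m %*% s
    g_new <- ifelse(score > 0, 1, ifelse(score < 0, -1, g))
    if (all(g_new == g)) break
    g <- g_new
  }
  score_mat <- sweep(m, 2, as.vector(s), `*`)
  asn <- assignments_from_scores(score_mat)
  low <- !is.na(asn$agreement_score) & asn$agreement_score < config$min_agreement
  asn$population[low] <- "uninformative"
  asn <- add_missing_cells(asn, counts)
  # extend the phase to every site (including those excluded from the
  # inference) from read-weighted population sums of the assigned cells
  w_all <- majority_matrix(counts, weighted = TRUE)
  g_all <- stats::setNames(ifelse(asn$population == "P1", 1,
                                  ifelse(asn$population == "P2", -1, 0)),
                           asn$cell_id)[rownames(w_all)]
  g_all[is.na(g_all)] <- 0
  s_all <- sign(colSums(w_all * g_all))
  s_all[s_all == 0] <- 1
  sites <- colnames(w_all)
  d <- counts[match(sites, counts$site_id), ]
  phase <- data.frame(site_id = sites,
                      p1_allele = ifelse(s_all > 0, d$ref_allele, d$alt_allele),
                      stringsAsFactors = FALSE, row.names = NULL)
  list(assignments = asn, phase = phase)
}

#' Aggregate allelic counts to Xa/Xi per gene
#'
#' For each informative cell the allele on that cell's active haplotype
#' contributes to the Xa count and the other allele to Xi; counts are then
#' summed across cells per site and per gene. The phase gives each site's
#' population-1 active allele (from trio phase: the maternal allele;
#' from inference: `p1_allele`). At the XIST gene — expressed from Xi in
#' every cell, hence anti-correlated with the pattern the phase was learned
#' from — the orientation is anchored so that its dominant allele maps to
#' Xi. Genes with zero aggregate reads are omitted.
#'
#' @param counts an [allele_count_table()] with `gene_id` (see
#'   [map_sites_to_genes()]).
#' @param assignments cell assignment data.frame.
#' @param phase data.frame `site_id, p1_allele`.
#' @param xist_gene_id gene anchored to Xi orientation.
#' @return data.frame `gene_id, xa_count, xi_count, n_cells,
#'   xist_flipped`.
#' @export
aggregate_xa_xi <- function(counts, assignments, phase, xist_gene_id = "XIST") {
  if (is.null(counts$gene_id)) stop("counts must carry gene_id")
  pop <- stats::setNames(assignments$population, assignments$cell_id)
  d <- counts[!is.na(counts$gene_id) & pop[counts$unit_id] %in% c("P1", "P2"), ,
              drop = FALSE]
  d <- d[d$site_id %in% phase$site_id, , drop = FALSE]
  if (nrow(d) == 0L) stop("no informative observations to aggregate")
  p1 <- stats::setNames(phase$p1_allele, phase$site_id)
  ref_active_p1 <- p1[d$site_id] == d$ref_allele
  cell_p1 <- pop[d$unit_id] == "P1"
  ref_is_active <- ref_active_p1 == cell_p1  # active allele in *this* cell
  d$xa <- ifelse(ref_is_active, d$ref_count, d$alt_count)
  d$xi <- ifelse(ref_is_active, d$alt_count, d$ref_count)
  agg <- do.call(rbind, lapply(split(d, d$gene_id), function(x) {
    data.frame(gene_id = x$gene_id[1], xa_count = sum(x$xa), xi_count = sum(x$xi),
               n_cells = length(unique(x$unit_id)), xist_flipped = FALSE,
               stringsAsFactors = FALSE)
  }))
  agg <- agg[agg$xa_count + agg$xi_count > 0, , drop = FALSE]
  ix <- which(agg$gene_id == xist_gene_id)
  if (length(ix) == 1L && agg$xa_count[ix] > agg$xi_count[ix]) {
    tmp <- agg$xa_count[ix]
    agg$xa_count[ix] <- agg$xi_count[ix]; agg$xi_count[ix] <- tmp
    agg$xist_flipped[ix] <- TRUE
  }
  rownames(agg) <- NULL
  agg
}

#' Call XCI status from aggregated single-cell counts
#'
#' Genes with fewer than `min_cells_per_gene` contributing cells or fewer
#' than `min_reads_per_site` aggregate reads are reported `not_assayed`
#' (distinct from inactive). For the rest, Xi expression is tested with a
#' one-sided binomial against the error bound `p0`; q-values are computed
#' within the sample, and `escape` is called at `q < q_thresh`.
#'
#' @param agg output of [aggregate_xa_xi()].
#' @param config an [sc_calling_config()].
#' @param fdr_method passed to [fdr_qvalues()].
#' @return input plus `total, xi_fraction, p, q, status`.
#' @export
call_xci_from_cells <- function(agg, config = sc_calling_config(),
                                fdr_method = "BH") {
  agg$total <- agg$xa_count + agg$xi_count
  agg$xi_fraction <- ifelse(agg$total > 0, agg$xi_count / agg$total, NA_real_)
  assay <- agg$n_cells >= config$min_cells_per_gene &
    agg$total >= config$min_reads_per_site
  agg$p <- NA_real_; agg$q <- NA_real_
  agg$p[assay] <- stats::pbinom(agg$xi_count[assay] - 1, agg$total[assay],
                                config$p0, lower.tail = FALSE)
  if (any(assay))
    agg$q[assay] <- fdr_qvalues(agg$p[assay], method = fdr_method)$q_values
  agg$status <- ifelse(!assay, "not_assayed",
                       ifelse(agg$q < config$q_thresh, "escape", "inactive"))
  rownames(agg) <- NULL
  agg
}

#' Xi/Xa expression ratio with Jeffreys CI
#'
#' The Xi-to-Xa ratio r = xi / xa, with a confidence interval obtained by
#' transforming the Jeffreys interval on the Xi fraction f = xi/(xi+xa)
#' through r = f / (1 - f). With `xa = 0` (the XIST pattern) the ratio is
#' reported as `Inf` with `inverted_orientation = TRUE`.
#'
#' @param xi_count,xa_count aggregate read counts.
#' @param level CI coverage.
#' @return list `ratio, ci_lo, ci_hi, inverted_orientation`.
#' @export
xi_xa_ratio <- function(xi_count, xa_count, level = 0.95) {
  n <- xi_count + xa_count
  if (n < 1) stop("no reads")
  if (xa_count == 0)
    return(list(ratio = Inf, ci_lo = NA_real_, ci_hi = NA_real_,
                inverted_orientation = TRUE))
  ci <- jeffreys_interval(xi_count, n, level)
  list(ratio = xi_count / xa_count,
       ci_lo = ci[["lo"]] / (1 - ci[["lo"]]),
       ci_hi = if (ci[["hi"]] < 1) ci[["hi"]] / (1 - ci[["hi"]]) else Inf,
       inverted_orientation = FALSE)
}

#' Percent split of cells between the two populations
#'
#' @param n_pop1,n_pop2 informative cell counts.
#' @return integer vector of rounded percents, e.g. `c(54, 46)`.
#' @export
skew_from_cell_counts <- function(n_pop1, n_pop2) {
  n <- n_pop1 + n_pop2
  if (n < 1) stop("no informative cells")
  c(round(100 * n_pop1 / n), round(100 * n_pop2 / n))
}

#' Single-cell XCI calling pipeline
#'
#' Runs the whole workflow for one sample: biallelic detection, exclusion
#' of PAR1 / frequently biallelic sites, cell assignment (trio-phased when
#' `phased` carries parental origin, otherwise reference-free inference),
#' Xa/Xi aggregation, and gene-level calling.
#'
#' @param counts an [allele_count_table()] of cells x sites.
#' @param genes a [gene_model_table()].
#' @param phased optional trio-phased genotypes; `NULL` triggers
#'   reference-free partition inference.
#' @param config an [sc_calling_config()].
#' @param seed RNG seed for the partition inference.
#' @param xist_gene_id Xi-anchor gene.
#' @return list: `calls`, `aggregate`, `assignments`, `phase`,
#'   `excluded_sites`, `biallelic`, `skew_split`.
#' @export
sc_call_xci <- function(counts, genes, phased = NULL,
                        config = sc_calling_config(), seed = 1L,
                        xist_gene_id = "XIST") {
  tab <- map_sites_to_genes(counts, genes)
  bi <- detect_biallelic_cells(tab, config)
  excl <- identify_frequently_biallelic_sites(counts, genes, config)
  if (is.null(phased)) {
    inf <- infer_partition_unphased(counts, excl, seed = seed, config = config)
    asn <- inf$assignments; phase <- inf$phase
    # XIST expresses the inactive haplotype, so its inferred "expressed
    # allele" is anti-oriented: anchor its site phase by flipping
    xs <- unique(tab$site_id[!is.na(tab$gene_id) & tab$gene_id == xist_gene_id])
    flip <- phase$site_id %in% xs
    if (any(flip)) {
      al <- counts[match(phase$site_id[flip], counts$site_id), ]
      phase$p1_allele[flip] <- ifelse(phase$p1_allele[flip] == al$ref_allele,
                                      al$alt_allele, al$ref_allele)
    }
  } else {
    asn <- assign_cells_with_parental_phase(counts, phased, excl)
    phase <- data.frame(site_id = phased$site_id, p1_allele = phased$hap_a,
                        stringsAsFactors = FALSE)
  }
  agg <- aggregate_xa_xi(tab, asn, phase, xist_gene_id)
  calls <- call_xci_from_cells(agg, config)
  n1 <- sum(asn$population == "P1"); n2 <- sum(asn$population == "P2")
  list(calls = calls, aggregate = agg, assignments = asn, phase = phase,
       excluded_sites = excl, biallelic = bi,
       skew_split = skew_from_cell_counts(n1, n2))
}
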