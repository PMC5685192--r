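#' Assign PAR1 allelic reads to X and Y chromosomes
#'
#' In a male, heterozygous PAR1 sites separate the X-borne (maternally
#' inherited) from the Y-borne (paternally inherited) allele. Given
#' trio-phased genotypes (haplotype a = maternal), each site's read counts
#' are assigned to X and Y and summed per gene across the gene's
#' informative sites. Sites outside PAR1 are rejected (this is a PAR1-only
#' analysis); unphased sites are skipped with a message.
#'
#' @param counts an [allele_count_table()] from one male sample.
#' @param phased trio-phased genotypes (see [read_phased_vcf()]).
#' @param genes a [gene_model_table()].
#' @return data.frame `gene_id, x_count, y_count, n_sites`.
#' @export
assign_par_reads <- function(counts, phased, genes) {
  tab <- map_sites_to_genes(counts, genes)
  tab <- tab[!is.na(tab$gene_id), , drop = FALSE]
  rc <- stats::setNames(genes$region_class, genes$gene_id)
  nonpar <- rc[tab$gene_id] != "PAR1"
  if (any(nonpar))
    stop(sum(nonpar), " observation(s) at non-PAR1 sites supplied; ",
         "this analysis is restricted to PAR1")
  ph <- phased[match(tab$site_id, phased$site_id), ]
  unph <- is.na(ph$phased) | !ph$phased
  if (any(unph)) message(sum(unph), " unphased site observation(s) skipped")
  tab <- tab[!unph, , drop = FALSE]; ph <- ph[!unph, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no phased PAR1 observations")
  ref_is_x <- ph$hap_a == ph$ref_allele
  tab$x <- ifelse(ref_is_x, tab$ref_count, tab$alt_count)
  tab$y <- ifelse(ref_is_x, tab$alt_count, tab$ref_count)
  out <- do.call(rbind, lapply(split(tab, tab$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], x_count = sum(d$x), y_count = sum(d$y),
               n_sites = length(unique(d$site_id)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Test equality of X and Y expression at a PAR1 gene
#'
#' Two-sided exact binomial test of the X read count against an equal
#' X/Y split, with a Jeffreys interval on the X fraction.
#'
#' @param x_count,y_count summed reads assigned to X and Y.
#' @param level CI coverage.
#' @return list: `test` (a `TestResult`), `x_fraction`, `ci` (lo, hi).
#' @export
test_xy_equality <- function(x_count, y_count, level = 0.95) {
  n <- x_count + y_count
  if (n < 1) stop("zero total reads")
  list(test = binom_test_exact(x_count, n, 0.5, "two_sided"),
       x_fraction = x_count / n,
       ci = jeffreys_interval(x_count, n, level))
}

#' PAR1 X/Y dosage analysis
#'
#' Driver combining [assign_par_reads()] and [test_xy_equality()] per gene.
#'
#' @inheritParams assign_par_reads
#' @return data.frame with per-gene counts, X fraction with Jeffreys CI,
#'   and two-sided binomial p.
#' @export
par_xy_analysis <- function(counts, phased, genes) {
  d <- assign_par_reads(counts, phased, genes)
  res <- lapply(seq_len(nrow(d)), function(i)
    test_xy_equality(d$x_count[i], d$y_count[i]))
  d$x_fraction <- vapply(res, `[[`, numeric(1), "x_fraction")
  d$ci_lo <- vapply(res, function(r) r$ci[["lo"]], numeric(1))
  d$ci_hi <- vapply(res, function(r) r$ci[["hi"]], numeric(1))
  d$p_value <- vapply(res, function(r) r$test$p_value, numeric(1))
  d
}
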