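#' Simulation configuration
#'
#' One config object drives every generator. Defaults encode the study
#' conditions the pipeline is built for: ~23% of X-linked genes escaping
#' XCI, of which 5.8% (of all genes) escape in a single tissue only; Xi
#' expression at escape genes averaging 33% of Xa; PAR1 genes expressing
#' both haplotypes at an Xi/Xa ratio near 0.80; an allele-miscall rate of
#' 2.5% (the empirical error bound used by the callers); 16 bulk tissues at
#' 100x mean site coverage; and single cells with heavy (70%) per-allele
#' dropout and a 50:50 XCI choice across cells.
#'
#' @param n_genes number of nonPAR genes.
#' @param n_par1_genes additional PAR1 genes (biallelic by construction).
#' @param include_xist add an XIST-like gene expressed from Xi only.
#' @param escape_fraction fraction of nonPAR genes escaping XCI (includes
#'   the tissue-specific ones).
#' @param tissue_specific_escape_fraction fraction of nonPAR genes escaping
#'   in exactly one tissue (subset of `escape_fraction`).
#' @param xi_to_xa_mean mean Xi/Xa expression ratio at escape genes.
#' @param xi_concentration Beta concentration for the per-gene Xi fraction.
#' @param par1_xi_to_xa_mean Xi/Xa ratio at PAR1 genes.
#' @param miscall_rate per-read probability of reporting the other allele.
#' @param n_tissues bulk tissues for the skewed-donor design.
#' @param depth_mean,depth_size negative-binomial read depth per site and
#'   tissue (mean / dispersion `size`).
#' @param n_cells single cells.
#' @param n_sites total heterozygous sites for the single-cell design
#'   (allocated across genes, each gene >= 1); `NULL` draws sites per gene
#'   from a truncated Poisson instead.
#' @param sites_per_gene_mean Poisson mean for heterozygous sites per gene
#'   (truncated at >= 1).
#' @param skew probability that a cell's active X is haplotype 1.
#' @param dropout_rate per-allele probability that a cell yields no reads
#'   for that allele at an expressed site.
#' @param sc_depth_mean,sc_depth_size negative-binomial per-cell site depth.
#' @param n_samples_per_sex samples per sex per tissue for the expression
#'   simulator.
#' @param n_autosomal_genes unbiased autosomal background genes in the
#'   expression simulator; they anchor library-size normalization the way
#'   the rest of the transcriptome does in real data, so that escape-driven
#'   female excess on chrX does not masquerade as male bias elsewhere.
#' @param expr_size negative-binomial size for expression counts.
#' @param seed integer RNG seed (mandatory).
#' @return a `xci_sim_config` list.
#' @export
sim_config <- function(n_genes = 500, n_par1_genes = 0, include_xist = TRUE,
                       escape_fraction = 0.23,
                       tissue_specific_escape_fraction = 0.058,
                       xi_to_xa_mean = 0.33, xi_concentration = 10,
                       par1_xi_to_xa_mean = 0.80, miscall_rate = 0.025,
                       n_tissues = 16, depth_mean = 100, depth_size = 5,
                       n_cells = 200, n_sites = NULL, sites_per_gene_mean = 2,
                       skew = 0.5, dropout_rate = 0.7,
                       sc_depth_mean = 20, sc_depth_size = 2,
                       n_samples_per_sex = 100, n_autosomal_genes = 1000,
                       expr_size = 10, seed = 1L) {
  cfg <- as.list(environment())
  fr <- c("escape_fraction", "tissue_specific_escape_fraction", "miscall_rate",
          "skew", "dropout_rate")
  for (f in fr) if (cfg[[f]] < 0 || cfg[[f]] > 1)
    stop(f, " must lie in [0, 1]")
  if (tissue_specific_escape_fraction > escape_fraction)
    stop("tissue-specific escapers are a subset of escape_fraction")
  if (n_genes < 1 || n_tissues < 1 || n_cells < 1) stop("n_* must be >= 1")
  if (is.null(seed)) stop("a seed is required")
  structure(cfg, class = "xci_sim_config")
}

# Poisson(lambda) truncated to >= 1
rpois_pos <- function(n, lambda) {
  x <- stats::rpois(n, lambda)
  while (any(x == 0)) x[x == 0] <- stats::rpois(sum(x == 0), lambda)
  x
}

# observed Xi-read probability given true Xi fraction f and miscall rate m
obs_frac <- function(f, m) f * (1 - m) + (1 - f) * m

ratio_to_frac <- function(r) r / (1 + r)

# per-gene Xi/Xa ratio drawn on the ratio scale (Beta on [0, 1], so Xi
# expression never exceeds Xa), then converted to the Xi read fraction
draw_xi_fraction <- function(n, cfg) {
  r <- stats::rbeta(n, cfg$xi_to_xa_mean * cfg$xi_concentration,
                    (1 - cfg$xi_to_xa_mean) * cfg$xi_concentration)
  ratio_to_frac(r)
}

random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  cbind(ref = ref, alt = unname(alt))
}

# gene layout: nonPAR genes spread along chrX between PAR1 and PAR2,
# PAR1 genes inside PAR1, plus an optional XIST-like gene at its hg19 locus
sim_gene_models <- function(cfg) {
  par <- par_boundaries_grch37()
  ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  span <- (par$par2$start - 2e6) - (par$par1$end + 1e5)
  starts <- par$par1$end + 1e5 + round(seq(0, span, length.out = cfg$n_genes))
  g <- data.frame(gene_id = ids, chrom = "X", start = as.integer(starts),
                  end = as.integer(starts + 2e4), stringsAsFactors = FALSE)
  if (cfg$include_xist) {
    # keep XIST's interval clear of the simulated genes
    g <- g[g$start > 73100000 | g$end < 73000000, ]
    g <- rbind(g, data.frame(gene_id = "XIST", chrom = "X",
                             start = 73040486L, end = 73072588L))
  }
  if (cfg$n_par1_genes > 0) {
    ps <- 100000 + round(seq(0, 2.4e6, length.out = cfg$n_par1_genes))
    g <- rbind(g, data.frame(gene_id = sprintf("PAR1G%02d", seq_len(cfg$n_par1_genes)),
                             chrom = "X", start = as.integer(ps),
                             end = as.integer(ps + 2e4)))
  }
  gene_model_table(g$gene_id, g$chrom, g$start, g$end, gene_name = g$gene_id)
}

# true status + Xi fraction per gene
sim_gene_truth <- function(genes, cfg) {
  n <- nrow(genes)
  status <- rep("inactive", n)
  nonpar <- genes$region_class %in% c("nonPAR_Xp", "nonPAR_Xq") &
    genes$gene_id != "XIST"
  u <- stats::runif(n)
  status[nonpar & u < cfg$escape_fraction] <- "escape"
  status[nonpar & u < cfg$tissue_specific_escape_fraction] <- "escape_ts"
  status[genes$region_class %in% c("PAR1", "PAR2")] <- "par"
  status[genes$gene_id == "XIST"] <- "xist"
  xi <- numeric(n)
  esc <- status %in% c("escape", "escape_ts")
  xi[esc] <- draw_xi_fraction(sum(esc), cfg)
  xi[status == "par"] <- ratio_to_frac(cfg$par1_xi_to_xa_mean)
  xi[status == "xist"] <- 1
  data.frame(gene_id = genes$gene_id, true_status = status,
             true_xi_fraction = xi, stringsAsFactors = FALSE)
}

# heterozygous sites within gene bodies; xi_is_alt / hap1_is_alt says which
# base sits on the inactive (or first) haplotype
sim_sites <- function(genes, cfg, n_sites = NULL) {
  k <- if (is.null(n_sites)) {
    rpois_pos(nrow(genes), cfg$sites_per_gene_mean)
  } else {
    if (n_sites < nrow(genes)) stop("n_sites must be >= number of genes")
    extra <- stats::rmultinom(1, n_sites - nrow(genes), rep(1, nrow(genes)))[, 1]
    extra + 1L
  }
  gene_ix <- rep(seq_len(nrow(genes)), k)
  pos <- genes$start[gene_ix] +
    unlist(lapply(k, function(m) sort(sample.int(2e4 - 1L, m))))
  al <- random_alleles(length(pos))
  data.frame(site_id = paste("X", pos, sep = ":"),
             chrom = "X", position = as.integer(pos),
             gene_id = genes$gene_id[gene_ix],
             ref_allele = al[, "ref"], alt_allele = al[, "alt"],
             alt_on_flagged_hap = sample(c(TRUE, FALSE), length(pos), replace = TRUE),
             stringsAsFactors = FALSE)
}

sites_to_phased <- function(sites, flagged_is_hap_a = FALSE) {
  # flagged haplotype = Xi (donor) or haplotype 1 (cells); hap_a is the
  # first VCF haplotype (maternal under transmission phasing)
  flagged <- ifelse(sites$alt_on_flagged_hap, sites$alt_allele, sites$ref_allele)
  other <- ifelse(sites$alt_on_flagged_hap, sites$ref_allele, sites$alt_allele)
  data.frame(site_id = sites$site_id, chrom = sites$chrom,
             position = sites$position,
             ref_allele = sites$ref_allele, alt_allele = sites$alt_allele,
             hap_a = if (flagged_is_hap_a) flagged else other,
             hap_b = if (flagged_is_hap_a) other else flagged,
             phased = TRUE, stringsAsFactors = FALSE)
}

#' Simulate a fully skewed multi-tissue donor
#'
#' Emulates bulk ASE from a female donor whose cells silence the same X in
#' every tissue. Inactive genes emit reads from Xi only through the
#' allele-miscall rate; escape genes emit Xi reads at a per-gene Beta-drawn
#' Xi fraction (same in every tissue); tissue-specific escapers do so in
#' exactly one randomly chosen tissue; the XIST-like gene expresses the Xi
#' haplotype only. Site depths are negative-binomial per site and tissue.
#'
#' @param cfg a [sim_config()].
#' @return list: `counts` (allele count table over tissues), `phased`
#'   (genotypes, haplotype b = Xi), `genes` (gene models), `truth`
#'   (per-gene status and Xi fraction, per-site Xi allele, per-gene-tissue
#'   Xi fraction), `config`.
#' @export
simulate_skewed_donor <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  genes <- sim_gene_models(cfg)
  truth <- sim_gene_truth(genes, cfg)
  tissues <- sprintf("T%02d", seq_len(cfg$n_tissues))
  ts_tissue <- stats::setNames(rep(NA_character_, nrow(genes)), genes$gene_id)
  ts <- truth$gene_id[truth$true_status == "escape_ts"]
  ts_tissue[ts] <- sample(tissues, length(ts), replace = TRUE)
  sites <- sim_sites(genes, cfg)

  xi_f <- stats::setNames(truth$true_xi_fraction, truth$gene_id)
  st <- stats::setNames(truth$true_status, truth$gene_id)
  rows <- vector("list", cfg$n_tissues)
  for (t in seq_along(tissues)) {
    f <- xi_f[sites$gene_id]
    g_ts <- st[sites$gene_id] == "escape_ts"
    f[g_ts & ts_tissue[sites$gene_id] != tissues[t]] <- 0
    n <- stats::rnbinom(nrow(sites), mu = cfg$depth_mean, size = cfg$depth_size)
    k_xi <- stats::rbinom(nrow(sites), n, obs_frac(f, cfg$miscall_rate))
    keep <- n > 0
    alt_is_xi <- sites$alt_on_flagged_hap
    rows[[t]] <- data.frame(
      chrom = sites$chrom[keep], position = sites$position[keep],
      ref_allele = sites$ref_allele[keep], alt_allele = sites$alt_allele[keep],
      unit_id = tissues[t],
      ref_count = ifelse(alt_is_xi[keep], n[keep] - k_xi[keep], k_xi[keep]),
      alt_count = ifelse(alt_is_xi[keep], k_xi[keep], n[keep] - k_xi[keep]),
      stringsAsFactors = FALSE)
  }
  counts <- allele_count_table(do.call(rbind, rows))
  truth$ts_tissue <- unname(ts_tissue[truth$gene_id])
  list(counts = counts,
       phased = sites_to_phased(sites, flagged_is_hap_a = FALSE),
       genes = genes,
       truth = list(genes = truth,
                    sites = data.frame(site_id = sites$site_id,
                                       gene_id = sites$gene_id,
                                       xi_allele = ifelse(sites$alt_on_flagged_hap,
                                                          sites$alt_allele,
                                                          sites$ref_allele),
                                       stringsAsFactors = FALSE)),
       config = cfg)
}

#' Simulate single-cell allelic counts
#'
#' Each cell silences haplotype 1 or 2 (haplotype 1 active with probability
#' `skew`). At inactive genes a cell expresses only its active-haplotype
#' allele (plus miscalls); escape and PAR genes express both alleles at the
#' gene's Xi fraction; the XIST-like gene expresses the inactive haplotype.
#' Per-allele dropout zeroes each allele's reads independently.
#'
#' @param cfg a [sim_config()]; `n_sites` fixes the total site count.
#' @return list: `counts` (cells x sites allele count table), `phased`
#'   (haplotype a = haplotype 1), `genes`, `truth` (per-cell active
#'   haplotype, per-site haplotype-1 allele, per-gene status), `config`.
#' @export
simulate_single_cells <- function(cfg = sim_config(n_genes = 25)) {
  set.seed(cfg$seed)
  genes <- sim_gene_models(cfg)
  truth <- sim_gene_truth(genes, cfg)
  sites <- sim_sites(genes, cfg, n_sites = cfg$n_sites)
  cells <- sprintf("C%04d", seq_len(cfg$n_cells))
  active_hap1 <- stats::runif(cfg$n_cells) < cfg$skew

  xi_f <- stats::setNames(truth$true_xi_fraction, truth$gene_id)
  st <- stats::setNames(truth$true_status, truth$gene_id)
  ns <- nrow(sites)
  rows <- vector("list", cfg$n_cells)
  for (c in seq_len(cfg$n_cells)) {
    f <- xi_f[sites$gene_id]  # one sample: tissue-specific escapers just escape
    # per-allele dropout removes that haplotype's transcripts from the pool;
    # reads are then sampled from what remains, with per-read miscalls
    drop_ac <- stats::runif(ns) < cfg$dropout_rate
    drop_in <- stats::runif(ns) < cfg$dropout_rate
    w_ac <- (1 - f) * !drop_ac
    w_in <- f * !drop_in
    w <- w_ac + w_in
    fp <- ifelse(w > 0, w_in / w, 0)
    # read depth scales with the surviving pool, so dropout thins coverage
    # instead of renormalizing it (keeps aggregate Xi fractions unbiased)
    n <- stats::rnbinom(ns, mu = cfg$sc_depth_mean * w, size = cfg$sc_depth_size)
    k_true <- stats::rbinom(ns, n, fp)                       # inactive-hap reads
    k_in <- stats::rbinom(ns, k_true, 1 - cfg$miscall_rate) +
      stats::rbinom(ns, n - k_true, cfg$miscall_rate)        # after miscalls
    k_ac <- n - k_in
    # map active/inactive to haplotype 1/2 for this cell
    k_h1 <- if (active_hap1[c]) k_ac else k_in
    k_h2 <- if (active_hap1[c]) k_in else k_ac
    alt_h1 <- sites$alt_on_flagged_hap
    keep <- k_h1 + k_h2 > 0
    if (!any(keep)) next
    rows[[c]] <- data.frame(
      chrom = sites$chrom[keep], position = sites$position[keep],
      ref_allele = sites$ref_allele[keep], alt_allele = sites$alt_allele[keep],
      unit_id = cells[c],
      ref_count = ifelse(alt_h1[keep], k_h2[keep], k_h1[keep]),
      alt_count = ifelse(alt_h1[keep], k_h1[keep], k_h2[keep]),
      stringsAsFactors = FALSE)
  }
  counts <- allele_count_table(do.call(rbind, rows[!vapply(rows, is.null, logical(1))]))
  list(counts = counts,
       phased = sites_to_phased(sites, flagged_is_hap_a = TRUE),
       genes = genes,
       truth = list(cells = data.frame(cell_id = cells,
                                       active_hap = ifelse(active_hap1, 1L, 2L)),
                    sites = data.frame(site_id = sites$site_id,
                                       gene_id = sites$gene_id,
                                       hap1_allele = ifelse(sites$alt_on_flagged_hap,
                                                            sites$alt_allele,
                                                            sites$ref_allele),
                                       stringsAsFactors = FALSE),
                    genes = truth),
       config = cfg)
}

#' Simulate sex-stratified expression counts
#'
#' Gene-level counts for equal numbers of male and female samples in each
#' tissue. NonPAR escape genes have female:male mean ratio (1 + r) where r
#' is the gene's Xi/Xa ratio; PAR genes have ratio (1 + r)/2 relative to
#' the male X+Y output; inactive genes have ratio 1. Counts are
#' negative-binomial around log-normal per-gene baselines.
#'
#' @param cfg a [sim_config()].
#' @return list: `counts` (genes x samples), `samples` (sample, sex,
#'   tissue), `genes`, `truth` (per-gene status, Xi fraction, expected
#'   female:male ratio), `config`.
#' @export
simulate_sex_expression <- function(cfg = sim_config(n_genes = 200)) {
  set.seed(cfg$seed)
  genes <- sim_gene_models(cfg)
  truth <- sim_gene_truth(genes, cfg)
  if (cfg$n_autosomal_genes > 0) {
    n_a <- cfg$n_autosomal_genes
    auto <- gene_model_table(sprintf("A%04d", seq_len(n_a)), chrom = "1",
                             start = 1e6 + seq_len(n_a) * 1e5,
                             end = 1e6 + seq_len(n_a) * 1e5 + 2e4)
    genes <- rbind(genes, auto)
    truth <- rbind(truth, data.frame(gene_id = auto$gene_id,
                                     true_status = "autosomal",
                                     true_xi_fraction = 0))
  }
  r <- truth$true_xi_fraction / (1 - truth$true_xi_fraction)  # xi/xa ratio
  ratio <- rep(1, nrow(genes))
  esc <- truth$true_status %in% c("escape", "escape_ts")
  ratio[esc] <- 1 + r[esc]
  ratio[truth$true_status == "par"] <- (1 + r[truth$true_status == "par"]) / 2
  ratio[truth$true_status == "xist"] <- 50  # female-specific
  base <- stats::rlnorm(nrow(genes), meanlog = log(500), sdlog = 1)

  tissues <- sprintf("T%02d", seq_len(cfg$n_tissues))
  nss <- cfg$n_samples_per_sex
  samp <- expand.grid(idx = seq_len(2 * nss), tissue = tissues,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samp$sex <- rep(c("male", "female"), each = nss, times = cfg$n_tissues)
  samp$sample <- sprintf("S_%s_%s%03d", samp$tissue, substr(samp$sex, 1, 1), samp$idx)
  mu <- base %o% rep(1, nrow(samp))
  fem <- samp$sex == "female"
  mu[, fem] <- mu[, fem] * ratio
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = cfg$expr_size),
                   nrow = nrow(genes),
                   dimnames = list(genes$gene_id, samp$sample))
  truth$expected_fm_ratio <- ratio
  list(counts = counts, samples = samp[c("sample", "sex", "tissue")],
       genes = genes, truth = truth, config = cfg)
}

#' Simulate chromatin-state gene-body coverage
#'
#' Per-gene fractions of the gene body assigned to each of the Roadmap core
#' 15 chromatin states (rows sum to 1 exactly), for an escape and an
#' inactive gene set. A configurable subset of states is shifted upward in
#' escape genes (Dirichlet concentration multiplied by `shift_factor`),
#' emulating the enrichment of active-transcription states at escape genes;
#' `shift_factor = 1` gives the null.
#'
#' @param n_escape,n_inactive gene-set sizes (defaults follow the scale of
#'   published escape/inactive sets: 86 and 399).
#' @param shift_states state names elevated in escape genes.
#' @param shift_factor multiplicative shift on those states' concentration.
#' @param concentration overall Dirichlet concentration.
#' @param seed RNG seed.
#' @return list: `coverage` (genes x 15 matrix, rows sum to 1), `labels`
#'   (escape/inactive), `shift_states`.
#' @export
simulate_chromatin_coverage <- function(n_escape = 86, n_inactive = 399,
                                        shift_states = c("TssA", "Tx"),
                                        shift_factor = 2, concentration = 50,
                                        seed = 1L) {
  set.seed(seed)
  states <- c("TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "EnhG", "Enh",
              "ZNF_Rpts", "Het", "TssBiv", "BivFlnk", "EnhBiv", "ReprPC",
              "ReprPCWk", "Quies")
  base <- c(4, 2, 1, 6, 10, 1, 3, 1, 8, 2, 1, 1, 10, 15, 35)
  base <- base / sum(base)
  rdirichlet <- function(n, alpha) {
    x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
                byrow = TRUE)
    x / rowSums(x)
  }
  a_in <- base * concentration
  a_esc <- a_in
  a_esc[match(shift_states, states)] <- a_esc[match(shift_states, states)] * shift_factor
  cov <- rbind(rdirichlet(n_escape, a_esc), rdirichlet(n_inactive, a_in))
  dimnames(cov) <- list(c(sprintf("ESC%03d", seq_len(n_escape)),
                          sprintf("INA%03d", seq_len(n_inactive))), states)
  list(coverage = cov,
       labels = c(rep("escape", n_escape), rep("inactive", n_inactive)),
       shift_states = shift_states)
}

#' Write phased genotypes as a minimal VCF
#'
#' @param phased data.frame as returned by [read_phased_vcf()] /
#'   the simulators.
#' @param path output file.
#' @param sample sample column name.
#' @export
write_phased_vcf <- function(phased, path, sample = "SIM") {
  sep <- ifelse(phased$phased, "|", "/")
  code <- function(a) ifelse(a == phased$ref_allele, "0", "1")
  gt <- paste0(code(phased$hap_a), sep, code(phased$hap_b))
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=X>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  body <- paste(phased$chrom, phased$position, phased$site_id,
                phased$ref_allele, phased$alt_allele, ".", "PASS", ".",
                "GT", gt, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
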