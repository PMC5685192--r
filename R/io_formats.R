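#' Allele count tables
#'
#' The central container is a plain data.frame with one row per
#' (heterozygous site, observation unit): columns `site_id` (chrom:1-based
#' position), `chrom`, `position`, `ref_allele`, `alt_allele`, `unit_id`
#' (tissue sample or cell), `ref_count`, `alt_count`, and `other_bases`
#' (TRUE when the source row reported reads beyond ref+alt). Only biallelic
#' SNPs are admitted; indels are always excluded because of mapping bias.
#'
#' @param df data.frame with the columns above (`site_id` and `other_bases`
#'   are derived if absent).
#' @return validated allele count table.
#' @export
allele_count_table <- function(df) {
  req <- c("chrom", "position", "ref_allele", "alt_allele",
           "unit_id", "ref_count", "alt_count")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  df$position <- as.integer(df$position)
  df$ref_count <- as.integer(df$ref_count)
  df$alt_count <- as.integer(df$alt_count)
  if (anyNA(df$ref_count) || anyNA(df$alt_count))
    stop("validation error: counts must be integers")
  if (any(df$ref_count < 0) || any(df$alt_count < 0))
    stop("validation error: negative read count")
  bad <- !grepl("^[ACGTacgt]$", df$ref_allele) | !grepl("^[ACGTacgt]$", df$alt_allele)
  if (any(bad))
    stop("validation error: alleles must be single bases (biallelic SNPs only); ",
         sum(bad), " offending row(s)")
  if (is.null(df$site_id)) df$site_id <- paste(df$chrom, df$position, sep = ":")
  if (is.null(df$other_bases)) df$other_bases <- FALSE
  key <- paste(df$site_id, df$unit_id)
  if (anyDuplicated(key))
    stop("validation error: duplicated (site_id, unit_id) pair")
  df[c("site_id", "chrom", "position", "ref_allele", "alt_allele",
       "unit_id", "ref_count", "alt_count", "other_bases")]
}

#' Read allelic counts
#'
#' Reads per-site allelic read counts in either the GATK ASEReadCounter TSV
#' dialect (columns `contig position variantID refAllele altAllele refCount
#' altCount totalCount ...`; one sample per file, so `unit_id` names the
#' sample) or the package's generic long TSV (adds `unit_id` per row).
#' Unknown dialects are rejected rather than sniffed: silently misparsing a
#' count column is the worst failure mode.
#'
#' Rows whose `totalCount` exceeds `refCount + altCount` (reads carrying
#' other bases) are kept with `other_bases = TRUE`; the total used downstream
#' is always recomputed as ref + alt.
#'
#' @param path TSV file.
#' @param dialect `"asereadcounter_tsv"` or `"generic_tsv"`.
#' @param unit_id observation-unit label for `asereadcounter_tsv` input;
#'   defaults to the file name without extension.
#' @return an [allele_count_table()].
#' @export
read_allele_counts <- function(path, dialect = c("asereadcounter_tsv", "generic_tsv"),
                               unit_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE, colClasses = "character"),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  if (dialect == "asereadcounter_tsv") {
    req <- c("contig", "position", "refAllele", "altAllele", "refCount", "altCount")
    miss <- setdiff(req, names(raw))
    if (length(miss))
      stop("parse error: ", path, " lacks ASEReadCounter column(s) ",
           paste(miss, collapse = ", "))
    if (is.null(unit_id)) unit_id <- sub("\\.[^.]*$", "", basename(path))
    df <- data.frame(chrom = raw$contig,
                     position = parse_count(raw$position, path, "position"),
                     ref_allele = raw$refAllele, alt_allele = raw$altAllele,
                     unit_id = rep_len(unit_id, nrow(raw)),
                     ref_count = parse_count(raw$refCount, path, "refCount"),
                     alt_count = parse_count(raw$altCount, path, "altCount"),
                     stringsAsFactors = FALSE)
    if (!is.null(raw$totalCount)) {
      tot <- parse_count(raw$totalCount, path, "totalCount")
      df$other_bases <- tot > df$ref_count + df$alt_count
    }
  } else {
    req <- c("chrom", "position", "ref_allele", "alt_allele",
             "unit_id", "ref_count", "alt_count")
    miss <- setdiff(req, names(raw))
    if (length(miss))
      stop("parse error: ", path, " lacks column(s) ", paste(miss, collapse = ", "))
    df <- raw[req]
    df$position <- parse_count(raw$position, path, "position")
    df$ref_count <- parse_count(raw$ref_count, path, "ref_count")
    df$alt_count <- parse_count(raw$alt_count, path, "alt_count")
    if (!is.null(raw$other_bases)) df$other_bases <- as.logical(raw$other_bases)
  }
  allele_count_table(df)
}

parse_count <- function(x, path, col) {
  bad <- !grepl("^-?[0-9]+$", x)
  if (any(bad))
    stop("parse error in ", path, ", column ", col, ", line ",
         which(bad)[1] + 1L, ": '", x[which(bad)[1]], "'")
  v <- as.integer(x)
  if (any(v < 0) && col != "position")
    stop("validation error in ", path, ": negative ", col)
  v
}

#' Write allelic counts
#'
#' Inverse of [read_allele_counts()]. `generic_tsv` writes one long file;
#' `asereadcounter_tsv` writes one GATK-style file per observation unit into
#' directory `path` (named `<unit_id>.tsv`). Positions stay 1-based.
#'
#' @param table an [allele_count_table()].
#' @param path output file (generic) or directory (asereadcounter).
#' @param dialect output dialect.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(table, path,
                                dialect = c("generic_tsv", "asereadcounter_tsv")) {
  dialect <- match.arg(dialect)
  table <- allele_count_table(table)
  if (dialect == "generic_tsv") {
    utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (u in unique(table$unit_id)) {
      sub <- table[table$unit_id == u, ]
      out <- data.frame(contig = sub$chrom, position = sub$position,
                        variantID = sub$site_id, refAllele = sub$ref_allele,
                        altAllele = sub$alt_allele, refCount = sub$ref_count,
                        altCount = sub$alt_count,
                        totalCount = sub$ref_count + sub$alt_count)
      utils::write.table(out, file.path(path, paste0(u, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}

#' Site filter configuration
#'
#' @param blacklist character vector of `site_id`s to drop (e.g. sites with
#'   non-unique mappability or failing manual curation).
#' @param min_total_reads minimum ref + alt reads per observation row.
#' @param exclude_indels kept for interface completeness; indels are always
#'   excluded at parse time.
#' @export
site_filter_config <- function(blacklist = character(0), min_total_reads = 0L,
                               exclude_indels = TRUE) {
  if (min_total_reads < 0) stop("min_total_reads must be >= 0")
  list(blacklist = as.character(blacklist),
       min_total_reads = as.integer(min_total_reads),
       exclude_indels = isTRUE(exclude_indels))
}

#' Apply site filters
#'
#' Removes blacklisted sites and observation rows below the coverage floor.
#' Idempotent; an empty result is allowed. Row counts in/out are reported
#' via `message()`.
#'
#' @param table an [allele_count_table()].
#' @param config a [site_filter_config()].
#' @export
apply_site_filters <- function(table, config = site_filter_config()) {
  table <- allele_count_table(table)
  n0 <- nrow(table)
  table <- table[!(table$site_id %in% config$blacklist), , drop = FALSE]
  table <- table[table$ref_count + table$alt_count >= config$min_total_reads, ,
                 drop = FALSE]
  message(sprintf("apply_site_filters: %d rows in, %d rows out", n0, nrow(table)))
  rownames(table) <- NULL
  table
}

#' Read phased genotypes from a VCF
#'
#' Extracts biallelic heterozygous SNPs for one sample. `hap_a` / `hap_b`
#' give the base on the first / second haplotype of the GT field; with
#' trio-based transmission phasing the first haplotype is the maternally
#' inherited allele. Multiallelic sites and indels are skipped with a
#' message; homozygous and missing genotypes are dropped.
#'
#' @param path VCF 4.x file (plain text or gzipped).
#' @param sample sample name; must be present in the VCF.
#' @return data.frame: `site_id, chrom, position, ref_allele, alt_allele,
#'   hap_a, hap_b, phased`.
#' @export
read_phased_vcf <- function(path, sample = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  if (is.null(sample)) sample <- samples[1]
  if (!sample %in% samples)
    stop("sample '", sample, "' not found in ", path,
         " (has: ", paste(samples, collapse = ", "), ")")
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[, sample]
  multi <- grepl(",", fix$ALT)
  indel <- nchar(fix$REF) != 1L | (nchar(fix$ALT) != 1L & !multi)
  if (any(multi)) message(sum(multi), " multiallelic site(s) skipped")
  if (any(indel)) message(sum(indel), " indel site(s) skipped")
  keep <- !multi & !indel & !is.na(gt) & gt != "." & !grepl("\\.", gt)
  fix <- fix[keep, , drop = FALSE]; gt <- gt[keep]
  phased <- grepl("\\|", gt)
  al <- strsplit(gt, "[|/]")
  ok <- lengths(al) == 2L
  fix <- fix[ok, , drop = FALSE]; gt <- gt[ok]; phased <- phased[ok]
  al <- do.call(rbind, al[ok])
  het <- al[, 1] != al[, 2]
  fix <- fix[het, , drop = FALSE]; phased <- phased[het]
  al <- al[het, , drop = FALSE]
  base <- function(code, ref, alt) ifelse(code == "0", ref, alt)
  data.frame(
    site_id = paste(fix$CHROM, fix$POS, sep = ":"),
    chrom = fix$CHROM, position = as.integer(fix$POS),
    ref_allele = fix$REF, alt_allele = fix$ALT,
    hap_a = base(al[, 1], fix$REF, fix$ALT),
    hap_b = base(al[, 2], fix$REF, fix$ALT),
    phased = phased, stringsAsFactors = FALSE, row.names = NULL)
}

#' GRCh37 pseudoautosomal boundaries
#'
#' Default X-chromosome region boundaries (hg19), shipped as a YAML config
#' so other builds can be supplied: PAR1 X:60,001-2,699,520, PAR2
#' X:154,931,044-155,260,560, and the Xp/Xq split at the centromeric gap.
#'
#' @param path optional alternative YAML config.
#' @return list with `par1`, `par2` (start/end) and `xp_xq_split`.
#' @export
par_boundaries_grch37 <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "par_boundaries_grch37.yaml", package = "xciase")
  yaml::read_yaml(path)
}

#' Classify X-chromosomal region
#'
#' @param chrom,start,end vectors describing gene intervals (1-based
#'   inclusive).
#' @param par boundary config, see [par_boundaries_grch37()].
#' @return character vector in `{PAR1, PAR2, nonPAR_Xp, nonPAR_Xq, autosome,
#'   chrY}`.
#' @export
classify_region <- function(chrom, start, end, par = par_boundaries_grch37()) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(sub("^chr", "", as.character(chrom)), n)
  start <- rep_len(start, n); end <- rep_len(end, n)
  out <- rep("autosome", length(chrom))
  out[chrom == "Y"] <- "chrY"
  isx <- chrom == "X"
  in1 <- isx & start <= par$par1$end & end >= par$par1$start
  in2 <- isx & start <= par$par2$end & end >= par$par2$start
  out[isx] <- ifelse(start[isx] < par$xp_xq_split, "nonPAR_Xp", "nonPAR_Xq")
  out[in1] <- "PAR1"
  out[in2] <- "PAR2"
  out
}

#' Build a gene model table
#'
#' @param gene_id,gene_name,chrom,start,end parallel vectors (1-based
#'   inclusive coordinates).
#' @param par PAR boundary config used to derive `region_class`.
#' @export
gene_model_table <- function(gene_id, chrom, start, end, gene_name = gene_id,
                             par = par_boundaries_grch37()) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) stop("malformed interval: start > end")
  if (anyDuplicated(gene_id)) stop("duplicate gene_id")
  data.frame(gene_id = as.character(gene_id), gene_name = as.character(gene_name),
             chrom = as.character(chrom), start = start, end = end,
             region_class = classify_region(chrom, start, end, par),
             stringsAsFactors = FALSE)
}

#' Read gene models from BED or GTF
#'
#' BED input is 0-based half-open and converted to 1-based inclusive on
#' read; GTF rows of type `gene` are used as-is (already 1-based).
#' Parsing is delegated to `rtracklayer::import`.
#'
#' @param path BED6 or GTF file.
#' @param format `"bed"` or `"gtf"` (default from the file extension).
#' @param par PAR boundary config.
#' @export
read_gene_models <- function(path, format = NULL, par = par_boundaries_grch37()) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.gtf(\\.gz)?$", path)) "gtf" else "bed"
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read gene models")
  gr <- rtracklayer::import(path, format = format)
  if (format == "gtf") {
    if ("type" %in% names(S4Vectors::mcols(gr))) gr <- gr[gr$type == "gene"]
    ids <- if (!is.null(gr$gene_id)) gr$gene_id else as.character(seq_along(gr))
    nm <- if (!is.null(gr$gene_name)) gr$gene_name else ids
  } else {
    ids <- if (!is.null(gr$name)) gr$name else as.character(seq_along(gr))
    nm <- ids
  }
  gene_model_table(gene_id = ids, gene_name = nm,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
                   par = par)
}

#' Map sites to genes by position
#'
#' Annotates an allele count table with the `gene_id` whose interval
#' contains each site (first containing gene wins on overlap; sites in no
#' gene get NA).
#'
#' @param table an [allele_count_table()].
#' @param genes a [gene_model_table()].
#' @export
map_sites_to_genes <- function(table, genes) {
  norm <- function(x) sub("^chr", "", x)
  gi <- rep(NA_character_, nrow(table))
  tc <- norm(table$chrom)
  for (j in seq_len(nrow(genes))) {
    hit <- is.na(gi) & tc == norm(genes$chrom[j]) &
      table$position >= genes$start[j] & table$position <= genes$end[j]
    gi[hit] <- genes$gene_id[j]
  }
  table$gene_id <- gi
  table
}
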