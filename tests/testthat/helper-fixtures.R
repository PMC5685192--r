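# Small in-code fixtures shared across test files.

tiny_allele_table <- function() {
  allele_count_table(data.frame(
    chrom = "X",
    position = c(1000, 2000, 3000, 1000, 2000, 3000),
    ref_allele = c("A", "C", "G", "A", "C", "G"),
    alt_allele = c("G", "T", "A", "G", "T", "A"),
    unit_id = rep(c("T01", "T02"), each = 3),
    ref_count = c(12, 5, 0, 8, 50, 3),
    alt_count = c(3, 5, 20, 1, 2, 3)))
}

tiny_genes <- function() {
  gene_model_table(gene_id = c("GENE1", "GENE2"),
                   chrom = "X",
                   start = c(500, 2500),
                   end = c(2400, 3500))
}

write_test_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=X>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    "X\t1000\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1",
    "X\t2000\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1",
    "X\t3000\trs3\tG\tA\t.\tPASS\t.\tGT\t1/1",
    "X\t4000\trs4\tT\tA,C\t.\tPASS\t.\tGT\t1/2",
    "X\t5000\trs5\tTA\tT\t.\tPASS\t.\tGT\t0|1",
    "X\t6000\trs6\tG\tC\t.\tPASS\t.\tGT\t1|0"), path)
  path
}
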