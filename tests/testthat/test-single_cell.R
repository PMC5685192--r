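cell_rows <- function(cell, sites, ref, alt, pos = NULL, gene = NA) {
  if (is.null(pos)) pos <- as.integer(sub("X:", "", sites))
  data.frame(site_id = sites, chrom = "X", position = pos,
             ref_allele = "A", alt_allele = "G", unit_id = cell,
             ref_count = ref, alt_count = alt, other_bases = FALSE,
             gene_id = gene, stringsAsFactors = FALSE)
}

test_that("biallelic detection applies the fraction and nominal-test rules", {
  cfg <- sc_calling_config()
  d <- rbind(
    cell_rows("c1", "X:1", 8, 0),            # monoallelic
    cell_rows("c2", "X:1", 10, 10),          # clearly biallelic
    cell_rows("c3", "X:1", 11, 1),           # 1 of 12: fails the nominal test
    cell_rows("c4", "X:1", 4, 2))            # below 8 reads: not assessed
  res <- detect_biallelic_cells(d, cfg)
  expect_equal(nrow(res$cell_site), 3)       # c4 dropped
  got <- setNames(res$cell_site$biallelic, res$cell_site$unit_id)
  expect_false(got[["c1"]])
  expect_true(got[["c2"]])
  expect_false(got[["c3"]])
  # closed form for the c3 one-sided p: 1 - 0.975^12
  p3 <- res$cell_site$p_biallelic[res$cell_site$unit_id == "c3"]
  expect_equal(p3, 1 - 0.975^12, tolerance = 1e-12)
  expect_gt(p3, 0.05)
})

test_that("gene-level biallelic flag needs two biallelic cell observations", {
  cfg <- sc_calling_config()
  d <- rbind(cell_rows("c1", "X:1", 10, 10, gene = "g1"),
             cell_rows("c2", "X:1", 12, 0, gene = "g1"),
             cell_rows("c3", "X:2", 10, 10, gene = "g2"),
             cell_rows("c4", "X:2", 10, 8, gene = "g2"))
  res <- detect_biallelic_cells(d, cfg)
  expect_false(res$gene$biallelic[res$gene$gene_id == "g1"])  # one observation
  expect_true(res$gene$biallelic[res$gene$gene_id == "g2"])
})

test_that("PAR1 sites are always excluded from phasing; frequent biallelics too", {
  genes <- gene_model_table(c("PARG", "NG"), "X",
                            start = c(100000, 5e6), end = c(120000, 5.1e6))
  mono <- do.call(rbind, lapply(1:10, function(i)
    rbind(cell_rows(paste0("c", i), "X:100500", 10, 0),
          cell_rows(paste0("c", i), "X:5000500", 10, 0))))
  excl <- identify_frequently_biallelic_sites(mono, genes)
  expect_true("X:100500" %in% excl)   # PAR1, never biallelic, excluded anyway
  expect_false("X:5000500" %in% excl) # nonPAR, never biallelic: retained

  # biallelic in 3 of 10 covered cells > 10% threshold
  bi <- do.call(rbind, lapply(1:10, function(i)
    cell_rows(paste0("c", i), "X:5000600",
              10, ifelse(i <= 3, 8, 0))))
  excl <- identify_frequently_biallelic_sites(rbind(mono, bi), genes)
  expect_true("X:5000600" %in% excl)
})

test_that("trio-phased assignment votes by expressed haplotype", {
  ph <- data.frame(site_id = paste0("X:", 1:5), chrom = "X", position = 1:5,
                   ref_allele = "A", alt_allele = "G",
                   hap_a = c("A", "A", "G", "A", "G"),
                   hap_b = c("G", "G", "A", "G", "A"), phased = TRUE)
  d <- rbind(
    cell_rows("mat", paste0("X:", 1:5), c(9, 8, 0, 7, 0), c(0, 0, 6, 0, 9)),
    cell_rows("pat", paste0("X:", 1:2), c(0, 0), c(5, 8)))
  asn <- assign_cells_with_parental_phase(d, ph)
  expect_equal(asn$population[asn$cell_id == "mat"], "P1")
  expect_equal(asn$n_supporting_sites[asn$cell_id == "mat"], 5L)
  expect_equal(asn$agreement_score[asn$cell_id == "mat"], 1)
  expect_equal(asn$population[asn$cell_id == "pat"], "P2")

  # cell expressing only excluded (PAR1-like) sites is uninformative
  asn2 <- assign_cells_with_parental_phase(d, ph,
                                           exclusions = paste0("X:", 1:2))
  expect_equal(asn2$population[asn2$cell_id == "pat"], "uninformative")
})

test_that("fully skewed sample assigns every informative cell to one population", {
  cfg <- sim_config(n_genes = 12, n_cells = 96, skew = 1, include_xist = FALSE,
                    seed = 17)
  sc <- simulate_single_cells(cfg)
  excl <- identify_frequently_biallelic_sites(sc$counts, sc$genes)
  asn <- assign_cells_with_parental_phase(sc$counts, sc$phased, excl)
  pops <- table(asn$population[asn$population != "uninformative"])
  expect_equal(skew_from_cell_counts(pops[["P1"]],
                                     ifelse("P2" %in% names(pops), pops[["P2"]], 0)),
               c(100, 0))
})

test_that("unphased partition puts agreeing cells together, disagreeing apart", {
  two_same <- rbind(cell_rows("c1", "X:1", 9, 0), cell_rows("c2", "X:1", 7, 0),
                    cell_rows("c1", "X:2", 5, 0), cell_rows("c2", "X:3", 0, 4))
  res <- infer_partition_unphased(two_same, seed = 1)
  p <- setNames(res$assignments$population, res$assignments$cell_id)
  expect_equal(p[["c1"]], p[["c2"]])

  two_diff <- rbind(cell_rows("c1", "X:1", 9, 0), cell_rows("c2", "X:1", 0, 7))
  res <- infer_partition_unphased(two_diff, seed = 1)
  p <- setNames(res$assignments$population, res$assignments$cell_id)
  expect_false(p[["c1"]] == p[["c2"]])

  # planted 2 vs 2 partition over 3 sites recovered exactly
  planted <- rbind(
    cell_rows("a1", paste0("X:", 1:3), c(9, 8, 7), c(0, 0, 0)),
    cell_rows("a2", paste0("X:", 1:3), c(8, 9, 9), c(0, 0, 0)),
    cell_rows("b1", paste0("X:", 1:3), c(0, 0, 0), c(9, 9, 8)),
    cell_rows("b2", paste0("X:", 1:3), c(0, 0, 0), c(7, 8, 9)))
  res <- infer_partition_unphased(planted, seed = 1)
  p <- setNames(res$assignments$population, res$assignments$cell_id)
  expect_equal(p[["a1"]], p[["a2"]])
  expect_equal(p[["b1"]], p[["b2"]])
  expect_false(p[["a1"]] == p[["b1"]])
  expect_equal(res$assignments$agreement_score, rep(1, 4))

  disjoint <- rbind(cell_rows("c1", "X:1", 9, 0), cell_rows("c2", "X:2", 9, 0))
  expect_error(infer_partition_unphased(disjoint, seed = 1), "unconnectable")
})

test_that("aggregation maps each cell's active allele to Xa and conserves reads", {
  asn <- data.frame(cell_id = c("c1", "c2", "c3"),
                    population = c("P1", "P2", "uninformative"),
                    n_supporting_sites = c(3L, 3L, 0L),
                    agreement_score = c(1, 1, NA))
  phase <- data.frame(site_id = "X:1", p1_allele = "A")
  d <- rbind(cell_rows("c1", "X:1", 10, 0, gene = "g1"),
             cell_rows("c2", "X:1", 0, 10, gene = "g1"),
             cell_rows("c3", "X:1", 50, 50, gene = "g1"))
  agg <- aggregate_xa_xi(d, asn, phase)
  # both informative cells expressed their own active allele
  expect_equal(agg$xa_count, 20L)
  expect_equal(agg$xi_count, 0L)
  expect_equal(agg$n_cells, 2L)

  # read conservation over included cells and sites
  cfg <- sim_config(n_genes = 10, n_cells = 40, seed = 23)
  sc <- simulate_single_cells(cfg)
  tab <- map_sites_to_genes(sc$counts, sc$genes)
  asn <- assign_cells_with_parental_phase(sc$counts, sc$phased)
  phase <- data.frame(site_id = sc$phased$site_id, p1_allele = sc$phased$hap_a)
  agg <- aggregate_xa_xi(tab, asn, phase)
  inf_cells <- asn$cell_id[asn$population != "uninformative"]
  kept <- tab[tab$unit_id %in% inf_cells & !is.na(tab$gene_id), ]
  expect_equal(sum(agg$xa_count + agg$xi_count),
               sum(kept$ref_count + kept$alt_count))
})

test_that("XIST aggregates to the inactive haplotype", {
  cfg <- sim_config(n_genes = 10, n_cells = 60, seed = 29)
  sc <- simulate_single_cells(cfg)
  run <- sc_call_xci(sc$counts, sc$genes, phased = sc$phased)
  xist <- run$aggregate[run$aggregate$gene_id == "XIST", ]
  expect_gt(xist$xi_count, xist$xa_count)
  run2 <- sc_call_xci(sc$counts, sc$genes, phased = NULL, seed = 29)
  xist2 <- run2$aggregate[run2$aggregate$gene_id == "XIST", ]
  expect_gt(xist2$xi_count, xist2$xa_count)
})

test_that("gene-level calls respect the assay filters and the error bound", {
  agg <- data.frame(gene_id = c("g1", "g2", "g3"),
                    xa_count = c(200L, 30L, 70L),
                    xi_count = c(0L, 5L, 30L),
                    n_cells = c(20L, 4L, 12L), xist_flipped = FALSE)
  out <- call_xci_from_cells(agg)
  expect_equal(setNames(out$status, out$gene_id),
               c(g1 = "inactive", g2 = "not_assayed", g3 = "escape"))
  # exact tail oracle for g3
  expect_equal(out$p[3], sum(dbinom(30:100, 100, 0.025)), tolerance = 1e-12)
})

test_that("Xi/Xa ratio and cell-split summaries match their closed forms", {
  r <- xi_xa_ratio(25, 75)
  expect_equal(r$ratio, 1 / 3, tolerance = 1e-12)
  expect_true(r$ci_lo < r$ratio && r$ratio < r$ci_hi)
  expect_equal(xi_xa_ratio(0, 50)$ratio, 0)
  expect_equal(xi_xa_ratio(80, 100)$ratio, 0.8)
  inv <- xi_xa_ratio(40, 0)
  expect_true(inv$inverted_orientation)

  expect_equal(skew_from_cell_counts(373, 315), c(54, 46))
  expect_equal(skew_from_cell_counts(90, 0), c(100, 0))
  expect_equal(skew_from_cell_counts(1, 1), c(50, 50))
  expect_error(skew_from_cell_counts(0, 0), "no informative")
})

test_that("pipeline output is equivariant to cell order", {
  cfg <- sim_config(n_genes = 8, n_cells = 30, seed = 31)
  sc <- simulate_single_cells(cfg)
  shuf <- sc$counts[sample(nrow(sc$counts)), ]
  r1 <- sc_call_xci(sc$counts, sc$genes, phased = sc$phased)
  r2 <- sc_call_xci(shuf, sc$genes, phased = sc$phased)
  norm <- function(d) { d <- d[order(d$gene_id), ]; rownames(d) <- NULL; d }
  expect_equal(norm(r1$calls), norm(r2$calls))
  expect_equal(r1$skew_split, r2$skew_split)
})
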