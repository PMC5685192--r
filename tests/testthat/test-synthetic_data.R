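test_that("config validation rejects out-of-range fractions", {
  expect_error(sim_config(escape_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(escape_fraction = 0.1,
                          tissue_specific_escape_fraction = 0.2), "subset")
  expect_error(sim_config(n_genes = 0), ">= 1")
})

test_that("same seed gives byte-identical output; emitted tables validate", {
  cfg <- sim_config(n_genes = 30, n_tissues = 4, seed = 5)
  a <- simulate_skewed_donor(cfg)
  b <- simulate_skewed_donor(cfg)
  expect_identical(a, b)
  expect_silent(allele_count_table(a$counts))
  cfg2 <- sim_config(n_genes = 10, n_cells = 20, seed = 5)
  expect_identical(simulate_single_cells(cfg2)$counts,
                   simulate_single_cells(cfg2)$counts)
})

test_that("degenerate donor configs emit no spurious Xi reads", {
  cfg <- sim_config(n_genes = 40, escape_fraction = 0,
                    tissue_specific_escape_fraction = 0,
                    miscall_rate = 0, include_xist = FALSE, seed = 2)
  sim <- simulate_skewed_donor(cfg)
  tab <- merge(sim$counts, sim$truth$sites, by = "site_id")
  xi <- ifelse(tab$xi_allele == tab$ref_allele, tab$ref_count, tab$alt_count)
  expect_true(all(xi == 0))

  # with miscall only, pooled Xi fraction stays at noise level
  cfg$miscall_rate <- 0.025
  sim <- simulate_skewed_donor(cfg)
  tab <- merge(sim$counts, sim$truth$sites, by = "site_id")
  xi <- ifelse(tab$xi_allele == tab$ref_allele, tab$ref_count, tab$alt_count)
  frac <- sum(xi) / sum(tab$ref_count + tab$alt_count)
  expect_lt(frac, 0.04)
  expect_gt(frac, 0.01)
})

test_that("donor ground truth is consistent with emitted counts", {
  cfg <- sim_config(n_genes = 200, seed = 8)
  sim <- simulate_skewed_donor(cfg)
  tab <- merge(sim$counts, sim$truth$sites, by = "site_id")
  tab$xi <- ifelse(tab$xi_allele == tab$ref_allele, tab$ref_count, tab$alt_count)
  tab$tot <- tab$ref_count + tab$alt_count
  obs <- tapply(tab$xi, tab$gene_id, sum) / tapply(tab$tot, tab$gene_id, sum)
  tr <- sim$truth$genes
  esc <- tr[tr$true_status == "escape", ]
  m <- cfg$miscall_rate
  expected <- esc$true_xi_fraction * (1 - m) + (1 - esc$true_xi_fraction) * m
  realized <- obs[esc$gene_id]
  # per-gene realized fraction close to its own drawn fraction
  expect_lt(mean(abs(realized - expected)), 0.02)
})

test_that("escape fraction and Xi/Xa levels land near their targets", {
  cfg <- sim_config(seed = 4)  # 500 genes
  sim <- simulate_skewed_donor(cfg)
  tr <- sim$truth$genes[sim$truth$genes$true_status != "xist", ]
  frac <- mean(tr$true_status %in% c("escape", "escape_ts"))
  expect_lt(abs(frac - 0.23), 3 * sqrt(0.23 * 0.77 / nrow(tr)))
  esc <- tr$true_xi_fraction[tr$true_status %in% c("escape", "escape_ts")]
  ratio <- esc / (1 - esc)
  expect_lt(abs(mean(ratio) - 0.33), 0.05)
  expect_true(all(esc < 0.5))  # Xi never exceeds Xa by construction
})

test_that("single-cell generator respects skew and consistency", {
  cfg <- sim_config(n_genes = 10, n_cells = 30, skew = 1, seed = 3)
  sc <- simulate_single_cells(cfg)
  expect_true(all(sc$truth$cells$active_hap == 1))

  # no dropout, no miscall, no escape: every cell perfectly haplotype-consistent
  cfg <- sim_config(n_genes = 10, n_cells = 20, skew = 0.5, dropout_rate = 0,
                    miscall_rate = 0, escape_fraction = 0,
                    tissue_specific_escape_fraction = 0,
                    include_xist = FALSE, seed = 3)
  sc <- simulate_single_cells(cfg)
  tab <- merge(sc$counts, sc$truth$sites, by = "site_id")
  tab <- merge(tab, sc$truth$cells, by.x = "unit_id", by.y = "cell_id")
  expressed <- ifelse(tab$ref_count > 0, tab$ref_allele, tab$alt_allele)
  active_allele <- ifelse(tab$active_hap == 1, tab$hap1_allele,
                          ifelse(tab$hap1_allele == tab$ref_allele,
                                 tab$alt_allele, tab$ref_allele))
  expect_true(all(tab$ref_count == 0 | tab$alt_count == 0))
  expect_true(all(expressed == active_allele))
})

test_that("realized cell split is binomially consistent with the skew", {
  cfg <- sim_config(n_genes = 5, n_cells = 688, skew = 0.54, seed = 12)
  sc <- simulate_single_cells(cfg)
  n1 <- sum(sc$truth$cells$active_hap == 1)
  expect_lt(abs(n1 / 688 - 0.54), 3 * sqrt(0.54 * 0.46 / 688))
})

test_that("sex-expression generator encodes the dosage model", {
  cfg <- sim_config(n_genes = 30, n_par1_genes = 4, n_tissues = 1,
                    n_samples_per_sex = 10, seed = 6)
  se <- simulate_sex_expression(cfg)
  tr <- se$truth
  par <- tr[tr$true_status == "par", ]
  # female:male ratio (1 + r) / 2 with r = Xi/Xa; at r = 0.8 this is 0.9
  expect_equal(par$expected_fm_ratio,
               rep((1 + 0.8) / 2, 4), tolerance = 1e-9)
  expect_true(all(tr$expected_fm_ratio[tr$true_status == "inactive"] == 1))
  expect_true(all(tr$expected_fm_ratio[tr$true_status == "autosomal"] == 1))
  esc <- tr[tr$true_status %in% c("escape", "escape_ts"), ]
  r <- esc$true_xi_fraction / (1 - esc$true_xi_fraction)
  expect_equal(esc$expected_fm_ratio, 1 + r, tolerance = 1e-9)
})

test_that("chromatin coverage rows sum to one and encode the planted shift", {
  ch <- simulate_chromatin_coverage(n_escape = 20, n_inactive = 50, seed = 9)
  expect_equal(unname(rowSums(ch$coverage)), rep(1, 70), tolerance = 1e-12)
  expect_true(all(ch$coverage >= 0 & ch$coverage <= 1))
  mean_esc <- colMeans(ch$coverage[ch$labels == "escape", ])
  mean_in <- colMeans(ch$coverage[ch$labels == "inactive", ])
  expect_true(all(mean_esc[ch$shift_states] > mean_in[ch$shift_states]))
})

test_that("simulated VCF output is readable by the VCF parser", {
  cfg <- sim_config(n_genes = 15, seed = 10)
  sim <- simulate_skewed_donor(cfg)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(sim$phased, f, sample = "DONOR")
  suppressMessages(back <- read_phased_vcf(f, "DONOR"))
  expect_equal(nrow(back), nrow(sim$phased))
  expect_equal(back$hap_a, sim$phased$hap_a)
  expect_equal(back$hap_b, sim$phased$hap_b)
  expect_true(all(back$phased))
})
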