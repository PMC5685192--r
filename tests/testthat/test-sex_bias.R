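sexbias_fixture <- function(seed = 3, n_genes = 80, n_tissues = 6) {
  cfg <- sim_config(n_genes = n_genes, n_tissues = n_tissues,
                    n_samples_per_sex = 50, seed = seed)
  se <- simulate_sex_expression(cfg)
  catalog <- data.frame(
    gene_id = se$truth$gene_id,
    status = ifelse(se$truth$true_status %in% c("escape", "escape_ts"),
                    "escape",
                    ifelse(se$truth$true_status == "inactive",
                           "inactive", "absent")))
  list(se = se, de = run_differential_expression(se$counts, se$samples),
       catalog = catalog)
}

test_that("null expression shows no sex bias; planted shifts are recovered", {
  # all genes unbiased
  cfg <- sim_config(n_genes = 40, n_tissues = 2, n_samples_per_sex = 60,
                    escape_fraction = 0, tissue_specific_escape_fraction = 0,
                    include_xist = FALSE, seed = 19)
  se <- simulate_sex_expression(cfg)
  de <- run_differential_expression(se$counts, se$samples)
  expect_lt(mean(de$q_value < 0.01), 0.01)

  # a 2-fold female-shifted gene is detected with the right direction
  set.seed(20)
  counts <- matrix(rnbinom(2000 * 100, mu = 200, size = 10), nrow = 2000,
                   dimnames = list(sprintf("g%04d", 1:2000), NULL))
  samples <- data.frame(sample = paste0("s", 1:100),
                        sex = rep(c("male", "female"), each = 50),
                        tissue = "T01")
  colnames(counts) <- samples$sample
  counts["g0001", samples$sex == "female"] <-
    rnbinom(50, mu = 400, size = 10)
  de <- run_differential_expression(counts, samples)
  hit <- de[de$gene_id == "g0001", ]
  expect_equal(hit$effect_direction, "female_higher")
  expect_lt(hit$q_value, 0.01)

  # constant-zero gene never passes the expression filter
  counts["g0002", ] <- 0
  de <- run_differential_expression(counts, samples)
  expect_false("g0002" %in% de$gene_id)

  one_sex <- samples; one_sex$sex <- "male"
  expect_error(run_differential_expression(counts, one_sex), "one sex")
})

test_that("per-category proportions are counted per tissue", {
  de <- data.frame(
    gene_id = rep(c("e1", "e2", "i1", "i2"), 2),
    tissue = rep(c("t1", "t2"), each = 4),
    effect_size = 1, effect_direction = "female_higher",
    q_value = c(0.001, 0.5, 0.5, 0.5,   0.001, 0.001, 0.001, 0.5),
    expressed = TRUE)
  catalog <- data.frame(gene_id = c("e1", "e2", "i1", "i2"),
                        status = c("escape", "escape", "inactive", "inactive"))
  pr <- proportion_sexbiased_by_category(de, catalog)
  get <- function(t, s) pr$proportion[pr$tissue == t & pr$status == s]
  expect_equal(get("t1", "escape"), 0.5)
  expect_equal(get("t1", "inactive"), 0)
  expect_equal(get("t2", "escape"), 1.0)
  expect_equal(get("t2", "inactive"), 0.5)

  # category with zero assessed genes is NA, not 0
  cat2 <- rbind(catalog, data.frame(gene_id = "v1", status = "variable"))
  pr2 <- proportion_sexbiased_by_category(de, cat2)
  expect_true(all(is.na(pr2$proportion[pr2$status == "variable"])))
})

test_that("paired category comparison reaches the 29-tissue extreme", {
  tissues <- sprintf("t%02d", 1:29)
  pr <- rbind(
    data.frame(tissue = tissues, status = "escape", n_assessed = 10,
               n_significant = 8, proportion = seq(0.5, 0.9, length.out = 29)),
    data.frame(tissue = tissues, status = "inactive", n_assessed = 10,
               n_significant = 1, proportion = seq(0.01, 0.2, length.out = 29)))
  res <- paired_category_comparison(pr, "escape", "inactive")
  expect_equal(res$p_value, 2 / 2^29, tolerance = 1e-12)

  pr$proportion[pr$status == "inactive"] <- pr$proportion[pr$status == "escape"]
  expect_error(paired_category_comparison(pr, "escape", "inactive"), "zero")
})

test_that("direction-bias test reduces genes to one direction", {
  de <- data.frame(
    gene_id = rep(c("g1", "g2", "g3"), each = 3),
    tissue = rep(c("t1", "t2", "t3"), 3),
    effect_size = c(1, 1, -1,   -1, -1, -1,   1, -1, 1),
    effect_direction = c("female_higher", "female_higher", "male_higher",
                         "male_higher", "male_higher", "male_higher",
                         "female_higher", "male_higher", "female_higher"),
    q_value = c(0.001, 0.001, 0.5,   0.001, 0.5, 0.5,   0.5, 0.5, 0.5),
    expressed = TRUE)
  res <- direction_bias_test(de, c("g1", "g2", "g3"))
  # g1 female (2 sig female), g2 male (1 sig male), g3 female (fallback 2/3)
  expect_equal(attr(res, "n_female_higher"), 2L)
  expect_equal(res$n, 3L)
  expect_error(direction_bias_test(de, "nope"), "no assessed")

  # two-sided symmetry: k of n and n-k of n give the same p
  expect_equal(binom_test_exact(15, 15, 0.5, "two_sided")$p_value,
               2 * 2^-15, tolerance = 1e-12)
  expect_equal(binom_test_exact(12, 40, 0.5, "two_sided")$p_value,
               binom_test_exact(28, 40, 0.5, "two_sided")$p_value)
})

test_that("direction consistency scores concordance with tie at 0.5", {
  mk <- function(g, dirs) data.frame(
    gene_id = g, tissue = paste0("t", seq_along(dirs)), effect_size = 1,
    effect_direction = dirs, q_value = 0.5, expressed = TRUE)
  de <- rbind(mk("g1", rep("female_higher", 10)),
              mk("g2", rep(c("female_higher", "male_higher"), 5)),
              mk("g3", c(rep("female_higher", 9), "male_higher")),
              mk("g4", rep("female_higher", 3)))
  cc <- direction_consistency(de, min_tissues = 5)
  got <- setNames(cc$concordance, cc$gene_id)
  expect_equal(got[["g1"]], 1.0)
  expect_equal(got[["g2"]], 0.5)
  expect_equal(got[["g3"]], 0.9)
  expect_false("g4" %in% cc$gene_id)  # below min_tissues
})

test_that("escape-like flagging needs concordance and significance together", {
  mk <- function(g, q1) data.frame(
    gene_id = g, tissue = paste0("t", 1:10), effect_size = 1,
    effect_direction = "female_higher",
    q_value = c(q1, rep(0.5, 9)), expressed = TRUE)
  de <- rbind(mk("chm", 0.001), mk("quiet", 0.5), mk("esc", 0.001))
  catalog <- data.frame(gene_id = c("chm", "quiet", "esc"),
                        status = c("inactive", "inactive", "escape"))
  fl <- flag_escape_like(de, catalog)
  got <- setNames(fl$flagged, fl$gene_id)
  expect_true(got[["chm"]])    # concordant + significant, catalogued inactive
  expect_false(got[["quiet"]]) # concordant but never significant
  expect_false(got[["esc"]])   # already catalogued escape
})

test_that("escape-like flagging recovers detectable planted escape genes", {
  fx <- sexbias_fixture(seed = 37)
  fl <- flag_escape_like(fx$de,
                         data.frame(gene_id = fx$catalog$gene_id,
                                    status = "inactive"))
  flagged <- fl$gene_id[fl$flagged]
  # sensitivity is assessed on escapers with a detectable dosage effect
  # (expected female:male ratio >= 1.2) at this sample size
  tr <- fx$se$truth
  detectable <- tr$gene_id[tr$true_status %in% c("escape", "escape_ts") &
                             tr$expected_fm_ratio >= 1.2]
  expect_gt(mean(detectable %in% flagged), 0.8)
  ina_true <- fx$catalog$gene_id[fx$catalog$status == "inactive"]
  expect_lt(mean(ina_true %in% flagged), 0.05)
})

test_that("X+Y combined re-test offsets or flips apparent female bias", {
  set.seed(41)
  n <- 60
  samples <- data.frame(sample = paste0("s", 1:(2 * n)),
                        sex = rep(c("male", "female"), each = n),
                        tissue = "T01")
  male <- samples$sex == "male"
  base <- matrix(rnbinom(500 * 2 * n, mu = 300, size = 20), nrow = 500,
                 dimnames = list(sprintf("bg%03d", 1:500), samples$sample))
  mk_gene <- function(mu_m, mu_f) {
    out <- numeric(2 * n)
    out[male] <- rnbinom(n, mu = mu_m, size = 20)
    out[!male] <- rnbinom(n, mu = mu_f, size = 20)
    out
  }
  counts <- rbind(base,
    X_off  = mk_gene(100, 150),  # female-biased X member
    Y_off  = mk_gene(50, 0),     # Y output exactly offsets it
    X_flip = mk_gene(100, 120),
    Y_flip = mk_gene(80, 0),     # Y output exceeds the female surplus
    X_sil  = mk_gene(100, 150),
    Y_sil  = c(rep(0, 2 * n)))   # silent Y: identical to X-only test

  pairs <- data.frame(x_gene = c("X_off", "X_flip", "X_sil"),
                      y_gene = c("Y_off", "Y_flip", "Y_sil"))
  de_x <- run_differential_expression(counts, samples)
  de_xy <- xy_combined_retest(counts, samples, pairs)
  getq <- function(de, g) de$q_value[de$gene_id == g]
  getd <- function(de, g) de$effect_direction[de$gene_id == g]

  expect_lt(getq(de_x, "X_off"), 0.01)            # biased before combining
  expect_gt(de_xy$p_value[de_xy$gene_id == "X_off"], 0.05)  # offset to null
  expect_equal(getd(de_xy, "X_flip"), "male_higher")        # flips
  expect_equal(getd(de_xy, "X_sil"), getd(de_x, "X_sil"))   # unchanged
  expect_equal(de_xy$effect_size[de_xy$gene_id == "X_sil"],
               de_x$effect_size[de_x$gene_id == "X_sil"], tolerance = 0.02)

  expect_error(xy_combined_retest(counts, samples,
                                  data.frame(x_gene = "X_off", y_gene = "NOPE")),
               "unmatched")
})
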