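#' Run the synthetic end-to-end pipeline
#'
#' One-command demo and orchestration entry point: generates synthetic
#' inputs, runs the skewed-donor and single-cell XCI callers and the
#' sex-bias category statistics, writes every output as TSV/JSON under
#' `out_dir`, and records a manifest with file hashes, the config
#' snapshot, the seed and the package version. Stage outputs produced
#' before a failure are retained and the manifest marks the failure.
#'
#' @param config a list (or path to a YAML file) with optional elements
#'   `seed`, `out_dir`, `stages` (subset of `"donor"`, `"cells"`,
#'   `"sexbias"`, `"chromatin"`), and per-stage config blocks `sim`
#'   (arguments to [sim_config()]), `calling` ([calling_config()]),
#'   `sc_calling` ([sc_calling_config()]).
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% "xci_pipeline_out"
  stages <- config$stages %||% c("donor", "cells", "sexbias", "chromatin")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "ground_truth"), showWarnings = FALSE)
  cfg_sim <- do.call(sim_config, utils::modifyList(list(seed = seed),
                                                   config$sim %||% list()))
  ccfg <- do.call(calling_config, config$calling %||% list())
  sccfg <- do.call(sc_calling_config, config$sc_calling %||% list())
  files <- character(0)
  status <- "ok"
  add <- function(path) { files <<- c(files, path); path }

  res <- tryCatch({
    if ("donor" %in% stages) {
      sim <- simulate_skewed_donor(cfg_sim)
      write_allele_counts(sim$counts, add(file.path(out_dir, "donor_ase.tsv")))
      write_phased_vcf(sim$phased, add(file.path(out_dir, "donor_phased.vcf")))
      jsonlite::write_json(sim$truth,
                           add(file.path(out_dir, "ground_truth", "donor.json")),
                           dataframe = "columns", digits = NA)
      filtered <- apply_site_filters(sim$counts, site_filter_config())
      calls <- donor_call_xci(filtered, sim$genes, ccfg)
      utils::write.table(calls$calls, add(file.path(out_dir, "donor_xci_calls.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if ("cells" %in% stages) {
      scfg <- utils::modifyList(cfg_sim, list(n_genes = 25L, n_sites = NULL))
      class(scfg) <- "xci_sim_config"
      sc <- simulate_single_cells(scfg)
      write_allele_counts(sc$counts, add(file.path(out_dir, "cells_ase.tsv")))
      jsonlite::write_json(sc$truth,
                           add(file.path(out_dir, "ground_truth", "cells.json")),
                           dataframe = "columns", digits = NA)
      run <- sc_call_xci(sc$counts, sc$genes, phased = NULL, config = sccfg,
                         seed = seed)
      utils::write.table(run$calls, add(file.path(out_dir, "sc_xci_calls.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(run$assignments,
                         add(file.path(out_dir, "cell_assignments.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if ("sexbias" %in% stages) {
      ecfg <- utils::modifyList(cfg_sim, list(n_genes = 100L, n_tissues = 8L))
      class(ecfg) <- "xci_sim_config"
      se <- simulate_sex_expression(ecfg)
      de <- run_differential_expression(se$counts, se$samples)
      cat <- data.frame(gene_id = se$truth$gene_id,
                        status = ifelse(se$truth$true_status %in%
                                          c("escape", "escape_ts"), "escape",
                                        ifelse(se$truth$true_status == "inactive",
                                               "inactive", "absent")))
      props <- proportion_sexbiased_by_category(de, cat)
      utils::write.table(de, add(file.path(out_dir, "sexbias_de.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(props, add(file.path(out_dir, "sexbias_proportions.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if ("chromatin" %in% stages) {
      ch <- simulate_chromatin_coverage(seed = seed)
      enr <- permutation_calibration(ch$coverage, ch$labels, n_perm = 1000,
                                     seed = seed)
      utils::write.table(enr, add(file.path(out_dir, "chromatin_enrichment.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(res)) status <- paste("failed:", res)

  manifest <- list(
    status = status, seed = seed,
    package_version = as.character(utils::packageVersion("xciase")),
    config = config,
    outputs = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (status != "ok") stop("pipeline ", status)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
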