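#' End-to-end pipeline stages
#'
#' Thin orchestration over the analysis modules, used by the command-line
#' dispatcher in \code{inst/cli/panmhc} and by the reproduction scripts.
#' Every stochastic stage takes an explicit seed; outputs are plain TSV /
#' FASTA / JSON files plus a JSON run manifest, so a run is fully
#' reproducible from its manifest.
#'
#' @name pipeline
NULL

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the simulate stage: write a simulated dataset to disk
#'
#' @param config a \code{simulation_config} (e.g.
#'   \code{\link{two_taxon_scenario}})
#' @param out_dir output directory (created if missing)
#' @return invisibly, the \code{simulated_dataset}
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- simulate_dataset(config)
  write_genotype_table(ds$genotypes, file.path(out_dir, "genotypes.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ds$sequences),
                              file.path(out_dir, "alleles_aligned.fasta"))
  truth <- do.call(rbind, lapply(names(ds$truth), function(l) data.frame(
    locus = l, taxon = ds$truth[[l]]$taxon,
    expected_pi_exons = ds$truth[[l]]$expected_pi_exons)))
  write_tsv(truth, file.path(out_dir, "truth.tsv"))
  jsonlite::write_json(list(stage = "simulate", seed = config$seed,
                            K = config$K, taxa = config$taxa),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(ds)
}

#' Run the catalog stage on a dataset
#'
#' @param gt a \code{genotype_table}
#' @param scopes named list of taxon filters
#' @param out_dir output directory
#' @return invisibly, the count table
#' @export
run_catalog <- function(gt, scopes, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ct <- build_count_table(gt, scopes)
  write_tsv(ct, file.path(out_dir, "counts.tsv"))
  invisible(ct)
}

#' Run the diversity stage on a simulated dataset
#'
#' @param ds a \code{simulated_dataset}
#' @param out_dir output directory
#' @return invisibly, the tidy diversity table
#' @export
run_diversity <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scopes <- stats::setNames(as.list(ds$config$taxa$label), ds$config$taxa$label)
  tab <- diversity_scan(ds$genotypes, ds$sequences, ds$models, scopes)
  write_tsv(tab, file.path(out_dir, "diversity.tsv"))
  invisible(tab)
}

#' Run the permutation-test stage between the two taxa of a dataset
#'
#' @param ds a \code{simulated_dataset} with exactly two taxa
#' @param n_perm,alpha,n_tests,seed see \code{\link{permutation_scan}}
#' @param out_dir output directory
#' @return invisibly, the \code{permutation_scan} result
#' @export
run_permtest <- function(ds, out_dir, n_perm = 10000L, alpha = 0.05,
                         n_tests = NULL, seed = ds$config$seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  taxa <- ds$config$taxa
  stopifnot(nrow(taxa) == 2L)
  base <- unique(vapply(ds$truth, function(t) t$base_locus, character(1)))
  comparisons <- data.frame(
    locus1 = paste0(taxa$prefix[1], "-", base),
    locus2 = paste0(taxa$prefix[2], "-", base),
    taxa1 = taxa$label[1], taxa2 = taxa$label[2],
    stringsAsFactors = FALSE)
  sc <- permutation_scan(ds$genotypes, ds$sequences, comparisons, ds$models,
                         n_perm = n_perm, alpha = alpha, n_tests = n_tests,
                         seed = seed)
  write_tsv(sc$results, file.path(out_dir, "permtest.tsv"))
  jsonlite::write_json(sc$manifest, file.path(out_dir, "permtest_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sc)
}

#' Run the replicate-QC stage on a dataset with replicate call sets
#'
#' @param ds a \code{simulated_dataset} generated with
#'   \code{artifact_rate > 0}
#' @param out_dir output directory
#' @return invisibly, the combined QC report
#' @export
run_qc <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(ds$replicates))
    stop("dataset has no replicate call sets (artifact_rate was 0)")
  rep <- do.call(rbind, lapply(names(ds$replicates), function(locus)
    qc_scan(ds$replicates[[locus]]$calls, ds$models[[locus]])))
  write_tsv(rep, file.path(out_dir, "qc_report.tsv"))
  invisible(rep)
}
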