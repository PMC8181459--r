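# End-to-end analysis pipeline: forensic statistics -> pairwise R_ST ->
# ordination -> neighbor-joining tree -> (optional) haplogroup prediction,
# with a reproducibility manifest.

.write_report_tables <- function(report, out_dir) {
  pl <- file.path(out_dir, "forensic_per_locus.tsv")
  sm <- file.path(out_dir, "forensic_summary.tsv")
  utils::write.table(report$per_locus, pl, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$summary, sm, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(pl, sm)
}

#' Run the full Y-STR analysis pipeline
#'
#' Reproduces the standard analysis flow on any haplotype table: forensic
#' report, pairwise population R_ST with permutation p-values, PCA and MDS
#' of the population allele-frequency matrix, a neighbor-joining tree of the
#' R_ST matrix (when >= 3 populations are present), optional haplogroup
#' prediction against a reference panel, and a manifest recording every
#' parameter, the seed, and md5 checksums of all inputs and outputs. The run
#' is deterministic given the configuration and seed.
#'
#' @param input Path to a haplotype table, or a [ystr_table()].
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed for the permutation tests (mandatory).
#' @param panel A [ystr_panel()], or path to a panel config; default
#'   [ppy23_panel()].
#' @param permutations Permutations per population pair (default 999).
#' @param metric MDS metric, `"euclidean"` or `"manhattan"`.
#' @param axes Ordination axes to retain (default 2, capped at what the
#'   population count allows).
#' @param reference Optional [reference_panel()] or path to a panel file;
#'   enables haplogroup prediction of all input haplotypes.
#' @param k Neighbors for haplogroup prediction (default 5).
#' @param min_confidence Assignment threshold (default 0.6).
#' @param overwrite Allow writing into a non-empty `out_dir` (default
#'   `FALSE`).
#' @return Invisibly, a named list of the written file paths.
#' @export
run_pipeline <- function(input, out_dir, seed, panel = ppy23_panel(),
                         permutations = 999,
                         metric = c("euclidean", "manhattan"), axes = 2,
                         reference = NULL, k = 5, min_confidence = 0.6,
                         overwrite = FALSE) {
  metric <- match.arg(metric)
  if (missing(seed)) .ystr_error("invalid_parameter", "seed is required")
  if (is.character(panel)) panel <- read_panel_config(panel)
  input_path <- NULL
  if (is.character(input)) {
    input_path <- input
    input <- read_haplotype_table(input, panel)
  }
  stopifnot(inherits(input, "ystr_table"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    .ystr_error("invalid_parameter",
                "output directory %s is not empty (use overwrite = TRUE)", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage <- function(name) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
  paths <- list()
  run_stage <- function(name, expr) {
    stage(name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  report <- run_stage("forensic statistics", forensic_report(input))
  paths$forensic <- .write_report_tables(report, out_dir)

  rst <- run_stage("pairwise R_ST",
                   pairwise_rst(input, n_permutations = permutations, seed = seed))
  paths$rst <- file.path(out_dir, "rst_matrix.tsv")
  write_distance_matrix(rst$rst, paths$rst)
  paths$rst_p <- file.path(out_dir, "rst_pvalues.tsv")
  write_distance_matrix(rst$p_value, paths$rst_p)

  fm <- run_stage("frequency matrix", build_frequency_matrix(input))
  kax <- min(axes, nrow(fm) - 1L, ncol(fm))
  pca <- run_stage("PCA", pca_ordination(fm, k = kax))
  paths$pca <- write_ordination(pca, file.path(out_dir, "pca_coordinates.tsv"))
  mds <- run_stage("MDS", classical_mds(population_distance(fm, metric), k = kax))
  paths$mds <- write_ordination(mds, file.path(out_dir, "mds_coordinates.tsv"))

  if (length(populations(input)) >= 3) {
    tree <- run_stage("neighbor joining", neighbor_joining(rst$rst))
    paths$tree <- file.path(out_dir, "nj_tree.nwk")
    to_newick(tree, path = paths$tree)
  } else {
    stage("neighbor joining skipped (< 3 populations)")
  }

  if (!is.null(reference)) {
    if (is.character(reference)) reference <- read_reference_panel(reference, panel)
    pred <- run_stage("haplogroup prediction",
                      predict_haplogroup(input, reference, k = k,
                                         min_confidence = min_confidence))
    paths$predictions <- file.path(out_dir, "predictions.tsv")
    utils::write.table(pred, paths$predictions, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  out_files <- unlist(paths, use.names = FALSE)
  manifest <- list(
    package = "ystrpopgen",
    version = as.character(utils::packageVersion("ystrpopgen")),
    parameters = list(seed = seed, permutations = permutations,
                      metric = metric, axes = kax, k = k,
                      min_confidence = min_confidence),
    input = list(path = input_path, n_samples = n_samples(input),
                 populations = as.list(table(input$population))),
    outputs = as.list(tools::md5sum(out_files))
  )
  paths$manifest <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, paths$manifest)
  stage(sprintf("done (%.1f s)", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(paths)
}
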