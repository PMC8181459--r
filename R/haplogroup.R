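# Nearest-neighbor Y-haplogroup prediction against a labeled reference
# panel. The classifier is an explicit, auditable k-NN over squared
# repeat-count distances; haplogroup names are opaque strings (no ISOGG
# tree logic).

#' Construct a haplogroup reference panel
#'
#' @param table A [ystr_table()] of reference haplotypes.
#' @param labels Character vector of haplogroup names, one per sample (or a
#'   named vector keyed by sample id).
#' @return Object of class `reference_panel`: list with `table` and `labels`
#'   (aligned to `table$sample_id`).
#' @export
reference_panel <- function(table, labels) {
  stopifnot(inherits(table, "ystr_table"))
  if (!is.null(names(labels))) labels <- labels[table$sample_id]
  labels <- as.character(labels)
  if (length(labels) != n_samples(table) || any(is.na(labels) | labels == ""))
    .ystr_error("validation", "every reference sample needs a haplogroup label")
  structure(list(table = table,
                 labels = stats::setNames(labels, table$sample_id)),
            class = "reference_panel")
}

#' Read a haplogroup reference panel file
#'
#' Same delimited format as [read_haplotype_table()] plus a `Haplogroup`
#' column.
#'
#' @param path File path.
#' @param panel A [ystr_panel()]; defaults to [ppy23_panel()].
#' @return A [reference_panel()].
#' @export
read_reference_panel <- function(path, panel = ppy23_panel()) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(), comment.char = "")
  if (!"Haplogroup" %in% names(df))
    .ystr_error("validation", "reference panel file lacks a Haplogroup column")
  labels <- df$Haplogroup
  df$Haplogroup <- NULL
  reference_panel(ystr_table(df, panel), labels)
}

#' Write a reference panel to delimited text
#' @param x A [reference_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_panel <- function(x, path) {
  stopifnot(inherits(x, "reference_panel"))
  df <- data.frame(SampleID = x$table$sample_id,
                   Population = x$table$population,
                   Haplogroup = unname(x$labels),
                   x$table$calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Predict Y-haplogroups by k-nearest-neighbor matching
#'
#' For each query haplotype, the k references nearest by squared
#' repeat-count distance ([repeat_distance_sq()]; multi-copy loci excluded)
#' vote on the haplogroup; the majority label is returned with its vote
#' fraction as confidence. Queries whose confidence falls below
#' `min_confidence` are reported `"unassigned"`. All tie rules are
#' order-free: neighbor ties are resolved by sample id, label ties by
#' smaller mean distance then lexicographic label, so permuting panel rows
#' never changes predictions.
#'
#' @param queries A [ystr_table()] of query haplotypes (same panel as the
#'   references).
#' @param panel A [reference_panel()].
#' @param k Number of neighbors (default 5).
#' @param min_confidence Vote fraction below which a query is left
#'   unassigned (default 0.6).
#' @return data.frame with columns `sample_id`, `haplogroup`, `confidence`,
#'   `mean_distance` (mean squared distance to the voting neighbors).
#' @export
predict_haplogroup <- function(queries, panel, k = 5, min_confidence = 0.6) {
  stopifnot(inherits(queries, "ystr_table"), inherits(panel, "reference_panel"))
  if (n_samples(panel$table) == 0)
    .ystr_error("empty_panel", "reference panel is empty")
  if (!identical(queries$panel$loci, panel$table$panel$loci))
    .ystr_error("panel_mismatch", "query and reference locus panels differ")
  if (k < 1 || k > n_samples(panel$table))
    .ystr_error("invalid_parameter", "k must be in 1..%d", n_samples(panel$table))
  qm <- .distance_allele_matrix(queries)
  rm_ <- .distance_allele_matrix(panel$table)
  ref_order <- order(panel$table$sample_id)
  out <- lapply(seq_len(nrow(qm)), function(qi) {
    diffs <- sweep(rm_, 2, qm[qi, ])^2
    d <- rowSums(diffs, na.rm = TRUE)
    # order-free neighbor selection: distance, then sample id
    nb <- ref_order[order(d[ref_order])][seq_len(k)]
    votes <- table(panel$labels[nb])
    top <- max(votes)
    cands <- names(votes)[votes == top]
    if (length(cands) > 1) {
      md <- vapply(cands, function(lb)
        mean(d[nb][panel$labels[nb] == lb]), 0)
      cands <- cands[md == min(md)]
      cands <- sort(cands)
    }
    label <- cands[1]
    conf <- top / k
    data.frame(sample_id = queries$sample_id[qi],
               haplogroup = if (conf < min_confidence) "unassigned" else label,
               confidence = conf,
               mean_distance = mean(d[nb][panel$labels[nb] == label]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize predicted haplogroup frequencies
#'
#' @param predictions A [predict_haplogroup()] result.
#' @return Object of class `haplogroup_spectrum`: data.frame with columns
#'   `haplogroup`, `count`, `percent` (over assigned samples, summing to
#'   100), plus attributes `n_unassigned` and `assignment_rate` (percent of
#'   queries assigned).
#' @export
haplogroup_spectrum <- function(predictions) {
  if (!nrow(predictions))
    .ystr_error("validation", "no predictions")
  assigned <- predictions[predictions$haplogroup != "unassigned", ]
  tab <- sort(table(assigned$haplogroup), decreasing = TRUE)
  res <- data.frame(haplogroup = names(tab), count = as.integer(tab),
                    percent = 100 * as.integer(tab) / nrow(assigned),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, n_unassigned = nrow(predictions) - nrow(assigned),
            assignment_rate = 100 * nrow(assigned) / nrow(predictions),
            class = c("haplogroup_spectrum", "data.frame"))
}

#' @export
print.haplogroup_spectrum <- function(x, ...) {
  cat(sprintf("Haplogroup spectrum: %.2f%% of queries assigned (%d unassigned)\n",
              attr(x, "assignment_rate"), attr(x, "n_unassigned")))
  df <- as.data.frame(x)
  df$percent <- round(df$percent, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
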