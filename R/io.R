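# Haplotype table container and delimited-text I/O.

# Header aliases accepted for the combined DYS385a/b column.
.normalize_locus_names <- function(x) {
  x <- sub("^DYS385a[/.]b$", "DYS385ab", x, ignore.case = FALSE)
  x
}

#' Construct a Y-STR haplotype table
#'
#' A haplotype table holds one row per male: a unique sample identifier, a
#' population label, and one allele call per panel locus. Calls are stored as
#' exact designation strings; multi-copy loci hold the unordered allele
#' multiset sorted ascending and comma-joined (`"13,17"`); missing calls are
#' `NA`.
#'
#' @param data A data.frame with columns `SampleID`, `Population`, then one
#'   column per panel locus (any order). Multi-copy cells may join values
#'   with `","` or `"-"`. `""`, `"0"` and `NA` denote missing calls.
#' @param panel A [ystr_panel()]; defaults to [ppy23_panel()].
#' @return An object of class `ystr_table`: a list with elements `panel`,
#'   `sample_id`, `population`, and `calls` (character matrix, samples x loci).
#' @export
ystr_table <- function(data, panel = ppy23_panel()) {
  names(data) <- .normalize_locus_names(names(data))
  need <- c("SampleID", "Population")
  if (!all(need %in% names(data)))
    .ystr_error("unknown_locus", "table must have SampleID and Population columns")
  missing_loci <- setdiff(panel$loci, names(data))
  if (length(missing_loci))
    .ystr_error("unknown_locus", "missing locus column(s): %s",
                paste(missing_loci, collapse = ", "))
  extra <- setdiff(names(data), c(need, panel$loci))
  if (length(extra))
    .ystr_error("unknown_locus", "unknown column(s): %s",
                paste(extra, collapse = ", "))
  sample_id <- as.character(data$SampleID)
  if (anyDuplicated(sample_id))
    .ystr_error("duplicate_id", "duplicate sample id(s): %s",
                paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  population <- as.character(data$Population)
  if (any(is.na(population) | population == ""))
    .ystr_error("invalid_parameter", "empty population label")
  n <- nrow(data)
  calls <- matrix(NA_character_, n, length(panel$loci),
                  dimnames = list(sample_id, panel$loci))
  for (loc in panel$loci) {
    mc <- loc %in% panel$multicopy_loci
    calls[, loc] <- vapply(data[[loc]], .parse_cell, character(1),
                           locus = loc, multicopy = mc, USE.NAMES = FALSE)
  }
  structure(list(panel = panel, sample_id = sample_id,
                 population = population, calls = calls),
            class = "ystr_table")
}

#' @export
print.ystr_table <- function(x, ...) {
  cat("Y-STR haplotype table:", length(x$sample_id), "samples,",
      length(x$panel$loci), "locus columns\n")
  tab <- table(x$population)
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of samples in a haplotype table
#' @param x A `ystr_table`.
#' @export
n_samples <- function(x) length(x$sample_id)

#' Population labels of a haplotype table
#' @param x A `ystr_table`.
#' @return Character vector of distinct population labels, in order of first
#'   appearance.
#' @export
populations <- function(x) unique(x$population)

#' Subset a haplotype table by row
#' @param x A `ystr_table`.
#' @param i Row indices or a logical vector.
#' @param ... Ignored.
#' @export
`[.ystr_table` <- function(x, i, ...) {
  structure(list(panel = x$panel, sample_id = x$sample_id[i],
                 population = x$population[i],
                 calls = x$calls[i, , drop = FALSE]),
            class = "ystr_table")
}

#' Read a haplotype table from delimited text
#'
#' Expects a header row naming `SampleID`, `Population` and the panel loci in
#' any order; tab- or comma-delimited is auto-detected from the header line.
#' Multi-copy loci (e.g. DYS385a/b, written `DYS385ab`) occupy one column
#' with comma- or hyphen-joined values. `""` and `"0"` are read as missing.
#'
#' @param path Path to the delimited file.
#' @param panel A [ystr_panel()]; defaults to [ppy23_panel()].
#' @return A [ystr_table()].
#' @export
read_haplotype_table <- function(path, panel = ppy23_panel()) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(), comment.char = "")
  ystr_table(df, panel)
}

#' Write a haplotype table to delimited text
#'
#' Writes a tab-delimited file (the default interchange dialect) that
#' [read_haplotype_table()] reads back field-identically: allele designations
#' are emitted exactly as stored, multi-copy multisets comma-joined, missing
#' calls as empty fields.
#'
#' @param x A [ystr_table()].
#' @param path Output file path.
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "ystr_table"))
  df <- data.frame(SampleID = x$sample_id, Population = x$population,
                   x$calls, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = sep == ",",
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Canonical haplotype identity keys
#'
#' Two haplotypes receive equal keys iff they carry equal allele multisets at
#' every panel locus; copy order at multi-copy loci is ignored (it is already
#' canonicalized on parse). Keys define the identity used to count distinct
#' haplotypes.
#'
#' @param x A [ystr_table()].
#' @param allow_missing If `FALSE` (default) any haplotype with a missing
#'   call raises a missing-data error, since identity is undefined for
#'   partial profiles; if `TRUE`, such haplotypes get `NA` keys.
#' @return Character vector of keys, one per sample.
#' @export
haplotype_key <- function(x, allow_missing = FALSE) {
  stopifnot(inherits(x, "ystr_table"))
  incomplete <- apply(is.na(x$calls), 1L, any)
  if (any(incomplete) && !allow_missing)
    .ystr_error("missing_data",
                "haplotype identity undefined for %d sample(s) with missing calls",
                sum(incomplete))
  keys <- apply(x$calls, 1L, function(row)
    paste(paste0(colnames(x$calls), "=", row), collapse = "|"))
  keys[incomplete] <- NA_character_
  unname(keys)
}
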