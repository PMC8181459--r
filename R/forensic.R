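# Per-locus and haplotype-level forensic parameters.
#
# Haplotype-level statistics (HD, MP, DC, FUH) all factor through the
# occurrence spectrum: the map multiplicity -> number of distinct haplotypes
# observed that many times, which is a sufficient statistic for them.

#' Occurrence spectrum of haplotype multiplicities
#'
#' @param counts Named integer vector: names are multiplicities (how many
#'   times a haplotype was observed), values the number of distinct
#'   haplotypes with that multiplicity. E.g. `c("1" = 208, "2" = 18,
#'   "3" = 4, "4" = 1)` for a sample of 260 with 231 distinct haplotypes.
#' @return An object of class `occurrence_spectrum` with fields `counts`,
#'   `n` (sample size, `sum(m * counts)`) and `k` (distinct haplotypes,
#'   `sum(counts)`).
#' @export
occurrence_spectrum <- function(counts) {
  m <- as.numeric(names(counts))
  cnt <- as.numeric(counts)
  if (!length(cnt) || any(is.na(m)) || any(m < 1) || any(m != round(m)) ||
      any(cnt < 0) || any(cnt != round(cnt)) || sum(cnt) < 1)
    .ystr_error("validation", "invalid occurrence spectrum")
  keep <- cnt > 0
  m <- m[keep]; cnt <- cnt[keep]
  o <- order(m)
  structure(list(counts = stats::setNames(as.integer(cnt[o]), m[o]),
                 n = as.integer(sum(m * cnt)), k = as.integer(sum(cnt))),
            class = "occurrence_spectrum")
}

#' @export
print.occurrence_spectrum <- function(x, ...) {
  cat("Occurrence spectrum: n =", x$n, ", distinct haplotypes k =", x$k, "\n")
  print(x$counts)
  invisible(x)
}

#' Haplotype occurrence spectrum of a table
#'
#' Groups complete haplotypes (no missing calls) by [haplotype_key()] and
#' tabulates how many distinct haplotypes occur once, twice, and so on.
#'
#' @param x A [ystr_table()].
#' @param population Optional label restricting to one population.
#' @return An [occurrence_spectrum()].
#' @export
haplotype_spectrum <- function(x, population = NULL) {
  stopifnot(inherits(x, "ystr_table"))
  if (!is.null(population)) x <- x[x$population == population]
  keys <- haplotype_key(x, allow_missing = TRUE)
  keys <- keys[!is.na(keys)]
  if (!length(keys))
    .ystr_error("empty_table", "no complete haplotypes")
  occurrence_spectrum(table(table(keys)))
}

#' Match probability
#'
#' MP = sum of squared haplotype frequencies: the probability that two males
#' drawn at random from the sample share a haplotype.
#'
#' @param s An [occurrence_spectrum()].
#' @return MP, in `[1/n, 1]`.
#' @export
match_probability <- function(s) {
  stopifnot(inherits(s, "occurrence_spectrum"))
  m <- as.numeric(names(s$counts))
  sum(s$counts * m^2) / s$n^2
}

#' Haplotype diversity
#'
#' HD = n/(n-1) * (1 - sum p_i^2) over haplotype frequencies, the
#' bias-corrected probability that two males differ in haplotype.
#'
#' @param s An [occurrence_spectrum()].
#' @return HD in `[0, 1]`.
#' @export
haplotype_diversity <- function(s) {
  stopifnot(inherits(s, "occurrence_spectrum"))
  if (s$n < 2)
    .ystr_error("undefined_diversity", "haplotype diversity needs n >= 2")
  s$n / (s$n - 1) * (1 - match_probability(s))
}

#' Discrimination capacity
#'
#' DC = distinct haplotypes / sample size.
#'
#' @param s An [occurrence_spectrum()].
#' @return DC in `(0, 1]`.
#' @export
discrimination_capacity <- function(s) {
  stopifnot(inherits(s, "occurrence_spectrum"))
  s$k / s$n
}

#' Fraction of unique haplotypes
#'
#' FUH = singleton haplotypes / distinct haplotypes.
#'
#' @param s An [occurrence_spectrum()].
#' @return FUH in `[0, 1]`.
#' @export
unique_haplotype_fraction <- function(s) {
  stopifnot(inherits(s, "occurrence_spectrum"))
  singletons <- if ("1" %in% names(s$counts)) s$counts[["1"]] else 0L
  singletons / s$k
}

#' Per-locus allele frequencies
#'
#' Frequencies of observed allele designations at one locus, over the
#' non-missing calls of one population (or the whole table). At a multi-copy
#' locus the default unit is the canonical sorted combination (the single-GD
#' treatment of DYS385a/b); `per_value = TRUE` instead counts the individual
#' allele values.
#'
#' @param x A [ystr_table()].
#' @param locus Locus name.
#' @param population Optional label restricting to one population.
#' @param per_value Count individual values at multi-copy loci.
#' @return An object of class `allele_freqs`: list with `locus`, `counts`
#'   (named integer), `freqs` (named numeric summing to 1), `n` (calls) and
#'   `k` (distinct designations).
#' @export
allele_frequencies <- function(x, locus, population = NULL, per_value = FALSE) {
  stopifnot(inherits(x, "ystr_table"))
  if (!locus %in% x$panel$loci)
    .ystr_error("unknown_locus", "unknown locus '%s'", locus)
  if (!is.null(population)) x <- x[x$population == population]
  cells <- x$calls[, locus]
  cells <- cells[!is.na(cells)]
  if (!length(cells))
    .ystr_error("empty_locus", "no calls at locus %s", locus)
  units <- if (per_value) unlist(strsplit(cells, ",", fixed = TRUE)) else cells
  counts <- table(units)
  counts <- counts[order(vapply(names(counts),
                                function(a) .cell_numeric(a)[1], 0),
                         names(counts))]
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(locus = locus, counts = counts,
                 freqs = counts / sum(counts),
                 n = sum(counts), k = length(counts)),
            class = "allele_freqs")
}

#' Gene diversity at a locus
#'
#' GD = n/(n-1) * (1 - sum P_i^2), the Y-chromosome analogue of expected
#' heterozygosity, over the allele frequencies P_i at one locus.
#'
#' @param freqs An [allele_frequencies()] result.
#' @return GD in `[0, 1]`; 0 iff the locus is monomorphic.
#' @export
gene_diversity <- function(freqs) {
  stopifnot(inherits(freqs, "allele_freqs"))
  if (freqs$n < 2)
    .ystr_error("undefined_diversity", "gene diversity needs n >= 2 calls")
  freqs$n / (freqs$n - 1) * (1 - sum(freqs$freqs^2))
}

#' Full forensic report for a haplotype table
#'
#' Per population: per-locus call counts, distinct-allele counts and gene
#' diversity, plus the haplotype-level summary (distinct haplotypes, FUH,
#' HD, MP, DC). Haplotype-level statistics exclude samples with any missing
#' call; per-locus statistics use each locus's available calls.
#'
#' @param x A [ystr_table()].
#' @return An object of class `forensic_report`: list with data.frames
#'   `per_locus` (population, locus, n_calls, n_alleles, n_allele_values,
#'   gene_diversity) and `summary` (population, n, n_complete, k, fuh, hd,
#'   mp, dc). Values are unrounded; the print method shows 4 decimals.
#' @export
forensic_report <- function(x) {
  stopifnot(inherits(x, "ystr_table"))
  pops <- populations(x)
  per_locus <- do.call(rbind, lapply(pops, function(p) {
    do.call(rbind, lapply(x$panel$loci, function(loc) {
      af <- allele_frequencies(x, loc, population = p)
      nv <- if (loc %in% x$panel$multicopy_loci)
        allele_frequencies(x, loc, population = p, per_value = TRUE)$k
      else af$k
      data.frame(population = p, locus = loc, n_calls = af$n,
                 n_alleles = af$k, n_allele_values = nv,
                 gene_diversity = if (af$n >= 2) gene_diversity(af) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  summary <- do.call(rbind, lapply(pops, function(p) {
    s <- haplotype_spectrum(x, population = p)
    data.frame(population = p, n = sum(x$population == p), n_complete = s$n,
               k = s$k, fuh = unique_haplotype_fraction(s),
               hd = if (s$n >= 2) haplotype_diversity(s) else NA_real_,
               mp = match_probability(s), dc = discrimination_capacity(s),
               stringsAsFactors = FALSE)
  }))
  rownames(per_locus) <- rownames(summary) <- NULL
  structure(list(per_locus = per_locus, summary = summary),
            class = "forensic_report")
}

#' @export
print.forensic_report <- function(x, digits = 4, ...) {
  cat("Forensic report\n\nHaplotype-level summary:\n")
  s <- x$summary
  s[c("fuh", "hd", "dc")] <- lapply(s[c("fuh", "hd", "dc")], round, digits)
  s$mp <- signif(s$mp, 3)
  print(s, row.names = FALSE)
  cat("\nPer-locus gene diversity (first rows):\n")
  pl <- x$per_locus
  pl$gene_diversity <- round(pl$gene_diversity, digits)
  print(utils::head(pl, 10), row.names = FALSE)
  if (nrow(pl) > 10) cat("  ...", nrow(pl) - 10, "more rows\n")
  invisible(x)
}
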