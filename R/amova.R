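# Squared repeat-count distances, one-level AMOVA, R_ST and permutation
# p-values.
#
# R_ST is the Phi-statistic of an AMOVA whose inter-individual distances are
# summed squared repeat-count differences, the microsatellite-specific
# differentiation statistic appropriate for stepwise-mutating Y-STRs.

# Numeric allele matrix over the panel's distance loci (samples x loci).
# Multi-copy loci listed in distance_loci are expanded into sorted-copy
# pseudo-columns (rank within the multiset as a proxy for copy orthology);
# the default panels keep them out of distance_loci entirely.
.distance_allele_matrix <- function(x, truncate_microvariants = FALSE) {
  cols <- lapply(x$panel$distance_loci, function(loc) {
    if (loc %in% x$panel$multicopy_loci) {
      vals <- lapply(x$calls[, loc], .cell_numeric)
      width <- max(1L, vapply(vals, length, 1L))
      m <- t(vapply(vals, function(v) c(v, rep(NA_real_, width - length(v))),
                    numeric(width)))
      colnames(m) <- paste0(loc, ".", seq_len(width))
      m
    } else {
      m <- matrix(suppressWarnings(as.numeric(x$calls[, loc])), ncol = 1,
                  dimnames = list(NULL, loc))
      m
    }
  })
  m <- do.call(cbind, cols)
  rownames(m) <- x$sample_id
  if (truncate_microvariants) m <- floor(m)
  m
}

#' Squared repeat-count distance between two haplotypes
#'
#' Sum over the panel's distance loci of the squared numeric allele
#' difference. Multi-copy loci are excluded (their unordered pairs lack copy
#' orthology). Loci missing in either haplotype are skipped (pairwise
#' deletion); the number of skipped loci is attached as attribute
#' `n_deleted`.
#'
#' @param x A [ystr_table()].
#' @param i,j Row indices of the two haplotypes.
#' @param truncate_microvariants If `TRUE`, microvariant designations are
#'   floored to their integer repeat count (19.1 -> 19); by default they
#'   enter at face numeric value (19.1 - 19 = 0.1).
#' @return Non-negative number; 0 iff the two haplotypes agree on every
#'   compared distance locus.
#' @export
repeat_distance_sq <- function(x, i, j, truncate_microvariants = FALSE) {
  m <- .distance_allele_matrix(x, truncate_microvariants = truncate_microvariants)
  diff <- m[i, ] - m[j, ]
  deleted <- is.na(diff)
  structure(sum(diff[!deleted]^2), n_deleted = sum(deleted))
}

#' All pairwise squared repeat-count distances of a table
#'
#' @param x A [ystr_table()].
#' @param truncate_microvariants See [repeat_distance_sq()].
#' @return Symmetric matrix of squared distances with zero diagonal, labeled
#'   by sample id; attribute `n_deleted_pairs` counts (pair, locus)
#'   combinations dropped by pairwise deletion.
#' @export
pairwise_sq_distances <- function(x, truncate_microvariants = FALSE) {
  m <- .distance_allele_matrix(x, truncate_microvariants = truncate_microvariants)
  n <- nrow(m)
  d2 <- matrix(0, n, n, dimnames = list(x$sample_id, x$sample_id))
  deleted <- 0L
  for (l in seq_len(ncol(m))) {
    v <- m[, l]
    dd <- outer(v, v, `-`)^2
    nas <- is.na(dd)
    if (any(nas)) {
      deleted <- deleted + (sum(nas) - sum(is.na(v))) / 2
      dd[nas] <- 0
    }
    d2 <- d2 + dd
  }
  structure(d2, n_deleted_pairs = as.integer(deleted))
}

# Core one-level AMOVA from a squared-distance matrix and a grouping factor.
# Returns ss/ms/variance components and rst; used directly by permutations.
.amova_from_d2 <- function(d2, fac) {
  fac <- as.factor(fac)
  N <- length(fac)
  G <- nlevels(fac)
  ng <- as.numeric(table(fac))
  ss_total <- sum(d2) / (2 * N)
  ss_within <- 0
  for (g in levels(fac)) {
    idx <- which(fac == g)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_among <- ss_total - ss_within
  df_among <- G - 1
  df_within <- N - G
  ms_among <- ss_among / df_among
  ms_within <- if (df_within > 0) ss_within / df_within else 0
  n0 <- (N - sum(ng^2) / N) / (G - 1)
  var_among <- (ms_among - ms_within) / n0
  var_within <- ms_within
  denom <- var_among + var_within
  list(ss_among = ss_among, ss_within = ss_within,
       df_among = df_among, df_within = df_within,
       var_among = var_among, var_within = var_within,
       rst = if (denom == 0) NA_real_ else var_among / denom)
}

#' AMOVA R_ST for a grouped haplotype table
#'
#' One-level analysis of molecular variance on squared repeat-count
#' distances: partitions total variation into among- and within-population
#' variance components and reports their Phi-statistic, R_ST. Haplotypes
#' with all distance-locus calls missing are excluded.
#'
#' @param x A [ystr_table()] with >= 2 populations and >= 3 usable samples.
#' @param grouping Optional vector of group labels (default: the table's
#'   population labels).
#' @param truncate_microvariants See [repeat_distance_sq()].
#' @return An object of class `rst_result`: list with `ss_among`,
#'   `ss_within`, `df_among`, `df_within`, `var_among`, `var_within`, `rst`.
#'   `rst` may be negative on undifferentiated data (interpreted as 0).
#' @export
amova_rst <- function(x, grouping = NULL, truncate_microvariants = FALSE) {
  stopifnot(inherits(x, "ystr_table"))
  fac <- if (is.null(grouping)) x$population else as.character(grouping)
  if (length(fac) != n_samples(x))
    .ystr_error("invalid_parameter", "grouping length != number of samples")
  m <- .distance_allele_matrix(x, truncate_microvariants = truncate_microvariants)
  usable <- rowSums(!is.na(m)) > 0
  if (any(!usable)) {
    lost <- unique(fac[!usable])
    keep_groups <- unique(fac[usable])
    if (length(setdiff(lost, keep_groups)))
      .ystr_error("degenerate_group", "group(s) with no usable haplotypes: %s",
                  paste(setdiff(lost, keep_groups), collapse = ", "))
    x <- x[usable]; fac <- fac[usable]
  }
  if (length(unique(fac)) < 2)
    .ystr_error("invalid_parameter", "AMOVA needs >= 2 groups")
  if (n_samples(x) < 3)
    .ystr_error("invalid_parameter", "AMOVA needs >= 3 haplotypes")
  d2 <- pairwise_sq_distances(x, truncate_microvariants = truncate_microvariants)
  res <- .amova_from_d2(d2, fac)
  if (is.na(res$rst))
    .ystr_error("undefined_rst", "all haplotypes identical: R_ST undefined")
  structure(res, class = "rst_result")
}

#' @export
print.rst_result <- function(x, ...) {
  cat("AMOVA R_ST\n")
  cat(sprintf("  SS among: %.6g (df %d)   SS within: %.6g (df %d)\n",
              x$ss_among, x$df_among, x$ss_within, x$df_within))
  cat(sprintf("  var among: %.6g   var within: %.6g\n",
              x$var_among, x$var_within))
  cat(sprintf("  R_ST = %.6g", x$rst))
  if (!is.null(x$p_value))
    cat(sprintf("   (p = %.4g, %d permutations)", x$p_value, x$n_permutations))
  cat("\n")
  invisible(x)
}

#' Pairwise population R_ST matrix with permutation p-values
#'
#' For every pair of populations, computes R_ST by one-level AMOVA and a
#' permutation p-value obtained by shuffling individuals between the two
#' populations: `p = (1 + #\{perm R_ST >= observed\}) / (1 + n_permutations)`
#' (add-one estimator).
#'
#' @param x A [ystr_table()] with >= 2 populations.
#' @param n_permutations Number of label permutations per pair (default
#'   9999).
#' @param seed Integer seed governing all permutations (mandatory).
#' @param truncate_microvariants See [repeat_distance_sq()].
#' @return List of class `pairwise_rst` with symmetric matrices `rst`
#'   (negative estimates floored at 0, zero diagonal), `rst_raw` (unfloored),
#'   `p_value` (diagonal `NA`), plus `n_permutations` and `seed`.
#' @export
pairwise_rst <- function(x, n_permutations = 9999, seed,
                         truncate_microvariants = FALSE) {
  stopifnot(inherits(x, "ystr_table"))
  if (n_permutations < 1)
    .ystr_error("invalid_parameter", "n_permutations must be >= 1")
  if (missing(seed)) .ystr_error("invalid_parameter", "seed is required")
  pops <- populations(x)
  if (length(pops) < 2)
    .ystr_error("invalid_parameter", "need >= 2 populations")
  d2 <- pairwise_sq_distances(x, truncate_microvariants = truncate_microvariants)
  P <- length(pops)
  rst_raw <- matrix(0, P, P, dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  withr::with_seed(seed, {
    for (a in seq_len(P - 1)) for (b in seq((a + 1), P)) {
      idx <- which(x$population %in% pops[c(a, b)])
      sub_d2 <- d2[idx, idx]
      fac <- x$population[idx]
      obs <- .amova_from_d2(sub_d2, fac)$rst
      if (is.na(obs))
        .ystr_error("undefined_rst",
                    "R_ST undefined for pair %s/%s (identical data)",
                    pops[a], pops[b])
      ge <- 0L
      for (p in seq_len(n_permutations)) {
        perm <- .amova_from_d2(sub_d2, sample(fac))$rst
        if (!is.na(perm) && perm >= obs) ge <- ge + 1L
      }
      rst_raw[a, b] <- rst_raw[b, a] <- obs
      pmat[a, b] <- pmat[b, a] <- (1 + ge) / (1 + n_permutations)
    }
  })
  structure(list(rst = pmax(rst_raw, 0), rst_raw = rst_raw, p_value = pmat,
                 n_permutations = as.integer(n_permutations), seed = seed),
            class = "pairwise_rst")
}

#' @export
print.pairwise_rst <- function(x, digits = 4, ...) {
  cat("Pairwise R_ST (", x$n_permutations, "permutations, seed", x$seed, ")\n")
  cat("R_ST (negative estimates floored at 0):\n")
  print(round(x$rst, digits))
  cat("p-values:\n")
  print(round(x$p_value, digits))
  invisible(x)
}

#' Read or write a distance matrix
#'
#' Two interchange formats: `"tsv"` — square tab-delimited with a header row
#' and a leading label column; `"phylip"` — PHYLIP square format (first line
#' the number of taxa, then one row per taxon: label followed by distances).
#'
#' @param d Symmetric numeric matrix with identical row/column labels.
#' @param path File path.
#' @param format `"tsv"` (default) or `"phylip"`; `read_distance_matrix()`
#'   auto-detects.
#' @return `write_distance_matrix()` returns `path` invisibly;
#'   `read_distance_matrix()` returns a labeled symmetric matrix.
#' @export
write_distance_matrix <- function(d, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(label = rownames(d), d, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("%5d", nrow(d)), con)
    for (i in seq_len(nrow(d)))
      writeLines(paste(c(rownames(d)[i],
                         sprintf("%.10g", d[i, ])), collapse = "  "), con)
  }
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  first <- trimws(readLines(path, n = 1L))
  if (grepl("^[0-9]+$", first)) {  # PHYLIP square
    n <- as.integer(first)
    rows <- utils::read.table(path, skip = 1, header = FALSE,
                              stringsAsFactors = FALSE)
    labels <- as.character(rows[[1]])
    d <- as.matrix(rows[, -1, drop = FALSE])
    dimnames(d) <- list(labels, labels)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    labels <- as.character(df[[1]])
    d <- as.matrix(df[, -1, drop = FALSE])
    dimnames(d) <- list(labels, labels)
  }
  storage.mode(d) <- "double"
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    .ystr_error("invalid_matrix", "distance matrix in %s is not square symmetric", path)
  d
}
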