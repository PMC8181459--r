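# Population x allele frequency matrices, PCA, and classical (Torgerson) MDS.

#' Build a population x allele frequency matrix
#'
#' One row per population, one column per (locus, allele designation)
#' observed anywhere; entries are within-population frequencies over the
#' locus's non-missing calls, zero-filled where an allele was not observed.
#' Columns are ordered by panel locus order, then allele ascending, so the
#' matrix is deterministic. At multi-copy loci the unit is the canonical
#' sorted combination.
#'
#' @param x A [ystr_table()] holding >= 2 populations, or a list of
#'   `ystr_table`s on the same panel (one or more populations each).
#' @return Numeric matrix (populations x allele columns) with column names
#'   `"locus:allele"` and attribute `locus` mapping columns to loci.
#' @export
build_frequency_matrix <- function(x) {
  tables <- if (inherits(x, "ystr_table")) list(x) else x
  stopifnot(all(vapply(tables, inherits, TRUE, "ystr_table")))
  panel <- tables[[1]]$panel
  for (t in tables[-1])
    if (!identical(t$panel$loci, panel$loci))
      .ystr_error("panel_mismatch", "tables use different locus panels")
  freq_sets <- list()
  for (t in tables) for (p in populations(t)) {
    if (p %in% names(freq_sets))
      .ystr_error("invalid_parameter", "population label '%s' appears twice", p)
    freq_sets[[p]] <- lapply(stats::setNames(panel$loci, panel$loci),
                             function(loc) allele_frequencies(t, loc, p))
  }
  if (length(freq_sets) < 2)
    .ystr_error("invalid_parameter", "need >= 2 populations")
  cols <- unlist(lapply(panel$loci, function(loc) {
    alleles <- unique(unlist(lapply(freq_sets, function(fs)
      names(fs[[loc]]$freqs))))
    alleles <- alleles[order(vapply(alleles, function(a) .cell_numeric(a)[1], 0),
                             alleles)]
    stats::setNames(paste0(loc, ":", alleles), rep(loc, length(alleles)))
  }))
  m <- matrix(0, length(freq_sets), length(cols),
              dimnames = list(names(freq_sets), unname(cols)))
  for (p in names(freq_sets)) for (loc in panel$loci) {
    f <- freq_sets[[p]][[loc]]$freqs
    m[p, paste0(loc, ":", names(f))] <- as.numeric(f)
  }
  attr(m, "locus") <- stats::setNames(names(cols), unname(cols))
  m
}

# Flip axis signs so each axis's largest-magnitude element is positive
# (run-to-run and platform stability).
.fix_signs <- function(coords, reference = coords) {
  for (j in seq_len(ncol(coords))) {
    v <- reference[, j]
    if (v[which.max(abs(v))] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

#' Principal component analysis of a frequency matrix
#'
#' PCA on column-centered, unscaled frequencies (frequencies share a scale,
#' so no unit-variance scaling): singular value decomposition of the
#' centered matrix, with explained fractions the squared singular values
#' over total variance. Axis signs follow the convention that the
#' largest-magnitude loading on each axis is positive.
#'
#' @param m A [build_frequency_matrix()] result (or any numeric matrix with
#'   row labels).
#' @param k Number of axes to retain (default 2); at most
#'   `min(nrow - 1, ncol)`.
#' @return Object of class `ystr_ordination`: list with `coordinates`
#'   (rows x k), `explained` (variance fractions, non-increasing),
#'   `loadings`, `method = "pca"`.
#' @export
pca_ordination <- function(m, k = 2) {
  if (nrow(m) < 2)
    .ystr_error("invalid_parameter", "PCA needs >= 2 rows")
  kmax <- min(nrow(m) - 1L, ncol(m))
  if (k < 1 || k > kmax)
    .ystr_error("invalid_parameter", "k must be in 1..%d", kmax)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  explained_all <- pc$sdev^2 / sum(pc$sdev^2)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  coords <- .fix_signs(pc$x[, seq_len(k), drop = FALSE], rot)
  loadings <- .fix_signs(rot, rot)
  dimnames(coords) <- list(rownames(m), paste0("PC", seq_len(k)))
  structure(list(coordinates = coords,
                 explained = explained_all[seq_len(k)],
                 loadings = loadings, method = "pca", metric = NA_character_,
                 negative_eigenvalue_mass = 0),
            class = "ystr_ordination")
}

#' Row distances of a frequency matrix
#'
#' @param m Numeric matrix with row labels (typically from
#'   [build_frequency_matrix()]).
#' @param metric `"euclidean"` (L2) or `"manhattan"` (L1).
#' @return Symmetric labeled distance matrix with zero diagonal.
#' @export
population_distance <- function(m, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (nrow(m) < 2)
    .ystr_error("invalid_parameter", "need >= 2 rows")
  as.matrix(stats::dist(m, method = metric))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Metric MDS by double-centering of the squared-distance matrix and
#' eigendecomposition; deterministic, no random starts. Coordinates come
#' from the top-k non-negative eigenpairs; negative eigenvalues (possible
#' for non-Euclidean inputs such as Manhattan distances) are truncated and
#' their total magnitude reported, never silently dropped.
#'
#' @param d Symmetric distance matrix with labels (e.g. from
#'   [population_distance()] or [pairwise_rst()]`$rst`).
#' @param k Number of axes (default 2); at most `nrow(d) - 1`.
#' @return Object of class `ystr_ordination`: `coordinates` (rows x k,
#'   zero-padded beyond the positive rank), `explained` (shares of the
#'   positive eigenvalue mass), `eigenvalues` (all), and
#'   `negative_eigenvalue_mass`.
#' @export
classical_mds <- function(d, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2 || ncol(d) != n)
    .ystr_error("invalid_matrix", "need a square matrix with >= 2 rows")
  if (max(abs(d - t(d))) > 1e-8)
    .ystr_error("invalid_matrix", "distance matrix is not symmetric")
  if (k < 1 || k > n - 1)
    .ystr_error("invalid_parameter", "k must be in 1..%d", n - 1)
  if (all(d == 0)) {
    coords <- matrix(0, n, k, dimnames = list(rownames(d),
                                              paste0("Dim", seq_len(k))))
    return(structure(list(coordinates = coords, explained = rep(0, k),
                          eigenvalues = rep(0, n), method = "mds",
                          metric = NA_character_,
                          negative_eigenvalue_mass = 0),
                     class = "ystr_ordination"))
  }
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE))
  eig <- fit$eig
  pos <- pmax(eig, 0)
  pts <- fit$points
  coords <- matrix(0, n, k, dimnames = list(rownames(d),
                                            paste0("Dim", seq_len(k))))
  if (!is.null(pts) && ncol(pts) > 0)
    coords[, seq_len(ncol(pts))] <- .fix_signs(pts)
  structure(list(coordinates = coords,
                 explained = (pos / sum(pos))[seq_len(k)],
                 eigenvalues = eig, method = "mds", metric = NA_character_,
                 negative_eigenvalue_mass = sum(abs(pmin(eig, 0)))),
            class = "ystr_ordination")
}

#' @export
print.ystr_ordination <- function(x, digits = 4, ...) {
  cat(toupper(x$method), "ordination:", nrow(x$coordinates), "entities,",
      ncol(x$coordinates), "axes\n")
  cat("  explained:", paste(sprintf("%.2f%%", 100 * x$explained),
                            collapse = ", "), "\n")
  if (x$negative_eigenvalue_mass > 0)
    cat("  truncated negative eigenvalue mass:",
        format(x$negative_eigenvalue_mass, digits = digits), "\n")
  print(round(x$coordinates, digits))
  invisible(x)
}

#' Write ordination coordinates to a delimited file
#'
#' @param x A `ystr_ordination`.
#' @param path Output path (tab-delimited; one row per entity, plus a
#'   trailing comment line with the explained fractions).
#' @return `path`, invisibly.
#' @export
write_ordination <- function(x, path) {
  df <- data.frame(label = rownames(x$coordinates), x$coordinates,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("# explained\t%s\n",
              paste(format(x$explained, digits = 10), collapse = "\t")),
      file = path, append = TRUE)
  invisible(path)
}
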