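# Neighbor-joining tree construction from distance matrices.
#
# The agglomeration is implemented here so that tie-breaking and
# negative-branch handling are fully specified and bit-stable; trees are
# returned as ape "phylo" objects and serialized via Newick.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining: repeatedly join the pair (i, j) minimizing
#' `Q(i,j) = (r - 2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` (r = current
#' number of clusters), with branch lengths from the rate-corrected split
#' formula. Exact on additive matrices. Determinism guarantees: Q-ties are
#' broken by the lowest (i, j) index pair, and negative branch lengths are
#' clamped to 0 with the total clamped deficit recorded (attribute
#' `clamp_deficit`; 0 on additive inputs).
#'
#' @param d Symmetric distance matrix with >= 3 labeled rows (e.g. a
#'   pairwise R_ST matrix).
#' @return An unrooted `phylo` object (ape) with attribute `clamp_deficit`.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3)
    .ystr_error("too_few_taxa", "neighbor joining needs >= 3 taxa")
  if (ncol(d) != n || max(abs(d - t(d))) > 1e-8)
    .ystr_error("invalid_matrix", "input is not a square symmetric matrix")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # build with placeholder tip names, restore the real labels on the phylo
  # object afterwards (labels may hold characters unsafe inside Newick)
  placeholders <- paste0("zz", seq_len(n), "zz")
  deficit <- 0
  clamp <- function(b) {
    if (b < 0) { deficit <<- deficit - b; 0 } else b
  }
  fmt <- function(b) sprintf("%.15g", b)
  # each active cluster: a newick fragment
  frag <- placeholders
  D <- d
  while (length(frag) > 3) {
    r <- length(frag)
    rs <- rowSums(D)
    Q <- (r - 2) * D - outer(rs, rs, `+`)
    diag(Q) <- Inf
    # lowest (i, j), i < j, among minima
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    bi <- clamp(D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2)))
    bj <- clamp(D[i, j] - (D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))))
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(bi), frag[j], fmt(bj))
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
  }
  # closed-form resolution of the final three clusters
  b1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  b3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frag[1], fmt(b1), frag[2], fmt(b2), frag[3], fmt(b3))
  tree <- ape::read.tree(text = newick)
  tree$tip.label <- labels[match(tree$tip.label, placeholders)]
  attr(tree, "clamp_deficit") <- deficit
  tree
}

#' Serialize a tree to Newick
#'
#' Delegates to [ape::write.tree()], which follows the usual Newick
#' conventions (spaces in labels become underscores).
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths (default 10).
#' @param path Optional file path; if given the string is also written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
to_newick <- function(tree, digits = 10, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
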