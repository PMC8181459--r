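# Fixtures built in code, plus independent oracles kept deliberately naive
# (explicit loops, no shared code with the package internals).

# Build a single-copy haplotype table from a numeric allele matrix.
make_table <- function(alleles, pops = "A", ids = NULL) {
  alleles <- as.matrix(alleles)
  n <- nrow(alleles)
  loci <- sprintf("L%02d", seq_len(ncol(alleles)))
  df <- data.frame(
    SampleID = if (is.null(ids)) sprintf("S%03d", seq_len(n)) else ids,
    Population = rep_len(pops, n), stringsAsFactors = FALSE)
  for (i in seq_along(loci)) df[[loci[i]]] <- alleles[, i]
  ystr_table(df, ystr_panel(loci))
}

# Small PowerPlex-style table (3 samples, 2 populations) written as the
# delimited text a submitting lab would produce.
ppy23_fixture_lines <- function() {
  pan <- ppy23_panel()
  single <- setdiff(pan$loci, "DYS385ab")
  vals1 <- c(14, 13, 29, 24, 10, 11, 12, 14, 10, 12, 19, 15, 17, 21, 12,
             22, 11, 12, 17, 19, 10)
  vals2 <- vals1; vals2[match("DYS576", single)] <- "19.1"
  vals3 <- vals1; vals3[1] <- 15
  row <- function(id, pop, d385, vals)
    paste(c(id, pop, d385, vals), collapse = "\t")
  header <- paste(c("SampleID", "Population", "DYS385ab", single),
                  collapse = "\t")
  c(header,
    row("S01", "Hakka", "13-17", vals1),
    row("S02", "Hakka", "13-17", vals2),
    row("S03", "She", "17,13", vals3))
}

write_ppy23_fixture <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(ppy23_fixture_lines(), path)
  path
}

# Independent brute-force AMOVA R_ST oracle: explicit pair loops over the
# squared repeat-count distances, variance components assembled directly.
oracle_rst <- function(alleles, pops) {
  alleles <- as.matrix(alleles)
  N <- nrow(alleles)
  d2 <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    d2[i, j] <- sum((alleles[i, ] - alleles[j, ])^2)
  ss_total <- 0
  for (i in seq_len(N - 1)) for (j in seq(i + 1, N))
    ss_total <- ss_total + d2[i, j]
  ss_total <- ss_total / N
  groups <- unique(pops)
  G <- length(groups)
  ss_within <- 0
  for (g in groups) {
    idx <- which(pops == g)
    ng <- length(idx)
    s <- 0
    if (ng >= 2)
      for (a in seq_len(ng - 1)) for (b in seq(a + 1, ng))
        s <- s + d2[idx[a], idx[b]]
    ss_within <- ss_within + s / ng
  }
  ss_among <- ss_total - ss_within
  ms_among <- ss_among / (G - 1)
  ms_within <- ss_within / (N - G)
  ng_all <- as.numeric(table(pops))
  n0 <- (N - sum(ng_all^2) / N) / (G - 1)
  var_among <- (ms_among - ms_within) / n0
  var_among / (var_among + ms_within)
}

# Direct Monte-Carlo oracle for the single-locus SMM random walk: one
# explicit per-generation loop, reflecting at allele 1.
oracle_smm_walk <- function(start, t, mu) {
  a <- start
  for (g in seq_len(t)) {
    if (stats::runif(1) < mu) {
      a <- a + (if (stats::runif(1) < 0.5) -1 else 1)
      if (a < 1) a <- 2 - a
    }
  }
  a
}
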