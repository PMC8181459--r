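# Synthetic Y-STR data: stepwise-mutation-model (SMM) evolution, tables
# realizing prescribed occurrence spectra, and labeled haplogroup reference
# panels with held-out queries.

# Apply n_mut single-step mutations to each allele (vectors aligned).
# Signs are iid +/-1; the walk reflects at allele 1 (a proposed step to 0 is
# mirrored to 2). When the walk cannot reach the boundary the net change is
# drawn in one shot from the sign-sum distribution, which is exact; the
# boundary case falls back to an explicit step-by-step walk.
.smm_apply <- function(alleles, n_mut) {
  out <- alleles
  hot <- which(n_mut > 0)
  if (!length(hot)) return(out)
  safe <- hot[alleles[hot] - n_mut[hot] >= 1]
  if (length(safe)) {
    m <- n_mut[safe]
    out[safe] <- alleles[safe] + 2 * stats::rbinom(length(safe), m, 0.5) - m
  }
  edge <- setdiff(hot, safe)
  for (i in edge) {
    a <- alleles[i]
    for (s in sample(c(-1L, 1L), n_mut[i], replace = TRUE)) {
      a <- a + s
      if (a < 1L) a <- 2L - a
    }
    out[i] <- a
  }
  out
}

# Evolve an allele matrix (rows = lineages, cols = loci) for t generations
# at per-locus per-generation mutation probability mu.
.smm_evolve <- function(alleles, t, mu) {
  if (t == 0 || mu == 0) return(alleles)
  n_mut <- matrix(stats::rbinom(length(alleles), t, mu), nrow = nrow(alleles))
  matrix(.smm_apply(as.vector(alleles), as.vector(n_mut)),
         nrow = nrow(alleles), dimnames = dimnames(alleles))
}

# Synthetic panel: n single-copy loci L01.. plus optionally one multi-copy
# locus LMC (two independently evolving copies, reported unordered).
.sim_panel <- function(n_loci, multicopy) {
  loci <- sprintf("L%02d", seq_len(n_loci))
  if (multicopy) ystr_panel(c(loci, "LMC"), multicopy_loci = "LMC")
  else ystr_panel(loci)
}

#' Simulate multi-population Y-STR haplotypes under the stepwise mutation
#' model
#'
#' Populations diverge in a star: one ancestral haplotype (all loci at
#' `ancestral_allele`) spawns one founder per population, each evolved
#' independently for `divergence_generations`; every individual then evolves
#' independently from its founder for `within_generations`. Per generation
#' and locus a mutation occurs with probability `mu` and shifts the allele
#' by +/-1 repeat (equal probability, reflecting at allele 1). The expected
#' squared allele difference between two populations at divergence t (and
#' within-depth 0) is `2 t mu`, the SMM variance-accumulation rate.
#'
#' @param n_populations Number of populations (default 2).
#' @param sample_sizes Integer vector of per-population sizes (recycled).
#' @param n_loci Number of single-copy loci (default 22).
#' @param mu Per-locus per-generation mutation probability (default 0.002,
#'   a typical Y-STR locus rate).
#' @param divergence_generations Generations from the star ancestor to each
#'   founder (scalar or per population).
#' @param within_generations Generations from a founder to each individual
#'   (default 0: individuals equal their founder).
#' @param ancestral_allele Ancestral repeat count at every locus (default 14).
#' @param multicopy Also simulate one multi-copy locus (two independent
#'   copies, reported as an unordered pair); default `TRUE`.
#' @param seed Integer seed (mandatory); the same seed reproduces the table
#'   byte-identically.
#' @return A [ystr_table()] with populations `Pop1..PopP`; attribute `truth`
#'   records the founders and all parameters.
#' @export
simulate_smm_populations <- function(n_populations = 2, sample_sizes = 50,
                                     n_loci = 22, mu = 0.002,
                                     divergence_generations = 1000,
                                     within_generations = 0,
                                     ancestral_allele = 14, multicopy = TRUE,
                                     seed) {
  if (missing(seed)) .ystr_error("validation", "seed is required")
  if (mu < 0 || mu > 1) .ystr_error("validation", "mu must be in [0, 1]")
  if (n_populations < 1 || n_loci < 1 || ancestral_allele < 1)
    .ystr_error("validation", "invalid simulation configuration")
  sizes <- rep_len(as.integer(sample_sizes), n_populations)
  if (any(sizes < 1)) .ystr_error("validation", "sample sizes must be >= 1")
  div <- rep_len(divergence_generations, n_populations)
  if (any(div < 0) || within_generations < 0)
    .ystr_error("validation", "generation counts must be >= 0")
  ncols <- n_loci + if (multicopy) 2L else 0L
  withr::with_seed(seed, {
    founders <- matrix(ancestral_allele, n_populations, ncols)
    for (p in seq_len(n_populations))
      founders[p, ] <- .smm_evolve(founders[p, , drop = FALSE], div[p], mu)
    rows <- lapply(seq_len(n_populations), function(p) {
      ind <- matrix(rep(founders[p, ], each = sizes[p]), nrow = sizes[p])
      .smm_evolve(ind, within_generations, mu)
    })
  })
  alleles <- do.call(rbind, rows)
  pop <- rep(paste0("Pop", seq_len(n_populations)), sizes)
  df <- data.frame(
    SampleID = sprintf("%s_%03d", pop,
                       unlist(lapply(sizes, seq_len))),
    Population = pop, stringsAsFactors = FALSE)
  for (l in seq_len(n_loci)) df[[sprintf("L%02d", l)]] <- alleles[, l]
  if (multicopy)
    df$LMC <- paste(pmin(alleles[, n_loci + 1], alleles[, n_loci + 2]),
                    pmax(alleles[, n_loci + 1], alleles[, n_loci + 2]),
                    sep = ",")
  tab <- ystr_table(df, .sim_panel(n_loci, multicopy))
  attr(tab, "truth") <- list(founders = founders, mu = mu,
                             divergence_generations = div,
                             within_generations = within_generations,
                             ancestral_allele = ancestral_allele, seed = seed)
  tab
}

#' Generate a haplotype table realizing an exact occurrence spectrum
#'
#' Constructs a table whose [haplotype_spectrum()] equals the requested
#' spectrum exactly: distinct haplotypes are guaranteed distinct by encoding
#' their index in the allele assignment (base-10 digits spread over the
#' single-copy loci, on top of seed-drawn per-locus base alleles), then each
#' is replicated to its multiplicity and rows are shuffled.
#'
#' @param spectrum An [occurrence_spectrum()] (or a named count vector
#'   accepted by it).
#' @param panel A [ystr_panel()]; defaults to [ppy23_panel()]. Must provide
#'   enough single-copy loci to encode the number of distinct haplotypes.
#' @param seed Integer seed (mandatory) governing base alleles, sample ids
#'   and row order.
#' @return A [ystr_table()] of `spectrum$n` samples in one population
#'   (`"PopA"`).
#' @export
generate_spectrum_table <- function(spectrum, panel = ppy23_panel(), seed) {
  if (missing(seed)) .ystr_error("validation", "seed is required")
  if (!inherits(spectrum, "occurrence_spectrum"))
    spectrum <- occurrence_spectrum(spectrum)
  single <- setdiff(panel$loci, panel$multicopy_loci)
  if (10^length(single) < spectrum$k)
    .ystr_error("validation", "panel too small to encode %d distinct haplotypes",
                spectrum$k)
  withr::with_seed(seed, {
    base <- sample(10:14, length(single), replace = TRUE)
    mults <- rep(as.numeric(names(spectrum$counts)), spectrum$counts)
    digits <- function(j) (j %/% 10^(seq_along(single) - 1)) %% 10
    hap <- t(vapply(seq_len(spectrum$k) - 1L,
                    function(j) base + digits(j), numeric(length(single))))
    rows <- hap[rep(seq_len(spectrum$k), mults), , drop = FALSE]
    ord <- sample(nrow(rows))
  })
  rows <- rows[ord, , drop = FALSE]
  df <- data.frame(SampleID = sprintf("S%04d", seq_len(nrow(rows))),
                   Population = "PopA", stringsAsFactors = FALSE)
  for (i in seq_along(single)) df[[single[i]]] <- rows[, i]
  for (mc in panel$multicopy_loci) df[[mc]] <- "13,17"
  ystr_table(df[, c("SampleID", "Population", panel$loci)], panel)
}

#' Generate a synthetic haplogroup reference panel with held-out queries
#'
#' Founder haplotypes, one per haplogroup, are constructed pairwise at least
#' `founders_min_separation` apart in summed squared repeat distance (each
#' founder shifts its own block of loci by +2 from the ancestral allele);
#' panel members and held-out queries are SMM perturbations of their founder
#' with `Poisson(within_noise_mu_t)` mutations per locus.
#'
#' @param n_haplogroups Number of haplogroups (default 6).
#' @param founders_min_separation Minimum pairwise squared distance between
#'   founders (default 8).
#' @param within_noise_mu_t Expected mutations per locus within a haplogroup
#'   (the mu x t product; default 0.05).
#' @param size_train Reference haplotypes per haplogroup (recycled to
#'   `n_haplogroups`).
#' @param size_test Held-out query haplotypes per haplogroup (recycled).
#' @param n_loci Number of single-copy loci (default 22).
#' @param ancestral_allele Default 14.
#' @param seed Integer seed (mandatory).
#' @return List with `panel` (a [reference_panel()]), `queries` (a
#'   [ystr_table()]), and `truth` (character vector of true haplogroup
#'   labels for the queries, named by sample id).
#' @export
generate_reference_panel <- function(n_haplogroups = 6,
                                     founders_min_separation = 8,
                                     within_noise_mu_t = 0.05,
                                     size_train = 50, size_test = 20,
                                     n_loci = 22, ancestral_allele = 14,
                                     seed) {
  if (missing(seed)) .ystr_error("validation", "seed is required")
  size_train <- rep_len(as.integer(size_train), n_haplogroups)
  size_test <- rep_len(as.integer(size_test), n_haplogroups)
  if (founders_min_separation <= 0 || any(size_train < 1) || any(size_test < 0))
    .ystr_error("validation", "invalid panel configuration")
  block <- ceiling(founders_min_separation / 8)
  if (block * n_haplogroups > n_loci)
    .ystr_error("constructive_failure",
                "cannot place %d founders >= %g apart with %d loci",
                n_haplogroups, founders_min_separation, n_loci)
  hg_names <- sprintf("HG%02d", seq_len(n_haplogroups))
  founders <- matrix(ancestral_allele, n_haplogroups, n_loci,
                     dimnames = list(hg_names, NULL))
  for (g in seq_len(n_haplogroups))
    founders[g, ((g - 1) * block + 1):(g * block)] <- ancestral_allele + 2
  perturb <- function(founder, n) {
    ind <- matrix(rep(founder, each = n), nrow = n)
    n_mut <- matrix(stats::rpois(length(ind), within_noise_mu_t), nrow = n)
    matrix(.smm_apply(as.vector(ind), as.vector(n_mut)), nrow = n)
  }
  withr::with_seed(seed, {
    train <- do.call(rbind, lapply(seq_len(n_haplogroups), function(g)
      perturb(founders[g, ], size_train[g])))
    test <- if (sum(size_test) > 0)
      do.call(rbind, lapply(seq_len(n_haplogroups), function(g)
        perturb(founders[g, ], size_test[g])))
  })
  pan <- .sim_panel(n_loci, multicopy = FALSE)
  as_table <- function(alleles, prefix, per_group) {
    labels <- rep(hg_names, per_group)
    df <- data.frame(
      SampleID = sprintf("%s_%s_%03d", prefix, labels,
                         unlist(lapply(per_group, seq_len))),
      Population = "Reference", stringsAsFactors = FALSE)
    for (l in seq_len(n_loci)) df[[sprintf("L%02d", l)]] <- alleles[, l]
    list(table = ystr_table(df, pan), labels = labels)
  }
  tr <- as_table(train, "R", size_train)
  out <- list(panel = reference_panel(tr$table, tr$labels),
              founders = founders)
  if (sum(size_test) > 0) {
    te <- as_table(test, "Q", size_test)
    te$table$population[] <- "Query"
    out$queries <- te$table
    out$truth <- stats::setNames(te$labels, te$table$sample_id)
  }
  out
}
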