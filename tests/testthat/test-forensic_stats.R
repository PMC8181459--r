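# Spectra printed for the two Guangdong samples (260 Hakka, 215 She);
# every haplotype-level statistic factors through these.
hakka_counts <- c("1" = 208, "2" = 18, "3" = 4, "4" = 1)
she_counts <- c("1" = 65, "2" = 43, "3" = 6, "4" = 5, "5" = 1, "6" = 1, "15" = 1)

test_that("allele frequencies are counts over non-missing calls", {
  tab <- make_table(cbind(c(10, 10, 11, 12)))
  af <- allele_frequencies(tab, "L01")
  expect_equal(af$freqs, c("10" = 0.5, "11" = 0.25, "12" = 0.25))
  expect_equal(af$n, 4)
  # one sample: single allele at frequency 1
  af1 <- allele_frequencies(make_table(cbind(14)), "L01")
  expect_equal(unname(af1$freqs), 1)
  # all-missing locus errors
  df <- data.frame(SampleID = "a", Population = "P", L01 = "",
                   stringsAsFactors = FALSE)
  tab2 <- ystr_table(df, ystr_panel("L01"))
  expect_error(allele_frequencies(tab2, "L01"), class = "ystr_empty_locus")
})

test_that("multi-copy loci expose both combination and per-value counts", {
  df <- data.frame(SampleID = c("a", "b", "c"), Population = "P",
                   MC = c("13-17", "17,13", "13-18"),
                   stringsAsFactors = FALSE)
  tab <- ystr_table(df, ystr_panel("MC", multicopy_loci = "MC"))
  comb <- allele_frequencies(tab, "MC")
  expect_equal(comb$freqs, c("13,17" = 2 / 3, "13,18" = 1 / 3))
  per <- allele_frequencies(tab, "MC", per_value = TRUE)
  expect_equal(per$freqs, c("13" = 0.5, "17" = 1 / 3, "18" = 1 / 6))
})

test_that("gene diversity follows n/(n-1)(1 - sum p^2)", {
  # monomorphic locus: 0
  expect_equal(gene_diversity(allele_frequencies(make_table(cbind(c(12, 12, 12))), "L01")), 0)
  # n = 2, two alleles: (2/1)(1 - 0.5) = 1
  expect_equal(gene_diversity(allele_frequencies(make_table(cbind(c(12, 13))), "L01")), 1)
  # {0.5, 0.25, 0.25} at n = 4: (4/3)(1 - 0.375)
  gd <- gene_diversity(allele_frequencies(make_table(cbind(c(10, 10, 11, 12))), "L01"))
  expect_equal(gd, (4 / 3) * (1 - 0.375))
  expect_error(gene_diversity(allele_frequencies(make_table(cbind(14)), "L01")),
               class = "ystr_undefined_diversity")
})

test_that("haplotype spectrum groups by canonical identity", {
  tab <- make_table(rbind(c(10, 11), c(10, 11), c(10, 11), c(10, 11)))
  s <- haplotype_spectrum(tab)
  expect_equal(s$counts, c("4" = 1L))
  expect_equal(c(s$n, s$k), c(4L, 1L))
  s3 <- haplotype_spectrum(make_table(rbind(c(10, 11), c(10, 12), c(11, 11))))
  expect_equal(s3$counts, c("1" = 3L))
})

test_that("printed Guangdong spectra yield the published MP, DC and FUH", {
  hakka <- occurrence_spectrum(hakka_counts)
  she <- occurrence_spectrum(she_counts)
  expect_equal(c(hakka$n, hakka$k), c(260L, 231L))
  expect_equal(c(she$n, she$k), c(215L, 122L))
  expect_equal(match_probability(hakka), 332 / 67600)
  expect_equal(signif(match_probability(hakka), 3), 4.91e-3)
  expect_equal(match_probability(she), 657 / 46225)
  expect_equal(signif(match_probability(she), 3), 1.42e-2)
  expect_equal(round(discrimination_capacity(hakka), 4), 0.8885)
  expect_equal(round(discrimination_capacity(she), 4), 0.5674)
  expect_equal(unique_haplotype_fraction(hakka), 208 / 231)
  expect_equal(round(100 * unique_haplotype_fraction(hakka), 2), 90.04)
  expect_equal(round(100 * unique_haplotype_fraction(she), 2), 53.28)
})

test_that("diversity statistics satisfy their defining identities", {
  # HD = n/(n-1)(1-MP), DC*n = k, FUH*k = singletons, on random spectra
  set.seed(101)
  for (r in 1:20) {
    counts <- table(sample(1:5, sample(2:30, 1), replace = TRUE,
                           prob = c(16, 8, 4, 2, 1)))
    s <- occurrence_spectrum(counts)
    expect_equal(haplotype_diversity(s),
                 s$n / (s$n - 1) * (1 - match_probability(s)))
    expect_equal(discrimination_capacity(s) * s$n, s$k)
    singles <- if ("1" %in% names(s$counts)) s$counts[["1"]] else 0L
    expect_equal(unique_haplotype_fraction(s) * s$k, singles)
    expect_gte(match_probability(s), 1 / s$n)
    expect_lte(match_probability(s), 1)
    expect_gte(haplotype_diversity(s), 0)
    expect_lte(haplotype_diversity(s), 1)
  }
  # degenerate edges
  mono <- occurrence_spectrum(c("6" = 1))
  expect_equal(haplotype_diversity(mono), 0)
  expect_equal(haplotype_diversity(occurrence_spectrum(c("1" = 2))), 1)
  expect_equal(match_probability(occurrence_spectrum(c("1" = 7))), 1 / 7)
  expect_equal(discrimination_capacity(occurrence_spectrum(c("1" = 7))), 1)
  expect_equal(unique_haplotype_fraction(occurrence_spectrum(c("2" = 3))), 0)
})

test_that("mutating one copy of the modal haplotype increases HD", {
  base <- rbind(c(10, 11), c(10, 11), c(10, 11), c(10, 12))
  hd0 <- haplotype_diversity(haplotype_spectrum(make_table(base)))
  mutated <- base
  mutated[1, 1] <- 15  # novel haplotype
  hd1 <- haplotype_diversity(haplotype_spectrum(make_table(mutated)))
  expect_gt(hd1, hd0)
})

test_that("table statistics factor through the spectrum and ignore row order", {
  tab <- simulate_smm_populations(n_populations = 1, sample_sizes = 40,
                                  n_loci = 4, mu = 0.05,
                                  divergence_generations = 0,
                                  within_generations = 60, seed = 9)
  s <- haplotype_spectrum(tab)
  rep1 <- forensic_report(tab)
  expect_equal(rep1$summary$mp, match_probability(s))
  expect_equal(rep1$summary$hd, haplotype_diversity(s))
  expect_equal(rep1$summary$dc, discrimination_capacity(s))
  perm <- tab[rev(seq_len(n_samples(tab)))]
  rep2 <- forensic_report(perm)
  expect_equal(rep2$summary, rep1$summary)
  expect_equal(rep2$per_locus$gene_diversity, rep1$per_locus$gene_diversity)
})

test_that("haplotypes with missing calls are excluded from haplotype-level
           statistics but kept per locus", {
  df <- data.frame(SampleID = c("a", "b", "c"), Population = "P",
                   L01 = c("10", "11", "12"), L02 = c("7", "", "8"),
                   stringsAsFactors = FALSE)
  tab <- ystr_table(df, ystr_panel(c("L01", "L02")))
  s <- haplotype_spectrum(tab)
  expect_equal(s$n, 2L)
  expect_equal(allele_frequencies(tab, "L01")$n, 3L)
  expect_equal(allele_frequencies(tab, "L02")$n, 2L)
  rep <- forensic_report(tab)
  expect_equal(rep$summary$n_complete, 2L)
  expect_equal(rep$summary$n, 3L)
})

test_that("a monomorphic single-population table gives zero diversities", {
  tab <- make_table(matrix(12, 5, 3))
  rep <- forensic_report(tab)
  expect_true(all(rep$per_locus$gene_diversity == 0))
  expect_equal(rep$summary$hd, 0)
  expect_equal(rep$summary$dc, 1 / 5)
})
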