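test_that("mu = 0 reproduces the ancestral haplotype everywhere", {
  tab <- simulate_smm_populations(n_populations = 3, sample_sizes = 5,
                                  n_loci = 6, mu = 0,
                                  divergence_generations = 1000,
                                  within_generations = 1000, seed = 1)
  expect_true(all(tab$calls[, sprintf("L%02d", 1:6)] == "14"))
  expect_true(all(tab$calls[, "LMC"] == "14,14"))
})

test_that("a fixed seed reproduces the table byte-identically", {
  args <- list(n_populations = 2, sample_sizes = c(7, 9), n_loci = 8,
               mu = 0.01, divergence_generations = 400,
               within_generations = 150, seed = 314)
  t1 <- do.call(simulate_smm_populations, args)
  t2 <- do.call(simulate_smm_populations, args)
  expect_identical(t1$calls, t2$calls)
  expect_identical(t1$sample_id, t2$sample_id)
  t3 <- do.call(simulate_smm_populations, modifyList(args, list(seed = 315)))
  expect_false(identical(t1$calls, t3$calls))
})

test_that("alleles never drop below 1 even under extreme mutation pressure", {
  tab <- simulate_smm_populations(n_populations = 1, sample_sizes = 40,
                                  n_loci = 10, mu = 0.5,
                                  divergence_generations = 30,
                                  within_generations = 30,
                                  ancestral_allele = 2, multicopy = FALSE,
                                  seed = 8)
  vals <- as.numeric(tab$calls)
  expect_true(all(vals >= 1))
})

test_that("net repeat change matches a per-generation Monte-Carlo oracle", {
  t_gen <- 40
  mu <- 0.05
  n <- 1500
  tab <- simulate_smm_populations(n_populations = 1, sample_sizes = n,
                                  n_loci = 1, mu = mu,
                                  divergence_generations = 0,
                                  within_generations = t_gen,
                                  multicopy = FALSE, seed = 303)
  mine <- as.numeric(tab$calls[, "L01"]) - 14
  set.seed(404)
  oracle <- replicate(n, oracle_smm_walk(14, t_gen, mu)) - 14
  # two-sample chi-square over pooled displacement bins
  bins <- sort(unique(c(mine, oracle)))
  bins <- pmin(pmax(bins, -3), 3)
  cut_disp <- function(x) factor(pmin(pmax(x, -3), 3), levels = -3:3)
  tab2 <- rbind(table(cut_disp(mine)), table(cut_disp(oracle)))
  tab2 <- tab2[, colSums(tab2) > 0, drop = FALSE]
  p <- suppressWarnings(stats::chisq.test(tab2)$p.value)
  expect_gt(p, 0.01)
  # first two moments agree with the lazy random walk
  expect_equal(mean(mine), 0, tolerance = 5 * sqrt(t_gen * mu / n))
  expect_equal(mean(mine^2), t_gen * mu, tolerance = 5 * sqrt(3) * t_gen * mu / sqrt(n))
})

test_that("between-population squared difference accumulates at 2 t mu", {
  mu <- 0.002
  for (t_gen in c(200, 2000)) {
    tab <- simulate_smm_populations(n_populations = 2, sample_sizes = 1,
                                    n_loci = 300, mu = mu,
                                    divergence_generations = t_gen,
                                    within_generations = 0,
                                    multicopy = FALSE, seed = 1000 + t_gen)
    a <- as.numeric(tab$calls[1, ])
    b <- as.numeric(tab$calls[2, ])
    sq <- (a - b)^2
    se <- stats::sd(sq) / sqrt(length(sq))
    expect_lt(abs(mean(sq) - 2 * t_gen * mu), 3 * se)
  }
})

test_that("spectrum tables realize the requested spectrum exactly", {
  she <- occurrence_spectrum(c("1" = 65, "2" = 43, "3" = 6, "4" = 5,
                               "5" = 1, "6" = 1, "15" = 1))
  tab <- generate_spectrum_table(she, seed = 2)
  expect_equal(n_samples(tab), 215)
  got <- haplotype_spectrum(tab)
  expect_identical(got$counts, she$counts)
  expect_equal(c(got$n, got$k), c(215L, 122L))
  # trivial spectra
  t3 <- generate_spectrum_table(c("3" = 1), seed = 4)
  expect_equal(length(unique(haplotype_key(t3))), 1L)
  expect_equal(n_samples(t3), 3)
  # different seeds change alleles but never the spectrum
  a <- generate_spectrum_table(c("1" = 2), seed = 5)
  b <- generate_spectrum_table(c("1" = 2), seed = 6)
  expect_false(identical(a$calls, b$calls))
  expect_identical(haplotype_spectrum(b)$counts, c("1" = 2L))
})

test_that("spectrum round trip holds on random spectra", {
  set.seed(55)
  for (r in 1:10) {
    counts <- table(sample(1:6, sample(3:40, 1), replace = TRUE,
                           prob = c(32, 16, 8, 4, 2, 1)))
    s <- occurrence_spectrum(counts)
    tab <- generate_spectrum_table(s, seed = r)
    expect_identical(haplotype_spectrum(tab)$counts, s$counts)
  }
})

test_that("invalid configurations raise validation errors", {
  expect_error(simulate_smm_populations(mu = 2, seed = 1),
               class = "ystr_validation")
  expect_error(simulate_smm_populations(sample_sizes = 0, seed = 1),
               class = "ystr_validation")
  expect_error(simulate_smm_populations(mu = 0.01),
               class = "ystr_validation")  # seed mandatory
  expect_error(generate_spectrum_table(c("1" = 0), seed = 1),
               class = "ystr_validation")
  expect_error(generate_reference_panel(n_haplogroups = 30, n_loci = 10,
                                        seed = 1),
               class = "ystr_constructive_failure")
})

test_that("reference panels keep founders apart and honor zero noise", {
  gen <- generate_reference_panel(n_haplogroups = 5,
                                  founders_min_separation = 8,
                                  within_noise_mu_t = 0, size_train = 3,
                                  size_test = 2, seed = 9)
  f <- gen$founders
  for (i in 1:4) for (j in (i + 1):5)
    expect_gte(sum((f[i, ] - f[j, ])^2), 8)
  # zero noise: every member equals its founder
  for (g in rownames(f)) {
    members <- gen$panel$table$calls[gen$panel$labels == g, , drop = FALSE]
    expect_true(all(t(members) == as.character(f[g, ])))
  }
})

test_that("mean R_ST increases with divergence time", {
  levels <- c(100, 1000, 5000)
  mean_rst <- vapply(levels, function(t_gen) {
    vals <- vapply(1:8, function(r) {
      tab <- simulate_smm_populations(n_populations = 2, sample_sizes = 10,
                                      n_loci = 10, mu = 0.002,
                                      divergence_generations = t_gen,
                                      within_generations = 200,
                                      multicopy = FALSE,
                                      seed = 7000 + 13 * t_gen + r)
      tryCatch(amova_rst(tab)$rst, ystr_error = function(e) NA_real_)
    }, 0)
    mean(vals, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(mean_rst) > 0))
})
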