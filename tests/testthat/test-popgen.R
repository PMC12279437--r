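test_that("individual heterozygosity counts het genotypes among calls", {
  g <- rbind(c(1, 1, 1, 0, 0, 2, 0, 2, 0, 0),   # 3 het of 10
             c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA),
             c(1, 1, NA, NA, 0, 0, 0, 0, 0, 0)) # 2 het of 8
  panel <- toy_panel(g, c("A", "A", "A"))
  h <- individual_heterozygosity(panel)
  expect_equal(unname(h), c(0.3, NA, 0.25))

  # HWE panel at p = 0.5: mean heterozygosity ~ 0.5
  hwe <- sample_genotypes(rep(0.5, 400), 50, seed = 1)
  h2 <- individual_heterozygosity(hwe)
  expect_lt(abs(mean(h2) - 0.5), 3 * sqrt(0.25 / (50 * 400)))
})

test_that("allele frequencies match a brute-force tally and pool linearly", {
  g <- rbind(c(0, 2), c(1, NA), c(NA, 2),    # pop A
             c(2, 0), c(2, 1))               # pop B
  panel <- toy_panel(g, c("A", "A", "A", "B", "B"))
  ft <- allele_frequencies(panel)
  expect_equal(ft$p["A", ], c(1 / 4, 4 / 4))
  expect_equal(ft$an["A", ], c(4, 4))
  expect_equal(ft$p["B", ], c(4 / 4, 1 / 4))

  # brute-force oracle on a random panel
  set.seed(2)
  sim <- generate_study_dataset(study_model(), 100, 0, study_sizes, seed = 2)
  ft2 <- allele_frequencies(sim$panel)
  labels <- sim$panel$pop_map[sim$panel$samples]
  for (pp in unique(labels)) {
    sub <- sim$panel$genotypes[labels == pp, , drop = FALSE]
    brute <- apply(sub, 2, function(col) sum(col, na.rm = TRUE) /
                     (2 * sum(!is.na(col))))
    expect_equal(unname(ft2$p[pp, ]), unname(brute))
  }
  # pooled frequency equals call-count-weighted mean of population freqs
  pooled_nc <- colSums(!is.na(sim$panel$genotypes))
  pooled <- colSums(sim$panel$genotypes, na.rm = TRUE) / (2 * pooled_nc)
  weighted <- colSums(ft2$p * ft2$an) / colSums(ft2$an)
  expect_equal(pooled, weighted)
})

test_that("folded MAF spectra fold correctly and flag rare variants", {
  mono <- toy_panel(matrix(1L, 4, 3), rep("A", 4))   # p = 0.5 everywhere
  sp <- maf_spectrum(mono)
  expect_equal(sp$frac_rare, 0)
  expect_true(all(sp$maf == 0.5))

  set.seed(3)
  g <- matrix(rbinom(20 * 50, 2, rep(runif(50, 0.05, 0.95), each = 20)),
              nrow = 20)
  a <- maf_spectrum(toy_panel(g, rep("A", 20)))
  b <- maf_spectrum(toy_panel(2L - g, rep("A", 20)))
  expect_equal(a$counts, b$counts)
  expect_equal(a$frac_rare, b$frac_rare)
})

test_that("Tajima constants and the micro-example match the frozen oracle", {
  k <- fwadapt:::tajima_constants(4)
  expect_equal(k$a1, 1 + 1 / 2 + 1 / 3)

  # 5 diploids (10 sequences), 8 sites with alt counts 1,5,3,0,9,2,10,4;
  # expected D frozen from an independent scalar evaluation of the
  # pairwise-difference and Watterson formulas.
  g <- cbind(c(1, 0, 0, 0, 0), c(2, 2, 1, 0, 0), c(1, 1, 1, 0, 0),
             c(0, 0, 0, 0, 0), c(2, 2, 2, 2, 1), c(1, 1, 0, 0, 0),
             c(2, 2, 2, 2, 2), c(2, 1, 1, 0, 0))
  panel <- toy_panel(g, rep("A", 5),
                     pos = as.integer(seq(1000, 8000, by = 1000)))
  res <- tajimas_d_windows(panel, "A", window_bp = 100000L)
  expect_identical(nrow(res), 1L)
  expect_identical(res$n_segregating, 6L)
  expect_equal(res$D, 0.3709917752, tolerance = 1e-9)

  # a window with no segregating sites yields NA
  fixed <- toy_panel(matrix(2L, 5, 4), rep("A", 5))
  res0 <- tajimas_d_windows(fixed, "A")
  expect_true(is.na(res0$D))
  lone <- toy_panel(matrix(1L, 1, 3), "A")
  expect_error(tajimas_d_windows(lone, "A"), "at least 2")
})

test_that("Tajima's D is near zero at neutral equilibrium and tracks demography", {
  # equilibrium 1/x spectrum (plus a short drift burn-in at large size)
  p_eq <- simulate_ancestral_frequencies(30000, spectrum_neutral(0.001),
                                         seed = 5)
  p_eq <- drift_forward(p_eq, 5000L, 10, seed = 6)
  panel <- sample_genotypes(p_eq, 20, seed = 6, population = "A")
  res <- tajimas_d_windows(panel, "A", window_bp = 100000L)
  expect_lt(abs(mean(res$D, na.rm = TRUE)), 0.3)

  # strong drift erodes rare variants, pushing D up relative to a large
  # (recently expanded) population that preserves them
  base <- simulate_ancestral_frequencies(2000, spectrum_neutral(0.001),
                                         seed = 7)
  post_exp <- drift_forward(base, 2000L, 100, seed = 7)
  post_bot <- drift_forward(base, 25L, 30, seed = 8)
  pan_exp <- sample_genotypes(post_exp[post_exp > 0 & post_exp < 1], 20,
                              seed = 9, population = "A")
  pan_bot <- sample_genotypes(post_bot[post_bot > 0 & post_bot < 1], 20,
                              seed = 10, population = "A")
  d_exp <- mean(tajimas_d_windows(pan_exp, "A")$D, na.rm = TRUE)
  d_bot <- mean(tajimas_d_windows(pan_bot, "A")$D, na.rm = TRUE)
  expect_lt(d_exp, d_bot)
})

test_that("Weir-Cockerham components match the frozen 5-site oracle", {
  gA <- rbind(c(0, 1, 0, 2, 0), c(0, 1, 0, 2, 1),
              c(1, 1, 0, 2, 2), c(2, 1, 1, 2, 2))
  gB <- rbind(c(2, 0, 0, 0, 2), c(2, 0, 0, 1, 2), c(1, 1, 0, 1, 1))
  panel <- toy_panel(rbind(gA, gB), rep(c("A", "B"), c(4, 3)))
  res <- weir_cockerham_fst(panel, "A", "B")
  expect_equal(res$a,
               c(0.0552083333, 0.0458333333, -0.0031250000, 0.2125000000,
                 -0.0281250000), tolerance = 1e-9)
  expect_equal(res$d - res$a,
               c(0.0994047619 + 0.1428571429, -0.1452380952 + 0.3571428571,
                 0.0017857143 + 0.0714285714, -0.0380952381 + 0.1428571429,
                 0.0994047619 + 0.1428571429), tolerance = 1e-9)
  expect_equal(res$fst, 0.2440499164, tolerance = 1e-9)
})

test_that("F_ST hits its boundary cases", {
  # fixed difference, 50/50: near-maximal differentiation
  g <- rbind(matrix(0L, 50, 20), matrix(2L, 50, 20))
  panel <- toy_panel(g, rep(c("A", "B"), each = 50))
  expect_gte(weir_cockerham_fst(panel, "A", "B")$fst, 0.95)

  # identical source frequencies: F_ST indistinguishable from 0
  null <- null_pair_panel(30, 500, seed = 11)
  perm <- fst_permutation_test(null, "grpA", "grpB", n_perm = 499, seed = 12)
  null_sd <- sd(perm$perm_fst, na.rm = TRUE)
  expect_lt(abs(perm$fst), 3 * null_sd)
  expect_gt(perm$p, 0.05)
})

test_that("F_ST rises with divergence time", {
  anc <- simulate_ancestral_frequencies(800, spectrum_uniform(0.1, 0.9),
                                        seed = 13)
  fst_at <- function(gens, seed) {
    p1 <- drift_forward(anc, 250L, gens, seed = seed)
    p2 <- drift_forward(anc, 250L, gens, seed = seed + 1)
    pan <- bind_panels(list(
      sample_genotypes(p1, 30, seed = seed + 2, population = "P1"),
      sample_genotypes(p2, 30, seed = seed + 3, population = "P2")))
    weir_cockerham_fst(pan, "P1", "P2")$fst
  }
  shallow <- vapply(1:5, function(i) fst_at(10, 100 + 10 * i), 0)
  deep <- vapply(1:5, function(i) fst_at(70, 200 + 10 * i), 0)
  expect_lt(t.test(shallow, deep, alternative = "less")$p.value, 0.01)
})

test_that("permutation p-values behave at the extremes and reject bad input", {
  g <- rbind(matrix(0L, 20, 10), matrix(2L, 20, 10))
  panel <- toy_panel(g, rep(c("A", "B"), each = 20))
  res <- fst_permutation_test(panel, "A", "B", n_perm = 199, seed = 14)
  expect_equal(res$p, 1 / 200)
  expect_error(fst_permutation_test(panel, "A", "B", n_perm = 0))
})

test_that("pairwise F_ST applies Bonferroni across pairs", {
  sim <- generate_study_dataset(study_model(), 150, 0, c(15L, 15L, 15L, 15L, 15L),
                                seed = 15)
  res <- pairwise_fst(sim$panel, n_perm = 99, seed = 16)
  expect_true(all(res$p_bonferroni >= res$p, na.rm = TRUE))
  expect_true(all(res$p_bonferroni <= 1, na.rm = TRUE))
  expect_equal(res$fst, t(res$fst))
})
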