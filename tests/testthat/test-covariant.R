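test_that("covariant extraction matches the sign-symmetry expectation", {
  # derived frequencies drawn independently and symmetrically about the
  # ancestral value: one allele rises everywhere with probability
  # 2 * 0.5^4 (continuous draws, no ties)
  set.seed(50)
  L <- 20000
  ft <- freq_table_from_freqs(list(
    anc = rep(0.5, L), d1 = runif(L), d2 = runif(L),
    d3 = runif(L), d4 = runif(L)))
  cov <- extract_covariant(ft, "anc")
  frac <- nrow(cov) / L
  expect_lt(abs(frac - 0.125), 3 * sqrt(0.125 * 0.875 / L))

  # FWA rising from an ancestral frequency of zero is included
  ft0 <- freq_table_from_freqs(list(anc = 0, d1 = 0.3, d2 = 0.2, d3 = 0.4,
                                    d4 = 0.1))
  expect_identical(nrow(extract_covariant(ft0, "anc")), 1L)

  # ties exclude
  ft_tie <- freq_table_from_freqs(list(anc = 0.5, d1 = 0.5, d2 = 0.7,
                                       d3 = 0.7, d4 = 0.7))
  expect_identical(nrow(extract_covariant(ft_tie, "anc")), 0L)
})

test_that("extract_covariant and direction_consistent agree exactly", {
  sim <- generate_study_dataset(study_model(), 500, 50, study_sizes, seed = 51)
  ft <- allele_frequencies(sim$panel)
  a <- extract_covariant(ft, "ancestral")
  b <- direction_consistent(ft, seq_len(ncol(ft$p)), "ancestral")
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("covariant thresholding is inclusive and monotone in delta", {
  ft <- freq_table_from_freqs(list(
    anc = c(0, 0), d1 = c(0.25, 0.25), d2 = c(0.20, 0.19),
    d3 = c(0.30, 0.30), d4 = c(0.21, 0.21)))
  cov <- extract_covariant(ft, "anc")
  expect_identical(nrow(cov), 2L)
  kept <- threshold_covariant(cov, 0.2)
  expect_identical(kept$site, 1L)      # increments (0.25,0.20,0.30,0.21)
  expect_identical(nrow(threshold_covariant(cov, 0)), nrow(cov))

  sim <- generate_study_dataset(study_model(), 400, 40, study_sizes, seed = 52)
  cov2 <- extract_covariant(allele_frequencies(sim$panel), "ancestral")
  sizes <- vapply(c(0, 0.1, 0.2, 0.3, 0.5),
                  function(d) nrow(threshold_covariant(cov2, d)), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("the analytic concordance arithmetic is exact", {
  expect_equal(neutral_concordance_probability(4), 0.125)
  expect_equal(neutral_concordance_probability(1), 1)
  expect_equal(neutral_concordance_probability(2), 0.5)
  expect_error(neutral_concordance_probability(0))

  expect_equal(expected_concordant_count(5440, 4), 680)
  expect_equal(expected_concordant_count(0, 4), 0)
  expect_equal(expected_concordant_count(1000, 2), 500)
})

test_that("the chi-squared concordance test matches direct arithmetic", {
  exact <- chi_square_concordance_test(680, 5440, 4)
  expect_equal(exact$statistic, 0)
  expect_equal(exact$p, 1)

  res <- chi_square_concordance_test(3031, 5440, 4)
  manual <- (3031 - 680)^2 / 680 + (2409 - 4760)^2 / 4760
  expect_equal(res$statistic, manual)
  expect_lt(res$p, 1e-15)
  expect_error(chi_square_concordance_test(10, 0, 4))
})

test_that("the chi-squared test holds its type-I error rate", {
  set.seed(53)
  n <- 5440
  obs <- rbinom(1e4, n, 0.125)
  rej <- vapply(obs, function(o) {
    chi_square_concordance_test(o, n, 4)$p < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.04)
  expect_lt(mean(rej), 0.06)
})

test_that("excess fractions reproduce the headline arithmetic", {
  expect_equal(round(100 * excess_fraction(3031, 680, 5440)), 43)
  expect_equal(excess_fraction(100, 100, 200), 0)
  expect_equal(excess_fraction(100, 0, 100), 1)
  expect_warning(z <- excess_fraction(10, 20, 100), "below")
  expect_equal(z, 0)
  expect_error(excess_fraction(1, 0, 0))
})

test_that("the Z-test against a simulated null behaves at its anchors", {
  null <- structure(list(counts = c(10L, 12L, 14L), mean = 12, sd = 2,
                         n_reps = 3L, n_samplings = 1L, delta = 0.2,
                         seed = 1L, degenerate = FALSE),
                    class = "null_distribution")
  expect_equal(z_test_excess(12, null)$z, 0)
  expect_equal(z_test_excess(12, null)$p, 0.5)
  expect_equal(z_test_excess(16, null)$z, 2)
  degen <- null
  degen$sd <- 0
  expect_error(z_test_excess(12, degen), "degenerate")
})

test_that("a pure-drift dataset sits inside its own simulated null", {
  # self-consistency: the observed covariant count of a neutral dataset
  # falls within mean +/- 3 SD of the matched null
  for (seed in 54:56) {
    sim <- generate_study_dataset(study_model(), 400, 0, study_sizes,
                                  seed = seed)
    ft <- allele_frequencies(sim$panel)
    obs <- nrow(threshold_covariant(extract_covariant(ft, "ancestral"), 0.2))
    anc_p <- ft$p["ancestral", ]
    null <- simulate_null_covariant_counts(anc_p[!is.na(anc_p)],
                                           study_model(), study_sizes,
                                           delta = 0.2, n_reps = 40,
                                           n_samplings = 5, seed = seed + 100)
    expect_gte(obs, null$mean - 3 * null$sd)
    expect_lte(obs, null$mean + 3 * null$sd)
  }
})

test_that("selection is detected by the Z-test and candidates are truth-enriched", {
  sim <- generate_study_dataset(study_model(derived_ne = 500L), 2000, 100,
                                study_sizes, seed = 57, s = 0.25)
  ft <- allele_frequencies(sim$panel)
  cand <- threshold_covariant(extract_covariant(ft, "ancestral"), 0.2)
  anc_p <- ft$p["ancestral", ]
  null <- simulate_null_covariant_counts(anc_p[!is.na(anc_p)],
                                         study_model(derived_ne = 500L),
                                         study_sizes, delta = 0.2,
                                         n_reps = 50, n_samplings = 4,
                                         seed = 58)
  zt <- z_test_excess(nrow(cand), null)
  expect_lt(zt$p, 0.01)

  # hypergeometric enrichment of truth-selected sites among candidates
  sel <- sim$truth$site[sim$truth$selected]
  x <- sum(cand$site %in% sel)
  p_enrich <- stats::phyper(x - 1, length(sel), 2000 - length(sel),
                            nrow(cand), lower.tail = FALSE)
  expect_lt(p_enrich, 0.01)
})
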