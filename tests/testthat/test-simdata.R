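test_that("ancestral spectra have the right support and moments", {
  expect_length(simulate_ancestral_frequencies(0), 0)
  expect_error(spectrum_uniform(0.9, 0.1))
  expect_error(spectrum_neutral(0.6))

  u <- simulate_ancestral_frequencies(1e5, spectrum_uniform(0.1, 0.9), seed = 11)
  expect_true(all(u > 0 & u < 1))
  se <- sqrt((0.8^2 / 12) / 1e5)          # SE of the mean of U(0.1, 0.9)
  expect_lt(abs(mean(u) - 0.5), 3 * se)

  x <- simulate_ancestral_frequencies(1e5, spectrum_neutral(0.05), seed = 12)
  expect_true(all(x >= 0.05 & x <= 0.95))
  # fraction with folded MAF <= 0.1 from the truncated 1/x density
  dens <- function(v) 1 / v
  norm <- integrate(dens, 0.05, 0.95)$value
  frac <- (integrate(dens, 0.05, 0.1)$value +
             integrate(dens, 0.9, 0.95)$value) / norm
  obs <- mean(pmin(x, 1 - x) <= 0.1)
  expect_lt(abs(obs - frac), 3 * sqrt(frac * (1 - frac) / 1e5))

  expect_identical(simulate_ancestral_frequencies(100, seed = 5),
                   simulate_ancestral_frequencies(100, seed = 5))
})

test_that("one-generation drift matches binomial variance and the selection map", {
  # absorbing boundaries
  expect_equal(drift_forward(c(0, 1), ne = 100, generations = 50,
                             s = 0.3, seed = 1), c(0, 1))
  expect_error(drift_forward(0.5, 100, 1, s = -1.5))

  # neutral drift variance p(1-p)/(2Ne): 1e4 iid loci stand in for replicates
  p1 <- drift_forward(rep(0.5, 1e4), ne = 100, generations = 1, seed = 2)
  v_exp <- 0.5 * 0.5 / 200
  se_v <- v_exp * sqrt(2 / 1e4)           # approximate SE of a variance
  expect_lt(abs(var(p1 - 0.5) - v_exp), 3 * se_v)

  # deterministic genic selection map at huge Ne
  p2 <- drift_forward(rep(0.5, 1e3), ne = 1e6, generations = 1, s = 0.1,
                      seed = 3)
  target <- 0.5 * 1.1 / 1.05
  expect_lt(abs(mean(p2) - target), 3 * sd(p2) / sqrt(1e3))
})

test_that("drift variance matches p(1-p)/(2Ne) across a parameter grid", {
  for (p0 in c(0.1, 0.3, 0.5)) {
    for (ne in c(50L, 500L)) {
      p1 <- drift_forward(rep(p0, 2e4), ne = ne, generations = 1,
                          seed = derive_seed(9, p0 * 10, ne))
      v_exp <- p0 * (1 - p0) / (2 * ne)
      expect_lt(abs(var(p1 - p0) - v_exp), 4 * v_exp * sqrt(2 / 2e4))
    }
  }
})

test_that("neutral drift is symmetric about 0.5 and fixes at the initial frequency", {
  p <- drift_forward(rep(0.5, 1e4), ne = 100, generations = 70, seed = 21)
  ks <- suppressWarnings(stats::ks.test(p, 1 - p))
  expect_gt(ks$p.value, 0.01)

  # long-run fixation probability of a neutral allele ~ initial frequency
  pf <- drift_forward(rep(0.2, 2000), ne = 50, generations = 2000, seed = 22)
  expect_true(all(pf %in% c(0, 1)))
  expect_lt(abs(mean(pf) - 0.2), 3 * sqrt(0.2 * 0.8 / 2000))
})

test_that("founding bottlenecks are single binomial draws", {
  expect_equal(found_population(c(0, 1), 5, seed = 1), c(0, 1))
  f <- found_population(rep(0.5, 1e4), founder_ne = 1, seed = 2)
  expect_true(all(f %in% c(0, 0.5, 1)))
  expect_lt(abs(mean(f == 0.5) - 0.5), 3 * sqrt(0.25 / 1e4))
  expect_lt(abs(mean(f == 0) - 0.25), 3 * sqrt(0.25 * 0.75 / 1e4))
  # large founder population: negligible shift
  big <- found_population(rep(0.3, 100), founder_ne = 1e6, seed = 3)
  expect_true(all(abs(big - 0.3) < 0.002))
})

test_that("genotype sampling is Hardy-Weinberg with no missing data", {
  p0 <- sample_genotypes(c(0, 0), 10, seed = 1)
  expect_true(all(p0$genotypes == 0))
  empty <- sample_genotypes(c(0.5, 0.2), 0, seed = 1)
  expect_identical(nrow(empty$genotypes), 0L)
  expect_identical(ncol(empty$genotypes), 2L)

  one <- sample_genotypes(0.5, 1e4, seed = 2)
  het <- mean(one$genotypes[, 1] == 1)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 1e4))
  expect_false(anyNA(one$genotypes))
})

test_that("demographic model enforces its invariants", {
  expect_error(demographic_model(1000, 500, founding_generation = 80,
                                 total_generations = 70))
  expect_error(demographic_model(1000, c(500, 500), c(10, 20, 30)))
  expect_error(demographic_model(0, 500, 10))
  m <- demographic_model(1e9, 1e9, 10, ne_cap = 100000L)
  expect_identical(m$ancestral_ne, 100000L)
  expect_identical(m$derived_ne, 100000L)
})

test_that("study datasets are reproducible and selection raises concordant shifts", {
  m <- study_model()
  a <- generate_study_dataset(m, 300, 20, study_sizes, seed = 5)
  b <- generate_study_dataset(m, 300, 20, study_sizes, seed = 5)
  expect_identical(a$panel$genotypes, b$panel$genotypes)
  expect_identical(a$truth, b$truth)
  expect_error(generate_study_dataset(m, 300, 20, c(10, 10), seed = 1))
  expect_error(generate_study_dataset(m, 10, 20, study_sizes, seed = 1))

  # with enormous derived Ne and no selection, frequencies barely move
  m_inf <- demographic_model(1000000L, rep(1000000L, 4), c(69L, 68L, 65L, 44L),
                             ne_cap = 1000000L)
  sim0 <- generate_study_dataset(m_inf, 200, 0, c(200L, rep(200L, 4)), seed = 6)
  anc <- sim0$freqs[[1]]
  for (i in 2:5) expect_lt(max(abs(sim0$freqs[[i]] - anc)), 0.05)

  # selected sites shift concordantly more than neutral ones
  sim <- generate_study_dataset(m, 2000, 100, study_sizes, seed = 7, s = 0.25)
  anc <- sim$freqs[[1]]
  dmat <- sapply(sim$freqs[-1], function(f) f - anc)
  sel <- sim$truth$selected
  mean_shift_sel <- rowMeans(dmat)[sel]
  mean_abs_neut <- abs(rowMeans(dmat))[!sel]
  tt <- t.test(mean_shift_sel, mean_abs_neut, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("the neutral null machinery has the advertised shape and limits", {
  m <- study_model()
  anc <- simulate_ancestral_frequencies(300, spectrum_uniform(0.1, 0.9),
                                        seed = 31)
  null <- simulate_null_covariant_counts(anc, m, study_sizes, delta = 0.2,
                                         n_reps = 4, n_samplings = 3,
                                         seed = 32)
  expect_length(null$counts, 12)
  expect_equal(null$mean, mean(null$counts))
  expect_equal(null$sd, sd(null$counts))

  # infinite-Ne limit: no drift, sampling error alone cannot reach 0.2
  m_inf <- demographic_model(1000000L, rep(1000000L, 4), c(69L, 68L, 65L, 44L),
                             ne_cap = 1000000L)
  expect_warning(
    null0 <- simulate_null_covariant_counts(anc, m_inf,
                                            c(200L, rep(200L, 4)),
                                            delta = 0.2, n_reps = 3,
                                            n_samplings = 3, seed = 33),
    "degenerate")
  expect_identical(max(null0$counts), 0L)
  expect_true(null0$degenerate)

  expect_error(simulate_null_covariant_counts(anc, m, study_sizes,
                                              n_reps = 0, seed = 1))
})

test_that("at delta = 0 the null concordance fraction approaches 2 * 0.5^4", {
  # the sign-symmetry argument needs the four contrasts independent: a
  # (near-)static ancestral population, splits at generation zero, and
  # large samples so shared ancestral sampling noise is negligible
  m <- demographic_model(1000000L, rep(1000L, 4), rep(70L, 4),
                         ne_cap = 1000000L)
  anc <- simulate_ancestral_frequencies(4000, spectrum_uniform(0.1, 0.9),
                                        seed = 41)
  null <- simulate_null_covariant_counts(anc, m, c(500L, rep(500L, 4)),
                                         delta = 0, n_reps = 5,
                                         n_samplings = 2, seed = 42)
  frac <- null$mean / 4000
  # large samples keep ties rare; allow 3 binomial SE plus a small tie margin
  expect_lt(abs(frac - 0.125), 3 * sqrt(0.125 * 0.875 / 4000) + 0.01)
})

test_that("frequencies stay in [0,1] and absorbing states never revive", {
  p <- simulate_ancestral_frequencies(500, spectrum_uniform(0.05, 0.95),
                                      seed = 51)
  p[1:10] <- 0; p[11:20] <- 1
  out <- drift_forward(p, ne = 30, generations = 100, seed = 52)
  expect_true(all(out >= 0 & out <= 1))
  expect_true(all(out[1:10] == 0))
  expect_true(all(out[11:20] == 1))
})
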