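#' Extract covariant SNPs
#'
#' All sites where one allele's frequency strictly increases in every
#' derived population relative to the ancestral population -- the
#' freshwater-favoured-allele (FWA) definition.  Uses the same strict tie
#' rule as [direction_consistent()]; the two agree exactly on any shared
#' input set.
#'
#' @param freq_table a `freq_table` over the ancestral and derived
#'   populations.
#' @param ancestral label of the ancestral population.
#' @return a `candidate_set` over all qualifying sites.
#' @export
extract_covariant <- function(freq_table, ancestral) {
  fwa_candidates(freq_table, ancestral, warn_na = FALSE)
}

#' Threshold covariant SNPs on the FWA increment
#'
#' Keeps sites whose FWA frequency increment is at least `delta`
#' (inclusive) in every derived population.
#'
#' @param covariant a `candidate_set` from [extract_covariant()].
#' @param delta increment threshold in `[0, 1]` (default 0.2); `delta = 0`
#'   returns the input set unchanged.
#' @return the thresholded `candidate_set`.
#' @export
threshold_covariant <- function(covariant, delta = 0.2) {
  .check_prob(delta, "delta")
  d <- as.matrix(covariant[, grep("^dfwa_", names(covariant)), drop = FALSE])
  keep <- if (nrow(covariant)) apply(d, 1, min) >= delta else logical(0)
  out <- covariant[keep, , drop = FALSE]
  attributes(out)[c("ancestral", "derived", "class")] <-
    attributes(covariant)[c("ancestral", "derived", "class")]
  rownames(out) <- NULL
  out
}

#' Neutral concordance probability
#'
#' Under sign-symmetric, independent, tie-free frequency changes, the
#' probability that all `n_derived` derived populations shift the same
#' allele in the same direction is `2 * 0.5^n_derived` (either allele can
#' be the rising one).
#'
#' @param n_derived number of derived populations (>= 1).
#' @return the probability.
#' @export
neutral_concordance_probability <- function(n_derived) {
  .check_count(n_derived, "n_derived", 1L)
  2 * 0.5^n_derived
}

#' Expected concordant count under neutrality
#'
#' @param n_snps number of SNPs considered.
#' @param n_derived number of derived populations.
#' @return `n_snps * neutral_concordance_probability(n_derived)`.
#' @export
expected_concordant_count <- function(n_snps, n_derived) {
  .check_count(n_snps, "n_snps")
  n_snps * neutral_concordance_probability(n_derived)
}

#' Chi-squared test of concordance excess
#'
#' One-degree-of-freedom goodness-of-fit of the observed concordant count
#' against the neutral two-cell expectation `(p0, 1 - p0)` with
#' `p0 = 2 * 0.5^n_derived`.
#'
#' @param observed observed concordant SNP count.
#' @param n_snps total SNPs considered (> 0).
#' @param n_derived number of derived populations.
#' @return list with `statistic`, `p`, `observed`, `expected`.
#' @export
chi_square_concordance_test <- function(observed, n_snps, n_derived) {
  .check_count(n_snps, "n_snps", 1L)
  .check_count(observed, "observed")
  if (observed > n_snps) stop("observed must not exceed n_snps")
  p0 <- neutral_concordance_probability(n_derived)
  E <- c(n_snps * p0, n_snps * (1 - p0))
  O <- c(observed, n_snps - observed)
  stat <- sum((O - E)^2 / E)
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = observed, expected = E[1])
}

#' Excess fraction of concordant outliers
#'
#' `(observed - expected) / total`: the share of the SNP set whose
#' concordance exceeds the neutral expectation (0, with a warning, if the
#' observed count falls below expectation).
#'
#' @param observed observed concordant count.
#' @param expected neutral expected count.
#' @param total size of the SNP set (> 0).
#' @return the fraction.
#' @export
excess_fraction <- function(observed, expected, total) {
  if (total == 0) stop("total must be positive")
  if (observed < expected) {
    warning("observed below expectation; excess fraction set to 0")
    return(0)
  }
  (observed - expected) / total
}

#' One-sided Z-test of covariant excess against a simulated null
#'
#' `Z = (observed - mean) / SD` with the mean and sample SD of the
#' replicate counts from [simulate_null_covariant_counts()]; the p-value
#' is the upper normal tail, since the hypothesis is an excess of
#' covariant SNPs over neutrality.
#'
#' @param observed_count observed candidate covariant SNP count.
#' @param null a `null_distribution`.
#' @return an object of class `covariant_test`: `z`, `p`, `observed`,
#'   `null_mean`, `null_sd`.
#' @export
z_test_excess <- function(observed_count, null) {
  stopifnot(inherits(null, "null_distribution"))
  if (!is.finite(null$sd) || null$sd <= 0) {
    stop("degenerate null distribution (SD = 0)")
  }
  z <- (observed_count - null$mean) / null$sd
  structure(list(z = z, p = stats::pnorm(z, lower.tail = FALSE),
                 observed = observed_count,
                 null_mean = null$mean, null_sd = null$sd,
                 n_replicates = length(null$counts)),
            class = "covariant_test")
}

#' @export
print.covariant_test <- function(x, ...) {
  cat(sprintf(
    "covariant excess Z-test: observed %d vs null %.1f +/- %.2f (n = %d)\n  Z = %.2f, one-sided P = %.3g\n",
    x$observed, x$null_mean, x$null_sd, x$n_replicates, x$z, x$p))
  invisible(x)
}
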