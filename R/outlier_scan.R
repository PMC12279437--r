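#' Two-sided Fisher exact p-value for a 2x2 allele-count table
#'
#' Exact hypergeometric enumeration: with margins fixed, the p-value is the
#' sum of probabilities of all tables no more probable than the observed
#' one (with the customary `1 + 1e-7` relative tolerance on the
#' comparison, matching [stats::fisher.test()]).  Vectorised over sites.
#'
#' @param alt1,ref1 alternate/reference allele counts in population 1.
#' @param alt2,ref2 alternate/reference allele counts in population 2.
#' @return list with `p` (numeric vector) and `degenerate` (logical vector
#'   flagging zero-margin tables, where `p = 1` by convention).
#' @export
fisher_exact_p <- function(alt1, ref1, alt2, ref2) {
  stopifnot(length(alt1) == length(ref1),
            length(alt1) == length(alt2), length(alt1) == length(ref2))
  n_sites <- length(alt1)
  p <- numeric(n_sites)
  degenerate <- logical(n_sites)
  rel <- 1 + 1e-7
  for (i in seq_len(n_sites)) {
    m <- alt1[i] + alt2[i]          # total alternate alleles
    nn <- ref1[i] + ref2[i]         # total reference alleles
    k <- alt1[i] + ref1[i]          # alleles drawn into population 1
    if (m == 0 || nn == 0 || k == 0 || k == m + nn) {
      p[i] <- 1
      degenerate[i] <- TRUE
      next
    }
    support <- max(0, k - nn):min(k, m)
    dens <- stats::dhyper(support, m, nn, k)
    d_obs <- stats::dhyper(alt1[i], m, nn, k)
    p[i] <- min(1, sum(dens[dens <= d_obs * rel]))
  }
  list(p = p, degenerate = degenerate)
}

#' Fisher exact test scan over a population pair
#'
#' Builds the 2x2 table of (reference, alternate) allele counts for the two
#' populations at every site and returns the two-sided exact p-value.
#' Allele counts come from a [allele_frequencies()] table (frequency times
#' callable allele count).
#'
#' @param freq_table a `freq_table`.
#' @param pair character vector of two population labels.
#' @return data.frame with columns `site`, `p`, `degenerate`; `p` is `NA`
#'   where either population has no calls.
#' @export
fisher_exact_scan <- function(freq_table, pair) {
  stopifnot(length(pair) == 2, all(pair %in% freq_table$pops))
  p1 <- freq_table$p[pair[1], ]
  p2 <- freq_table$p[pair[2], ]
  an1 <- freq_table$an[pair[1], ]
  an2 <- freq_table$an[pair[2], ]
  alt1 <- as.integer(round(p1 * an1))
  alt2 <- as.integer(round(p2 * an2))
  ok <- !is.na(p1) & !is.na(p2) & an1 > 0 & an2 > 0
  res_p <- rep(NA_real_, length(p1))
  res_d <- rep(NA, length(p1))
  if (any(ok)) {
    fet <- fisher_exact_p(alt1[ok], an1[ok] - alt1[ok],
                          alt2[ok], an2[ok] - alt2[ok])
    res_p[ok] <- fet$p
    res_d[ok] <- fet$degenerate
  }
  data.frame(site = seq_along(p1), p = res_p, degenerate = res_d)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone-enforced, capped at
#' 1), delegating to [stats::p.adjust()].  `NA` entries are passed through.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' PCA-Mahalanobis outlier scan
#'
#' A pcadapt-style genome scan.  Genotypes are mean-imputed per site,
#' centred and scaled by `sqrt(2 p (1 - p))`; the top-`k` sample scores are
#' computed by truncated SVD; each site's scaled genotype vector is
#' regressed on the `k` score vectors, giving `k` z-scores per site; the
#' squared Mahalanobis distance `D^2` of the z-scores (component scales
#' estimated robustly by MAD, i.e. a diagonal robust covariance) is
#' rescaled by the genomic inflation factor
#' `lambda = median(D^2) / qchisq(0.5, k)` and referred to a chi-squared
#' distribution with `k` degrees of freedom; q-values via [bh_fdr()].
#'
#' @param panel a [genotype_panel()] restricted to the samples to scan
#'   (typically one ecotype pair); monomorphic sites must be excluded
#'   beforehand.
#' @param k number of principal components (default 2).
#' @return an object of class `pca_scan`: data.frame `stats` (`D2`, `p`,
#'   `q`), scalar `lambda`, the `k` used, and the `zscores` matrix
#'   (k x sites).
#' @export
pca_outlier_scan <- function(panel, k = 2L) {
  g <- panel$genotypes
  n <- nrow(g)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (n < k + 2) stop("need at least k + 2 samples")
  cm <- colMeans(g, na.rm = TRUE)
  if (any(is.nan(cm))) stop("sites with no called genotypes reached the scan")
  p_hat <- cm / 2
  if (any(p_hat <= 0 | p_hat >= 1)) {
    stop("monomorphic sites reached the scan; filter them first")
  }
  imput <- g
  na_idx <- which(is.na(imput))
  if (length(na_idx)) imput[na_idx] <- cm[(na_idx - 1) %/% n + 1]
  X <- sweep(imput, 2, 2 * p_hat)
  X <- sweep(X, 2, sqrt(2 * p_hat * (1 - p_hat)), "/")
  sv <- svd(X, nu = k, nv = 0)
  U <- sv$u[, seq_len(k), drop = FALSE]
  B <- crossprod(U, X)                       # k x L regression coefficients
  rss <- pmax(colSums(X^2) - colSums(B^2), 0)
  sigma <- sqrt(pmax(rss / (n - k), 1e-12))
  z <- sweep(B, 2, sigma, "/")
  scale_l <- apply(z, 1, stats::mad)
  scale_l[scale_l <= 0] <- 1e-12
  D2 <- colSums((z / scale_l)^2)
  lambda <- stats::median(D2) / stats::qchisq(0.5, df = k)
  pvals <- stats::pchisq(D2 / lambda, df = k, lower.tail = FALSE)
  structure(list(stats = data.frame(D2 = D2, p = pvals, q = bh_fdr(pvals)),
                 lambda = lambda, k = k, zscores = z),
            class = "pca_scan")
}

#' @export
print.pca_scan <- function(x, ...) {
  cat(sprintf("pca_scan: %d sites, K = %d, lambda = %.3f\n",
              nrow(x$stats), x$k, x$lambda))
  invisible(x)
}

#' Dual-method outlier scan for one ecotype pair
#'
#' Runs the Fisher exact scan and the PCA-Mahalanobis scan on one derived
#' population contrasted with the ancestral population, adjusts each
#' p-value set by Benjamini-Hochberg within the pair, and flags outliers at
#' the configured thresholds.  Sites that are monomorphic across the pair
#' (or uncalled in either population) are excluded from the PCA scan and
#' carry `NA` statistics.
#'
#' @param panel a [genotype_panel()] containing both populations.
#' @param derived,ancestral population labels for the ecotype pair.
#' @param fet_fdr FET outlier threshold on the q-value (default 0.05).
#' @param pca_q PCA outlier threshold on the q-value (default 0.1).
#' @param k principal components for the PCA scan (default 2).
#' @return an object of class `outlier_scan`: a data.frame with columns
#'   `site`, `chrom`, `pos`, `fet_p`, `fet_q`, `pca_D2`, `pca_p`, `pca_q`,
#'   `fet_outlier`, `pca_outlier`, `dual_outlier`; attributes `lambda`,
#'   `pair`, `thresholds`.
#' @export
outlier_scan_pair <- function(panel, derived, ancestral,
                              fet_fdr = 0.05, pca_q = 0.1, k = 2L) {
  sub <- subset_populations(panel, c(derived, ancestral))
  ft <- allele_frequencies(sub)
  fet <- fisher_exact_scan(ft, c(derived, ancestral))
  fet_q <- bh_fdr(fet$p)

  L <- ncol(sub$genotypes)
  nc <- colSums(!is.na(sub$genotypes))
  pooled <- ifelse(nc > 0, colSums(sub$genotypes, na.rm = TRUE) / (2 * nc),
                   NA_real_)
  poly <- !is.na(pooled) & pooled > 0 & pooled < 1 &
    ft$an[derived, ] > 0 & ft$an[ancestral, ] > 0
  pca_D2 <- pca_p <- pca_qv <- rep(NA_real_, L)
  lambda <- NA_real_
  if (sum(poly) >= k + 2) {
    scan <- pca_outlier_scan(subset_sites(sub, poly), k = k)
    pca_D2[poly] <- scan$stats$D2
    pca_p[poly] <- scan$stats$p
    pca_qv[poly] <- scan$stats$q
    lambda <- scan$lambda
  }
  fet_out <- !is.na(fet_q) & fet_q < fet_fdr
  pca_out <- !is.na(pca_qv) & pca_qv < pca_q
  df <- data.frame(site = seq_len(L),
                   chrom = sub$sites$chrom, pos = sub$sites$pos,
                   fet_p = fet$p, fet_q = fet_q,
                   pca_D2 = pca_D2, pca_p = pca_p, pca_q = pca_qv,
                   fet_outlier = fet_out, pca_outlier = pca_out,
                   dual_outlier = fet_out & pca_out,
                   stringsAsFactors = FALSE)
  structure(df, class = c("outlier_scan", "data.frame"),
            lambda = lambda, pair = c(derived = derived, ancestral = ancestral),
            thresholds = c(fet_fdr = fet_fdr, pca_q = pca_q, k = k))
}

#' Scan every ecotype pair
#'
#' Applies [outlier_scan_pair()] to each derived population against the
#' ancestral one.
#'
#' @param panel a [genotype_panel()].
#' @param ancestral label of the ancestral population; all other
#'   populations are treated as derived.
#' @inheritParams outlier_scan_pair
#' @return a named list of `outlier_scan` objects (one per derived
#'   population), of class `outlier_scan_set`.
#' @export
scan_all_pairs <- function(panel, ancestral, fet_fdr = 0.05, pca_q = 0.1,
                           k = 2L) {
  pops <- panel_populations(panel)
  if (!ancestral %in% pops) stop("ancestral population not found: ", ancestral)
  derived <- setdiff(pops, ancestral)
  out <- lapply(derived, function(d) {
    outlier_scan_pair(panel, d, ancestral, fet_fdr = fet_fdr,
                      pca_q = pca_q, k = k)
  })
  names(out) <- derived
  structure(out, class = "outlier_scan_set", ancestral = ancestral)
}

#' @export
print.outlier_scan_set <- function(x, ...) {
  cat(sprintf("outlier_scan_set: %d ecotype pairs vs '%s'\n",
              length(x), attr(x, "ancestral")))
  for (nm in names(x)) {
    cat(sprintf("  %s: %d FET, %d PCA, %d dual outliers (lambda %.2f)\n",
                nm, sum(x[[nm]]$fet_outlier), sum(x[[nm]]$pca_outlier),
                sum(x[[nm]]$dual_outlier), attr(x[[nm]], "lambda")))
  }
  invisible(x)
}
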