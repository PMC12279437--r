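#' Individual-level heterozygosity
#'
#' Proportion of heterozygous genotypes among each sample's non-missing
#' genotypes; `NA` for samples with no called genotypes.
#'
#' @param panel a filtered [genotype_panel()].
#' @return named numeric vector, one proportion per sample.
#' @export
individual_heterozygosity <- function(panel) {
  g <- panel$genotypes
  called <- rowSums(!is.na(g))
  het <- rowSums(g == 1L, na.rm = TRUE)
  out <- ifelse(called > 0, het / called, NA_real_)
  stats::setNames(out, panel$samples)
}

#' Per-population allele frequencies
#'
#' For every population and site: the alternate-allele frequency
#' `p = (alt allele count) / (2 x called individuals)` and the callable
#' allele count `2n`.  `p` is `NA` where a population has no calls.
#'
#' @param panel a [genotype_panel()].
#' @return an object of class `freq_table`: matrices `p` and `an`
#'   (populations x sites), the population labels `pops`, and the panel's
#'   site table.
#' @export
allele_frequencies <- function(panel) {
  pops <- panel_populations(panel)
  g <- panel$genotypes
  labels <- panel$pop_map[panel$samples]
  p <- an <- matrix(NA_real_, nrow = length(pops), ncol = ncol(g),
                    dimnames = list(pops, NULL))
  for (pp in pops) {
    rows <- labels == pp
    nc <- colSums(!is.na(g[rows, , drop = FALSE]))
    alt <- colSums(g[rows, , drop = FALSE], na.rm = TRUE)
    an[pp, ] <- 2 * nc
    p[pp, ] <- ifelse(nc > 0, alt / (2 * nc), NA_real_)
  }
  structure(list(p = p, an = an, pops = pops, sites = panel$sites),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("freq_table: %d populations x %d sites\n",
              length(x$pops), ncol(x$p)))
  cat("populations:", paste(x$pops, collapse = ", "), "\n")
  invisible(x)
}

#' Folded minor-allele-frequency spectrum
#'
#' Histogram of pooled folded MAF `min(p, 1 - p)` over all sites with at
#' least one call, plus the fraction of sites with MAF at or below 0.05
#' (the rare-variant excess that makes a neutral spectrum L-shaped).
#' Intended for panels *not* filtered on MAF.
#'
#' @param panel a [genotype_panel()].
#' @param breaks histogram break points over `[0, 0.5]` (default 25 bins).
#' @return list with `maf` (per-site folded frequency), `breaks`, `counts`,
#'   and `frac_rare` (fraction of sites with MAF <= 0.05).
#' @export
maf_spectrum <- function(panel, breaks = seq(0, 0.5, length.out = 26)) {
  g <- panel$genotypes
  nc <- colSums(!is.na(g))
  p <- ifelse(nc > 0, colSums(g, na.rm = TRUE) / (2 * nc), NA_real_)
  maf <- pmin(p, 1 - p)
  maf <- maf[!is.na(maf)]
  h <- graphics::hist(maf, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  list(maf = maf, breaks = h$breaks, counts = h$counts,
       frac_rare = if (length(maf)) mean(maf <= 0.05) else NA_real_)
}

# Tajima (1989) normalising constants for n sequences.
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D for one population
#'
#' Computes `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))` per
#' non-overlapping window (bins of `window_bp` anchored at position 0),
#' with nucleotide diversity `pi` accumulated from per-site allele counts
#' (`2 a (n_i - a) / (n_i (n_i - 1))`) and the normalising constants
#' evaluated at the window's median number of called sequences (missing
#' genotypes make the sequence count vary by site).  Windows with fewer
#' than `min_segregating` segregating sites get `NA`.
#'
#' @param panel a [genotype_panel()].
#' @param population population label to analyse.
#' @param window_bp window width in base pairs (default 100000).
#' @param min_segregating minimum segregating sites per window (default 3).
#' @return data.frame with columns `chrom`, `start`, `end` (1-based,
#'   inclusive start, exclusive end), `n_sites`, `n_segregating`,
#'   `n_sequences`, `D`.
#' @export
tajimas_d_windows <- function(panel, population, window_bp = 100000L,
                              min_segregating = 3L) {
  sub <- subset_populations(panel, population)
  if (2 * nrow(sub$genotypes) < 4) {
    stop("Tajima's D needs at least 2 diploid individuals (4 sequences)")
  }
  g <- sub$genotypes
  n_seq <- 2 * colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  seg <- n_seq > 0 & alt > 0 & alt < n_seq
  pi_site <- ifelse(n_seq >= 2,
                    2 * alt * (n_seq - alt) / (n_seq * (n_seq - 1)),
                    0)
  bin <- sub$sites$pos %/% window_bp
  keys <- split(seq_along(bin), list(chrom = sub$sites$chrom, bin = bin),
                drop = TRUE)
  rows <- lapply(keys, function(idx) {
    S <- sum(seg[idx])
    usable <- n_seq[idx] >= 2
    n_med <- if (any(usable)) max(2L, as.integer(round(stats::median(n_seq[idx][usable])))) else NA_integer_
    D <- NA_real_
    if (S >= min_segregating && !is.na(n_med)) {
      k <- tajima_constants(n_med)
      num <- sum(pi_site[idx]) - S / k$a1
      den <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
      if (den > 0) D <- num / den
    }
    data.frame(chrom = sub$sites$chrom[idx[1]],
               start = bin[idx[1]] * window_bp,
               end = (bin[idx[1]] + 1) * window_bp,
               n_sites = length(idx), n_segregating = S,
               n_sequences = n_med, D = D,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Weir & Cockerham (1984) per-site variance components for two populations.
# Inputs are per-population called sample sizes, alt frequencies and
# observed heterozygote fractions; returns per-site a, b, c.
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

# Per-population site summaries needed by the FST machinery.
pop_site_stats <- function(g, rows) {
  sub <- g[rows, , drop = FALSE]
  n <- colSums(!is.na(sub))
  alt <- colSums(sub, na.rm = TRUE)
  het <- colSums(sub == 1L, na.rm = TRUE)
  list(n = n, p = ifelse(n > 0, alt / (2 * n), NA_real_),
       h = ifelse(n > 0, het / n, NA_real_))
}

#' Weir-Cockerham F_ST between two populations
#'
#' The Weir & Cockerham (1984) two-population estimator.  Per-site variance
#' components `a` (among populations) and `a + b + c` (total) are computed
#' at every site where both populations have at least two called
#' individuals, and the global estimate is the ratio of sums
#' `sum(a) / sum(a + b + c)` over sites with a defined denominator.
#'
#' @param panel a [genotype_panel()].
#' @param popA,popB population labels.
#' @return an object of class `wc_fst`: per-site `a` and `d = a + b + c`
#'   vectors (NA at non-contributing sites), the site index used, and the
#'   global `fst`.
#' @export
weir_cockerham_fst <- function(panel, popA, popB) {
  g <- panel$genotypes
  labels <- panel$pop_map[panel$samples]
  s1 <- pop_site_stats(g, labels == popA)
  s2 <- pop_site_stats(g, labels == popB)
  use <- s1$n >= 2 & s2$n >= 2
  if (!any(use)) stop("no sites with >= 2 called individuals in both populations")
  comp <- wc_components(s1$n[use], s2$n[use], s1$p[use], s2$p[use],
                        s1$h[use], s2$h[use])
  a <- d <- rep(NA_real_, ncol(g))
  a[use] <- comp$a
  d[use] <- comp$a + comp$b + comp$c
  denom <- sum(d, na.rm = TRUE)
  structure(list(a = a, d = d, sites_used = which(use),
                 fst = if (denom != 0) sum(a, na.rm = TRUE) / denom else NA_real_,
                 popA = popA, popB = popB),
            class = "wc_fst")
}

#' @export
print.wc_fst <- function(x, ...) {
  cat(sprintf("Weir-Cockerham FST (%s vs %s): %.5f over %d sites\n",
              x$popA, x$popB, x$fst, length(x$sites_used)))
  invisible(x)
}

# Global WC FST from a genotype submatrix and a logical group-A assignment;
# the permutation workhorse.
fst_from_assignment <- function(g, is_a) {
  s1 <- pop_site_stats(g, is_a)
  s2 <- pop_site_stats(g, !is_a)
  use <- s1$n >= 2 & s2$n >= 2
  if (!any(use)) return(NA_real_)
  comp <- wc_components(s1$n[use], s2$n[use], s1$p[use], s2$p[use],
                        s1$h[use], s2$h[use])
  denom <- sum(comp$a + comp$b + comp$c)
  if (denom == 0) return(NA_real_)
  sum(comp$a) / denom
}

#' Permutation test for pairwise F_ST
#'
#' Individuals are permuted between the two populations (preserving sample
#' sizes) and the global Weir-Cockerham estimate recomputed each time.  The
#' p-value uses the add-one correction
#' `p = (1 + #\{F_ST^perm >= F_ST^obs\}) / (1 + n_perm)`, which cannot be
#' exactly zero.
#'
#' @param panel a [genotype_panel()].
#' @param popA,popB population labels.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list with `fst` (observed), `p`, `n_perm`, `perm_fst`.
#' @export
fst_permutation_test <- function(panel, popA, popB, n_perm = 10000L,
                                 seed = 1L) {
  .check_count(n_perm, "n_perm", 1L)
  sub <- subset_populations(panel, c(popA, popB))
  g <- sub$genotypes
  labels <- sub$pop_map[sub$samples]
  is_a <- labels == popA
  obs <- fst_from_assignment(g, is_a)
  nA <- sum(is_a)
  n <- length(is_a)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, nA)
    fst_from_assignment(g, seq_len(n) %in% idx)
  }, 0)
  p <- (1 + sum(perm >= obs, na.rm = TRUE)) / (1 + n_perm)
  list(fst = obs, p = p, n_perm = n_perm, perm_fst = perm,
       popA = popA, popB = popB)
}

#' Pairwise F_ST matrix with permutation p-values
#'
#' All population pairs, with raw permutation p-values and a Bonferroni
#' adjustment across the pairs.
#'
#' @param panel a [genotype_panel()].
#' @param n_perm permutations per pair (default 10000).
#' @param seed master seed (per-pair seeds are derived from it).
#' @return list of matrices `fst`, `p`, `p_bonferroni` (populations x
#'   populations; lower triangle filled symmetrically).
#' @export
pairwise_fst <- function(panel, n_perm = 10000L, seed = 1L) {
  pops <- panel_populations(panel)
  k <- length(pops)
  fst <- p <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pairs <- utils::combn(k, 2)
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    res <- fst_permutation_test(panel, pops[i1], pops[i2], n_perm = n_perm,
                                seed = derive_seed(seed, "fst", j))
    fst[i1, i2] <- fst[i2, i1] <- res$fst
    p[i1, i2] <- p[i2, i1] <- res$p
  }
  list(fst = fst, p = p,
       p_bonferroni = pmin(p * ncol(pairs), 1))
}
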