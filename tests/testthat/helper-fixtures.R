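# Fixture builders shared across the suite; everything is generated in code.

# A small panel built directly from a genotype matrix.  `pops` maps each
# sample row to a population label.
toy_panel <- function(g, pops, chrom = NULL, pos = NULL, qual = 60,
                      multiallelic = FALSE, gq = NULL, dp = NULL) {
  g <- as.matrix(g)
  n_sites <- ncol(g)
  if (is.null(chrom)) chrom <- rep("chr1", n_sites)
  if (is.null(pos)) pos <- ave(seq_len(n_sites), chrom, FUN = seq_along) * 1000L
  samples <- sprintf("s%02d", seq_len(nrow(g)))
  rownames(g) <- samples
  genotype_panel(g,
                 data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                            qual = rep_len(qual, n_sites),
                            multiallelic = rep_len(multiallelic, n_sites)),
                 samples = samples,
                 pop_map = stats::setNames(pops, samples),
                 gq = gq, dp = dp)
}

# One panmictic population split arbitrarily into two labels -- a null
# dataset for scan calibration.
null_pair_panel <- function(n_per_group = 30, n_sites = 1000, seed = 1) {
  set.seed(seed)
  p <- runif(n_sites, 0.1, 0.9)
  n <- 2 * n_per_group
  g <- matrix(rbinom(n * n_sites, 2, rep(p, each = n)), nrow = n)
  toy_panel(g, rep(c("grpA", "grpB"), each = n_per_group))
}

# The study-design demographic model used throughout the tests.
study_model <- function(ancestral_ne = 1000L, derived_ne = 500L) {
  demographic_model(ancestral_ne, rep(derived_ne, 4), c(69L, 68L, 65L, 44L))
}

study_sizes <- c(20L, 46L, 48L, 24L, 23L)

# Independent brute-force Fisher exact p for a 2x2 table via choose();
# same two-sided rule as the scan (probability <= observed's, with the
# 1 + 1e-7 relative tolerance).
enum_fisher_p <- function(alt1, ref1, alt2, ref2) {
  m <- alt1 + alt2; n <- ref1 + ref2; k <- alt1 + ref1
  N <- m + n
  supp <- max(0, k - n):min(k, m)
  prob <- choose(m, supp) * choose(n, k - supp) / choose(N, k)
  p_obs <- choose(m, alt1) * choose(n, k - alt1) / choose(N, k)
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Frequency table assembled directly from per-population frequency
# vectors (callable allele counts `an`), bypassing genotype sampling.
freq_table_from_freqs <- function(p_list, an = 100) {
  pops <- names(p_list)
  p <- do.call(rbind, p_list)
  L <- ncol(p)
  structure(list(p = p,
                 an = matrix(an, nrow = length(pops), ncol = L,
                             dimnames = list(pops, NULL)),
                 pops = pops,
                 sites = data.frame(chrom = "chr1", pos = seq_len(L) * 1000L,
                                    ref = "A", alt = "T", qual = 60,
                                    multiallelic = FALSE)),
            class = "freq_table")
}
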