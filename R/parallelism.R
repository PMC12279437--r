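# Shared workhorse for direction-consistency: at each requested site,
# determine whether one allele's frequency is strictly greater in every
# derived population than in the ancestral population; if so, that allele
# is the freshwater-favoured allele (FWA).  Ties (any increment exactly 0)
# or mixed signs disqualify a site.  Returns the candidate table with the
# FWA frequency per population and the increment per derived population.
fwa_candidates <- function(freq_table, ancestral, sites = NULL,
                           warn_na = TRUE) {
  stopifnot(inherits(freq_table, "freq_table"),
            ancestral %in% freq_table$pops)
  derived <- setdiff(freq_table$pops, ancestral)
  if (!length(derived)) stop("no derived populations in the frequency table")
  if (is.null(sites)) sites <- seq_len(ncol(freq_table$p))
  sites <- sort(unique(as.integer(sites)))
  p_anc <- freq_table$p[ancestral, sites]
  p_der <- freq_table$p[derived, sites, drop = FALSE]
  delta <- sweep(p_der, 2, p_anc)                   # alt-allele increments
  has_na <- is.na(p_anc) | colSums(is.na(delta)) > 0
  if (warn_na && any(has_na)) {
    warning(sum(has_na), " site(s) dropped: undefined frequency in some population")
  }
  dmin <- apply(delta, 2, min)
  dmax <- apply(delta, 2, max)
  up <- !has_na & dmin > 0
  down <- !has_na & dmax < 0
  keep <- up | down
  fwa <- ifelse(up, "alt", "ref")[keep]
  idx <- sites[keep]
  dfwa <- delta[, keep, drop = FALSE]
  dfwa[, fwa == "ref"] <- -dfwa[, fwa == "ref", drop = FALSE]
  freq <- freq_table$p[c(ancestral, derived), idx, drop = FALSE]
  freq[, fwa == "ref"] <- 1 - freq[, fwa == "ref", drop = FALSE]
  out <- data.frame(site = idx,
                    chrom = freq_table$sites$chrom[idx],
                    pos = freq_table$sites$pos[idx],
                    fwa_allele = fwa, stringsAsFactors = FALSE)
  for (pp in c(ancestral, derived)) out[[paste0("fwa_freq_", pp)]] <- freq[pp, ]
  for (pp in derived) out[[paste0("dfwa_", pp)]] <- dfwa[pp, ]
  structure(out, class = c("candidate_set", "data.frame"),
            ancestral = ancestral, derived = derived)
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d sites, derived populations: %s\n",
              nrow(x), paste(attr(x, "derived"), collapse = ", ")))
  if (nrow(x)) {
    d <- as.matrix(x[, grep("^dfwa_", names(x)), drop = FALSE])
    cat(sprintf("  mean FWA increment: %.3f\n", mean(d)))
  }
  invisible(x)
}

#' Dual-method outlier sets per ecotype pair
#'
#' Sites flagged as outliers by both the exact-test scan and the PCA scan
#' within each pair.
#'
#' @param scan_results an `outlier_scan_set` (or a list of `outlier_scan`
#'   objects).
#' @param fet_fdr,pca_q thresholds re-applied to the stored q-values
#'   (defaults 0.05 and 0.1).
#' @return named list of integer site-index vectors, one per pair.
#' @export
dual_method_outliers <- function(scan_results, fet_fdr = 0.05, pca_q = 0.1) {
  lapply(scan_results, function(sc) {
    ok <- !is.na(sc$fet_q) & sc$fet_q < fet_fdr &
      !is.na(sc$pca_q) & sc$pca_q < pca_q
    sc$site[ok]
  })
}

#' Sites shared across ecotype pairs
#'
#' @param per_pair_sets list of site-index vectors.
#' @param min_pairs minimum number of pairs a site must appear in
#'   (default 3).
#' @return sorted integer vector of shared site indices.
#' @export
shared_outliers <- function(per_pair_sets, min_pairs = 3L) {
  if (min_pairs > length(per_pair_sets)) {
    stop("min_pairs exceeds the number of pairs supplied")
  }
  counts <- table(unlist(lapply(per_pair_sets, unique)))
  sort(as.integer(names(counts)[counts >= min_pairs]))
}

#' Direction-consistent candidates
#'
#' Keeps the sites in `sites` where one allele's frequency is strictly
#' greater in every derived population than in the ancestral population;
#' that allele is recorded as the freshwater-favoured allele (FWA).  A tie
#' (any increment exactly zero) or mixed signs excludes the site, as does
#' an undefined frequency in any population (with a warning).
#'
#' @param freq_table a `freq_table` covering the ancestral and all derived
#'   populations.
#' @param sites integer site indices to evaluate.
#' @param ancestral label of the ancestral population.
#' @return a `candidate_set` data.frame: `site`, `chrom`, `pos`,
#'   `fwa_allele`, per-population `fwa_freq_*`, per-derived `dfwa_*`.
#' @export
direction_consistent <- function(freq_table, sites, ancestral) {
  fwa_candidates(freq_table, ancestral, sites = sites)
}

#' Exact multi-set intersection test
#'
#' Distribution of the intersection size of `t` random subsets of sizes
#' `m_1..m_t` drawn uniformly from a universe of `N` elements.  The exact
#' distribution is built by iterated convolution: the overlap after adding
#' set `i` is hypergeometric given the overlap after set `i - 1`.  The tail
#' p-value is `P(X >= x)` and the expected intersection is
#' `N * prod(m_i / N)`.  For configurations where the exact recursion
#' would exceed `cost_bound` operations, a seeded Monte-Carlo fallback is
#' used (reporting its standard error).
#'
#' @param sizes integer vector of set sizes.
#' @param universe universe size `N` (all `sizes <= N`).
#' @param observed observed intersection count `x <= min(sizes)`.
#' @param method `"auto"` (default), `"exact"` or `"mc"`.
#' @param n_draws Monte-Carlo draws when the fallback is used
#'   (default 1e5).
#' @param cost_bound operation bound above which `"auto"` switches to
#'   Monte-Carlo (default 5e7).
#' @param seed seed for the Monte-Carlo fallback.
#' @return an object of class `intersection_test`: `sizes`, `universe`,
#'   `observed`, `expected`, `p`, `method`, and (exact method only) the
#'   full `distribution` over 0..min(sizes); Monte-Carlo results carry
#'   `mc_se`.
#' @export
multiset_intersection_test <- function(sizes, universe, observed,
                                       method = c("auto", "exact", "mc"),
                                       n_draws = 1e5, cost_bound = 5e7,
                                       seed = 1L) {
  method <- match.arg(method)
  .check_count(sizes, "sizes")
  .check_count(universe, "universe", 1L)
  .check_count(observed, "observed")
  if (any(sizes > universe)) stop("set sizes must not exceed the universe")
  if (observed > min(sizes)) stop("observed overlap exceeds the smallest set")
  t <- length(sizes)
  expected <- universe * prod(sizes / universe)
  cost <- t * (min(sizes) + 1)^2
  if (method == "auto") method <- if (cost <= cost_bound) "exact" else "mc"
  if (method == "exact") {
    # dist[j + 1] = P(intersection of first i sets == j)
    dist <- rep(0, min(sizes) + 1)
    dist[min(sizes[1], length(dist) - 1) + 1] <- 0
    dist <- numeric(sizes[1] + 1)
    dist[sizes[1] + 1] <- 1
    for (i in seq_len(t)[-1]) {
      prev <- dist
      max_new <- min(length(prev) - 1, sizes[i])
      dist <- numeric(max_new + 1)
      for (j in which(prev > 0) - 1) {
        l <- 0:min(j, sizes[i])
        dist[l + 1] <- dist[l + 1] +
          prev[j + 1] * stats::dhyper(l, j, universe - j, sizes[i])
      }
    }
    p <- sum(dist[(observed + 1):length(dist)])
    p <- min(max(p, .Machine$double.xmin), 1)
    res <- list(distribution = dist, p = p, mc_se = NA_real_)
  } else {
    set.seed(seed)
    draws <- vapply(seq_len(n_draws), function(i) {
      inter <- sample.int(universe, sizes[1])
      for (j in seq_len(t)[-1]) {
        inter <- intersect(inter, sample.int(universe, sizes[j]))
        if (!length(inter)) break
      }
      length(inter)
    }, 0L)
    phat <- mean(draws >= observed)
    res <- list(distribution = NULL,
                p = max(phat, 1 / (n_draws + 1)),
                mc_se = sqrt(phat * (1 - phat) / n_draws))
  }
  structure(list(sizes = sizes, universe = universe, observed = observed,
                 expected = expected, p = res$p, method = method,
                 distribution = res$distribution, mc_se = res$mc_se),
            class = "intersection_test")
}

#' @export
print.intersection_test <- function(x, ...) {
  cat(sprintf(
    "intersection_test (%s): %d sets in universe %d\n  observed %d, expected %.3f, P(X >= obs) = %.4g\n",
    x$method, length(x$sizes), x$universe, x$observed, x$expected, x$p))
  invisible(x)
}

#' Frequency-shift summaries for a candidate set
#'
#' Per-population mean FWA frequency, and per derived population the mean
#' increment, the fraction of candidates whose FWA is fixed (frequency 1)
#' and the fraction above 0.8.
#'
#' @param candidates a `candidate_set`.
#' @param freq_table unused placeholder kept for call-site symmetry with
#'   the extraction functions (the candidate table already carries the
#'   frequencies); may be omitted.
#' @return data.frame, one row per population, with columns
#'   `population`, `role`, `mean_fwa_freq`, `mean_dfwa`, `frac_fixed`,
#'   `frac_above_0.8`.  Empty candidate sets yield an empty frame with a
#'   warning.
#' @export
fwa_shift_summary <- function(candidates, freq_table = NULL) {
  anc <- attr(candidates, "ancestral")
  der <- attr(candidates, "derived")
  if (!nrow(candidates)) {
    warning("empty candidate set")
    return(data.frame(population = character(0), role = character(0),
                      mean_fwa_freq = numeric(0), mean_dfwa = numeric(0),
                      frac_fixed = numeric(0), frac_above_0.8 = numeric(0)))
  }
  rows <- lapply(c(anc, der), function(pp) {
    f <- candidates[[paste0("fwa_freq_", pp)]]
    d <- if (pp %in% der) candidates[[paste0("dfwa_", pp)]] else NA_real_
    data.frame(population = pp,
               role = if (pp == anc) "ancestral" else "derived",
               mean_fwa_freq = mean(f),
               mean_dfwa = mean(d),
               frac_fixed = if (pp %in% der) mean(f == 1) else NA_real_,
               frac_above_0.8 = if (pp %in% der) mean(f > 0.8) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' The full candidate funnel
#'
#' Composes the parallelism filters: dual-method outliers per pair, shared
#' across at least `min_pairs` pairs, then strict direction consistency
#' across every derived population.
#'
#' @param scan_results an `outlier_scan_set`.
#' @param freq_table a `freq_table` over all populations.
#' @param ancestral ancestral population label.
#' @param min_pairs sharing threshold (default 3).
#' @param fet_fdr,pca_q outlier thresholds (defaults 0.05, 0.1).
#' @return a `candidate_set` with an extra `n_pairs_flagged` column.
#' @export
candidate_outliers <- function(scan_results, freq_table, ancestral,
                               min_pairs = 3L, fet_fdr = 0.05, pca_q = 0.1) {
  duals <- dual_method_outliers(scan_results, fet_fdr = fet_fdr,
                                pca_q = pca_q)
  shared <- shared_outliers(duals, min_pairs = min_pairs)
  cand <- direction_consistent(freq_table, shared, ancestral)
  counts <- table(unlist(lapply(duals, unique)))
  cand$n_pairs_flagged <- as.integer(counts[as.character(cand$site)])
  cand
}
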