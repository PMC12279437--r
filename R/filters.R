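#' Site filter configuration
#'
#' Thresholds for the seven-part SNP filter: genotype-level masking
#' (genotype quality, depth) followed by site-level tests (biallelic, site
#' quality, call rate overall and per population, observed heterozygosity,
#' and a global-MAF test with a local-MAF rescue).
#'
#' @param min_q minimum site quality score (default 30).
#' @param min_gq minimum genotype quality; genotypes below are masked
#'   (default 20).
#' @param min_depth minimum per-genotype depth; genotypes below are masked
#'   (default 7).
#' @param min_call_fraction minimum fraction of all samples called at a
#'   site (default 0.9).
#' @param min_per_pop_calls minimum called individuals per population
#'   (default 12).
#' @param max_het maximum global observed heterozygosity, the fraction of
#'   non-missing genotypes that are heterozygous (default 0.8).
#' @param min_global_maf minimum pooled minor-allele frequency
#'   (default 0.05).
#' @param local_maf_rescue a site failing the global MAF test is retained
#'   if its within-population MAF reaches this value in any population
#'   (default 0.2).
#' @return an object of class `site_filter_config`.
#' @export
site_filter_config <- function(min_q = 30, min_gq = 20L, min_depth = 7L,
                               min_call_fraction = 0.9,
                               min_per_pop_calls = 12L,
                               max_het = 0.8, min_global_maf = 0.05,
                               local_maf_rescue = 0.2) {
  .check_prob(min_call_fraction, "min_call_fraction")
  .check_prob(max_het, "max_het")
  .check_prob(min_global_maf, "min_global_maf")
  .check_prob(local_maf_rescue, "local_maf_rescue")
  structure(list(min_q = min_q, min_gq = min_gq, min_depth = min_depth,
                 min_call_fraction = min_call_fraction,
                 min_per_pop_calls = min_per_pop_calls,
                 max_het = max_het, min_global_maf = min_global_maf,
                 local_maf_rescue = local_maf_rescue),
            class = "site_filter_config")
}

#' Apply the SNP site filters
#'
#' Individual genotypes failing the GQ or depth thresholds are masked
#' (set missing) first, since the call-rate tests depend on post-masking
#' missingness.  Sites are then dropped unless they pass, in order:
#' biallelic; site quality; call rate (overall fraction and per-population
#' count); observed heterozygosity; and global MAF with the local-MAF
#' rescue.  Each removed site is charged to the first criterion it fails,
#' so the per-criterion counts plus the survivors sum to the input count.
#' The whole procedure is idempotent.
#'
#' @param panel a [genotype_panel()].
#' @param config a [site_filter_config()].
#' @return an object of class `site_filter_result`: `panel` (the filtered
#'   panel), `removed` (named per-criterion removal counts),
#'   `masked_genotypes` (number of genotype calls masked), and `n_input`.
#' @export
apply_site_filters <- function(panel, config = site_filter_config()) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(config, "site_filter_config"))
  if (ncol(panel$genotypes) == 0) stop("panel has no sites")
  g <- panel$genotypes
  masked <- 0L
  if (!is.null(panel$gq)) {
    bad <- !is.na(g) & (is.na(panel$gq) | panel$gq < config$min_gq)
    masked <- masked + sum(bad)
    g[bad] <- NA_integer_
  }
  if (!is.null(panel$dp)) {
    bad <- !is.na(g) & (is.na(panel$dp) | panel$dp < config$min_depth)
    masked <- masked + sum(bad)
    g[bad] <- NA_integer_
  }
  n_samples <- nrow(g)
  pops <- panel$pop_map[panel$samples]
  called <- !is.na(g)
  n_called <- colSums(called)
  alt <- colSums(g, na.rm = TRUE)
  het <- colSums(g == 1L, na.rm = TRUE)

  p_global <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  maf_global <- pmin(p_global, 1 - p_global)
  ho <- ifelse(n_called > 0, het / n_called, NA_real_)

  pop_levels <- unique(unname(pops))
  pop_called_ok <- rep(TRUE, ncol(g))
  local_rescue <- rep(FALSE, ncol(g))
  for (pp in pop_levels) {
    rows <- pops == pp
    nc <- colSums(called[rows, , drop = FALSE])
    pop_called_ok <- pop_called_ok & (nc >= config$min_per_pop_calls)
    ap <- colSums(g[rows, , drop = FALSE], na.rm = TRUE)
    pl <- ifelse(nc > 0, ap / (2 * nc), NA_real_)
    mafl <- pmin(pl, 1 - pl)
    local_rescue <- local_rescue | (!is.na(mafl) & mafl >= config$local_maf_rescue)
  }

  pass <- list(
    biallelic = !panel$sites$multiallelic,
    site_quality = is.na(panel$sites$qual) | panel$sites$qual >= config$min_q,
    call_rate = n_called >= config$min_call_fraction * n_samples & pop_called_ok,
    heterozygosity = !is.na(ho) & ho <= config$max_het,
    maf = (!is.na(maf_global) & maf_global >= config$min_global_maf) | local_rescue
  )
  alive <- rep(TRUE, ncol(g))
  removed <- stats::setNames(integer(length(pass)), names(pass))
  for (crit in names(pass)) {
    fail <- alive & !pass[[crit]]
    removed[crit] <- sum(fail)
    alive <- alive & !fail
  }
  out <- panel
  out$genotypes <- g
  out <- subset_sites(out, alive)
  structure(list(panel = out, removed = removed,
                 masked_genotypes = masked,
                 n_input = ncol(panel$genotypes)),
            class = "site_filter_result")
}

#' @export
print.site_filter_result <- function(x, ...) {
  cat(sprintf("site_filter_result: %d of %d sites retained\n",
              ncol(x$panel$genotypes), x$n_input))
  cat(sprintf("  genotypes masked (GQ/depth): %d\n", x$masked_genotypes))
  for (crit in names(x$removed)) {
    cat(sprintf("  removed by %-15s %d\n", paste0(crit, ":"), x$removed[[crit]]))
  }
  invisible(x)
}

#' Write a filter report TSV
#' @param result a `site_filter_result`.
#' @param path output path.
#' @export
write_filter_report <- function(result, path) {
  df <- data.frame(criterion = c(names(result$removed), "retained"),
                   count = c(unname(result$removed),
                             ncol(result$panel$genotypes)))
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Thin sites to one SNP per window
#'
#' Within each non-overlapping `[k * window, (k + 1) * window)` bin per
#' chromosome (bins anchored at position 0), only the first SNP is kept --
#' the standard crude guard against linkage disequilibrium between nearby
#' markers.
#'
#' @param panel a [genotype_panel()] with sites sorted by position.
#' @param window_bp bin width in base pairs (default 10000).
#' @return the thinned [genotype_panel()].
#' @export
thin_by_window <- function(panel, window_bp = 10000L) {
  if (!is.numeric(window_bp) || window_bp <= 0) {
    stop("window_bp must be a positive number")
  }
  key <- paste(panel$sites$chrom, panel$sites$pos %/% window_bp)
  subset_sites(panel, !duplicated(key))
}
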