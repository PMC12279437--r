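#' Construct a genotype panel
#'
#' The central data container of the pipeline: a samples-by-sites matrix of
#' diploid genotype codes together with per-site metadata and a
#' sample-to-population map.  Genotypes are coded 0 (homozygous reference),
#' 1 (heterozygous), 2 (homozygous alternate) or `NA` (missing).
#'
#' @param genotypes integer matrix, samples in rows, sites in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param sites data.frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`; optional `qual` (site quality) and `multiallelic`
#'   (logical flag set by the VCF reader for records with >1 ALT allele).
#' @param samples character vector of sample identifiers (defaults to the
#'   rownames of `genotypes`).
#' @param pop_map named character vector mapping every sample id to a
#'   population label.
#' @param gq,dp optional integer matrices of per-genotype quality and depth,
#'   same shape as `genotypes`.
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(genotypes, sites, samples = rownames(genotypes),
                           pop_map, gq = NULL, dp = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(genotypes)))
  rownames(genotypes) <- samples
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (is.null(sites$qual)) sites$qual <- NA_real_
  if (is.null(sites$multiallelic)) sites$multiallelic <- FALSE
  rownames(sites) <- NULL
  obj <- structure(list(genotypes = genotypes, sites = sites,
                        samples = samples, pop_map = pop_map,
                        gq = gq, dp = dp),
                   class = "genotype_panel")
  validate_panel(obj)
  obj
}

#' Validate a genotype panel
#'
#' Checks the container invariants: genotype codes in `{0,1,2,NA}`,
#' strictly increasing positions within each chromosome, and a population
#' label for every sample.
#'
#' @param panel a `genotype_panel`.
#' @return the panel, invisibly; errors describe the first violation.
#' @export
validate_panel <- function(panel) {
  g <- panel$genotypes
  if (nrow(panel$sites) != ncol(g)) {
    stop("site table and genotype matrix disagree on the number of sites")
  }
  bad <- !(g %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (nrow(panel$sites) > 1) {
    by_chr <- split(panel$sites$pos, panel$sites$chrom)
    if (any(vapply(by_chr, function(p) any(diff(p) <= 0), FALSE))) {
      stop("positions must be strictly increasing within each chromosome")
    }
  }
  missing_pop <- setdiff(panel$samples, names(panel$pop_map))
  if (length(missing_pop)) {
    stop("samples missing from the population map: ",
         paste(missing_pop, collapse = ", "))
  }
  for (m in c("gq", "dp")) {
    if (!is.null(panel[[m]]) && !identical(dim(panel[[m]]), dim(g))) {
      stop(sprintf("'%s' matrix must match the genotype matrix shape", m))
    }
  }
  invisible(panel)
}

#' @export
print.genotype_panel <- function(x, ...) {
  pops <- table(x$pop_map[x$samples])
  cat(sprintf("genotype_panel: %d samples x %d sites\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  cat("populations:",
      paste(sprintf("%s (%d)", names(pops), as.integer(pops)), collapse = ", "),
      "\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Population labels present in a panel
#' @param panel a `genotype_panel`.
#' @return character vector of population labels in order of first appearance.
#' @export
panel_populations <- function(panel) {
  unique(unname(panel$pop_map[panel$samples]))
}

#' Subset a panel by site index
#' @param panel a `genotype_panel`.
#' @param idx integer or logical index over sites.
#' @return the reduced `genotype_panel`.
#' @export
subset_sites <- function(panel, idx) {
  genotype_panel(panel$genotypes[, idx, drop = FALSE],
                 panel$sites[idx, , drop = FALSE],
                 samples = panel$samples,
                 pop_map = panel$pop_map,
                 gq = if (!is.null(panel$gq)) panel$gq[, idx, drop = FALSE],
                 dp = if (!is.null(panel$dp)) panel$dp[, idx, drop = FALSE])
}

#' Subset a panel to a set of populations
#' @param panel a `genotype_panel`.
#' @param pops character vector of population labels to keep.
#' @return the reduced `genotype_panel`.
#' @export
subset_populations <- function(panel, pops) {
  keep <- panel$samples[panel$pop_map[panel$samples] %in% pops]
  if (!length(keep)) stop("no samples in populations: ",
                          paste(pops, collapse = ", "))
  genotype_panel(panel$genotypes[keep, , drop = FALSE],
                 panel$sites,
                 samples = keep,
                 pop_map = panel$pop_map[keep],
                 gq = if (!is.null(panel$gq)) panel$gq[keep, , drop = FALSE],
                 dp = if (!is.null(panel$dp)) panel$dp[keep, , drop = FALSE])
}

#' Combine single-population panels over the same sites
#' @param panels list of `genotype_panel` objects sharing a site table.
#' @return one merged `genotype_panel`.
#' @export
bind_panels <- function(panels) {
  stopifnot(length(panels) >= 1)
  sites <- panels[[1]]$sites
  g <- do.call(rbind, lapply(panels, `[[`, "genotypes"))
  samples <- unlist(lapply(panels, `[[`, "samples"), use.names = FALSE)
  if (anyDuplicated(samples)) stop("duplicate sample ids across panels")
  pop_map <- do.call(c, lapply(panels, `[[`, "pop_map"))
  genotype_panel(g, sites, samples = samples, pop_map = pop_map)
}
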