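#' Read a sample-to-population map
#'
#' Whitespace-delimited two-column file: `sample_id population_id`.
#'
#' @param path file path.
#' @return named character vector mapping sample id to population label.
#' @export
read_pop_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("sample", "population"))
  if (anyDuplicated(tab$sample)) stop("duplicate sample ids in population map")
  stats::setNames(tab$population, tab$sample)
}

#' Write a sample-to-population map
#' @param pop_map named character vector (names are sample ids).
#' @param path output path.
#' @export
write_pop_map <- function(pop_map, path) {
  utils::write.table(data.frame(sample = names(pop_map),
                                population = unname(pop_map)),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a multi-sample VCF into a genotype panel
#'
#' Parses the VCF with vcfR and assembles the panel: genotype codes
#' (alternate-allele dosage), per-site QUAL, and per-genotype GQ and DP
#' matrices when the FORMAT declares them.  Multiallelic records are
#' retained but flagged; genotypes carrying alleles beyond the first ALT are
#' set missing (such records are removed by the biallelic filter criterion).
#' No GQ/DP masking happens here -- that is a filtering-stage concern.
#'
#' @param path VCF 4.x file (gzip-transparent).
#' @param pop_map_path path to the two-column sample-to-population map.
#' @return a [genotype_panel()].
#' @export
read_vcf <- function(path, pop_map_path) {
  pop_map <- read_pop_map(pop_map_path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"],
                      alt = fix[, "ALT"],
                      qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
                      multiallelic = grepl(",", fix[, "ALT"], fixed = TRUE),
                      stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  missing_pop <- setdiff(samples, names(pop_map))
  if (length(missing_pop)) {
    stop("VCF samples absent from the population map: ",
         paste(missing_pop, collapse = ", "))
  }
  g <- t(gt_to_dosage(gt))
  fmt_has <- function(el) {
    any(grepl(paste0("(^|:)", el, "(:|$)"), vcf@gt[, "FORMAT"]))
  }
  grab <- function(el) {
    if (!fmt_has(el)) return(NULL)
    m <- t(vcfR::extract.gt(vcf, element = el, as.numeric = TRUE))
    storage.mode(m) <- "integer"
    m
  }
  genotype_panel(g, sites, samples = samples, pop_map = pop_map[samples],
                 gq = grab("GQ"), dp = grab("DP"))
}

# "0/1", "1|1", "./." ... -> dosage 0/1/2/NA; alleles >1 -> NA.
gt_to_dosage <- function(gt) {
  codes <- c("0/0" = 0L, "0|0" = 0L,
             "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
             "1/1" = 2L, "1|1" = 2L)
  out <- codes[gt]
  dim(out) <- dim(gt)
  dimnames(out) <- dimnames(gt)
  out
}

#' Write a genotype panel as VCF 4.2
#'
#' Emits CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO plus FORMAT GT (and GQ/DP
#' when the panel carries them).  A `.gz` suffix triggers gzip compression.
#'
#' @param panel a [genotype_panel()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(panel, path) {
  s <- panel$sites
  gt_codes <- c("0/0", "0/1", "1/1")
  g <- panel$genotypes
  body <- matrix(gt_codes[g + 1L], nrow = nrow(g))
  body[is.na(g)] <- "./."
  fmt <- "GT"
  fmt_append <- function(body, m, tag) {
    v <- matrix(as.character(m), nrow = nrow(m))
    v[is.na(m)] <- "."
    matrix(paste(body, v, sep = ":"), nrow = nrow(body))
  }
  if (!is.null(panel$gq)) { body <- fmt_append(body, panel$gq, "GQ"); fmt <- paste0(fmt, ":GQ") }
  if (!is.null(panel$dp)) { body <- fmt_append(body, panel$dp, "DP"); fmt <- paste0(fmt, ":DP") }
  qual <- ifelse(is.na(s$qual), ".", format(s$qual, trim = TRUE, scientific = FALSE))
  lines <- c("##fileformat=VCFv4.2",
             "##source=fwadapt",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             if (!is.null(panel$gq)) '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
             if (!is.null(panel$dp)) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", panel$samples), collapse = "\t"))
  rows <- vapply(seq_len(nrow(s)), function(j) {
    paste(c(s$chrom[j], s$pos[j], ".", s$ref[j], s$alt[j], qual[j], "PASS",
            ".", fmt, body[, j]), collapse = "\t")
  }, "")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(lines, rows), con)
  invisible(path)
}

#' Write a simulation truth table
#' @param truth the `truth` data.frame from [generate_study_dataset()].
#' @param path output TSV path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
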