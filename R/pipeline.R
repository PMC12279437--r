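stop_config <- function(...) {
  stop(structure(class = c("fwadapt_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
stop_input <- function(...) {
  stop(structure(class = c("fwadapt_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis.  In `"simulate"` mode
#' the input panel comes from [generate_study_dataset()]; in `"vcf"` mode
#' it is read from `vcf`/`pop_map`.  The demographic model always has to
#' be supplied (it drives the simulator and the neutral null; founding
#' times and effective sizes are inputs, not estimates).
#'
#' @param mode `"simulate"` or `"vcf"`.
#' @param model a [demographic_model()].
#' @param out_dir output directory for reports and stage TSVs.
#' @param seed master seed; every stage seed is derived from it.
#' @param vcf,pop_map input paths (`"vcf"` mode).
#' @param ancestral label of the ancestral population.
#' @param n_loci,n_selected,s simulation size and selection
#'   (`"simulate"` mode).
#' @param sample_sizes individuals per population, ancestral first
#'   (`"simulate"` mode; defaults to the study design 20/46/48/24/23).
#' @param filter a [site_filter_config()].
#' @param thin_window optional thinning window in bp (`NULL` = no
#'   thinning; thinning is reported but the scans run on the full filtered
#'   panel).
#' @param fet_fdr,pca_q,k outlier-scan thresholds.
#' @param min_pairs sharing threshold for candidate outliers.
#' @param delta,n_reps,n_samplings covariant threshold and neutral-null
#'   replication.
#' @param fst_n_perm permutations per population pair for the FST test.
#' @return an object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "vcf"), model, out_dir,
                       seed = 1L, vcf = NULL, pop_map = NULL,
                       ancestral = "ancestral",
                       n_loci = 2000L, n_selected = 100L, s = 0.25,
                       sample_sizes = c(20L, 46L, 48L, 24L, 23L),
                       filter = site_filter_config(),
                       thin_window = NULL,
                       fet_fdr = 0.05, pca_q = 0.1, k = 2L,
                       min_pairs = 3L,
                       delta = 0.2, n_reps = 200L, n_samplings = 10L,
                       fst_n_perm = 10000L) {
  mode <- match.arg(mode)
  if (!inherits(model, "demographic_model")) {
    stop_config("'model' must be a demographic_model")
  }
  if (mode == "vcf" && (is.null(vcf) || is.null(pop_map))) {
    stop_config("vcf mode requires 'vcf' and 'pop_map' paths")
  }
  for (v in c(fet_fdr, pca_q, delta)) .check_prob(v, "threshold")
  .check_count(min_pairs, "min_pairs", 1L)
  structure(list(mode = mode, model = model, out_dir = out_dir, seed = seed,
                 vcf = vcf, pop_map = pop_map, ancestral = ancestral,
                 n_loci = n_loci, n_selected = n_selected, s = s,
                 sample_sizes = sample_sizes, filter = filter,
                 thin_window = thin_window,
                 fet_fdr = fet_fdr, pca_q = pca_q, k = k,
                 min_pairs = min_pairs, delta = delta,
                 n_reps = n_reps, n_samplings = n_samplings,
                 fst_n_perm = fst_n_perm),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  path
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$model <- unclass(out$model)
  out$filter <- unclass(out$filter)
  out
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- input (simulate or ingest), site
#' filtering, population-genetic summaries, dual-method outlier scans,
#' cross-pair parallelism, and the covariant procedure with its simulated
#' neutral null -- writing stage TSVs, a machine-readable `report.json`
#' and a timing log into `config$out_dir`.  Identical config + seed gives
#' byte-identical reports (timings go to the log only).
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages (default TRUE).
#' @return an object of class `fwadapt_run`: the `report` list plus the
#'   major intermediate objects (`panel`, `scans`, `candidates`,
#'   `covariant`, `null`, `ztest`).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$out_dir, "run.log")
  cat("", file = logfile)
  t0 <- Sys.time()
  note <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    cat(msg, "\n", file = logfile, append = TRUE)
    if (!quiet) message(msg)
  }
  jsonlite::write_json(config_as_list(config),
                       file.path(config$out_dir, "config_used.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  report <- list(seed = config$seed, stages = list())
  stage_sites <- function(name, n) report$stages[[name]] <<- list(sites = n)

  # --- input ----------------------------------------------------------
  note("stage input (", config$mode, " mode)")
  truth <- NULL
  if (config$mode == "simulate") {
    sim <- generate_study_dataset(config$model, config$n_loci,
                                  config$n_selected, config$sample_sizes,
                                  seed = derive_seed(config$seed, "dataset"),
                                  s = config$s,
                                  ancestral_name = config$ancestral)
    panel <- sim$panel
    truth <- sim$truth
    write_tsv(truth, file.path(config$out_dir, "truth.tsv"))
  } else {
    if (!file.exists(config$vcf)) stop_input("VCF not found: ", config$vcf)
    panel <- read_vcf(config$vcf, config$pop_map)
  }
  pops <- panel_populations(panel)
  if (length(pops) < 2) stop_input("need at least 2 populations")
  if (!config$ancestral %in% pops) {
    stop_input("ancestral population '", config$ancestral, "' not in panel")
  }
  derived <- setdiff(pops, config$ancestral)
  if (config$min_pairs > length(derived)) {
    stop_config("min_pairs (", config$min_pairs, ") exceeds the number of ecotype pairs (",
                length(derived), ")")
  }
  stage_sites("input", ncol(panel$genotypes))

  # --- filter ---------------------------------------------------------
  note("stage filter")
  filt <- apply_site_filters(panel, config$filter)
  panel <- filt$panel
  write_filter_report(filt, file.path(config$out_dir, "filter_report.tsv"))
  report$stages$filter <- list(sites = ncol(panel$genotypes),
                               removed = as.list(filt$removed),
                               masked_genotypes = filt$masked_genotypes)
  if (ncol(panel$genotypes) == 0) stop_input("no sites survived filtering")
  if (!is.null(config$thin_window)) {
    thinned <- thin_by_window(panel, config$thin_window)
    report$stages$thin <- list(sites = ncol(thinned$genotypes),
                               window_bp = config$thin_window)
  }

  # --- summaries ------------------------------------------------------
  note("stage stats")
  het <- individual_heterozygosity(panel)
  write_tsv(data.frame(sample = names(het),
                       population = unname(panel$pop_map[names(het)]),
                       heterozygosity = unname(het)),
            file.path(config$out_dir, "heterozygosity.tsv"))
  ft <- allele_frequencies(panel)
  freq_long <- do.call(rbind, lapply(ft$pops, function(pp) {
    data.frame(population = pp, site = seq_len(ncol(ft$p)),
               chrom = ft$sites$chrom, pos = ft$sites$pos,
               p = ft$p[pp, ], an = ft$an[pp, ])
  }))
  write_tsv(freq_long, file.path(config$out_dir, "frequencies.tsv"))
  taj <- do.call(rbind, lapply(pops, function(pp) {
    cbind(population = pp, tajimas_d_windows(panel, pp))
  }))
  write_tsv(taj, file.path(config$out_dir, "tajimas_d.tsv"))
  fst <- pairwise_fst(panel, n_perm = config$fst_n_perm,
                      seed = derive_seed(config$seed, "fst"))
  fst_long <- do.call(rbind, apply(utils::combn(length(pops), 2), 2, function(ij) {
    data.frame(popA = pops[ij[1]], popB = pops[ij[2]],
               fst = fst$fst[ij[1], ij[2]], p = fst$p[ij[1], ij[2]],
               p_bonferroni = fst$p_bonferroni[ij[1], ij[2]])
  }))
  write_tsv(fst_long, file.path(config$out_dir, "fst_pairwise.tsv"))
  report$stages$stats <- list(sites = ncol(panel$genotypes),
                              mean_heterozygosity = mean(het, na.rm = TRUE),
                              fst = fst_long)

  # --- outlier scans --------------------------------------------------
  note("stage scan")
  scans <- scan_all_pairs(panel, config$ancestral, fet_fdr = config$fet_fdr,
                          pca_q = config$pca_q, k = config$k)
  for (nm in names(scans)) {
    write_tsv(as.data.frame(scans[[nm]]),
              file.path(config$out_dir, paste0("scan_", nm, ".tsv")))
  }
  report$stages$scan <- list(
    sites = ncol(panel$genotypes),
    lambda = lapply(scans, attr, "lambda"),
    dual_outliers = lapply(scans, function(s) sum(s$dual_outlier)))

  # --- parallelism ----------------------------------------------------
  note("stage parallelism")
  duals <- dual_method_outliers(scans, config$fet_fdr, config$pca_q)
  shared <- shared_outliers(duals, config$min_pairs)
  candidates <- candidate_outliers(scans, ft, config$ancestral,
                                   min_pairs = config$min_pairs,
                                   fet_fdr = config$fet_fdr,
                                   pca_q = config$pca_q)
  write_tsv(as.data.frame(candidates),
            file.path(config$out_dir, "candidates.tsv"))
  inter <- NULL
  if (length(duals) >= 2 && all(lengths(duals) > 0)) {
    all_shared <- Reduce(intersect, duals)
    inter <- multiset_intersection_test(lengths(duals),
                                        ncol(panel$genotypes),
                                        length(all_shared),
                                        seed = derive_seed(config$seed, "inter"))
    jsonlite::write_json(
      list(sizes = inter$sizes, universe = inter$universe,
           observed = inter$observed, expected = inter$expected,
           p = inter$p, method = inter$method),
      file.path(config$out_dir, "intersection_test.json"),
      auto_unbox = TRUE, digits = NA)
  }
  report$stages$parallelism <- list(
    dual_per_pair = lapply(duals, length),
    shared = length(shared), candidates = nrow(candidates),
    intersection = if (!is.null(inter)) {
      list(observed = inter$observed, expected = inter$expected, p = inter$p)
    })

  # --- covariant ------------------------------------------------------
  note("stage covariant")
  cov_all <- extract_covariant(ft, config$ancestral)
  cov_cand <- threshold_covariant(cov_all, config$delta)
  write_tsv(as.data.frame(cov_cand),
            file.path(config$out_dir, "covariant_candidates.tsv"))
  dual_union <- sort(unique(unlist(duals)))
  chisq <- NULL
  if (length(dual_union) > 0) {
    obs_cov_dual <- sum(dual_union %in% cov_all$site)
    chisq <- chi_square_concordance_test(obs_cov_dual, length(dual_union),
                                         length(derived))
    chisq$excess_fraction <- excess_fraction(obs_cov_dual, chisq$expected,
                                             length(dual_union))
  }
  anc_p <- ft$p[config$ancestral, ]
  usable <- !is.na(anc_p)
  pop_sizes <- as.integer(table(factor(panel$pop_map[panel$samples],
                                       levels = c(config$ancestral, derived))))
  null <- simulate_null_covariant_counts(
    anc_p[usable], config$model, pop_sizes, delta = config$delta,
    n_reps = config$n_reps, n_samplings = config$n_samplings,
    seed = derive_seed(config$seed, "null"))
  ztest <- z_test_excess(nrow(cov_cand), null)
  report$stages$covariant <- list(
    covariant = nrow(cov_all), candidate_covariant = nrow(cov_cand),
    delta = config$delta,
    chi_square = if (!is.null(chisq)) {
      list(n_dual_union = length(dual_union), observed = chisq$observed,
           expected = chisq$expected, statistic = chisq$statistic,
           p = chisq$p, excess_fraction = chisq$excess_fraction)
    },
    null_mean = null$mean, null_sd = null$sd,
    z = ztest$z, z_p = ztest$p)
  jsonlite::write_json(report$stages$covariant,
                       file.path(config$out_dir, "covariant_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  if (!is.null(truth)) {
    report$truth_selected <- sum(truth$selected)
    report$recovered_selected <- sum(cov_cand$site %in%
                                       truth$site[truth$selected])
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  note(sprintf("done in %.1f s", as.numeric(Sys.time() - t0, units = "secs")))
  invisible(structure(list(report = report, panel = panel, freq_table = ft,
                           scans = scans, candidates = candidates,
                           covariant = cov_cand, covariant_all = cov_all,
                           null = null, ztest = ztest, truth = truth,
                           intersection = inter, config = config),
                      class = "fwadapt_run"))
}

#' @export
print.fwadapt_run <- function(x, ...) {
  r <- x$report
  cat("fwadapt_run\n")
  cat(sprintf("  filtered sites: %d\n", r$stages$filter$sites))
  cat(sprintf("  candidate outliers (shared >= %d pairs, direction-consistent): %d\n",
              x$config$min_pairs, r$stages$parallelism$candidates))
  cat(sprintf("  covariant SNPs: %d; candidate covariant (delta >= %g): %d\n",
              r$stages$covariant$covariant, x$config$delta,
              r$stages$covariant$candidate_covariant))
  cat(sprintf("  covariant excess: Z = %.2f, P = %.3g (null %.1f +/- %.2f)\n",
              r$stages$covariant$z, r$stages$covariant$z_p,
              r$stages$covariant$null_mean, r$stages$covariant$null_sd))
  invisible(x)
}

#' Write a synthetic study fixture to disk
#'
#' Generates a dataset with [generate_study_dataset()] under one of three
#' presets and writes it as VCF + population map + truth TSV.
#' `tiny_null` is 1,000 neutral loci; `tiny_selected` is 2,000 loci with
#' 100 under selection at `s = 0.25`; `paper_like` uses the full study
#' design (sample sizes 20/46/48/24/23, founding generations 69/68/65/44,
#' 70 generations) over 5,000 loci.  All presets use the study founding
#' design; effective sizes are ancestral 1,000 and derived 500
#' (`paper_like`: 10,000 and 1,000).
#'
#' @param preset `"tiny_null"`, `"tiny_selected"` or `"paper_like"`.
#' @param seed master seed.
#' @param dir output directory.
#' @return named list of the three file paths, plus the truth table.
#' @export
make_fixture <- function(preset = c("tiny_null", "tiny_selected", "paper_like"),
                         seed = 1L, dir = tempdir()) {
  preset <- match.arg(preset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  founding <- c(69L, 68L, 65L, 44L)
  spec <- switch(preset,
    tiny_null = list(model = demographic_model(1000L, rep(500L, 4), founding),
                     n_loci = 1000L, n_selected = 0L),
    tiny_selected = list(model = demographic_model(1000L, rep(500L, 4), founding),
                         n_loci = 2000L, n_selected = 100L),
    paper_like = list(model = demographic_model(10000L, rep(1000L, 4), founding),
                      n_loci = 5000L, n_selected = 250L))
  sim <- generate_study_dataset(spec$model, spec$n_loci, spec$n_selected,
                                sample_sizes = c(20L, 46L, 48L, 24L, 23L),
                                seed = seed, s = 0.25)
  paths <- list(vcf = file.path(dir, paste0(preset, ".vcf")),
                pop_map = file.path(dir, paste0(preset, ".popmap.tsv")),
                truth = file.path(dir, paste0(preset, ".truth.tsv")))
  write_vcf(sim$panel, paths$vcf)
  write_pop_map(sim$panel$pop_map, paths$pop_map)
  write_truth(sim$truth, paths$truth)
  c(paths, list(truth_table = sim$truth, model = spec$model))
}
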