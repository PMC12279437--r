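#' Demographic model for the forward simulator
#'
#' Describes one ancestral population plus any number of derived populations
#' founded from it at given generations before present.  Effective sizes are
#' diploid individual counts; any size above `ne_cap` is truncated to
#' `ne_cap` before use (the cap keeps binomial sampling feasible and mirrors
#' common practice when externally estimated sizes explode).
#'
#' @param ancestral_ne diploid effective size of the ancestral population.
#' @param derived_ne integer vector, one effective size per derived
#'   population.
#' @param founding_generation integer vector, generations before present at
#'   which each derived population splits from the ancestor (each must be
#'   `<= total_generations`).
#' @param founder_ne founding bottleneck sizes; defaults to `derived_ne`.
#' @param total_generations total generations simulated (default 70).
#' @param selection_coeff optional named numeric vector mapping site index
#'   (1-based, as character or integer names) to a selection coefficient
#'   `s >= -1` applied in the derived populations.
#' @param ne_cap truncation bound for all effective sizes (default 100000).
#' @param derived_names optional labels for the derived populations.
#' @return an object of class `demographic_model`.
#' @export
#' @examples
#' demographic_model(1000, c(500, 500, 500, 500), c(69, 68, 65, 44))
demographic_model <- function(ancestral_ne, derived_ne, founding_generation,
                              founder_ne = derived_ne,
                              total_generations = 70L,
                              selection_coeff = NULL,
                              ne_cap = 100000L,
                              derived_names = NULL) {
  .check_count(ancestral_ne, "ancestral_ne", 1L)
  .check_count(derived_ne, "derived_ne", 1L)
  .check_count(founder_ne, "founder_ne", 1L)
  .check_count(founding_generation, "founding_generation", 0L)
  .check_count(total_generations, "total_generations", 0L)
  .check_count(ne_cap, "ne_cap", 1L)
  k <- length(derived_ne)
  if (length(founding_generation) != k || length(founder_ne) != k) {
    stop("derived_ne, founder_ne and founding_generation must have equal length")
  }
  if (any(founding_generation > total_generations)) {
    stop("every founding_generation must be <= total_generations")
  }
  if (!is.null(selection_coeff) && any(selection_coeff < -1)) {
    stop("selection coefficients must be >= -1")
  }
  cap <- function(x) pmin(as.integer(x), as.integer(ne_cap))
  if (is.null(derived_names)) derived_names <- paste0("derived", seq_len(k))
  structure(list(ancestral_ne = cap(ancestral_ne),
                 derived_ne = cap(derived_ne),
                 founder_ne = cap(founder_ne),
                 founding_generation = as.integer(founding_generation),
                 total_generations = as.integer(total_generations),
                 selection_coeff = selection_coeff,
                 ne_cap = as.integer(ne_cap),
                 derived_names = derived_names),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("demographic_model: ancestral Ne %d; %d derived populations\n",
              x$ancestral_ne, length(x$derived_ne)))
  cat(sprintf("  founded %s generations ago (of %d total)\n",
              paste(x$founding_generation, collapse = "/"),
              x$total_generations))
  ns <- length(x$selection_coeff %||% numeric())
  cat(sprintf("  derived Ne %s; %d site(s) under selection\n",
              paste(x$derived_ne, collapse = "/"), ns))
  invisible(x)
}

#' Ancestral allele-frequency spectra
#'
#' Constructors for the two built-in standing-variation spectra: a uniform
#' spectrum on `(a, b)` and the neutral equilibrium `1/x` spectrum truncated
#' to `[min_maf, 1 - min_maf]`.
#'
#' @param min,max bounds of the uniform spectrum, within (0, 1).
#' @return a spectrum description consumed by
#'   [simulate_ancestral_frequencies()].
#' @export
spectrum_uniform <- function(min = 0.05, max = 0.95) {
  if (!(min > 0 && max < 1 && min < max)) {
    stop("uniform spectrum bounds must satisfy 0 < min < max < 1")
  }
  structure(list(type = "uniform", min = min, max = max),
            class = "freq_spectrum")
}

#' @rdname spectrum_uniform
#' @param min_maf truncation bound of the 1/x spectrum, within (0, 0.5).
#' @export
spectrum_neutral <- function(min_maf = 0.05) {
  if (!(min_maf > 0 && min_maf < 0.5)) {
    stop("min_maf must lie in (0, 0.5)")
  }
  structure(list(type = "neutral_1_over_x", min_maf = min_maf),
            class = "freq_spectrum")
}

#' Draw ancestral alternate-allele frequencies
#'
#' Samples per-locus starting frequencies from a chosen spectrum of standing
#' variation.  The neutral spectrum has density proportional to `1/x` on
#' `[min_maf, 1 - min_maf]`, sampled by inverse CDF.
#'
#' @param n_loci number of loci.
#' @param spectrum a spectrum from [spectrum_uniform()] or
#'   [spectrum_neutral()].
#' @param seed integer seed.
#' @return numeric vector of length `n_loci`, all values strictly in (0, 1).
#' @export
simulate_ancestral_frequencies <- function(n_loci,
                                           spectrum = spectrum_uniform(),
                                           seed = 1L) {
  .check_count(n_loci, "n_loci")
  if (!inherits(spectrum, "freq_spectrum")) stop("invalid spectrum")
  if (n_loci == 0) return(numeric(0))
  set.seed(seed)
  if (spectrum$type == "uniform") {
    stats::runif(n_loci, spectrum$min, spectrum$max)
  } else {
    m <- spectrum$min_maf
    u <- stats::runif(n_loci)
    m * ((1 - m) / m)^u
  }
}

#' Evolve allele frequencies forward under drift and genic selection
#'
#' Each generation applies the deterministic genic-selection update
#' `p* = p (1 + s) / (1 + p s)` followed by binomial sampling of `2 ne`
#' allele copies.  Frequencies 0 and 1 are absorbing; loci evolve
#' independently (free recombination).
#'
#' @param freqs numeric vector of alternate-allele frequencies in `[0, 1]`.
#' @param ne diploid effective population size (>= 1).
#' @param generations number of generations to simulate (>= 0).
#' @param s per-locus selection coefficients (recycled; each `>= -1`).
#' @param seed optional integer seed; if `NULL` the current RNG state is
#'   used (callers composing several streams seed externally).
#' @return numeric vector of evolved frequencies.
#' @export
drift_forward <- function(freqs, ne, generations, s = 0, seed = NULL) {
  .check_prob(freqs, "freqs")
  .check_count(ne, "ne", 1L)
  .check_count(generations, "generations")
  if (any(s < -1)) stop("selection coefficients must be >= -1")
  if (2 * ne > .Machine$integer.max) stop("ne too large for binomial sampling")
  if (!is.null(seed)) set.seed(seed)
  L <- length(freqs)
  if (L == 0 || generations == 0) return(freqs)
  s <- rep_len(s, L)
  p <- freqs
  n2 <- 2 * ne
  for (g in seq_len(generations)) {
    p <- p * (1 + s) / (1 + p * s)
    p <- stats::rbinom(L, n2, p) / n2
  }
  p
}

#' Found a derived population through a binomial bottleneck
#'
#' One binomial draw of `2 * founder_ne` allele copies per locus from the
#' ancestral frequencies, modelling the sampling of founders at the moment a
#' derived population is isolated.
#'
#' @param ancestral_freqs numeric vector of frequencies in `[0, 1]`.
#' @param founder_ne number of founding diploid individuals (>= 1).
#' @param seed optional integer seed.
#' @return numeric vector of post-bottleneck frequencies.
#' @export
found_population <- function(ancestral_freqs, founder_ne, seed = NULL) {
  .check_prob(ancestral_freqs, "ancestral_freqs")
  .check_count(founder_ne, "founder_ne", 1L)
  if (!is.null(seed)) set.seed(seed)
  n2 <- 2 * founder_ne
  stats::rbinom(length(ancestral_freqs), n2, ancestral_freqs) / n2
}

#' Sample diploid genotypes from population frequencies
#'
#' Draws Hardy-Weinberg genotypes: each individual's alternate-allele dosage
#' at a site is Binomial(2, p).  Simulated output has no missing data.
#'
#' @param freqs numeric vector of alternate-allele frequencies.
#' @param n_individuals number of diploid individuals to sample (>= 0).
#' @param seed optional integer seed.
#' @param population population label for the sampled individuals.
#' @param sites optional site metadata data.frame; synthesised when absent.
#' @param sample_prefix prefix for generated sample ids.
#' @return a single-population [genotype_panel()].
#' @export
sample_genotypes <- function(freqs, n_individuals, seed = NULL,
                             population = "pop1", sites = NULL,
                             sample_prefix = population) {
  .check_prob(freqs, "freqs")
  .check_count(n_individuals, "n_individuals")
  if (!is.null(seed)) set.seed(seed)
  L <- length(freqs)
  g <- matrix(stats::rbinom(n_individuals * L, 2L,
                            rep(freqs, each = n_individuals)),
              nrow = n_individuals, ncol = L)
  if (is.null(sites)) sites <- default_site_table(L)
  samples <- if (n_individuals > 0) {
    sprintf("%s_%03d", sample_prefix, seq_len(n_individuals))
  } else character(0)
  pop_map <- stats::setNames(rep(population, n_individuals), samples)
  genotype_panel(g, sites, samples = samples, pop_map = pop_map)
}

# Synthetic site metadata: loci spread over chromosomes, 15 kb apart so the
# default 10-kb thinning never collapses simulated loci.
default_site_table <- function(n_loci, per_chrom = 1000L, spacing = 15000L) {
  if (n_loci == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  }
  idx <- seq_len(n_loci) - 1L
  data.frame(chrom = paste0("chr", idx %/% per_chrom + 1L),
             pos = (idx %% per_chrom) * spacing + 1L,
             ref = "A", alt = "T",
             qual = 60, multiallelic = FALSE,
             stringsAsFactors = FALSE)
}

# Evolve the ancestral population to the present, founding each derived
# population at its configured generation, and return present-day frequency
# vectors for every population.  `s` applies in derived populations only
# (the derived environment is where the favoured allele is favoured).
simulate_population_history <- function(ancestral_freqs, model, s = 0,
                                        seed = 1L) {
  stopifnot(inherits(model, "demographic_model"))
  L <- length(ancestral_freqs)
  s <- rep_len(s, max(L, 1L))
  T <- model$total_generations
  k <- length(model$derived_ne)
  split_time <- T - model$founding_generation  # generations elapsed at split
  snapshots <- vector("list", k)
  a <- ancestral_freqs
  for (i in which(split_time == 0L)) snapshots[[i]] <- a
  if (T > 0) {
    set.seed(derive_seed(seed, "ancestral"))
    n2 <- 2 * model$ancestral_ne
    for (t in seq_len(T)) {
      a <- stats::rbinom(L, n2, a) / n2
      for (i in which(split_time == t)) snapshots[[i]] <- a
    }
  }
  derived <- vector("list", k)
  for (i in seq_len(k)) {
    f0 <- found_population(snapshots[[i]], model$founder_ne[i],
                           seed = derive_seed(seed, "founder", i))
    derived[[i]] <- drift_forward(f0, model$derived_ne[i],
                                  model$founding_generation[i], s = s,
                                  seed = derive_seed(seed, "derived", i))
  }
  names(derived) <- model$derived_names
  list(ancestral = a, derived = derived)
}

#' Generate a synthetic study dataset with known selected loci
#'
#' Emulates the study design: one ancestral population carrying standing
#' variation, several derived populations founded from it tens of
#' generations ago, a subset of loci under positive directional selection
#' (favouring the alternate allele, which therefore becomes the
#' freshwater-favoured allele) in every derived population, and present-day
#' genotype sampling at the empirical sample sizes.
#'
#' @param model a [demographic_model()].  If `model$selection_coeff` is set
#'   it defines the selected sites and their coefficients; otherwise
#'   `n_selected` sites are drawn uniformly and given coefficient `s`.
#' @param n_loci number of simulated loci.
#' @param n_selected number of loci under selection (`<= n_loci`).
#' @param sample_sizes integer vector of individuals sampled per population:
#'   ancestral first, then one entry per derived population.
#' @param seed master integer seed.
#' @param s selection coefficient for the sampled selected sites
#'   (default 0.25).
#' @param spectrum ancestral frequency spectrum (default uniform(0.05, 0.95)).
#' @param ancestral_name label for the ancestral population.
#' @return a list with elements `panel` (a [genotype_panel()] over all
#'   populations), `truth` (data.frame: site, chrom, pos, selected, s,
#'   fwa_allele) and `freqs` (true present-day frequency vectors).
#' @export
generate_study_dataset <- function(model, n_loci, n_selected, sample_sizes,
                                   seed = 1L, s = 0.25,
                                   spectrum = spectrum_uniform(0.05, 0.95),
                                   ancestral_name = "ancestral") {
  .check_count(n_loci, "n_loci")
  .check_count(n_selected, "n_selected")
  if (n_selected > n_loci) stop("n_selected must be <= n_loci")
  k <- length(model$derived_ne)
  if (length(sample_sizes) != k + 1) {
    stop(sprintf("sample_sizes must have %d entries (ancestral + %d derived)",
                 k + 1, k))
  }
  anc <- simulate_ancestral_frequencies(n_loci, spectrum,
                                        seed = derive_seed(seed, "anc_freqs"))
  s_vec <- numeric(n_loci)
  if (!is.null(model$selection_coeff)) {
    idx <- as.integer(names(model$selection_coeff))
    s_vec[idx] <- unname(model$selection_coeff)
    selected <- sort(idx[model$selection_coeff != 0])
  } else if (n_selected > 0) {
    set.seed(derive_seed(seed, "pick_selected"))
    selected <- sort(sample.int(n_loci, n_selected))
    s_vec[selected] <- s
  } else {
    selected <- integer(0)
  }
  hist <- simulate_population_history(anc, model, s = s_vec, seed = seed)
  sites <- default_site_table(n_loci)
  pops <- c(ancestral_name, model$derived_names)
  freqs <- c(list(hist$ancestral), hist$derived)
  names(freqs) <- pops
  panels <- lapply(seq_along(pops), function(i) {
    sample_genotypes(freqs[[i]], sample_sizes[i],
                     seed = derive_seed(seed, "sample", i),
                     population = pops[i], sites = sites)
  })
  truth <- data.frame(site = seq_len(n_loci),
                      chrom = sites$chrom, pos = sites$pos,
                      selected = seq_len(n_loci) %in% selected,
                      s = s_vec,
                      fwa_allele = ifelse(seq_len(n_loci) %in% selected,
                                          "alt", NA_character_),
                      stringsAsFactors = FALSE)
  list(panel = bind_panels(panels), truth = truth, freqs = freqs, seed = seed)
}

#' Count covariant loci from frequency vectors
#'
#' Number of loci at which one allele's frequency increment relative to the
#' ancestral population is at least `delta` in every derived population
#' (strict concordance in all populations when `delta = 0`).  Operates on
#' plain frequency vectors, so it serves both the simulator's null counting
#' and quick frequency-level experiments.
#'
#' @param anc_freqs ancestral alternate-allele frequencies.
#' @param derived_freqs list of derived-population frequency vectors.
#' @param delta increment threshold in `[0, 1]`.
#' @return integer count.
#' @export
count_covariant_loci <- function(anc_freqs, derived_freqs, delta) {
  d <- lapply(derived_freqs, function(f) f - anc_freqs)
  dmin <- do.call(pmin, d)
  dmax <- do.call(pmax, d)
  sum((dmin > 0 & dmin >= delta) | (dmax < 0 & -dmax >= delta), na.rm = TRUE)
}

#' Neutral null distribution of covariant-SNP counts
#'
#' Forward-simulates the configured demography with no selection, starting
#' from the supplied ancestral frequency vector, and counts in each
#' simulation-sampling replicate the loci whose direction-concordant allele
#' rises by at least `delta` in every derived population.  Each of the
#' `n_reps` independent simulations contributes `n_samplings` binomial
#' genotype-sampling draws at the empirical sample sizes, giving
#' `n_reps * n_samplings` replicate counts in total.
#'
#' @param ancestral_freqs observed (or simulated) ancestral alternate-allele
#'   frequencies used to initialise every replicate.
#' @param model a [demographic_model()]; any selection coefficients are
#'   ignored (the null is neutral).
#' @param sample_sizes individuals sampled per population (ancestral first).
#' @param delta frequency-increment threshold in `[0, 1]` (default 0.2).
#' @param n_reps number of independent simulations (default 200).
#' @param n_samplings sampling draws per simulation (default 10).
#' @param seed master integer seed.
#' @return an object of class `null_distribution`: replicate `counts`
#'   (length `n_reps * n_samplings`), their `mean` and sample `sd`, the
#'   generating `seed`, and a `degenerate` flag set when the null collapses
#'   to a single value on polymorphic input.
#' @export
simulate_null_covariant_counts <- function(ancestral_freqs, model,
                                           sample_sizes, delta = 0.2,
                                           n_reps = 200L, n_samplings = 10L,
                                           seed = 1L) {
  .check_prob(ancestral_freqs, "ancestral_freqs")
  .check_prob(delta, "delta")
  .check_count(n_reps, "n_reps", 1L)
  .check_count(n_samplings, "n_samplings", 1L)
  k <- length(model$derived_ne)
  if (length(sample_sizes) != k + 1) {
    stop("sample_sizes must cover the ancestral and every derived population")
  }
  L <- length(ancestral_freqs)
  counts <- integer(n_reps * n_samplings)
  for (r in seq_len(n_reps)) {
    hist <- simulate_population_history(ancestral_freqs, model, s = 0,
                                        seed = derive_seed(seed, "rep", r))
    set.seed(derive_seed(seed, "sampling", r))
    n2 <- 2 * sample_sizes
    for (j in seq_len(n_samplings)) {
      # Allele counts sampled directly as Binomial(2n, p): identical in law
      # to summing n HWE diploid genotypes, without materialising them.
      p_anc <- stats::rbinom(L, n2[1], hist$ancestral) / n2[1]
      p_der <- lapply(seq_len(k), function(i) {
        stats::rbinom(L, n2[i + 1], hist$derived[[i]]) / n2[i + 1]
      })
      counts[(r - 1) * n_samplings + j] <-
        count_covariant_loci(p_anc, p_der, delta)
    }
  }
  degenerate <- n_reps > 1 && stats::sd(counts) == 0 &&
    any(ancestral_freqs > 0 & ancestral_freqs < 1)
  if (degenerate) {
    warning("degenerate null: all replicate counts identical on polymorphic input")
  }
  structure(list(counts = counts, mean = mean(counts),
                 sd = stats::sd(counts),
                 n_reps = as.integer(n_reps),
                 n_samplings = as.integer(n_samplings),
                 delta = delta, seed = seed, degenerate = degenerate),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "null_distribution: %d replicates (%d simulations x %d samplings)\n",
    length(x$counts), x$n_reps, x$n_samplings))
  cat(sprintf("  covariant count at delta >= %g: mean %.1f, sd %.2f\n",
              x$delta, x$mean, x$sd))
  if (isTRUE(x$degenerate)) cat("  WARNING: degenerate (zero variance)\n")
  invisible(x)
}
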