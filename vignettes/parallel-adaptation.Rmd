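---
title: "Detecting parallel adaptation from standing variation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parallel adaptation from standing variation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

When several populations are independently founded from one ancestral
population and face the same new environment — the motivating case is
freshwater lakes colonised by an anadromous (sea-migrating) fish — a central
question is whether they adapt *in parallel*, by repeatedly recruiting the
same alleles that already segregated in the ancestor (standing genetic
variation), rather than waiting for new mutations. `fwadapt` implements a
genome-scan pipeline for that question. Its core object is the
**freshwater-favoured allele (FWA)**: at a given SNP, the allele whose
frequency is *strictly higher in every derived population* than in the
ancestral population. Three layers of evidence are combined:

1. **Per-pair outlier scans.** Each derived population is contrasted with
   the ancestor ("ecotype pair") using two methods — Fisher's exact test on
   allele counts (Benjamini–Hochberg FDR < 0.05) and a PCA–Mahalanobis
   statistic with genomic-inflation correction (q < 0.1, K = 2). A SNP must
   be flagged by *both* methods ("dual outlier"), shared across at least
   three pairs, and direction-consistent across all pairs to become a
   candidate outlier. A multi-set hypergeometric intersection test asks
   whether the overlap across pairs exceeds chance.
2. **The covariant screen.** Outlier scans need large frequency shifts;
   polygenic adaptation mostly produces small ones. The covariant screen
   keeps every SNP with an FWA (concordant direction in all derived
   populations) and then thresholds on the increment
   ΔFWA ≥ 0.2 in *every* derived population.
3. **Two nulls for the covariant count.** Analytically, with $k$
   independent, sign-symmetric, tie-free frequency changes, the chance that
   one allele rises everywhere is $2 \times 0.5^k$ (12.5% for $k=4$),
   giving a χ² test of excess. Because real populations share ancestral
   drift and sampling noise, the thresholded count is instead referred to a
   forward-simulation null: the configured demography is re-simulated with
   $s=0$, re-sampled at the empirical sample sizes, and the observed count
   compared to the replicate distribution by a one-sided Z-test.

# The Wright–Fisher simulator

The generator is first-class code, not a fixture: it produces both the
synthetic study datasets (with a known truth table of selected loci) and
the neutral null.

**Model.** Loci are biallelic and unlinked (free recombination). Each
generation applies deterministic genic selection
$p^* = p(1+s)/(1+ps)$ followed by binomial sampling of $2N_e$ allele
copies. Genic selection is the simplest model with $s=0$ as the neutral
special case; dominance is deliberately out of scope. Frequencies 0 and 1
are absorbing; there is no mutation, because the hypothesis under test is
adaptation from *standing* variation over tens of generations.

**Demography.** One ancestral population drifts for `total_generations`
(default 70). Each derived population splits `founding_generation`
generations before present (study design: 69/68/65/44), through a single
binomial bottleneck of `founder_ne` diploids (defaulting to the derived
$N_e$, since only split times are known), then drifts with selection at the
selected loci. Any $N_e$ above `ne_cap` (default 100,000) is truncated
before use. Sizes above $10^9$ are rejected outright (binomial sampling of
$2N_e$ copies must stay within integer range).

**Standing variation.** Ancestral frequencies are drawn either from
uniform$(a,b)$ (default 0.05–0.95; moderate frequencies, the regime where
the covariant analysis has power) or from the neutral equilibrium
$1/x$ density truncated to $[m, 1-m]$ (for site-frequency-spectrum
realism). Draws are continuous, so exact ties have probability zero at the
frequency level; ties do arise after genotype sampling and are always
excluded by the strict direction rule.

**Seeds.** A single master seed is hashed (`derive_seed()`) into
independent streams per population, per replicate and per stage, so any
sub-computation can be reproduced in isolation and replicate counts are
independent. All derived seeds stay below $2^{31}$.

**What the generator does not emulate.** Linked selection and LD (loci are
unlinked; the 10-kb thinning step therefore only matters for real data),
mutation during the simulated window, migration between derived
populations, overlapping generations, and genotyping error (simulated
panels have no missing data; missingness handling is exercised by
hand-built fixtures instead). Passing tests on synthetic data therefore
demonstrate correctness of the statistics and calibration of the nulls
under the stated model — not robustness to LD or call-rate artefacts in
real data.

# Filtering

Genotype-level masking precedes site-level tests, because the call-rate
criteria depend on post-masking missingness (the source protocol lists
criteria without an order; this is our documented choice). Genotypes with
GQ < 20 or depth < 7 are set missing — we *mask* the genotype rather than
drop the site, reading the per-individual depth rule as a genotype-level
rule. Sites are then dropped, each charged to the *first* criterion it
fails: (i) biallelic; (ii) site quality ≥ 30; (iv) called in ≥ 90% of all
samples and ≥ 12 individuals in every population; (v) global observed
heterozygosity ≤ 0.8 (fraction of non-missing genotypes that are
heterozygous); (vi) global MAF ≥ 0.05, rescued by (vii) local MAF ≥ 0.2 in
any one population. Global MAF pools all samples; both MAFs exclude
missing genotypes. The procedure is idempotent, and removal counts plus
survivors always sum to the input.

Thinning keeps the first SNP in each non-overlapping 10-kb bin anchored at
position 0 — deterministic, where "one SNP per 10 kb" underdetermines
which SNP survives.

# Summary statistics

*Heterozygosity* is the per-sample fraction of heterozygous calls among
non-missing calls — hard genotypes, an approximation to
genotype-likelihood-based estimates appropriate at ≥ 20× coverage.

*Tajima's D* uses non-overlapping 100-kb windows ("zero step size" read as
step = window, since a zero-advance sliding window never advances).
Within a window, $\pi$ accumulates per-site unbiased heterozygosity
$2a(n_i-a)/(n_i(n_i-1))$ from allele counts, $S$ counts segregating
sites, and the normalising constants use the window's *median* number of
called sequences, rounded to an integer — missingness makes $n$ vary per
site, whereas fixed-$n$ implementations assume complete data; the
difference is negligible at high call rates. Windows with fewer than 3
segregating sites return `NA`.

*F\_ST* is the Weir–Cockerham (1984) two-population estimator with the
global value as ratio of summed components $\sum a / \sum(a+b+c)$ —
standard practice, less biased than averaging per-site ratios. Sites need
≥ 2 called individuals in both populations. Significance comes from
permuting individuals between the two populations (10,000 by default) with
the add-one p-value $(1 + \#\{F_{ST}^{perm} \ge F_{ST}^{obs}\})/(1+n)$,
then Bonferroni across pairs.

# The outlier scans

The exact test enumerates the hypergeometric distribution of the 2×2
allele-count table per site (two-sided rule: sum of probabilities no
greater than the observed table's, with the conventional $1+10^{-7}$
relative tolerance). Zero-margin tables return $p=1$ and are flagged.

The PCA scan mirrors the pcadapt construction: mean-impute missing
genotypes per site; centre by $2\hat p$ and scale by
$\sqrt{2\hat p(1-\hat p)}$; compute the top-$K$ sample scores by truncated
SVD; regress each site's scaled genotype vector on the $K$ score vectors
to get $K$ z-scores; take the Mahalanobis distance $D^2$ of the z-scores.
Details the reference construction leaves open were resolved
conservatively: the robust covariance of the z-scores is diagonal with
MAD-estimated scales (full minimum-covariance-determinant adds cost
without changing the ranking in our calibration experiments), and
q-values come from Benjamini–Hochberg rather than a $\pi_0$-estimating
procedure. $\lambda = \mathrm{median}(D^2)/\chi^2_{K,0.5}$ rescales $D^2$
before the $\chi^2_K$ tail. $K=2$ is kept even for a two-population pair,
for fidelity to the published setting; scans run per ecotype pair (the
published description is ambiguous between per-pair and joint; per-pair is
the reading consistent with "for each ecotype pair").

Calibration on panmictic panels split arbitrarily in two gives
$\lambda \in [0.8, 1.25]$ and under 1% discoveries at $q<0.1$; both are
asserted in the test suite.

# Parallelism and the candidate funnel

Ties break direction consistency: the FWA requires a *strictly* higher
frequency in every derived population, so any $\Delta = 0$ excludes the
site. The analytic 12.5% presumes tie-free changes, and tie exclusion
makes empirical neutral fractions fall slightly below it at small sample
sizes — documented rather than corrected. Sites with an undefined
frequency in any population are excluded with a warning.

The funnel (dual-method ∩ per pair, then shared ≥ 3 pairs, then direction
consistency) is order-independent, which the suite asserts. The
intersection test's universe is the filtered SNP set, not the genome. The
exact multi-set distribution comes from iterated convolution — the overlap
after adding set $i$ is hypergeometric given the overlap after $i-1$ — and
reduces to the classical hypergeometric tail for two sets; a seeded
Monte-Carlo fallback (with reported SE) guards configurations where the
convolution would exceed a cost bound.

# The covariant null

Null simulations initialise from the *observed* ancestral frequency vector
of the analysed panel (mirroring initialisation from the ancestral
population's variation), run the configured demography with $s=0$, and
draw population allele counts as Binomial$(2n, p)$ at the empirical sample
sizes — identical in law to summing Hardy–Weinberg diploid genotypes, an
equivalence asserted in the tests. Each of 200 independent simulations
contributes 10 sampling draws (2,000 replicate counts). The Z-test is
one-sided (upper) because the hypothesis is an excess of covariant SNPs; a
zero-variance null on polymorphic input is flagged degenerate rather than
silently producing infinite Z.

Why the simulation null matters: the four derived-vs-ancestral contrasts
share both the ancestral drift trajectory after each split and the
sampling noise of the ancestral frequency estimate, so even with $s=0$ the
concordant fraction exceeds the idealised 12.5% — the suite demonstrates
exactly this. The analytic expectation is reserved for the χ² arithmetic
on the dual-outlier set, where it is used as the published procedure does.

# Numerical and design choices

- Genotypes are coded 0/1/2 with `NA` for missing; positions are 1-based
  at I/O boundaries and throughout the site tables.
- ΔFWA thresholds compare inclusively (≥ 0.2).
- Site quality `NA` (VCF `.`) passes the quality criterion, so simulated
  panels without QUAL annotations are not discarded.
- The FET implementation is a vectorised hypergeometric enumeration; it is
  cross-checked against both `stats::fisher.test()` and an independent
  `choose()`-based enumeration to $10^{-12}$.
- Residual variances in the PCA regression are floored at $10^{-12}$ so a
  perfectly structure-aligned site yields a very large (finite or
  infinite) $D^2$ rather than `NaN`.
- In the pipeline, timing information goes to `run.log` only, keeping
  `report.json` and all stage TSVs byte-reproducible for a fixed
  config + seed.

# Problem sizes used in the shipped experiments

The test suite and the reproduction script run entirely on synthetic data
at desk scale, chosen as the smallest sizes at which each property is
statistically decisive: 10,000 loci for the neutral concordance fraction
(3 binomial SE ≈ 1 percentage point); 2,000 loci with 100 selected at
$s = 0.25$, derived $N_e = 500$, and the study sample sizes
(20/46/48/24/23) for the power experiments, with the full 200 × 10
replicate null per seed and ten seeds; 1,500-site panels for scan
calibration; and a 300–400 locus configuration for end-to-end pipeline
checks. The `paper_like` fixture preset uses ancestral $N_e = 10{,}000$
and derived $N_e = 1{,}000$ over 5,000 loci — effective sizes are
config inputs in this pipeline, and these values are a plausible order of
magnitude for a recently land-locked fish, chosen once for the preset.

# Known limitations

- Unlinked loci mean no LD, so the thinning step and any haplotype-scale
  signal are untested against realistic linkage.
- Heterozygosity and all scans use hard genotype calls, not genotype
  likelihoods; low-coverage data would need upstream likelihood handling.
- The per-window median-$n$ Tajima's D differs slightly from fixed-$n$
  implementations under heavy missingness.
- The analytic concordance probability assumes independence across derived
  populations; it is reported alongside, never instead of, the simulation
  null.
- Real-data scale results (hundreds of thousands of SNPs) are outside the
  shipped experiments; the implementation is vectorised but single-core.

# A worked example

```{r example}
library(fwadapt)

model <- demographic_model(ancestral_ne = 1000, derived_ne = rep(500, 4),
                           founding_generation = c(69, 68, 65, 44))
cfg <- run_config(mode = "simulate", model = model,
                  out_dir = "fwadapt_demo", seed = 42,
                  n_loci = 2000, n_selected = 100, s = 0.25)
run <- run_pipeline(cfg)
print(run)

# the covariant excess test against the simulated neutral null
run$ztest

# candidate table and per-population shift summary
head(run$candidates)
fwa_shift_summary(run$covariant)
```
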