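---
title: "Methods: ROH detection, genomic inbreeding and mixed-model GWAS in rohscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH detection, genomic inbreeding and mixed-model GWAS in rohscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

`rohscan` implements the standard analysis chain for medium-density
SNP-array data from a livestock herd: quality control, runs-of-homozygosity
(ROH) detection, genomic inbreeding (F~ROH~), ROH-island selection scans,
and single-marker association with population-structure correction. This
vignette documents the models, the parameter choices and their defaults,
the numerical decisions, and what the bundled simulator does and does not
emulate.

## Quality control and the two marker sets

Downstream analyses use two different marker sets built by
`build_dataset()`:

* **GWAS profile** — samples with call rate ≤ 0.90 removed; markers removed
  when call rate < 0.95, more than two observed alleles, or MAF < 0.01;
  then windowed LD pruning; autosomes *and* X retained (an all-female
  cohort has ordinary 0/1/2 dosages on X).
* **ROH profile** — the same sample and call-rate/biallelic filters, but
  *no* MAF filter and *no* LD pruning, and the X chromosome is dropped.
  Rare and redundant markers carry real information about homozygous
  stretches, so removing them would bias ROH detection; conversely F~ROH~
  is defined on autosomes only.

Boundary conventions are deliberate and asymmetric: the sample filter
removes at the boundary ("success rate ≤ 0.90 removed") while the marker
filter keeps at the boundary (removal is "< 0.95"). Removal reasons are
tallied with fixed precedence (call rate, then multi-allelic, then MAF) so
report counts are additive. MAF is computed after sample filtering, with
missing calls excluded from denominators.

LD pruning follows the `indep-pairwise` convention: within a sliding window
(default 50 markers, step 5) pairs with genotype r² > 0.5 are resolved by
dropping the lower-MAF member (tie: the later position). The source study
did not state its pruning tool or threshold, so the exact surviving marker
count on real chips is configuration-dependent; the defaults are the
field's common starting point and are fully exposed in `qc_config()`.

## ROH detection

A ROH is defined by four rules (`roh_params()`): at least `min_snp = 25`
homozygous markers, spanning at least `min_length_bp = 1,000,000` bp, with
no heterozygote (`max_het = 0`) and at most `max_missing = 5` unread calls
inside the run. Segment length is `pos(last hom) − pos(first hom) + 1`:
runs are trimmed to homozygous endpoints so missing edge markers never
extend a span, and the `+ 1` makes a single-base interval have length 1.

The missing-call budget applies per segment: when a scan window would
accumulate a sixth missing call, the current run is closed at the last
homozygous marker and scanning resumes, i.e. a run is *split* rather than
discarded. One subtlety motivates the exact scan semantics: with
interspersed missing calls, two *overlapping* marker intervals can both
maximally satisfy all four rules. Since segments of one animal must not
overlap (they are summed into F~ROH~), `rohscan` defines the canonical
call greedily from the left: take the leftmost homozygous start that admits
a qualifying run, extend it as far as the budgets allow, emit it, and
resume after it. The production scanner is a linear pass over precomputed
prefix counts; the test suite checks it against an independent quadratic
enumerator of all qualifying subintervals on hundreds of random
chromosomes.

Called segments are binned into the five reporting classes with half-open
intervals [1,2), [2,4), [4,8), [8,16), [16,∞) Mbp, so every qualifying
length maps to exactly one class and 2.0 Mbp falls in "2–4".

Per-class population statistics in `summarize_roh()` (mean, SD, median,
min, max of counts and lengths) are computed **over animals having at least
one ROH of that class**; the fraction of animals lacking the class is
reported separately. This is the only convention consistent with reporting
a positive minimum for the rarest class while many animals have none of
it. Overall ROHs-per-animal, by contrast, averages over *all* animals.

## Genomic inbreeding

F~ROH~ is the summed ROH length divided by the autosome length. On real
bovine data the denominator is the fixed constant `BTA_AUTOSOME_BP`
(2,512,082,506 bp) rather than the sum of covered map lengths — this
reproduces the published arithmetic exactly (433.37 Mbp of ROH gives
0.173) and keeps values comparable across chips. Simulated genomes pass
their own autosome length. Per-class F~ROH~ uses the same denominator, so
the five class values add up to the total exactly. Tables round to three
decimals; files keep full precision.

## ROH islands

`snp_in_roh_frequency()` computes, per marker, the percentage of animals
whose ROH covers the marker position, counting each animal at most once
(segments are unioned per animal first). `detect_islands()` then reports
maximal runs of consecutive markers at or above the threshold — inclusive
at the default 30%, so a marker at exactly 30% qualifies. Island
coordinates span the first to last member marker (reproducible from the
marker map alone, rather than midpoints to flanking markers), and
`min_markers` (default 1, as no minimum is part of the definition) can
suppress singleton islands. Note that a planted or real sweep carried by a
fraction *c* of animals yields a peak near *c* plus the background ROH
coverage at that locus, so peaks are interpretable only relative to the
cohort's baseline inbreeding.

## Association scans

The kinship matrix is VanRaden's method 1,
G = ZZᵀ / (2 Σ pᵢ(1−pᵢ)), with columns centred by 2p̂ and missing dosages
mean-imputed per marker. Principal components come from the
standardized-genotype SVD with signs fixed by making each component's
largest-magnitude marker loading positive, so covariate matrices are
reproducible.

`glm_scan()` fits, per marker, ordinary least squares of the trait on
intercept + covariates + dosage and reports the two-sided t-test of the
dosage coefficient (vectorized via Frisch–Waugh–Lovell residualization).
`mlm_scan()` fits the kinship mixed model
y = Xb + gβ + u + e, u ~ N(0, σ²g K), e ~ N(0, σ²e I). Variance components
are estimated once by REML on the *null* model and then fixed for all
marker tests (the P3D/EMMAX approximation); `exact_reml = TRUE`
re-estimates them per marker. REML profiles the likelihood over
δ = σ²e/σ²g in the eigenbasis of K, with a grid on log₁₀δ ∈ [−5, 5]
refined by golden-section search. When the optimum sits at the upper
boundary the polygenic component is taken as exactly zero and the scan
collapses to the GLM — making the σ²g = 0 limit exact rather than
approximate. K must be symmetric and positive semidefinite within 1e−8;
small negative eigenvalues are clipped to zero.

Other conventions: missing phenotypes drop the sample from that trait's
scan; monomorphic markers are flagged untestable with β = 0 and p = 1;
p-values are floored at the smallest positive double rather than reported
as 0; the Bonferroni threshold is α/m with the family-wise α defaulting to
0.01; the genomic inflation factor λ is the median 1-d.f. χ² quantile of
the p-values over 0.4549. Traits are analyzed untransformed with no fixed
effects beyond the intercept and the requested covariates (three PCs by
default, matching common practice for a single-herd cohort).

Of the many published single- and multi-locus GWAS models, `rohscan`
implements the two structural poles — unadjusted GLM and the
kinship-random-effect MLM. Multi-locus iterative methods (MLMM, FarmCPU,
Blink, SUPER, CMLM and variants) are distinct algorithms out of scope
here; their re-implementation would dominate the package without changing
what the pipeline measures.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` is first-class, tested code, not a fixture. Its
design principle is that **truth is identity-by-descent, not observed
homozygosity**: founder haplotypes carry unique labels, gametes are
piecewise founder-origin tracks recombined with Poisson crossovers at
1 cM/Mbp, and an animal's true autozygous intervals are exactly the
regions where its two gametes carry the same founder label. F~ROH~
accuracy measured against this truth is a real measurement, not circular.

Defaults (`sim_config()`) describe a cohort of 334 cows on a scaled-down
chip: 5 autosomes × 50 Mbp with 1,000 markers each (20 markers/Mbp —
matching the density regime of a ~50–60k bovine chip), 40 founder
haplotypes, 6 non-overlapping generations with 25% full-sib matings
(producing autozygous tracts across all five length classes and mean
F~ROH~ around 0.1–0.15), U-shaped founder allele frequencies truncated to
[0.05, 0.95], first-order neighbour-copying LD (ρ = 0.3), 1% missingness
and 0.1% heterozygote-error rates. The scaled genome keeps the full test
suite in minutes; the statistical regimes (marker density per Mbp, tract
length distribution, relatedness) are what matter for validating the
methods, not the absolute genome size.

Features of real data deliberately *not* emulated: coalescent-exact LD
(the copying process gives only first-order decay), selection acting on
the trait during the simulation, genotyping batch effects, and true
X-chromosome inheritance (X markers, when emitted, are simulated as
autosomal — defensible only because every sample is female). Passing tests
therefore demonstrate correctness of the algorithms under realistic tract
and density regimes, not calibration against any particular real
population.

Experiment-specific configurations used by the validation suite are also
deliberate choices rather than defaults:

* *Island recovery* plants sweeps in a weakly inbred cohort (200 founder
  haplotypes, random mating), because a planted carrier fraction is only
  cleanly recoverable as a peak percentage when background ROH coverage
  (~3–6%) does not confound it. The null-island check uses the same
  outbred regime.
* *F~ROH~ recovery* uses error-free genotypes, since a single heterozygote
  misread inside a long tract legitimately splits it — a property of the
  ROH definition, not an implementation fault.
* *GWAS calibration and power* uses n = 300 animals and 5,000 markers with
  polygenic h² = 0.5 and a QTL explaining 5% of phenotypic variance,
  20 replicates.

## Known limitations

* The expected association statistic for a QTL explaining a share *s* of
  phenotypic variance is |t| ≈ √(n·s/(1−s)) regardless of how well the
  mixed model absorbs polygenic variance, because genome-wide-estimated
  kinship leaves no noise-free directions for a common marker. At n = 300
  and s = 0.05 this is ≈ 4.0, while genome-wide Bonferroni significance at
  α = 0.01 over 5,000 tests needs |t| > 4.75 — so a single cohort of this
  size detects such a QTL at genome-wide significance only in a minority
  of replicates, and the validation suite reports the measured rate
  honestly rather than asserting high power.
* The greedy left-to-right ROH call is one of several defensible
  resolutions of overlapping qualifying runs around dense missing-call
  clusters; alternatives differ only in those rare configurations.
* `ld_prune()` recomputes window correlations after each drop; it is
  quadratic per window and intended for chip-scale, not sequence-scale,
  marker counts.
* The REML search range log₁₀δ ∈ [−5, 5] caps the detectable
  variance-ratio extremes; optima at the upper edge are interpreted as
  σ²g = 0, which is the desired behaviour for null traits but means
  heritabilities below ~1e−5 are indistinguishable from zero.
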