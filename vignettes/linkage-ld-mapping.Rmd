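---
title: "Joint linkage and LD mapping of dynamic growth traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint linkage and LD mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkLD)
```

# Overview

`linkLD` implements a two-population strategy for dissecting longitudinal
quantitative traits in an outcrossing tree species: family-based QTL
interval mapping on a pseudo-testcross full-sib pedigree localises broad
trait loci on the genetic map; anchor markers project those loci onto the
genome as segmental homology regions (SHRs); and a panel of unrelated
individuals from several climatic regions is then used *within* the SHRs
for selection scans, linkage-disequilibrium (LD) structure, mixed-model
association with additive/dominance decomposition, and two-locus epistasis.
Because real pedigrees and resequencing panels of this kind are proprietary,
the package ships simulators that generate both populations with planted
ground truth, so every downstream stage is testable end to end.

This vignette records the models, the parameters that matter, the numerical
choices, and the limits of what the synthetic data can show.

# The full-sib linkage population

## Pseudo-testcross simplification

The real mapping family is genotyped mostly with dominant markers that are
heterozygous in one parent and null in the other, so each marker segregates
1:1 and can be analysed like a backcross. We therefore code progeny calls as
two classes `{0, 1}` (the two gametes of the informative parent) and do not
attempt four-allele outbred phase inference. This preserves exactly the
statistical structure the scan uses — a binary predictor per locus with
recombination-driven spatial correlation — at a fraction of the complexity.

## Recombination model

Progeny genotypes arise from a Markov chain along each linkage group with
transition probability given by the Haldane map function (no interference),
`r = (1 - exp(-2d/100))/2` for a gap of `d` cM. At the default mean marker
interval of 2.3 cM adjacent markers recombine with probability
`haldane_r(2.3)` ≈ 0.0225. Map spacings are drawn from an exponential
distribution (floored at 0.2 cM), which produces the occasional 5–8 cM gap
seen on real dominant-marker maps; those gaps bound the achievable QTL
localisation accuracy (see "Support intervals" below).

## Phenotypes

Each planted QTN contributes `a(t) * s` to the phenotype, where `s = ±1` is
the (latent) QTN class and `a(t)` is chosen so the locus explains its target
PVE at each timepoint. Target PVE follows one of four trajectory classes —
`level`, `increasing`, `decreasing`, `increase-then-level` — mirroring the
patterns that dynamic growth QTL display across a growing season. Residuals
are AR(1)-correlated across timepoints (default correlation 0.6, marginal
variance 1). The AR(1) choice is ours: longitudinal growth measurements are
strongly serially correlated, and a single correlation parameter is the
simplest structure that reproduces that feature; no claim is made that real
residuals are exactly AR(1).

# QTL scanning

## Haley–Knott regression

At each grid position (1-cM step, marker positions included) the expected
genotype score is computed from the flanking markers through the Haldane
recombination fractions and the phenotype is regressed on that score:

  LOD = (n/2) · log10(RSS0 / RSS1),  PVE = 1 − 10^(−2·LOD/n).

Haley–Knott regression gives LOD surfaces nearly identical to full
maximum-likelihood interval mapping for a two-class cross at far lower cost;
at a fully informative marker the statistic reduces exactly to single-marker
regression, which the test suite exploits as an oracle. Missing flank calls
fall back to the single available flank, or to an uninformative score of 0.5
when both flanks are missing (with the default 2% missing rate this affects
a negligible fraction of scores). Positions whose residualized score is
constant (monomorphic flanks) are skipped.

## Permutation thresholds

Genome-wide significance uses phenotype permutation: the `(1 − α)` quantile
of the maximum LOD over 1,000 permutations at α = 0.05. A uniform LOD ≥ 3.0
reporting cut-off is also applied by default, matching common practice for
maps of this size; both are configurable.

## Multiple-QTL (cofactor) rescans

The `mqm_scan()` scheme iterates: scan, take the nearest marker to each
supra-threshold peak as a cofactor candidate, keep candidates whose partial
regression P < 0.02, rescan with the retained cofactors excluded within a
10-cM window of the test position, and stop when the cofactor set is stable
(oscillating sets stop at 10 iterations and are flagged). The 10-cM
exclusion window is our choice; it must exceed the span over which a
cofactor absorbs its own QTL signal, and 10 cM (≈ 0.09 recombination
fraction) does so comfortably on these maps.

## Support intervals

A QTL's support interval is the maximal interval around the peak with LOD
within 1 of the peak, expanded first to the next grid position outside the
drop region and then to the nearest flanking markers. The marker expansion
deserves a note: between markers the Haley–Knott likelihood is an
interpolation of the flanking-marker information, so an interval endpoint
placed between two markers overstates the map resolution — particularly in
the long gaps an exponential-spacing map contains. With the marker-expanded
convention, the interval of a planted QTN (PVE 0.20, n = 400) covers the
true position in ≈ 92% of simulated families; with endpoints left between
markers the coverage drops to ≈ 85%, the well-known undercoverage of narrow
1-LOD intervals.

## Co-localisation and hotspots

QTL from different trait × timepoint sets are merged into discrete overlap
regions by single-linkage clustering under a conjunction: support intervals
overlap *and* peaks are < 1.0 cM apart. The hotspot test redistributes all
QTL peaks uniformly over the map 1,000 times and flags 1-cM bins whose
observed count exceeds the 95th percentile of the null *maximum* per-bin
count. The maximum-count null controls the family-wise error over bins; a
pooled per-bin variant is available behind `per_bin = TRUE` but is anti-
conservative when many bins are scanned.

# SHR projection

Anchor markers with both map (cM) and genome (bp) coordinates define a
piecewise-linear interpolation per linkage group, fitted only when at least
three anchors exist and the two coordinate systems are co-monotone; local
inversions are flagged and never silently resolved, because reconciling
discordant anchors would manufacture genomic coordinates with no evidential
basis. Queries beyond the terminal anchors extrapolate with the nearest
segment's slope and carry an `extrapolated` flag. Projected regions whose
genomic intervals overlap by at least 1 bp merge into a single SHR — this is
exactly the arithmetic by which slightly-overlapping map regions collapse
into fewer genomic regions. A global linear cM/bp fit was rejected because
recombination-rate variation along a chromosome makes it systematically
biased at the ends.

# Windowed population-genetic statistics

All statistics use fixed 250-bp non-overlapping windows, complete cases per
site, and haplotype counts of `n = 2 ×` non-missing diploids (no phasing,
no imputation). Per site, π = 2c(n−c)/(n(n−1)); window π sums per-site
values over the window and divides by the full window length in bp,
monomorphic positions included. Watterson's θw divides each segregating
site by its own harmonic number a1(n) (sites differ in call rate), again
per bp. Tajima's D uses the 1989 constants with n taken as the rounded mean
haplotype count over the window's segregating sites, and is *undefined*
(not zero) when S = 0 — a distinction that matters downstream, because a
window swept clean of variation carries no neutrality evidence of its own.

Weir–Cockerham Fst accumulates the per-site variance components a, b, c and
reports the windowed ratio of sums Σa/Σ(a+b+c); negative values are kept
raw (flagged) so empirical quantiles are honest. The reduction-of-diversity
statistic is ROD = 1 − π_obj/π_ref. The diversity log-ratio
log(π_ref/π_obj) is +Inf when the objective subpopulation has lost all
diversity in a window that still segregates in the reference — maximal
reduction must stay flag-eligible — and NA only when the reference itself
is invariant.

## Selection scan

Candidate windows must lie in the top 1% of the empirical Fst distribution
*and* the top 1% of the diversity log-ratio for the same subpopulation pair
(scan domain: the SHRs plus 10-kb flanks; quantiles computed per pairwise
comparison). Flagged windows merge across gaps of at most one window, and
merged regions are confirmed by a one-sided rank-sum test of window-level
Tajima's D (objective vs reference, confirmed when P < 0.05 with the lower
objective mean; regions with fewer than three D-defined windows per side
are "not evaluable").

A candid note on sensitivity: at the 250-bp scale with desk-scale panels
(40–60 individuals per subpopulation, ~19 SNPs per window) the two axes of
the joint rule anti-correlate — the strongest diversity-reduction windows
are often *not* the strongest differentiation windows, because a swept
haplotype mostly carries the same alleles as the reference majority. In our
simulations roughly a third of truly swept windows clear both top-1% tails,
and fully swept windows have undefined D, which limits rank-sum
confirmation. Detection of the swept *region* (at least one window flagged
inside it) is nonetheless reliable; per-window sensitivity is not, and
users should read the window-level flags accordingly.

## Fixation classes

Per SNP and subpopulation MAF: `completely_fixed` when MAF = 0 in at least
one subpopulation, `nearly_fixed` when MAF < 0.05 in at least one (but
non-zero in all), else `segregating`.

# LD structure

Pairwise LD is the composite (dosage-correlation) r², which is well defined
without phase and monotone with haplotype r² under HWE. Permutation
P-values shuffle one site's labels (1,000 permutations in tests, 10⁵ in
production configurations) with plus-one correction; one shared set of
permutations per complete-case count is reused across pairs, which is valid
for marginal P-values and removes the dominant cost. Blocks are maximal
runs of consecutive sites in which *every* within-run pair satisfies
r² ≥ 0.75 and P ≤ 10⁻³ — the block criterion applied literally,
rather than Haploview's Gabriel confidence-interval method, which is
parameterised differently. Decay is fitted by Levenberg–Marquardt nonlinear
least squares of the Hill–Weir drift-recombination expectation with its
finite-sample correction; the reported summary is the fitted ρ and the
distance at which the curve crosses r² = 0.2 (reported as "beyond data
range" when it does not cross within the observed distances).

# Mixed-model association

The model is y = Qβ + x·b + u + e with u ~ N(0, σg²K), K the IBS kinship
(diagonal 1, bent to positive semi-definiteness by eigenvalue flooring when
needed). The variance ratio is fitted *once* per phenotype set on the
no-SNP model by restricted likelihood on the spectral decomposition of K —
the "population parameters previously determined" approximation — and every
SNP is then tested by generalized least squares with a Wald chi-square on
the dosage term; per-SNP REML refits are available behind `per_snp_reml`.
Structure covariates Q default to the known subpopulation labels (the
panel's regions of origin are known); a PC matrix can be supplied instead.
Missing dosages are mean-imputed per SNP for the association design matrix
only — the population-genetic statistics never impute. On structured null
panels the genomic inflation factor pooled over several phenotype sets sits
within [0.9, 1.1].

Significance uses the modified Bonferroni pair: suggestive P = 1/n and
significant P = 0.05/n for n markers (1.9 × 10⁻⁵ and 9.4 × 10⁻⁷ at
n = 52,949).

## Additive/dominance decomposition

Least-squares means of the three genotype classes under the Q-adjusted
linear model give a = (mean(AA) − mean(aa))/2 and
d = mean(Aa) − (mean(AA) + mean(aa))/2, each with a t-test at P < 0.001
(the decision threshold for declaring an effect class; configurable). A SNP
is `additive`, `dominant`, `both`, or `none`; when any genotype class has
fewer than 3 individuals only the dosage (additive) test is run and the
record is flagged `restricted`. PVE trajectories across timepoints classify
by the signs of the first-half and second-half slopes against a tolerance
of 0.005 PVE per timepoint step.

## Hotspots and lead SNPs

A feature (gene or ncRNA) is an association hotspot when it is associated
in at least `k` distinct phenotype sets (12 at the suggestive threshold, 8
at the significant threshold) *and* exceeds the 95th percentile of a null
built by shuffling phenotype-set labels over the association events. Unique
signals per phenotype set are formed greedily: the lowest-P SNP leads,
absorbs all significant SNPs with r² ≥ 0.2 to it, and the procedure repeats
(ties in P resolve to the smaller coordinate); candidate features are
collected within 10 kb of each lead.

# Two-locus epistasis

The 3×3 genotype-class table is partitioned by a fixed-effects two-way
model: the overall interaction test compares the full cell-mean model to
the additive (locus A + locus B) model (4 df when all classes are
populated), and the interaction sum of squares decomposes into orthogonal
1-df components a×a, a×d, d×a, d×d. Contrast weights come from the
*observed* per-locus genotype frequencies (Gram–Schmidt against the
intercept and each other), so the components stay orthogonal under
departures from Hardy–Weinberg proportions; classical equal-frequency
weights are available for oracle checks, under which the component sums of
squares add exactly to the interaction SS on balanced designs. Pairs with
fewer than 5 populated classes of at least 2 individuals are skipped.

The contribution of a pair is reported as c = SS_interaction / SS_total.
The source convention divides the interaction sum of squares by the
phenotypic *variance*, which is dimensionally inconsistent; dividing by the
total sum of squares (equivalently n·Var up to n − 1 vs n) bounds c in
[0, 1] and is what this package reports — flagged here deliberately.

# The synthetic panel

Subpopulation allele frequencies follow the Balding–Nichols model:
Beta(p(1−F)/F, (1−p)(1−F)/F) around an ancestral frequency p, with
per-subpopulation F (default 0.10) and Hardy–Weinberg genotypes within
subpopulations. Two features deserve explanation:

* **Ancestral frequency distribution.** The default draw has density
  ∝ p^(−1.4) truncated to [0.001, 0.999]. A uniform ancestral MAF
  (available as `maf_dist = "uniform"`) produces a strong excess of
  intermediate-frequency variants and a windowed Tajima's D around +1.6 —
  far from neutral expectations. The exponent 1.4 was calibrated once so
  that *after* Balding–Nichols drift at the default F the within-
  subpopulation site-frequency spectrum approximates the neutral 1/p
  spectrum (mean windowed D ≈ 0), which is the behaviour a neutral panel
  should show; the drift smoothing is why the exponent exceeds 1.
* **LD.** With `n_founder_haps` set, genotypes are mosaics of founder
  haplotypes (per region and subpopulation) with a per-bp switch rate, so
  r² decays with distance; by default sites are independent, which is the
  correct null for the calibration checks. No coalescent machinery is used.

Sweeps act at the haplotype level in copying mode (all founders collapse to
one haplotype inside the interval; a fraction ρ_sweep of sites escape) and
at the frequency level otherwise, with hitchhiking semantics: the allele on
the swept haplotype fixes with probability equal to its frequency.
Phenotypes for all 27 trait × timepoint sets are built from standardized
components — additive and dominance terms of planted QTNs, planted
epistatic interactions, a polygenic term drawn with covariance proportional
to the realized kinship and orthogonalized against the planted components
(so each planted locus explains its target variance fraction in-sample) —
plus Gaussian noise filling the variance to 1.

## What the simulations do not show

The generators emulate the *statistical* structure the pipeline needs:
segregation and recombination, drift-driven differentiation, LD decay,
variance-component phenotypes. They do not model sequencing error,
call-rate heterogeneity, gene conversion, demography beyond the island-like
Balding–Nichols drift, selection other than the planted sweeps, or
genotype–environment interaction. Passing tests therefore demonstrate
correctness of the estimators and decision rules under a known generating
model — not robustness to every artefact of real resequencing data.

# Problem sizes and runtime

Default desk-scale sizes — 300 progeny on 19 LGs (~15 markers each), a
150-member panel (60/40/50) with 1,000–5,000 SNPs over a handful of SHRs,
1,000 permutations, 10³ LD permutations — keep the full pipeline in the
low minutes on one CPU. `full_scale = TRUE` switches the simulators to the
emulated study's dimensions (1,200 progeny, ~67 markers per LG, panel
180/95/160). Calibration experiments in the test suite use 100–200
replicates of the cheapest sufficient configuration; the methods above do
not change with scale.

# Known limitations

* The two-class pseudo-testcross coding discards the minority of fully
  informative co-dominant markers a real map contains.
* Tajima's D per 250-bp window rests on very few segregating sites; its
  window-level values are useful in rank-based aggregates (as in the
  confirmation test), not individually.
* The joint top-1% selection rule has limited per-window sensitivity (see
  the selection-scan section); region-level detection is the supported use.
* Composite r² underestimates haplotype r² when HWE fails within
  subpopulations; the EM-haplotype variant is intentionally not implemented
  (phase is never inferred anywhere in the package).
* The MLM's one-fit variance-component approximation slightly misstates
  per-SNP tests when a SNP explains a large variance fraction; use
  `per_snp_reml = TRUE` where that matters.
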