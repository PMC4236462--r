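---
title: "Methods: phylogeographic statistics and multi-model refugium delimitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogeographic statistics and multi-model refugium delimitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`medrefugia` implements the two analysis arms that are commonly combined to
study Mediterranean taxa whose ranges mix natural history with
human-mediated transport: (1) single-locus phylogeographic statistics and
objective lineage delimitation from geo-referenced mitochondrial
alignments, and (2) paleoclimate-based ecological niche modeling across an
ensemble of general circulation models (GCMs), with glacial refugia
delimited as areas continuously suitable from the Last Glacial Maximum
(LGM) through the mid-Holocene to the present. A synthetic-data module
generates both kinds of input with known ground truth, so every stage can
be validated end to end at desk scale.

# The molecular arm

## Haplotypes and diversity

Sequences are collapsed into haplotypes by exact identity over resolved
sites. Sites that are not A/C/G/T are unresolved; a partially resolved
sequence joins a class only when it is compatible (equal at all mutually
resolved sites) with exactly one class. When several classes are
compatible, the merge would be arbitrary, so the default strict policy
excludes the sequence with a warning rather than resolving the ambiguity
silently; a lenient policy (join the largest compatible class) is
available. Partial sequences are fragile in exactly this way in real
cox1 datasets, which is why surfacing the ambiguity is the default.

Summary statistics follow the conventions of the standard
population-genetics programs: haplotype diversity with the small-sample
correction $H_d = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$, nucleotide
diversity $\pi$ as the mean per-site pairwise difference with complete
deletion of sites containing unresolved bases (the per-locus mean pairwise
difference $\bar k = \pi L_\mathrm{eff}$), and per-sequence singleton
counts $U_i$. Pairwise p-distance matrices instead use pairwise deletion,
matching the usual division of labour between the programs that made these
two conventions standard; both are switchable. p-distances need not obey
the triangle inequality and the package does not assert it.

## Neutrality tests

Fu's $F_S$ uses the Ewens sampling formula: with $\hat\theta = \bar k$,
$S' = \Pr(K \ge H_\mathrm{obs})$ where
$\Pr(K = k) = |s(n,k)|\,\hat\theta^k / \prod_{i=0}^{n-1}(\hat\theta + i)$,
and $F_S = \ln(S'/(1-S'))$. The unsigned Stirling numbers of the first
kind are evaluated with a log-space recurrence, which keeps the statistic
finite and accurate beyond $n = 300$ (direct integer evaluation overflows
near $n = 20$). $H_\mathrm{obs} = 1$ makes $S' = 1$; the statistic is
reported as $+\infty$ with a warning rather than an arbitrary large value.

The Ramos-Onsins & Rozas statistic is
$R_2 = \sqrt{\tfrac1n \sum_i (U_i - \bar k/2)^2} / S$. Both tests are
undefined at $S = 0$ and error explicitly.

Significance comes from coalescent simulation conditioned on the observed
number of segregating sites: standard coalescent genealogies with exactly
$S$ mutations placed multinomially proportional to branch length. The
reported $p$ is the left tail $(1 + \#\{\mathrm{sim} \le
\mathrm{obs}\})/(n_\mathrm{sims}+1)$, with the right tail exposed
alongside because the conventional significance call for $F_S$ uses the
2% left tail for a 5% test. The same fixed-$S$ simulator doubles as the
generator's conditioning mode, so its calibration is tested directly: on
neutral replicates ($n = 30$, $S = 20$) the 5% left-tail rejection rate of
both statistics must fall inside the 99% binomial band around 0.05.

## Isolation by distance

The Mantel test correlates locality-level mean p-distances with
log-transformed great-circle distances (haversine, sphere radius 6371 km)
and assesses significance by simultaneous row/column permutation,
$p = (1 + \#\{r_\mathrm{perm} \ge r_\mathrm{obs}\})/(n_\mathrm{perm}+1)$.
Two conventions needed fixing where the source material is silent: zero
geographic distances are replaced by half the smallest positive distance
before the log, and the default permutation count is 999 (the number named
in the methods of the motivating study; its results table mentions 10000,
so the count is an argument, not a constant). Matrices of fewer than five
localities are refused outright, mirroring the exclusion rule used for
sparsely sampled lineages.

## Diversity and rarity mapping

Grid points are laid every 100 km (default) in latitude and longitude over
the sampled area; samples within a radius (default equal to the spacing,
the neighbourhood being only loosely specified in the field) form a pool.
Pools of at least $m = 5$ are bootstrapped $B = 1000$ times with
subsamples of size $m$ drawn without replacement, yielding bootstrap means
of total haplotype diversity $H_T$, haplotype richness $H_R$, and a rarity
index $R$. The rarity index is defined here as the mean over drawn
individuals of one over the number of localities occupied by their
haplotype dataset-wide: bounded in $(0, 1]$, monotone in geographic
restrictedness, and equal to 1 exactly when every drawn haplotype is a
single-locality endemic. This is an interpretation of a diversity-mapping
tradition that cites the index without printing a formula; it is recorded
as such. Bootstrap means are verified against exhaustive enumeration on
pools small enough to enumerate.

## Statistical-parsimony networks

The connection limit — the maximum number of mutational steps for which a
parsimonious relationship (no multiple substitutions underlying any single
difference) holds with stated confidence — is computed from the cumulative
parsimony probability

$$P_j = \prod_{i=1}^{j} \left(1 - \frac{i}{2L}\right),$$

the largest $j$ with $P_j \ge$ confidence being the limit. The $i$-th
additional substitution must avoid the $i$ sites already struck among the
$2L$ site-lineage copies of the two diverging sequences. For $L = 1016$
sites this yields 13 steps at 95% and 5 at 99%, the published behaviour of
the classic network program, and plausible limits across other alignment
lengths (10 at ~600 bp, 14 at ~1140 bp). Networks are then built by
joining haplotype pairs at mutational distance 1, 2, ... up to the limit;
all equal-length alternative connections at a level are retained (loops
are never broken by frequency criteria), and the connected components are
the putative evolutionary units.

## GMYC

The single-threshold generalized mixed Yule-coalescent model is fitted on
a binary ultrametric tree with one tip per haplotype. A threshold age $T$
splits branching into a between-lineage process with $n_Y$ lineages and
within-lineage coalescent processes with $n_c$ lineages in cluster $c$;
between successive branching events the hazard is
$b = \lambda_1 n_Y^{p_1} + \lambda_2 \sum_c (n_c(n_c-1))^{p_2}$ and the
log-likelihood is $\sum_i (\ln b_i - b_i x_i)$ over waiting times $x_i$.
Candidate thresholds are the branching ages plus the all-singleton
threshold at age zero; including the latter makes the single-process null
$b = \lambda n^p$ an exact special case of the alternative, so the
likelihood ratio is non-negative by construction. Optimization is
multi-start L-BFGS-B over log-rates (log-exponents bounded in
$[1/3, 3]$ when free); ties in $T$ break toward the older threshold. The
likelihood-ratio test uses $\chi^2_3$ ($\chi^2_1$ with exponents fixed) as
a convention, exposed as an argument: the threshold search makes the test
anti-conservative on single-process trees, which the test suite documents
with a bounded (not nominal) rejection-rate check. The confidence set for
the number of entities collects thresholds within two log-likelihood units
of the maximum.

# The niche-modeling arm

## Climate preparation

Nineteen bioclimatic variables are computed from monthly climatologies
with quarters as the twelve wrap-around three-month windows;
$\mathrm{BIO4} = 100 \times \mathrm{SD}(T_\mathrm{monthly})$ and
$\mathrm{BIO15} = 100 \times \mathrm{SD}(P)/(1 + \bar P)$. Four layers
known for spatial artifacts (mean temperature of the wettest/driest
quarters, precipitation of the warmest/coldest quarters) are computed but
excluded from modeling, leaving 15.

Paleoclimate simulations are downscaled by the change-factor approach:
coarse anomalies (absolute for temperatures, relative for precipitation
with a 0.01 mm guard against arid-cell division) are interpolated to the
fine grid and combined with the fine present-day climatology. The
interpolator is bilinear by default; the variogram-based interpolation
sometimes used for this step is deliberately not reproduced, because the
acceptance surface does not depend on the interpolator and no variogram
model was available to copy. The zero-anomaly identity (past equal to
current implies output equal to the fine current climatology, exactly) is
asserted in the tests.

A principal component analysis of the 15 retained variables over the
calibration region (correlation matrix, since the variables mix units)
defines the environmental space; components are retained to 99%
cumulative variance. Numerically constant layers (relative standard
deviation below 1e-10) are dropped with a warning before the
decomposition — a synthetic constant-seasonality world otherwise injects
roundoff noise through the standardization. Scores are whitened so the
calibration cells have zero mean and unit variance on every retained axis,
and past conditions are always projected with the stored present-day
transform, never refit.

## Maximum-entropy modeling

The suitability model minimizes relative entropy between presence and
background densities in feature space: linear and quadratic functions of
the PCA scores, standardized over the background. The L1-regularized
concave objective is maximized by cyclic coordinate descent with soft
thresholding and an exact KKT stopping rule (tolerance 1e-6);
$\beta_j = \mathrm{reg}\times s_j/\sqrt m$ with $s_j$ the feature's
presence standard deviation. The feature set is intentionally small —
quadratic features suffice to recover the synthetic truth, keep the
problem convex, and make the solver auditable; hinge features are an
extension point, not a default. Bootstrap replicates resample presences
with replacement with the background fixed. Raw output sums to one over
the background; the logistic-style output rescales by the exponential of
the model entropy for a bounded display scale. Aggregation follows the
median pipeline of the motivating protocol: cell-wise median over
bootstrap replicates, times 1000, floored to integers, then median over
occurrence subsets.

Occurrences are thinned to a minimum 50 km spacing by randomized greedy
passes (each replicate maximal by construction); models are calibrated
within a region built by buffering occurrences 350 km and rasterizing.
Binarization uses minimum training presence: the threshold is the lowest
suitability at any training occurrence on the present-day aggregated
surface, and that same threshold is applied to the paleo projections —
thresholds belong to the training conditions, not to the projection.

Evaluation uses partial ROC restricted to sensitivity $\ge 1 - E$
(default $E = 0.01$): the AUC ratio of the model curve over the null line
in sensitivity versus proportional-predicted-area coordinates, bootstrap
resampling 50% of test points with replacement, $p$ the fraction of
bootstrap ratios at or below one. The proportional-predicted-area x-axis
is a stated convention choice. The ratio carries a small positive bias
under no-signal conditions when few test points populate the
low-omission region; the tests bound rather than idealize this.

Mobility-oriented parity (MOP) flags strict extrapolation (any
environmental dimension outside the calibration min-max) and scores other
projection cells by similarity to the nearest 10% of the calibration
cloud. Suitable-and-extrapolative cells can be removed from binary maps.

## Refugium delimitation

A refugium is an area continuously suitable across all time slices. Two
orders of operations are provided and algebraically related: M1 takes the
k-of-G consensus of the GCM binary maps within each slice and intersects
the slices; M2 intersects the slices within each GCM and takes the
k-of-G consensus of the per-GCM refugium maps. M2(k) is always nested in
M1(k); both shrink monotonically in k and coincide at k = G when every
model covers every slice. Agreement thresholds are specified as fractions
{1/G, 1/2, 3/4, 1} and converted to counts by ceiling, so the classic
{1, 4, 6, 8}-of-8 thresholds are reproduced exactly and slices missing
some models (mid-Holocene outputs are absent for some GCMs in the real
archives) are thresholded against the available count. Components are
labeled with queen adjacency by default (coastal cells touching
diagonally belong together) and areas use latitude-corrected cell sizes.

By default the consensus consumes the unmasked binary maps, with MOP
products computed and exported alongside (`use_mop_mask` switches the
consensus to masked maps). The strict min-max rule removes genuinely
suitable cells whose climate lies marginally outside the sampled
present-day range — an epistemic caution that biases truth-recovery
toward omission, while the empirical report this package follows found
refugium delimitation robust to the models where masking mattered most.

# The synthetic world

The generator is the package's test bed and defines the study conditions:

* **Sequences.** Coalescent genealogies (`ape::rcoal`), infinite-sites
  mutations with a 4-letter alphabet, either Poisson with rate $\theta/2$
  per unit branch length or exactly $S$ mutations placed multinomially —
  the latter is also the neutrality-test null simulator. Default locus
  length 1016 sites (a cox1 fragment), $\theta = 8$ per locus.
* **Geography.** Localities are uniform points in a Mediterranean-like
  box; sample coordinates evolve by Brownian dispersal along each
  genealogy (scale `ibd_scale`, default 300 km per unit coalescent time)
  and snap to the nearest locality, so relatedness decays with distance.
  A `mixing_fraction` of samples has localities reassigned uniformly,
  emulating human transport; at 1 the spatial signal is destroyed by
  construction. Lineages (default 3) are rooted at random localities with
  ~3% diagnostic divergence between lineage ancestors. The
  Mantel-recovery checks run at $n = 60$, $L = 800$, $\theta = 20$,
  25 localities, 4 lineages: a power analysis during design showed these
  conditions give the structured arm ~95% detection while the fully mixed
  arm stays at the nominal false-positive rate; weaker structure tests the
  climate of the test, not the code.
* **Climate.** Monthly temperature follows a latitudinal gradient with a
  seasonal cycle and fixed orographic bumps; precipitation follows a
  longitudinal gradient; diurnal range widens with longitude
  (continentality) — deliberately not with latitude, so that no variable
  is collinear with mean temperature in the present yet decoupled from it
  in the past, a configuration that would defeat any
  projection method that learns mixtures (the package's own recovery runs
  uncovered exactly that failure mode during design). The mid-Holocene is
  0.5 degC cooler, the LGM 4.5 degC cooler with 10% less precipitation, so
  the suitable band shifts ~5 degrees south at the LGM. Each pseudo-GCM
  receives one coherent smooth perturbation (default SD 0.5 degC,
  proportional for precipitation) shared across months and slices. The
  noise default was set by a perfect-model decomposition: at 1 degC even
  the true suitability function applied to each GCM's climate cannot meet
  the package's own recovery bar, so that level measures climate noise
  rather than implementation error.
* **Truth.** Suitability is a steep logistic band in annual mean
  temperature with a weak annual-precipitation term,
  $\mathrm{plogis}(50(1 - ((\mathrm{BIO1}-12)/4)^2 -
  ((\mathrm{BIO12}-816)/1200)^2))$, evaluated on the unperturbed fields;
  the steepness makes the band effectively hard-edged, which is the
  regime in which a minimum-training-presence threshold is informative
  (with a soft band, occurrences sampled proportionally to suitability
  inevitably include marginal cells and MTP dilates accordingly — a
  property of the threshold rule, not a bug). True refugia are the cells
  at or above 0.5 in every slice; the truth object is internally
  consistent by construction and asserted so in the tests.

What the generator does not emulate: recombination, selection, migration
matrices, sequencing error, rate heterogeneity, real CMIP5/PMIP3 spatial
structure, coastlines/ocean masking, and observation bias in occurrence
records. Passing recovery tests therefore demonstrates correctness of the
implementations under clean assumptions, not robustness to the full messiness
of real data.

# Desk-scale sizes

The shipped tests and the acceptance script run everything from scratch:
the end-to-end recovery uses the default synthetic suite (4 pseudo-GCMs,
3 slices, 60x60 half-degree grid, 150 occurrences) with 2 occurrence
subsets and 3 maxent bootstrap replicates per subset across seeds 1-3;
the full protocol sizes (10 subsets x 100 replicates, 999+ permutations,
1000 simulations) remain available through `pipeline_config()`. Recovery
is scored as Jaccard overlap with the true refugia at the
three-quarters-agreement stringency (the 6-of-8 analog for 4 models), the
intermediate level at which ensemble agreement is usually interpreted.

# Known limitations

* The GMYC likelihood-ratio test is anti-conservative under the null, a
  known property of threshold optimization; interpret borderline p-values
  cautiously and prefer the entity confidence set.
* Fu's $F_S$ significance uses fixed-$S$ conditioning; programs that
  condition on $\hat\theta$ instead will give slightly different null
  distributions.
* The maxent implementation is a transparent linear+quadratic density
  estimator, not a re-implementation of any particular desktop program's
  feature classes, clamping, or logistic calibration constant.
* Partial ROC requires enough test points to populate the low-omission
  region; with very few points the AUC ratio is biased upward and its
  bootstrap "significance" is not a calibrated p-value.
* Rasters are plain lon/lat grids; there is no projection handling, and
  component areas use a spherical cosine correction only.
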