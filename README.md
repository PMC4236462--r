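# medrefugia

Phylogeographic statistics and multi-model paleoclimate refugium
delimitation for Mediterranean taxa.

Species complexes whose present-day ranges mix natural history with
human-mediated transport — the Mediterranean recluse spiders are the
textbook case — are studied with two complementary data streams: the
geographic structure of mitochondrial lineages, and ecological niche
models projected onto Last Glacial Maximum (LGM) and mid-Holocene
paleoclimates to ask where climate stayed continuously suitable.
`medrefugia` implements both arms as tested, scriptable R functions, for
population geneticists and biogeographers who want the full pipeline —
from aligned sequences and monthly climatologies to neutrality tests,
haplotype networks, and consensus refugium maps — without stitching
together half a dozen desktop programs.

## What it computes

**Molecular arm** (input: aligned FASTA + sample CSV with coordinates):

* haplotype collapsing with explicit ambiguity policy; haplotype
  diversity `Hd = n(1 − Σp²)/(n − 1)`, nucleotide diversity π, mean
  pairwise differences, singleton counts;
* Fu's `F_S = ln(S′/(1−S′))` with `S′ = Pr(K ≥ H_obs)` under the Ewens
  sampling formula (log-space Stirling numbers, stable past n = 300), and
  the Ramos-Onsins & Rozas `R2 = √(mean((U_i − k̄/2)²))/S`, both with
  significance from coalescent simulations conditioned on the observed
  number of segregating sites;
* Mantel tests of isolation by distance on log-transformed great-circle
  distances with permutation significance;
* grid-based bootstrap mapping of haplotype diversity, richness and
  rarity;
* statistical-parsimony networks under 95%/99% connection limits, the
  limit computed from the cumulative parsimony probability
  `P_j = Π_{i=1..j}(1 − i/(2L))`;
* single-threshold GMYC lineage delimitation on ultrametric trees, with
  a likelihood-ratio test against a single-process null.

**Niche-modeling arm** (input: occurrence CSV + monthly climatologies per
GCM per time slice, as ESRI ASCII grids or in-memory rasters):

* the 19 bioclim variables (four artifact-prone layers excluded from
  modeling), change-factor downscaling of paleo anomalies, and a shared
  principal-component environmental space (99% variance, projected —
  never refit — onto past conditions);
* maximum-entropy suitability models (linear + quadratic features, L1
  regularization, exact coordinate-descent solver), occurrence thinning,
  median aggregation, minimum-training-presence binarization, partial ROC
  evaluation, and MOP extrapolation masking;
* refugium delimitation by two orders of operations — consensus across
  GCMs then intersection across time slices (M1), or per-GCM
  intersection then consensus (M2) — over agreement thresholds
  {1/G, 1/2, 3/4, 1}, with connected-component labeling and
  latitude-corrected areas.

A synthetic-data module (`sim_config()`, `simulate_geo_dataset()`,
`simulate_climate_suite()`, `sample_occurrences()`) generates both kinds
of input with known truth, so the whole pipeline is verified end to end.

## Worked example

```r
library(medrefugia)

# a synthetic world with known refugia
cfg <- pipeline_config(seed = 1, sim = sim_config(seed = 1))
run <- run_pipeline(cfg, stages = c("simulate", "climate", "enm", "refugia"))

# how well do consensus refugia recover the truth?
truth <- run$simulate$climate_truth$true_refugia
sc <- run$refugia$scenarios$M1_f0.75
sc
jaccard_overlap(sc$result, truth)
```

```
refugia M1 (k = 0.75 of models): 575 suitable cells in 1 component(s)
[1] 0.7768456
```

At three-quarters agreement among the four pseudo-GCMs, the delimited
refugia cover 575 half-degree cells in one connected component and
overlap the true refugia (cells suitable in every time slice) with a
Jaccard index of 0.78.

The molecular arm on the same synthetic world:

```r
s <- alignment_summary(run$simulate$geo)
s
fu_fs(s)
connection_limit(1016, 0.95)
```

```
n=60  sites=1016  S=152  H=35  Hd=0.976  pi=0.04738  kbar=48.140
[1] 2.342112
connection limit: 13 steps at 95% for L = 1016 (P = 0.9561)
```

Here `S` counts segregating sites, `Hd` is haplotype diversity, and π the
per-site nucleotide diversity; the positive Fu's Fs reflects the deep
structure among the simulated lineages rather than demographic
expansion. The connection limit says haplotypes up to 13 mutational steps
apart may be joined into one network with 95% confidence at this locus
length.

A thin command-line wrapper is installed at `inst/cli/medrefugia.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/medrefugia.R", package="medrefugia"))')" \
    --stages simulate,popgen,delimit --seed 1 --out runs/demo
```

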