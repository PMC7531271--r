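---
title: "Evaluating sampling designs for population genomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating sampling designs for population genomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

popsampling answers a practical question: when a population-genomic study
cannot afford to genotype everything, what is lost by sampling fewer loci,
fewer individuals per population, or fewer populations? The package
simulates hierarchically structured populations with known ground truth,
computes the classic summary statistics and landscape-genetic associations
on the full data, re-computes them on replicated random subsamples, and
quantifies the deviation as relative error. This vignette documents the
models, the estimators, and every numerically consequential choice.

## The demographic model

`build_hierarchical_model()` describes 50 demes split into two genetic
clusters of 25 ("old" and "young"), mimicking a pair of subspecies with
higher gene flow within than between clusters. Backward in time:

* between the present and `t_split` (default 20,000 generations) all 50
  demes exist; each lineage emigrates with total probability `m_within`
  (default 0.001 per generation) towards demes of its own cluster, split
  uniformly across them, and `m_between` towards the other cluster
  (default 1e-4 under the high-gene-flow regime, 0 under the low regime);
* at `t_split` the young demes fuse into the first old deme (the young
  cluster's founder), and the remaining 25 old demes continue exchanging
  migrants until `t_ancestral` (default 140,000 generations);
* at `t_ancestral` everything fuses into a single ancestral deme.

Mean diploid effective sizes are 5,000 per old deme and 5,000/1.5 per young
deme. Migration is interpreted as a per-lineage, per-generation backward
emigration probability whose total is split across eligible target demes;
an alternative reading (a fixed probability per source-target pair) changes
overall mixing but, as we verified by simulation, not the qualitative
behaviour of any statistic studied here.

**Parameter jitter.** Real populations are not exchangeable, so each deme
draws its own `Ne`, `m_within` and `m_between` from truncated normal
distributions (truncated at zero) centred on the regime means with
coefficient of variation `jitter_cv = 0.10`. A small CV produces
between-population spread in the summary statistics without destabilising
the model. Split times are kept global: a per-deme coalescent time has no
coherent single-genealogy interpretation.

**Inbreeding.** Each deme draws an inbreeding coefficient
`F = max(Normal(0, 0.05), 0)`, giving `E[F] ~ 0.02` with a point mass at
zero: most demes mate randomly, a few are moderately inbred. At sampling
time an individual's second haplotype is, with probability `F`, an
identical-by-descent copy of its first — applied per individual across all
loci, so a deme with `F = 1` is homozygous everywhere. This reproduces
within-population FIS of the intended magnitude (~0.01–0.02 on average)
with realistic between-population variance.

## The coalescent simulator

Each locus is an independent structured-coalescent genealogy of all sampled
haplotypes, simulated as a continuous-time Markov jump process (pairwise
coalescence at rate `1/(2 Ne_d)` within deme *d*, per-lineage migration at
the emigration rates above, deterministic fusion events at the two epoch
boundaries). The core is implemented in C++ (via Rcpp) because a 50-deme,
1,500-haplotype genealogy involves thousands of events and thousands of
independent loci are needed per dataset.

**SNP ascertainment.** A SNP dataset consists of loci that *are*
polymorphic — the observation process conditions on segregation. Under the
infinite-sites model the correct sampling measure weights each genealogy by
its total branch length and then places the single mutation uniformly along
the tree; the resulting ascertained frequency spectrum in a panmictic
sample of *n* haplotypes is exactly `P(i derived copies) proportional to 1/i`. Placing a
mutation uniformly on an *unweighted* tree is subtly wrong (it samples
`E[l_i/l_tot]` rather than `E[l_i]/E[l_tot]`; for n = 4 the expected
heterozygosity differs by ~0.3%, detectable at 10^5 loci). We implement the
length-weighted measure exactly with a Poisson acceptance step: draw
`K ~ Poisson(r * length)`, accept the tree with probability `min(K, c)/c`,
then place the mutation uniformly. The rate `r` is calibrated from pilot
trees so `E[K] ~ 25` and `c = 110`, making the truncation error (the
Poisson mass above `c`) negligible (< 1e-9) and the acceptance rate ~20–25%.
The package's single-deme test recovers the closed form
`E[1 - sum p^2] = 4.5/11` at Monte-Carlo precision over 10^5 loci.

**Microsatellites.** The same genealogies carry Poisson mutations along
branches (rate `mutation_rate` per generation) under the stepwise mutation
model (±1 repeat, equal probability) from a root repeat count of 100. No
ascertainment is applied — loci can be monomorphic — and the single-deme
equilibrium gene diversity approaches `1 - 1/sqrt(1 + 8 Ne mu)` as it
should.

**A consequence worth knowing.** Because SNP loci are ascertained as
polymorphic in the pooled *total* sample (not per population), the expected
within-deme gene diversity of an ascertained locus is bounded by roughly
`1/H_{n-1}` of the total sample size (~0.13 for 1,500 haplotypes), and
hierarchical structure pushes it lower still, because deep branches that
separate clusters absorb mutation probability while being monomorphic
within every deme. Simulated per-population Hs therefore sits near
0.05–0.06 at the default design — a *property of total-sample
ascertainment*, not a bug; SNP-chip data ascertained in small discovery
panels behave very differently. Comparisons in this package are therefore
made within the simulation (subsample versus full data), never between
simulated and chip-scale absolute diversity levels.

## Estimators and undefined-value semantics

All estimators are implemented from scratch (with naive per-term reference
implementations in the test suite, agreeing to 1e-10 on randomized inputs):

* per locus and population, with `n` typed individuals (both allele calls
  present): observed heterozygosity `Ho`; Nei's corrected gene diversity
  `Hs = n/(n-1) (1 - sum p^2 - Ho/(2n))`; `FIS = 1 - Ho/Hs`, **undefined**
  when `Hs = 0` (e.g. the locus is fixed in that population);
* per locus across the `s` populations with data: Nei–Chesser total
  diversity `Ht = 1 - sum pbar^2 + Hsbar/(nh s) - Hobar/(2 nh s)` with `nh`
  the per-locus harmonic mean sample size (so missingness propagates
  exactly), and `FST = (Ht - Hsbar)/Ht`, reported as computed — negative
  values are never clamped;
* pairwise FST: Weir–Cockerham (1984) theta (genotype components a, b, c;
  the haploid moment analogue for pooled counts), multilocus ratio of sums;
  or the Nei form restricted to the pair. Note that the corrected WC theta
  of a population paired with a copy of itself is not exactly zero but
  `~ -1/(2(n-1))` — the price of the finite-sample correction;
* pooled data: `Ho` and `FIS` are *unavailable* (NA with the pooled flag
  set), never silently zero; `Hs` uses half the haploid pool count.

Undefined FIS cells ("NaN" cells) are counted per population, never
dropped from the accounting: they are the paper trail of the mechanism by
which sparse individual sampling depresses FIS (rare alleles go unsampled,
loci appear fixed, and the remaining defined cells are a biased subset).
`fis_nan_correlation()` quantifies it. Monomorphic-within-subsample loci
stay in all denominators, contributing zero diversity. Per-population means
across loci skip undefined cells but record their count; grand means weight
populations equally. The overall FST is the ratio of per-locus sums by
default (variance reduction); the mean of per-locus ratios is also exposed,
since the two conventions differ in small samples.

## The subsampling engine

`sampling_design()` fixes an axis (loci, individuals per population,
populations, or the joint tradeoff pair), a level, a replicate count and a
seed. Replicate `i` uses the deterministic seed `replicate_seed(seed, i)`
(an affine hash mod 2^31 - 1), so any replicate is individually
reproducible. Sampling is uniform without replacement within a replicate;
replicates are independent, so the same subset can recur. Populations with
fewer individuals than an individuals-axis level are an error, not a
silent truncation. Statistics undefined on a subsample (FST of a single
sampled population, say) are recorded as NA and counted, never fatal.

Relative error follows the convention `(X_est - X_sim)/X_est` against the
full-data reference: underestimates are positive, overestimates negative,
and a zero reference leaves the error undefined. Both the relative error
of the replicate mean and the mean of per-replicate errors are reported —
they answer different questions (bias of the design versus typical error of
one study). For association statistics the summary also reports the
sign-flip proportion: the fraction of replicates whose coefficient has the
opposite sign to the reference, i.e. studies that would reach the opposite
qualitative conclusion. In replicate tables the undefined-FIS statistic is
expressed as a per-locus *rate* so that loci-axis levels are comparable;
`basic_stats()` itself reports raw counts.

## Landscape statistics

* **Environmental PC1** — PCA on centred *and scaled* variables
  (bioclimatic layers have heterogeneous units), sign fixed by making the
  largest-magnitude loading positive so subsets score consistently.
  Zero-variance variables are dropped with a warning.
* **Distances** — geographic: haversine with Earth radius 6,371 km for
  lon/lat data, Euclidean for planar synthetic landscapes; environmental:
  absolute PC1 difference (one-dimensional Euclidean, matching the use of
  a single temperature axis).
* **MRM** — OLS of the unfolded lower triangle of the genetic-distance
  matrix on both predictor triangles jointly (simultaneous testing is the
  point of the method). Significance: permute rows and columns of the
  *response* matrix together, refit, and use
  `p = (1 + #{|b_perm| >= |b_obs|})/(n_perm + 1)` per coefficient — the
  observed statistic counts, so `p >= 1/(n_perm + 1)`. Permutation
  p-values are exchangeable under relabelling but only equal in
  distribution, not realization. Exactly collinear predictors are refused.
* **Centroid distances** — geographic centroid: coordinate-wise mean;
  niche centroid: mean in the space of the first two environmental PCs
  (one if only one is available; a fully degenerate environment puts every
  population at the niche centre). Distances are Euclidean in the
  respective space.
* **CAH regression** — simple linear regression of per-population Hs on
  centroid distance; a negative slope is the central-abundance signal.

The landscape generator plants verifiable ground truth: `ibd` mode
rescales within-cluster migration by `exp(-d_ij/sigma)` (per-deme totals
preserved, so `sigma = Inf` recovers the island model); `cah` mode replaces
the jittered deme sizes with a deterministic, strictly decreasing function
of centroid distance (`Ne bar * exp(-lambda d / d_max)`), making
Spearman(cor(Ne, distance)) = -1 by construction. Environmental variables
are linear spatial gradients plus noise, so space and environment are
correlated — as in real landscapes — which is why the MRM keeps both
predictors in one model.

## Outlier detection

The detector is a fully specified two-stage scan:

1. **Differentiation**: per-locus allele-count Weir–Cockerham theta; the
   null re-draws, for each locus, population frequencies from
   `Beta(pbar(1-theta)/theta, (1-pbar)(1-theta)/theta)` (the
   migration–drift equilibrium implied by the genome-wide theta) and
   binomial counts at the observed sample sizes, then recomputes theta.
   Upper-tail p with the observed value counted; the same allele-count
   statistic is used for observed and null values so the comparison is
   internally consistent. A global theta outside (0,1) skips the test with
   an explicit status.
2. **Environmental association**: per-locus |Pearson r| between population
   allele frequencies and the environmental score, nulled by permuting the
   environment vector over populations (permutations shared across loci).

Both stages produce Benjamini–Hochberg q-values; a locus is an outlier only
if *both* q-values fall below the threshold (default 0.05) — a conservative
intersection rule. Practical note: the attainable q floor is roughly
`p_floor * L / k` for `k` truly extreme loci among `L`, so null sizes must
scale with the locus count (e.g. 1,000+ nulls for 500 loci at q < 0.05);
the package's experiment functions expose these sizes explicitly.

`population_count_experiment()` varies the number of sampled populations
(one shared locus subsample drawn once per experiment), records per
replicate the maximum per-locus FST and the outlier count, and intersects
outlier sets across replicates and levels. With planted cline loci
(`plant_cline_loci()` deforms chosen loci towards a logistic cline in the
environment under within-population Hardy–Weinberg), true and false
positives are countable: detections rise, and the maximum FST falls, as
more populations are sampled.

## Problem sizes and numerical choices

Defaults follow the study design (50 demes, 15 diploids, 1,000 replicates
per design, 1,000 permutations, 10,000 nulls); the package's own analyses
and tests use deliberately reduced sizes chosen for stable results: 3,000
ascertained loci for calibration of means (per-locus draws are i.i.d., so
3,000 loci pin a mean Hs to ±0.002), 200 replicates for design summaries,
100-1,000 loci within subsampling experiments, 400–2,000 nulls for
outlier scans at 500-locus scale, and 10^5 loci for the single-deme
spectrum check. Floating-point comparisons against the per-term oracles use
an absolute tolerance of 1e-10; permutation counts always include the
observed statistic; BH q-values come from `stats::p.adjust`.

## What the synthetic data do and do not emulate

The generator reproduces hierarchical structure, migration-drift balance,
between-population parameter heterogeneity, inbreeding, missing-data
semantics (via the IO layer), pooled data, and plantable landscape/selection
signals. It does **not** emulate: discovery-panel ascertainment bias of
commercial SNP chips (which inflates absolute diversity and deflates
differentiation in ways that depend on the panel), recombination or linked
selection (loci are exchangeable and independent), sequencing error or
allele dropout, non-equilibrium spatial expansions, or empirical niche
models (environmental variables are synthetic gradients). Passing tests
therefore validate the estimators, the subsampling machinery and the
directional conclusions about sampling effort — not the absolute diversity
levels of any particular empirical marker system.

## Known limitations

* Simulated absolute Hs under total-sample ascertainment is low (see
  above); designs that need chip-like site-frequency spectra should model
  the discovery panel explicitly.
* The beta-binomial outlier null ignores hierarchical covariance among
  populations within clusters; with strong two-cluster structure, strongly
  cluster-partitioned loci are the first "outliers" even without
  environmental selection. The intersection rule with the environmental
  test is what keeps the false-positive count near zero in calibration.
* Pairwise WC theta retains its small-sample bias (the duplicated-
  population case above); relative-error comparisons between designs are
  unaffected because reference and subsample share the estimator.
* The pipeline is single-threaded by design (determinism first); large
  grids parallelise naturally by running designs in separate processes
  with distinct seeds.
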