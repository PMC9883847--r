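---
title: "Models and methods behind AKPtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind AKPtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AKPtools)
```

AKPtools quantifies inter-individual gut-microbiome variation and its
association with binary exposures and with diet. This vignette explains the
models, the tunable parameters and their defaults, what the synthetic data
emulate (and do not), and the numerical and design choices that were
genuinely open.

## The C-index and the AKP screen

For samples closed to relative abundance, the Ružička similarity
$C(x, y) = \sum_i \min(x_i, y_i) / \sum_i \max(x_i, y_i)$ is the weighted
Jaccard similarity: 1 for identical compositions, 0 for disjoint support.
For one exposure factor, `intraGroupSimilarity()` collects $C$ over every
unordered within-group pair — $g(g-1)/2$ values for a group of size $g$ —
separately for exposed and non-exposed subjects. `akpTest()` then compares
the two collections with the two-sample rank-sum test under all three
alternatives and summarizes medians and interquartile ranges.

Two conventions are offered for turning the one-sided p-values into a
verdict, because the field's reading and the ecological reading of a
*similarity* index point in opposite directions:

* `paper` (default): significantly **higher** exposed C-index ⇒ AKP;
  significantly lower ⇒ anti-AKP. This matches the convention of the
  clinical AKP literature that treats the C-index as a stochasticity
  measure.
* `ecological`: the labels are swapped. Higher within-group similarity
  means a more homogeneous (less dispersed) group, so under the classic
  beta-dispersion definition of the Anna Karenina principle a *lower*
  exposed similarity is the AKP signature.

The two verdicts are exact mirror images on every input (a tested
invariant), so nothing is lost by choosing either; what matters is stating
the convention, which every output records.

"Wilcoxon test" is implemented as the two-sample rank-sum (Mann–Whitney)
test: the exposed and non-exposed C collections come from different,
unpaired pair sets, so a signed-rank pairing is not defined. `wilcox.test`
uses the exact null distribution for small untied samples and the
tie-corrected normal approximation otherwise.

Pairwise C-values within a group share samples, so they are not
independent observations and the rank-sum p-value is anti-conservative.
The package therefore also ships `akpPermutationTest()`: the contrast
`median(C_exposed) − median(C_non_exposed)` is recomputed under
permutations of the subject-level exposure labels, with
$p = (1 + \#\{\text{as extreme}\}) / (1 + n_{perm})$. This test is exactly
level-α under exchangeability (a tested calibration property) and is the
one to report when calibration matters; the rank-sum version reproduces
the conventional workflow.

## Synthetic cohort and microbiome

`generateCohort()` matches requested positive-case counts **exactly** by
assigning each factor's positive cases to a random subset of subjects,
rather than flipping independent coins. The packaged defaults are the
study-cohort marginals (n = 331; 115 with dietary data; 65 ever smokers;
126 ever drinkers; 134 obese; 130 hypertensive; 70 diabetic; 209 male; 40
with family history; 41 with neoadjuvant therapy; age 61.9 ± 11.0 years).
When a different `n` is requested with the default marginal list, counts
are rescaled proportionally. BMI is drawn from two truncated normals on
either side of the 25.0 kg/m² cutoff (27.2 ± 2.0 above, 22.7 ± 1.9 below),
which makes the obesity count exact, keeps the `obesity ⇔ BMI ≥ 25`
invariant structural, and reproduces an overall mean near 24.4 kg/m².

`generateMicrobiome()` uses a hierarchical Dirichlet-multinomial: subject
$s$ draws composition $\pi_s \sim \mathrm{Dirichlet}(\theta_s m_s)$ and
counts $\sim \mathrm{Multinomial}(\text{depth}, \pi_s)$. Defaults: 100
taxa with a power-law base mean $m \propto i^{-0.7}$ (a handful of
dominant taxa plus a long tail, as in stool profiles), baseline
concentration θ = 50 (between-subject compositional CV broadly comparable
to human cohorts), fixed depth 10,000 reads. The count layer is
multinomial rather than negative-binomial: between-subject Dirichlet
variation already dominates technical overdispersion at these depths, and
a single overdispersion knob (θ) keeps the planted effects interpretable.

Planted effects mirror the two dysbiosis regimes:

* **AKP (responder model)** — a `responderFraction` subset of exposed
  subjects each receives an idiosyncratic, independently re-drawn
  community mean (log-normal perturbation of scale `shiftMagnitude`), and
  their concentration is divided by `dispersionRatio`. Only part of the
  group shifts, each in its own direction: heterogeneity rises.
* **anti-AKP (shared depletion)** — *all* exposed subjects switch to one
  common depleted mean with a `richnessLoss` fraction of taxa structurally
  zeroed, and the group concentration is multiplied by `dispersionRatio`.
  Everyone shifts the same way: heterogeneity falls.

`dispersionRatio` is therefore always ≥ 1 "in the direction of the planted
mode"; this keeps one parameter meaning "effect strength" in both regimes
instead of requiring the user to remember which side of 1 to use.

## Food tree and dietary diversity

`buildFoodHierarchy()` turns a level-columns classification (top /
group17 / group35 / item, optionally subitem) into a rooted tree with
deterministic lexicographic ordering within levels. All edges default to
length 1.0: no data-driven branch lengths exist for a food
classification, so UniFrac weights then reflect classification depth
only; per-level lengths are configurable. The packaged classification is
synthetic but reproduces the canonical level sizes 4/17/35/106(/663); the
packaged composition matrix is likewise a synthetic stand-in for a
nutrient database, with plant-only channels zeroed for animal foods,
`total_fatty_acids = SFA + MUFA + PUFA` by construction, and the weight
coefficient fixed at 1. The 663-subitem layer is off by default — the
106-item questionnaire is the native resolution, and either leaf set is
supported for UniFrac.

Chao1 is undefined for continuous intakes, so `discretizeIntake()` maps
grams/day to pseudo-counts via `round(amount / scale)` with scale = 1 g
and a floor of 1 for any positive intake (presence is never lost). Shannon
uses natural log; Simpson is reported as Gini–Simpson $1 - \sum p_i^2$.
Weighted UniFrac defaults to the normalized variant (division by the
depth-weighted total mass), which is the bounded [0, 1] form in common
use; the raw form is available via `normalized = FALSE`. The Aitchison
distance adds a pseudocount of 1 count by default before the CLR;
pseudocount 0 is accepted for strictly positive data.

`generateDiet()` draws, for each subject with dietary data, a random
subset of consumed items (baseline probability 0.45) with log-normal
grams/day (meanlog 2.5, sdlog 1 — median ≈ 12 g/day per consumed item).
With coupling ρ > 0 a shared per-subject latent score — the same scores
used by the microbiome generator under the same master seed — shifts both
the consumption log-odds and the log-intake means along fixed random
directions, and simultaneously tilts the microbiome community means; ρ
scales the strength, with ρ = 0 giving full independence. A single master
seed fans out to fixed per-stage substreams, so each table can be
regenerated independently and reproducibly.

## Procrustes / PROTEST and PERMANOVA

`procrustesProtest()` embeds both distance matrices by principal
coordinates (negative eigenvalues discarded by default; the Cailliez
additive correction is available), keeps $k$ = number of positive
eigenvalues capped at 10, centers and scales each configuration to unit
sum of squares, and computes $m^2 = 1 - (\sum_i \sigma_i)^2$ from the SVD
of the cross-product. PROTEST permutes the row order of one configuration;
permuted $m^2$ values *smaller than or equal to* the observed one count as
extreme (a better fit). `permanova()` computes the one-factor pseudo-F
from within- and between-group sums of squared distances and permutes raw
labels; when the number of distinct assignments `choose(n, n1)` is at most
10,000 it enumerates all of them and reports an exact p with the
enumeration count. Both agree with their vegan counterparts (`protest`,
`adonis2`) to numerical precision in the test suite.

`alphaGlm()` is a Gaussian linear model: diversity indices are continuous
and roughly symmetric at these sample sizes, and with a single binary
factor the p-value reduces to the pooled t-test (a tested identity).
Covariates are passed through; perfectly collinear designs are rejected
rather than silently dropped.

## Co-abundance networks

`hurdleEncode()` represents a rank-aggregated count table as binary
incidence plus CLR-on-nonzero abundances (zeros carried as missing).
`estimateNetwork()` regresses each taxon's two hurdle columns on all other
taxa's columns with L1 penalties, takes the union of selected neighbours
over both responses, symmetrizes by the OR rule and weights each edge by
the Spearman partial correlation of the pair's abundance ranks (zeros tied
at the minimum) given their selected neighbours. This is a deliberately
simple, fully specified surrogate for graphical hurdle-model estimators:
it shares their I/O contract and encoding but not their joint likelihood.

Two numerical choices matter here. First, penalty selection uses the
*relaxed* extended BIC: each support along the glmnet path is re-fit by
OLS before scoring with $n\log(\mathrm{RSS}/n) + |S|(\log n + 2\gamma\log
P)$, γ = 0.5, so lasso shrinkage does not distort the likelihood term.
Second, CLR-encoded designs obey an exact per-sample zero-sum constraint,
which makes regressions using (almost) every other taxon's abundance
column fit spuriously well; supports containing more than half of the
available abundance columns are therefore excluded from the search. A
consequence of the same constraint is that, at small taxon numbers, the
latent-space partial-correlation structure of a compositional count table
is not identifiable from CLR data; recovery benchmarks therefore plant the
ground-truth graph in the encoded space itself (`rHurdleNetwork()`
generates the hurdle design directly from a sparse-precision Gaussian with
a Bernoulli occurrence layer), which is how hurdle-model network
estimators are conventionally benchmarked. Stability selection (edge
frequency ≥ 0.9 over 50 half-sample refits) is available as the
alternative selection rule. The default rank is phylum; with few nodes
and hundreds of samples both rules are comfortable, and a warning is
raised when n < 3p.

## LEfSe-style differential abundance

`cladeAbundance()` sums leaf relative abundances (per sample, ×10⁶) over
every clade at all seven ranks. `lefseTwoClass()` screens each clade with
Kruskal–Wallis at α = 0.05, then estimates over 30 bootstrap rounds (2/3
stratified subsampling) a ridge-regularized two-class linear discriminant
on the survivors; a clade's effect size averages its raw between-class
mean difference with its share of the class separation along the
discriminant, and the LDA score is log10 of the bootstrap-averaged effect
on the ppm scale, thresholded at 2. Only the two-class, no-subclass case
is implemented — all exposures here are binary — so the subclass Wilcoxon
stage of the original procedure is skipped by construction, not silently.

One property of clade-summed *relative* abundances deserves emphasis: a
multiplicative shift planted on one clade necessarily changes every other
clade's relative abundance through compositional closure. On planted-shift
benchmarks the shifted clade and its ancestors dominate the ranking (a
tested property), but correctly signed secondary hits among unshifted
clades are genuine features of relative-abundance data, not false
positives of the implementation.

## What the synthetic data do and do not show

The generators emulate exact cohort marginals, Dirichlet-multinomial
compositional noise, responder-style and shared-depletion dysbiosis,
sparse log-normal FFQ intakes and a controllable diet–microbiome
coupling. They do not emulate sequencing error, chimeras or OTU-picking
artifacts, longitudinal drift, taxon-taxon ecological interactions in the
null model, or realistic nutrient correlation structure in the
composition matrix. Green recovery tests therefore demonstrate that the
estimators detect the planted signal classes at realistic sizes — not
that real cohorts contain such signals, nor that effect sizes transfer.

## Problem sizes used by the shipped checks

The test suite runs the AKP/PERMANOVA/PROTEST null calibrations at 100
replicates (40–24 samples each, 99 permutations), direction-recovery at
50 replicates of 150 subjects per group at depth 10⁴, coupling power at
50 replicates of 115 dietary subjects, network recovery on the 10-node
chain at n = 200, and differential-abundance recovery over 20 seeds of 60
subjects. These sizes give the binomial recovery bounds (≥ 90% of
replicates) enough resolution while keeping a full run of the suite at
about a minute and a half on one core.

## Known limitations

* The rank-sum AKP p-values inherit the non-independence of pairwise
  similarities; use the permutation companion for calibrated inference.
* The network estimator is a surrogate: its edge sets are not claimed to
  reproduce graphical-hurdle-model fits edge for edge, and hyperparameters
  of published real-data networks are not reproduced.
* C-indexes are computed at whatever taxon level the input table carries
  (OTU by default); the choice of level changes absolute C values, though
  the exposed/non-exposed contrast is typically stable.
* Chao1 on discretized intakes depends on the discretization scale; 1 g
  is a convention, not an estimate.
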