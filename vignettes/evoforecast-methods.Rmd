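---
title: "Models and methods behind evoforecast"
author: "evoforecast authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind evoforecast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoforecast)
```

## The problem

Adaptive laboratory evolution (ALE) experiments evolve microbial populations
under a defined culture condition and resequence the evolved clones. Pooled
over many published experiments, the fixed mutations form a *compendium*:
per evolved replicate, a set of mutation events at named genome sites (genes,
or intergenic regions written `flankA-flankB`), together with metadata about
the condition — strain, medium, stress set and evolution duration.
`evoforecast` implements the analysis stack that such a compendium supports:

1. where on the genome mutations concentrate (hotspots and depletion spots),
2. which mutations co-occur across conditions,
3. how convergent replicate evolution is, as a function of replicate number,
4. whether the mutated gene set of a *novel* condition can be predicted from
   the compendium.

## Data model and conventions

A `compendium` is three tables: conditions, replicates (with hypermutator
flags) and mutation events, plus a derived site index. Conventions that the
rest of the package relies on:

* **Site names.** Gene aliases are rewritten to canonical names via the
  annotation's synonym map. Intergenic sites are the two flanking genes
  joined by a dash, ordered by genome coordinate (the dash notation itself
  carries no orientation). Insertion-sequence involvement is tagged with a
  `::` suffix (`pykF::IS5`), which makes a tagged site distinct from its
  untagged gene. Normalization is idempotent.
* **Deletion spans.** Deletions reported only by their two flanks are
  expanded to every gene between them (inclusive), looked up in the
  annotation.
* **Coordinates.** 1-based inclusive, as in GFF3. Window arithmetic converts
  internally.
* **Duration bins.** Generations are one-hot encoded into seven
  left-exclusive, right-inclusive intervals from (0,500] to (30000,40000].
  Durations above 40,000 generations are rejected rather than binned — the
  encoding has no bucket for them, and silently clamping would alias very
  long experiments onto shorter ones.
* **Condition encoding.** A condition is one strain bit, one medium bit,
  multi-hot stress bits, one duration bit, over a data-driven vocabulary
  (the curated compendium this design mirrors had 83 attributes; the
  vocabulary here is whatever the condition table contains).
* **Binary profiles.** All analyses treat mutation presence per site as
  binary: a SNP in one replicate and a deletion in another set the same bit,
  and amplifications/inversions count like any other event type.
* **Replicates without events.** The exchange format (events.tsv +
  conditions.tsv) enumerates replicates implicitly through events and
  hypermutator flags, so a replicate with neither is not representable.
  Sequencing-derived mutation tables share this property; the generator's
  parameter ranges make all-empty replicates vanishingly rare.

## Hotspot significance

The null hypothesis is that, absent selection, mutations land anywhere on
the genome with probability proportional to target length. Each evolution
run `r` mutated `m_r` distinct sites; a null world redraws, for every run,
`m_r` distinct sites without replacement with length-proportional weights
(a weighted, hypergeometric-like draw; with equal lengths the per-run hit
indicator reduces to the binomial case). The p-value of a site observed in
`k` runs is the Monte-Carlo exceedance probability

\[ p = \frac{1 + \#\{\text{worlds with} \ge k \text{ hits}\}}{1 + n_{\text{samples}}} , \]

with add-one smoothing so `p` is never exactly zero, and a reported
Monte-Carlo standard error. The sampler is written in C++ (one pass scores
every site simultaneously) and driven by R's RNG, so results are seeded.
The tests compare it against an independent exact oracle (enumerated
inclusion probabilities combined through a Poisson-binomial tail) on all
instances small enough to enumerate, and check type-I calibration on a
structure-free generated compendium (200 genes, 50 runs, 20,000 samples:
the fraction of genes at p < 0.05 must stay inside the 99% binomial band
around 0.05).

Intergenic sites take the inter-flank interval as their length; IS-tagged
sites take their gene's length. Both enter the null universe as separate
sites — a deliberate simplification that slightly enlarges the universe.

The 5-kb window scan counts positioned events per non-overlapping window
(overlapping windows are available but excluded from distribution fitting,
since overlapping counts are not a sample). A gamma distribution is fitted
by maximum likelihood (`MASS::fitdistr`); zero-count windows get a 0.5
pseudo-count *for the fit only*, because the gamma MLE is undefined at
zeros. Hotspot windows are the top 5% by raw count — the fit provides the
plotted significance line, not the calls. Depletion windows are those never
hit. `top_share(fraction)` summarizes the heavy tail of per-site counts
(share of all events carried by the top 0.5% of sites, by default).

## Co-occurrence

Runs sharing strain, medium and stress set are merged into one binary
profile per unique combination. Pairwise association between sites is
plug-in mutual information (base 2) over the 2×2 empirical joint across
profiles; sites mutated under fewer than two conditions are excluded first
(their MI is dominated by the single observation). The spectral clustering
pipeline is fixed for reproducibility: the MI matrix is used as a similarity
graph (diagonal removed), normalized symmetrically as
`D^{-1/2} A D^{-1/2}`, the `k` leading eigenvectors are row-normalized and
clustered by seeded k-means; clusters are reported in decreasing order of
mean within-cluster MI. `k` is a hyperparameter with no privileged value (the default of 19 matches
the setting used in the compendium analyses this design follows), and the
choice of log base affects scale only, not clustering.

Stresses are clustered per strain+medium group by Euclidean distance between
merged stress profiles with Ward's `ward.D2` criterion (`stats::hclust`),
and dendrograms are serialized to Newick via `ape`.

## Convergence laws

For a condition with replicate site sets \(A_1,\dots,A_N\) and union \(U\):

* averaged frequency \(F\): mean over distinct mutations of the fraction of
  replicates carrying each;
* global overlap \(G\): mean over replicates of \(|A_i|/|U|\);
* pairwise overlap \(P\): mean Jaccard index over unordered replicate pairs.

\(F\) and \(G\) are algebraically identical — both equal
\(\sum_i |A_i| / (N|U|)\) — which is why their fitted laws against \(1/N\)
come out nearly the same on real compendia; both are kept because they are
operationally different definitions and reporting both makes the identity
visible. "Percentage of shared mutations between two clones" does not pin
down a denominator; Jaccard was chosen for \(P\) because it is symmetric and
bounded, and the alternative (mean-size normalization) is a one-line change.
Conventions for degenerate input: an empty replicate contributes 0 to
\(G\); a pair of empty replicates counts as identical (Jaccard 1, with a
message); a single replicate has \(F = G = 1\) and undefined \(P\).

Conditions sharing a replicate count `N` are averaged into one point before
ordinary least squares of \(F\) (and \(G\)) on \(1/N\) — grouping first
keeps heavily replicated designs from dominating the fit. Under pure
contingency (every mutation private to one replicate) \(F = 1/N\) exactly,
so the fit must recover slope 1 and intercept 0 to machine precision; a
positive intercept measures the shared, deterministic component. \(P\) is
summarized per `N` with a linear trend against `N` — a near-zero slope says
pair-level convergence does not depend on how many replicates were run.

Hypermutators are classified by fixation rate strictly above 0.1 mutations
per genome per generation. Mutation accumulation is fitted either linearly
(free intercept) or exponentially (log-linear least squares on positive
counts, R² always computed on the original count scale, so the two models
are comparable).

Group comparisons (e.g. antibiotic vs no stress on pairwise overlap, or the
DNA-maintenance-gene fraction between replicates above/below the mean
fixation rate) use a two-sided Mann-Whitney test by default — the
distributions are bounded and skewed, so a rank test is the safe default —
with Welch's t available.

## The ensemble predictor

For every genome site mutated under more than two merged conditions
(threshold configurable), a dataset is built: rows are merged conditions
encoded as binary attribute vectors, the label is presence of the site in
the merged profile. Three component models are trained:

* **Bernoulli naive Bayes** with Laplace smoothing
  \((\text{count} + \alpha)/(n_{\text{class}} + 2\alpha)\), so no estimated
  parameter and no predictive probability is ever exactly 0 or 1;
* **RBF-kernel SVM** (`e1071::svm`) grid-searched over
  c ∈ {0.001, 0.01, 0.1, 1, 10} and kernel width σ ∈ {0.001, 0.01, 0.1, 1},
  selected by inner stratified 3-fold AUC with ties resolved in grid order;
  probabilities come from a Platt-style logistic calibration of the decision
  values (which also fixes the decision-value sign convention);
* **feedforward neural network**, two tanh hidden layers of 57 and 37
  units by default, sigmoid output, cross-entropy loss, full-batch Adam at
  learning rate 0.01, inverted dropout 0.4 on hidden activations. No
  installed R package provides multi-hidden-layer nets with dropout and
  Adam, so the network is implemented in the package (~100 lines of matrix
  code) and is fully seeded: identical seeds give bit-identical weights.
  An optional random architecture search (`tune_ann`) samples layer/width
  configurations under a small budget.

The ensemble probability is the plain average of the three components —
an invariant tested to machine precision. Class imbalance is handled by
duplicating minority rows to parity (seeded); fancier resampling schemes
were deliberately left out. Backward wrapper feature selection starts from
all attributes and greedily removes the feature whose removal best improves
(or at worst preserves) inner cross-validated AUC, stopping when every
removal hurts; ties break toward the lowest feature index and the subset
never empties. By default the wrapper is scored with the naive Bayes
component (the cheapest by orders of magnitude) and the subset is shared by
all three components; per-component selection is a flag
(`fs_per_component`). The selection protocol inside folds was an open
design point; stratified 3-fold AUC is used everywhere an inner estimate is
needed.

Evaluation is leave-one-condition-out: one fold per merged condition, with
oversampling and feature selection redone inside every fold, pooled ROC and
precision-recall curves over the held-out predictions. The baseline ranks
each held-out condition by the site's training-fold frequency. Within a
single site this baseline is intentionally weak — leaving out a positive
condition lowers the training frequency, so the baseline actually
anti-ranks — which is exactly why frequency alone is not a predictor and an
honest floor for the comparison.

Forward validation is bootstrapped: each round resamples merged conditions
with replacement, retrains every eligible site model, and predicts the site
set of a novel condition (probability > 0.5 by default; the threshold is a
parameter because no principled value exists). Precision and recall per
round are reported as mean ± SD; rounds that predict nothing have undefined
precision and are excluded from the mean (and counted). A site is "called"
when predicted in more than 5 of 10 rounds, reproducing the published
call-marking convention.

## The synthetic-data generator

The generator is first-class, tested code: it is the package's source of
data with known truth. Its model per condition: a shared core of `S` genes,
each fixing independently with probability `q` in every replicate (the
deterministic component); a Poisson(λ·g) number of background mutations per
replicate, assigned to genes with length-proportional probability (the
contingent component — and exactly the null of the hotspot statistic, so
calibration tests are true type-I checks); optional planted
attribute-to-gene associations with their own fixation probabilities;
a hypermutator subpopulation with a multiplied rate and background weights
biased toward a designated DNA-maintenance gene set; mutation types drawn
from the empirical mixture (SNP 0.57, deletion 0.26, insertion 0.09,
amplification 0.08, inversion ≈ 0) and positions uniform within the gene.

Defaults mirror the curated compendium the design follows: 178 conditions,
replicate counts 1-115 with mean ≈ 3, background rate λ = 0.0068 mutations
per genome per generation, ~6% hypermutators at 40× (clearing the 0.1
classification threshold by construction), 4,000 genes covering 86% of a
4.64-Mb genome. Tests and the acceptance script state smaller problem sizes
explicitly (e.g. 200 genes / 50 runs for hotspot calibration, 100
conditions for predictor recovery, 50 conditions × N ∈ {2..50} for the
convergence law) — chosen as the sizes at which the tested quantities
concentrate, and stated in each test.

What the generator does *not* emulate: clonal interference and selection
coefficients, linkage between sites, sequence-level mutation spectra,
condition-correlated gene lengths, or curation noise (misreported
coordinates, heterogeneous naming). Passing recovery tests therefore
demonstrates correctness of the estimators under the stated model, not that
real compendia satisfy the model.

### The analytic convergence-law expectation

For recovery tests the generator ships the model-implied expectation of
\(F\). Within one condition with core probabilities \(q_1..q_S\) and
background mean \(b\) per replicate: core gene \(i\) appears in
\(C_i \sim \mathrm{Bin}(N, q_i)\) replicates; background mutations are
singletons, \(B \sim \mathrm{Pois}(Nb)\) of them in total. Then
\(F = (T_c + B) / (N (D_c + B))\) with \(T_c = \sum C_i\) and
\(D_c = \#\{C_i > 0\}\). The joint law of \((T_c, D_c)\) is enumerated by
dynamic programming (convolving genes one at a time), and the background is
integrated with a truncated Poisson sum using
\(\mathbb E[(t+B)/(d+B)] = 1 + (t-d)\,\mathbb E[1/(d+B)]\); conditions with
no mutation at all are excluded, matching the estimator. Because ordinary
least squares is linear in the per-`N` means, the expected fitted intercept
equals the intercept fitted to the expected values — so the recovery test
compares like with like. The formula assumes background mutations do not
collide on a gene; the law-test parameters (3,000 genes, b ≈ 3.4) keep the
collision bias well under the ±0.01 tolerance. The formula itself is
cross-checked in the tests against a brute-force simulation of the reduced
model.

## Numerical choices and degenerate inputs

* Monte-Carlo p-values: add-one smoothing, floor \(1/(n+1)\); `k = 0` gives
  p = 1 identically.
* Gamma window fit: 0.5 pseudo-count on zero windows, fit refused below 10
  windows.
* MI: `0·log 0 = 0`; values clipped at 0 against rounding noise; diagonal
  holds marginal entropies.
* Spectral embedding: zero-degree nodes keep zero rows; `k` equal to the
  number of sites short-circuits to singleton clusters (k-means cannot
  split ties).
* `rank_pairs` breaks ties lexicographically; k-means uses a seeded init
  with 25 restarts.
* Exponential fixation fits drop zero counts (log undefined) but score R²
  on all points.
* Identical-empty replicate pairs score Jaccard 1 (logged); empty
  replicates contribute 0 to G.
* Every stochastic routine takes a seed and restores the caller's RNG
  state.

## Known limitations

* The tabular format cannot express an event-free, unflagged replicate.
* MC p-values for many sites share null worlds, so they are correlated
  across sites (each is individually unbiased).
* SVM probability calibration is fitted on training decision values; with
  tiny or separable training sets the calibrated probabilities saturate.
* The per-site LOCO baseline is a weak (anti-ranking) floor by
  construction; cross-site baselines would require pooling across sites,
  which the per-site evaluation deliberately avoids.
* The forward-validation bootstrap resamples merged conditions, not
  replicates, consistent with training on merged profiles; replicate-level
  uncertainty is not propagated.
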