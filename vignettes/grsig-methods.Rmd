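---
title: "Methods: joint signature and growth-rate analysis of drug screens"
author: "grsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint signature and growth-rate analysis of drug screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsig)
```

# The problem

Large perturbational screens expose panels of cell lines to drug panels
across a dose series and read out the response two ways: molecularly,
with the L1000 landmark assay (978 directly measured transcripts per
well, quantile-normalized "level 3" profiles in GCT 1.3 files), and
phenotypically, by counting viable cells. The two readouts answer
different questions — *what program did the cells engage* versus *did
they stop growing* — and disagree often enough that their joint analysis
is informative: conditions with a strong, reproducible transcriptional
response but no growth effect flag adaptive resistance and suggest
combination therapies.

`grsig` implements the full desk-side pipeline: differential-expression
signatures per perturbation, an empirical-null consistency score,
consensus fuzzy clustering and signature networks, growth-rate (GR)
metrics, a four-class molecular-by-phenotypic response taxonomy, and
excess-over-Bliss synergy scoring, together with a synthetic-data
generator that provides planted ground truth for every stage.

# Molecular arm

## Characteristic directions

Expression wells are grouped into *batches*: all experimental conditions
for one cell line at one time point, measured on `J` replicate plates
(replicate `j` of every condition sits on plate `j`), each plate carrying
`N` vehicle-control (DMSO) wells. For a treated profile \(x\) and the
same-plate control matrix \(C\) the per-replicate signature is the
regularized discriminant direction

\[
  D = \frac{\hat\Sigma^{-1}(x - \bar C)}{\lVert \hat\Sigma^{-1}(x - \bar C) \rVert},
  \qquad
  \hat\Sigma = (1-\gamma)\,S + \gamma\,\nu I + \lambda I ,
\]

with \(S\) the control sample covariance, \(\nu = \mathrm{tr}(S)/G\),
shrinkage \(\gamma \in [0,1]\) (default 0.5) and a small ridge
\(\lambda\) (default `1e-8`). Because the treated "group" has size one,
only the control covariance is estimable; with `N` far below `G = 978`
the raw \(S\) is rank-deficient, hence the shrinkage toward a scaled
identity. At \(\gamma = 1\) the estimator reduces exactly to the
normalized mean-difference vector, which (together with a small-`G`
brute-force inverse) is the oracle the tests pin it against. Discriminant
directions are sign-ambiguous; we fix the sign so the direction has
non-negative projection on the raw difference. Comparing each replicate
only to *its own plate's* controls removes additive plate effects by
construction.

The condition signature is the unit-normalized mean of its per-replicate
directions; the pre-normalization magnitude (`amplitude`, in \([0,1]\))
measures replicate agreement and, on signal, grows with dose.

## Signature Consistency Score

Replicate agreement is scored against what "agreement" looks like among
unrelated perturbations of the same batch. The observed statistic is the
mean pairwise cosine distance \(S_i\) of a condition's `J` replicate
directions. The null draws `J` directions from the batch's pool of all
\(M \cdot J\) replicate directions, records their mean pairwise cosine
distance, and repeats (default 10,000 draws). Then

\[
  p = \frac{1 + \#\{S_n \le S_i\}}{n_{\mathrm{null}} + 1},
  \qquad \mathrm{SCS} = -\log_{10} p .
\]

The add-one pseudo-count keeps the score finite when the condition beats
every draw, which also caps SCS at \(\log_{10}(n_{\mathrm{null}}+1)\) —
the reason observed scores saturate (about 4.0 at 10,000 draws). Ties
count toward the null. `SCS > 1.3` is exactly the 5% one-tail filter.

**Plate-stratified null draws.** Directions computed against the same
plate's controls share the control-mean estimate and are therefore
slightly positively correlated (expected cosine roughly \(1/(N+1)\)).
A draw that ignores plates mixes such same-plate pairs into the null,
shifting it left relative to true replicate sets (which occupy one plate
each); the score then loses calibration — on null data essentially
nothing reaches SCS > 1.3. Each null draw here therefore picks `J`
distinct plates and one direction from each, reproducing the replicate
structure and making observed and null dispersions exchangeable under
the null hypothesis. With this choice the empirical false-positive rate
of the `SCS > 1.3` filter on signal-free simulations is 0.04 at 504
conditions (the acceptance suite asserts 0.05 ± 0.015). The
unconstrained draw remains available in `build_null()` by omitting
`strata`.

The condition's own replicates stay in the pool; the resulting bias is
\(O(J/(MJ))\) and negligible for screens of this size.

## Clustering and networks

Signatures passing the consistency filter are clustered with fuzzy
c-means on unit-normalized vectors; for unit vectors squared Euclidean
distance is twice cosine distance, so the FCM objective ordering is the
cosine one without a bespoke distance. Parameters follow the method's
published settings: fuzzifier 1.22 (near-crisp memberships), `k = 20`
clusters at screen scale, membership cutoff 0.55, and 101 independent
runs. Cluster labels are arbitrary per run, so each run's centroids are
aligned to run 1 by greedy maximum-cosine matching and each condition is
assigned to the cluster it lands in most often among runs where its
aligned membership clears the cutoff; conditions that never clear it
stay unassigned, and ties go to the cluster with the higher mean
membership. Reported soft memberships come from the run with the median
objective. The consensus matters: on a planted eight-group benchmark,
single runs reach ARI 0.63–0.86 against ground truth while the 101-run
consensus reaches 1.0.

*A caveat found during validation:* when `k` exceeds the number of
well-separated planted groups, surplus centroids split large groups
differently in every run; greedy alignment then has no stable identity
for them and consensus votes scramble into mixed clusters. On real
screens the groups are diffuse enough that moderate changes of `k`
merely coarsen or refine the grouping; in the idealized generator the
stability-across-`k` claim holds only at the planted `k`, and the tests
assert it there.

Signature networks connect conditions whose cosine distance falls at or
below an empirical percentile of all pairwise distances (linear
interpolation; ties included): the 2nd percentile for a whole-screen
network, the 5th for single-cell-line networks. Cluster composition is
tested per (cluster, category) with a one-sided binomial test against
the category's global frequency, and each cluster is summarized by its
*consensus signature*, the plain average of member signatures (not
re-normalized, so its magnitude reflects member agreement).

# Phenotypic arm

Viable-cell counts are converted to growth-rate inhibition

\[
  \mathrm{GR}(c) =
  2^{\log_2(x(c)/x_0)\,/\,\log_2(x_{\mathrm{ctrl}}/x_0)} - 1,
\]

with \(x_{\mathrm{ctrl}}\) the mean same-plate vehicle count and
\(x_0\) the 50%-trimmed mean (a quarter discarded from each end) of a
day-0 untreated plate. GR equals 1 under untreated growth, 0 at complete
cytostasis, and is negative for cytotoxic responses; it is invariant to
common count rescaling and to division rate. Technical plate replicates
are averaged after the GR computation. Dose series are summarized by
`GR_AOC`, the mean of \(1-\mathrm{GR}\) over tested doses — for the
uniform 3.33-fold dilution design this coincides with trapezoidal
integration over log-dose; for irregular grids it would not. A sigmoid
\( \mathrm{GR}(c) = \mathrm{GR}_\infty + (1-\mathrm{GR}_\infty)/(1 +
(c/\mathrm{GEC}_{50})^{h}) \) is fitted by bounded multi-start least
squares (GEC50 started at every tested dose, hill at 1 and 2); the fit
is kept only if it beats a flat line by an F-test at \(\alpha = 0.05\),
otherwise the flat fit is reported with a flag. GR_50/GR_max are
descriptive outputs of the fit, not acceptance surfaces.

# Response classes and synergy

Each perturbation is placed in the (GR, SCS) plane with GR at the
matched concentration from the 72 h counts and SCS from the 24 h
expression batch (exact concentration match; unmatched conditions are
skipped with a warning). Quadrants at GR = 0.66 and SCS = 1.3: **I**
non-responsive by both measures, **II** responsive by both, **III**
growth response without a consistent signature, **IV** consistent
signature without growth response. Values exactly at a cutoff fall on
the non-responsive side, generalizing the strict `SCS > 1.3` filter.

Combinations are scored on the \(1-\mathrm{GR}\) effect scale against
Bliss independence:

\[
  \mathrm{EOB}_{\mathrm{GR}} = (1-\mathrm{GR}_{AB})
    - (1-\mathrm{GR}_A) - (1-\mathrm{GR}_B)
    + (1-\mathrm{GR}_A)(1-\mathrm{GR}_B),
\]

which is exactly observed-minus-predicted effect, zero at independence,
positive for synergy. GR values above 1 are used as-is (the effect scale
goes negative). Checkerboards take single-agent values from their own
margins; per dose pair, per-replicate EOB values are tested against zero
with a two-sided one-sample t-test (the minimal reading of a published
"mean ± SE, t-test" report), with a zero-variance flag when replicates
are degenerate.

# The synthetic world

`simulation_config()` encodes the screen design the pipeline assumes:
978 genes, 6 cell lines, ~100 drugs in 10 target classes, six doses in
3.33-fold dilutions from 10 µM (243-fold, the "~250-fold" design),
expression at 3 and 24 h on `J = 3` plates with `N = 8` controls each,
counts at day 0 and 72 h.

Choices the assays only constrain loosely, fixed once and documented:

* **Expression noise**: additive Gaussian per gene, SD 0.5 on a baseline
  of mean 6, SD 1 per (gene, line) — level-3 data are continuous and
  roughly homoscedastic after quantile normalization. The magnitude is
  arbitrary (the source study reports none); it is chosen so the
  signal-free calibration invariant is informative rather than trivial.
* **Plate effects**: one additive scalar per plate (SD 1), removed
  implicitly by same-plate control comparison.
* **Dose–amplitude link**: \(a(c) = E \cdot s \cdot c/(c + K)\) with
  `K = 1 µM`; amplitudes rise monotonically and saturate. Default
  effect size `E = 5` puts top-dose amplitudes at ~10× per-gene noise,
  which makes mid-dose conditions straddle the SCS filter — the
  realistic regime (the source screen kept 37% of pairs).
* **Universal vs specific classes**: a `shared_fraction` (default 0.5)
  of classes shares one direction per time point across lines; the rest
  get one direction per line *and* a per-(drug, line) sensitivity factor
  drawn from `[0.1, 1.9]`. The floor near zero is deliberate: the
  pattern being emulated is signaling-kinase inhibitors whose clusters
  are dominated by one or two lines, i.e. some lines barely respond.
  This heterogeneity is what makes the cross-line CV of SCS larger for
  specific classes — with a narrow range all lines saturate the score
  and the contrast disappears.
* **Rotation classes** emulate RTK/ECM inhibitors: the planted direction
  interpolates between two orthogonal endpoints along the dose series,
  so high doses differ in angle, not just amplitude.
* **Counts**: vehicle wells grow exponentially from a day-0 count of
  1000 at a doubling time drawn once per line from 24–48 h (typical for
  breast cancer lines); treated counts invert the planted GR sigmoid
  exactly and then receive multiplicative log-normal noise (SD 0.05).
  Combination grids satisfy Bliss independence exactly before noise,
  with a planted constant (or dose-bump-shaped) excess added in the
  synergistic/antagonistic modes.

What a green test does **not** establish: the generator has no
count-depth noise floor, no edge effects or spatial plate gradients, no
drug polypharmacology (one direction per class, not per compound), no
transcriptional-phenotypic coupling (GR curves are drawn independently
of expression effects unless planted), and real L1000 level-3 noise is
neither Gaussian nor independent across genes. Results on it validate
the machinery and its calibration, not biological effect sizes.

# Numerical choices

* Unit-norm tolerance 1e-9 for signatures; degenerate inputs (treated
  equal to control mean, replicates that cancel, zero vectors) raise
  typed errors rather than propagating NaNs.
* The shrunk control covariance is Cholesky-factorized once per plate
  and reused by all conditions on that plate.
* Percentiles use type-7 linear interpolation; ties at the network
  threshold are included as edges.
* FCM: convergence when the membership matrix changes by less than 1e-6
  (max 300 iterations); zero distances are clamped at 1e-12, which
  splits membership evenly among coincident centroids (so fully
  degenerate inputs end up unassigned under the 0.55 cutoff).
* The empirical p-value is add-one on both numerator and denominator;
  ties count toward the null (conservative).
* Master seeds derive per-component child seeds below 2^31; generators
  save and restore the caller's RNG state.

# Known limitations

* The characteristic-direction shrinkage recipe is this package's
  explicit choice (\(\gamma\) configurable, default 0.5); numerical
  equivalence with other published implementations is not claimed —
  the tested guarantees are the \(\gamma = 1\) closed form and the
  brute-force oracle.
* SCS saturates at the pseudo-count ceiling, so very consistent
  conditions are indistinguishable beyond \(\log_{10}(n_{\mathrm{null}}+1)\).
* Consensus assignment degrades when `k` far exceeds the number of
  genuinely distinct response programs (see the clustering caveat).
* `GR_AOC` as a plain mean assumes a uniform log-dose design.
* The cross-assay pairing requires exact concentration matches and does
  not interpolate between dose grids.
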