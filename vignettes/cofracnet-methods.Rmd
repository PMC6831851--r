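---
title: "Inferring and comparing interactomes from co-fractionation MS profiles"
author: "cofracnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and comparing interactomes from co-fractionation MS profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Co-fractionation mass spectrometry (CF-MS, also called biochemical
fractionation/MS) separates a native protein extract — for example a
mitochondrial extract from cultured cells — over a chromatographic gradient
and measures peptide counts for every protein in every collected fraction.
Subunits of the same stable complex co-elute, so the similarity of two
proteins' elution profiles carries evidence about their physical
association. Combining two orthogonal separations (size exclusion, SEC,
which sorts by assembly mass, and ion exchange, IEC, which sorts by surface
charge) sharpens that evidence considerably: unrelated proteins rarely
co-elute on both axes.

`cofracnet` implements the complete inference chain from
fraction-by-protein count matrices to condition-specific interaction
networks, a differential ("rewiring") network between two cell states,
predicted protein complexes, enrichment statistics, and phosphosite
filtering. A first-class synthetic-data generator plants known complexes,
rewiring events and phosphosites so every stage can be validated against a
known answer.

## Pair scoring

Counts below 2 distinct peptides per fraction are zeroed (single-peptide
identifications are unreliable), and proteins detected in fewer than 2
fractions are dropped — a one-fraction profile has no co-elution
information. For each separation technique, a pair is scored only if both
proteins survive this filter in **both** replicates of that technique, so
every score is backed by reproducible detections.

Three complementary similarity measures are computed per technique:

* **PCC** — Pearson correlation of the replicate-concatenated profiles;
  sensitive to overall shape agreement across all fractions.
* **WCC** — weighted cross-correlation:
  `max over |s| <= S of (1 - |s|/(S+1)) * cos(x, shift(y, s))`,
  the cosine similarity of the overlapping segments under an integer shift
  `s`, down-weighted with the size of the shift (default `S = 2`).
  Chromatographic peaks can be offset by a fraction or two between related
  species; WCC tolerates that where PCC does not. Negative values are
  floored at 0 (counts are non-negative, so this only matters for
  degenerate overlaps).
* **Co-apex** — the fraction of experiments in which both proteins attain
  their maximum count in the same fraction, among experiments where both
  are detected. Apex ties resolve to the earliest fraction; this matters
  for integer count matrices, which tie often.

Replicates are concatenated for PCC/WCC by default (an `"average"` mode is
provided); because co-detection in both replicates is already required,
concatenation simply treats replicates as additional fractions.

## Log-likelihood integration

Raw similarities are converted to a single log-likelihood score per pair by
binned naive Bayes against a reference complex catalog (a CORUM-like
table). Positives are catalog pairs sharing a complex; negatives are
catalog proteins that never share one. For each (technique, metric)
evidence source, scores of the labeled pairs are cut into equal-frequency
bins and each bin receives

```
LLS(bin) = ln[ ((pos_bin + c) / (neg_bin + c)) / (pos_total / neg_total) ]
```

with pseudocount `c = 1` keeping every bin finite. A pair's summed score
(sigma-LLS) adds the bin LLS of every evidence source it has; missing
evidence contributes 0.

Two numerical choices deserve emphasis:

* **Bin placement.** Bin edges are quantiles of the *positive* reference
  scores (default 10 bins). Positives are a percent or two of the labeled
  pairs; pooled quantiles would collapse essentially all of them into the
  single top bin per metric, quantizing sigma-LLS so coarsely that
  co-complex pairs and strongly co-eluting negatives become inseparable.
  Placing the resolution where the positive evidence lives avoids that
  while leaving the definition equal-frequency.
* **Monotonization.** Greater co-elution similarity cannot imply lower
  co-complex odds, so the bin table is monotonized by weighted isotonic
  regression (pool-adjacent-violators), which de-noises bins holding few
  reference pairs. `monotone = FALSE` disables it.

## Thresholding and validation

The ROC of sigma-LLS against the labeled reference pairs gives the AUC; the
network retains pairs with sigma-LLS strictly above a threshold. A fixed
stringent cutoff can be supplied (1.45 is the conventional value for this
assay family, i.e. associations at or below 1.45 are eliminated). When the
threshold is chosen automatically it maximizes the Youden index in its
prevalence-weighted (cost-sensitive) form, `J = se + r*sp - 1` with
`r = (1 - prev)/prev` at the empirical prevalence of the labeled pairs.
The classic equal-weight form (`weighted = FALSE`) is inappropriate here:
with negatives outnumbering positives by one to two orders of magnitude it
settles wherever sensitivity is maximal and admits hundreds of false edges
— the opposite of a stringent, high-confidence cutoff. The weighted form is
parameter-free (equal misclassification costs; prevalence measured from the
data) and accepts edges only while one additional true pair costs at most
about one false one.

Cross-validation is 5-fold and split at the **complex** level: all pairs of
a complex share a fold. Pair-level splits leak badly — two pairs from the
same complex are near-duplicates — and complex-level folds are the honest
unit of exchangeability. Held-out negatives are pairs of held-out-complex
proteins that never co-occur in the *full* catalog, so no test pair is
mislabeled by an unseen training complex.

## The differential network

For two states A (reference) and B, each pair gets `fc = sigma_B/sigma_A`
and `log2fc`. The DF edge universe is every pair retained in at least one
static network, but the per-state values come from the full scored tables:
a pair confidently present in B contributes its actual, possibly
sub-threshold, score in A. Pairs unscored (or scoring below the floor) in
one state take a positive floor; the default floor is the smallest
*positive* sigma-LLS observed in either state. (Log-likelihood sums can be
negative, so the raw minimum would be an invalid denominator; the smallest
positive score is the natural resolution and keeps every fold change
positive.)

Significance is a z-score of `log2fc` at the two-sided 5% normal critical
value, `|z| >= 1.96`. The null mean and standard deviation are estimated
from the **un-floored** edges (both states observed above the floor). This
matters: floored fold changes are bounded by `log2(max score / floor)`, and
when a realistic share of edges is floored the all-edge standard deviation
grows toward half that bound, at which point `|z| >= 1.96` can become
unsatisfiable for *every* edge — the gate must be calibrated on the null
(quantitatively comparable) part of the data. `null = "all"` restores the
naive behavior.

Rewiring classification gates on significance first: among significant
edges, `fc >= 2` is specific to state B and `fc <= 1/2` to state A.
Swapping the two states maps `fc` to `1/fc`, `z` to `-z` and exchanges the
labels, which the test suite checks as a property.

## Complex discovery

Three algorithms partition a weighted network (sigma-LLS edge weights).
Ties everywhere break by lexicographic node order, so all three are
deterministic.

* **Markov clustering** — the classical expand/inflate/prune iteration on
  the column-stochastic transition matrix with self-loops (inflation 2.0,
  expansion 2, prune `1e-5`); clusters are connected components of the
  limit matrix's support. On disjoint cliques this provably coincides with
  connected components, which the tests exploit as an oracle.
* **Cohesiveness growth** (ClusterONE-style) — greedy seed-and-grow
  maximizing `f(V) = w_in / (w_in + w_bound + penalty)`; grown sets with
  overlap score >= 0.8 merge; minimum size 2 (heterodimers are legitimate
  complexes in this assay).
* **Core-attachment** — unweighted-density cores grown greedily from the
  heaviest unused edges (density >= `core_density`, default 0.6), plus
  attachment proteins touching at least `attach_ratio` (default 0.5) of the
  core.

Predictions are matched to the reference catalog with the overlap score
`omega = |A∩B|^2/(|A||B|)`; `omega >= 0.25` counts as recovered. Algorithm
selection uses a hypergeometric test of each algorithm's recovered count
against the pooled predictions of all algorithms (ties: higher recovery
rate, then name), making the selection deterministic.

Interaction-profile correlation (Pearson over the two proteins' edge-weight
vectors, excluding self and the mutual edge, absent edges = 0) provides an
orthogonal check: subunits of the same complex share partners, so
within-complex pairs should out-correlate between-complex pairs under a
one-sided rank-sum test.

## Enrichment and phosphosites

All enrichment is the upper-tail hypergeometric probability `P(X >= k)`
(over-representation only; depletion is never tested here), with
Benjamini-Hochberg control across tested terms. Marker-based class
assignment gives each entity the minimum-p marker set when that p reaches
`1 - confidence` (default 95%).

The phosphosite filter retains a site in a state iff its localization
Ascore is at least 13 — the Ascore is `-10*log10` of the localization
p-value, so 13 is approximately 95% confidence — and the site was detected
in at least 2 of the state's 3 replicates *or* is a previously catalogued
site. The known-site flag is an input column: the pipeline stays offline by
design. Ascore filtering is applied per site (best spectrum), not per
spectrum. Retained sites are partitioned into state-specific and shared
sets and tallied per residue class (pS/pT/pY); the partition is exhaustive
and disjoint and the residue tallies always sum to the total, both enforced
as test properties.

## The synthetic-data generator

The generator emulates the study design this pipeline targets: two cell
states, SEC and IEC separations, duplicate replicates. Defaults: 50 planted
complexes with sizes uniform on 2-10, 200 monomeric background proteins,
20% of complexes rewired between the states, SEC = 80 and IEC = 95
fractions per replicate (per-technique fraction counts of this magnitude
are typical for deep fractionation designs totalling several hundred
fractions).

Each complex elutes as a shared discretized Gaussian peak (s.d. 2
fractions). SEC apexes follow decreasing summed member mass — large
assemblies elute first — with masses log-normal around 60 kDa; IEC apexes
are uniform random. Counts are Poisson around the peak intensity (expected
apex count 15 x a per-protein abundance multiplier of 1-5); `"exact"` mode
produces noise-free integer profiles in which within-complex pairs
correlate perfectly, the planted-signal sanity check. Whole-protein dropout
(probability 0.1 per protein per replicate) exercises the both-replicates
co-detection rule; 10% of complex members additionally elute as free
monomers. Rewiring swaps one member of each selected complex for a
background protein in the second state, and the truth object records
exactly the co-complex pairs present in one state only.

Chromatographic behavior is deliberately state-independent: apex positions
and monomer propensities are drawn per technique, keyed to complex names
and protein ids, because a protein's elution is its biochemistry. The
planted membership differences are therefore the only systematic
between-state signal, which is what the differential stage is supposed to
detect.

What the generator does **not** emulate: peptide-level identification and
protein inference, correlated (batch-like) noise between proteins,
abundance-dependent dropout, partial complex occupancy, overlapping
(moonlighting) complex membership, and chromatographic tailing. Passing the
recovery benchmark therefore demonstrates the statistical machinery is
sound on idealized-but-noisy profiles; it does not certify performance on
real extracts, where reference catalogs are also incomplete and biased.

## Reference benchmark and problem sizes

`run_simulation_benchmark()` runs the default study end to end (about 520
proteins, roughly 180,000 scored pair-technique records per state) and
measures: per-state and 5-fold cross-validated AUC against planted labels;
recall of planted co-complex pairs among the scored reference pairs and the
false-discovery rate against planted negatives at the chosen thresholds;
the fraction of planted rewired pairs receiving the correct
state-specific label plus a rank-sum enrichment p; and per-algorithm
complex recovery at `omega >= 0.25`. These sizes keep a full run around ten
seconds while leaving every statistic comfortably away from its
small-sample regime. All benchmark quantities are stochastic under the
seed; the test suite pins one seed, and `scripts/acceptance.R` recomputes
them for any seed.

## Known limitations

* The LLS integration assumes evidence sources are independent given the
  class (naive Bayes); PCC and WCC are in fact correlated, so sigma-LLS is
  optimistically scaled. Ranking, thresholding by ROC, and everything
  downstream are unaffected by a monotone rescaling.
* Negatives are defined catalog-internally (catalog proteins never sharing
  a complex). Incomplete catalogs mislabel some true pairs as negatives;
  on real data this biases AUC downward.
* The DF stage has no per-edge p-value; significance is purely the
  z-threshold rule on the null-calibrated distribution.
* `coapex` requires exact apex coincidence; under heavy count noise the
  apex of a flat peak jitters and the score dilutes. It remains a useful
  low-weight evidence source rather than a primary discriminator.
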