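---
title: "Reverse chemical ecology with orscreen: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse chemical ecology with orscreen: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(orscreen)
```

## The problem

Insect odorant receptors (ORs) can be screened *in silico* before any animal
is tested: a binary QSAR classifier trained on the receptor's known agonists
and non-agonists nominates new candidate agonists from a volatile library,
and only the nominations go to electrophysiology and behavior. `orscreen`
implements this modeling chain for small, imbalanced datasets of the kind OR
deorphanization produces — tens of compounds, a minority of them active —
together with the statistics used to validate predictions downstream.

The package works at the level of descriptor matrices. Chemistry enters only
at the front: SMILES are standardized (largest organic fragment, charge
neutralization, canonicalization) and featurized by a pluggable backend. The
bundled backends (a four-descriptor toy set and an OpenBabel physchem set)
are deliberately small; commercial descriptor engines compute hundreds of
descriptors and their exact outputs are not reproducible here, which is why
every modeling stage is tested against synthetic descriptor tables with a
planted structure–activity rule rather than against real descriptor values.

## The modeling chain and its assumptions

**Descriptor filtering.** Columns are removed in a fixed order: any missing
value, constant, near-constant (dominant value on more than 95% of rows or
SD below 1e-8), then a greedy left-to-right correlation scan that removes
the *later* column of any pair with |r| at or above the cutoff. The cutoff
is a per-receptor configuration value (0.90 and 0.95 are the conventional
presets). The greedy scan is order-dependent by design: it makes the
surviving set deterministic and reproducible, at the cost of not being the
globally minimal redundant set.

**Normalization.** Min–max scaling to [0, 1] fitted on training rows only.
External compounds may fall outside [0, 1] and are not clipped: detecting
extrapolation is the applicability domain's job, and clipping would silently
move queries toward the training manifold.

**Sphere-exclusion splitting.** The test set is grown by MinMax selection
(each new test compound maximizes its minimum distance to the current test
set) with an exclusion radius: every compound strictly within the radius of
a selected compound is removed from candidacy. Selection starts at the
compound nearest the dataset centroid (or a seeded random compound for the
alternative-split procedure) and stops at `floor(0.24 * N)` — the only
integer rule consistent with published test sizes of 12/51 and 19/83.
Excluded-but-unselected compounds go to training, so train and test always
partition the dataset. All ties break toward the lowest row index, making
the split deterministic. Exclusion uses a strict inequality, so two test
compounds exactly at the radius are legal and the pairwise test–test
distance invariant is `>= radius`.

**Model selection.** Candidates (kNN with k in {1,3,5,7,9} × uniform or
inverse-distance weights; 100-tree random forests with all-feature and
sqrt-feature splits; a CART tree; RBF SVCs at three costs) are ranked by
leave-one-out MCC on the training set. MCC is the right currency for
imbalanced agonist data: accuracy saturates when 80% of compounds are
inactive. Candidates whose LOO confusion matrix makes MCC undefined are
flagged and rank below every defined candidate rather than aborting the
loop. Ties go to the earlier candidate in the search space, so selection is
bit-for-bit reproducible under fixed seeds.

Score semantics are pinned per family: kNN reports the weighted
active-neighbour mass (inverse-distance weights are `1/(d + 1e-12)`, so an
exact structural match dominates its neighbourhood), forests report the
fraction of trees voting active, and the SVC reports a logistic transform of
its decision value — Platt-style probability fitting is internally
cross-validated and not deterministic, which disqualifies it here. The class
call is `active` iff score ≥ 0.5, ties to active: a screening tool prefers a
false candidate over a missed agonist.

**Applicability domain.** A similarity-distance domain: `Dc = <D> + Z*sigma`
where `<D>` and `sigma` are the mean and sample SD of each training
compound's distance to its single nearest neighbour, and Z climbs a ladder
(0.5 start, 0.5 steps — conventional in similarity-distance practice) until
every training compound's own kNN distance is within `Dc`. The phrase
"distance to the kNN" is ambiguous for k > 1; the package implements three
readings (`mean_knn` — the default, `kth_nn`, `nn`) as a configuration
switch and claims none of them as canonical. Reliability is
`1 + (D - Dc)/Dc = D/Dc`: 0 on a training point, 1 on the boundary, > 1
outside. The sample (n−1) SD is used because training sets are small and the
larger SD gives the more conservative (wider) cutoff at fixed Z.

**Screening and consensus.** Every library compound is reported with its
prediction, score, reliability and in-domain flag; the "predicted agonist"
gate (active AND in-domain) is a downstream filter, never a pre-filter, so
screens stay auditable. Consensus across screens intersects the gate after
applicability-domain gating — a compound outside one model's domain cannot
be a consensus agonist even if both models score it active.

**Bioassay statistics.** Single-sensillum responses are net firing rates
(stimulation minus spontaneous, negative = inhibition). Activity calls use a
global tie-corrected Kruskal–Wallis test plus per-odorant Wilcoxon rank-sum
comparisons against the solvent control with Holm step-down adjustment.
This is a documented substitution: the Dunnett-type nonparametric
multiple-contrast procedure of specialized packages is not re-derived, but
the inferential intent — each odorant versus solvent at familywise 0.05 —
is preserved and is what the calibration tests pin (familywise error ≤ 7%
on null panels). Choice assays use the chi-squared test for given
probabilities (0.5/0.5) on deciding animals only, and arm residence times a
paired two-sided t-test.

## The synthetic generator: what it emulates, what it does not

`gen_qsar_dataset()` plants a linear-separation rule: `n_informative`
descriptor columns shift their class means apart by `effect_size` within-
class standard deviations; all other columns are exchangeable noise; a
fraction of labels is flipped after generation to emulate assay error.
Defaults are `n_informative = 5`, `effect_size = 1.5`,
`label_flip_rate = 0.05`, `noise_sd = 1`. Every generator is a pure
function of its spec and seed.

The two shape presets mirror the published study shapes: `or24` (51
compounds, 10 actives, radius 4.8, correlation cutoff 0.90, AD k = 6, 288
descriptors) and `or25` (83/25, radius 4.0, cutoff 0.95, AD k = 9, 493
descriptors). The descriptor counts equal the surviving descriptor library
sizes of the corresponding published models. That choice is forced by
geometry, not taste: in [0,1]-normalized space the expected pairwise
Euclidean distance grows like `sqrt(0.08 * p)`, so exclusion radii of 4.8
and 4.0 are only meaningful near p ≈ 288 and 493 — at p = 100 the radius
would exceed almost every pairwise distance and the split would stall after
one or two test compounds. With the preset dimensionality both presets
reach their full 12- and 19-compound test sets.

What the generator does *not* emulate: correlated descriptor blocks (real
descriptor sets are heavily redundant before filtering), non-linear or
interaction-based activity rules, activity cliffs, and any actual
chemistry — synthetic compounds are descriptor vectors with surrogate ids.
Passing tests on synthetic data therefore demonstrate that the pipeline's
machinery is correct and well-calibrated, not that any particular receptor
model will generalize.

A consequence worth stating plainly: planting only 5 informative directions
among 493 noise dimensions, with 64 training compounds and a deliberately
diverse 19-compound test set, is a hard recovery problem. Euclidean kNN
degrades badly in that regime (distances concentrate), and even the forest
models sit near the edge of the recovery thresholds the acceptance tests
assert. The package reports whatever the runs produce; the thresholds were
not tuned to the observed outcomes, and the end-to-end recovery check is
the one place where the pipeline's performance under these study conditions
is allowed to fail visibly rather than being papered over with an easier
geometry.

## Numerical choices and degenerate inputs

* Tie-breaks everywhere are "lowest row index" / "earlier candidate":
  deterministic and documented, at the cost of a formal row-order
  dependence that only manifests on exact ties.
* `standardize_smiles()` is idempotent by construction (parse → largest
  organic fragment → neutralize → canonicalize); unparseable input errors
  with the offending string, it is never silently dropped.
* Metrics with zero denominators are flagged rather than thrown (MCC
  reported as 0 with a flag) so LOO loops can rank degenerate candidates.
* An all-identical training set yields `Dc = 0`; queries at distance 0 get
  reliability 0, any other distance is an error rather than an infinity.
* A radius larger than the data diameter produces a one-compound test set
  plus a warning record on the split object, not an exception.
* Leaving out the sole member of a class during LOO trains on single-class
  data; the reduced model predicts that class deterministically.

## Problem sizes used in the tests

The test suite runs the invariant sweeps at small sizes (200 random tables
of 10–24 compounds for the splitter; 50 tables for the applicability
domain; 500 instances for the AUROC oracle equivalence; 2000 replicates for
the choice-test calibration) and the end-to-end recovery at the full or25
shape over 20 seeds. These sizes were chosen to make the properties sharp
(the AUROC and reliability identities are asserted to 1e-9 and 1e-12) while
keeping a full run of suite plus acceptance script in the minutes range on
one core.

## A worked example

```{r example, eval = FALSE}
pre <- receptor_preset("or25", seed = 1)
run <- run_qsar_pipeline(pre)

run$split                 # 64 train / 19 test, radius 4.0
format(run$selection$best)           # winning candidate by LOO MCC
run$test_metrics$mcc                 # held-out MCC
run$enrichment$p_value               # planted actives among predicted agonists
head(run$hits)                       # ranked screening report
```

## Known limitations

* Descriptor backends are small open sets; models built on them are
  demonstrations of the machinery, not replacements for a full descriptor
  engine.
* No tautomer handling by default (a hook exists); stereoisomer duplicates
  are not de-duplicated.
* The Dunnett-type many-to-one procedure is approximated by Holm-adjusted
  rank-sum tests (slightly conservative).
* AUROC for published models cannot be recomputed from confusion counts —
  it needs per-compound scores — and is carried as documentation only.
* Cost-sensitive training and probability calibration are out of scope.
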