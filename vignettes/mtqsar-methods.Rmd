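---
title: "Multi-target QSAR modelling of drug-enzyme interactions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-target QSAR modelling of drug-enzyme interactions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtqsar)
```

## The modelling problem

Classical QSAR fits one model per biological target: activity of a compound
against a single enzyme is regressed on molecular descriptors computed from
the compound's structure. That framing cannot answer the question drug
discovery increasingly asks — *which of many enzyme families will this
compound touch?* — without training and maintaining one model per family.

The multi-target alternative implemented here encodes the *(compound,
target)* pair jointly. Every observation is a drug paired with an Enzyme
Commission (EC) subclass at two-level resolution (e.g. `1.1` alcohol
dehydrogenases, `2.7` phosphotransferases) plus a binary label: interacting
or non-interacting. One two-output classifier then serves all subclasses at
once, and a single prediction call scores a compound against every family in
the model.

## Moving-average features: MD, \<MD\> and DMD

The target-awareness comes from a Box–Jenkins-style moving-average
construction. Let $MD_j(x)$ be the value of topological descriptor $j$ for
drug $x$, and let

$$\langle MD_j \rangle_c = \frac{1}{n_c} \sum_{i \in c} MD_j(x_i)$$

be the arithmetic mean of that descriptor over the pairs of subclass $c$
(all training pairs of the subclass, interacting and non-interacting alike;
an actives-only variant is available via `build_class_profiles(...,
actives_only = TRUE)`). The deviation

$$DMD_j(x, c) = MD_j(x) - \langle MD_j \rangle_c$$

measures how far the drug sits from the subclass's descriptor profile. Each
(drug, subclass) pair is represented by the triple $(MD_j, \langle MD_j
\rangle_c, DMD_j)$ for every selected descriptor $j$ — 13 selected base
descriptors give the reference 39-input configuration. The class means act
as a learned coordinate system: the same drug produces different feature
vectors against different subclasses, which is what lets one network answer
many target questions.

Class profiles are computed from the **training partition only** and then
frozen for validation and prediction. Computing them on all data would leak
validation information into the features through the means; the
`scope` choice is therefore not configurable downstream of the split.

## The topological descriptor registry

Only topological (graph-based) descriptors are used; they are computed on
the hydrogen-suppressed heavy-atom skeleton parsed from SMILES (parsing and
aromatic perception are delegated to Open Babel through ChemmineR). The
registry is fixed and version-stamped (`topo-1.0`), with 17 entries:

| descriptor | definition |
|---|---|
| `heavy_atoms`, `bond_count` | counts on the heavy-atom graph |
| `ring_count` | cyclomatic number $m - n + 1$ |
| `wiener` | $\tfrac12 \sum_{i,j} d(i,j)$, bond-count shortest paths |
| `zagreb_m1`, `zagreb_m2` | $\sum_i \delta_i^2$ and $\sum_{(i,j) \in E} \delta_i \delta_j$ |
| `randic` | $\sum_{(i,j) \in E} (\delta_i \delta_j)^{-1/2}$ |
| `chi0`, `chi2` | Kier–Hall path indices of order 0 and 2 |
| `kappa1`–`kappa3` | Kier shape indices |
| `balaban_j` | distance-sum connectivity index |
| `eccentric_connectivity` | $\sum_i \delta_i \, \mathrm{ecc}(i)$ |
| `diameter`, `radius`, `petitjean` | eccentricity extremes and $(D - R)/R$ |

Conventions, chosen once and tested:

* The order-1 chi path index is identical to the Randić index, so it appears
  once (as `randic`); keeping both would plant a perfectly collinear column.
* Chi and kappa indices use the simple vertex degree (connectivity
  variants), not valence-corrected degrees — this keeps the brute-force
  oracles exact and the registry free of element-specific parameter tables.
* Multi-fragment molecules (dot-separated SMILES) are reduced to their
  largest fragment before any descriptor is computed, so distance-based
  descriptors never see an infinite distance. `distance_matrix()` itself
  marks cross-fragment pairs with `NA`, a declared sentinel rather than a
  numeric infinity that could leak into a sum.
* Degenerate cases take defined fill values: a single atom has Wiener 0,
  diameter/radius/Petitjean 0; `kappa3` is 0 when no 3-bond path exists.

Every registry entry carries an algorithmically independent brute-force
oracle (Floyd–Warshall distances, explicit path enumeration, degrees
recounted from the bond list). The test suite checks fast-vs-oracle
agreement on over 500 random graphs of up to 12 atoms at a relative
tolerance of $10^{-9}$, plus the closed form $W(P_n) = n(n^2-1)/6$ for
paths.

## Descriptor selection

Selection follows the classic forward-stepwise scheme: forward entry while
possible, backward removal while possible, stop when neither fires or the
feature cap (default 13) is reached. The scoring criterion is a
likelihood-ratio test on a logistic-regression surrogate with p-to-enter
0.05 and p-to-remove 0.10 — the conventional defaults for this procedure;
entry stricter than removal prevents enter/remove cycling. Ties break
lexicographically, so a selection replays identically, and the step log
(`$log`) records every action with its p-value.

Selection operates on **base descriptors**, not individual columns: through
the `groups` argument each candidate enters as its (MD, DMD) column pair —
which spans the same space as (MD, \<MD\>) since $DMD = MD - \langle MD
\rangle$ — so the three feature forms of a selected descriptor always travel
together into the model. When no candidate passes the entry threshold, the
pipeline respects that verdict and fits an intercept-only network that
reproduces the training base rate; refitting on descriptors the selector
just rejected would contradict the selection and, on null data, silently
memorize noise.

## The network and the training protocol

The classifier is a single-hidden-layer perceptron with two softmax outputs
(interacting / non-interacting probabilities summing to one), trained with
`nnet`'s BFGS optimizer on the cross-entropy loss with weight decay 0.01.
Hidden units are logistic sigmoids — the same model family as tanh units up
to an affine reparameterization. Inputs are z-standardized with training
statistics that are frozen into the model. Classification uses the argmax
of the two outputs, i.e. a 0.5 threshold on the interacting probability.

Initial weights are random, which is precisely why the protocol trains many
networks: `repeat_model_search()` gives every model its own fresh random
70/30 split (pair-level, exact to one record), its own hidden size drawn
from the configured range (default 40–50, where the best architectures
concentrate; 20–60 available) and its own derived seed, then ranks by
overall accuracy. One master seed drives everything, so a search replays
bit-identically.

Early stopping monitors a 15% carve-out of the *training* partition
(optimization proceeds in 25-iteration blocks, patience 3, best weights
restored). The validation partition is never touched during training, so it
behaves as an external test set. The carve-out matters beyond the usual
overfitting argument: the split is at pair level, so the same drug
legitimately appears in both partitions (with different subclasses), and an
over-trained network can memorize drug fingerprints. The carve-out shares
drugs with the fitting set, which makes that memorization visible as
non-improving carve-out error and stops it. `nnet` does not expose whether
its optimizer stopped at the iteration cap, so no convergence warning is
raised; the block structure bounds the consequences.

## Evaluation battery

`confusion_stats()` reports TP/TN/FP/FN with sensitivity, specificity,
accuracy and the Matthews correlation coefficient

$$MCC = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$

defined as 0 (and flagged) when a denominator factor vanishes.
`roc_auc()` builds the threshold step curve and integrates by the trapezoid
rule; the tests verify it against the Mann–Whitney pairwise-comparison
normalization and against pROC. `per_class_report()` splits accuracy by
true label within each subclass, mirroring the per-family view a
multi-target model owes its users.

## Prediction interface

`predict_one()` computes a drug's descriptors once and scores the (MD,
\<MD\>, DMD) vector against every family profile in the bundle, reporting
the raw interacting-class softmax probability per family — no clamping or
rounding beyond the 6-decimal export format, since any display rounding is
presentation-layer. `predict_batch()` maps a capped 100-row SMILES batch to
one output row per input row in order; malformed SMILES are flagged per row
(`status = "malformed"` with a message) and never abort the batch. Model
bundles serialize to JSON with 17-significant-digit numerics, so a
save/load round trip reproduces predictions bit-identically and refuses
mismatched schema or registry versions.

## The synthetic data generator

Real curated drug–enzyme interaction sets are large (tens of thousands of
pairs over ~23 subclasses, roughly 43% interacting) and are built on
externally hosted databases. The generator provides desk-scale stand-ins
with *known* ground truth so that every stage — parser, descriptors,
profiles, selection, training, evaluation — runs on its real code path and
can be checked for recovery. Reference conditions: 8 subclasses, 500
distinct drugs, 4,000 pairs, 43% interacting, effect size $d = 2$, 5
informative descriptors, 2% label-flip noise.

Molecules are random valence-respecting trees over C/N/O with occasional
double bonds and up to two rings, written as SMILES and guaranteed unique
by canonical form (so curation never merges two generated drugs). Crucially,
the multi-target signal is planted **only through label assignment** —
descriptor values are always the real computed ones:

1. Descriptors are z-scored over the drug pool; each subclass $c$ receives
   a unit direction $u_c$ over the informative descriptors with positive
   weights bounded away from zero ($u_c \propto 1 + 0.5\,|N(0,1)|$,
   normalized). Positive orientation makes per-descriptor marginal shifts
   reinforce across classes; the varying weight profiles keep the classes
   genuinely different.
2. A drug's affinity for subclass $c$ is the score $s = u_c^\top z$. The
   interacting pairs of the subclass are the top `label_balance` fraction
   ranked by the noisy score $r = s + \tau \epsilon$.
3. $\tau$ is set from the effect size: a top-$b$ / bottom-$(1-b)$ split of a
   unit-variance pool can separate group means along $s$ by at most
   $\Delta_{max}(b) = \varphi(\Phi^{-1}(1-b)) \left(\tfrac1b +
   \tfrac1{1-b}\right)$ (about $1.6\sigma$ at $b = 0.43$), so the
   correlation between $s$ and $r$ is chosen as $\min(d, \Delta_{max}) /
   \Delta_{max}$. The realized standardized shift then *equals*
   $\min(d, \Delta_{max})$: $d = 0$ is pure noise with no special-casing,
   and $d \ge \Delta_{max}$ a deterministic rule — $d$ saturates against the
   pool-partition bound, and the per-class realized shift is reported in the
   ground-truth record.
4. Finally `noise_rate` of the labels are flipped, emulating assay error.

Informative descriptors are drawn only from the *identifiable* part of the
registry: candidates must have no external proxy above $|r| = 0.9$ and
mutual correlations at most 0.85, both measured on the generated pool.
Topological descriptors share a dominant molecular-size factor (several
pairs correlate above 0.97 on random molecules); a signal planted on a
descriptor with a near-perfect twin could be carried equally well by the
twin, making "which descriptors carry the signal" unrecoverable for any
method — an ill-posed test rather than a hard one. On this pool the
identifiable set is typically `{ring_count, kappa2, kappa3, balaban_j,
petitjean}`.

What the generator does **not** emulate: real chemotype clustering (actives
sharing scaffolds), assayed versus randomly-paired negatives, class-size
imbalance across families, and medicinal-chemistry descriptor
distributions. Passing the recovery tests therefore demonstrates that the
pipeline's machinery is sound — features built correctly, no leakage,
selection and training able to find planted structure — not that comparable
accuracy would be reached on any particular real dataset.

## Problem sizes and reproducibility

All shipped tests and the acceptance script run at the reference desk scale
(8 classes / 4,000 pairs; 10 seeds for the end-to-end battery), which keeps
the complete suite in the low minutes while leaving every code path
exercised. Every stochastic step — molecule generation, pair sampling,
splitting, weight initialization, search — consumes an explicit seed, and
user-facing RNG state is saved and restored around internal draws, so
package calls never perturb the caller's random stream.

## Known limitations

* The pair-level split shares drugs between training and validation (by
  design, matching the repeated-split protocol); generalization to entirely
  unseen chemotypes is a stronger claim that would need a drug-level or
  scaffold-level split.
* One global model and one global descriptor selection serve all families;
  families whose signal lives in unselected descriptors are not separately
  accommodated.
* Charge neutralization during canonicalization covers common single-atom
  cases only; exotic salts or tautomers may evade deduplication.
* The stepwise surrogate is a linear logistic model; structure visible only
  through interactions or magnitudes (and not through means or linear
  trends) can be under-selected.
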