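---
title: "Consistent differentially correlated edges: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistent differentially correlated edges: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcedge)
```

## The model

`dcedge` selects features from longitudinal two-group expression data by
looking at second moments. A gene pair — an *edge* of a prior interaction
network — carries signal when the within-group Spearman correlation of the
two genes differs between the groups, and does so at every measured
timepoint. Writing $\rho_{g,t}(i,j)$ for the Spearman correlation of genes
$i,j$ within group $g \in \{R, NR\}$ at timepoint $t$, the per-timepoint
criterion is

$$ |\rho_{R,t}(i,j) - \rho_{NR,t}(i,j)| > \tau , $$

and the edge is a *consistent differentially correlated edge* (consistent
DCE) when this holds for all $t$. The package reduces the conjunction to a
single statistic,

$$ S(i,j) = \min_t \, |\rho_{R,t}(i,j) - \rho_{NR,t}(i,j)| , $$

the smallest between-group difference across timepoints, so that
consistency at level $\tau$ is exactly $S > \tau$. $S$ is also the
statistic of the permutation test: it is the minimal quantity that
certifies the selection rule, so "significant" and "selected" refer to the
same functional of the data.

Assumptions worth stating explicitly:

* **Timepoints are ordinal indices.** The method never uses visit spacing,
  so unevenly spaced designs (day 2 next to month 24) are treated
  identically; only the per-timepoint grouping matters.
* **Correlations are estimated per cell.** Each (group, timepoint) cell is
  an independent estimation problem over the patients present in it. With
  typical cohorts (~9 per group) each Spearman estimate is noisy; the
  intersection over timepoints is what controls false positives, not the
  per-cell precision.
* **The reference network is prior information.** Only pairs with a
  confidence score strictly above the cutoff (default 0.6, STRING scores
  rescaled from 0–1000 to the unit interval) are tested. This is both a
  biological prior and the computational device that keeps the edge count
  linear in the network size rather than quadratic in the gene count.

## Inference

Group labels are exchangeable across patients under the null, so the test
permutes *patients* — a patient's entire trajectory moves as one unit,
preserving within-patient dependence across timepoints and both group
sizes. Permuting individual samples would break that dependence and
invalidate the null. The permutation scheme is shared across edges within
one run (one set of $B$ relabelings evaluated for every candidate edge),
which is the standard and cheap choice; per-edge independent draws are
available via `share_null = FALSE`.

P-values follow the add-one convention $(b + 1)/(B + 1)$ by default, which
is bounded away from zero and valid at any $B$; the plug-in estimate $b/B$
is available to mirror tables that print 0. For cohorts small enough to
enumerate ($\binom{n}{n_R}$ below the requested $B$, or `exact = TRUE`),
all assignments are evaluated, the observed one included, and the p-value
is the exact exceedance proportion.

Two numerical details. Rank statistics take finitely many rational values,
and different label assignments can produce the *same* exact value through
different floating-point paths; exceedance comparisons therefore tolerate
$10^{-9}$ of rounding noise, which is far below the spacing of the
statistic at any realistic cohort size. Second, a permuted cell can in
principle contain a constant gene (undefined correlation); such permuted
statistics are counted as exceedances, a conservative choice that cannot
deflate a p-value. Observed edges with an undefined cell are excluded from
detection outright and reported separately.

The selection cutoff is a raw $p < \alpha$ (default 0.01), deliberately
uncorrected — candidate edges already passed the consistency filter, and
the original procedure uses the same rule; `fill_p_values(..., fdr = TRUE)`
adds a Benjamini–Hochberg column for users who want one.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tau` | 0.6 | threshold on the absolute Spearman difference (scale: correlation difference, range 0–2). 0.6 captures either a strong correlation in one group against a weak one in the other, or moderate correlations of opposite sign |
| `confidence` | 0.6 | reference-network confidence cutoff on [0, 1], strict inequality |
| `B` | 10000 | permutations; enough to resolve p-values near $10^{-4}$ |
| `alpha` | 0.01 | significance cutoff on the permutation p-value, strict |
| `epsilon` | 0 | rounding tolerance used only when re-checking published 3-decimal tables (0.0005 there); never applied to full-precision data |
| `cost` | 1 | SVM regularization for the signature classifier |

Ties in ranks use mid-ranks (average ranks), the standard Spearman
convention. Cells with fewer than 3 patients are undefined.

## The classifier

The signature genes feed a linear SVM with one training instance per
sample (patient × timepoint) — the instance unit implied by per-visit
posterior probabilities on a validation cohort. Features are standardized
with training-set means and standard deviations only; posteriors come from
a Platt-style sigmoid fit to the training decision scores with smoothed
targets, fitted by a quasibinomial GLM, which keeps the calibration finite
on separable data and the whole fit deterministic. The decision rule is
responder iff posterior ≥ 0.5, ties toward responder. Genes missing from a
validation platform can be dropped by intersection (with a warning);
weights are then used as-is, which is an approximation the user opts into.

## What the simulator emulates — and what it does not

`simulate_dce_study()` draws each (group, timepoint) cell from a
multivariate normal whose correlation matrix embeds the planted edges and
is identity elsewhere. Planting works on the *Spearman* scale: a target
$\rho_S$ becomes the Gaussian Pearson correlation $2\sin(\pi\rho_S/6)$, so
the population Spearman of the planted pair is exactly $\rho_S$ — the
right scale for a rank-based method. When planted edges share genes the
matrix is repaired to the nearest positive-definite correlation matrix by
eigenvalue clipping and diagonal renormalization; if the repair moves a
planted entry by more than 0.05 the pattern is rejected as infeasible
rather than silently distorted. Timepoints are independent by default,
matching the method's treatment of timepoints as separate problems; an
`autocorrelation` knob adds a shared patient-level latent factor for
robustness experiments. Values are mapped to a log2-expression-like scale
(center 8, default sd 1) — cosmetic for rank statistics, but it keeps the
I/O layer honest.

The simulator does **not** emulate probe-level noise, batch or platform
effects, heavy-tailed or discrete expression marginals, or correlation
structure among non-planted edges. Passing tests on simulated data
therefore demonstrate the statistical machinery — calibration, power,
determinism — not robustness to microarray artifacts; on real data the
upstream normalization and the reference network quality matter in ways no
test here measures.

## Study sizes used by the checks

The packaged experiments run at sizes a desk machine handles comfortably,
chosen to match the designs the method targets:

* **Null calibration / p-uniformity:** 9 + 9 patients, 5 timepoints, 200
  edges, $B = 999$. The network for this check spans 400 genes so the 200
  edges are nearly disjoint: when many edges share endpoints their
  statistics are correlated, and the empirical distribution of 200
  dependent p-values drifts from uniform by more than the
  independent-sample Kolmogorov–Smirnov bound even though each marginal
  p-value is perfectly valid. With near-disjoint edges the observed
  fraction of $p \le 0.05$ sits inside the binomial 99% envelope and the
  KS distance stays below 0.1.
* **Power / recovery:** 5 planted edges (Spearman −0.6 vs +0.6, a
  difference of 1.2) among 95 null edges, 30 + 30 patients, $B = 999$:
  the pipeline recovers the planted edges at $p < 0.01$ with at most a
  couple of false positives.
* **Exactness:** 4 + 4 patients, all 70 label assignments enumerated and
  compared edge-by-edge against a brute-force oracle.
* **Worked example:** the published 22-pair table, re-checked with the
  3-decimal tolerance $\varepsilon = 0.0005$ — all 22 consistent at
  $\tau = 0.6$, 41 distinct signature genes.

## Design choices that were genuinely open

* **Probe collapsing** (`collapse_features`): the convention of keeping
  the probe with the highest mean expression (`max-mean`) is the default,
  per-sample averaging the alternative; upstream annotation handling is
  out of scope and the mapping is user input.
* **Permutation unit:** patient, for the exchangeability argument above.
* **Test statistic:** $\min_t |\Delta_t|$, chosen so that the significance
  machinery tests exactly the selection rule.
* **Exact-mode p-value:** includes the identity assignment, so it is never
  zero and never anti-conservative.
* **Run config format:** YAML.
* **Signed deltas:** the detector stores $\rho_R - \rho_{NR}$ with sign
  and a per-edge category (same-sign / opposite-sign / mixed across
  timepoints) because the sign pattern — e.g. negatively correlated in
  responders, positively in non-responders — is the biologically
  interpretable output.

## Known limitations

* Intersecting over all timepoints is strict: one noisy cell removes an
  edge, and power decays as timepoints are added. (A reference-timepoint
  variant would relax this; it is out of scope here.)
* Per-cell Spearman with ~9 patients has a granular sampling distribution;
  $\tau = 0.6$ should be read as a screening threshold, not an effect-size
  estimate.
* The permutation test conditions on the candidate set when run only on
  consistent edges (the default pipeline), which is the original
  procedure's shape; p-values are valid per edge but selection and testing
  share data.
* The classifier assumes the validation cohort is on a comparable
  expression scale after its own normalization; only gene-set mismatch is
  handled explicitly.
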