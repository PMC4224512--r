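---
title: "Methods: qPCR-array Ct analysis and cross-severity signatures with ctsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qPCR-array Ct analysis and cross-severity signatures with ctsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsig)
```

## The problem

Low-density TaqMan qPCR arrays profile several hundred miRNAs over two
plates (Pool A / Pool B) per sample. Each reaction reports a threshold
cycle Ct — the PCR cycle at which fluorescence crosses a fixed threshold —
which is inversely log2-proportional to template abundance; reactions that
never cross threshold are exported as "Undetermined". `ctsig` implements
the downstream analysis used in serum biomarker discovery with a calibrator
(sham) group and several contrast groups of biological replicates: which
targets are reliably detected, how to normalize without designated
reference genes, which targets change relative to the calibrator, which
changes recur across all contrast groups, which targets are stable enough
to serve as endogenous controls for singleplex validation, and whether
group-level profiles order the groups as expected.

Throughout, "undetected" is an explicit state (`NA` in the Ct matrix),
never a sentinel number. A numeric stand-in (the cap, below) enters only
inside the fold computation, because that is the only place a quantity is
defined for an absent reaction.

## Detection filtering and Ct status

A target is **expressed** in a group when every replicate has Ct strictly
below the ceiling `ct_max` (default 36 cycles); a single undetected or
at-ceiling replicate disqualifies the group (`max_failures = 0`). The
boundary is strict: Ct = 36.0 fails. `max_failures` is exposed for panels
where a more permissive rule is wanted; raising `ct_max` can only grow the
expressed set (monotonicity, covered by a property test).

Each (target, contrast group) pair gets a **Ct status**:

| sham expressed | injured expressed | status |
|---|---|---|
| yes | yes | `valid` |
| no  | yes | `calibrator_not_detected` |
| yes | no  | `target_not_detected` |
| no  | no  | `excluded` |

`excluded` targets are dropped before normalization and differential
analysis — no relative quantity is defined for them. No imputation is
performed anywhere.

## Global normalization

With no validated reference genes for serum, each sample is centered on
the mean Ct of the targets detected in *all* samples of the comparison
(global mean normalization): dCt(t, s) = Ct(t, s) − mean over the
normalization set in sample s. Restricting the set to commonly detected
targets keeps the centering set identical across samples, so dropout
cannot bias it; partially detected targets are centered but do not
contribute to the centering. A `center = "median"` switch provides a
robust variant. `reference_normalize()` implements the endogenous-control
analogue used for singleplex validation; the two agree exactly when the
normalization set equals the reference list (tested).

Normalization is location-invariant: adding a constant to every Ct of a
sample leaves all dCt unchanged. This is the property that makes the
centering a normalization, and it is asserted exactly in the test suite.

Normalization uses only detected values and happens before any
substitution of undetected cells; the capped values used for
absent-in-one-group folds never enter the centering.

## Relative quantitation and significance

For `valid` targets, the group contrast is the comparative-Ct quantity
ddCt = mean dCt(injured) − mean dCt(sham), RQ = 2^(−ddCt), reported as
log10(RQ). One cycle fewer in the injured group is a doubling. For
`calibrator_not_detected` / `target_not_detected` targets, the fold is
computed on raw Ct with undetected replicates set to the cap (`ct_cap`,
default 40, the final PCR cycle) and observed values above the cap clipped
— detected values keep their actual Ct. These rows are not re-normalized:
the capped value is an abundance floor, not a measurement, and centering
it would launder it into one.

The per-target p-value is an unpaired two-tailed Welch t-test on the same
replicate values the fold uses (dCt for valid rows, substituted raw Ct
otherwise). Welch is the default because with n = 6 per group equal
variances cannot be assumed; a pooled-variance switch (`var_equal = TRUE`)
is provided. When both groups are constant the statistic is undefined:
equal constants give p = 1, unequal constants a 0-adjacent sentinel, each
with a warning — this occurs only on fully capped rows. The suite checks
the closed-form p-values against `stats::t.test` and checks that their
two-sided ordering agrees with an exhaustive 3-vs-3 permutation oracle.

A target is **significantly modulated** when |log10 RQ| >= log10(1.5)
(within 1e-12, guarding the binary representation of the threshold) and
p < 0.05, both raw. No multiple-testing correction is applied by default,
matching the screening character of the design; `p_adjust = "BH"` is
available. Direction is the sign of log10 RQ.

## Cross-group signature

Per-group significant sets are intersected after target-name
canonicalization: a trailing `#` sigil is rewritten to `*` (both denote
the passenger strand and instrument exports mix them), whitespace is
stripped, and species prefixes are preserved as distinct identities.
Without the sigil rule, one passenger-strand target fails to match across
the packaged tables and the intersection loses a member — canonicalization
is load-bearing, not cosmetic. The common signature is ordered by
descending mean |log10 RQ| then name (the ordering is a package
convention; membership and values are what the fixtures pin down).
Direction consistency is same-sign log10 RQ in every group; magnitudes are
not compared. Venn region counts over up to five groups partition the
union (tested).

## Stable-reference selection

Candidate endogenous controls are screened stepwise on raw Ct across
*all* samples, calibrator included: (1) eliminate SD > 1 cycle;
(2) eliminate |mean − median| > 0.5 cycles (outlier skew); (3) keep mean
Ct in the inclusive abundance window [14, 20]. Targets undetected in any
sample are ineligible — stability across every sample is the point.
The window boundaries are config values: abundance conventions vary
(a looser Ct < 25 screen is sometimes used), and the default window is
the stricter one, which both of the usual serum candidates (means near
15.5 and 14.9 cycles) satisfy. Each step's pass flag is kept in the
report, and passing targets are ranked by ascending SD. Tightening any
criterion can only shrink the pass set (property-tested).

## Clustering of group profiles

Group-level ddCt profiles are built from targets with `valid` status in
*every* group — capped substitutions would distort distances — and
clustered agglomeratively (Euclidean distance, average linkage by
default; correlation distance and complete/Ward linkage available).
Columns are sorted by name before the distance computation so the tree is
invariant to input order. The tree is exported as Newick with branch
lengths via `ape`. Group-level profiles are the package's reading of the
clustering question; sample-level clustering can be had by passing
per-sample dCt columns to `cluster_groups()` directly, but no dedicated
wrapper is provided.

## The synthetic generator

Raw Ct data for this kind of serum study are rarely deposited, so the
package ships a seeded generator that emulates the design the analysis
assumes, and every statistical claim about the pipeline is made against
its known truth:

- 368 targets over two panels; 4 contrast groups plus a sham calibrator,
  6 biological replicates each (30 samples).
- Per-target baseline Ct uniform on [14, 35]; replicate noise additive
  Gaussian on the Ct scale (SD 0.5 cycles) — multiplicative on abundance,
  the standard qPCR error model.
- 10% of targets carry a true shift whose magnitude scales 1:2:4:4.5 with
  the severity index (default −0.5·(1, 2, 4, 4.5) cycles); each effect
  target is randomly oriented up or down, consistently across groups, as
  observed signatures contain both directions.
- Dropout is deterministic: a realized Ct at or above 36 is emitted as
  undetected. This is simpler than a probabilistic detection curve and
  exercises every Ct-status branch.
- 5 designed stable targets: baseline uniform on [15, 16], noise SD 0.3,
  zero shift.

What the generator does **not** emulate: plate/batch effects,
pre-amplification bias, hemolysis artifacts, inter-target correlation,
or a realistic abundance distribution (real panels are not uniform in
Ct). Passing tests therefore demonstrate that the pipeline's statistics
are calibrated and its mechanics correct under the stated model — not
that any particular biological signature would be recovered from real
serum.

With the default baseline range the panel sits almost entirely below the
detection ceiling; simulations that exercise realistic dropout rates
(per-group expressed counts around 315–363 of 368) extend the baseline
range to (14, 38) so a share of targets straddles the ceiling.

## Problem sizes and numerical choices

The test suite's simulation studies use: 200 null panels for type-I
calibration (the joint rate of the p-filter and fold-filter compared with
an independent 40,000-draw Monte-Carlo evaluation of the same rule, within
a 99% binomial bound that conservatively treats the four contrasts as one
because they share sham replicates); 10 panels of 4-fold effects at noise
SD 0.3 for power and direction accuracy; 50 panels for stable-reference
recovery; 100 panels for the first-merge clustering frequency. These sizes
give comfortable Monte-Carlo margins for the bounds being asserted while
keeping the default test run quick.

Numerical conventions: the fold threshold uses `>=` with a 1e-12 guard;
RQ/log identities hold to 1e-12 and are asserted on a grid including 0 and
±1; the normalization set mean of dCt is 0 to 1e-9 per sample; ordering
ties in the signature break by name; `hclust` trees are computed after
sorting group columns, making leaf order deterministic.

## Known limitations

- The t-test on substituted (capped) rows treats the cap as data; the
  resulting p-values are conventional but should be read as ranking
  evidence of presence/absence, not as calibrated probabilities. The
  Ct-status column flags exactly which rows these are.
- Global mean normalization assumes most targets do not change; with many
  strong shared effects the centering absorbs part of the signal.
- No amplification-efficiency correction (the 2-fold model is assumed),
  no standard-curve quantitation, no moderated (shrinkage) statistics.
- `venn_counts()` is limited to five sets.
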