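---
title: "Credal decision-tree rule mining for injury severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Credal decision-tree rule mining for injury severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irnvrules)
```

## The model and its assumptions

`irnvrules` mines IF-THEN rules for fatal injury in urban accidents of
novice drivers from categorical records following a fixed 22-variable schema
(`table1_schema()`). The class is binary — slight (1) versus fatal (2,
meaning killed or seriously injured within 30 days) — and strongly
imbalanced, with a fatal share below 10%. Accidents at intersections are
treated as a separate population from those away from intersections: the two
partitions carry slightly different variable sets (intersection type and
priority regulation exist only at intersections, road tracing only away from
them) and are mined independently.

The mining engine is an ensemble of shallow decision trees. Three split
criteria are implemented:

- **IGR** — the C4.5 info-gain ratio, `(H(C) − H(C|X)) / H(X)` in bits.
- **IIG** — the imprecise info-gain. Class frequencies are replaced by the
  imprecise Dirichlet model's interval `[n_c/(N+s), (n_c+s)/(N+s)]` per
  class; the interval box intersected with the probability simplex is a
  credal set, summarized by its maximum Shannon entropy `H*`. The gain is
  `H*(marginal) − Σ p(xᵢ) H*(branch i)`.
- **A-NPIM** — the same construction over the parameter-free approximate
  nonparametric predictive inference box
  `[max(0,(n_c−1)/N), min((n_c+1)/N, 1)]`.

The imprecise gains are *not* bounded below by zero. A negative value means
the variable, after accounting for estimation uncertainty, worsens the
information on the class; the ensemble exploits this as a veto (below). Both
credal constructions accept real-valued counts, which is what makes
fractional instance weighting for missing values well-defined.

All probabilities in the criteria are relative frequencies of *observed*
weight. When a candidate variable has missing values, its criterion value is
computed on the observed-weight records and scaled by the observed-weight
fraction — the C4.5 convention, matched because the rest of the tree
machinery follows C4.5's treatment of missing data.

## The maximum-entropy solver

`H*` maximizes a strictly concave function over a box intersected with the
simplex. The KKT conditions force every coordinate of the maximizer to a
common level clamped to its interval: `p_i = clamp(λ, l_i, u_i)` with `λ`
chosen so the probabilities sum to one. `max_entropy_distribution()` solves
this by bisection on `λ` to a width of 1e-12, then spreads the residual
(at most a few 1e-12) over the unclamped coordinates. For the binary class
used throughout the pipeline the solution is closed-form — clamp `p₁` to
one-half within its feasible range — and that fast path is used during tree
induction. The test suite validates the solver against an independent
brute-force oracle (multi-scale grid search with a pairwise-exchange polish)
on hundreds of random interval systems; agreement is at the 1e-12 level,
far inside the 1e-4 bits the acceptance checks demand.

Degenerate inputs: an empty credal set (`Σl > 1` or `Σu < 1`) is rejected at
construction; a point set (`l = u`) returns that point. Zero class counts
are fine in both models (the NPI lower bound clamps at 0, the upper at 1).

## Tree induction and the IRNV ensemble

Trees are unpruned and depth-limited to **four split levels**, so every
extracted rule carries one to four antecedent conditions — short enough for
a road-safety analyst to act on. A node splits only when the best unused
variable has a strictly positive criterion score and at least two branches
would receive at least `min_leaf_weight = 2` (fractional) instances, the J48
default. Leaves are labeled with the weighted majority class, ties toward
the majority (slight) class; ranking and split ties break by schema column
order. All of this makes induction fully deterministic.

Records missing the split variable descend *every* branch, their weight
scaled by each branch's share of observed weight; classification of a record
with a missing split value aggregates class mass across branches the same
way. Leaf weights therefore sum to the root weight exactly (to 1e-6 in the
tests), conserving the fractional pieces.

A single tree only yields rules phrased under its own root. The information
root node variation (IRNV) ensemble therefore ranks all predictors by the
criterion, then builds one tree per predictor with that predictor *forced*
as the root, per criterion, and pools every extracted rule (duplicates — the
same antecedent set and consequent — collapse). Two design points needed a
decision:

- The forced root splits even when uninformative (that is IRNV's point), but
  for the imprecise criteria a *strictly negative* root score vetoes the
  whole tree: it contributes an empty rule set. The veto is the published
  behaviour of the negative-gain property; forcing a split on a
  negatively-scored root would manufacture rules from a variable the
  criterion explicitly disqualifies.
- Rankings are computed once per partition per criterion, on the full
  partition. Whether the original procedure re-ranked per dataset is not
  documented; one ranking per dataset is the natural reading and keeps the
  ensemble at most `3 m` trees for `m` predictors.

## Rule scoring and selection

A rule's support `S` is the fraction of records matching antecedent *and*
consequent; its probability `Pr` is the confidence `P(A,B)/P(A)`. Both are
computed on the original unit-weight records, with a missing antecedent
value counting as a non-match — the published tables report fractions of the
whole dataset, and no validation split is used because carving one from so
imbalanced a dataset would leave too few fatal cases to score rules at all.
Selection keeps fatal-consequent rules with `Pr ≥ 10%` and `S ≥ 0.1%`
(thresholds appropriate to heavily imbalanced data and a minority class of
interest; balanced-data studies have used 60%/0.6%, and both are
configurable), deduplicates, and sorts by `Pr`, then `S`, then antecedent.
Selection is idempotent, and `Pr ≥ S` always.

## The synthetic generator

The original DGT microdata are not packaged, so the generator emulates the
preprocessed schema instead: per-variable categorical draws over the coded
value sets, a configurable intersection share (default 0.52), base fatal
rate 0.07, and per-variable missingness echoing the published missing-count
pattern (visibility restrictions and priority regulation largely
unrecorded; core variables nearly complete). Marginals are uniform except
where the published frequency tables are plainly skewed (dry/clean surface,
good weather, male drivers, "other maneuver", appropriate speed, no
anomaly); the skews are editable defaults, not fitted values. Partition-only
variables are populated only in their partition. Missingness is never
applied to the class.

Planted rules overwrite the antecedent variables of a target share of
records (guaranteeing prevalence exactly) and redraw those records' severity
from `Bernoulli(fatal_probability)`; a truth log records memberships and
realized rates. Planting after value generation and before missingness means
a planted record can still lose an antecedent value to missingness — as a
real informative record could.

What the generator does **not** emulate: the dependence structure of real
accident variables (draws are independent), exposure, geography, or the raw
DGT recodings. Passing tests therefore demonstrate that the machinery
recovers known mechanisms under this data shape, not that it reproduces
any particular real-data rule table, which would require the
undistributable microdata.

### Choosing a recoverable planted antecedent

For end-to-end recovery tests the planted antecedent is `SE=1, F_T=2,
S_W=4, ACT_TY=3`: three moderate-frequency values and one rare one. The
structure matters. Planting overwrites all four variables, so inside the
planted subset any three conditions make the fourth variable constant and
hence unsplittable; if all four values are rare, the tree isolates the
planted records after three conditions and can never append the fourth.
Moderate values keep background records flowing down the path (so deeper
planted variables still vary), while the rare final value keeps the
recovered rule's probability close to the planted conditional probability
(background matches of the full antecedent are negligible). With ~150
planted records the recovered `Pr` is a binomial mean with standard error
`√(0.6·0.4/150) ≈ 0.04`, so it tracks the *realized* planted fatal rate
closely but scatters around the configured 0.6 by several points across
seeds — an irreducible feature of drawing severities, not an estimation
error.

## Problem sizes used by the checks

Unit tests run on hand-built fixtures (10–12 records) and small simulations
(300–8,000 records). The end-to-end recovery study uses the study-scale
configuration — 30,000 records, 7% base fatal rate, one planted
four-condition antecedent at 0.5% prevalence and 0.6 fatal probability —
over 20 seeds, both in the test suite and in `scripts/acceptance.R`. A full
pipeline run at that scale (three criteria, both partitions, roughly 50
trees) takes a few seconds; the 20-seed study a few minutes.

## Known limitations

- Only categorical predictors; no numeric splits and no pruning, by design.
- The imprecise-criterion veto is applied at the forced root only; interior
  nodes simply require a positive score.
- Support and probability are in-sample; no validation split or significance
  testing of rules is provided.
- The generator's independence assumption makes planted mechanisms the only
  real structure; spontaneous high-probability rules in synthetic data are
  noise and appear mainly at small sample sizes.
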