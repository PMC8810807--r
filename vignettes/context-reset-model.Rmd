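---
title: "A temporal-context reset model of event boundaries and order memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A temporal-context reset model of event boundaries and order memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(contextreset)
```

## The model and its assumptions

Temporal context models hold that every studied item is bound to a slowly
changing context signal, and that judging which of two items came later
amounts to comparing their stored contexts. `contextreset` implements a
binary-vector member of this family with one addition: at an event boundary
(here, the list position where a coloured frame around the stimuli updates)
the context does not merely change — it *resets*, reinstating a proportion
of the first context of the list.

Concretely, context is a vector of `F = 100` binary features. At a
non-boundary step each element flips state independently with drift rate
`p`; at a boundary step each element is, with probability `lam`, copied
from the first context `C1`, and otherwise drifts as usual. These are the
element-wise realizations of the mixture updates
`C_t = (1-p) C_{t-1} + p C_IN` and
`C_t = (1-lam)((1-p) C_{t-1} + p C_IN) + lam C_1`. Writing them as
stochastic per-element selections rather than real-valued convex
combinations keeps every context strictly 0/1, which keeps Dice similarity
(the model's similarity measure) well defined; for symmetric binary noise
the flip rule is distributionally equivalent to mixing in an independent
noise vector `C_IN`. The model deliberately contains no item-context
associative matrix and no sequential scanning stage at retrieval: a recency
judgment is a one-shot comparison.

That comparison is the **memory index**. For a probed pair, let `R1` and
`R2` be the Dice similarities of the earlier and later item's context to a
reference context — by default the first context of the list — and
`d = 1 - R`. Then `MI = d2 - d1`. The item more dissimilar to the first
context is judged later, so positive MI is a correct ordering and the
magnitude serves as an accuracy proxy. MI is never thresholded into
simulated binary choices; condition-level predictions are means of MI over
iterations (an optional affine MI-to-probability link exists only in the
synthetic-data generator, for end-to-end tests).

Why this produces the behavioural pattern: resetting pulls each boundary
item's context back toward `C1`. Across a boundary, the later item is
thereby made *more* similar to the reference, shrinking `d2 - d1` —
across-event order memory suffers. Within an event just after a boundary,
the context sits closer to `C1`, where each drift step buys a larger
increment in dissimilarity (`Δd` shrinks as contexts saturate away from the
reference), so `d2 - d1` accumulated over a within-event pair grows —
within-event and early-local-position order memory improve. The per-step
increments telescope exactly: the MI of a pair equals the summed `Δd`
between its two positions, a machine-precision identity in the test suite.

## Simulated experiment designs

All four 36-item list-learning designs are encoded as data
(`builtin_design()`, `builtin_designs()`), each with its boundary schedule
and typed probe-pair table; `validate_design()` checks position bounds, the
straddle rules (within-type pairs never cross a boundary, across-type pairs
cross exactly one) and item-disjointness.

Some probe tables are not printed in full anywhere and were reconstructed
under the stated constraints:

* **Six-item events** (boundaries 7, 13, 19, 25, 31): six within pairs at
  local positions 2-4 of each event, five across pairs with one intervening
  item; the no-boundary baseline probes identical list positions.
* **Four-item events**: nine within lag-1 pairs, plus four across lag-1
  ("items 3'-1") and four across lag-3 ("items 3'-3") pairs on alternating
  boundaries. At the published per-sequence counts these two across tables
  *cannot* be made item-disjoint from each other (the lag-3 anchor at one
  boundary always shares an item with any pair at the next boundary), so
  the validator enforces disjointness within each pair type and reports
  cross-type sharing only under `strict = TRUE`.
* **Event-length comparison** (4- vs 6-item events): pair type 1 at
  identical list *and* local positions in both conditions — (2,4), (14,16),
  (26,28) are the only such lag-2 pairs; pair type 2 at identical list
  positions but earlier local positions under 4-item segmentation; pair
  type 3 across pairs chosen item-disjoint and matched for mean list
  position (19 in both conditions).
* **Mixed event lengths** (3-3-6... vs 6-3-3...): within pairs at local
  1-3 of 3-item events versus local 4-6 of 6-item events occupy the same
  absolute positions in the two schedules and swap roles between them;
  short-lag across pairs sit at the five boundary positions the two
  schedules share, which yields the published 35/35 early/late totals; the
  longer-lag table is the least constrained part of the published design
  and ships as a documented default.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `p` | per-step element flip probability (dimensionless rate) | 0.02 | canonical illustrative cell; sweep grid 0.01-0.4 |
| `lam` | proportion of `C1` reinstated at a boundary | 0.2 | canonical illustrative cell; sweep grid 0.05-1 |
| `n_features` | binary context features | 100 | standard size for binary context vectors |
| `n_iter` | Monte-Carlo iterations per condition | 1000 | the scale at which condition means stabilize |
| `init_density` | activation probability of `C1` elements | 0.5 | symmetric, uninformative start |
| `margin` | effect-recovery margin (Monte-Carlo SEs) | 2 | conventional two-sigma evidence for a sign |

The random-shift alternative (`simulate_alternative()`) drifts at 0.01 off
boundaries and 0.08 at boundaries with no reinstatement, and is scored
either by this package's MI or by the similarity of the two probed contexts
— the index that account originally used. Under that index the boundary
effect and the temporal distance effect cannot co-exist (similarity only
decays with lag), which the falsification tests assert.

## Effect recovery, fitting and the sweep

`check_effect_recovery()` reduces a simulated suite to thirteen named
contrasts — three for the six-item-event experiment, three for the
four-item-event experiment, three for the event-length comparison, four for
the mixed-length experiment — each required to carry the behavioural sign by
more than `margin` Monte-Carlo SEs; the one matched-position control must
instead stay *within* the margin. Contrast SEs pair pair-types within a
condition across iterations and treat different conditions as independent
simulation streams.

A note on the equivalence flag: the model's true pair-type-1 condition
difference at the canonical cell is small but not exactly zero (about
+0.0006 MI units). A two-SE window around zero therefore passes with
probability around 0.8 at 1000 iterations, and would fail almost surely at
arbitrarily high iteration counts. This is a property of operationalizing
"recovers a null" as a Monte-Carlo equivalence band at a fixed resolution;
the package reports the per-seed outcome rather than hiding it.

`fit_glm()` regresses cell-level group accuracy (percent) on mean MI by
ordinary least squares — the identity-link special case is used because the
fitted quantity is a group-mean accuracy, not trial-level correctness — and
reports R² and the overall F-test. `fit_glmm()` adds a random intercept per
grouping level (experiment by default, sequence where per-sequence means
exist) via lme4/lmerTest; the reported R² is the *conditional* one (fixed
plus random variance over total), a choice documented here because more
than one mixed-model R² flavour exists. `parameter_sweep()` repeats the
suite per grid cell with per-cell seeds derived deterministically from the
master seed.

## Behavioural statistics

`rm_anova()` implements fully-within one- and two-factor repeated-measures
ANOVA on subject-pooled accuracies: sums of squares from the classic
subject-stratified decomposition, Greenhouse-Geisser epsilon from the
subject covariance of the cell scores whenever an effect has more than one
numerator degree of freedom (two-level factors need no correction), and
generalized eta squared in percent (effect SS over effect plus all
subject-level error SS). Accuracies are pooled within subject across
sequences before testing, matching how subject means are analysed.
`paired_t()` wraps the two-sided paired t with its 95% CI (a one-tailed
option exists for the single directional distance comparison);
`fdr_correct()` is Benjamini-Hochberg; `experiment_stats()` bundles each
experiment's ANOVA-plus-contrasts battery; `primacy_followup()` runs the
2 x 2 early/late-by-condition follow-up. Numerical edge cases: an effect
whose SS is exactly zero reports F = 0 rather than 0/0; a zero-variance
paired difference raises an error rather than returning an undefined t;
two all-zero context vectors make Dice undefined and raise rather than
silently returning 0.

## The synthetic-data generator

`generate_subjects()` emulates subject-level recency-judgment tables: every
design cell has a true accuracy probability, each subject draws a logit-scale
random intercept (SD 0.5 by default — heterogeneity on the logit scale keeps
probabilities bounded), and per-sequence correct counts are binomial with
the design's pairs-per-sequence as trial counts. Presets for the four
experiments use accuracy levels whose signs and rough spacings follow the
group-level findings (e.g. 76/64/71.5/69.5% for the six-item-event cells);
these magnitudes are illustrative generator settings chosen once, not
estimates of any dataset. The generator omits item effects, sequence
effects, response bias, and any trial-order or fatigue structure — so
passing tests show that the *pipelines* behave correctly on data with the
assumed structure, not that real data satisfy those assumptions.
`model_coupled_generate()` maps suite MI through an affine link into cell
probabilities, closing the loop for slope-recovery tests of the fitting
layer.

## Reproducibility and numerical choices

Every stochastic entry point takes a seed; `run_experiment_suite()` runs
its conditions sequentially on one stream so the whole table is
deterministic given the master seed, and sweep cells derive their seeds as
`seed + 131 * cell_index` (kept under 2^31). Inside a reset step the flip
mask is drawn before the copy mask; that order is fixed and documented
because it makes a `lam = 0` reset reproduce a drift step exactly under the
same seed, which the limit tests rely on. Problem sizes in the test suite
are scaled for a single CPU: 1000 iterations for the headline recovery
check, 200-500 for pattern-level unit tests, 2000 replicate datasets for
the type-I-error calibration of the paired t at the null preset, and
reduced grids for sweep behaviour; the full 40 x 96 grid at 1000 iterations
is available through `parameter_sweep()` but is a long run.

## Known limitations

* The context space is binary with i.i.d. features; orthonormal or
  real-valued context spaces, learned item-context associations and
  retrieval dynamics beyond the one-shot comparison are out of scope.
* MI is an accuracy *proxy*; mapping it onto percent-correct requires the
  affine link, whose parameters are not identified by the model itself.
* The published probe tables for the mixed-length experiment's longer-lag
  pairs are under-determined; the shipped defaults satisfy the stated
  constraints but other choices exist.
* Group-level fits on synthetic presets quantify pipeline behaviour only;
  fitting real deposited group means requires supplying that table to
  `fit_glm()`/`fit_glmm()` via the subject-table loader and its column
  mapping.
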