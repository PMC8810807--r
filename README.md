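# contextreset

Event boundaries — salient changes such as a background frame switching
colour partway through a list — reorganize memory for *when* things
happened. Behavioural work with 36-item picture lists shows a dual effect on
temporal order memory (TOM, measured by recency judgments): order memory is
better for item pairs inside one event and worse for pairs straddling a
boundary, better for pairs separated by more intervening items (the temporal
distance effect), and better for pairs at earlier positions inside their
event even when absolute list positions are matched (the local primacy
effect).

`contextreset` implements a temporal-context account that produces all of
these patterns from two parameters, together with the simulation designs,
fitting machinery and behavioural statistics needed to evaluate it. It is
aimed at memory researchers who want to simulate the model, probe its
parameter space, or run the matching analysis pipeline on their own
recency-judgment data.

## The model

Context is a vector of F = 100 binary features. Between items it drifts —
each element flips state with probability *p*:

    C_t = (1 - p) C_{t-1} + p C_IN

and at an event boundary a proportion *λ* of the very first context is
reinstated:

    C_t = (1 - λ)((1 - p) C_{t-1} + p C_IN) + λ C_1

Both updates are realized per element so contexts stay strictly binary.
Similarity between contexts is the Dice coefficient R; to order a probed
pair, the model compares each item's context to the first context of the
list and computes the memory index

    MI = (1 - R2) - (1 - R1) = d2 - d1

where d2, d1 are the Dice dissimilarities of the later/earlier item's
context to that reference. Positive MI orders the pair correctly; its
magnitude is the accuracy proxy. Resetting makes boundary items more similar
to the first context, which simultaneously compresses dissimilarity across
boundaries (impairing across-event order memory) and enlarges the
step-to-step dissimilarity increments just after a boundary (enhancing
within-event and early-local-position order memory).

## Worked example

```r
library(contextreset)

params <- model_params(p = 0.02, lam = 0.2, n_iter = 1000)
suite  <- run_experiment_suite(params, reference = "first", seed = 1)
pattern <- check_effect_recovery(suite)
pattern$contrasts[1:3, c("effect", "value", "se", "recovered")]
#> # A tibble: 3 x 4
#>   effect                           value       se recovered
#>   <chr>                            <dbl>    <dbl> <lgl>
#> 1 exp1_boundary_within_gt_across 0.0430  0.000510 TRUE
#> 2 exp1_within_enhanced           0.00550 0.000354 TRUE
#> 3 exp1_across_impaired           0.0378  0.000434 TRUE
pattern$all_recovered
#> [1] TRUE
```

The first row says that, at drift 0.02 and reset 0.2, simulated memory
indices for within-event pairs exceed those for across-event pairs by 0.043
MI units (Monte-Carlo SE 0.0005) in the six-item-event design — the
boundary effect. The next rows are the dual enhancement/impairment against
the position-matched no-boundary baseline; `all_recovered` reports whether
every behavioural contrast across the four experiment designs comes out
with the behavioural sign (and the one matched-position control stays
null).

Other entry points: `simulate_condition()` for one design,
`parameter_sweep()` for the (p, λ) grid, `simulate_alternative()` for the
random-shift comparison model, `fit_glm()`/`fit_glmm()` to regress group
accuracy on model MI, `generate_subjects()` for synthetic subject tables,
and `rm_anova()`/`paired_t()`/`fdr_correct()`/`experiment_stats()` for the
behavioural test battery. `inst/cli/contextreset` exposes the same
operations as a command-line tool (`simulate`, `sweep`, `fit`, `stats`,
`synth`, `validate`).

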