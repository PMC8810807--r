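#' @title Effect recovery, model-behaviour fitting and the parameter sweep
#'
#' @description
#' The behavioural studies establish a fixed pattern of effects: the dual
#' boundary effect of Experiment 1 (within > across inside the boundary
#' condition, within enhanced and across impaired relative to the
#' position-matched no-boundary baseline), the co-existing boundary and
#' temporal-distance effects of Experiment 2, the pair-type pattern of
#' Experiment 3 (null for position-and-local-position-matched pairs, short
#' events better otherwise) and the local primacy pattern of Experiment 4
#' (early > late for within and across pairs, within > across, long lag >
#' short lag). A parameter cell "recovers" the pattern when every contrast of
#' simulated memory indices has the behavioural sign and exceeds a
#' Monte-Carlo margin (default 2 standard errors); the one null effect must
#' instead stay inside the margin.
#'
#' @name model-evaluation
NULL

#' Definitions of the behavioural effects
#'
#' @return A list of effect definitions; each has a `name`, `experiment`,
#'   `type` (`"gt"` for a signed contrast, `"null"` for an equivalence
#'   check) and a `cells` tibble of (condition, pair_type, weight) whose
#'   weighted sum of mean memory indices is the contrast value.
#' @export
tom_effects <- function() {
  cells <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    tibble::tibble(condition = m[, 1], pair_type = m[, 2],
                   weight = as.numeric(m[, 3]))
  }
  eff <- function(name, experiment, cells, type = "gt") {
    list(name = name, experiment = experiment, cells = cells, type = type)
  }
  list(
    eff("exp1_boundary_within_gt_across", 1L,
        cells("boundary", "within", 1, "boundary", "across", -1)),
    eff("exp1_within_enhanced", 1L,
        cells("boundary", "within", 1, "no_boundary", "within", -1)),
    eff("exp1_across_impaired", 1L,
        cells("no_boundary", "across", 1, "boundary", "across", -1)),
    eff("exp2_within_lag1_gt_across_lag1", 2L,
        cells("standard", "within_lag1", 1, "standard", "across_lag1", -1)),
    eff("exp2_across_lag3_gt_across_lag1", 2L,
        cells("standard", "across_lag3", 1, "standard", "across_lag1", -1)),
    eff("exp2_within_lag1_gt_across_lag3", 2L,
        cells("standard", "within_lag1", 1, "standard", "across_lag3", -1)),
    eff("exp3_pairtype1_null", 3L,
        cells("event4", "pairtype1", 1, "event6", "pairtype1", -1),
        type = "null"),
    eff("exp3_pairtype2_event4_gt_event6", 3L,
        cells("event4", "pairtype2", 1, "event6", "pairtype2", -1)),
    eff("exp3_pairtype3_event4_gt_event6", 3L,
        cells("event4", "pairtype3", 1, "event6", "pairtype3", -1)),
    eff("exp4_within_early_gt_late", 4L,
        cells("schedule_336", "within_early", 0.5,
              "schedule_633", "within_early", 0.5,
              "schedule_336", "within_late", -0.5,
              "schedule_633", "within_late", -0.5)),
    eff("exp4_across_early_gt_late", 4L,
        cells("schedule_336", "across_early", 0.5,
              "schedule_633", "across_early", 0.5,
              "schedule_336", "across_late", -0.5,
              "schedule_633", "across_late", -0.5)),
    eff("exp4_within_gt_across", 4L,
        cells("schedule_336", "within_early", 0.25,
              "schedule_633", "within_early", 0.25,
              "schedule_336", "within_late", 0.25,
              "schedule_633", "within_late", 0.25,
              "schedule_336", "across_early", -0.25,
              "schedule_633", "across_early", -0.25,
              "schedule_336", "across_late", -0.25,
              "schedule_633", "across_late", -0.25)),
    eff("exp4_long_lag_gt_short_lag", 4L,
        cells("schedule_336", "across_long", 0.5,
              "schedule_633", "across_long", 0.5,
              "schedule_336", "across_early", -0.25,
              "schedule_633", "across_early", -0.25,
              "schedule_336", "across_late", -0.25,
              "schedule_633", "across_late", -0.25))
  )
}

mi_iterations <- function(mi) {
  if (inherits(mi, "mi_table")) mi$iterations
  else stop("expected an `mi_table`", call. = FALSE)
}

#' Behavioural-effect contrasts of a simulated MI table
#'
#' For each effect the weighted combination of per-iteration pair-type means
#' is computed within every condition (paired across iterations), and
#' combined across conditions assuming independent simulation streams; the
#' contrast standard error follows accordingly.
#'
#' @param mi An `mi_table` (normally from [run_experiment_suite()]).
#' @param margin Monte-Carlo margin in standard-error multiples (default 2).
#' @param experiments Optional subset of experiment ids to evaluate.
#' @return Tibble with one row per effect: `effect`, `experiment`, `type`,
#'   `value`, `se`, `recovered`.
#' @export
effect_contrasts <- function(mi, margin = 2, experiments = NULL) {
  iters <- mi_iterations(mi)
  effs <- tom_effects()
  if (!is.null(experiments)) {
    effs <- Filter(function(e) e$experiment %in% experiments, effs)
  }
  have <- unique(iters[, c("experiment", "condition", "pair_type")])
  rows <- lapply(effs, function(e) {
    need <- e$cells
    key <- paste(e$experiment, need$condition, need$pair_type)
    ok <- key %in% paste(have$experiment, have$condition, have$pair_type)
    if (!all(ok)) {
      stop("MI table is missing cell(s): ",
           paste(key[!ok], collapse = ", "), call. = FALSE)
    }
    value <- 0
    var_sum <- 0
    for (cond in unique(need$condition)) {
      w <- need[need$condition == cond, ]
      sub <- iters[iters$experiment == e$experiment &
                     iters$condition == cond &
                     iters$pair_type %in% w$pair_type, ]
      wide <- tidyr::pivot_wider(sub, id_cols = "iter",
                                 names_from = "pair_type",
                                 values_from = "mi")
      s <- as.matrix(wide[, w$pair_type, drop = FALSE]) %*% w$weight
      value <- value + mean(s)
      var_sum <- var_sum + stats::var(as.vector(s)) / length(s)
    }
    se <- sqrt(var_sum)
    recovered <- if (e$type == "gt") value > margin * se else abs(value) <= margin * se
    tibble::tibble(effect = e$name, experiment = e$experiment, type = e$type,
                   value = value, se = se, recovered = recovered)
  })
  dplyr::bind_rows(rows)
}

#' Check whether a simulation recovers the full behavioural pattern
#'
#' @inheritParams effect_contrasts
#' @return An object of class `effect_pattern`: list with `flags` (named
#'   logical, one per effect), `all_recovered`, the `contrasts` tibble and
#'   the `margin` used.
#' @export
#' @examples
#' \donttest{
#' suite <- run_experiment_suite(model_params(n_iter = 200), seed = 1)
#' check_effect_recovery(suite)$all_recovered
#' }
check_effect_recovery <- function(mi, margin = 2) {
  contrasts <- effect_contrasts(mi, margin = margin)
  flags <- stats::setNames(contrasts$recovered, contrasts$effect)
  structure(
    list(flags = flags, all_recovered = all(flags), contrasts = contrasts,
         margin = margin),
    class = "effect_pattern"
  )
}

#' @export
print.effect_pattern <- function(x, ...) {
  cat(sprintf("<effect_pattern> all_recovered = %s (margin %g SE)\n",
              x$all_recovered, x$margin))
  print(x$contrasts)
  invisible(x)
}

join_behav_mi <- function(behav, mi) {
  behav <- tibble::as_tibble(behav)
  summ <- if (inherits(mi, "mi_table")) mi$summary else tibble::as_tibble(mi)
  stopifnot(all(c("experiment", "condition", "pair_type", "accuracy") %in%
                  names(behav)))
  merged <- dplyr::inner_join(
    behav, summ, by = c("experiment", "condition", "pair_type"))
  key <- function(d) paste(d$experiment, d$condition, d$pair_type)
  lost_b <- setdiff(key(behav), key(merged))
  lost_m <- setdiff(key(summ), key(merged))
  if (length(lost_b) > 0L || length(lost_m) > 0L) {
    stop("behavioural and model rows do not align; unmatched key(s): ",
         paste(unique(c(lost_b, lost_m)), collapse = ", "), call. = FALSE)
  }
  merged
}

#' Fit group-mean accuracy on the model's memory index
#'
#' Ordinary least-squares fit of group-averaged accuracy (percent) on the
#' condition-level mean MI, one observation per (experiment, condition,
#' pair_type) cell. Reported as explained variance and the overall F-test
#' p-value.
#'
#' @param behav Tibble of group means with columns `experiment`, `condition`,
#'   `pair_type`, `accuracy` (percent).
#' @param mi An `mi_table` or its summary tibble (needs `mean_mi`).
#' @return An object of class `tom_fit` with `method = "glm"`, `r2`,
#'   `p_value`, `coefficients`, `n` and the underlying `model`.
#' @export
fit_glm <- function(behav, mi) {
  merged <- join_behav_mi(behav, mi)
  model <- stats::lm(accuracy ~ mean_mi, data = merged)
  s <- summary(model)
  f <- s$fstatistic
  structure(
    list(method = "glm", r2 = unname(s$r.squared),
         p_value = unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE)),
         coefficients = stats::coef(model), n = nrow(merged), model = model),
    class = "tom_fit"
  )
}

#' Mixed-model fit with a random grouping intercept
#'
#' Linear mixed fit of group accuracy on mean MI with a random intercept per
#' grouping level (experiment by default, sequence when per-sequence means
#' are supplied). The reported explained variance is the conditional R\eqn{^2}
#' (fixed plus random components over total variance); the p-value is the
#' Satterthwaite test of the fixed MI slope.
#'
#' @inheritParams fit_glm
#' @param grouping Name of the grouping column in `behav` (default
#'   `"experiment"`).
#' @return A `tom_fit` with `method = "glmm"`, plus the random-intercept
#'   standard deviation `re_sd` and residual standard deviation `resid_sd`.
#' @export
fit_glmm <- function(behav, mi, grouping = "experiment") {
  merged <- join_behav_mi(behav, mi)
  if (!grouping %in% names(merged)) {
    stop(sprintf("grouping column `%s` not found", grouping), call. = FALSE)
  }
  merged$.grp <- factor(merged[[grouping]])
  if (nlevels(merged$.grp) < 2L) {
    stop("grouping factor has a single level; random intercept is degenerate",
         call. = FALSE)
  }
  model <- lmerTest::lmer(accuracy ~ mean_mi + (1 | .grp), data = merged,
                          REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(model))
  var_re <- sum(vc$vcov[vc$grp != "Residual"])
  var_resid <- vc$vcov[vc$grp == "Residual"]
  var_fixed <- stats::var(as.vector(stats::model.matrix(model) %*%
                                      lme4::fixef(model)))
  r2c <- (var_fixed + var_re) / (var_fixed + var_re + var_resid)
  ct <- stats::coef(summary(model))
  structure(
    list(method = "glmm", r2 = unname(r2c),
         p_value = unname(ct["mean_mi", "Pr(>|t|)"]),
         coefficients = lme4::fixef(model), n = nrow(merged),
         re_sd = sqrt(var_re), resid_sd = sqrt(var_resid), model = model),
    class = "tom_fit"
  )
}

#' @export
print.tom_fit <- function(x, ...) {
  cat(sprintf("<tom_fit> method = %s, R^2 = %.3f, p = %.3g, n = %d\n",
              x$method, x$r2, x$p_value, x$n))
  invisible(x)
}

#' Sweep the drift and reset rates over a grid
#'
#' Runs the full experiment suite at every `(p, lam)` cell with a
#' deterministic per-cell seed derived from the master seed, records the
#' effect-recovery pattern, and — when group behavioural means are supplied —
#' the GLM and GLMM fit statistics. The full grids used in the original
#' analysis are `p = seq(0.01, 0.4, 0.01)` and `lam = seq(0.05, 1, 0.01)`;
#' reduced grids and `n_iter` are supported for quick runs.
#'
#' @param p_grid,lam_grid Strictly increasing numeric grids.
#' @param params Base [model_params()] (its `p`/`lam` are overridden
#'   cell-wise; `n_iter` applies to every cell).
#' @param reference `"first"` or `"last"` reference context.
#' @param behav Optional group-means tibble for [fit_glm()]/[fit_glmm()].
#' @param margin Effect-recovery margin in SE multiples.
#' @param seed Master seed.
#' @return A tibble of class `sweep_grid`, one row per cell: `p`, `lam`,
#'   `all_recovered`, one logical column per effect, and (with `behav`)
#'   `r2_glm`, `p_glm`, `r2_glmm`, `p_glmm`.
#' @export
parameter_sweep <- function(p_grid, lam_grid, params = model_params(),
                            reference = c("first", "last"), behav = NULL,
                            margin = 2, seed = 1L) {
  reference <- match.arg(reference)
  if (length(p_grid) < 1L || length(lam_grid) < 1L) {
    stop("grids must be non-empty", call. = FALSE)
  }
  if (is.unsorted(p_grid, strictly = TRUE) ||
      is.unsorted(lam_grid, strictly = TRUE)) {
    stop("grid axes must be strictly increasing", call. = FALSE)
  }
  seed <- as.integer(seed)
  rows <- vector("list", length(p_grid) * length(lam_grid))
  idx <- 0L
  for (i in seq_along(p_grid)) {
    for (j in seq_along(lam_grid)) {
      idx <- idx + 1L
      cell_params <- model_params(
        n_features = params$n_features, p = p_grid[i], lam = lam_grid[j],
        n_iter = params$n_iter, init_density = params$init_density)
      cell_seed <- (seed + 131L * idx) %% 2147483647L
      mi <- run_experiment_suite(cell_params, reference, seed = cell_seed)
      pat <- check_effect_recovery(mi, margin = margin)
      row <- tibble::tibble(p = p_grid[i], lam = lam_grid[j],
                            all_recovered = pat$all_recovered)
      row <- dplyr::bind_cols(row, tibble::as_tibble(as.list(pat$flags)))
      if (!is.null(behav)) {
        g <- fit_glm(behav, mi)
        m <- fit_glmm(behav, mi)
        row$r2_glm <- g$r2
        row$p_glm <- g$p_value
        row$r2_glmm <- m$r2
        row$p_glmm <- m$p_value
      }
      rows[[idx]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_grid", class(out))
  attr(out, "reference") <- reference
  attr(out, "seed") <- seed
  out
}
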