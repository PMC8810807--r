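#' @title Synthetic subject-level recency-judgment data
#'
#' @description
#' The generator produces per-subject, per-sequence binomial correctness
#' counts with the statistical structure the analysis layers assume: every
#' design cell has a true accuracy probability, subjects differ by a random
#' intercept on the logit scale (which keeps probabilities bounded), and
#' trial counts follow the design's pair counts times the number of
#' sequences. Presets ship for all four experiments with accuracy patterns
#' whose signs and rough magnitudes follow the group-level behavioural
#' findings; the magnitudes are illustrative settings of the generator, not
#' estimates. No item effects are modelled.
#'
#' @name synthetic-behaviour
NULL

preset_cells <- function(preset) {
  t_ <- function(...) {
    m <- matrix(c(...), ncol = 5, byrow = TRUE)
    tibble::tibble(experiment = as.integer(m[, 1]), condition = m[, 2],
                   pair_type = m[, 3], prob = as.numeric(m[, 4]),
                   trials_per_seq = as.integer(m[, 5]))
  }
  switch(
    preset,
    exp1 = list(
      cells = t_(1, "boundary", "within", 0.760, 6,
                 1, "boundary", "across", 0.640, 5,
                 1, "no_boundary", "within", 0.715, 6,
                 1, "no_boundary", "across", 0.695, 5),
      n_subjects = 26L, n_sequences = 7L),
    exp1_primacy = list(
      cells = t_(1, "boundary", "early", 0.780, 3,
                 1, "boundary", "late", 0.740, 3,
                 1, "no_boundary", "early", 0.780, 3,
                 1, "no_boundary", "late", 0.685, 3),
      n_subjects = 26L, n_sequences = 7L),
    exp2 = list(
      cells = t_(2, "standard", "within_lag1", 0.820, 9,
                 2, "standard", "across_lag1", 0.600, 4,
                 2, "standard", "across_lag3", 0.700, 4),
      n_subjects = 27L, n_sequences = 14L),
    exp3 = list(
      cells = t_(3, "event4", "pairtype1", 0.720, 3,
                 3, "event4", "pairtype2", 0.720, 3,
                 3, "event4", "pairtype3", 0.680, 4,
                 3, "event6", "pairtype1", 0.720, 3,
                 3, "event6", "pairtype2", 0.675, 3,
                 3, "event6", "pairtype3", 0.584, 4),
      n_subjects = 32L, n_sequences = 7L),
    exp4 = list(
      cells = t_(4, "schedule_336", "within_early", 0.750, 3,
                 4, "schedule_336", "within_late", 0.718, 3,
                 4, "schedule_336", "across_early", 0.700, 3,
                 4, "schedule_336", "across_late", 0.647, 2,
                 4, "schedule_336", "across_long", 0.715, 5,
                 4, "schedule_633", "within_early", 0.750, 3,
                 4, "schedule_633", "within_late", 0.718, 3,
                 4, "schedule_633", "across_early", 0.700, 2,
                 4, "schedule_633", "across_late", 0.647, 3,
                 4, "schedule_633", "across_long", 0.715, 5),
      n_subjects = 30L, n_sequences = 7L),
    null = list(
      cells = t_(1, "null", "a", 0.700, 6,
                 1, "null", "b", 0.700, 6),
      n_subjects = 26L, n_sequences = 7L),
    stop(sprintf("unknown preset \"%s\"", preset), call. = FALSE)
  )
}

#' Configure the synthetic-behaviour generator
#'
#' @param preset One of `"exp1"`, `"exp1_primacy"`, `"exp2"`, `"exp3"`,
#'   `"exp4"`, `"null"` (two identical cells, for calibration checks), or
#'   `"custom"` with an explicit `cells` table.
#' @param cells For `preset = "custom"`: tibble with columns `experiment`,
#'   `condition`, `pair_type`, `prob` (true accuracy in (0,1)) and
#'   `trials_per_seq`.
#' @param n_subjects,n_sequences Override the preset's sample sizes.
#' @param sd_logit Subject random-intercept SD on the logit scale
#'   (default 0.5).
#' @return An object of class `tcr_effect_config`.
#' @export
effect_config <- function(preset = "exp1", cells = NULL, n_subjects = NULL,
                          n_sequences = NULL, sd_logit = 0.5) {
  if (identical(preset, "custom")) {
    if (is.null(cells)) stop("`cells` required for a custom preset",
                             call. = FALSE)
    base <- list(cells = tibble::as_tibble(cells),
                 n_subjects = 20L, n_sequences = 7L)
  } else {
    base <- preset_cells(preset)
  }
  if (!is.null(n_subjects)) base$n_subjects <- as.integer(n_subjects)
  if (!is.null(n_sequences)) base$n_sequences <- as.integer(n_sequences)
  if (base$n_subjects < 1L || base$n_sequences < 1L) {
    stop("subject and sequence counts must be >= 1", call. = FALSE)
  }
  if (any(base$cells$prob <= 0 | base$cells$prob >= 1)) {
    stop("cell probabilities must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(base$cells$trials_per_seq < 1L)) {
    stop("`trials_per_seq` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(sd_logit) || sd_logit < 0) {
    stop("`sd_logit` must be >= 0", call. = FALSE)
  }
  structure(
    list(preset = preset, cells = base$cells, n_subjects = base$n_subjects,
         n_sequences = base$n_sequences, sd_logit = sd_logit),
    class = "tcr_effect_config"
  )
}

#' @export
print.tcr_effect_config <- function(x, ...) {
  cat(sprintf("<tcr_effect_config> preset = %s, %d subjects x %d sequences, sd_logit = %g\n",
              x$preset, x$n_subjects, x$n_sequences, x$sd_logit))
  print(x$cells)
  invisible(x)
}

#' Generate a synthetic subject accuracy table
#'
#' Each subject draws a logit-scale intercept from `N(0, sd_logit^2)`; per
#' cell and sequence, correct counts are binomial with probability
#' `plogis(qlogis(prob) + intercept)`.
#'
#' @param config An [effect_config()] object.
#' @param seed Optional integer seed.
#' @return Tidy tibble with columns `subject_id`, `experiment`,
#'   `sequence_id`, `condition`, `pair_type`, `n_trials`, `n_correct`.
#' @export
#' @examples
#' generate_subjects(effect_config("exp1"), seed = 1)
generate_subjects <- function(config, seed = NULL) {
  stopifnot(inherits(config, "tcr_effect_config"))
  if (!is.null(seed)) set.seed(seed)
  intercepts <- stats::rnorm(config$n_subjects, 0, config$sd_logit)
  grid <- tidyr::expand_grid(
    subject_id = seq_len(config$n_subjects),
    sequence_id = seq_len(config$n_sequences),
    config$cells
  )
  p_subj <- stats::plogis(stats::qlogis(grid$prob) +
                            intercepts[grid$subject_id])
  grid$n_trials <- grid$trials_per_seq
  grid$n_correct <- stats::rbinom(nrow(grid), grid$n_trials, p_subj)
  grid[, c("subject_id", "experiment", "sequence_id", "condition",
           "pair_type", "n_trials", "n_correct")]
}

#' Generate behaviour coupled to model outputs
#'
#' Maps each cell's mean memory index through an affine link
#' `prob = intercept + slope * mean_mi` and then samples subjects as in
#' [generate_subjects()], closing the loop for end-to-end recovery tests of
#' the fitting layer.
#'
#' @param mi An `mi_table` (its summary provides the cells and mean MI).
#' @param intercept,slope Affine link coefficients; every cell probability
#'   must land strictly inside (0, 1).
#' @param n_subjects,n_sequences,trials_per_seq,sd_logit Generator settings.
#' @param seed Optional integer seed.
#' @return A subject accuracy table as in [generate_subjects()].
#' @export
model_coupled_generate <- function(mi, intercept = 0.6, slope = 1,
                                   n_subjects = 30L, n_sequences = 7L,
                                   trials_per_seq = 4L, sd_logit = 0.5,
                                   seed = NULL) {
  summ <- if (inherits(mi, "mi_table")) mi$summary else tibble::as_tibble(mi)
  prob <- intercept + slope * summ$mean_mi
  if (any(prob <= 0 | prob >= 1)) {
    stop("link maps some cell MI outside (0, 1); adjust intercept/slope",
         call. = FALSE)
  }
  cells <- tibble::tibble(
    experiment = summ$experiment, condition = summ$condition,
    pair_type = summ$pair_type, prob = prob,
    trials_per_seq = as.integer(trials_per_seq))
  config <- effect_config("custom", cells = cells, n_subjects = n_subjects,
                          n_sequences = n_sequences, sd_logit = sd_logit)
  generate_subjects(config, seed = seed)
}

#' Synthetic group means for all four experiments
#'
#' Generates every experiment preset at its study sample size and pools the
#' tables to cell-level group means — the synthetic stand-in for the
#' deposited group-averaged behavioural results used when fitting model
#' outputs.
#'
#' @param seed Integer seed (per-experiment seeds are derived from it).
#' @param sd_logit Subject heterogeneity passed to each preset.
#' @return Tibble of group means (see [group_means()]).
#' @export
synthetic_behaviour_means <- function(seed = 1L, sd_logit = 0.5) {
  seed <- as.integer(seed)
  tables <- lapply(seq_along(c("exp1", "exp2", "exp3", "exp4")), function(i) {
    preset <- c("exp1", "exp2", "exp3", "exp4")[i]
    generate_subjects(effect_config(preset, sd_logit = sd_logit),
                      seed = (seed + 977L * i) %% 2147483647L)
  })
  dplyr::bind_rows(lapply(tables, group_means))
}
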