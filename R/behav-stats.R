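#' @title Repeated-measures test battery for recency-judgment accuracy
#'
#' @description
#' Subject-level accuracy tables are analysed the way the behavioural
#' experiments were: accuracies are pooled within subject across sequences
#' first, then fully-within repeated-measures ANOVAs (with Greenhouse-Geisser
#' correction whenever an effect has more than one numerator degree of
#' freedom), two-sided paired t-tests with 95% confidence intervals, and
#' Benjamini-Hochberg FDR correction across planned contrasts. Effect sizes
#' are generalized eta squared, reported in percent.
#'
#' @name behavioural-stats
NULL

#' Paired t-test on per-subject accuracies
#'
#' @param a,b Numeric vectors of per-subject accuracies, paired by position.
#' @param alternative `"two.sided"` (default), `"greater"` (a > b) or
#'   `"less"`.
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_diff`,
#'   `ci_low`, `ci_high`, `alternative`.
#' @export
#' @examples
#' paired_t(c(80, 75, 90, 85), c(70, 72, 80, 79))
paired_t <- function(a, b, alternative = c("two.sided", "greater", "less"),
                     conf_level = 0.95) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) {
    stop("`a` and `b` must have the same length (paired by subject)",
         call. = FALSE)
  }
  if (length(a) < 2L) {
    stop("need at least 2 paired observations", call. = FALSE)
  }
  d <- a - b
  if (stats::sd(d) == 0) {
    stop("zero variance of paired differences; t statistic undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = alternative,
                      conf.level = conf_level)
  tibble::tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, mean_diff = unname(tt$estimate),
    ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
    alternative = alternative
  )
}

#' Benjamini-Hochberg FDR correction
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q FDR threshold (default 0.05).
#' @return Tibble with `p`, `p_adjusted` (BH step-up) and `significant`
#'   (`p_adjusted <= q`). Empty input yields an empty tibble.
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (length(p) == 0L) {
    return(tibble::tibble(p = numeric(0), p_adjusted = numeric(0),
                          significant = logical(0)))
  }
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_adjusted = adj, significant = adj <= q)
}

#' Pool a subject table to per-subject cell accuracies
#'
#' Accepts either aggregated rows (`n_trials`, `n_correct`) or trial-level
#' rows (`correct` 0/1) and pools within subject across sequences: the
#' subject's cell accuracy is 100 * total correct / total trials.
#'
#' @param table Subject accuracy table with columns `subject_id` and the
#'   cell columns in `by`, plus `n_trials`/`n_correct` or `correct`.
#' @param by Cell-defining columns (default experiment, condition,
#'   pair_type; columns absent from `table` are ignored).
#' @return Tibble of subject x cell accuracies (percent).
#' @export
subject_accuracy <- function(table,
                             by = c("experiment", "condition", "pair_type")) {
  table <- tibble::as_tibble(table)
  if (!"subject_id" %in% names(table)) {
    stop("table must have a `subject_id` column", call. = FALSE)
  }
  if ("correct" %in% names(table) && !"n_correct" %in% names(table)) {
    table$n_trials <- 1L
    table$n_correct <- as.integer(table$correct)
  }
  if (!all(c("n_trials", "n_correct") %in% names(table))) {
    if ("accuracy" %in% names(table)) {
      by <- intersect(by, names(table))
      return(dplyr::summarise(
        dplyr::group_by(table, .data$subject_id, !!!rlang::syms(by)),
        accuracy = mean(.data$accuracy), .groups = "drop"))
    }
    stop("table must have `n_trials`/`n_correct`, trial-level `correct`, or `accuracy`",
         call. = FALSE)
  }
  if (any(table$n_correct < 0 | table$n_correct > table$n_trials)) {
    stop("`n_correct` must lie in [0, n_trials]", call. = FALSE)
  }
  by <- intersect(by, names(table))
  dplyr::summarise(
    dplyr::group_by(table, .data$subject_id,
                    !!!rlang::syms(by)),
    accuracy = 100 * sum(.data$n_correct) / sum(.data$n_trials),
    .groups = "drop"
  )
}

#' Group-mean accuracy per design cell
#'
#' Subject-first pooling: each subject's cell accuracy is computed with
#' [subject_accuracy()], then averaged across subjects.
#'
#' @inheritParams subject_accuracy
#' @return Tibble of cell-level `accuracy` (percent) and `n_subjects`,
#'   suitable as the behavioural side of [fit_glm()]/[fit_glmm()].
#' @export
group_means <- function(table,
                        by = c("experiment", "condition", "pair_type")) {
  subj <- subject_accuracy(table, by = by)
  by <- intersect(by, names(subj))
  dplyr::summarise(
    dplyr::group_by(subj, !!!rlang::syms(by)),
    accuracy = mean(.data$accuracy),
    n_subjects = dplyr::n_distinct(.data$subject_id),
    .groups = "drop"
  )
}

# orthonormal Helmert-style contrast basis for k levels (k x (k-1))
orthonormal_contrasts <- function(k) {
  h <- stats::contr.helmert(k)
  h %*% diag(1 / sqrt(colSums(h^2)), ncol(h), ncol(h))
}

# Greenhouse-Geisser epsilon for an effect subspace spanned by C (cells x df)
gg_epsilon <- function(sigma, C) {
  e <- t(C) %*% sigma %*% C
  df <- ncol(C)
  (sum(diag(e)))^2 / (df * sum(e^2))
}

#' Repeated-measures ANOVA on a subject accuracy table
#'
#' Fully-within design with one or two factors. Accuracies are pooled within
#' subject first; the design must be completely crossed for every subject.
#' Sums of squares come from the classic subject-stratified decomposition
#' (via [stats::aov()] error strata); whenever an effect has more than one
#' numerator degree of freedom its degrees of freedom are multiplied by the
#' Greenhouse-Geisser epsilon computed from the subject covariance of the
#' cell scores, and the reported p-value uses the corrected df. Effect size
#' is generalized eta squared (percent): the effect sum of squares over the
#' effect plus all subject-level error sums of squares.
#'
#' @param table Subject accuracy table (see [subject_accuracy()]).
#' @param within Character vector of 1 or 2 within-subject factor columns.
#' @param dv Ignored unless the table already carries an `accuracy` column
#'   and no trial counts; name of that column (default `"accuracy"`).
#' @return Tibble with one row per effect: `effect`, `F`, `df1`, `df2`,
#'   `epsilon`, `df1_corr`, `df2_corr`, `p_value`, `eta_sq_pct`.
#' @export
rm_anova <- function(table, within, dv = "accuracy") {
  if (!length(within) %in% 1:2) {
    stop("`within` must name 1 or 2 factor columns", call. = FALSE)
  }
  table <- tibble::as_tibble(table)
  if (all(c("n_trials", "n_correct") %in% names(table)) ||
      "correct" %in% names(table)) {
    subj <- subject_accuracy(table, by = within)
    dv <- "accuracy"
  } else {
    if (!dv %in% names(table)) {
      stop(sprintf("column `%s` not found", dv), call. = FALSE)
    }
    subj <- dplyr::summarise(
      dplyr::group_by(table, .data$subject_id, !!!rlang::syms(within)),
      accuracy = mean(.data[[dv]]), .groups = "drop")
    dv <- "accuracy"
  }
  for (w in within) subj[[w]] <- factor(subj[[w]])
  # completeness: every subject must have every cell exactly once
  cells <- do.call(interaction, c(subj[within], drop = FALSE))
  tab <- table(subj$subject_id, cells)
  if (any(tab != 1L)) {
    gaps <- which(tab != 1L, arr.ind = TRUE)
    msg <- apply(gaps, 1L, function(g) {
      sprintf("subject %s x cell %s", rownames(tab)[g[1]], colnames(tab)[g[2]])
    })
    stop("incomplete within-subject design: ", paste(msg, collapse = ", "),
         call. = FALSE)
  }
  subj$subject_id <- factor(subj$subject_id)
  n <- nlevels(subj$subject_id)

  if (length(within) == 1L) {
    a <- within[1]
    ka <- nlevels(subj[[a]])
    form <- stats::as.formula(
      sprintf("%s ~ %s + Error(subject_id/%s)", dv, a, a))
  } else {
    a <- within[1]; b <- within[2]
    ka <- nlevels(subj[[a]]); kb <- nlevels(subj[[b]])
    form <- stats::as.formula(
      sprintf("%s ~ %s * %s + Error(subject_id/(%s * %s))", dv, a, b, a, b))
  }
  fit <- stats::aov(form, data = subj)
  ss <- lapply(summary(fit), function(s) {
    d <- s[[1]]
    stats::setNames(
      data.frame(term = trimws(rownames(d)), df = d$Df, ss = d$`Sum Sq`),
      c("term", "df", "ss"))
  })
  flat <- do.call(rbind, ss)
  get_ss <- function(term) flat$ss[flat$term == term][1]
  get_df <- function(term) flat$df[flat$term == term][1]
  ss_subj <- flat$ss[grepl("Residuals", flat$term)][1] # subject stratum
  err_ss <- flat$ss[grepl("Residuals", flat$term)][-1] # within strata errors
  denom_g <- sum(c(ss_subj, err_ss))

  # subject x cell matrix in the factor-crossing order used for epsilon
  ord <- do.call(order, subj[c("subject_id", within)])
  scores <- matrix(subj[[dv]][ord], nrow = n, byrow = TRUE)
  sigma <- stats::cov(scores)

  if (length(within) == 1L) {
    effects <- list(list(name = a, C = orthonormal_contrasts(ka),
                         err = sprintf("subject_id:%s", a)))
  } else {
    ca <- orthonormal_contrasts(ka); cb <- orthonormal_contrasts(kb)
    ua <- rep(1 / sqrt(ka), ka); ub <- rep(1 / sqrt(kb), kb)
    # cell order from the ordering above: first factor varies slowest
    effects <- list(
      list(name = a, C = kronecker(ca, matrix(ub)),
           err = sprintf("subject_id:%s", a)),
      list(name = b, C = kronecker(matrix(ua), cb),
           err = sprintf("subject_id:%s", b)),
      list(name = paste0(a, ":", b), C = kronecker(ca, cb),
           err = sprintf("subject_id:%s:%s", a, b))
    )
  }

  rows <- lapply(effects, function(e) {
    ss_eff <- get_ss(e$name)
    df1 <- get_df(e$name)
    # the error term lives in the same stratum as the effect
    stratum <- vapply(ss, function(d) e$name %in% d$term, logical(1))
    d <- ss[[which(stratum)[1]]]
    ss_err <- d$ss[d$term == "Residuals"]
    df2 <- d$df[d$term == "Residuals"]
    # exactly additive data has zero effect and error SS in its stratum
    # (up to floating-point dust); report F = 0 rather than 0/0
    ss_scale <- sum(abs(flat$ss))
    f <- if (ss_eff <= 1e-10 * max(ss_scale, 1e-300)) 0
         else (ss_eff / df1) / (ss_err / df2)
    eps <- if (df1 > 1L) gg_epsilon(sigma, e$C) else 1
    df1c <- eps * df1
    df2c <- eps * df2
    tibble::tibble(
      effect = e$name, F = f, df1 = df1, df2 = df2, epsilon = eps,
      df1_corr = df1c, df2_corr = df2c,
      p_value = stats::pf(f, df1c, df2c, lower.tail = FALSE),
      eta_sq_pct = 100 * ss_eff / (ss_eff + denom_g)
    )
  })
  dplyr::bind_rows(rows)
}

#' Early/late primacy follow-up for the six-item-event experiment
#'
#' Runs the 2 (condition: boundary vs no-boundary) x 2 (position: early vs
#' late within-event pairs) repeated-measures ANOVA together with the four
#' follow-up paired contrasts: early vs late inside each condition and
#' boundary vs no-boundary at each position.
#'
#' @param table Subject table with columns `subject_id`, `condition`
#'   (`"boundary"`/`"no_boundary"`), a position column (`position`, or
#'   `pair_type` holding `"early"`/`"late"`), and counts or accuracies.
#' @return List with `anova` (the [rm_anova()] table) and `contrasts` (four
#'   paired t rows with FDR-adjusted p-values).
#' @export
primacy_followup <- function(table) {
  table <- tibble::as_tibble(table)
  if (!"position" %in% names(table)) {
    if ("pair_type" %in% names(table) &&
        all(table$pair_type %in% c("early", "late"))) {
      table$position <- table$pair_type
    } else {
      stop("table needs a `position` column with values early/late",
           call. = FALSE)
    }
  }
  anova <- rm_anova(table, within = c("condition", "position"))
  subj <- subject_accuracy(table, by = c("condition", "position"))
  wide <- tidyr::pivot_wider(subj, id_cols = "subject_id",
                             names_from = c("condition", "position"),
                             values_from = "accuracy")
  ct <- dplyr::bind_rows(
    dplyr::mutate(paired_t(wide$boundary_early, wide$boundary_late),
                  contrast = "early_vs_late_boundary"),
    dplyr::mutate(paired_t(wide$no_boundary_early, wide$no_boundary_late),
                  contrast = "early_vs_late_no_boundary"),
    dplyr::mutate(paired_t(wide$boundary_early, wide$no_boundary_early),
                  contrast = "boundary_vs_no_boundary_early"),
    dplyr::mutate(paired_t(wide$boundary_late, wide$no_boundary_late),
                  contrast = "boundary_vs_no_boundary_late")
  )
  fdr <- fdr_correct(ct$p_value)
  ct$p_adjusted <- fdr$p_adjusted
  ct$significant <- fdr$significant
  list(anova = anova, contrasts = ct)
}

#' Run an experiment's published test battery on a subject table
#'
#' Dispatches to the ANOVA and planned-contrast set matching the experiment:
#' Experiment 1, 2x2 condition-by-list-position ANOVA with three contrasts;
#' Experiment 2, one-way pair-type ANOVA (Greenhouse-Geisser) with three
#' contrasts; Experiment 3, 2x3 condition-by-pair-type ANOVA with the three
#' per-pair-type condition contrasts; Experiment 4, 2x2 pair-type-by-position
#' ANOVA on the short-lag pairs with the two position contrasts plus the
#' one-tailed long-vs-short-lag comparison. Contrast p-values are FDR
#' corrected within the battery.
#'
#' @param table Subject accuracy table for a single experiment.
#' @param experiment Experiment id in 1-4.
#' @return List with `anova` and `contrasts` tibbles.
#' @export
experiment_stats <- function(table, experiment) {
  experiment <- as.integer(experiment)
  table <- tibble::as_tibble(table)
  contrast_rows <- function(specs, wide) {
    dplyr::bind_rows(lapply(specs, function(s) {
      dplyr::mutate(
        paired_t(wide[[s[2]]], wide[[s[3]]],
                 alternative = if (length(s) > 3) s[4] else "two.sided"),
        contrast = s[1])
    }))
  }
  if (experiment == 1L) {
    anova <- rm_anova(table, within = c("condition", "pair_type"))
    subj <- subject_accuracy(table)
    wide <- tidyr::pivot_wider(subj, id_cols = "subject_id",
                               names_from = c("condition", "pair_type"),
                               values_from = "accuracy")
    ct <- contrast_rows(list(
      c("within_vs_across_boundary", "boundary_within", "boundary_across"),
      c("within_boundary_vs_no_boundary", "boundary_within",
        "no_boundary_within"),
      c("across_boundary_vs_no_boundary", "boundary_across",
        "no_boundary_across")), wide)
  } else if (experiment == 2L) {
    anova <- rm_anova(table, within = "pair_type")
    subj <- subject_accuracy(table)
    wide <- tidyr::pivot_wider(subj, id_cols = "subject_id",
                               names_from = "pair_type",
                               values_from = "accuracy")
    ct <- contrast_rows(list(
      c("within_lag1_vs_across_lag1", "within_lag1", "across_lag1"),
      c("across_lag3_vs_across_lag1", "across_lag3", "across_lag1"),
      c("within_lag1_vs_across_lag3", "within_lag1", "across_lag3")), wide)
  } else if (experiment == 3L) {
    anova <- rm_anova(table, within = c("condition", "pair_type"))
    subj <- subject_accuracy(table)
    wide <- tidyr::pivot_wider(subj, id_cols = "subject_id",
                               names_from = c("condition", "pair_type"),
                               values_from = "accuracy")
    ct <- contrast_rows(list(
      c("pairtype1_event4_vs_event6", "event4_pairtype1", "event6_pairtype1"),
      c("pairtype2_event4_vs_event6", "event4_pairtype2", "event6_pairtype2"),
      c("pairtype3_event4_vs_event6", "event4_pairtype3", "event6_pairtype3")),
      wide)
  } else if (experiment == 4L) {
    short <- table[table$pair_type %in% c("within_early", "within_late",
                                          "across_early", "across_late"), ]
    short$kind <- ifelse(grepl("^within", short$pair_type), "within", "across")
    short$position <- ifelse(grepl("early$", short$pair_type), "early", "late")
    anova <- rm_anova(short, within = c("kind", "position"))
    subj <- subject_accuracy(short, by = c("kind", "position"))
    wide <- tidyr::pivot_wider(subj, id_cols = "subject_id",
                               names_from = c("kind", "position"),
                               values_from = "accuracy")
    ct <- contrast_rows(list(
      c("within_early_vs_late", "within_early", "within_late"),
      c("across_early_vs_late", "across_early", "across_late")), wide)
    subj_all <- subject_accuracy(table, by = "pair_type")
    wide_all <- tidyr::pivot_wider(subj_all, id_cols = "subject_id",
                                   names_from = "pair_type",
                                   values_from = "accuracy")
    short_acc <- (wide_all$across_early + wide_all$across_late) / 2
    ct <- dplyr::bind_rows(
      ct,
      dplyr::mutate(paired_t(wide_all$across_long, short_acc,
                             alternative = "greater"),
                    contrast = "across_long_vs_short_lag"))
  } else {
    stop("`experiment` must be 1, 2, 3 or 4", call. = FALSE)
  }
  fdr <- fdr_correct(ct$p_value)
  ct$p_adjusted <- fdr$p_adjusted
  ct$significant <- fdr$significant
  list(anova = anova, contrasts = ct)
}
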