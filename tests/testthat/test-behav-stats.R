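test_that("paired t matches the closed form and enforces its preconditions", {
  a <- c(80, 76, 71, 68)
  b <- a - c(1, 2, 3, 6) # differences 1, 2, 3, 6: t = 3 / (sqrt(14/3)/2)
  res <- paired_t(a, b)
  expect_equal(res$statistic, 3 / (sqrt(14 / 3) / 2), tolerance = 1e-12)
  expect_equal(res$df, 3)
  oracle <- brute_paired_t(a, b)
  expect_equal(res$statistic, oracle$t)
  expect_equal(res$p_value, oracle$p)
  # 95% CI of the mean difference by the closed form
  half <- qt(0.975, 3) * sd(a - b) / 2
  expect_equal(res$ci_low, 3 - half, tolerance = 1e-10)
  expect_equal(res$ci_high, 3 + half, tolerance = 1e-10)

  expect_error(paired_t(a, a), "zero variance")
  expect_error(paired_t(1, 2), "at least 2")
  expect_error(paired_t(a, b[1:3]), "same length")

  one_sided <- paired_t(a, b, alternative = "greater")
  expect_equal(one_sided$p_value, res$p_value / 2, tolerance = 1e-12)
})

test_that("BH step-up matches direct enumeration and the worked cases", {
  expect_true(fdr_correct(0.01, q = 0.05)$significant)
  r <- fdr_correct(c(0.01, 0.02, 0.04), q = 0.05)
  expect_true(all(r$significant)) # largest p <= (3/3) * 0.05
  expect_false(any(fdr_correct(rep(1, 5))$significant))
  expect_equal(nrow(fdr_correct(numeric(0))), 0)

  set.seed(91)
  for (i in 1:10) {
    p <- runif(12)^2
    expect_equal(fdr_correct(p)$significant, brute_bh(p, 0.05))
  }
})

test_that("lowering a p-value never removes a BH discovery", {
  set.seed(92)
  for (i in 1:10) {
    p <- runif(10)
    before <- fdr_correct(p)$significant
    j <- sample(10, 1)
    p2 <- p
    p2[j] <- p[j] * runif(1)
    after <- fdr_correct(p2)$significant
    expect_true(all(after[before]))
  }
})

test_that("two-factor repeated-measures ANOVA matches the brute-force decomposition", {
  # 4-subject 2x2 toy table
  d <- tibble::tibble(
    subject_id = rep(1:4, each = 4),
    condition = rep(rep(c("c1", "c2"), each = 2), 4),
    pair_type = rep(c("t1", "t2"), 8),
    accuracy = c(70, 60, 65, 57, 80, 69, 72, 70, 66, 59, 62, 55, 75, 66, 71, 64))
  res <- rm_anova(d, within = c("condition", "pair_type"))
  oracle <- brute_rm_anova_2w(d$subject_id, d$condition, d$pair_type,
                              d$accuracy)
  expect_equal(res$F[res$effect == "condition"], oracle$F_a, tolerance = 1e-10)
  expect_equal(res$F[res$effect == "pair_type"], oracle$F_b, tolerance = 1e-10)
  expect_equal(res$F[res$effect == "condition:pair_type"], oracle$F_ab,
               tolerance = 1e-10)
  # generalized eta squared from the same decomposition
  ss <- oracle$ss
  eta_int <- 100 * ss$ab / (ss$ab + ss$s + ss$sa + ss$sb + ss$sab)
  expect_equal(res$eta_sq_pct[res$effect == "condition:pair_type"], eta_int,
               tolerance = 1e-10)

  # larger randomized tables
  for (seed in c(101, 202)) {
    rt <- random_2x2_table(n = 10, seed = seed)
    res2 <- rm_anova(rt, within = c("condition", "pair_type"))
    o2 <- brute_rm_anova_2w(rt$subject_id, rt$condition, rt$pair_type,
                            rt$accuracy)
    expect_equal(res2$F, c(o2$F_a, o2$F_b, o2$F_ab), tolerance = 1e-9)
  }
})

test_that("for two-level factors the ANOVA F is the square of the paired t", {
  for (seed in c(7, 8, 9)) {
    d <- random_2x2_table(n = 9, seed = seed)
    one <- d[d$condition == "c1", ]
    res <- rm_anova(one, within = "pair_type")
    wide <- tidyr::pivot_wider(one, id_cols = "subject_id",
                               names_from = "pair_type",
                               values_from = "accuracy")
    t_res <- paired_t(wide$t1, wide$t2)
    expect_equal(res$F[1], t_res$statistic^2, tolerance = 1e-10)
    expect_equal(res$p_value[1], t_res$p_value, tolerance = 1e-10)
  }
})

test_that("perfectly additive data yields a zero interaction F", {
  d <- tidyr::expand_grid(subject_id = 1:6, condition = c("c1", "c2"),
                          pair_type = c("t1", "t2"))
  subj_eff <- c(0, 2, -1, 3, 1, -2)
  d$accuracy <- 70 + subj_eff[d$subject_id] +
    3 * (d$condition == "c2") + 5 * (d$pair_type == "t2")
  res <- rm_anova(d, within = c("condition", "pair_type"))
  expect_equal(res$F[res$effect == "condition:pair_type"], 0)
})

test_that("Greenhouse-Geisser correction agrees with the established reference implementation", {
  set.seed(303)
  n <- 14
  d <- tidyr::expand_grid(subject_id = seq_len(n), condition = c("x", "y"),
                          pair_type = c("a", "b", "c"))
  d$accuracy <- rnorm(nrow(d), 70, 8) + 3 * (d$condition == "y") +
    4 * (d$pair_type == "b")
  mine <- rm_anova(d, within = c("condition", "pair_type"))

  cells <- expand.grid(condition = c("x", "y"), pair_type = c("a", "b", "c"))
  Y <- sapply(seq_len(nrow(cells)), function(i) {
    sub <- d[d$condition == cells$condition[i] &
               d$pair_type == cells$pair_type[i], ]
    sub$accuracy[order(sub$subject_id)]
  })
  av <- car::Anova(stats::lm(Y ~ 1), idata = cells,
                   idesign = ~ condition * pair_type, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  u <- s$univariate.tests
  expect_equal(mine$F, unname(u[-1, "F value"]), tolerance = 1e-8)
  adj <- s$pval.adjustments
  expect_equal(mine$epsilon[mine$effect == "pair_type"],
               unname(adj["pair_type", "GG eps"]), tolerance = 1e-8)
  expect_equal(mine$p_value[mine$effect == "pair_type"],
               unname(adj["pair_type", "Pr(>F[GG])"]), tolerance = 1e-8)
  expect_equal(mine$p_value[mine$effect == "condition:pair_type"],
               unname(adj["condition:pair_type", "Pr(>F[GG])"]),
               tolerance = 1e-8)
  # epsilon only shrinks effects with more than one numerator df
  expect_equal(mine$epsilon[mine$effect == "condition"], 1)
  expect_lte(mine$epsilon[mine$effect == "pair_type"], 1)
  expect_gte(mine$epsilon[mine$effect == "pair_type"], 1 / 2)
})

test_that("incomplete within-subject designs are rejected with the gaps named", {
  d <- random_2x2_table(n = 5, seed = 5)
  d <- d[-3, ]
  expect_error(rm_anova(d, within = c("condition", "pair_type")),
               "incomplete within-subject design")
})

test_that("primacy follow-up runs the 2x2 ANOVA plus four paired contrasts", {
  # deterministic table whose interaction contrast averages exactly to zero
  d <- tidyr::expand_grid(subject_id = 1:8,
                          condition = c("boundary", "no_boundary"),
                          position = c("early", "late"))
  subj_eff <- seq(-3.5, 3.5, by = 1)
  jitter <- c(-1.5, -1, -0.5, -0.25, 0.25, 0.5, 1, 1.5) # sums to zero
  d$accuracy <- 75 + subj_eff[d$subject_id] - 4 * (d$position == "late") -
    2 * (d$condition == "no_boundary") +
    jitter[d$subject_id] * (d$condition == "boundary" & d$position == "early") +
    rev(jitter)[d$subject_id] * (d$condition == "no_boundary" &
                                   d$position == "late")
  res <- primacy_followup(d)
  expect_equal(res$anova$F[res$anova$effect == "condition:position"], 0)
  expect_equal(nrow(res$contrasts), 4)
  expect_setequal(
    res$contrasts$contrast,
    c("early_vs_late_boundary", "early_vs_late_no_boundary",
      "boundary_vs_no_boundary_early", "boundary_vs_no_boundary_late"))

  expect_error(primacy_followup(d[, setdiff(names(d), "position")]),
               "position")
})

test_that("a built-in crossover of known size produces interaction F near its analytic expectation", {
  # no subject heterogeneity: the noncentrality of the interaction F is
  # lambda = n * delta^2 / var(contrast); E[F] = (1 + lambda) * df2/(df2 - 2)
  probs <- c(b_early = 0.80, b_late = 0.72, nb_early = 0.78, nb_late = 0.62)
  m <- 21 # trials per cell
  n <- 26
  delta <- 100 * ((probs[1] - probs[2]) - (probs[3] - probs[4]))
  var_contrast <- sum(100^2 * probs * (1 - probs) / m)
  lambda <- n * delta^2 / var_contrast
  e_f <- (1 + lambda) * (n - 1) / (n - 3)
  cells <- tibble::tibble(
    experiment = 1L,
    condition = rep(c("boundary", "no_boundary"), each = 2),
    pair_type = rep(c("early", "late"), 2),
    prob = unname(probs), trials_per_seq = 3L)
  cfg <- effect_config("custom", cells = cells, n_subjects = n,
                       n_sequences = 7, sd_logit = 0)
  reps <- 30
  Fs <- vapply(seq_len(reps), function(i) {
    tab <- generate_subjects(cfg, seed = 5000 + i)
    res <- primacy_followup(tab)
    res$anova$F[res$anova$effect == "condition:position"]
  }, numeric(1))
  mc_se <- sd(Fs) / sqrt(reps)
  expect_lt(abs(mean(Fs) - e_f), max(3 * mc_se, 0.35 * e_f))
})

test_that("each experiment's battery produces its ANOVA and FDR-corrected contrasts", {
  res1 <- experiment_stats(generate_subjects(effect_config("exp1"), seed = 71),
                           1)
  expect_setequal(res1$anova$effect,
                  c("condition", "pair_type", "condition:pair_type"))
  expect_equal(nrow(res1$contrasts), 3)
  expect_true(all(c("p_adjusted", "significant") %in% names(res1$contrasts)))
  # the preset's dual pattern shows up with the published signs
  ct <- res1$contrasts
  expect_gt(ct$statistic[ct$contrast == "within_vs_across_boundary"], 0)
  expect_lt(ct$statistic[ct$contrast == "across_boundary_vs_no_boundary"], 0)

  res2 <- experiment_stats(generate_subjects(effect_config("exp2"), seed = 72),
                           2)
  # one-way with three levels: fractional Greenhouse-Geisser df
  expect_lt(res2$anova$df1_corr, 2)
  expect_gt(res2$anova$df1_corr, 1)

  res4 <- experiment_stats(generate_subjects(effect_config("exp4"), seed = 74),
                           4)
  expect_true("across_long_vs_short_lag" %in% res4$contrasts$contrast)
  expect_equal(
    res4$contrasts$alternative[res4$contrasts$contrast ==
                                 "across_long_vs_short_lag"], "greater")
})
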