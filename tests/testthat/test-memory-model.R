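hand_traj <- function() {
  # 3 time points, 4 features, written out by hand
  contexts <- rbind(
    c(1L, 1L, 0L, 0L), # C1
    c(1L, 0L, 1L, 0L), # C2: dice with C1 = 2*1/(2+2) = 0.5
    c(0L, 0L, 1L, 1L)  # C3: dice with C1 = 0
  )
  structure(list(contexts = contexts, boundary_flags = rep(FALSE, 3)),
            class = "context_trajectory")
}

test_that("memory index equals the hand-computed Dice arithmetic", {
  traj <- hand_traj()
  res <- memory_index(traj, list(pos_early = 2, pos_late = 3))
  expect_equal(res$R1, 0.5)
  expect_equal(res$R2, 0)
  expect_equal(res$d1, 0.5)
  expect_equal(res$d2, 1)
  expect_equal(res$MI, 0.5)
  # identities d = 1 - R and MI = d2 - d1
  expect_equal(res$d1, 1 - res$R1)
  expect_equal(res$MI, res$d2 - res$d1)

  # probing the same time point twice is degenerate: MI = 0
  same <- memory_index(traj, list(pos_early = 2, pos_late = 2))
  expect_equal(same$MI, 0)

  expect_error(memory_index(traj, list(pos_early = 1, pos_late = 9)),
               "outside")
})

test_that("per-step dissimilarity increments telescope to d_u - d_t exactly", {
  set.seed(12)
  traj <- simulate_trajectory(builtin_design(1, "boundary"),
                              model_params(p = 0.05, lam = 0.3))
  d <- 1 - vapply(1:36, function(t) {
    dice_similarity(traj$contexts[t, ], traj$contexts[1, ])
  }, numeric(1))
  for (pair in list(c(2, 9), c(5, 30), c(1, 36))) {
    t <- pair[1]; u <- pair[2]
    expect_equal(sum(diff(d)[t:(u - 1)]), d[u] - d[t], tolerance = 1e-12)
  }
})

test_that("boundary condition yields a within > across memory-index advantage", {
  mi <- simulate_condition(builtin_design(1, "boundary"),
                           model_params(p = 0.02, lam = 0.2, n_iter = 400),
                           seed = 5)
  s <- mi$summary
  w <- s[s$pair_type == "within", ]
  a <- s[s$pair_type == "across", ]
  expect_gt(w$mean_mi - a$mean_mi,
            3 * sqrt(w$se_mi^2 + a$se_mi^2))
})

test_that("with reset disabled the boundary and no-boundary designs coincide in distribution", {
  params <- model_params(p = 0.02, lam = 0, n_iter = 400)
  mi <- bind_mi_tables(list(
    simulate_condition(builtin_design(1, "boundary"), params, seed = 31),
    simulate_condition(builtin_design(1, "no_boundary"), params, seed = 32)
  ))
  ct <- effect_contrasts(mi, experiments = 1)
  matched <- ct[ct$effect %in% c("exp1_within_enhanced",
                                 "exp1_across_impaired"), ]
  expect_true(all(abs(matched$value) < 3 * matched$se))
})

test_that("short-event design orders pair types as within-lag1 > across-lag3 > across-lag1", {
  mi <- simulate_condition(builtin_design(2, "standard"),
                           model_params(p = 0.02, lam = 0.2, n_iter = 400),
                           seed = 6)
  s <- mi$summary
  m <- setNames(s$mean_mi, s$pair_type)
  se <- setNames(s$se_mi, s$pair_type)
  expect_gt(m["within_lag1"] - m["across_lag3"],
            2 * sqrt(se["within_lag1"]^2 + se["across_lag3"]^2))
  expect_gt(m["across_lag3"] - m["across_lag1"],
            2 * sqrt(se["across_lag3"]^2 + se["across_lag1"]^2))
})

test_that("the suite is deterministic under a fixed master seed and stable in sign at low iteration counts", {
  p <- model_params(p = 0.02, lam = 0.2, n_iter = 30)
  s1 <- run_experiment_suite(p, seed = 123)
  s2 <- run_experiment_suite(p, seed = 123)
  expect_identical(s1$summary, s2$summary)
  expect_identical(s1$iterations, s2$iterations)

  # low-iteration runs keep the sign of the principal contrast but with
  # larger uncertainty
  big <- run_experiment_suite(model_params(p = 0.02, lam = 0.2,
                                           n_iter = 300), seed = 9)
  small_ct <- effect_contrasts(s1, experiments = 1)
  big_ct <- effect_contrasts(big, experiments = 1)
  main <- "exp1_boundary_within_gt_across"
  expect_gt(small_ct$value[small_ct$effect == main], 0)
  expect_gt(big_ct$value[big_ct$effect == main], 0)
  expect_gt(small_ct$se[small_ct$effect == main],
            big_ct$se[big_ct$effect == main])
})

test_that("local primacy mechanism: early local positions beat late ones at matched list positions", {
  # the pairs (4,6), (16,18), (28,30) occupy local positions 1-3 of 3-item
  # events in the 3-3-6 schedule but local positions 4-6 of 6-item events in
  # the 6-3-3 schedule; same absolute positions, same boundary count
  pairs <- tibble::tibble(pos_early = c(4L, 16L, 28L),
                          pos_late = c(6L, 18L, 30L),
                          pair_type = "matched")
  early <- experiment_design("early", 36,
                             builtin_design(4, "schedule_336")$boundaries,
                             pairs)
  late <- experiment_design("late", 36,
                            builtin_design(4, "schedule_633")$boundaries,
                            pairs)
  params <- model_params(p = 0.02, lam = 0.2, n_iter = 2000)
  mi_early <- simulate_condition(early, params, seed = 77)$summary
  mi_late <- simulate_condition(late, params, seed = 78)$summary
  se <- sqrt(mi_early$se_mi^2 + mi_late$se_mi^2)
  expect_gt(mi_early$mean_mi - mi_late$mean_mi, 2 * se)
})

test_that("alternative model without boundaries reduces to plain drift at the base rate", {
  d <- toy_design(10)
  set.seed(55)
  alt_traj <- simulate_trajectory_alt(d, alt_params(p_base = 0.03),
                                      model_params())
  set.seed(55)
  base_traj <- simulate_trajectory(d, model_params(p = 0.03))
  expect_identical(alt_traj$contexts, base_traj$contexts)
})

test_that("alternative model flips about 1 element off-boundary and 8 at boundaries", {
  d <- toy_design(3, boundaries = 3)
  set.seed(66)
  n <- 4000
  flips_plain <- numeric(n)
  flips_bound <- numeric(n)
  for (i in seq_len(n)) {
    traj <- simulate_trajectory_alt(d, alt_params(0.01, 0.08), model_params())
    flips_plain[i] <- sum(traj$contexts[2, ] != traj$contexts[1, ])
    flips_bound[i] <- sum(traj$contexts[3, ] != traj$contexts[2, ])
  }
  expect_lt(abs(mean(flips_plain) - 1), 3 * sd(flips_plain) / sqrt(n))
  expect_lt(abs(mean(flips_bound) - 8), 3 * sd(flips_bound) / sqrt(n))
})

test_that("pair similarity under the random-shift model cannot host boundary and distance effects together", {
  mi <- simulate_alternative(builtin_design(2, "standard"), alt_params(),
                             model_params(n_iter = 400),
                             metric = "pair_similarity", seed = 14)
  s <- mi$summary
  m <- setNames(s$mean_mi, s$pair_type)
  se <- setNames(s$se_mi, s$pair_type)
  boundary_effect <- m["within_lag1"] - m["across_lag1"] >
    2 * sqrt(se["within_lag1"]^2 + se["across_lag1"]^2)
  distance_effect <- m["across_lag3"] - m["across_lag1"] >
    2 * sqrt(se["across_lag3"]^2 + se["across_lag1"]^2)
  expect_false(boundary_effect && distance_effect)
  # similarity decays with lag, so the distance effect is the one that fails
  expect_lt(m["across_lag3"], m["across_lag1"])
})
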