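test_that("coverage accounting scores null sets as non-covering", {
  cond <- sim_condition(mu = 0, tau = 0.2, pi_c = 0.5, k = 5, reps = 40,
                        seed = 9)
  res <- evaluate_coverage(cond)
  rows <- res$reps
  # recompute covered from the stored bounds
  manual <- ifelse(rows$status == "null_set", FALSE,
                   rows$lb <= 0.04 & 0.04 <= rows$ub)
  expect_equal(rows$covered, manual)
  # null-set widths are excluded, not zero-filled
  expect_true(all(is.na(rows$width[rows$status == "null_set"])))
  expect_true(all(rows$width[rows$status != "null_set"] >= 0))
  # summary coverage is the mean of per-rep indicators
  for (m in res$methods) {
    expect_equal(res$summary$coverage[res$summary$method == m],
                 mean(rows$covered[rows$method == m]))
  }
  # width wins/losses/ties account for every repetition
  expect_true(all(abs(res$width_wins$a_narrower + res$width_wins$b_narrower +
                        res$width_wins$ties - 1) < 1e-12))
})

test_that("coverage results are reproducible and worker-invariant", {
  cond <- sim_condition(mu = 0, tau = 0.1, pi_c = 0.5, k = 5, reps = 12,
                        seed = 33)
  r1 <- evaluate_coverage(cond, methods = "qprofile")
  r2 <- evaluate_coverage(cond, methods = "qprofile")
  expect_identical(r1$reps, r2$reps)
  r3 <- evaluate_coverage(cond, methods = "qprofile", workers = 2L)
  expect_equal(r1$reps, r3$reps)
})

test_that("zero-cell subsets partition the runs and reweight coverage", {
  cond <- sim_condition(mu = 0, tau = 0.3, pi_c = 0.1, k = 10,
                        group_sizes = 30, reps = 60, seed = 13)
  res <- evaluate_coverage(cond, methods = "qprofile")
  sub <- subset_coverage(res)
  row <- sub[sub$method == "qprofile" & sub$flag == "any_zero", ]
  n_zero <- sum(res$flags$any_zero)
  expect_equal(row$prop_in_subset, n_zero / 60)
  # overall coverage is the mixture of the two subsets
  overall <- res$summary$coverage
  mix <- row$prop_in_subset * row$coverage_in_subset +
    (1 - row$prop_in_subset) * row$coverage_outside
  expect_equal(mix, overall)
  # rare events + small samples: the zero subset dominates
  expect_gt(row$prop_in_subset, 0.5)

  # balanced outcome at the standard sizes: zero cells are rare
  cond2 <- sim_condition(mu = 0, tau = 0.2, pi_c = 0.5, k = 10, reps = 60,
                         seed = 14)
  res2 <- evaluate_coverage(cond2, methods = "qprofile")
  expect_lt(mean(res2$flags$any_zero), 0.15)
})

test_that("generalized-Q replicates follow chi-square in ideal-normal mode", {
  cond <- sim_condition(mu = 0, tau = 0.4, pi_c = 0.5, k = 10, reps = 2000,
                        seed = 15, generator_mode = "ideal_normal")
  s <- qstat_distribution(cond)
  expect_equal(length(s$q), 2000)
  expect_equal(s$ref_mean, 9)
  expect_equal(s$ref_var, 18)
  se_mean <- sd(s$q) / sqrt(2000)
  expect_lt(abs(s$mean_q - 9), 3 * se_mean)
  expect_equal(s$mean_ratio, s$mean_q / 9)
  # variance within MC error of 2(k-1)
  se_var <- sd((s$q - mean(s$q))^2) / sqrt(2000)
  expect_lt(abs(s$var_q - 18), 3.5 * se_var)
})

test_that("coverage_grid flattens conditions and flags acceptability", {
  conds <- list(
    sim_condition(mu = 0, tau = 0, pi_c = 0.5, k = 5, reps = 30, seed = 1,
                  generator_mode = "ideal_normal"),
    sim_condition(mu = 0, tau = 0.5, pi_c = 0.5, k = 5, group_sizes = 30,
                  reps = 30, seed = 2, generator_mode = "ideal_normal"))
  g <- coverage_grid(conds, methods = "qprofile")
  expect_equal(nrow(g), 2)
  expect_equal(g$acceptable, g$coverage > 0.9)
  expect_equal(g$size, c(NA_integer_, 30L))
  # a single-cell grid reduces to evaluate_coverage
  single <- evaluate_coverage(conds[[1]], methods = "qprofile")
  expect_equal(g$coverage[1], single$summary$coverage)
})

test_that("bias-coverage correlation is Pearson with guarded input", {
  bias <- c(0, 0.1, 0.2, 0.3)
  expect_equal(bias_coverage_correlation(bias, 0.95 - 0.5 * bias), -1)
  expect_equal(bias_coverage_correlation(bias, c(0.9, 0.95, 0.85, 0.94)),
               cor(bias, c(0.9, 0.95, 0.85, 0.94)))
  expect_error(bias_coverage_correlation(bias, rep(0.9, 4)), "vary")
  expect_error(bias_coverage_correlation(c(0, 1), c(0.9, 0.8)), "at least 3")
})
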