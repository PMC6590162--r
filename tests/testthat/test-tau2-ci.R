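test_that("weighted mean and generalized Q reproduce closed forms", {
  expect_equal(weighted_mean(c(0, 2), c(1, 1)), 1)
  expect_equal(weighted_mean(5, 3), 5)
  expect_equal(weighted_mean(c(1, 2, 3), c(1, 2, 1)), 2)
  expect_error(weighted_mean(numeric(0), numeric(0)), "empty")
  expect_error(weighted_mean(c(1, 2), c(1, -1)), "positive")

  s <- meta_sample(c(0, 2), c(1, 1))
  expect_equal(generalized_q(s, 0), 2)       # Cochran's Q
  expect_equal(generalized_q(s, 1), 1)       # 2 / (1 + 1)
  same <- meta_sample(rep(0.3, 4), c(1, 2, 3, 4))
  expect_equal(generalized_q(same, 0.7), 0)
  expect_error(generalized_q(s, -0.1), "non-negative")
})

test_that("Paule-Mandel solves Q(tau2) = k - 1 and truncates at zero", {
  s <- meta_sample(c(0, 2), c(1, 1))
  pm <- paule_mandel(s)
  expect_equal(pm$tau2, 1, tolerance = 1e-7)
  expect_false(pm$truncated)

  flat <- meta_sample(rep(1.2, 5), runif(5, 0.1, 1))
  pm0 <- paule_mandel(flat)
  expect_equal(pm0$tau2, 0)
  expect_true(pm0$truncated)

  # grid-search oracle on a random k = 5 sample
  set.seed(11)
  y <- rnorm(5, 0, 0.8)
  v <- runif(5, 0.05, 0.3)
  pm5 <- paule_mandel(meta_sample(y, v))
  expect_equal(pm5$tau2, pm_grid_oracle(y, v), tolerance = 1e-4)
})

test_that("Q-profile CI matches the two-study closed form and statuses", {
  s <- meta_sample(c(0, 2), c(1, 1))
  ci <- q_profile_ci(s, 0.95)
  # Q(t2) = 2/(1+t2); Q(0) = 2 < qchisq(.975, 1) so lower bound truncates
  expect_equal(ci$status, "lower_truncated")
  expect_equal(ci$lb, 0)
  expect_equal(ci$ub, 2 / qchisq(0.025, 1) - 1, tolerance = 1e-6)

  # regular interval when Q(0) is large
  s2 <- meta_sample(c(0, 4), c(0.5, 0.5))
  ci2 <- q_profile_ci(s2)
  expect_equal(ci2$status, "regular")
  expect_equal(generalized_q(s2, ci2$lb), qchisq(0.975, 1), tolerance = 1e-6)
  expect_equal(generalized_q(s2, ci2$ub), qchisq(0.025, 1), tolerance = 1e-6)

  # null set when even tau2 = 0 sits below the lower critical value
  flat <- meta_sample(c(0.5, 0.5001, 0.4999, 0.5), rep(1, 4))
  ci3 <- q_profile_ci(flat)
  expect_equal(ci3$status, "null_set")
  expect_true(is.na(ci3$lb) && is.na(ci3$ub))

  expect_error(q_profile_ci(s, level = 1.2), "level")
})

test_that("GENQ statistic and eigenvalue weights obey their algebra", {
  s <- meta_sample(c(0, 2), c(1, 1))
  expect_equal(genq_statistic(s, "variance"), 2)
  expect_equal(genq_statistic(meta_sample(c(0, 2), c(4, 4)), "se"), 1)
  expect_equal(genq_statistic(meta_sample(rep(1, 3), 1:3), "variance"), 0)

  # centering-matrix eigenvalues at equal unit variances, tau2 = 0
  lam <- genq_lambdas(meta_sample(c(0, 1, 2), c(1, 1, 1)), "variance", 0)
  expect_equal(sort(lam), c(0, 1, 1))

  # scalar-matrix case: nonzero eigenvalues all (t + c)/c
  lam2 <- genq_lambdas(meta_sample(rnorm(6), rep(0.5, 6)), "variance", 0.3)
  expect_equal(lam2[1:5], rep(0.8 / 0.5, 5), tolerance = 1e-12)
  expect_equal(lam2[6], 0)

  # trace identity on random heterogeneous samples, both schemes
  set.seed(21)
  for (scheme in c("variance", "se")) {
    for (rep in 1:5) {
      s3 <- random_sample(sample(3:12, 1))
      t2 <- runif(1, 0, 1)
      a <- genq_weights(s3, scheme)
      sv <- t2 + s3$v
      expect_equal(sum(genq_lambdas(s3, scheme, t2)),
                   sum(a * sv) - sum(a^2 * sv) / sum(a))
    }
  }
})

test_that("weighted chi-square survival function is accurate and monotone", {
  # chi-square identities
  expect_equal(weighted_chisq_sf(1, 2.3), pchisq(2.3, 1, lower.tail = FALSE))
  expect_equal(weighted_chisq_sf(rep(1, 4), 6), pchisq(6, 4, lower.tail = FALSE),
               tolerance = 1e-8)
  expect_equal(weighted_chisq_sf(rep(2.5, 7), 10),
               pchisq(4, 7, lower.tail = FALSE), tolerance = 1e-8)
  # series route must agree with the Imhof integral route
  lam <- c(5, 1, 0.3, 0.05)
  for (q in c(0.5, 3, 10, 25)) {
    expect_equal(weighted_chisq_sf(lam, q), metatau:::.imhof_sf(lam, q),
                 tolerance = 1e-7)
  }
  # monotone non-increasing in q
  qs <- seq(0, 30, length.out = 40)
  ps <- vapply(qs, function(q) weighted_chisq_sf(lam, q), numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  expect_equal(ps[1], 1)
  expect_error(weighted_chisq_sf(c(0, 0), 1), "positive")
})

test_that("GENQ CI inverts its tail probability and handles statuses", {
  set.seed(31)
  s <- random_sample(6, tau2 = 0.4)
  for (scheme in c("variance", "se")) {
    ci <- genq_ci(s, scheme)
    q_obs <- genq_statistic(s, scheme)
    sf_at <- function(t2) weighted_chisq_sf(genq_lambdas(s, scheme, t2), q_obs)
    expect_equal(sf_at(ci$ub), 0.975, tolerance = 1e-6)
    if (ci$status == "regular") {
      expect_equal(sf_at(ci$lb), 0.025, tolerance = 1e-6)
    }
  }
  # all-identical effect sizes: q_a = 0, every tau2 rejected from above
  flat <- meta_sample(rep(0.7, 4), runif(4, 0.1, 0.5))
  expect_equal(genq_ci(flat, "variance")$status, "null_set")
  expect_error(genq_ci(s, "variance", level = 0), "level")
})
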