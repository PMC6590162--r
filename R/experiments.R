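#' Monte-Carlo coverage experiment for tau-squared CI methods
#'
#' For each repetition a meta-analysis is generated from `condition`, each
#' requested method's interval is computed, and the repetition is scored as
#' covering when the interval is not the null set and
#' \eqn{lb \le \tau^2 \le ub} for the condition's true \eqn{\tau^2}. A
#' null-set interval contains no value, so it is always scored as
#' non-covering. Interval width is \eqn{ub - lb}; null-set repetitions have
#' no width and are excluded from width averaging (tracked through the
#' null-set proportion instead).
#'
#' The pooled-mean estimate \eqn{\hat\mu} (weights
#' \eqn{1/(\hat\tau^2_{PM} + v_i)} at the Paule-Mandel estimate) is
#' recorded per repetition so designs can correlate bias in \eqn{\hat\mu}
#' with coverage across conditions.
#'
#' @param condition a [sim_condition()]; `condition$reps` repetitions are
#'   run under per-repetition RNG substreams seeded by `condition$seed`.
#' @param methods subset of `"qprofile"`, `"genq_variance"`, `"genq_se"`.
#' @param level nominal two-sided confidence level.
#' @param workers parallel workers (fork-based; results are invariant to
#'   the worker count given the seed).
#' @return object of class `coverage_result`: the per-repetition records
#'   (`$reps`), per-method summary (`$summary`), pairwise width-win
#'   proportions (`$width_wins`), and `$mu_bias`.
#' @export
evaluate_coverage <- function(condition,
                              methods = c("qprofile", "genq_variance", "genq_se"),
                              level = 0.95, workers = 1L) {
  stopifnot(inherits(condition, "sim_condition"))
  methods <- match.arg(methods, several.ok = TRUE)
  tau2_true <- condition$tau^2

  one_rep <- function(i) {
    sim <- simulate_meta(condition)
    flags <- if (is.null(sim$tables)) c(FALSE, FALSE) else {
      zc <- count_zero_cells(sim$tables)
      c(any(zc >= 1L), any(zc >= 2L))
    }
    pm <- paule_mandel(sim$sample)
    mu_hat <- weighted_mean(sim$sample$y, 1 / (pm$tau2 + sim$sample$v))
    rows <- lapply(methods, function(m) {
      ci <- switch(m,
        qprofile      = q_profile_ci(sim$sample, level),
        genq_variance = genq_ci(sim$sample, "variance", level),
        genq_se       = genq_ci(sim$sample, "se", level))
      data.frame(
        rep = i, method = m, lb = ci$lb, ub = ci$ub, status = ci$status,
        covered = ci$status != "null_set" &&
          ci$lb <= tau2_true && tau2_true <= ci$ub,
        width = if (ci$status == "null_set") NA_real_ else ci$ub - ci$lb,
        stringsAsFactors = FALSE)
    })
    list(rows = do.call(rbind, rows),
         any_zero = flags[1], any_two_zero = flags[2], mu_hat = mu_hat)
  }

  per_rep <- with_substreams(condition$seed, condition$reps, one_rep, workers)
  rows <- do.call(rbind, lapply(per_rep, `[[`, "rows"))
  flags <- data.frame(
    rep = seq_len(condition$reps),
    any_zero = vapply(per_rep, `[[`, logical(1), "any_zero"),
    any_two_zero = vapply(per_rep, `[[`, logical(1), "any_two_zero"),
    mu_hat = vapply(per_rep, `[[`, numeric(1), "mu_hat"))

  summary <- do.call(rbind, lapply(methods, function(m) {
    r <- rows[rows$method == m, ]
    data.frame(method = m,
               coverage = mean(r$covered),
               mean_width = mean(r$width, na.rm = TRUE),
               sd_width = stats::sd(r$width[!is.na(r$width)]),
               null_set_prop = mean(r$status == "null_set"),
               stringsAsFactors = FALSE)
  }))

  # pairwise strict width wins; repetitions where either width is undefined
  # (null set) are counted as ties so wins + losses + ties = reps
  width_wins <- NULL
  if (length(methods) > 1L) {
    pairs <- utils::combn(methods, 2, simplify = FALSE)
    width_wins <- do.call(rbind, lapply(pairs, function(p) {
      w1 <- rows$width[rows$method == p[1]]
      w2 <- rows$width[rows$method == p[2]]
      comparable <- !is.na(w1) & !is.na(w2)
      wins1 <- sum(comparable & w1 < w2)
      wins2 <- sum(comparable & w2 < w1)
      data.frame(method_a = p[1], method_b = p[2],
                 a_narrower = wins1 / condition$reps,
                 b_narrower = wins2 / condition$reps,
                 ties = 1 - (wins1 + wins2) / condition$reps,
                 stringsAsFactors = FALSE)
    }))
  }

  structure(list(condition = condition, level = level, methods = methods,
                 reps = rows, flags = flags, summary = summary,
                 width_wins = width_wins,
                 mu_bias = mean(flags$mu_hat) - condition$mu),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("coverage_result: %d reps, level %.2f\n",
              x$condition$reps, x$level))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Coverage within zero-cell subsets of simulation runs
#'
#' Splits the repetitions of a [evaluate_coverage()] result on whether the
#' generated meta-analysis contained at least one primary study with a zero
#' cell (and separately, with two zero cells) and recomputes each method's
#' coverage within each subset. Under rare events and many small studies
#' nearly every run lands in the zero subset; under a balanced outcome the
#' subset is small.
#'
#' @param result a `coverage_result`.
#' @return data frame with one row per (method, subset definition):
#'   columns `method`, `flag` (`"any_zero"`/`"any_two_zero"`),
#'   `prop_in_subset`, `coverage_in_subset`, `coverage_outside` (`NA` when
#'   a subset is empty).
#' @export
subset_coverage <- function(result) {
  stopifnot(inherits(result, "coverage_result"))
  out <- list()
  for (flag in c("any_zero", "any_two_zero")) {
    in_subset <- result$flags[[flag]]
    for (m in result$methods) {
      cov <- result$reps$covered[result$reps$method == m]
      out[[length(out) + 1L]] <- data.frame(
        method = m, flag = flag,
        prop_in_subset = mean(in_subset),
        coverage_in_subset = if (any(in_subset)) mean(cov[in_subset]) else NA_real_,
        coverage_outside = if (any(!in_subset)) mean(cov[!in_subset]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Sampling distribution of the generalized Q-statistic
#'
#' Per repetition a meta-analysis is generated and the Q-profile pivot
#' [generalized_q()] is evaluated at the condition's *true* \eqn{\tau^2}
#' (weights \eqn{1/(\tau^2 + v_i)}, with matching weighted mean); at
#' \eqn{\tau = 0} this is Cochran's Q. Under the random-effects model
#' assumptions the replicates would follow \eqn{\chi^2_{k-1}} (mean
#' \eqn{k-1}, variance \eqn{2(k-1)}); the summary records how far the
#' empirical mean and variance fall from that reference.
#'
#' @param condition a [sim_condition()].
#' @param reps number of replicate Q values; defaults to `condition$reps`.
#' @param workers parallel workers.
#' @return object of class `qdist_summary` with the replicate values and
#'   `mean_q`, `var_q`, `ref_mean` (k-1), `ref_var` (2(k-1)) and
#'   `mean_ratio` = `mean_q / (k-1)`.
#' @export
qstat_distribution <- function(condition, reps = condition$reps,
                               workers = 1L) {
  stopifnot(inherits(condition, "sim_condition"))
  tau2 <- condition$tau^2
  q <- unlist(with_substreams(condition$seed, reps, function(i) {
    generalized_q(simulate_meta(condition)$sample, tau2)
  }, workers))
  structure(list(q = q,
                 mean_q = mean(q), var_q = stats::var(q),
                 ref_mean = condition$k - 1,
                 ref_var = 2 * (condition$k - 1),
                 mean_ratio = mean(q) / (condition$k - 1),
                 condition = condition),
            class = "qdist_summary")
}

#' @export
print.qdist_summary <- function(x, ...) {
  cat(sprintf(
    "generalized Q over %d replicates: mean %.3f (ref %d), var %.3f (ref %d), mean ratio %.3f\n",
    length(x$q), x$mean_q, x$ref_mean, x$var_q, x$ref_var, x$mean_ratio))
  invisible(x)
}

#' Coverage over a grid of simulation conditions
#'
#' Runs [evaluate_coverage()] for every supplied condition and returns a
#' long-format table, one row per (condition, method), with the coverage
#' and an acceptability flag (coverage > 0.9, the conventional cut for
#' "usable in practice"). Typical grids vary the control-arm event
#' probability against the number of studies at a fixed study size, or
#' against the study size at a fixed number of studies.
#'
#' @param conditions list of [sim_condition()] objects.
#' @param methods,level,workers passed to [evaluate_coverage()].
#' @return data frame with columns `mu`, `tau`, `pi_c`, `k`, `size`,
#'   `reps`, `method`, `coverage`, `acceptable`.
#' @export
coverage_grid <- function(conditions,
                          methods = c("qprofile", "genq_variance", "genq_se"),
                          level = 0.95, workers = 1L) {
  if (inherits(conditions, "sim_condition")) conditions <- list(conditions)
  do.call(rbind, lapply(conditions, function(cond) {
    res <- evaluate_coverage(cond, methods, level, workers)
    data.frame(mu = cond$mu, tau = cond$tau, pi_c = cond$pi_c, k = cond$k,
               size = if (length(unique(cond$group_sizes)) == 1L)
                 cond$group_sizes[1] else NA_integer_,
               reps = cond$reps,
               method = res$summary$method,
               coverage = res$summary$coverage,
               acceptable = res$summary$coverage > 0.9,
               stringsAsFactors = FALSE)
  }))
}

#' Correlation between pooled-mean bias and coverage across conditions
#'
#' Product-moment (Pearson) correlation between per-condition bias of the
#' pooled-mean estimator and a method's per-condition coverage rate. A
#' negative correlation indicates that conditions where the pooled mean is
#' overestimated are also the conditions where the interval undercovers.
#'
#' @param bias numeric vector of per-condition mean \eqn{\hat\mu - \mu}.
#' @param coverage numeric vector of matching per-condition coverage rates.
#' @return Pearson correlation coefficient.
#' @export
bias_coverage_correlation <- function(bias, coverage) {
  if (length(bias) != length(coverage) || length(bias) < 3L) {
    stop("need at least 3 paired conditions", call. = FALSE)
  }
  if (stats::sd(bias) == 0 || stats::sd(coverage) == 0) {
    stop("bias and coverage must both vary across conditions", call. = FALSE)
  }
  stats::cor(bias, coverage)
}
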