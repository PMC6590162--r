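#' Inverse-variance weighted mean
#'
#' The pooled estimate \eqn{\hat\theta = \sum w_i y_i / \sum w_i}. Used with
#' \eqn{w_i = 1/v_i} for Cochran's Q and with \eqn{w_i = 1/(\tau^2 + v_i)}
#' inside the Q-profile pivot.
#'
#' @param y numeric vector of effect estimates.
#' @param w positive weights, same length as `y`.
#' @return scalar weighted mean.
#' @export
weighted_mean <- function(y, w) {
  if (length(y) == 0L) stop("empty input", call. = FALSE)
  if (length(y) != length(w)) stop("y and w must have equal length", call. = FALSE)
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive", call. = FALSE)
  sum(w * y) / sum(w)
}

#' Generalized Q-statistic of the Q-profile pivot
#'
#' \deqn{Q(\tau^2) = \sum_i \frac{(y_i - \hat\mu)^2}{\tau^2 + v_i}}
#' with \eqn{\hat\mu} the weighted mean recomputed at this \eqn{\tau^2}
#' using weights \eqn{1/(\tau^2 + v_i)}. At \eqn{\tau^2 = 0} this is
#' Cochran's Q. Under the random-effects model assumptions the statistic,
#' evaluated at the true \eqn{\tau^2}, is a pivot with a
#' \eqn{\chi^2_{k-1}} distribution; it is strictly decreasing in
#' \eqn{\tau^2} whenever at least two \eqn{y_i} differ.
#'
#' @param sample a [meta_sample()].
#' @param tau2 non-negative scalar between-study variance.
#' @return scalar value of the pivot.
#' @export
generalized_q <- function(sample, tau2 = 0) {
  sample <- as_meta_sample(sample)
  if (!is.numeric(tau2) || length(tau2) != 1L || is.na(tau2) || tau2 < 0) {
    stop("tau2 must be a non-negative scalar", call. = FALSE)
  }
  w <- 1 / (tau2 + sample$v)
  mu <- weighted_mean(sample$y, w)
  sum(w * (sample$y - mu)^2)
}

# Monotone bisection on tau2: f is monotone, find tau2 with f(tau2) = 0.
# f(0) must have the sign indicating a root at tau2 > 0 (checked by caller).
# Upper bracket found by doubling from 1, hard cap 1e7.
.bisect_tau2 <- function(f, tol = 1e-9, cap = 1e7) {
  lo <- 0
  hi <- 1
  f_lo <- f(lo)
  f_hi <- f(hi)
  while (sign(f_hi) == sign(f_lo)) {
    hi <- hi * 2
    if (hi > cap) {
      stop("failed to bracket the tau2 root below the cap of 1e7",
           call. = FALSE)
    }
    f_hi <- f(hi)
  }
  while ((hi - lo) > tol) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid
      f_lo <- f_mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Paule-Mandel estimator of the between-study variance
#'
#' Solves \eqn{Q(\tau^2) = k - 1} for \eqn{\tau^2 \ge 0} by bisection; when
#' \eqn{Q(0) \le k - 1} the solution would be negative and the estimate is
#' truncated to zero. The estimate always lies inside the Q-profile
#' confidence interval computed from the same sample.
#'
#' @param sample a [meta_sample()].
#' @param tol absolute bisection tolerance on tau2.
#' @return list with `tau2` (the estimate) and `truncated` (logical).
#' @export
paule_mandel <- function(sample, tol = 1e-9) {
  sample <- as_meta_sample(sample)
  target <- sample$k - 1
  if (generalized_q(sample, 0) <= target) {
    return(list(tau2 = 0, truncated = TRUE))
  }
  root <- .bisect_tau2(function(t2) generalized_q(sample, t2) - target, tol)
  list(tau2 = root, truncated = FALSE)
}

#' Construct a tau-squared confidence interval object
#'
#' Intervals carry an explicit status rather than sentinel bounds because
#' coverage accounting must treat an empty (null-set) interval as
#' non-covering. `lower_truncated` means the inverted lower bound was
#' negative and was truncated to zero, the usual case for small samples.
#'
#' @param lb,ub interval bounds on the tau-squared scale (`NA` for a null
#'   set).
#' @param status `"regular"`, `"lower_truncated"` or `"null_set"`.
#' @param level nominal two-sided confidence level.
#' @param method label of the producing method.
#' @return object of class `tau2_interval`.
#' @keywords internal
tau2_interval <- function(lb, ub, status, level, method) {
  status <- match.arg(status, c("regular", "lower_truncated", "null_set"))
  if (status == "null_set") {
    lb <- NA_real_
    ub <- NA_real_
  } else {
    stopifnot(lb >= 0, ub >= lb)
    if (status == "lower_truncated") stopifnot(lb == 0)
  }
  structure(list(lb = lb, ub = ub, status = status, level = level,
                 method = method),
            class = "tau2_interval")
}

#' @export
print.tau2_interval <- function(x, ...) {
  cat(sprintf("%.0f%% CI for tau^2 (%s): ", 100 * x$level, x$method))
  if (x$status == "null_set") {
    cat("null set (empty interval)\n")
  } else {
    cat(sprintf("[%.6g, %.6g]%s\n", x$lb, x$ub,
                if (x$status == "lower_truncated") "  (lower bound truncated to 0)" else ""))
  }
  invisible(x)
}

#' Q-profile confidence interval for the between-study variance
#'
#' Test inversion of the pivot \eqn{Q(\tau^2) \sim \chi^2_{k-1}}: the
#' bounds are the \eqn{\tau^2} values where \eqn{Q(\tau^2)} equals the
#' upper and lower \eqn{\chi^2_{k-1}} quantiles,
#' \deqn{Q(\hat\tau^2_{LB}) = \chi^2_{k-1;(1+level)/2}, \qquad
#'       Q(\hat\tau^2_{UB}) = \chi^2_{k-1;(1-level)/2}.}
#' If \eqn{Q(0)} falls below the upper quantile the lower bound is
#' truncated to zero; if it falls below the lower quantile even
#' \eqn{\tau^2 = 0} is rejected from above and the interval is the null
#' set.
#'
#' @param sample a [meta_sample()].
#' @param level nominal two-sided confidence level in (0, 1).
#' @param tol absolute bisection tolerance on tau2.
#' @return a `tau2_interval`.
#' @examples
#' s <- meta_sample(y = c(0, 2), v = c(1, 1))
#' q_profile_ci(s)
#' @export
q_profile_ci <- function(sample, level = 0.95, tol = 1e-9) {
  sample <- as_meta_sample(sample)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must be a scalar in (0, 1)", call. = FALSE)
  }
  df <- sample$k - 1
  crit_hi <- stats::qchisq((1 + level) / 2, df)
  crit_lo <- stats::qchisq((1 - level) / 2, df)
  q0 <- generalized_q(sample, 0)
  if (q0 < crit_lo) {
    return(tau2_interval(NA, NA, "null_set", level, "qprofile"))
  }
  ub <- .bisect_tau2(function(t2) generalized_q(sample, t2) - crit_lo, tol)
  if (q0 < crit_hi) {
    return(tau2_interval(0, ub, "lower_truncated", level, "qprofile"))
  }
  lb <- .bisect_tau2(function(t2) generalized_q(sample, t2) - crit_hi, tol)
  tau2_interval(lb, ub, "regular", level, "qprofile")
}

#' Generalized Q-statistic with arbitrary fixed weights
#'
#' \eqn{q_a = \sum_i a_i (y_i - \hat\mu_a)^2} with
#' \eqn{\hat\mu_a = \sum a_i y_i / \sum a_i}. Unlike the Q-profile pivot the
#' weights are fixed positive constants, so the statistic's exact
#' distribution under the random-effects model is a weighted sum of
#' independent one-degree chi-squares.
#'
#' @param sample a [meta_sample()].
#' @param scheme weight scheme, see [genq_weights()].
#' @return scalar statistic.
#' @export
genq_statistic <- function(sample, scheme = c("variance", "se")) {
  sample <- as_meta_sample(sample)
  a <- genq_weights(sample, scheme)
  mu <- weighted_mean(sample$y, a)
  sum(a * (sample$y - mu)^2)
}

#' Eigenvalue weights of the exact GENQ distribution
#'
#' Under the random-effects model,
#' \eqn{Q_a \overset{d}{=} \sum_i \lambda_i \chi^2_i(1)} where the
#' \eqn{\lambda_i} are the eigenvalues of
#' \eqn{S^{1/2} B S^{1/2}} with \eqn{S = \mathrm{diag}(\tau^2 + v_i)} and
#' \eqn{B = \mathrm{diag}(a) - a a^\top / \sum a_i}, the centering matrix
#' whose quadratic form in \eqn{y} is \eqn{q_a}. All eigenvalues are
#' non-negative (one is structurally zero); values in \eqn{(-10^{-10}, 0)}
#' arising from floating-point error are clipped to zero and anything more
#' negative is an error.
#'
#' @param sample a [meta_sample()].
#' @param scheme weight scheme, see [genq_weights()].
#' @param tau2 non-negative between-study variance at which the
#'   distribution is evaluated.
#' @return numeric vector of k non-negative eigenvalues (decreasing).
#' @export
genq_lambdas <- function(sample, scheme = c("variance", "se"), tau2 = 0) {
  sample <- as_meta_sample(sample)
  if (!is.numeric(tau2) || length(tau2) != 1L || is.na(tau2) || tau2 < 0) {
    stop("tau2 must be a non-negative scalar", call. = FALSE)
  }
  a <- genq_weights(sample, scheme)
  s <- tau2 + sample$v
  rs <- sqrt(s)
  # S^{1/2} B S^{1/2} = diag(a*s) - u u^T, u_i = sqrt(s_i) a_i / sqrt(sum a)
  u <- rs * a / sqrt(sum(a))
  m <- diag(a * s, nrow = sample$k) - tcrossprod(u)
  lam <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (any(lam < -1e-10)) {
    stop("unexpected negative eigenvalue in GENQ weight matrix", call. = FALSE)
  }
  pmax(lam, 0)
}

#' Survival function of a weighted sum of one-degree chi-squares
#'
#' Computes \eqn{P(\sum_i \lambda_i \chi^2_i(1) \ge q)}, the tail the GENQ
#' method inverts. The primary algorithm is Farebrother/Ruben's expansion
#' of the distribution as an infinite mixture of central chi-squares
#' \deqn{P(Q \le q) = \sum_{m \ge 0} a_m\,F_{k+2m}(q/\beta), \quad
#'       \beta = \min_i \lambda_i,}
#' whose coefficients \eqn{a_m \ge 0} sum to one, giving the rigorous
#' truncation bound \eqn{1 - \sum_{m<M} a_m}; the series is cut when that
#' bound falls below 1e-10. When the weight spectrum is too disparate for
#' the series to converge within 5000 terms (or the leading coefficient
#' underflows), the tail is computed instead by Imhof's
#' numerical-inversion integral
#' \deqn{P(Q \ge q) = \frac12 + \frac1\pi \int_0^\infty
#'   \frac{\sin\theta(u)}{u\,\rho(u)}\,du}
#' with \eqn{\theta(u) = \frac12\sum_i \arctan(\lambda_i u) - \frac12 q u}
#' and \eqn{\rho(u) = \prod_i (1 + \lambda_i^2 u^2)^{1/4}}, via adaptive
#' quadrature on the infinite range. Either route is well inside the 1e-6
#' absolute-accuracy contract; equal weights short-circuit to the exact
#' chi-square tail.
#'
#' @param lambdas non-negative weights, at least one positive. Zero
#'   weights -- including eigenvalue noise below `1e-12` of the largest
#'   weight -- are dropped; they contribute nothing to the distribution
#'   but would spoil the series scaling.
#' @param q non-negative quantile.
#' @return upper-tail probability in `[0, 1]`, monotone non-increasing in
#'   `q`.
#' @export
weighted_chisq_sf <- function(lambdas, q) {
  if (!is.numeric(lambdas) || any(!is.finite(lambdas)) || any(lambdas < 0)) {
    stop("lambdas must be finite and non-negative", call. = FALSE)
  }
  if (length(lambdas) == 0L || max(lambdas) == 0) {
    stop("at least one lambda must be positive", call. = FALSE)
  }
  lambdas <- lambdas[lambdas > 1e-12 * max(lambdas)]
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0) {
    stop("q must be a non-negative scalar", call. = FALSE)
  }
  if (q == 0) return(1)
  # exact chi-square when all weights coincide
  if (max(lambdas) - min(lambdas) < 1e-13 * max(lambdas)) {
    return(stats::pchisq(q / lambdas[1], df = length(lambdas),
                         lower.tail = FALSE))
  }
  p <- .ruben_sf(lambdas, q)
  if (!is.na(p)) return(p)
  .imhof_sf(lambdas, q)
}

# Ruben mixture series with beta = min(lambda): coefficients are positive
# and sum to 1, so the truncation error is bounded by the missing mass.
# Returns NA when not converged within max_terms (caller falls back).
.ruben_sf <- function(lambdas, q, tol = 1e-10, max_terms = 5000L) {
  beta <- min(lambdas)
  k <- length(lambdas)
  ratio <- 1 - beta / lambdas          # each in [0, 1)
  log_a0 <- 0.5 * sum(log(beta / lambdas))
  if (log_a0 < log(.Machine$double.xmin) + 50) return(NA_real_)
  a <- numeric(max_terms)
  g <- numeric(max_terms)
  a[1] <- exp(log_a0)
  total <- a[1]
  pw <- ratio
  m_used <- max_terms
  for (m in seq_len(max_terms - 1L)) {
    g[m] <- 0.5 * sum(pw)
    pw <- pw * ratio
    a[m + 1L] <- sum(g[m:1] * a[1:m]) / m
    total <- total + a[m + 1L]
    if (1 - total < tol) {
      m_used <- m + 1L
      break
    }
  }
  if (1 - total >= tol) return(NA_real_)
  cdf <- sum(a[1:m_used] *
               stats::pchisq(q / beta, df = k + 2 * (0:(m_used - 1L))))
  # cdf underestimates by at most the missing mass (< tol)
  min(max(1 - cdf, 0), 1)
}

.imhof_sf <- function(lambdas, q) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambdas, u))) - 0.5 * q * u
    log_rho <- 0.25 * colSums(log1p(outer(lambdas^2, u^2)))
    out <- sin(theta) * exp(-log_rho) / u
    out[u == 0] <- 0.5 * (sum(lambdas) - q)  # limit as u -> 0
    out
  }
  val <- stats::integrate(integrand, 0, Inf, subdivisions = 5000L,
                          rel.tol = 1e-9, abs.tol = 1e-11,
                          stop.on.error = FALSE)$value
  min(max(0.5 + val / pi, 0), 1)
}

#' GENQ confidence interval for the between-study variance
#'
#' Inverts the exact distribution of the generalized Q-statistic with fixed
#' positive weights: given the observed \eqn{q_a}, the bounds are the
#' \eqn{\tau^2} values where
#' \deqn{P(Q_a \ge q_a \mid \tau^2 = \hat\tau^2_{LB}) = (1-level)/2, \qquad
#'       P(Q_a \ge q_a \mid \tau^2 = \hat\tau^2_{UB}) = (1+level)/2,}
#' the tail probability being computed from the eigenvalue weights
#' ([genq_lambdas()]) via [weighted_chisq_sf()]. The tail probability is a
#' continuous increasing function of \eqn{\tau^2}, so bisection is
#' guaranteed. A negative lower bound is truncated to zero; when both
#' bounds would be negative the interval is the null set.
#'
#' @inheritParams q_profile_ci
#' @param scheme weight scheme, see [genq_weights()].
#' @return a `tau2_interval`.
#' @examples
#' s <- meta_sample(y = c(0.2, 0.9, -0.3, 0.6), v = c(0.04, 0.09, 0.06, 0.05))
#' genq_ci(s, scheme = "se")
#' @export
genq_ci <- function(sample, scheme = c("variance", "se"), level = 0.95,
                    tol = 1e-9) {
  sample <- as_meta_sample(sample)
  scheme <- match.arg(scheme)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must be a scalar in (0, 1)", call. = FALSE)
  }
  q_obs <- genq_statistic(sample, scheme)
  method <- paste0("genq_", if (scheme == "variance") "variance" else "se")
  if (q_obs <= 0) {
    # all y identical: P(Q_a >= 0) = 1 at every tau2, both bounds negative
    return(tau2_interval(NA, NA, "null_set", level, method))
  }
  sf <- function(t2) weighted_chisq_sf(genq_lambdas(sample, scheme, t2), q_obs)
  alpha_lo <- (1 - level) / 2
  alpha_hi <- (1 + level) / 2
  sf0 <- sf(0)
  if (sf0 >= alpha_hi) {
    return(tau2_interval(NA, NA, "null_set", level, method))
  }
  ub <- .bisect_tau2(function(t2) sf(t2) - alpha_hi, tol)
  if (sf0 >= alpha_lo) {
    return(tau2_interval(0, ub, "lower_truncated", level, method))
  }
  lb <- .bisect_tau2(function(t2) sf(t2) - alpha_lo, tol)
  tau2_interval(lb, ub, "regular", level, method)
}
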