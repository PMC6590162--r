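#' Probability of observing a particular 2x2 table
#'
#' With independent binomial arms the probability of the table
#' \eqn{(x^E, n^E - x^E, x^C, n^C - x^C)} is the product of the two
#' binomial point masses
#' \eqn{B(x^E; n^E, \pi^E)\,B(x^C; n^C, \pi^C)}.
#'
#' @param x_e,n_e event count and size of the experimental arm.
#' @param pi_e event probability in the experimental arm.
#' @param x_c,n_c event count and size of the control arm.
#' @param pi_c event probability in the control arm.
#' @return probability (vectorized over counts).
#' @export
table_probability <- function(x_e, n_e, pi_e, x_c, n_c, pi_c) {
  stats::dbinom(x_e, n_e, pi_e) * stats::dbinom(x_c, n_c, pi_c)
}

# per-process memo for exact moments; keys carry full float precision
.moments_cache <- new.env(parent = emptyenv())

#' Exact moments of the continuity-corrected log odds ratio
#'
#' Enumerates all \eqn{(n^E + 1)(n^C + 1)} possible 2x2 tables for two
#' independent binomial arms, computes the +0.5-corrected log odds ratio
#' \eqn{Y} for each, and returns the exact expectation
#' \eqn{E[Y] = \sum p\,Y} and the true sampling variance as the central
#' second moment \eqn{\sigma_T^2 = E[Y^2] - (E[Y])^2}. Binomial masses are
#' evaluated in log space so that enumeration stays stable up to arm sizes
#' of several hundred.
#'
#' Supply either `pi_e` directly or a true log odds ratio `theta`, in which
#' case \eqn{\pi^E = \pi^C e^\theta / (1 - \pi^C + \pi^C e^\theta)}.
#'
#' Results are memoized per R session on the key
#' `(n_e, n_c, pi_e, pi_c)` at full float precision; simulation runs with
#' many studies sharing event probabilities reuse the enumeration.
#'
#' @param n_e,n_c arm sizes (>= 1).
#' @param pi_e event probability in the experimental arm, in (0, 1).
#' @param pi_c event probability in the control arm, in (0, 1).
#' @param theta optional true log odds ratio used to derive `pi_e`.
#' @return list with `mean_y`, `var_y` and `n_tables`.
#' @examples
#' exact_log_or_moments(30, 30, pi_e = 0.1, pi_c = 0.1)
#' @export
exact_log_or_moments <- function(n_e, n_c, pi_e = NULL, pi_c, theta = NULL) {
  if (is.null(pi_e)) {
    if (is.null(theta)) stop("supply pi_e or theta", call. = FALSE)
    pi_e <- pi_experimental(theta, pi_c)
  }
  stopifnot(n_e >= 1, n_c >= 1, pi_e > 0, pi_e < 1, pi_c > 0, pi_c < 1)
  key <- paste(n_e, n_c,
               sprintf("%.17g", pi_e), sprintf("%.17g", pi_c), sep = "|")
  hit <- .moments_cache[[key]]
  if (!is.null(hit)) return(hit)

  x_e <- 0:n_e
  x_c <- 0:n_c
  log_pe <- stats::dbinom(x_e, n_e, pi_e, log = TRUE)
  log_pc <- stats::dbinom(x_c, n_c, pi_c, log = TRUE)
  # probability matrix over the (n_e+1) x (n_c+1) grid of tables
  p <- exp(outer(log_pe, log_pc, `+`))
  ly_e <- log(x_e + 0.5) - log(n_e - x_e + 0.5)   # corrected log odds per arm
  ly_c <- log(x_c + 0.5) - log(n_c - x_c + 0.5)
  y <- outer(ly_e, ly_c, `-`)
  m1 <- sum(p * y)
  m2 <- sum(p * y * y)
  out <- list(mean_y = m1, var_y = m2 - m1^2,
              n_tables = (n_e + 1L) * (n_c + 1L))
  assign(key, out, envir = .moments_cache)
  out
}
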