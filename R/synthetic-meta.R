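#' Event probability in the experimental arm implied by a log odds ratio
#'
#' Solves the log odds ratio identity for the experimental-arm probability:
#' \deqn{\pi^E = \frac{\pi^C e^\theta}{1 - \pi^C + \pi^C e^\theta}}
#' so that the log odds difference between the arms equals `theta` exactly.
#'
#' @param theta true log odds ratio (vectorized).
#' @param pi_c control-arm event probability in (0, 1).
#' @return probability in (0, 1).
#' @export
pi_experimental <- function(theta, pi_c) {
  if (any(pi_c <= 0) || any(pi_c >= 1)) {
    stop("pi_c must lie strictly between 0 and 1", call. = FALSE)
  }
  odds <- pi_c / (1 - pi_c) * exp(theta)
  odds / (1 + odds)
}

#' Standard per-group sample-size pattern
#'
#' The generator holds the average study size constant across numbers of
#' studies by replicating the per-group sizes (30, 50, 100, 150, 300)
#' `k/5` times. Designs with a constant study size bypass this pattern by
#' passing an explicit `group_sizes` vector to [sim_condition()].
#'
#' @param k number of studies; must be a positive multiple of 5.
#' @return integer vector of k per-group sizes.
#' @examples
#' group_size_pattern(10)
#' @export
group_size_pattern <- function(k) {
  if (length(k) != 1L || k <= 0 || k %% 5 != 0) {
    stop("k must be a positive multiple of 5 to use the standard size pattern; ",
         "pass explicit group_sizes otherwise", call. = FALSE)
  }
  rep(c(30L, 50L, 100L, 150L, 300L), each = k / 5)
}

#' Define a simulation condition
#'
#' One cell of a Monte-Carlo design: true log odds ratios are drawn as
#' \eqn{\theta_i \sim N(\mu, \tau^2)} and, in the binomial generator, each
#' study contributes a 2x2 table with `group_sizes[i]` subjects per arm,
#' control-arm events \eqn{x^C \sim Bin(n, \pi^C)} and experimental-arm
#' events \eqn{x^E \sim Bin(n, \pi^E(\theta_i))}.
#'
#' `variance_mode` selects what the CI methods are fed as sampling
#' variances: `"estimated"` uses the +0.5-corrected large-sample estimate
#' from each observed table; `"exact"` keeps the same observed `y` but
#' substitutes the enumeration-exact true variance of the corrected log
#' odds ratio at study i's own event probabilities.
#'
#' `generator_mode = "ideal_normal"` draws
#' \eqn{y_i \sim N(\mu, \tau^2 + \sigma_i^2)} directly with known, fixed
#' \eqn{\sigma_i^2 = 8 / n_i} (the large-sample log odds ratio variance of
#' a balanced table at event probability one half), satisfying every
#' random-effects-model assumption; both CI methods are exact there.
#'
#' @param mu mean true log odds ratio.
#' @param tau between-study standard deviation (>= 0).
#' @param pi_c control-arm event probability in (0, 1).
#' @param k number of studies (>= 2).
#' @param group_sizes per-group sample size per study; defaults to
#'   [group_size_pattern()] of `k`. A scalar is recycled to length k.
#' @param reps Monte-Carlo repetitions.
#' @param seed RNG seed for the condition.
#' @param variance_mode `"estimated"` or `"exact"`.
#' @param generator_mode `"binomial"` or `"ideal_normal"`.
#' @return object of class `sim_condition`.
#' @export
sim_condition <- function(mu = 0, tau = 0, pi_c = 0.5, k = 5,
                          group_sizes = NULL, reps = 1000L, seed = 1L,
                          variance_mode = c("estimated", "exact"),
                          generator_mode = c("binomial", "ideal_normal")) {
  variance_mode <- match.arg(variance_mode)
  generator_mode <- match.arg(generator_mode)
  stopifnot(tau >= 0, pi_c > 0, pi_c < 1, k >= 2, reps >= 1)
  if (is.null(group_sizes)) {
    group_sizes <- group_size_pattern(k)
  } else if (length(group_sizes) == 1L) {
    group_sizes <- rep(as.integer(group_sizes), k)
  }
  if (length(group_sizes) != k || any(group_sizes < 1)) {
    stop("group_sizes must be k positive sizes", call. = FALSE)
  }
  structure(list(mu = mu, tau = tau, pi_c = pi_c, k = as.integer(k),
                 group_sizes = as.integer(group_sizes),
                 reps = as.integer(reps), seed = as.integer(seed),
                 variance_mode = variance_mode,
                 generator_mode = generator_mode),
            class = "sim_condition")
}

#' @export
print.sim_condition <- function(x, ...) {
  cat(sprintf(
    "sim_condition: mu=%g tau=%g pi_c=%g k=%d reps=%d seed=%d (%s, %s)\n",
    x$mu, x$tau, x$pi_c, x$k, x$reps, x$seed, x$generator_mode,
    x$variance_mode))
  cat("  group sizes:", paste(unique(x$group_sizes), collapse = "/"), "\n")
  invisible(x)
}

#' Generate one meta-analysis from a simulation condition
#'
#' Draws true effects \eqn{\theta_i \sim N(\mu, \tau^2)} and then either k
#' binomial 2x2 tables (converted by [log_odds_ratio()], with exact
#' variances substituted when `variance_mode = "exact"`) or, in
#' `ideal_normal` mode, normal effect estimates with known variances and no
#' tables. Consumes the current R RNG stream; seed management (per-rep
#' substreams) lives in the experiment harness.
#'
#' @param condition a [sim_condition()].
#' @return list with `theta` (k true log odds ratios), `tables` (data frame
#'   or `NULL` in ideal-normal mode) and `sample` (a [meta_sample()]).
#' @export
simulate_meta <- function(condition) {
  stopifnot(inherits(condition, "sim_condition"))
  k <- condition$k
  n <- condition$group_sizes
  theta <- stats::rnorm(k, condition$mu, condition$tau)
  if (condition$generator_mode == "ideal_normal") {
    sigma2 <- 8 / n
    y <- stats::rnorm(k, condition$mu, sqrt(condition$tau^2 + sigma2))
    return(list(theta = theta, tables = NULL,
                sample = meta_sample(y, sigma2)))
  }
  pi_e <- pi_experimental(theta, condition$pi_c)
  tables <- data.frame(
    x_e = stats::rbinom(k, n, pi_e),
    n_e = n,
    x_c = stats::rbinom(k, n, condition$pi_c),
    n_c = n
  )
  est <- log_odds_ratio(tables)
  v <- est$v
  if (condition$variance_mode == "exact") {
    v <- vapply(seq_len(k), function(i) {
      exact_log_or_moments(n[i], n[i], pi_e = pi_e[i],
                           pi_c = condition$pi_c)$var_y
    }, numeric(1))
  }
  list(theta = theta, tables = tables, sample = meta_sample(est$y, v))
}

# Per-repetition L'Ecuyer-CMRG substreams: results are then invariant to
# how repetitions are distributed over workers.
substream_seeds <- function(seed, n) {
  state <- local({
    old_kind <- RNGkind()
    on.exit(do.call(RNGkind, as.list(old_kind)))
    set.seed(seed, kind = "L'Ecuyer-CMRG")
    get(".Random.seed", envir = globalenv())
  })
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- state
    state <- parallel::nextRNGSubStream(state)
  }
  out
}

# Evaluate fn() once per repetition under its own RNG substream.
with_substreams <- function(seed, reps, fn, workers = 1L) {
  streams <- substream_seeds(seed, reps)
  run_one <- function(i) {
    assign(".Random.seed", streams[[i]], envir = globalenv())
    fn(i)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(reps), run_one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(reps), run_one)
  }
}
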