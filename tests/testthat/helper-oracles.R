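# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Grid-search oracle for the Paule-Mandel root Q(tau2) = k - 1.
pm_grid_oracle <- function(y, v, upper = 20, step = 1e-4) {
  grid <- seq(0, upper, by = step)
  qvals <- vapply(grid, function(t2) {
    w <- 1 / (t2 + v)
    mu <- sum(w * y) / sum(w)
    sum(w * (y - mu)^2)
  }, numeric(1))
  grid[which.min(abs(qvals - (length(y) - 1)))]
}

# Monte-Carlo oracle for the tail of a weighted sum of 1-df chi-squares.
# Returns the estimate and its standard error.
wchisq_mc_oracle <- function(lambdas, q, n_draws = 1e6, seed = 4242) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  k <- length(lambdas)
  hits <- 0L
  block <- 1e5
  done <- 0
  while (done < n_draws) {
    m <- min(block, n_draws - done)
    draws <- colSums(matrix(stats::rchisq(k * m, df = 1), nrow = k) * lambdas)
    hits <- hits + sum(draws >= q)
    done <- done + m
  }
  p <- hits / n_draws
  list(p = p, se = sqrt(p * (1 - p) / n_draws))
}

# Random meta-analytic sample with heterogeneous variances.
random_sample <- function(k, tau2 = 0.2, v_range = c(0.02, 0.5)) {
  v <- stats::runif(k, v_range[1], v_range[2])
  meta_sample(stats::rnorm(k, 0, sqrt(tau2 + v)), v)
}
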