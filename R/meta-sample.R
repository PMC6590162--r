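#' Construct a meta-analytic sample
#'
#' Bundles k paired effect estimates and sampling variances; the unit all
#' tau-squared confidence-interval methods consume. Variances may be the
#' estimated sampling variances of the log odds ratios or enumeration-exact
#' true variances, depending on how the sample was built.
#'
#' @param y numeric vector of k study effect estimates.
#' @param v numeric vector of k positive sampling variances.
#' @return object of class `meta_sample` with elements `y`, `v`, `k`.
#' @examples
#' meta_sample(y = c(0.1, 0.5, -0.2), v = c(0.04, 0.09, 0.05))
#' @export
meta_sample <- function(y, v) {
  if (!is.numeric(y) || !is.numeric(v) || length(y) != length(v)) {
    stop("y and v must be numeric vectors of equal length", call. = FALSE)
  }
  if (length(y) < 2L) stop("a meta-analysis needs at least 2 studies", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(v)) || any(v <= 0)) {
    stop("all y must be finite and all v finite and positive", call. = FALSE)
  }
  structure(list(y = as.numeric(y), v = as.numeric(v), k = length(y)),
            class = "meta_sample")
}

#' @export
print.meta_sample <- function(x, ...) {
  cat("meta_sample: k =", x$k, "studies\n")
  cat("  y: ", paste(signif(utils::head(x$y, 6), 4), collapse = ", "),
      if (x$k > 6) ", ..." else "", "\n", sep = "")
  cat("  v: ", paste(signif(utils::head(x$v, 6), 4), collapse = ", "),
      if (x$k > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

as_meta_sample <- function(x) {
  if (inherits(x, "meta_sample")) return(x)
  if (is.data.frame(x) && all(c("y", "v") %in% names(x))) {
    return(meta_sample(x$y, x$v))
  }
  stop("cannot interpret input as a meta_sample", call. = FALSE)
}

#' Study weights for the generalized Q-statistic
#'
#' The GENQ method accepts any fixed positive weights \eqn{a_i}. The two
#' schemes studied here keep the method exact under the random-effects model
#' assumptions: inverse-variance weights \eqn{a_i = 1/v_i} and
#' inverse-standard-error weights \eqn{a_i = 1/\sqrt{v_i}}.
#'
#' @param sample a [meta_sample()].
#' @param scheme `"variance"` (\eqn{a_i = 1/v_i}) or `"se"`
#'   (\eqn{a_i = 1/\sqrt{v_i}}).
#' @return numeric vector of k positive weights.
#' @export
genq_weights <- function(sample, scheme = c("variance", "se")) {
  sample <- as_meta_sample(sample)
  scheme <- match.arg(scheme)
  a <- switch(scheme, variance = 1 / sample$v, se = 1 / sqrt(sample$v))
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("weights must be finite and positive", call. = FALSE)
  }
  a
}
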