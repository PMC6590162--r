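#' Validate 2x2 frequency tables
#'
#' A "table" is one study's arm-level counts: `x_e` events out of `n_e` in
#' the experimental arm and `x_c` events out of `n_c` in the control arm.
#' Tables are represented as a data frame with these four columns, one study
#' per row.
#'
#' @param tables data frame with integer columns `x_e`, `n_e`, `x_c`, `n_c`.
#' @return the validated data frame, invisibly coerced to integer counts.
#' @keywords internal
validate_tables <- function(tables) {
  required <- c("x_e", "n_e", "x_c", "n_c")
  if (!is.data.frame(tables) || !all(required %in% names(tables))) {
    stop("tables must be a data frame with columns x_e, n_e, x_c, n_c",
         call. = FALSE)
  }
  tables <- tables[required]
  for (col in required) {
    v <- tables[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != round(v))) {
      stop("column '", col, "' must hold non-missing integer counts",
           call. = FALSE)
    }
  }
  if (any(tables$n_e <= 0L) || any(tables$n_c <= 0L)) {
    stop("arm sizes n_e and n_c must be positive", call. = FALSE)
  }
  if (any(tables$x_e < 0L) || any(tables$x_e > tables$n_e) ||
      any(tables$x_c < 0L) || any(tables$x_c > tables$n_c)) {
    stop("event counts must satisfy 0 <= x <= n in each arm", call. = FALSE)
  }
  tables
}

#' Continuity-corrected log odds ratio and its sampling variance
#'
#' Converts 2x2 tables to log odds ratios with the conventional +0.5
#' continuity correction added to *every* cell of *every* table (not only
#' tables with zero cells). The correction permits computation of the log
#' odds ratio and its variance in the presence of zero cells and reduces
#' small-sample bias of the estimator. For a table with cells
#' \eqn{x^E, n^E - x^E, x^C, n^C - x^C}:
#' \deqn{y = \log\frac{(x^E + 0.5)(n^C - x^C + 0.5)}{(n^E - x^E + 0.5)(x^C + 0.5)}}
#' \deqn{v = \frac{1}{x^E + 0.5} + \frac{1}{n^E - x^E + 0.5} +
#'           \frac{1}{x^C + 0.5} + \frac{1}{n^C - x^C + 0.5}}
#'
#' @param tables data frame with columns `x_e`, `n_e`, `x_c`, `n_c`
#'   (one study per row), or four count vectors passed positionally.
#' @param n_e,x_c,n_c optional count vectors when `tables` is given as the
#'   `x_e` vector.
#' @return data frame with columns `y` (log odds ratio), `v` (estimated
#'   sampling variance, always finite and positive) and `zero_cells`
#'   (number of zero cells among the four, 0--4).
#' @examples
#' log_odds_ratio(data.frame(x_e = 1, n_e = 30, x_c = 0, n_c = 30))
#' @export
log_odds_ratio <- function(tables, n_e = NULL, x_c = NULL, n_c = NULL) {
  if (!is.data.frame(tables)) {
    tables <- data.frame(x_e = tables, n_e = n_e, x_c = x_c, n_c = n_c)
  }
  tables <- validate_tables(tables)
  a <- tables$x_e + 0.5
  b <- tables$n_e - tables$x_e + 0.5
  cc <- tables$x_c + 0.5
  d <- tables$n_c - tables$x_c + 0.5
  data.frame(
    y = log(a * d / (b * cc)),
    v = 1 / a + 1 / b + 1 / cc + 1 / d,
    zero_cells = count_zero_cells(tables)
  )
}

#' Count zero cells of 2x2 tables
#'
#' Counts, per study, how many of the four cells
#' \eqn{x^E, n^E - x^E, x^C, n^C - x^C} equal zero. Zero cells are prevalent
#' under rare events and small samples and degrade sampling-variance
#' estimation; subset analyses of simulation runs condition on them.
#'
#' @inheritParams log_odds_ratio
#' @return integer vector, one count in 0--4 per table.
#' @export
count_zero_cells <- function(tables, n_e = NULL, x_c = NULL, n_c = NULL) {
  if (!is.data.frame(tables)) {
    tables <- data.frame(x_e = tables, n_e = n_e, x_c = x_c, n_c = n_c)
  }
  tables <- validate_tables(tables)
  as.integer((tables$x_e == 0L) + (tables$n_e - tables$x_e == 0L) +
             (tables$x_c == 0L) + (tables$n_c - tables$x_c == 0L))
}
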