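#' Construct a period life table
#'
#' A life table holds the annual probability of death `qx` for every integer
#' age in a contiguous range. It is the mortality substrate that every model
#' arm scales by its post-fracture relative risks. The final age is absorbing:
#' if the supplied table does not end in `qx = 1`, a row with `qx = 1` is
#' appended one year past the last supplied age, so that any cohort run on the
#' table terminates.
#'
#' @param age Integer vector of contiguous ages (ascending).
#' @param qx Numeric vector of annual death probabilities in `[0, 1]`,
#'   one per age.
#' @return An object of class `life_table` with fields `min_age`, `max_age`
#'   and `qx` (a numeric vector named by age, ending in 1).
#' @examples
#' lt <- life_table(65:66, c(0.01, 0.012))
#' qx_at(lt, 67) # appended absorbing row
#' @export
life_table <- function(age, qx) {
  if (length(age) != length(qx) || length(age) < 1L) {
    stop("`age` and `qx` must be non-empty vectors of equal length",
         call. = FALSE)
  }
  age <- as.integer(age)
  if (anyNA(age) || anyNA(qx)) stop("life table contains missing values", call. = FALSE)
  if (any(diff(age) != 1L)) {
    stop("ages must form a contiguous ascending integer range (gap detected)",
         call. = FALSE)
  }
  if (any(qx < 0 | qx > 1)) {
    stop("all qx must lie in [0, 1]", call. = FALSE)
  }
  if (qx[length(qx)] < 1) {
    age <- c(age, age[length(age)] + 1L)
    qx <- c(qx, 1)
  }
  qx <- as.numeric(qx)
  names(qx) <- age
  structure(
    list(min_age = age[1L], max_age = age[length(age)], qx = qx),
    class = "life_table"
  )
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> ages %d-%d (absorbing at %d)\n",
              x$min_age, x$max_age, x$max_age))
  invisible(x)
}

#' Annual death probability at an age
#'
#' @param table A [life_table()].
#' @param age Integer age (scalar or vector) within the table range.
#' @return Numeric vector of annual death probabilities.
#' @export
qx_at <- function(table, age) {
  stopifnot(inherits(table, "life_table"))
  if (any(age < table$min_age | age > table$max_age)) {
    stop(sprintf("age outside life table range [%d, %d]",
                 table$min_age, table$max_age), call. = FALSE)
  }
  unname(table$qx[as.character(as.integer(age))])
}

#' Read a life table from delimited text
#'
#' Expects a two-column CSV with header `age,qx`; lines beginning with `#`
#' are comments. Ages must be contiguous and `qx` within `[0, 1]`; the
#' absorbing-cap rule of [life_table()] is applied.
#'
#' @param path Path to a CSV file.
#' @return A [life_table()].
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- c("age", "qx")
  if (!all(need %in% names(df))) {
    stop("life table file must have columns 'age' and 'qx'", call. = FALSE)
  }
  if (!is.numeric(df$age) || !is.numeric(df$qx)) {
    stop("columns 'age' and 'qx' must be numeric", call. = FALSE)
  }
  life_table(df$age, df$qx)
}

#' Write a life table as CSV
#'
#' @param table A [life_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(table, path) {
  stopifnot(inherits(table, "life_table"))
  df <- data.frame(age = as.integer(names(table$qx)), qx = unname(table$qx))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Gompertz-Makeham annual death probability
#'
#' The hazard is `lambda + exp(beta * (age - modal_age))`: a constant
#' (Makeham) background plus an exponentially increasing (Gompertz) senescent
#' component. The annual death probability is `1 - exp(-hazard)`, clamped to
#' `[0, 1]`, and is monotone non-decreasing in age.
#'
#' @param age Age in years (vectorized).
#' @param lambda Makeham background hazard (per year), `>= 0`.
#' @param beta Gompertz slope (per year), `> 0`.
#' @param modal_age Age at which the senescent hazard equals 1.
#' @return Annual death probability in `[0, 1]`.
#' @examples
#' gompertz_makeham_qx(106.52, lambda = 0, beta = 0.115, modal_age = 106.52)
#' # = 1 - exp(-1)
#' @export
gompertz_makeham_qx <- function(age, lambda, beta, modal_age) {
  if (beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  h <- lambda + exp(beta * (age - modal_age))
  pmin(pmax(1 - exp(-h), 0), 1)
}

#' Generate a Gompertz-Makeham life table
#'
#' Builds a [life_table()] from the parametric hazard of
#' [gompertz_makeham_qx()], with a hard absorbing cap. The default parameters
#' were fitted to all-cause adult mortality of the 2009 US period (see
#' [us2009_life_table()]).
#'
#' @param min_age First age in the table.
#' @param cap Age at which `qx` is forced to 1 (absorbing).
#' @param lambda,beta,modal_age Hazard parameters, see
#'   [gompertz_makeham_qx()].
#' @return A [life_table()].
#' @export
gm_life_table <- function(min_age = 50L, cap = 110L,
                          lambda = 0.0043424, beta = 0.115,
                          modal_age = 106.52) {
  ages <- seq(as.integer(min_age), as.integer(cap))
  qx <- gompertz_makeham_qx(ages, lambda, beta, modal_age)
  qx[length(qx)] <- 1
  life_table(ages, qx)
}

#' Synthetic 2009-calibrated US period life table
#'
#' Loads the bundled life-table fixture: a smooth Gompertz-Makeham table whose
#' parameters were fitted to published 2009 US total-population period
#' life-table death probabilities at ages 65-95. It is a synthetic stand-in
#' constructed for reproducibility, not a transcription of the official table;
#' remaining life expectancy at 80 is approximately 9.0 years.
#'
#' @return A [life_table()] covering ages 50-110.
#' @export
us2009_life_table <- function() {
  path <- system.file("extdata", "us2009_synthetic_life_table.csv",
                      package = "hipcea", mustWork = TRUE)
  read_life_table(path)
}

#' Survival curve from a life table
#'
#' `S(k)` is the probability that a person of age `from_age` is still alive
#' after `k` whole years, for `k = 1, ..., max_age - from_age + 1`. It is
#' non-increasing and reaches 0 at the absorbing cap.
#'
#' @param table A [life_table()].
#' @param from_age Starting age within the table range.
#' @return Numeric vector of survival probabilities.
#' @export
survival_curve <- function(table, from_age) {
  stopifnot(inherits(table, "life_table"))
  from_age <- as.integer(from_age)
  if (from_age < table$min_age || from_age > table$max_age) {
    stop("`from_age` outside life table range", call. = FALSE)
  }
  ages <- seq(from_age, table$max_age)
  cumprod(1 - qx_at(table, ages))
}

#' Remaining life expectancy from a life table
#'
#' The curtate expectation is the expected number of whole years lived, i.e.
#' the sum of the survival curve; the complete expectation adds half a year
#' for the fraction of the death year lived.
#'
#' @param table A [life_table()].
#' @param at_age Age at which to evaluate.
#' @param type `"curtate"` (default) or `"complete"`.
#' @return Expected remaining years.
#' @export
life_expectancy <- function(table, at_age, type = c("curtate", "complete")) {
  type <- match.arg(type)
  e <- sum(survival_curve(table, at_age))
  if (type == "complete") e <- e + 0.5
  e
}

#' Discounted natural person-years from a life table
#'
#' Present value of one unit of annual accrual per surviving year, evaluated
#' on natural (general-population) mortality. Used by the actuarial
#' nursing-home accounting (see [accumulate_costs()]). With `discount = 0`
#' this is the complete remaining life expectancy.
#'
#' @param table A [life_table()].
#' @param at_age Age at which to evaluate.
#' @param discount Annual discount rate (default 0).
#' @return Discounted expected person-years.
#' @keywords internal
natural_person_years <- function(table, at_age, discount = 0) {
  s <- survival_curve(table, at_age)
  v <- (1 + discount)^-(seq_along(s) - 1)
  sum(s * v) + 0.5
}
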