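#' One-way sensitivity sweep
#'
#' Re-runs the incremental analysis with one parameter set to each value in
#' turn, all other parameters at base. Parameters are addressed by the dotted
#' paths of [apply_override()]. Values that fail validation produce a
#' per-value error entry (`NA` outputs, message in `error`) rather than
#' aborting the sweep.
#'
#' @param pair A [strategy_pair()].
#' @param table A [life_table()].
#' @param path Dotted parameter path.
#' @param values Numeric vector (length >= 2, or 1 for an identity check).
#' @param start_age Age at fracture (default 80, the representative
#'   sensitivity-analysis patient).
#' @param ... Passed to [run_incremental()].
#' @return Data frame with columns `value`, `delta_total`, `delta_qaly`,
#'   `error`.
#' @export
one_way_sweep <- function(pair, table, path, values, start_age = 80, ...) {
  stopifnot(inherits(pair, "strategy_pair"), length(values) >= 1)
  rows <- lapply(values, function(v) {
    res <- tryCatch({
      r <- run_incremental(apply_override(pair, path, v), table, start_age, ...)
      data.frame(value = v, delta_total = r$delta_total,
                 delta_qaly = r$delta_qaly, error = NA_character_)
    }, error = function(e) {
      data.frame(value = v, delta_total = NA_real_, delta_qaly = NA_real_,
                 error = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "parameter_path") <- path
  attr(out, "start_age") <- start_age
  out
}

#' Threshold (breakeven) analysis by bisection
#'
#' Solves for the parameter value at which total incremental savings cross
#' zero, by bisection on a user-supplied bracket whose endpoints must differ
#' in sign. For the immobile nursing-home rate the result also reports the
#' implied *overall* nonoperative nursing-home rate (the mobility-split
#' mixture with the band rate), which is how the threshold is usually
#' quoted against the surgical comparator rate.
#'
#' @param pair A [strategy_pair()].
#' @param table A [life_table()].
#' @param path Dotted parameter path.
#' @param bracket Length-2 numeric interval.
#' @param start_age Age at fracture (default 80).
#' @param tolerance_usd Absolute tolerance on total savings at the root
#'   (default 1 USD).
#' @param max_iter Bisection iteration cap (default 200).
#' @param ... Passed to [run_incremental()].
#' @return A `breakeven_result`: list with `parameter_path`, `root`,
#'   `overall_rate_at_root` (`NA` unless the parameter is a nursing-home
#'   rate), `bracket`, `achieved_tolerance_usd`, `iterations`.
#' @export
breakeven <- function(pair, table, path, bracket, start_age = 80,
                      tolerance_usd = 1, max_iter = 200L, ...) {
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2])
  f <- function(v) {
    run_incremental(apply_override(pair, path, v), table, start_age,
                    ...)$delta_total
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- f(lo); f_hi <- f(hi)
  if (sign(f_lo) == sign(f_hi)) {
    stop("total savings do not change sign over the bracket", call. = FALSE)
  }
  it <- 0L
  mid <- (lo + hi) / 2; f_mid <- f(mid)
  while (abs(f_mid) > tolerance_usd && it < max_iter) {
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid; f_hi <- f_mid
    }
    mid <- (lo + hi) / 2; f_mid <- f(mid)
    it <- it + 1L
  }
  overall <- NA_real_
  if (path %in% c("nh_rates.rate_immobile", "nonoperative.nh_rates.rate_immobile")) {
    p <- pair$nonoperative$strategy$prob_mobile_if_survive
    band <- nh_band_rate(pair$nonoperative$nh_rates, start_age)
    overall <- p * band + (1 - p) * mid
  }
  structure(list(parameter_path = path, root = mid,
                 overall_rate_at_root = overall,
                 bracket = bracket,
                 achieved_tolerance_usd = abs(f_mid),
                 iterations = it),
            class = "breakeven_result")
}

#' @export
print.breakeven_result <- function(x, ...) {
  cat(sprintf("<breakeven_result> %s = %.6f (|savings| <= %.3g USD, %d iter)\n",
              x$parameter_path, x$root, x$achieved_tolerance_usd, x$iterations))
  if (!is.na(x$overall_rate_at_root)) {
    cat(sprintf("  implied overall nonoperative nursing-home rate: %.4f\n",
                x$overall_rate_at_root))
  }
  invisible(x)
}

#' Multi-parameter scenario run
#'
#' Applies a set of overrides jointly and runs the incremental analysis
#' once. Duplicate parameter paths are an error (a scenario must be
#' unambiguous).
#'
#' @param pair A [strategy_pair()].
#' @param table A [life_table()].
#' @param overrides Named list or named numeric vector: names are parameter
#'   paths, values the scenario values. Empty = base run.
#' @param start_age Age at fracture (default 80).
#' @param ... Passed to [run_incremental()].
#' @return An `incremental_result`.
#' @export
scenario_run <- function(pair, table, overrides = list(), start_age = 80, ...) {
  paths <- names(overrides)
  if (length(overrides) && (is.null(paths) || any(paths == ""))) {
    stop("`overrides` must be named by parameter paths", call. = FALSE)
  }
  if (anyDuplicated(paths)) {
    stop("duplicate parameter paths in scenario", call. = FALSE)
  }
  for (p in paths) pair <- apply_override(pair, p, overrides[[p]])
  run_incremental(pair, table, start_age, ...)
}

#' Write a sensitivity sweep as CSV
#'
#' Two-point sweeps are written in the endpoint layout of a tornado-style
#' report (`parameter, lo, hi, saving_lo, saving_hi, qaly_lo, qaly_hi`);
#' longer sweeps are written in long format.
#'
#' @param sweeps A list of sweep data frames from [one_way_sweep()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweeps, path) {
  if (is.data.frame(sweeps)) sweeps <- list(sweeps)
  two_pt <- all(vapply(sweeps, nrow, integer(1)) == 2L)
  if (two_pt) {
    df <- do.call(rbind, lapply(sweeps, function(s) {
      data.frame(parameter = attr(s, "parameter_path"),
                 lo = s$value[1], hi = s$value[2],
                 saving_lo = s$delta_total[1], saving_hi = s$delta_total[2],
                 qaly_lo = s$delta_qaly[1], qaly_hi = s$delta_qaly[2])
    }))
  } else {
    df <- do.call(rbind, lapply(sweeps, function(s) {
      cbind(parameter = attr(s, "parameter_path"), s)
    }))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
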