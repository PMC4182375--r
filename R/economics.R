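#' Lifetime costs by category for one cohort trace
#'
#' Accumulates the four societal cost categories over a cohort trace, in the
#' currency of the cost schedule (2009 USD at defaults):
#'
#' * **direct_medical** - the acute index-episode cost (posted in cycle 1 for
#'   the whole entering cohort; it covers hospitalization through 6 months)
#'   plus the revision/conversion episode cost for every revision or
#'   conversion event.
#' * **longterm_medical** - the annual long-term medical cost times alive
#'   person-years, with the first cycle weighted 0.5 because its first six
#'   months fall inside the acute window.
#' * **nursing_home** - long-term custodial care for the designated fraction.
#'   For nonoperative arms the designation follows the mobility trace: the
#'   immobile occupancy accrues at `rate_immobile` and the mobile occupancy
#'   at the age-band rate, every alive cycle. For surgical arms the default
#'   accounting is *actuarial*: the age-band designation rate times the
#'   annual cost times the general-population complete remaining life
#'   expectancy at the age at fracture, applied to the whole entering
#'   cohort. Surgical long-run survival is close to natural, and the band
#'   rates describe lifetime institutionalization of the general elderly
#'   population, so the comparator's custodial exposure is valued
#'   actuarially rather than through the transient post-fracture trace;
#'   `nh_surgical_accrual = "trace"` switches to occupancy-based accrual.
#' * **home_modification** - a one-time cost paid at the end of cycle 1 by
#'   survivors who are not designated nursing-home users.
#'
#' @param trace A `cohort_trace`.
#' @param costs The `costs` component of a `param_bundle`.
#' @param nh_rates The `nh_rates` component of a `param_bundle`.
#' @param table The [life_table()] the trace was run on (needed for the
#'   actuarial nursing-home accounting).
#' @param discount Annual discount rate (default 0: undiscounted base case).
#' @param nh_surgical_accrual `"actuarial"` (default) or `"trace"`.
#' @param nh_replaces_longterm If `TRUE`, nursing-home designation replaces
#'   (rather than adds to) long-term annual medical cost. Default `FALSE`.
#' @return A `cost_breakdown`: list with the four categories and `total`.
#' @export
accumulate_costs <- function(trace, costs, nh_rates, table,
                             discount = 0,
                             nh_surgical_accrual = c("actuarial", "trace"),
                             nh_replaces_longterm = FALSE) {
  stopifnot(inherits(trace, "cohort_trace"))
  nh_surgical_accrual <- match.arg(nh_surgical_accrual)
  arm <- attr(trace, "arm")
  start_age <- attr(trace, "start_age")
  band_rate <- nh_band_rate(nh_rates, start_age)
  v <- (1 + discount)^-(trace$cycle - 1)
  alive <- alive_mass(trace)
  events <- trace$new_revisions_aseptic + trace$new_revisions_infection +
    trace$new_conversions

  direct <- costs$acute_cost * v[1] +
    costs$revision_or_conversion_cost * sum(events * v)

  lt_weight <- ifelse(trace$cycle == 1, 0.5, 1)
  if (arm == "surgical") {
    nh_frac_alive <- rep(band_rate, nrow(trace))
  } else {
    # designation fraction among the alive mass, by mobility state
    nh_mass <- nh_rates$rate_immobile * trace$immobile +
      band_rate * trace$mobile
    nh_frac_alive <- ifelse(alive > 0, nh_mass / alive, 0)
  }
  lt_base <- if (nh_replaces_longterm) alive * (1 - nh_frac_alive) else alive
  longterm <- costs$longterm_annual * sum(lt_base * lt_weight * v)

  if (arm == "surgical") {
    if (nh_surgical_accrual == "actuarial") {
      nursing <- costs$nursing_home_annual * band_rate *
        natural_person_years(table, start_age, discount)
    } else {
      nursing <- costs$nursing_home_annual * band_rate * sum(alive * v)
    }
    home_mod_mass <- (1 - band_rate) * alive[1]
  } else {
    nursing <- costs$nursing_home_annual *
      sum((nh_rates$rate_immobile * trace$immobile +
             band_rate * trace$mobile) * v)
    home_mod_mass <- (1 - band_rate) * trace$mobile[1] +
      (1 - nh_rates$rate_immobile) * trace$immobile[1]
  }
  home_mod <- costs$home_modification_once * home_mod_mass * v[1]

  out <- list(direct_medical = direct, longterm_medical = longterm,
              nursing_home = nursing, home_modification = home_mod)
  out$total <- direct + longterm + nursing + home_mod
  structure(out, class = "cost_breakdown")
}

#' Lifetime quality-adjusted life years for one cohort trace
#'
#' QALYs are the utility-weighted sum of state occupancy over all cycles,
#' plus one-time disutilities: the index-surgery disutility is posted in
#' cycle 1 on the whole entering cohort (surgical arms only), and the
#' revision disutility on every revising or converting mass.
#'
#' @param trace A `cohort_trace`.
#' @param strategy The `strategy` component of a `param_bundle`.
#' @param discount Annual discount rate (default 0).
#' @return Lifetime QALYs (scalar).
#' @export
accumulate_qalys <- function(trace, strategy, discount = 0) {
  stopifnot(inherits(trace, "cohort_trace"))
  v <- (1 + discount)^-(trace$cycle - 1)
  util_map <- c(
    well = "utility_well",
    post_conversion = "utility_post_conversion",
    post_aseptic_revision = "utility_post_aseptic_revision",
    post_infection_revision = "utility_post_infection_revision",
    mobile = "utility_mobile",
    immobile = "utility_immobile"
  )
  q <- 0
  for (st in names(util_map)) {
    occ <- trace[[st]]
    if (all(occ == 0)) next
    u <- strategy[[util_map[[st]]]]
    if (is.null(u)) {
      stop(sprintf("state '%s' is occupied but '%s' is not set",
                   st, util_map[[st]]), call. = FALSE)
    }
    q <- q + u * sum(occ * v)
  }
  if (identical(attr(trace, "arm"), "surgical")) {
    q <- q + strategy$disutility_index_surgery * v[1]
    events <- trace$new_revisions_aseptic + trace$new_revisions_infection +
      trace$new_conversions
    q <- q + strategy$disutility_revision * sum(events * v)
  }
  q
}

#' Evaluate one treatment arm at one starting age
#'
#' Runs the cohort engine and accumulates costs and QALYs.
#'
#' @param bundle A `param_bundle`.
#' @param table A [life_table()].
#' @param start_age Age at fracture.
#' @param ... Passed to [accumulate_costs()] (`discount`,
#'   `nh_surgical_accrual`, `nh_replaces_longterm`).
#' @param discount Annual discount rate (default 0).
#' @return An `arm_evaluation`: list with `trace`, `costs`, `qaly`.
#' @export
evaluate_arm <- function(bundle, table, start_age, discount = 0, ...) {
  trace <- run_cohort(bundle, table, start_age)
  costs <- accumulate_costs(trace, bundle$costs, bundle$nh_rates, table,
                            discount = discount, ...)
  qaly <- accumulate_qalys(trace, bundle$strategy, discount = discount)
  structure(list(trace = trace, costs = costs, qaly = qaly),
            class = "arm_evaluation")
}

#' Incremental result: surgery relative to nonoperative care
#'
#' Savings are nonoperative cost minus surgical cost per category (positive =
#' surgery saves money); the QALY difference is surgical minus nonoperative.
#' Surgery *dominates* when both total savings and the QALY gain are
#' positive; when surgery costs more but gains QALYs, the incremental
#' cost-effectiveness ratio (extra cost per extra QALY) is reported instead.
#'
#' @param surgical,nonoperative `arm_evaluation`s computed on the same start
#'   age and life table.
#' @return An `incremental_result`: list with `savings` (named vector over
#'   the four categories), `delta_total`, `delta_qaly`, `icer` (`NA` unless
#'   surgery costs more), and `dominance` (`"dominant"`, `"dominated"` or
#'   `"tradeoff"`).
#' @export
incremental <- function(surgical, nonoperative) {
  cats <- c("direct_medical", "longterm_medical", "nursing_home",
            "home_modification")
  savings <- vapply(cats, function(k) {
    nonoperative$costs[[k]] - surgical$costs[[k]]
  }, numeric(1))
  delta_total <- sum(savings)
  delta_qaly <- surgical$qaly - nonoperative$qaly
  make_incremental(savings, delta_total, delta_qaly)
}

make_incremental <- function(savings, delta_total, delta_qaly) {
  dominance <- if (delta_total > 0 && delta_qaly > 0) {
    "dominant"
  } else if (delta_total < 0 && delta_qaly < 0) {
    "dominated"
  } else {
    "tradeoff"
  }
  icer <- if (delta_total < 0 && delta_qaly != 0) {
    (-delta_total) / delta_qaly
  } else {
    NA_real_
  }
  structure(list(savings = savings, delta_total = delta_total,
                 delta_qaly = delta_qaly, icer = icer, dominance = dominance),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat("<incremental_result> surgery vs nonoperative\n")
  s <- round(c(x$savings, total = x$delta_total))
  for (k in names(s)) cat(sprintf("  savings %-18s %10.0f USD\n", k, s[[k]]))
  cat(sprintf("  delta QALY %19.2f\n", x$delta_qaly))
  cat(sprintf("  %s%s\n", x$dominance,
              if (!is.na(x$icer)) sprintf(" (ICER %0.0f USD/QALY)", x$icer) else ""))
  invisible(x)
}

#' Run a strategy pair and form the incremental result
#'
#' @param pair A [strategy_pair()].
#' @param table A [life_table()].
#' @param start_age Age at fracture.
#' @param ... Passed to [evaluate_arm()].
#' @return An `incremental_result`.
#' @examples
#' \donttest{
#' lt <- gm_life_table(min_age = 65)
#' run_incremental(strategy_pair("hemiarthroplasty"), lt, 80)
#' }
#' @export
run_incremental <- function(pair, table, start_age, ...) {
  stopifnot(inherits(pair, "strategy_pair"))
  surg <- evaluate_arm(pair$surgical, table, start_age, ...)
  nonop <- evaluate_arm(pair$nonoperative, table, start_age, ...)
  incremental(surg, nonop)
}

#' Age-weighted summary of incremental results
#'
#' Element-wise weighted average of the per-age savings and QALY deltas;
#' dominance and the ICER are recomputed from the weighted totals.
#'
#' @param results Named list of `incremental_result`s, names = ages.
#' @param weights Named numeric vector of weights over the same ages,
#'   summing to 1.
#' @return An `incremental_result`.
#' @export
age_weighted_summary <- function(results, weights) {
  if (is.null(names(results)) || is.null(names(weights)) ||
      !setequal(names(results), names(weights))) {
    stop("`results` and `weights` must be named by the same ages", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("weights must sum to 1", call. = FALSE)
  }
  weights <- weights[names(results)]
  savings <- Reduce(`+`, Map(function(r, w) r$savings * w, results, weights))
  delta_total <- sum(vapply(names(results), function(a) {
    results[[a]]$delta_total * weights[[a]]
  }, numeric(1)))
  delta_qaly <- sum(vapply(names(results), function(a) {
    results[[a]]$delta_qaly * weights[[a]]
  }, numeric(1)))
  make_incremental(savings, delta_total, delta_qaly)
}

#' Incremental results across ages, plus the weighted overall row
#'
#' Convenience wrapper running [run_incremental()] at every age of an age
#' distribution and summarizing with [age_weighted_summary()].
#'
#' @param pair A [strategy_pair()].
#' @param table A [life_table()].
#' @param age_distribution Named numeric vector (names = ages, values =
#'   weights summing to 1).
#' @param ... Passed to [run_incremental()].
#' @return List with `by_age` (named list of `incremental_result`s) and
#'   `overall` (the weighted `incremental_result`).
#' @export
run_age_profile <- function(pair, table, age_distribution, ...) {
  ages <- names(age_distribution)
  by_age <- stats::setNames(lapply(ages, function(a) {
    run_incremental(pair, table, as.integer(a), ...)
  }), ages)
  list(by_age = by_age,
       overall = age_weighted_summary(by_age, age_distribution))
}

#' Write incremental results as a savings table CSV
#'
#' One row per age group plus overall; columns mirror the savings
#' decomposition (direct medical, long-term medical, nursing home, home
#' modification, total, QALY delta, ICER, dominance).
#'
#' @param profile Result of [run_age_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_savings_csv <- function(profile, path) {
  rows <- c(profile$by_age, list(overall = profile$overall))
  df <- do.call(rbind, lapply(names(rows), function(nm) {
    r <- rows[[nm]]
    data.frame(age_group = nm,
               savings_direct = r$savings[["direct_medical"]],
               savings_longterm = r$savings[["longterm_medical"]],
               savings_nh = r$savings[["nursing_home"]],
               savings_homemod = r$savings[["home_modification"]],
               total = r$delta_total, delta_qaly = r$delta_qaly,
               icer = r$icer, dominance = r$dominance)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
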