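#' National cohort counts by fracture type
#'
#' Sizes the annual US elderly surgical cohorts from discharge counts:
#' extracapsular fractures are half of elderly discharges, and displaced
#' intracapsular fractures are 85% of the intracapsular half. Counts are
#' rounded half-up.
#'
#' @param inputs A [national_inputs()].
#' @return Named list: `n_intracapsular_displaced`, `n_extracapsular`.
#' @examples
#' cohort_counts(national_inputs())
#' @export
cohort_counts <- function(inputs) {
  stopifnot(inherits(inputs, "national_inputs"))
  elderly <- inputs$annual_discharges * inputs$fraction_age65plus
  extra <- elderly * inputs$fraction_extracapsular
  intra_disp <- elderly * (1 - inputs$fraction_extracapsular) *
    inputs$fraction_intracapsular_displaced
  round_half_up <- function(x) floor(x + 0.5)
  list(n_intracapsular_displaced = round_half_up(intra_disp),
       n_extracapsular = round_half_up(extra))
}

#' Scale per-patient results to the national cohort
#'
#' Multiplies the per-patient (age-weighted overall) incremental results of
#' each fracture type by the corresponding annual cohort count. *Benefits*
#' are the indirect savings categories (long-term medical + nursing home +
#' home modification); the *direct cost increase* is the extra direct
#' medical cost of surgery (minus the direct-medical savings). Net savings
#' equal benefits minus the direct cost increase, exactly linearly in the
#' counts.
#'
#' @param per_patient Named list with `incremental_result`s for
#'   `intracapsular` and `extracapsular`.
#' @param counts Result of [cohort_counts()].
#' @return A `national_estimate`: list with the counts, `total_benefits`,
#'   `total_direct_cost_increase`, `net_savings` (all USD) and
#'   `benefit_shares` (fractions by category, summing to 1).
#' @export
national_rollup <- function(per_patient, counts) {
  need <- c("intracapsular", "extracapsular")
  if (!all(need %in% names(per_patient))) {
    stop("`per_patient` must contain 'intracapsular' and 'extracapsular' results",
         call. = FALSE)
  }
  n <- c(intracapsular = counts$n_intracapsular_displaced,
         extracapsular = counts$n_extracapsular)
  benefit_cats <- c("longterm_medical", "nursing_home", "home_modification")
  benefit_by_cat <- stats::setNames(numeric(length(benefit_cats)), benefit_cats)
  benefits <- 0; direct_increase <- 0
  for (ft in need) {
    r <- per_patient[[ft]]
    benefit_by_cat <- benefit_by_cat + r$savings[benefit_cats] * n[[ft]]
    benefits <- benefits + sum(r$savings[benefit_cats]) * n[[ft]]
    direct_increase <- direct_increase + (-r$savings[["direct_medical"]]) * n[[ft]]
  }
  structure(list(
    n_intracapsular_displaced = counts$n_intracapsular_displaced,
    n_extracapsular = counts$n_extracapsular,
    total_benefits = benefits,
    total_direct_cost_increase = direct_increase,
    net_savings = benefits - direct_increase,
    benefit_shares = if (benefits != 0) benefit_by_cat / benefits else
      benefit_by_cat * NA_real_
  ), class = "national_estimate")
}

#' @export
print.national_estimate <- function(x, ...) {
  b <- function(v) sprintf("%.1f billion USD", v / 1e9)
  cat("<national_estimate>\n")
  cat(sprintf("  cohorts: %s intracapsular displaced, %s extracapsular\n",
              format(x$n_intracapsular_displaced, big.mark = ","),
              format(x$n_extracapsular, big.mark = ",")))
  cat(sprintf("  benefits %s, direct cost increase %s, net savings %s\n",
              b(x$total_benefits), b(x$total_direct_cost_increase),
              b(x$net_savings)))
  cat(sprintf("  nursing-home share of benefits: %.1f%%\n",
              100 * x$benefit_shares[["nursing_home"]]))
  invisible(x)
}

#' Full national analysis from strategy pairs
#'
#' Runs age profiles for an intracapsular and an extracapsular strategy
#' pair, takes the age-weighted overall per-patient results, and rolls them
#' up to the national cohort.
#'
#' @param intracapsular_pair,extracapsular_pair [strategy_pair()]s of the
#'   respective fracture types.
#' @param table A [life_table()].
#' @param age_distribution Named weight vector over ages (sums to 1).
#' @param inputs A [national_inputs()].
#' @param ... Passed to [run_incremental()].
#' @return List with `per_patient` (overall `incremental_result` per
#'   fracture type) and `national` (`national_estimate`).
#' @export
national_analysis <- function(intracapsular_pair, extracapsular_pair, table,
                              age_distribution, inputs = national_inputs(),
                              ...) {
  per_patient <- list(
    intracapsular = run_age_profile(intracapsular_pair, table,
                                    age_distribution, ...)$overall,
    extracapsular = run_age_profile(extracapsular_pair, table,
                                    age_distribution, ...)$overall
  )
  list(per_patient = per_patient,
       national = national_rollup(per_patient, cohort_counts(inputs)))
}
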