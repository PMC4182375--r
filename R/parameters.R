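#' @keywords internal
SURGICAL_IDS <- c("hemiarthroplasty", "tha", "sliding_hip_screw", "gamma_nail")
#' @keywords internal
NONOP_IDS <- c("nonoperative_intracapsular", "nonoperative_extracapsular")

#' Recognized strategy identifiers
#'
#' Four surgical techniques (hemiarthroplasty and total hip arthroplasty for
#' displaced intracapsular fractures; sliding hip screw and Gamma
#' intramedullary nail for extracapsular fractures) and the two nonoperative
#' comparators. Internal fixation of displaced intracapsular fractures is
#' deliberately not modeled: it is not the preferred treatment in this age
#' group.
#'
#' @return Character vector of strategy ids.
#' @export
strategy_ids <- function() c(SURGICAL_IDS, NONOP_IDS)

# Base-case clinical parameters and utilities per strategy. Utilities are
# annual quality weights; disutilities are one-time decrements attached to an
# operation. Extracapsular "revision" rates are the post-conversion (THA)
# rates: the fixed-implant well state has no revision exits after year 1.
strategy_defaults <- function(strategy_id) {
  base_surgical <- list(
    revision_mortality_aseptic = 0.012,
    revision_mortality_infection = 0.0193,
    disutility_index_surgery = -0.15,
    disutility_revision = -0.2
  )
  switch(strategy_id,
    hemiarthroplasty = c(list(
      strategy_id = "hemiarthroplasty", fracture_type = "intracapsular",
      arm = "surgical",
      annual_revision_aseptic = 0.034, annual_revision_infection = 0.0053,
      utility_well = 0.66,
      utility_post_aseptic_revision = 0.66,
      utility_post_infection_revision = 0.39), base_surgical),
    tha = c(list(
      strategy_id = "tha", fracture_type = "intracapsular",
      arm = "surgical",
      annual_revision_aseptic = 0.0067, annual_revision_infection = 0.0033,
      utility_well = 0.7,
      utility_post_aseptic_revision = 0.7,
      utility_post_infection_revision = 0.39), base_surgical),
    sliding_hip_screw = c(list(
      strategy_id = "sliding_hip_screw", fracture_type = "extracapsular",
      arm = "surgical",
      conversion_rate_year1 = 0.04,
      annual_revision_aseptic = 0.0067, annual_revision_infection = 0.0033,
      utility_well = 0.54,
      utility_post_conversion = 0.54,
      utility_post_aseptic_revision = 0.54,
      utility_post_infection_revision = 0.38), base_surgical),
    gamma_nail = c(list(
      strategy_id = "gamma_nail", fracture_type = "extracapsular",
      arm = "surgical",
      conversion_rate_year1 = 0.06,
      annual_revision_aseptic = 0.0067, annual_revision_infection = 0.0033,
      utility_well = 0.54,
      utility_post_conversion = 0.54,
      utility_post_aseptic_revision = 0.54,
      utility_post_infection_revision = 0.38), base_surgical),
    nonoperative_intracapsular = list(
      strategy_id = "nonoperative_intracapsular",
      fracture_type = "intracapsular", arm = "nonoperative",
      prob_mobile_if_survive = 0.5,
      utility_mobile = 0.39, utility_immobile = 0),
    nonoperative_extracapsular = list(
      strategy_id = "nonoperative_extracapsular",
      fracture_type = "extracapsular", arm = "nonoperative",
      prob_mobile_if_survive = 0.5,
      utility_mobile = 0.38, utility_immobile = 0),
    stop(sprintf("unknown strategy '%s'", strategy_id), call. = FALSE)
  )
}

# Acute (index episode to 6 months) all-payer cost per strategy, 2009 USD.
acute_costs <- c(
  hemiarthroplasty = 52126, tha = 49207,
  sliding_hip_screw = 54054, gamma_nail = 54054,
  nonoperative_intracapsular = 40795, nonoperative_extracapsular = 34509
)

#' Default parameter bundle for a strategy
#'
#' Assembles the base-case clinical parameters, utilities, cost schedule,
#' excess-mortality multipliers and nursing-home utilization rates for one
#' treatment arm. All values are the model's base case (2009 USD).
#'
#' The excess-mortality multipliers scale the natural annual death
#' probability: 3.07 in the first year after fracture, 1.87 in the second,
#' back to natural thereafter; nonoperative arms carry an additional factor
#' of 1.33 in the first two years. Long-term nursing-home designation rates
#' are 0.16 / 0.243 / 0.481 by age band (65-74 / 75-84 / 85+) for surgically
#' treated and mobile nonoperative patients, and 0.9 for immobile
#' nonoperative patients regardless of age.
#'
#' @param strategy_id One of [strategy_ids()].
#' @return A `param_bundle`: list with components `strategy`, `costs`,
#'   `multipliers` and `nh_rates`.
#' @examples
#' b <- default_parameters("hemiarthroplasty")
#' b$strategy$annual_revision_aseptic # 0.034
#' @export
default_parameters <- function(strategy_id) {
  strategy_id <- match.arg(strategy_id, strategy_ids())
  strat <- strategy_defaults(strategy_id)
  costs <- list(
    acute_cost = unname(acute_costs[[strategy_id]]),
    revision_or_conversion_cost = 44784,
    longterm_annual = if (strat$arm == "surgical") 12941 else 14790,
    nursing_home_annual = 74498,
    home_modification_once = 349
  )
  multipliers <- list(
    rr_year1 = 3.07, rr_year2 = 1.87, nonop_factor = 1.33,
    excess_years = 2L, rr_beyond = 1.0
  )
  nh_rates <- list(
    band_lo = c(65L, 75L, 85L),
    band_hi = c(74L, 84L, 110L),
    rate_surgical_or_mobile = c(0.16, 0.243, 0.481),
    rate_immobile = 0.9
  )
  bundle <- structure(
    list(strategy = strat, costs = costs, multipliers = multipliers,
         nh_rates = nh_rates),
    class = "param_bundle"
  )
  validate_bundle(bundle)
  bundle
}

#' @export
print.param_bundle <- function(x, ...) {
  cat(sprintf("<param_bundle> %s (%s, %s arm)\n", x$strategy$strategy_id,
              x$strategy$fracture_type, x$strategy$arm))
  invisible(x)
}

in_unit <- function(x) all(x >= 0 & x <= 1)

#' Validate a parameter bundle
#'
#' Checks probability, utility, cost and multiplier bounds and the structural
#' invariants of the nursing-home rate bands. Called automatically by
#' [default_parameters()] and [apply_override()].
#'
#' @param bundle A `param_bundle`.
#' @return `bundle`, invisibly; errors on violation.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "param_bundle"))
  s <- bundle$strategy
  probs <- c(s$annual_revision_aseptic, s$annual_revision_infection,
             s$revision_mortality_aseptic, s$revision_mortality_infection,
             s$conversion_rate_year1, s$prob_mobile_if_survive)
  if (!in_unit(probs)) {
    stop("strategy probabilities must lie in [0, 1]", call. = FALSE)
  }
  utils_ <- unlist(s[grep("^(utility_|disutility_)", names(s))])
  if (length(utils_) && !all(utils_ >= -1 & utils_ <= 1)) {
    stop("utilities and disutilities must lie in [-1, 1]", call. = FALSE)
  }
  if (s$arm == "surgical") {
    exit1 <- s$annual_revision_aseptic + s$annual_revision_infection
    if (exit1 > 1) stop("total annual revision probability exceeds 1", call. = FALSE)
    if (s$fracture_type == "intracapsular" &&
        !is.null(s$conversion_rate_year1)) {
      stop("conversion_rate_year1 is only defined for extracapsular surgical strategies",
           call. = FALSE)
    }
  }
  co <- bundle$costs
  if (any(unlist(co) < 0)) stop("costs must be non-negative", call. = FALSE)
  m <- bundle$multipliers
  if (any(c(m$rr_year1, m$rr_year2, m$nonop_factor, m$rr_beyond) <= 0)) {
    stop("mortality multipliers must be positive", call. = FALSE)
  }
  if (m$excess_years < 2) stop("excess_years must be >= 2", call. = FALSE)
  nh <- bundle$nh_rates
  if (!in_unit(c(nh$rate_surgical_or_mobile, nh$rate_immobile))) {
    stop("nursing-home rates must lie in [0, 1]", call. = FALSE)
  }
  if (any(nh$band_lo[-1] != nh$band_hi[-length(nh$band_hi)] + 1L)) {
    stop("nursing-home age bands must partition the age range", call. = FALSE)
  }
  if (any(nh$rate_immobile < nh$rate_surgical_or_mobile)) {
    warning("rate_immobile is below a surgical/mobile band rate", call. = FALSE)
  }
  invisible(bundle)
}

#' Nursing-home designation rate for the surgical/mobile band
#'
#' Looks up the long-term nursing-home use probability for surgically treated
#' (or mobile nonoperative) patients by the age band of the age at fracture.
#' The band is fixed at the age at fracture and not updated as the cohort
#' ages.
#'
#' @param nh_rates The `nh_rates` component of a `param_bundle`.
#' @param age Age at fracture.
#' @return A probability.
#' @export
nh_band_rate <- function(nh_rates, age) {
  i <- which(age >= nh_rates$band_lo & age <= nh_rates$band_hi)
  if (length(i) != 1L) {
    stop(sprintf("no nursing-home age band covers age %s", age), call. = FALSE)
  }
  nh_rates$rate_surgical_or_mobile[i]
}

#' Overall nonoperative nursing-home rate
#'
#' The population-level nursing-home use rate of the nonoperative arm is the
#' mobility-split mixture `p_mobile * band_rate + (1 - p_mobile) *
#' rate_immobile`. At base values this reproduces 53% / 57% / 69% across the
#' three age bands.
#'
#' @param bundle A nonoperative `param_bundle`.
#' @param age Age at fracture.
#' @return A probability.
#' @export
overall_nonop_nh_rate <- function(bundle, age) {
  stopifnot(bundle$strategy$arm == "nonoperative")
  p <- bundle$strategy$prob_mobile_if_survive
  p * nh_band_rate(bundle$nh_rates, age) +
    (1 - p) * bundle$nh_rates$rate_immobile
}

# Resolve a dotted parameter path inside a bundle; returns list(idx = index
# vector usable with [[ ]]) or NULL when the path does not exist.
resolve_path <- function(bundle, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) < 2L) return(NULL)
  node <- bundle
  for (k in seq_len(length(parts) - 1L)) {
    if (!is.list(node) || is.null(node[[parts[k]]])) return(NULL)
    node <- node[[parts[k]]]
  }
  leaf <- parts[length(parts)]
  idx <- as.list(parts)
  if (is.list(node)) {
    if (is.null(node[[leaf]])) return(NULL)
    if (!is.numeric(node[[leaf]]) || length(node[[leaf]]) != 1L) return(NULL)
    return(idx)
  }
  # named numeric vector leaf addressed by element (e.g. band rates)
  NULL
}

#' Override one scalar parameter
#'
#' Returns a copy of the bundle with the parameter named by a dotted path
#' (e.g. `"costs.nursing_home_annual"`, `"strategy.prob_mobile_if_survive"`,
#' `"multipliers.nonop_factor"`) replaced, and validation re-run. Elements of
#' the banded nursing-home rate are addressed as
#' `"nh_rates.rate_surgical_or_mobile[2]"` (1 = ages 65-74, 2 = 75-84,
#' 3 = 85+).
#'
#' @param bundle A `param_bundle` or `strategy_pair`.
#' @param path Dotted parameter path.
#' @param value Replacement scalar.
#' @return A new object of the same class.
#' @export
apply_override <- function(bundle, path, value) UseMethod("apply_override")

#' @export
apply_override.param_bundle <- function(bundle, path, value) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
    stop("`value` must be a single non-missing number", call. = FALSE)
  }
  band <- regmatches(path, regexec("^nh_rates\\.rate_surgical_or_mobile\\[([123])\\]$", path))[[1]]
  if (length(band) == 2L) {
    bundle$nh_rates$rate_surgical_or_mobile[as.integer(band[2])] <- value
    validate_bundle(bundle)
    return(bundle)
  }
  idx <- resolve_path(bundle, path)
  if (is.null(idx)) {
    stop(sprintf("unknown parameter path '%s'", path), call. = FALSE)
  }
  bundle[[idx[[1]]]][[idx[[2]]]] <- value
  if (identical(idx[[2]], "excess_years")) {
    bundle$multipliers$excess_years <- as.integer(value)
  }
  validate_bundle(bundle)
  bundle
}

# Does a path exist (and name a scalar) in this bundle?
has_path <- function(bundle, path) {
  if (grepl("^nh_rates\\.rate_surgical_or_mobile\\[[123]\\]$", path)) return(TRUE)
  !is.null(resolve_path(bundle, path))
}

#' Pair a surgical strategy with its nonoperative comparator
#'
#' @param surgical_id A surgical strategy id.
#' @param nonoperative_id A nonoperative strategy id of the same fracture
#'   type; defaults to the matching comparator.
#' @return A `strategy_pair`: list with `surgical` and `nonoperative`
#'   `param_bundle`s.
#' @examples
#' pair <- strategy_pair("hemiarthroplasty")
#' @export
strategy_pair <- function(surgical_id, nonoperative_id = NULL) {
  surgical_id <- match.arg(surgical_id, SURGICAL_IDS)
  surg <- default_parameters(surgical_id)
  if (is.null(nonoperative_id)) {
    nonoperative_id <- paste0("nonoperative_", surg$strategy$fracture_type)
  }
  nonoperative_id <- match.arg(nonoperative_id, NONOP_IDS)
  nonop <- default_parameters(nonoperative_id)
  if (surg$strategy$fracture_type != nonop$strategy$fracture_type) {
    stop("surgical and nonoperative strategies must share a fracture type",
         call. = FALSE)
  }
  structure(list(surgical = surg, nonoperative = nonop),
            class = "strategy_pair")
}

#' @export
print.strategy_pair <- function(x, ...) {
  cat(sprintf("<strategy_pair> %s vs %s\n", x$surgical$strategy$strategy_id,
              x$nonoperative$strategy$strategy_id))
  invisible(x)
}

#' @rdname apply_override
#' @details For a `strategy_pair`, a path prefixed `"surgical."` or
#'   `"nonoperative."` is applied to that arm only; an unprefixed path is
#'   applied to every arm in which it exists (shared parameters such as
#'   `"costs.nursing_home_annual"` thus stay synchronized across arms).
#' @export
apply_override.strategy_pair <- function(bundle, path, value) {
  arm <- sub("\\..*$", "", path)
  if (arm %in% c("surgical", "nonoperative")) {
    sub_path <- sub("^[a-z]+\\.", "", path)
    bundle[[arm]] <- apply_override(bundle[[arm]], sub_path, value)
    return(bundle)
  }
  hit <- vapply(bundle, has_path, logical(1), path = path)
  if (!any(hit)) {
    stop(sprintf("unknown parameter path '%s'", path), call. = FALSE)
  }
  for (a in names(bundle)[hit]) {
    bundle[[a]] <- apply_override(bundle[[a]], path, value)
  }
  bundle
}

#' Serialize / restore parameter bundles
#'
#' `bundle_to_config()` converts a `param_bundle` or `strategy_pair` to a
#' plain nested list suitable for writing as YAML or JSON;
#' `bundle_from_config()` restores (and re-validates) it. Full double
#' precision survives a JSON round trip written with `digits = NA`.
#'
#' @param bundle A `param_bundle` or `strategy_pair`.
#' @return A plain list (`bundle_to_config`) or restored object
#'   (`bundle_from_config`).
#' @export
bundle_to_config <- function(bundle) {
  if (inherits(bundle, "strategy_pair")) {
    return(list(surgical = bundle_to_config(bundle$surgical),
                nonoperative = bundle_to_config(bundle$nonoperative)))
  }
  stopifnot(inherits(bundle, "param_bundle"))
  unclass(bundle)
}

#' @rdname bundle_to_config
#' @param config A list produced by `bundle_to_config()` (possibly read back
#'   from YAML/JSON).
#' @export
bundle_from_config <- function(config) {
  if (!is.null(config$surgical) && !is.null(config$nonoperative) &&
      is.null(config$strategy)) {
    pair <- structure(list(surgical = bundle_from_config(config$surgical),
                           nonoperative = bundle_from_config(config$nonoperative)),
                      class = "strategy_pair")
    return(pair)
  }
  need <- c("strategy", "costs", "multipliers", "nh_rates")
  if (!all(need %in% names(config))) {
    stop("config is missing bundle components", call. = FALSE)
  }
  config$multipliers$excess_years <- as.integer(config$multipliers$excess_years)
  config$nh_rates$band_lo <- as.integer(unlist(config$nh_rates$band_lo))
  config$nh_rates$band_hi <- as.integer(unlist(config$nh_rates$band_hi))
  config$nh_rates$rate_surgical_or_mobile <-
    as.numeric(unlist(config$nh_rates$rate_surgical_or_mobile))
  b <- structure(config[need], class = "param_bundle")
  validate_bundle(b)
  b
}

#' National cohort inputs
#'
#' Annual US hospital discharges for hip fracture and the fractions used to
#' size the elderly surgical cohorts: 307,538 discharges in 2009, 90% in
#' patients 65 or older, half extracapsular, and 85% of intracapsular
#' fractures displaced.
#'
#' @param annual_discharges Annual hip-fracture discharges.
#' @param fraction_age65plus Fraction aged 65+.
#' @param fraction_extracapsular Fraction of elderly fractures that are
#'   extracapsular.
#' @param fraction_intracapsular_displaced Fraction of intracapsular
#'   fractures that are displaced.
#' @return A `national_inputs` list.
#' @export
national_inputs <- function(annual_discharges = 307538,
                            fraction_age65plus = 0.90,
                            fraction_extracapsular = 0.5,
                            fraction_intracapsular_displaced = 0.85) {
  fr <- c(fraction_age65plus, fraction_extracapsular,
          fraction_intracapsular_displaced)
  if (!in_unit(fr)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (annual_discharges < 0) stop("discharges must be >= 0", call. = FALSE)
  structure(list(annual_discharges = annual_discharges,
                 fraction_age65plus = fraction_age65plus,
                 fraction_extracapsular = fraction_extracapsular,
                 fraction_intracapsular_displaced = fraction_intracapsular_displaced),
            class = "national_inputs")
}
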