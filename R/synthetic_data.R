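#' Derive a stream seed from a master seed
#'
#' Single-integer seed convention: one master seed plus a stream counter
#' deterministically yields the seed of each random stream (microsimulation
#' replicates, sweeps), so that any analysis is reproducible bit-for-bit
#' from one integer.
#'
#' @param seed Master seed (integer).
#' @param stream Stream counter (integer >= 0).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, stream = 0L) {
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(stream)) %% 2147483646) + 1L
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Synthetic model inputs: life table and age-at-fracture distribution
#'
#' Generates every input the analysis needs without external data: a
#' Gompertz-Makeham life table (defaults calibrated to 2009 US
#' total-population mortality, remaining life expectancy at 80 of about 9
#' years) and a discretized age-at-fracture distribution over ages 65-98.
#' The age distribution is a truncated-normal shape with default mean 84 and
#' SD 7, matching the old-skewed age profile of elderly surgical hip
#' fracture patients in US claims data. Output is deterministic given the
#' seed (the seed labels the population and seeds downstream stochastic
#' streams via [split_seed()]).
#'
#' @param seed Master seed.
#' @param lambda,beta,modal_age Gompertz-Makeham parameters, see
#'   [gm_life_table()].
#' @param age_mean,age_sd Location and spread of the age-at-fracture
#'   distribution.
#' @param min_age,max_age Support of the age distribution.
#' @param cap Life-table absorbing cap.
#' @return A `synthetic_population`: list with `seed`, `age_distribution`
#'   (named weights over `min_age:max_age`, summing to 1) and `life_table`.
#' @examples
#' pop <- make_synthetic_inputs(seed = 1)
#' sum(pop$age_distribution) # 1
#' @export
make_synthetic_inputs <- function(seed = 1L,
                                  lambda = 0.0043424, beta = 0.115,
                                  modal_age = 106.52,
                                  age_mean = 84, age_sd = 7,
                                  min_age = 65L, max_age = 98L,
                                  cap = 110L) {
  if (age_sd <= 0) stop("`age_sd` must be positive", call. = FALSE)
  ages <- seq(as.integer(min_age), as.integer(max_age))
  w <- stats::dnorm(ages, mean = age_mean, sd = age_sd)
  if (sum(w) <= 0) stop("degenerate age distribution (zero mass)", call. = FALSE)
  w <- w / sum(w)
  lt <- gm_life_table(min_age = min(50L, min_age), cap = cap,
                      lambda = lambda, beta = beta, modal_age = modal_age)
  structure(list(seed = as.integer(seed),
                 age_distribution = stats::setNames(w, ages),
                 life_table = lt),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  ages <- as.integer(names(x$age_distribution))
  cat(sprintf("<synthetic_population> seed %d; ages %d-%d (mean %.1f); life table to %d\n",
              x$seed, min(ages), max(ages),
              sum(ages * x$age_distribution), x$life_table$max_age))
  invisible(x)
}

#' Write the synthetic inputs as CSV files
#'
#' @param pop A `synthetic_population`.
#' @param dir Output directory.
#' @return Character vector of the two paths, invisibly.
#' @export
write_synthetic_inputs <- function(pop, dir) {
  stopifnot(inherits(pop, "synthetic_population"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lt_path <- file.path(dir, "life_table.csv")
  ad_path <- file.path(dir, "age_distribution.csv")
  write_life_table(pop$life_table, lt_path)
  utils::write.csv(
    data.frame(age = as.integer(names(pop$age_distribution)),
               weight = unname(pop$age_distribution)),
    ad_path, row.names = FALSE, quote = FALSE)
  invisible(c(lt_path, ad_path))
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n_patients` individual annual trajectories drawing every
#' transition from the same probabilities the cohort engine uses, and
#' returns Monte-Carlo means and standard errors of the aggregates the
#' cohort engine computes deterministically. It shares no code path with
#' [run_cohort()] / [accumulate_costs()] / [accumulate_qalys()] beyond the
#' parameter bundle, so agreement within Monte-Carlo error validates the
#' cohort engine. Undiscounted accounting only.
#'
#' @param bundle A `param_bundle`.
#' @param table A [life_table()].
#' @param start_age Age at fracture.
#' @param n_patients Number of simulated patients.
#' @param seed Seed for the simulation stream.
#' @param nh_surgical_accrual `"actuarial"` (default) or `"trace"`, as in
#'   [accumulate_costs()].
#' @return A `microsim_result`: list with `n`, `survival` (data frame:
#'   cycle, mean, se), `state_years` (data frame: state, mean, se),
#'   and one `c(mean, se)` pair each for `revisions`, `conversions`,
#'   `qaly`, `cost_total`, `cost_direct`, `cost_longterm`,
#'   `cost_nursing_home`, `cost_home_modification`.
#' @export
microsim_oracle <- function(bundle, table, start_age, n_patients,
                            seed = 1L,
                            nh_surgical_accrual = c("actuarial", "trace")) {
  stopifnot(inherits(bundle, "param_bundle"), n_patients >= 1)
  nh_surgical_accrual <- match.arg(nh_surgical_accrual)
  s <- bundle$strategy
  m <- bundle$multipliers
  arm <- s$arm
  n <- as.integer(n_patients)
  with_seed(seed, {
    # state codes: 0 dead, 1 well, 2 post-conversion, 3 post-aseptic,
    # 4 post-infection, 5 mobile, 6 immobile
    state <- integer(n)
    years <- matrix(0, n, 6)
    rev_a <- integer(n); rev_i <- integer(n); conv_n <- integer(n)
    alive_mat <- NULL
    surv_frac <- numeric(0)
    extracap <- s$fracture_type == "extracapsular"
    cycle <- 0L
    repeat {
      cycle <- cycle + 1L
      age <- start_age + cycle - 1L
      if (age > table$max_age) break
      alive <- if (cycle == 1L) rep(TRUE, n) else state > 0L
      if (!any(alive)) break
      p_d <- annual_mortality(age, cycle, arm, m, table)
      dies <- alive & (stats::runif(n) < p_d)
      if (cycle == 1L) {
        surv <- !dies
        if (arm == "surgical") {
          state[surv] <- 1L
          if (extracap) {
            cvt <- surv & (stats::runif(n) < s$conversion_rate_year1)
            state[cvt] <- 2L
            conv_n[cvt] <- 1L
          }
        } else {
          mob <- surv & (stats::runif(n) < s$prob_mobile_if_survive)
          state[mob] <- 5L
          state[surv & !mob] <- 6L
        }
        state[dies] <- 0L
      } else {
        state[dies] <- 0L
        if (arm == "surgical") {
          src <- if (extracap) 2L else 1L  # revisable state
          at_risk <- state == src & !dies
          u <- stats::runif(n)
          to_a <- at_risk & u < s$annual_revision_aseptic
          to_i <- at_risk & !to_a &
            u < s$annual_revision_aseptic + s$annual_revision_infection
          rev_a[to_a] <- 1L; rev_i[to_i] <- 1L
          # operative mortality at the revision
          op_die_a <- to_a & (stats::runif(n) < s$revision_mortality_aseptic)
          op_die_i <- to_i & (stats::runif(n) < s$revision_mortality_infection)
          state[to_a] <- 3L; state[to_i] <- 4L
          state[op_die_a | op_die_i] <- 0L
        }
      }
      live <- state > 0L
      idx <- which(live)
      years[cbind(idx, state[idx])] <- years[cbind(idx, state[idx])] + 1
      surv_frac <- c(surv_frac, mean(live))
      if (cycle == 1L) alive1 <- live
      if (!any(live)) break
    }

    utils_by_state <- c(
      `1` = s$utility_well %||% 0, `2` = s$utility_post_conversion %||% 0,
      `3` = s$utility_post_aseptic_revision %||% 0,
      `4` = s$utility_post_infection_revision %||% 0,
      `5` = s$utility_mobile %||% 0, `6` = s$utility_immobile %||% 0)
    qaly <- years %*% utils_by_state
    events <- rev_a + rev_i + conv_n
    if (arm == "surgical") {
      qaly <- qaly + s$disutility_index_surgery +
        s$disutility_revision * events
    }

    co <- bundle$costs
    nh <- bundle$nh_rates
    band <- nh_band_rate(nh, start_age)
    years_total <- rowSums(years)
    direct <- co$acute_cost + co$revision_or_conversion_cost * events
    longterm <- co$longterm_annual * (years_total - 0.5 * alive1)
    if (arm == "surgical") {
      designated <- stats::runif(n) < band
      nursing <- if (nh_surgical_accrual == "actuarial") {
        designated * co$nursing_home_annual *
          natural_person_years(table, start_age)
      } else {
        designated * co$nursing_home_annual * years_total
      }
    } else {
      p_des <- ifelse(years[, 6] > 0, nh$rate_immobile,
                      ifelse(years[, 5] > 0, band, 0))
      designated <- stats::runif(n) < p_des
      nursing <- designated * co$nursing_home_annual * years_total
    }
    homemod <- co$home_modification_once * (alive1 & !designated)
    total <- direct + longterm + nursing + homemod

    mean_se <- function(x) {
      c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
    }
    structure(list(
      n = n,
      survival = data.frame(cycle = seq_along(surv_frac), mean = surv_frac,
                            se = sqrt(surv_frac * (1 - surv_frac) / n)),
      state_years = data.frame(
        state = c("well", "post_conversion", "post_aseptic_revision",
                  "post_infection_revision", "mobile", "immobile"),
        mean = colMeans(years),
        se = apply(years, 2, stats::sd) / sqrt(n)),
      revisions = mean_se(rev_a + rev_i),
      conversions = mean_se(conv_n),
      qaly = mean_se(as.numeric(qaly)),
      cost_total = mean_se(total),
      cost_direct = mean_se(direct),
      cost_longterm = mean_se(longterm),
      cost_nursing_home = mean_se(nursing),
      cost_home_modification = mean_se(homemod)
    ), class = "microsim_result")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
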