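#' Annual mortality probability for a model cycle
#'
#' The natural annual death probability `qx(age)` is scaled by the
#' post-fracture relative risk of the cycle: `rr_year1` in cycle 1,
#' `rr_year2` in cycle 2, `rr_beyond` in cycles 3..`excess_years` (when
#' `excess_years > 2`), and 1 thereafter. Nonoperative arms are additionally
#' multiplied by `nonop_factor` in cycles 1-2 only. The product is clamped to
#' `[0, 1]`.
#'
#' @param age Age during the cycle.
#' @param cycle Cycle index (1 = first year after fracture).
#' @param arm `"surgical"` or `"nonoperative"`.
#' @param multipliers The `multipliers` component of a `param_bundle`.
#' @param table A [life_table()].
#' @return A probability.
#' @examples
#' m <- default_parameters("hemiarthroplasty")$multipliers
#' lt <- life_table(80, 0.05)
#' annual_mortality(80, 1, "surgical", m, lt) # 3.07 * 0.05
#' @export
annual_mortality <- function(age, cycle, arm = c("surgical", "nonoperative"),
                             multipliers, table) {
  arm <- match.arg(arm)
  m <- cycle_multiplier(cycle, arm, multipliers)
  pmin(pmax(m * qx_at(table, age), 0), 1)
}

cycle_multiplier <- function(cycle, arm, multipliers) {
  m <- if (cycle == 1) {
    multipliers$rr_year1
  } else if (cycle == 2) {
    multipliers$rr_year2
  } else if (multipliers$excess_years > 2 && cycle <= multipliers$excess_years) {
    multipliers$rr_beyond
  } else {
    1
  }
  if (arm == "nonoperative" && cycle <= 2) m <- m * multipliers$nonop_factor
  m
}

trace_states <- c("well", "post_conversion", "post_aseptic_revision",
                  "post_infection_revision", "mobile", "immobile", "dead")

new_trace_row <- function() {
  row <- as.list(stats::setNames(numeric(length(trace_states)), trace_states))
  c(row, list(new_deaths = 0, new_revisions_aseptic = 0,
              new_revisions_infection = 0, new_conversions = 0))
}

#' Run the annual-cycle cohort model for one strategy
#'
#' Propagates a unit cohort of the given starting age through the health
#' states of its treatment arm, one-year cycles, until the cohort is
#' extinct (dead mass within `1e-9` of 1), the life-table cap is reached, or
#' `max_cycles` cycles have run. Within a cycle, competing risks are applied
#' sequentially: death first, then (among survivors) revision/conversion or
#' the mobility split.
#'
#' Surgical intracapsular arms occupy well / post-aseptic-revision /
#' post-infection-revision / dead; in cycle 1 the cohort either dies or
#' enters well, and from cycle 2 the well state can exit to death or to one
#' revision (at most one per patient; the transiting mass additionally faces
#' the operative mortality of the revision). Surgical extracapsular arms add
#' a post-conversion state: a fraction of cycle-1 survivors converts to
#' arthroplasty, the fixed-implant well state has no later revision exits,
#' and revisions occur only from post-conversion at the arthroplasty
#' revision rates. Nonoperative arms split cycle-1 survivors once into
#' mobile/immobile and thereafter only die or stay.
#'
#' @param bundle A `param_bundle`.
#' @param table A [life_table()].
#' @param start_age Age at fracture (integer, within the table range).
#' @param max_cycles Optional cycle cap (default: run to extinction).
#' @return A `cohort_trace`: data frame with one row per cycle, columns
#'   `cycle`, `age`, one occupancy column per state (end-of-cycle
#'   probability mass), and the per-cycle event masses `new_deaths`,
#'   `new_revisions_aseptic`, `new_revisions_infection`, `new_conversions`.
#'   Attributes `start_age`, `strategy_id`, `arm`, `fracture_type`.
#' @export
run_cohort <- function(bundle, table, start_age, max_cycles = Inf) {
  stopifnot(inherits(bundle, "param_bundle"), inherits(table, "life_table"))
  start_age <- as.integer(start_age)
  if (start_age < table$min_age || start_age > table$max_age) {
    stop("`start_age` outside life table range", call. = FALSE)
  }
  if (bundle$strategy$arm == "surgical") {
    run_surgical_cohort(bundle, table, start_age, max_cycles)
  } else {
    run_nonoperative_cohort(bundle, table, start_age, max_cycles)
  }
}

#' @rdname run_cohort
#' @export
run_surgical_cohort <- function(bundle, table, start_age, max_cycles = Inf) {
  s <- bundle$strategy
  if (s$arm != "surgical") {
    stop("run_surgical_cohort() requires a surgical strategy", call. = FALSE)
  }
  extracapsular <- s$fracture_type == "extracapsular"
  conv_rate <- if (extracapsular) s$conversion_rate_year1 else 0
  r_a <- s$annual_revision_aseptic
  r_i <- s$annual_revision_infection
  mort_a <- s$revision_mortality_aseptic
  mort_i <- s$revision_mortality_infection

  well <- conv <- ra <- ri <- dead <- 0
  rows <- list()
  cycle <- 0L
  repeat {
    cycle <- cycle + 1L
    age <- start_age + cycle - 1L
    if (cycle > max_cycles || age > table$max_age || dead > 1 - 1e-9) break
    p_d <- annual_mortality(age, cycle, "surgical", bundle$multipliers, table)
    row <- new_trace_row()
    if (cycle == 1L) {
      deaths <- p_d
      surv <- 1 - p_d
      conv_new <- surv * conv_rate
      well <- surv - conv_new
      conv <- conv_new
      dead <- deaths
      row$new_deaths <- deaths
      row$new_conversions <- conv_new
    } else {
      deaths <- 0
      # well state
      d_w <- well * p_d
      surv_w <- well - d_w
      deaths <- deaths + d_w
      if (!extracapsular) {
        ra_new <- surv_w * r_a
        ri_new <- surv_w * r_i
        well <- surv_w - ra_new - ri_new
      } else {
        ra_new <- ri_new <- 0
        well <- surv_w
      }
      # post-conversion state (extracapsular only)
      d_c <- conv * p_d
      surv_c <- conv - d_c
      deaths <- deaths + d_c
      if (extracapsular) {
        ra_c <- surv_c * r_a
        ri_c <- surv_c * r_i
        conv <- surv_c - ra_c - ri_c
        ra_new <- ra_new + ra_c
        ri_new <- ri_new + ri_c
      } else {
        conv <- surv_c
      }
      # operative mortality on the transiting revision mass
      ra_dead <- ra_new * mort_a
      ri_dead <- ri_new * mort_i
      deaths <- deaths + ra_dead + ri_dead
      # revision states: death is the only exit
      d_ra <- ra * p_d
      d_ri <- ri * p_d
      deaths <- deaths + d_ra + d_ri
      ra <- ra - d_ra + ra_new - ra_dead
      ri <- ri - d_ri + ri_new - ri_dead
      dead <- dead + deaths
      row$new_deaths <- deaths
      row$new_revisions_aseptic <- ra_new
      row$new_revisions_infection <- ri_new
    }
    row$well <- well; row$post_conversion <- conv
    row$post_aseptic_revision <- ra; row$post_infection_revision <- ri
    row$dead <- dead
    row$cycle <- cycle; row$age <- age
    rows[[cycle]] <- row
  }
  finish_trace(rows, bundle, start_age)
}

#' @rdname run_cohort
#' @export
run_nonoperative_cohort <- function(bundle, table, start_age, max_cycles = Inf) {
  s <- bundle$strategy
  if (s$arm != "nonoperative") {
    stop("run_nonoperative_cohort() requires a nonoperative strategy", call. = FALSE)
  }
  p_m <- s$prob_mobile_if_survive
  mobile <- immobile <- 0
  dead <- 0
  rows <- list()
  cycle <- 0L
  repeat {
    cycle <- cycle + 1L
    age <- start_age + cycle - 1L
    if (cycle > max_cycles || age > table$max_age || dead > 1 - 1e-9) break
    p_d <- annual_mortality(age, cycle, "nonoperative", bundle$multipliers, table)
    row <- new_trace_row()
    if (cycle == 1L) {
      deaths <- p_d
      surv <- 1 - p_d
      mobile <- surv * p_m
      immobile <- surv - mobile
      dead <- deaths
    } else {
      deaths <- (mobile + immobile) * p_d
      mobile <- mobile * (1 - p_d)
      immobile <- immobile * (1 - p_d)
      dead <- dead + deaths
    }
    row$new_deaths <- deaths
    row$mobile <- mobile; row$immobile <- immobile; row$dead <- dead
    row$cycle <- cycle; row$age <- age
    rows[[cycle]] <- row
  }
  finish_trace(rows, bundle, start_age)
}

finish_trace <- function(rows, bundle, start_age) {
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  first <- c("cycle", "age")
  df <- df[, c(first, setdiff(names(df), first))]
  structure(df,
            start_age = start_age,
            strategy_id = bundle$strategy$strategy_id,
            arm = bundle$strategy$arm,
            fracture_type = bundle$strategy$fracture_type,
            class = c("cohort_trace", "data.frame"))
}

#' End-of-cycle alive mass of a trace
#'
#' @param trace A `cohort_trace`.
#' @return Numeric vector, one element per cycle.
#' @export
alive_mass <- function(trace) 1 - trace$dead

#' Export a trace as tidy long-format CSV
#'
#' One row per (cycle, state), with columns `cycle`, `age`, `state`,
#' `occupancy`, plus the per-cycle event columns repeated for
#' reference.
#'
#' @param trace A `cohort_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  long <- do.call(rbind, lapply(trace_states, function(st) {
    data.frame(cycle = trace$cycle, age = trace$age, state = st,
               occupancy = trace[[st]],
               new_deaths = trace$new_deaths,
               new_revisions_aseptic = trace$new_revisions_aseptic,
               new_revisions_infection = trace$new_revisions_infection,
               new_conversions = trace$new_conversions)
  }))
  long <- long[order(long$cycle), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
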