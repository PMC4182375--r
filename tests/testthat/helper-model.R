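# Shared fixtures, built in code.

# Constant-hazard life table (absorbing cap appended automatically when qx < 1).
flat_life_table <- function(qx, from = 65, to = 120) {
  life_table(from:to, rep(qx, to - from + 1))
}

ref_table <- function() us2009_life_table()

# Zero all costs in a bundle or pair.
zero_costs <- function(x) {
  for (p in c("costs.acute_cost", "costs.revision_or_conversion_cost",
              "costs.longterm_annual", "costs.nursing_home_annual",
              "costs.home_modification_once")) {
    x <- apply_override(x, p, 0)
  }
  x
}

# Neutralize all excess mortality and revision pathways so both arms share
# the natural survival curve.
natural_mortality_pair <- function(pair) {
  for (p in c("multipliers.rr_year1", "multipliers.rr_year2",
              "multipliers.nonop_factor")) {
    pair <- apply_override(pair, p, 1)
  }
  for (p in c("surgical.strategy.annual_revision_aseptic",
              "surgical.strategy.annual_revision_infection")) {
    pair <- apply_override(pair, p, 0)
  }
  if (!is.null(pair$surgical$strategy$conversion_rate_year1)) {
    pair <- apply_override(pair, "surgical.strategy.conversion_rate_year1", 0)
  }
  pair
}

withr_local_tempfile <- function(env = parent.frame()) {
  withr::local_tempfile(fileext = ".csv", .local_envir = env)
}
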