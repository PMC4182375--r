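test_that("annual mortality applies the cycle multiplier schedule and clamps", {
  m <- default_parameters("hemiarthroplasty")$multipliers
  lt <- flat_life_table(0.05)
  expect_equal(annual_mortality(70, 1, "surgical", m, lt), 0.1535)
  expect_equal(annual_mortality(70, 1, "nonoperative", m, lt), 0.204155)
  expect_equal(annual_mortality(70, 2, "surgical", m, lt), 1.87 * 0.05)
  expect_equal(annual_mortality(70, 3, "surgical", m, lt), 0.05)
  expect_equal(annual_mortality(70, 3, "nonoperative", m, lt), 0.05)
  # clamped at 1
  lt4 <- flat_life_table(0.4)
  expect_equal(annual_mortality(70, 1, "surgical", m, lt4), 1)
  # extended excess-mortality window
  m2 <- m; m2$excess_years <- 5L; m2$rr_beyond <- 1.7
  expect_equal(annual_mortality(70, 4, "surgical", m2, lt), 1.7 * 0.05)
  expect_equal(annual_mortality(70, 6, "surgical", m2, lt), 0.05)
  expect_error(annual_mortality(200, 1, "surgical", m, lt), "range")
})

test_that("with no exits the surgical cohort stays well forever", {
  b <- default_parameters("hemiarthroplasty")
  b <- apply_override(b, "strategy.annual_revision_aseptic", 0)
  b <- apply_override(b, "strategy.annual_revision_infection", 0)
  tr <- run_cohort(b, flat_life_table(0), 65, max_cycles = 20)
  expect_equal(nrow(tr), 20L)
  expect_equal(tr$well, rep(1, 20))
  expect_equal(tr$dead, rep(0, 20))
})

test_that("two-cycle occupancy matches a hand-built transition matrix", {
  b <- default_parameters("hemiarthroplasty")
  lt <- flat_life_table(0.1)
  tr <- run_cohort(b, lt, 70, max_cycles = 2)

  # independent oracle: explicit matrix product over states
  # (well, post_aseptic, post_infection, dead)
  p1 <- 3.07 * 0.1
  v1 <- c(1 - p1, 0, 0, p1)
  expect_equal(unname(tr$dead[1]), 0.307)
  expect_equal(unname(tr$well[1]), 0.693)

  p2 <- 1.87 * 0.1
  r_a <- 0.034; r_i <- 0.0053
  M <- rbind(
    well = c((1 - p2) * (1 - r_a - r_i),
             (1 - p2) * r_a * (1 - 0.012),
             (1 - p2) * r_i * (1 - 0.0193),
             p2 + (1 - p2) * (r_a * 0.012 + r_i * 0.0193)),
    post_aseptic = c(0, 1 - p2, 0, p2),
    post_infection = c(0, 0, 1 - p2, p2),
    dead = c(0, 0, 0, 1))
  v2 <- as.numeric(v1 %*% M)
  expect_equal(tr$well[2], v2[1], tolerance = 1e-12)
  expect_equal(tr$post_aseptic_revision[2], v2[2], tolerance = 1e-12)
  expect_equal(tr$post_infection_revision[2], v2[3], tolerance = 1e-12)
  expect_equal(tr$dead[2], v2[4], tolerance = 1e-12)
  expect_equal(tr$new_revisions_aseptic[2], (1 - p1) * (1 - p2) * r_a)
})

test_that("extracapsular pathway: year-1 conversion, later revisions only from it", {
  b <- default_parameters("gamma_nail")
  tr <- run_cohort(b, flat_life_table(0), 65, max_cycles = 5)
  expect_equal(tr$post_conversion[1], 0.06)
  expect_equal(tr$new_conversions[1], 0.06)
  expect_equal(tr$well[1], 0.94)
  # fixed-implant well state never revises after year 1
  expect_equal(tr$well[5], 0.94)
  # post-conversion mass decays at the arthroplasty revision rates
  expect_equal(tr$new_revisions_aseptic[2], 0.06 * 0.0067)
  expect_equal(tr$new_revisions_infection[2], 0.06 * 0.0033)
  expect_equal(tr$post_conversion[2],
               0.06 * (1 - 0.0067 - 0.0033))
})

test_that("nonoperative cohort splits once and then only dies", {
  b <- default_parameters("nonoperative_intracapsular")
  tr <- run_cohort(b, flat_life_table(0), 65, max_cycles = 10)
  expect_equal(tr$mobile, rep(0.5, 10))
  expect_equal(tr$immobile, rep(0.5, 10))

  b2 <- apply_override(b, "strategy.prob_mobile_if_survive", 1)
  tr2 <- run_cohort(b2, flat_life_table(0.02), 65, max_cycles = 10)
  expect_equal(tr2$immobile, rep(0, 10))

  # certain death in year 1 (clamped 1.33 * 3.07 * 1)
  tr3 <- run_cohort(b, life_table(65, 1), 65)
  expect_equal(tr3$dead[1], 1)
  expect_equal(nrow(tr3), 1L)
})

test_that("arm dispatch rejects the wrong strategy kind", {
  lt <- flat_life_table(0.05)
  expect_error(run_surgical_cohort(default_parameters("nonoperative_intracapsular"),
                                   lt, 65), "surgical strategy")
  expect_error(run_nonoperative_cohort(default_parameters("tha"), lt, 65),
               "nonoperative strategy")
})

test_that("mass is conserved, death monotone, and revisions capped at one", {
  set.seed(42)
  lt <- ref_table()
  for (rep in 1:8) {
    id <- sample(strategy_ids(), 1)
    b <- default_parameters(id)
    b <- apply_override(b, "multipliers.rr_year1", runif(1, 1, 4.6))
    b <- apply_override(b, "multipliers.rr_year2", runif(1, 1, 2.8))
    if (b$strategy$arm == "surgical") {
      b <- apply_override(b, "strategy.annual_revision_aseptic", runif(1, 0, 0.1))
      b <- apply_override(b, "strategy.annual_revision_infection", runif(1, 0, 0.05))
    } else {
      b <- apply_override(b, "strategy.prob_mobile_if_survive", runif(1))
    }
    tr <- run_cohort(b, lt, sample(65:95, 1))
    occ <- tr$well + tr$post_conversion + tr$post_aseptic_revision +
      tr$post_infection_revision + tr$mobile + tr$immobile + tr$dead
    expect_true(all(abs(occ - 1) < 1e-9))
    expect_true(all(diff(tr$dead) >= -1e-12))
    state_cols <- c("well", "mobile", "immobile", "dead", "post_conversion",
                    "post_aseptic_revision", "post_infection_revision")
    expect_true(all(tr[state_cols] >= -1e-12))
    # at most one revision per patient, cumulatively
    expect_lte(sum(tr$new_revisions_aseptic + tr$new_revisions_infection), 1)
    # cohort extinct at the end
    expect_gt(tr$dead[nrow(tr)], 1 - 1e-9)
  }
})

test_that("without excess mortality both arms share the natural survival curve", {
  pair <- natural_mortality_pair(strategy_pair("hemiarthroplasty"))
  lt <- ref_table()
  ts <- run_cohort(pair$surgical, lt, 80)
  tn <- run_cohort(pair$nonoperative, lt, 80)
  expect_equal(ts$dead, tn$dead, tolerance = 1e-12)
  expect_equal(1 - ts$dead, survival_curve(lt, 80)[seq_len(nrow(ts))],
               tolerance = 1e-12)
})

test_that("tidy trace export has one row per cycle and state", {
  tr <- run_cohort(default_parameters("hemiarthroplasty"), flat_life_table(0.1),
                   70, max_cycles = 3)
  path <- withr_local_tempfile()
  write_trace(tr, path)
  long <- read.csv(path)
  expect_equal(nrow(long), 3 * 7)
  expect_setequal(unique(long$state),
                  c("well", "post_conversion", "post_aseptic_revision",
                    "post_infection_revision", "mobile", "immobile", "dead"))
  occ <- tapply(long$occupancy, long$cycle, sum)
  expect_true(all(abs(occ - 1) < 1e-9))
})
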