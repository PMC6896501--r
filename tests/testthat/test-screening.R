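test_that("examination schedules follow strategy windows and surveillance intervals", {
  col <- strategies$COL
  fit <- strategies$FIT
  expect_true(is_screening_due(col, "regular", 60)$due)
  expect_equal(is_screening_due(col, "regular", 60)$test, "colonoscopy")
  expect_false(is_screening_due(col, "regular", 55)$due)
  expect_false(is_screening_due(col, "regular", 80)$due)
  expect_false(is_screening_due(fit, "regular", 39)$due)
  expect_true(is_screening_due(fit, "regular", 40)$due)
  expect_true(is_screening_due(fit, "regular", 75)$due)
  expect_false(is_screening_due(fit, "regular", 76)$due)
  # surveillance: due at the interval, colonoscopy-based, never after 75
  expect_true(is_screening_due(fit, "surv3y", 73, 70)$due)
  expect_equal(is_screening_due(fit, "surv3y", 73, 70)$test, "colonoscopy")
  expect_false(is_screening_due(fit, "surv3y", 76, 73)$due)
  expect_true(is_screening_due(fit, "surv5y", 65, 60)$due)
  expect_true(is_screening_due(col, "colo10y", 70, 60)$due)
  expect_false(is_screening_due(col, "colo10y", 69, 60)$due)
})

test_that("test positivity follows sensitivity by lesion class and 1-specificity when healthy", {
  expect_equal(apply_test("H", dp$tests$FIT)$positive, 1 - 0.928)
  expect_equal(apply_test("A", dp$tests$FIT)$positive, 0.076)
  expect_equal(apply_test("AA", dp$tests$FIT)$positive, 0.367)
  for (s in paste0("P", 1:4)) {
    expect_equal(apply_test(s, dp$tests$FIT)$positive, 0.872)
  }
  expect_equal(apply_test("H", dp$tests$colonoscopy)$positive, 0)
  perfect <- list(sensitivity_adenoma = 1, sensitivity_advanced_adenoma = 1,
                  sensitivity_crc = 1, specificity = 1)
  expect_equal(apply_test("A", perfect)$positive, 1)
  expect_error(apply_test("DX", dp$tests$FIT), "living, undiagnosed")
})

test_that("surveillance track transitions follow the finding-based rules", {
  # advanced adenoma found anywhere -> 3-yearly surveillance
  expect_equal(resolve_positive("advanced", "regular")$new_track, "surv3y")
  expect_equal(resolve_positive("advanced", "surv5y")$new_track, "surv3y")
  expect_equal(resolve_positive("advanced", "colo10y")$new_track, "surv3y")
  # non-advanced adenoma in 3-yearly surveillance -> de-escalate to 5-yearly
  expect_equal(resolve_positive("adenoma", "surv3y")$new_track, "surv5y")
  # clean 3-yearly exam also de-escalates
  expect_equal(resolve_positive("none", "surv3y")$new_track, "surv5y")
  # non-advanced adenoma under a stool-test strategy -> 10-yearly colonoscopy
  expect_equal(resolve_positive("adenoma", "regular", stool_regular = TRUE)$new_track,
               "colo10y")
  # under the colonoscopy strategy the 10-yearly schedule just continues
  expect_equal(resolve_positive("adenoma", "regular")$new_track, "regular")
  # false-positive stool test: state and track unchanged
  fp <- resolve_positive("none", "regular", stool_regular = TRUE)
  expect_true(is.na(fp$new_class))
  expect_equal(fp$new_track, "regular")
  # removals return to healthy; cancers to the diagnosed state
  expect_equal(resolve_positive("adenoma", "surv3y")$new_class, "H")
  expect_equal(resolve_positive("crc", "regular")$new_class, "DX")
})

test_that("the 5-yearly track is reachable only through the 3-yearly track", {
  st <- make_state_table()
  surv5_ids <- st$id[!is.na(st$track) & st$track == "surv5y"]
  for (strat in list(strategies$FIT, strategies$COL)) {
    for (age in c(50, 60, 70)) {
      S <- crcscreen:::screening_kernel(strat, age, dp, st)
      if (is.null(S)) next
      from <- which(rowSums(S$P[, surv5_ids, drop = FALSE]) > 0)
      from <- setdiff(from, surv5_ids)  # self-continuation is allowed
      expect_true(all(st$track[from] == "surv3y"))
      # surv3y must be reachable from every track via an advanced finding
      surv3_ids <- st$id[!is.na(st$track) & st$track == "surv3y"]
      reach3 <- st$track[setdiff(which(rowSums(S$P[, surv3_ids, drop = FALSE]) > 0),
                                 surv3_ids)]
      expect_true(length(reach3) > 0)
    }
  }
})

test_that("cumulative multi-round sensitivity follows 1-(1-s)^k", {
  expect_equal(ten_year_sensitivity(0, 10), 0)
  expect_equal(ten_year_sensitivity(1, 10), 1)
  expect_equal(ten_year_sensitivity(0.367, 10), 1 - (1 - 0.367)^10)
  expect_equal(ten_year_sensitivity(0.367, 10), 0.9897, tolerance = 1e-4)
  expect_error(ten_year_sensitivity(1.2, 10), "range error")
})

test_that("expected complications are linear in colonoscopy volume", {
  expect_equal(complication_risk(1000, 0.001), 1)
  expect_equal(complication_risk(0, 0.5), 0)
  expect_error(complication_risk(10, 1.5), "range error")
})

test_that("insensitive never-positive tests leave all health outcomes at no-screening values", {
  z <- zero_sens_params()
  s0 <- summarize_cohort(run_cohort(strategies$no_screening, z), z)
  for (nm in c("FIT", "gFOBT", "COL")) {
    s <- summarize_cohort(run_cohort(strategies[[nm]], z), z)
    expect_equal(s$life_years, s0$life_years)
    expect_equal(s$disc_life_years, s0$disc_life_years)
    expect_equal(s$crc_cases, s0$crc_cases)
    expect_equal(s$crc_deaths, s0$crc_deaths)
    expect_equal(s$positive_tests, 0)
    # only program/test (and for COL, examination) costs may differ
    b <- s$cost_breakdown
    b0 <- s0$cost_breakdown
    same <- c("staging", "inpatient", "medication_iv", "followup", "end_of_life")
    expect_equal(b[same], b0[same])
  }
})

test_that("positive-test counts decrease as specificity increases", {
  res <- vapply(c(0.90, 0.95, 0.99), function(sp) {
    p <- dp
    p$tests$FIT$specificity <- sp
    summarize_cohort(run_cohort(strategies$FIT, p), p)$positive_tests
  }, 1.0)
  expect_true(all(diff(res) < 0))
})
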