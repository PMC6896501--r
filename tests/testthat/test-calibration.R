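test_that("the objective is zero iff predictions match targets exactly", {
  scn <- make_scenario(3, "paper-like", sigma = 0)
  pred <- predict_targets(scn$params)
  expect_lt(calibration_objective(pred, scn$targets), 1e-20)
})

test_that("the objective is a weighted quadratic form in relative deviations", {
  targets <- list(
    incidence = data.frame(age_lo = c(50, 60), age_hi = c(59, 69),
                           incidence_per_100k = c(100, 200)),
    stage_distribution = NULL, cum_mortality_75 = NA
  )
  mk_pred <- function(vals) list(
    incidence = data.frame(age_lo = c(50, 60), age_hi = c(59, 69),
                           incidence_per_100k = vals),
    stage_distribution = rep(NA_real_, 4), cum_mortality_75 = 0)
  w <- list(incidence = c(1, 1), stage = rep(0, 4), cum_mortality = 0)
  # hand-computed: (10/100)^2 + (40/200)^2
  o1 <- calibration_objective(mk_pred(c(110, 240)), targets, w)
  expect_equal(o1, 0.1^2 + 0.2^2)
  # doubling all deviations quadruples the objective
  o2 <- calibration_objective(mk_pred(c(120, 280)), targets, w)
  expect_equal(o2, 4 * o1)
  # zero-valued targets fall back to absolute deviations
  t0 <- targets
  t0$incidence$incidence_per_100k <- c(0, 200)
  expect_equal(calibration_objective(mk_pred(c(0.3, 200)), t0, w), 0.09)
})

test_that("predicted targets are well-formed and flag the degenerate case", {
  pred <- predict_targets(dp)
  expect_true(all(pred$incidence$incidence_per_100k >= 0))
  expect_equal(sum(pred$stage_distribution), 1)
  expect_false(pred$degenerate)
  pred0 <- predict_targets(no_crc_params())
  expect_true(pred0$degenerate)
  expect_true(all(pred0$incidence$incidence_per_100k == 0))
  expect_true(anyNA(pred0$stage_distribution))
})

test_that("an already-optimal start converges immediately with unchanged objective", {
  scn <- make_scenario(5, "paper-like", sigma = 0)
  res <- calibrate(scn$targets, scn$params,
                   calibrate_control(seed = 1, hops = 0, maxit = 40))
  expect_lt(res$objective, 1e-6)
  expect_true(res$converged)
})

test_that("calibration is deterministic given the seed", {
  scn <- make_scenario(8, "easy", sigma = 0.05)
  ctrl <- calibrate_control(seed = 77, hops = 1, maxit = 40)
  r1 <- calibrate(scn$targets, scn$params, ctrl)
  r2 <- calibrate(scn$targets, scn$params, ctrl)
  expect_identical(r1$theta, r2$theta)
  expect_identical(r1$objective, r2$objective)
})

test_that("calibration improves the full objective over its starting point", {
  scn <- make_scenario(13, "easy", sigma = 0)
  start <- scn$params
  th <- crcscreen:::nh_to_theta(start$natural_history) * 1.25
  box <- crcscreen:::nh_par_box()
  th <- pmin(pmax(th, box$lo * 1.01), box$hi * 0.99)
  start$natural_history <- crcscreen:::theta_to_nh(th, start$natural_history)
  start_obj <- calibration_objective(predict_targets(start), scn$targets)
  res <- calibrate(scn$targets, start, calibrate_control(seed = 3, hops = 0, maxit = 150))
  expect_lt(res$objective, start_obj)
  # the joint polish never undoes the hierarchical stages' own improvements
  expect_lte(res$stage_objectives[["C"]], res$objective + 1e-12)
})

test_that("unknown-stage and DCO cases are redistributed as specified", {
  d <- redistribute_stages(c(20, 30, 30, 20), unknown = 10, dco = 10)
  expect_equal(sum(d), 1)
  # unknown spread proportionally: relative shares of I vs II preserved
  expect_equal(d[1] / d[2], 20 / 30)
  # DCO only inflates stages III and IV
  base <- redistribute_stages(c(20, 30, 30, 20), unknown = 0, dco = 0)
  with_dco <- redistribute_stages(c(20, 30, 30, 20), unknown = 0, dco = 20)
  expect_lt(with_dco[1], base[1])
  expect_gt(with_dco[3] + with_dco[4], base[3] + base[4])
  expect_equal(with_dco[1] / with_dco[2], base[1] / base[2])
})

test_that("calibration targets round-trip through CSV", {
  scn <- make_scenario(4, "paper-like", sigma = 0)
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "targets.csv")
  write_calibration_targets(scn$targets, path)
  back <- read_calibration_targets(path)
  expect_equal(back$incidence, scn$targets$incidence)
  expect_equal(back$stage_distribution, scn$targets$stage_distribution)
  expect_equal(back$cum_mortality_75, scn$targets$cum_mortality_75)
})
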