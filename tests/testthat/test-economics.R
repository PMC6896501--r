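# minimal hand-built trace: zero events except those set via `...`
fake_trace <- function(strategy, ...) {
  tr <- run_cohort(strategy, dp)
  tr$events[] <- 0
  ev <- list(...)
  for (nm in names(ev)) tr$events["50", nm] <- ev[[nm]]
  tr
}

test_that("the cost ledger maps events to published unit costs", {
  # one screening colonoscopy with polypectomy: 228 + 64 = 292
  tr <- fake_trace(strategies$COL, colonoscopies = 1, polypectomies = 1)
  led <- colSums(program_costs(tr, dp))
  expect_equal(unname(led["colonoscopy"] + led["polypectomy"]), 292)
  # one FIT test event: EUR 41
  tr <- fake_trace(strategies$FIT, stool_tests = 1)
  expect_equal(unname(colSums(program_costs(tr, dp))["stool_tests"]), 41)
  # gFOBT unit cost differs
  tr <- fake_trace(strategies$gFOBT, stool_tests = 1)
  expect_equal(unname(colSums(program_costs(tr, dp))["stool_tests"]), 37)
  # CRC death at stage III carries the one-time end-of-life cost
  tr <- fake_trace(strategies$no_screening, crc_deaths_3 = 1)
  expect_equal(unname(colSums(program_costs(tr, dp))["end_of_life"]), 36492)
  # stage-I/II deaths use the joint tabulated value
  tr <- fake_trace(strategies$no_screening, crc_deaths_1 = 1, crc_deaths_2 = 1)
  expect_equal(unname(colSums(program_costs(tr, dp))["end_of_life"]), 2 * 55530)
  # a stage-IV diagnosis charges staging + inpatient + one-time medication
  tr <- fake_trace(strategies$no_screening, sym_dx_4 = 1)
  led <- colSums(program_costs(tr, dp))
  expect_equal(unname(led["staging"] + led["inpatient"] + led["medication_iv"]),
               461 + 24059 + 12433)
})

test_that("present values match the term-by-term oracle", {
  expect_equal(discount_stream(c(100, 100), 0.03), 100 + 100 / 1.03)
  expect_equal(discount_stream(c(100, 100), 0.03), 197.087, tolerance = 1e-5)
  expect_equal(discount_stream(c(0, 103), 0.03), 100)
  x <- c(12.5, 0, 7.25, 91, 3)
  expect_equal(discount_stream(x, 0), sum(x))
  brute <- sum(vapply(seq_along(x), function(t) x[t] / 1.05^(t - 1), 1.0))
  expect_lt(abs(discount_stream(x, 0.05) - brute), 1e-12)
  expect_error(discount_stream(x, -0.1), ">= 0")
})

test_that("the published economics table yields the published frontier", {
  tab4 <- data.frame(
    name = c("No Screening", "COL", "gFOBT", "FIT"),
    cost = c(1138, 754, 1398, 1352),
    effect = c(0, 0.12, 0.15, 0.16)
  )
  fr <- icer_frontier(tab4)
  cls <- setNames(fr$classification, fr$name)
  expect_equal(unname(cls["No Screening"]), "dominated")
  expect_equal(unname(cls["gFOBT"]), "dominated")
  expect_equal(unname(cls["COL"]), "frontier")
  expect_equal(unname(cls["FIT"]), "frontier")
  # ICER from the printed rounded rows: 598 / 0.04
  expect_equal(fr$icer[fr$name == "FIT"], (1352 - 754) / (0.16 - 0.12))
  expect_equal(fr$icer[fr$name == "FIT"], 14950)
})

test_that("dominance handles simple and degenerate configurations", {
  # equal cost, one more effective: the other is dominated
  fr <- icer_frontier(data.frame(name = c("a", "b"), cost = c(10, 10),
                                 effect = c(1, 2)))
  expect_equal(fr$classification[fr$name == "a"], "dominated")
  # exact ties in both: both kept, flagged
  fr <- icer_frontier(data.frame(name = c("a", "b"), cost = c(10, 10),
                                 effect = c(1, 1)))
  expect_true(all(fr$tie))
  expect_true(all(fr$classification == "frontier"))
  # removing a dominated strategy leaves frontier ICERs unchanged
  tab4 <- data.frame(name = c("n", "c", "g", "f"),
                     cost = c(1138, 754, 1398, 1352),
                     effect = c(0, 0.12, 0.15, 0.16))
  fr_all <- icer_frontier(tab4)
  fr_red <- icer_frontier(tab4[tab4$name != "g", ])
  expect_equal(fr_all$icer[fr_all$name == "f"], fr_red$icer[fr_red$name == "f"])
})

test_that("frontier ICERs are strictly increasing with effectiveness", {
  set.seed(11)
  for (rep in 1:50) {
    df <- data.frame(name = letters[1:5], cost = runif(5, 0, 1000),
                     effect = runif(5))
    fr <- icer_frontier(df)
    fr <- fr[order(fr$effect), ]
    ic <- fr$icer[fr$classification == "frontier"]
    ic <- ic[!is.na(ic)]
    if (length(ic) > 1) expect_true(all(diff(ic) > 0))
  }
})

test_that("the frontier algorithm agrees with the brute-force dominance oracle", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(2:6, 1)
    df <- data.frame(name = paste0("s", seq_len(n)),
                     cost = round(runif(n, 0, 1000), 2),
                     effect = round(runif(n, 0, 2), 4))
    fr <- icer_frontier(df)
    expect_equal(fr$classification, brute_force_frontier(df),
                 info = paste("instance", rep))
  }
})

test_that("with zero unit costs the frontier orders by effect alone", {
  p <- dp
  for (f in c("colonoscopy", "polypectomy", "gfobt_test", "fit_test", "staging",
              "medication_uicc_iv", "followup_longterm_per_5y",
              "complication_surgical", "complication_inpatient")) {
    p$costs[[f]] <- 0
  }
  p$costs$inpatient_by_stage[] <- 0
  p$costs$followup_by_year[] <- 0
  p$costs$end_of_life[] <- 0
  p$costs$program_cost[] <- 0
  econ <- strategy_economics(p)
  expect_true(all(econ$table$cost == 0))
  best <- econ$table$name[which.max(econ$table$disc_lyg)]
  expect_true(best %in% econ$frontier$name[econ$frontier$classification == "frontier"])
})
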