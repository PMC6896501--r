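test_that("transition matrices are row-stochastic across ages and state spaces", {
  for (st in list(make_state_table("regular"), make_state_table())) {
    for (age in c(20, 45, 60, 85, 110)) {
      M <- build_transition_matrix(dp_ext, age, st)
      expect_lt(max(abs(rowSums(M) - 1)), 1e-12)
      expect_true(all(M >= 0))
    }
  }
})

test_that("with zero progression the only transitions are self-loops and other-cause death", {
  p <- no_crc_params(dp_ext)
  p$natural_history$adenoma_to_advanced <- 0
  p$natural_history$advanced_to_preclinical <- 0
  p$natural_history$stage_progression <- c(0, 0, 0)
  p$natural_history$symptomatic_detection <- c(0, 0, 0, 0)
  st <- make_state_table("regular")
  M <- build_transition_matrix(p, 60, st)
  q <- p$mortality$life_table$qx[p$mortality$life_table$age == 60]
  living <- st$id[st$alive & !st$diagnosed]
  death_other <- which(colnames(M) == "death_other")
  for (i in living) {
    expect_equal(M[i, i], 1 - q)
    expect_equal(M[i, death_other], q)
    expect_equal(sum(M[i, -c(i, death_other)]), 0)
  }
})

test_that("ages outside the supported 20-110 range are rejected", {
  expect_error(build_transition_matrix(dp_ext, 120), "out of supported range")
  expect_error(build_transition_matrix(dp_ext, 19), "out of supported range")
})

test_that("death states are absorbing and adenomas never regress", {
  st <- make_state_table()
  M <- build_transition_matrix(dp_ext, 60, st)
  for (d in c("death_crc", "death_other")) {
    expect_equal(unname(M[d, d]), 1)
  }
  # no probability mass from adenoma states back to healthy without screening
  a_rows <- st$id[st$class %in% c("A", "AA")]
  h_cols <- st$id[st$class == "H"]
  expect_equal(sum(M[a_rows, h_cols]), 0)
})

test_that("life-table extrapolation continues the hazard log-linearly", {
  # two-point oracle: the continuation ratio equals the observed ratio
  lt <- data.frame(age = 99:100, qx = c(0.20, 0.22))
  ext <- extrapolate_mortality(lt, 103)
  expect_equal(ext$qx[ext$age == 101], 0.22 * (0.22 / 0.20))
  expect_equal(ext$qx[ext$age == 102], 0.22 * (0.22 / 0.20)^2)

  # constant-rate table: exponential with zero slope stays constant
  ltc <- data.frame(age = 95:100, qx = rep(0.25, 6))
  extc <- extrapolate_mortality(ltc, 110)
  expect_true(all(extc$qx == 0.25))

  # monotone non-decreasing and capped at 1
  extd <- extrapolate_mortality(dp$mortality$life_table, 110)
  tail_qx <- extd$qx[extd$age >= 100]
  expect_true(all(diff(tail_qx) >= 0))
  expect_true(all(extd$qx <= 1))
  expect_gte(extd$qx[extd$age == 105], extd$qx[extd$age == 101])

  expect_error(extrapolate_mortality(data.frame(age = 100, qx = 0.3), 110),
               "at least 2")
})

test_that("screen-detected survival applies the hazard ratio on the hazard scale", {
  m <- dp$mortality
  m$hazard_ratios <- c(0.5, 0.5, 0.5, 0.5)
  m$crc_survival$annual_death_prob[m$crc_survival$stage == 2 &
                                     m$crc_survival$year == 1] <- 0.2
  expect_equal(crc_death_prob(2, "screen", 1, m), 1 - 0.8^0.5)
  # HR = 1: detection mode makes no difference
  m1 <- dp$mortality
  m1$hazard_ratios <- rep(1, 4)
  for (s in 1:4) {
    expect_equal(crc_death_prob(s, "screen", 3, m1),
                 crc_death_prob(s, "symptom", 3, m1))
  }
  # HR < 1 implies lower screen-detected mortality at every stage/year
  for (s in 1:4) for (y in c(1, 4, 6)) {
    expect_lt(crc_death_prob(s, "screen", y, dp$mortality),
              crc_death_prob(s, "symptom", y, dp$mortality))
  }
  expect_error(crc_death_prob(5, "screen", 1, dp$mortality), "unknown stage")
})

test_that("cohort mass is conserved over the full 90-cycle horizon", {
  for (nm in c("no_screening", "FIT", "COL")) {
    tr <- run_cohort(strategies[[nm]], dp)
    expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-10)
  }
})

test_that("repeated single-cycle application equals the one-shot matrix product", {
  st <- make_state_table("regular")
  v <- numeric(nrow(st))
  v[1] <- 1
  P <- diag(nrow(st))
  for (age in 50:59) {
    M <- build_transition_matrix(dp_ext, age, st)
    v <- as.numeric(v %*% M)
    P <- P %*% M
  }
  v10 <- numeric(nrow(st)); v10[1] <- 1
  expect_lt(max(abs(v - as.numeric(v10 %*% P))), 1e-12)
})

test_that("inconsistent natural-history probabilities raise an error rather than renormalizing", {
  p <- dp_ext
  p$natural_history$symptomatic_detection <- c(0.05, 0.12, 0.30, 1.3)
  expect_error(build_transition_matrix(p, 60, make_state_table("regular")),
               "parameter inconsistency")
})
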