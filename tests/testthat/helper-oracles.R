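# Independent oracles used by the test suite.

# Individual-level Monte Carlo simulator: propagates n individuals through
# the same per-cycle kernels (screening, then natural history) by multinomial
# sampling instead of expected-value bookkeeping. Returns life expectancy
# from age 40 (half-cycle corrected, same accounting as the cohort engine),
# lifetime CRC cases per person from age 40, and their standard errors.
mc_simulate <- function(strategy, params, n, seed) {
  set.seed(seed)
  states <- if (strategy$index_test == "none") {
    make_state_table("regular")
  } else {
    make_state_table()
  }
  lt <- params$mortality$life_table
  if (max(lt$age) < 110) params$mortality$life_table <- extrapolate_mortality(lt, 110)
  kern <- crcscreen:::nh_kernel_factory(params, states)
  ns <- nrow(states)
  counts <- integer(ns)
  counts[crcscreen:::lu_id(states, "H", "regular", 0L)] <- n
  alive_ids <- states$id[states$alive]
  scr1 <- vapply(1:4, function(s) crcscreen:::dx_id(states, s, "screen", 1L), 1L)
  sym1 <- vapply(1:4, function(s) crcscreen:::dx_id(states, s, "symptom", 1L), 1L)

  ages <- 20:110
  alive_at <- setNames(numeric(length(ages)), ages)
  cases <- 0
  step <- function(counts, P) {
    out <- integer(ns)
    occupied <- which(counts > 0L)
    for (i in occupied) {
      row <- P[i, ]
      nz <- which(row > 0)
      if (length(nz) == 1L) {
        out[nz] <- out[nz] + counts[i]
      } else {
        draw <- stats::rmultinom(1, counts[i], row[nz])
        out[nz] <- out[nz] + draw[, 1]
      }
    }
    out
  }
  for (a in 20:109) {
    alive_at[as.character(a)] <- sum(counts[alive_ids])
    S <- if (a >= 40) crcscreen:::screening_kernel(strategy, a, params, states) else NULL
    if (!is.null(S)) {
      before_scr <- sum(counts[scr1])
      counts <- step(counts, S$P)
      if (a >= 40) cases <- cases + (sum(counts[scr1]) - before_scr)
    }
    counts <- step(counts, kern(a))
    if (a >= 40) cases <- cases + sum(counts[sym1])
  }
  alive_at["110"] <- sum(counts[alive_ids])

  acc <- as.character(40:110)
  w <- crcscreen:::half_cycle_weights(length(acc))
  le <- sum(w * alive_at[acc]) / n
  # life-years of an individual dying in cycle a: alive at starts 40..a,
  # half-weight at 40 -> a - 39.5; survivors to 110 get the full 70 years
  deaths_in <- -diff(alive_at[acc])
  ly_vals <- c(40:109 - 39.5, 70)
  ly_n <- c(deaths_in, alive_at["110"])
  never <- n - alive_at["40"]  # died before 40: zero accumulated life-years
  ly_mean <- sum(ly_vals * ly_n) / n
  ly_var <- (sum(ly_vals^2 * ly_n) + 0 * never) / n - ly_mean^2
  p_case <- cases / n
  list(
    life_years = le,
    life_years_se = sqrt(ly_var / n),
    crc_cases = p_case,
    crc_cases_se = sqrt(p_case * (1 - p_case) / n)
  )
}

# Brute-force dominance oracle: classifies strategies by direct pairwise and
# convex-combination checks, independent of the frontier algorithm.
brute_force_frontier <- function(df) {
  n <- nrow(df)
  cls <- rep("frontier", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && df$effect[j] >= df$effect[i] && df$cost[j] <= df$cost[i] &&
          (df$effect[j] > df$effect[i] || df$cost[j] < df$cost[i])) {
        cls[i] <- "dominated"
        break
      }
    }
  }
  repeat {
    changed <- FALSE
    for (i in which(cls == "frontier")) {
      others <- which(cls == "frontier")
      others <- others[others != i]
      for (j in others) for (k in others) {
        if (j >= k) next
        de <- df$effect[k] - df$effect[j]
        if (de == 0) next
        lam <- (df$effect[i] - df$effect[j]) / de
        if (lam <= 0 || lam >= 1) next
        mix_cost <- (1 - lam) * df$cost[j] + lam * df$cost[k]
        if (mix_cost < df$cost[i]) {
          cls[i] <- "extended-dominated"
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
    if (!changed) break
  }
  cls
}
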