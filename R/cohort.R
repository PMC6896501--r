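#' Half-cycle correction
#'
#' Weights the first and last accumulation cycles by 0.5 (all intermediate
#' cycles by 1), the trapezoid-equivalent correction at the ends of a
#' Markov trace, and returns the corrected total of a per-cycle stream.
#'
#' @param x numeric vector of per-cycle contributions (first element =
#'   first accumulation cycle)
#' @return the half-cycle-corrected total.
#' @export
half_cycle_correct <- function(x) {
  if (length(x) == 0) stop("empty trace: nothing to correct")
  w <- rep(1, length(x))
  w[1] <- 0.5
  w[length(x)] <- 0.5
  sum(w * x)
}

half_cycle_weights <- function(n) {
  w <- rep(1, n)
  w[1] <- 0.5
  w[n] <- 0.5
  w
}

#' Run the cohort simulation for one strategy
#'
#' Propagates a closed cohort (mass 1) through the model with a 1-year
#' cycle. Natural history runs from age 20; screening examinations and all
#' outcome accumulation (life-years, costs, event counters) start at the
#' decision age of 40. Within each cycle, screening is applied first (to
#' living, undiagnosed states only), then other-cause death, natural-history
#' progression and symptomatic detection, then diagnosed-cancer survival.
#' The trace terminates at age 110, by which the life-table extrapolation
#' leaves negligible living mass.
#'
#' @param strategy a `crc_strategy`
#' @param params a `crc_params` bundle
#' @param states optional state table; defaults to the reduced (regular
#'   track only) space for no-screening runs and the full space otherwise
#' @return A `cohort_trace`: list with `ages` (20-110), `occupancy`
#'   (age x state matrix at cycle starts), `events` (age x counter matrix
#'   of expected per-person event counts during each cycle), `states`,
#'   `strategy`.
#' @export
run_cohort <- function(strategy, params, states = NULL) {
  stopifnot(inherits(strategy, "crc_strategy"), inherits(params, "crc_params"))
  if (is.null(states)) {
    states <- if (strategy$index_test == "none") {
      make_state_table("regular")
    } else {
      make_state_table()
    }
  }
  lt <- params$mortality$life_table
  if (max(lt$age) < 110) {
    params$mortality$life_table <- extrapolate_mortality(lt, 110)
  }
  kern <- nh_kernel_factory(params, states)
  n <- nrow(states)
  ages <- 20:110
  v <- numeric(n)
  v[lu_id(states, "H", "regular", 0L)] <- 1

  dx_scr1 <- vapply(1:4, function(s) dx_id(states, s, "screen", 1L), 1L)
  dx_sym1 <- vapply(1:4, function(s) dx_id(states, s, "symptom", 1L), 1L)
  dx_by_stage <- lapply(1:4, function(s) states$id[states$diagnosed & states$stage == s])
  dx_by_band <- lapply(1:6, function(b) states$id[states$diagnosed & states$band == b])
  alive_ids <- states$id[states$alive]
  death_crc <- state_id(states, "death_crc")
  death_other <- state_id(states, "death_other")

  ev_names <- c("alive_start", "in_program", "stool_tests", "colonoscopies",
                "sym_colonoscopies", "positive_tests", "polypectomies",
                "complications", paste0("screen_dx_", 1:4),
                paste0("sym_dx_", 1:4), paste0("crc_deaths_", 1:4),
                "deaths_other", paste0("followup_band_", 1:6))
  occupancy <- matrix(0, length(ages), n, dimnames = list(ages, states$name))
  events <- matrix(0, length(ages), length(ev_names), dimnames = list(ages, ev_names))
  p_adm <- params$complications$per_colonoscopy_admission

  for (a in 20:109) {
    r <- as.character(a)
    occupancy[r, ] <- v
    alive_mass <- sum(v[alive_ids])
    events[r, "alive_start"] <- alive_mass
    if (strategy$index_test != "none" &&
        a >= strategy$start_age && a <= strategy$stop_age) {
      events[r, "in_program"] <- alive_mass
    }
    S <- if (a >= 40) screening_kernel(strategy, a, params, states) else NULL
    if (!is.null(S)) {
      cnt <- as.numeric(v %*% S$W)
      names(cnt) <- colnames(S$W)
      events[r, names(cnt)] <- cnt
      v <- as.numeric(v %*% S$P)
    }
    M <- kern(a)
    # diagnosed-state occupancy after screening, before survival: carries
    # year-specific follow-up costs for the year being lived
    for (b in 1:6) events[r, paste0("followup_band_", b)] <- sum(v[dx_by_band[[b]]])
    death_col <- M[, death_crc]
    for (s in 1:4) {
      ids <- dx_by_stage[[s]]
      events[r, paste0("crc_deaths_", s)] <- sum(v[ids] * death_col[ids])
    }
    v_next <- as.numeric(v %*% M)
    events[r, paste0("sym_dx_", 1:4)] <- v_next[dx_sym1]
    events[r, "sym_colonoscopies"] <- sum(v_next[dx_sym1])
    events[r, "deaths_other"] <- v_next[death_other] - v[death_other]
    events[r, "complications"] <-
      (events[r, "colonoscopies"] + events[r, "sym_colonoscopies"]) * p_adm
    v <- v_next
  }
  occupancy["110", ] <- v
  structure(list(ages = ages, occupancy = occupancy, events = events,
                 states = states, strategy = strategy),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  last <- x$occupancy[nrow(x$occupancy), ]
  alive <- sum(last[x$states$id[x$states$alive]])
  cat(sprintf("<cohort_trace> %s: ages %d-%d, %d states, residual living mass %.2e\n",
              x$strategy$name, min(x$ages), max(x$ages), nrow(x$states), alive))
  invisible(x)
}

#' Summarize a cohort trace
#'
#' Accumulates life-years (half-cycle corrected), lifetime costs and event
#' counts from the decision age of 40. Discounting is anchored at age 40
#' with factor `(1 + rate)^-(age - 40)`.
#'
#' @param trace a `cohort_trace`
#' @param params the parameter bundle used for the run (unit costs)
#' @param discount_rate annual discount rate (>= 0), default 3%
#' @return an `outcome_summary` list with per-person values (`life_years`,
#'   `disc_life_years`, `cost`, `disc_cost`, `crc_cases`, `crc_deaths`,
#'   `positive_tests`, `colonoscopies`, `complications`) and a `per_1000`
#'   vector, plus the undiscounted cost breakdown by category.
#' @export
summarize_cohort <- function(trace, params, discount_rate = 0.03) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (discount_rate < 0) stop("discount rate must be >= 0")
  acc_ages <- 40:110
  rows <- as.character(acc_ages)
  alive_ids <- trace$states$id[trace$states$alive]
  alive <- rowSums(trace$occupancy[rows, alive_ids, drop = FALSE])
  w <- half_cycle_weights(length(acc_ages))
  df <- (1 + discount_rate)^-(acc_ages - 40)
  life_years <- sum(w * alive)
  disc_life_years <- sum(w * alive * df)

  ledger <- program_costs(trace, params)  # age x category, undiscounted
  cyc_cost <- rowSums(ledger)
  cost <- sum(cyc_cost)
  disc_cost <- sum(cyc_cost * (1 + discount_rate)^-(as.numeric(rownames(ledger)) - 40))

  ev <- trace$events[rows, , drop = FALSE]
  tot <- colSums(ev)
  crc_cases <- sum(tot[paste0("screen_dx_", 1:4)]) + sum(tot[paste0("sym_dx_", 1:4)])
  crc_deaths <- sum(tot[paste0("crc_deaths_", 1:4)])
  out <- list(
    strategy = trace$strategy$name,
    discount_rate = discount_rate,
    life_years = life_years, disc_life_years = disc_life_years,
    cost = cost, disc_cost = disc_cost,
    crc_cases = crc_cases, crc_deaths = crc_deaths,
    positive_tests = tot[["positive_tests"]],
    stool_tests = tot[["stool_tests"]],
    colonoscopies = tot[["colonoscopies"]] + tot[["sym_colonoscopies"]],
    polypectomies = tot[["polypectomies"]],
    complications = tot[["complications"]],
    cost_breakdown = colSums(ledger)
  )
  out$per_1000 <- 1000 * c(
    life_years = life_years, crc_cases = crc_cases, crc_deaths = crc_deaths,
    positive_tests = out$positive_tests, complications = out$complications
  )
  class(out) <- "outcome_summary"
  out
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("<outcome_summary> %s (discount %.1f%%)\n", x$strategy,
              100 * x$discount_rate))
  cat(sprintf("  life-years %.3f (disc %.3f); cost EUR %.0f (disc %.0f)\n",
              x$life_years, x$disc_life_years, x$cost, x$disc_cost))
  cat(sprintf("  per person: CRC cases %.4f, CRC deaths %.4f, positives %.2f, complications %.4f\n",
              x$crc_cases, x$crc_deaths, x$positive_tests, x$complications))
  invisible(x)
}

#' Export a cohort trace as a tidy data frame
#'
#' @param trace a `cohort_trace`
#' @return data frame with columns `age`, `state`, `occupancy` (cycle-start
#'   occupancy, zero rows dropped).
#' @export
trace_as_data_frame <- function(trace) {
  occ <- trace$occupancy
  df <- data.frame(
    age = rep(as.integer(rownames(occ)), times = ncol(occ)),
    state = rep(colnames(occ), each = nrow(occ)),
    occupancy = as.vector(occ)
  )
  df[df$occupancy > 0, ]
}

# Participation-weighted mixture of two outcome summaries (all-or-none
# participation: non-participants follow no-screening natural history).
mix_summaries <- function(screened, unscreened, participation) {
  stopifnot(participation >= 0, participation <= 1)
  out <- screened
  num <- c("life_years", "disc_life_years", "cost", "disc_cost", "crc_cases",
           "crc_deaths", "positive_tests", "stool_tests", "colonoscopies",
           "polypectomies", "complications")
  for (f in num) {
    out[[f]] <- participation * screened[[f]] + (1 - participation) * unscreened[[f]]
  }
  out$cost_breakdown <- participation * screened$cost_breakdown +
    (1 - participation) * unscreened$cost_breakdown
  out$per_1000 <- 1000 * c(
    life_years = out$life_years, crc_cases = out$crc_cases,
    crc_deaths = out$crc_deaths, positive_tests = out$positive_tests,
    complications = out$complications
  )
  out
}
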