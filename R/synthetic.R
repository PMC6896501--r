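#' Synthetic Gompertz life table
#'
#' Abridged all-cause life table with annual death probability
#' `qx = 1 - exp(-(makeham + a * exp(b * age)))`, a Gompertz(-Makeham)
#' hazard. Stands in for a national statistical life table.
#'
#' @param a Gompertz level parameter (> 0)
#' @param b Gompertz slope per year of age (>= 0; 0 gives a constant
#'   hazard, i.e. exponential survival)
#' @param max_age last tabulated age
#' @param makeham age-independent background hazard
#' @return data frame with columns `age` (0..max_age), `qx`.
#' @export
make_life_table <- function(a, b, max_age = 100, makeham = 0) {
  stopifnot(a > 0, b >= 0, makeham >= 0)
  age <- 0:max_age
  data.frame(age = age, qx = pmin(1, 1 - exp(-(makeham + a * exp(b * age)))))
}

#' Life expectancy implied by a life table
#'
#' Half-cycle-corrected expectation of remaining years at `from_age`,
#' consistent with the cohort engine's accounting.
#'
#' @param life_table data frame with `age`, `qx`
#' @param from_age starting age
#' @return expected remaining life-years.
#' @export
life_expectancy <- function(life_table, from_age = 40) {
  lt <- life_table[order(life_table$age), ]
  lt <- lt[lt$age >= from_age, ]
  surv <- cumprod(c(1, 1 - lt$qx[-nrow(lt)]))
  half_cycle_correct(surv)
}

#' Synthetic stage-specific cancer survival table
#'
#' Annual post-diagnosis death probabilities by UICC stage for years 1-5
#' plus a long-term band (year 6), for symptom-detected cancers; values
#' decline with time since diagnosis and worsen with stage. Five-year
#' survival is roughly 89/75/50/9% for stages I-IV, consistent with the
#' mid-1990s registry era that the packaged cumulative-mortality
#' calibration target refers to.
#'
#' @return data frame with columns `stage`, `year`, `annual_death_prob`.
#' @export
make_survival_table <- function() {
  probs <- rbind(
    c(0.030, 0.026, 0.023, 0.020, 0.018, 0.008),
    c(0.070, 0.060, 0.055, 0.050, 0.045, 0.015),
    c(0.170, 0.150, 0.130, 0.110, 0.090, 0.025),
    c(0.550, 0.450, 0.350, 0.280, 0.220, 0.060)
  )
  data.frame(stage = rep(1:4, each = 6), year = rep(1:6, 4),
             annual_death_prob = as.vector(t(probs)))
}

#' Generate a synthetic calibration scenario
#'
#' Produces everything a calibration experiment needs with known ground
#' truth: a parameter bundle whose natural-history block is the truth, and
#' calibration targets generated from it by the model itself, optionally
#' perturbed with multiplicative lognormal noise (registry sampling
#' variation). `difficulty = "easy"` jitters the packaged natural-history
#' defaults mildly; `"paper-like"` uses them as-is, so the implied
#' no-screening cumulative CRC mortality at 75 stays in a realistic
#' 1.5-2.5% band. Regeneration with the same seed is bit-identical.
#'
#' @param seed integer RNG seed
#' @param difficulty `"easy"` or `"paper-like"`
#' @param sigma lognormal noise sd on the targets (0 = exact targets)
#' @param params base bundle (defaults to the packaged bundle)
#' @return a `synthetic_scenario`: list with `seed`, `difficulty`, `sigma`,
#'   `params` (truth), `targets`.
#' @export
make_scenario <- function(seed, difficulty = c("easy", "paper-like"),
                          sigma = 0, params = default_parameters()) {
  difficulty <- match.arg(difficulty)
  set.seed(seed)
  p <- params
  if (difficulty == "easy") {
    theta <- nh_to_theta(p$natural_history)
    jitter <- exp(stats::rnorm(length(theta), 0, 0.10))
    box <- nh_par_box()
    theta <- pmin(pmax(theta * jitter, box$lo * 1.05), box$hi * 0.95)
    p$natural_history <- theta_to_nh(theta, p$natural_history)
  }
  pred <- predict_targets(p)
  targets <- list(
    incidence = pred$incidence,
    stage_distribution = pred$stage_distribution,
    cum_mortality_75 = pred$cum_mortality_75
  )
  if (sigma > 0) {
    ni <- nrow(targets$incidence)
    targets$incidence$incidence_per_100k <-
      targets$incidence$incidence_per_100k * exp(stats::rnorm(ni, 0, sigma))
    sd <- targets$stage_distribution * exp(stats::rnorm(4, 0, sigma))
    targets$stage_distribution <- sd / sum(sd)
    targets$cum_mortality_75 <- targets$cum_mortality_75 * exp(stats::rnorm(1, 0, sigma))
  }
  class(targets) <- c("calibration_targets", "list")
  structure(list(seed = seed, difficulty = difficulty, sigma = sigma,
                 params = p, targets = targets),
            class = "synthetic_scenario")
}

#' Write a synthetic scenario to disk
#'
#' Emits the same formats the parameter loader reads: a JSON bundle with
#' companion life-table and survival CSVs, plus a calibration-targets CSV.
#'
#' @param scenario a `synthetic_scenario`
#' @param dir output directory (created if missing)
#' @return named vector of written paths.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pj <- file.path(dir, "scenario_params.json")
  tc <- file.path(dir, "scenario_targets.csv")
  write_parameters(scenario$params, pj)
  write_calibration_targets(scenario$targets, tc)
  c(params = pj, targets = tc)
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("<synthetic_scenario> seed %d, %s difficulty, target noise sigma %.2f\n",
              x$seed, x$difficulty, x$sigma))
  cat(sprintf("  cumulative CRC mortality at 75 (truth): %.3f%%\n",
              100 * x$targets$cum_mortality_75))
  invisible(x)
}
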