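# Calibrated natural-history parameter vector: adenoma onset level and age
# slope, adenoma->advanced, advanced->preclinical, three preclinical stage
# progressions, four stage-specific symptomatic detection probabilities.
nh_par_names <- function() {
  c("onset_base", "onset_slope", "adenoma_to_advanced", "advanced_to_preclinical",
    "prog_1_2", "prog_2_3", "prog_3_4", "det_1", "det_2", "det_3", "det_4")
}

# Epidemiologically plausible bounds: adenoma dwell times of years to a few
# decades, preclinical sojourn of a few years, detection hazard increasing
# with stage.
nh_par_box <- function() {
  list(
    lo = c(onset_base = 1e-3, onset_slope = 0, adenoma_to_advanced = 0.005,
           advanced_to_preclinical = 0.01, prog_1_2 = 0.10, prog_2_3 = 0.10,
           prog_3_4 = 0.10, det_1 = 0.01, det_2 = 0.02, det_3 = 0.05,
           det_4 = 0.10),
    hi = c(onset_base = 0.05, onset_slope = 0.10, adenoma_to_advanced = 0.10,
           advanced_to_preclinical = 0.15, prog_1_2 = 0.80, prog_2_3 = 0.80,
           prog_3_4 = 0.80, det_1 = 0.30, det_2 = 0.50, det_3 = 0.70,
           det_4 = 0.95)
  )
}

nh_to_theta <- function(nh) {
  c(onset_base = nh$onset_base, onset_slope = nh$onset_slope,
    adenoma_to_advanced = nh$adenoma_to_advanced,
    advanced_to_preclinical = nh$advanced_to_preclinical,
    prog_1_2 = nh$stage_progression[[1]], prog_2_3 = nh$stage_progression[[2]],
    prog_3_4 = nh$stage_progression[[3]],
    det_1 = nh$symptomatic_detection[[1]], det_2 = nh$symptomatic_detection[[2]],
    det_3 = nh$symptomatic_detection[[3]], det_4 = nh$symptomatic_detection[[4]])
}

theta_to_nh <- function(theta, nh) {
  nh$onset_base <- unname(theta[["onset_base"]])
  nh$onset_slope <- unname(theta[["onset_slope"]])
  nh$adenoma_to_advanced <- unname(theta[["adenoma_to_advanced"]])
  nh$advanced_to_preclinical <- unname(theta[["advanced_to_preclinical"]])
  nh$stage_progression <- unname(c(theta[["prog_1_2"]], theta[["prog_2_3"]],
                                   theta[["prog_3_4"]]))
  nh$symptomatic_detection <- unname(c(theta[["det_1"]], theta[["det_2"]],
                                       theta[["det_3"]], theta[["det_4"]]))
  nh
}

#' Epidemiological predictions for calibration
#'
#' Runs the no-screening natural-history cohort and summarizes it as the
#' quantities the model is calibrated to: age-group-specific CRC incidence
#' (new diagnoses per 100,000 person-years, person-years counted over the
#' whole living cohort as in registry rates), the UICC stage distribution
#' over all incident diagnoses, and the cumulative CRC-related mortality by
#' age 75 (fraction of the age-20 cohort).
#'
#' @param params a `crc_params` bundle
#' @param age_groups data frame with columns `age_lo`, `age_hi` (closed)
#' @return list with `incidence` (data frame adding `incidence_per_100k`),
#'   `stage_distribution` (length 4, `NA` and flagged degenerate if there
#'   are no diagnoses), `cum_mortality_75`.
#' @export
predict_targets <- function(params, age_groups = default_age_groups()) {
  tr <- run_cohort(default_strategies()$no_screening, params)
  ev <- tr$events
  ages <- as.numeric(rownames(ev))
  dx <- rowSums(ev[, paste0("sym_dx_", 1:4), drop = FALSE])
  inc <- age_groups
  inc$incidence_per_100k <- vapply(seq_len(nrow(age_groups)), function(g) {
    sel <- ages >= age_groups$age_lo[g] & ages <= age_groups$age_hi[g]
    py <- sum(ev[sel, "alive_start"])
    if (py <= 0) return(0)
    1e5 * sum(dx[sel]) / py
  }, 1.0)
  stage_tot <- colSums(ev[, paste0("sym_dx_", 1:4), drop = FALSE])
  total_dx <- sum(stage_tot)
  stage_dist <- if (total_dx > 0) stage_tot / total_dx else rep(NA_real_, 4)
  cum75 <- sum(rowSums(ev[ages < 75, paste0("crc_deaths_", 1:4), drop = FALSE]))
  list(incidence = inc,
       stage_distribution = unname(stage_dist),
       cum_mortality_75 = cum75,
       degenerate = total_dx <= 0)
}

default_age_groups <- function() {
  lo <- seq(40, 85, by = 5)
  data.frame(age_lo = lo, age_hi = c(lo[-1] - 1, 99))
}

#' Calibration deviation between prediction and targets
#'
#' Weighted sum of squared relative deviations. By default each incidence
#' group has weight 1, the four stage proportions share an aggregate weight
#' equal to the incidence block, and the optional cumulative-mortality
#' target — the headline validation quantity — carries a full incidence
#' block on its own. Targets equal to zero fall back to absolute
#' deviations.
#'
#' @param predicted output of [predict_targets()]
#' @param targets a `calibration_targets` list (same shape)
#' @param weights optional list with `incidence`, `stage`, `cum_mortality`
#' @return non-negative scalar, zero iff the fit is exact.
#' @export
calibration_objective <- function(predicted, targets, weights = NULL) {
  n_inc <- nrow(targets$incidence)
  if (is.null(weights)) {
    weights <- list(incidence = rep(1, n_inc),
                    stage = rep(n_inc / 4, 4),
                    cum_mortality = n_inc)
  }
  rel2 <- function(pred, obs) {
    ifelse(obs == 0, pred^2, ((pred - obs) / obs)^2)
  }
  obj <- sum(weights$incidence *
               rel2(predicted$incidence$incidence_per_100k,
                    targets$incidence$incidence_per_100k))
  if (!is.null(targets$stage_distribution) && !anyNA(predicted$stage_distribution)) {
    obj <- obj + sum(weights$stage *
                       rel2(predicted$stage_distribution, targets$stage_distribution))
  } else if (anyNA(predicted$stage_distribution)) {
    obj <- obj + sum(weights$stage)  # degenerate: maximal stage penalty
  }
  if (!is.null(targets$cum_mortality_75) && !is.na(targets$cum_mortality_75)) {
    obj <- obj + weights$cum_mortality *
      rel2(predicted$cum_mortality_75, targets$cum_mortality_75)
  }
  obj
}

#' Calibration settings
#'
#' @param seed RNG seed controlling basin-hopping perturbations
#' @param hops number of basin-hopping restarts in the joint polish stage
#' @param step_frac perturbation size as a fraction of the parameter box
#'   width
#' @param maxit Nelder-Mead iteration cap per local search
#' @param tol objective value below which the fit is declared converged
#' @return list of settings.
#' @export
calibrate_control <- function(seed = 2019, hops = 8, step_frac = 0.25,
                              maxit = 400, tol = 1e-4) {
  list(seed = seed, hops = hops, step_frac = step_frac, maxit = maxit, tol = tol)
}

#' Calibrate the natural-history parameters
#'
#' Hierarchical three-stage fit of the 11 natural-history parameters to
#' epidemiological targets: (A) adenoma onset and progression-to-cancer
#' parameters against the incidence curve (and cumulative mortality),
#' with preclinical stage dynamics fixed; (B) preclinical stage-progression
#' and symptomatic-detection parameters against the stage distribution;
#' (C) a joint Nelder-Mead polish of all parameters inside a
#' basin-hopping loop (random box-scaled perturbations, monotone accept).
#' Deterministic given the seed.
#'
#' @param targets `calibration_targets` list (`incidence` data frame,
#'   `stage_distribution`, optional `cum_mortality_75`)
#' @param params starting `crc_params` bundle (also supplies mortality
#'   tables and the parameter-box bounds context)
#' @param control see [calibrate_control()]
#' @return a `calibration_result`: `params` (bundle with fitted
#'   natural-history block), `objective`, `predicted`, `deviations`,
#'   `stage_objectives`, `diagnostics`, `converged`.
#' @export
calibrate <- function(targets, params, control = calibrate_control()) {
  set.seed(control$seed)
  lt <- params$mortality$life_table
  if (max(lt$age) < 110) params$mortality$life_table <- extrapolate_mortality(lt, 110)
  box <- nh_par_box()
  nms <- nh_par_names()
  theta0 <- nh_to_theta(params$natural_history)[nms]
  theta0 <- pmin(pmax(theta0, box$lo + 1e-9), box$hi - 1e-9)
  n_evals <- 0L

  full_obj <- function(theta, blocks = c("incidence", "stage", "cum")) {
    n_evals <<- n_evals + 1L
    p <- params
    p$natural_history <- theta_to_nh(theta, p$natural_history)
    pred <- predict_targets(p, targets$incidence[, c("age_lo", "age_hi")])
    tg <- targets
    if (!"incidence" %in% blocks) tg$incidence$incidence_per_100k <- pred$incidence$incidence_per_100k
    if (!"stage" %in% blocks) tg$stage_distribution <- NULL
    if (!"cum" %in% blocks) tg$cum_mortality_75 <- NA
    calibration_objective(pred, tg)
  }

  to_z <- function(x, free) {
    u <- (x[free] - box$lo[free]) / (box$hi - box$lo)[free]
    stats::qlogis(pmin(pmax(u, 1e-9), 1 - 1e-9))  # keep start strictly inside the box
  }
  local_fit <- function(theta, free, blocks) {
    fn <- function(z) {
      # simplex excursions to non-finite z or infeasible corners are
      # penalized rather than allowed to abort the search
      if (any(!is.finite(z))) return(1e12)
      th <- theta
      th[free] <- box$lo[free] + (box$hi - box$lo)[free] * stats::plogis(z)
      val <- tryCatch(full_obj(th, blocks), error = function(e) NA_real_)
      if (!is.finite(val)) 1e12 else val
    }
    o <- stats::optim(to_z(theta, free), fn, method = "Nelder-Mead",
                      control = list(maxit = control$maxit, reltol = 1e-9))
    theta[free] <- box$lo[free] + (box$hi - box$lo)[free] * stats::plogis(o$par)
    list(theta = theta, value = o$value, convergence = o$convergence)
  }

  free_a <- nms[1:4]
  free_b <- nms[5:11]
  stage_a <- local_fit(theta0, free_a, c("incidence", "cum"))
  stage_b <- local_fit(stage_a$theta, free_b, c("stage", "cum"))

  best <- local_fit(stage_b$theta, nms, c("incidence", "stage", "cum"))
  hops_done <- 0L
  conv_codes <- c(A = stage_a$convergence, B = stage_b$convergence,
                  C0 = best$convergence)
  width <- box$hi - box$lo
  for (h in seq_len(control$hops)) {
    if (best$value < control$tol) break
    cand0 <- best$theta + stats::runif(length(nms), -1, 1) * control$step_frac * width
    cand0 <- pmin(pmax(cand0, box$lo + 1e-9), box$hi - 1e-9)
    cand <- local_fit(cand0, nms, c("incidence", "stage", "cum"))
    hops_done <- h
    if (cand$value < best$value) best <- cand
  }

  fitted <- params
  fitted$natural_history <- theta_to_nh(best$theta, fitted$natural_history)
  pred <- predict_targets(fitted, targets$incidence[, c("age_lo", "age_hi")])
  dev <- list(
    incidence_rel = (pred$incidence$incidence_per_100k -
                       targets$incidence$incidence_per_100k) /
      pmax(targets$incidence$incidence_per_100k, 1e-12),
    stage_abs = pred$stage_distribution - targets$stage_distribution,
    cum_mortality_rel = if (!is.null(targets$cum_mortality_75) &&
                            !is.na(targets$cum_mortality_75)) {
      (pred$cum_mortality_75 - targets$cum_mortality_75) / targets$cum_mortality_75
    } else NA_real_
  )
  structure(list(
    params = fitted,
    theta = best$theta,
    objective = best$value,
    stage_objectives = c(A = stage_a$value, B = stage_b$value, C = best$value),
    predicted = pred,
    deviations = dev,
    diagnostics = list(seed = control$seed, hops = hops_done,
                       evaluations = n_evals, convergence = conv_codes),
    converged = best$value < control$tol || all(conv_codes == 0)
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> objective %.3e (%s), %d evaluations, %d hops, seed %d\n",
              x$objective, if (x$converged) "converged" else "NOT converged",
              x$diagnostics$evaluations, x$diagnostics$hops, x$diagnostics$seed))
  cat(sprintf("  cumulative CRC mortality at 75: %.3f%%\n", 100 * x$predicted$cum_mortality_75))
  cat("  fitted:", paste(sprintf("%s=%.4g", names(x$theta), x$theta), collapse = ", "), "\n")
  invisible(x)
}

#' Redistribute unknown-stage and DCO registry cases
#'
#' Registry stage distributions contain cases with unknown stage and
#' death-certificate-only (DCO) notifications. Unknown-stage cases are
#' spread proportionally over the four known stages; DCO cases, assumed
#' more severe, are split between UICC III and IV in proportion to those
#' two stages.
#'
#' @param stage_counts counts or proportions for UICC I-IV
#' @param unknown count/proportion of unknown-stage cases
#' @param dco count/proportion of DCO cases
#' @return normalized stage distribution (length 4, sums to 1).
#' @export
redistribute_stages <- function(stage_counts, unknown = 0, dco = 0) {
  stopifnot(length(stage_counts) == 4, all(stage_counts >= 0),
            unknown >= 0, dco >= 0)
  x <- stage_counts + unknown * stage_counts / sum(stage_counts)
  w34 <- x[3:4] / sum(x[3:4])
  x[3:4] <- x[3:4] + dco * w34
  x / sum(x)
}

#' Read / write calibration targets
#'
#' Single CSV with columns `block` (`incidence`, `stage`, `cum_mortality`),
#' `key` (age group `"lo-hi"`, stage `I`-`IV`, or empty) and `value`.
#'
#' @param path CSV path
#' @return for `read_calibration_targets`, a `calibration_targets` list.
#' @export
read_calibration_targets <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character", "numeric"))
  inc <- df[df$block == "incidence", ]
  parts <- strsplit(inc$key, "-", fixed = TRUE)
  targets <- list(
    incidence = data.frame(
      age_lo = as.numeric(vapply(parts, `[`, "", 1)),
      age_hi = as.numeric(vapply(parts, `[`, "", 2)),
      incidence_per_100k = inc$value),
    stage_distribution = df$value[df$block == "stage"][
      match(c("I", "II", "III", "IV"), df$key[df$block == "stage"])],
    cum_mortality_75 = if (any(df$block == "cum_mortality")) {
      df$value[df$block == "cum_mortality"][1]
    } else NA_real_
  )
  sp <- targets$stage_distribution
  if (abs(sum(sp) - 1) > 1e-6) stop("stage proportions must sum to 1")
  if (any(targets$incidence$incidence_per_100k < 0)) stop("incidence must be >= 0")
  class(targets) <- c("calibration_targets", "list")
  targets
}

#' @rdname read_calibration_targets
#' @param targets a `calibration_targets` list
#' @export
write_calibration_targets <- function(targets, path) {
  inc <- targets$incidence
  df <- rbind(
    data.frame(block = "incidence",
               key = sprintf("%d-%d", inc$age_lo, inc$age_hi),
               value = inc$incidence_per_100k),
    data.frame(block = "stage", key = c("I", "II", "III", "IV"),
               value = targets$stage_distribution),
    if (!is.null(targets$cum_mortality_75) && !is.na(targets$cum_mortality_75)) {
      data.frame(block = "cum_mortality", key = "75", value = targets$cum_mortality_75)
    }
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
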