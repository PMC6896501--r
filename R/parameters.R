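#' Load a model parameter bundle
#'
#' Reads a JSON parameter bundle together with its companion CSV tables
#' (life table, cancer survival) and validates every field against the
#' model's invariants. The package ships a default bundle
#' (`default_parameters()`) whose natural-history block is a reconstructed
#' set obtained by calibrating the model to synthetic Austrian-style
#' incidence, stage-distribution and cumulative-mortality targets; test
#' accuracies, unit costs and strategy schedules are the published values.
#'
#' @param path path to a JSON parameter bundle. Relative CSV paths inside
#'   the file are resolved against the bundle's directory.
#' @return An object of class `crc_params`: a list with elements
#'   `natural_history`, `tests`, `mortality` (life table, survival table,
#'   detection-mode hazard ratios), `costs`, `complications`, `meta`.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  lt_path <- file.path(dir, raw$files$life_table)
  sv_path <- file.path(dir, raw$files$crc_survival)
  if (!file.exists(lt_path)) stop("life table not found: ", lt_path)
  if (!file.exists(sv_path)) stop("survival table not found: ", sv_path)
  life_table <- utils::read.csv(lt_path)
  survival <- utils::read.csv(sv_path)
  p <- list(
    meta = raw$meta,
    natural_history = raw$natural_history,
    tests = raw$tests,
    mortality = list(
      life_table = life_table,
      crc_survival = survival,
      hazard_ratios = unlist(raw$hazard_ratios)
    ),
    costs = raw$costs,
    complications = raw$complications
  )
  p$costs$inpatient_by_stage <- unlist(p$costs$inpatient_by_stage)
  p$costs$followup_by_year <- unlist(p$costs$followup_by_year)
  p$costs$end_of_life <- unlist(p$costs$end_of_life)
  p$costs$program_cost <- unlist(p$costs$program_cost)
  p$natural_history$stage_progression <- unlist(p$natural_history$stage_progression)
  p$natural_history$symptomatic_detection <- unlist(p$natural_history$symptomatic_detection)
  class(p) <- "crc_params"
  validate_parameters(p)
  p
}

#' Packaged default parameter bundle
#' @return A validated `crc_params` bundle.
#' @export
default_parameters <- function() {
  load_parameters(system.file("extdata", "default_parameters.json",
                              package = "crcscreen", mustWork = TRUE))
}

#' Serialize a parameter bundle
#'
#' Writes the JSON bundle plus companion CSVs such that
#' `load_parameters()` reads back an identical object (round-trip).
#'
#' @param params a `crc_params` object
#' @param path output JSON path; CSVs are written next to it
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "crc_params"))
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- sub("\\.json$", "", basename(path))
  lt <- paste0(base, "_life_table.csv")
  sv <- paste0(base, "_crc_survival.csv")
  utils::write.csv(params$mortality$life_table, file.path(dir, lt), row.names = FALSE)
  utils::write.csv(params$mortality$crc_survival, file.path(dir, sv), row.names = FALSE)
  costs <- params$costs
  costs$program_cost <- as.list(costs$program_cost)   # keep names in JSON
  costs$end_of_life <- as.list(costs$end_of_life)
  out <- list(
    meta = params$meta,
    files = list(life_table = lt, crc_survival = sv),
    natural_history = params$natural_history,
    tests = params$tests,
    hazard_ratios = as.list(params$mortality$hazard_ratios),
    costs = costs,
    complications = params$complications
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

chk_prob <- function(x, field) {
  if (is.null(x) || anyNA(x)) stop("validation error: missing value in field '", field, "'")
  if (any(x < 0 | x > 1)) {
    stop("range error: field '", field, "' must lie in [0,1], got ",
         paste(signif(x[x < 0 | x > 1], 4), collapse = ", "))
  }
  invisible(TRUE)
}

chk_nonneg <- function(x, field) {
  if (is.null(x) || anyNA(x)) stop("validation error: missing value in field '", field, "'")
  if (any(x < 0)) stop("range error: field '", field, "' must be >= 0")
  invisible(TRUE)
}

#' Validate a parameter bundle
#'
#' Checks every probability lies in \[0,1\], costs are non-negative, the
#' life table covers ages through 100, the survival table has annual death
#' probabilities for stages I-IV over years 1-5 plus a long-term band, and
#' colonoscopy specificity is fixed at 1 (expert assumption).
#'
#' @param params a `crc_params` object
#' @return the bundle, invisibly; errors name the offending field.
#' @export
validate_parameters <- function(params) {
  nh <- params$natural_history
  chk_prob(nh$onset_base, "natural_history.onset_base")
  if (is.null(nh$onset_slope) || nh$onset_slope < 0)
    stop("validation error: natural_history.onset_slope must be >= 0")
  chk_prob(nh$onset_cap, "natural_history.onset_cap")
  chk_prob(nh$adenoma_to_advanced, "natural_history.adenoma_to_advanced")
  chk_prob(nh$advanced_to_preclinical, "natural_history.advanced_to_preclinical")
  if (length(nh$stage_progression) != 3)
    stop("validation error: natural_history.stage_progression needs 3 values (I>II, II>III, III>IV)")
  chk_prob(nh$stage_progression, "natural_history.stage_progression")
  if (length(nh$symptomatic_detection) != 4)
    stop("validation error: natural_history.symptomatic_detection needs 4 values (stages I-IV)")
  chk_prob(nh$symptomatic_detection, "natural_history.symptomatic_detection")

  for (tn in c("FIT", "gFOBT", "colonoscopy")) {
    tt <- params$tests[[tn]]
    if (is.null(tt)) stop("validation error: tests.", tn, " missing")
    for (f in c("sensitivity_adenoma", "sensitivity_advanced_adenoma",
                "sensitivity_crc", "specificity")) {
      chk_prob(tt[[f]], paste0("tests.", tn, ".", f))
    }
  }
  if (abs(params$tests$colonoscopy$specificity - 1) > 1e-12)
    stop("validation error: tests.colonoscopy.specificity is fixed at 1")

  lt <- params$mortality$life_table
  if (!all(c("age", "qx") %in% names(lt)))
    stop("validation error: life table needs columns age, qx")
  if (max(lt$age) < 100) stop("validation error: life table must cover ages through 100")
  chk_prob(lt$qx, "mortality.life_table.qx")

  sv <- params$mortality$crc_survival
  need <- c("stage", "year", "annual_death_prob")
  if (!all(need %in% names(sv)))
    stop("validation error: survival table needs columns stage, year, annual_death_prob")
  chk_prob(sv$annual_death_prob, "mortality.crc_survival.annual_death_prob")
  for (s in 1:4) {
    if (!all(1:6 %in% sv$year[sv$stage == s]))
      stop("validation error: survival table incomplete for stage ", s,
           " (need years 1-5 plus long-term band 6)")
  }
  hr <- params$mortality$hazard_ratios
  if (length(hr) != 4 || any(hr <= 0))
    stop("validation error: hazard_ratios needs 4 positive values (stages I-IV)")

  co <- params$costs
  for (f in c("colonoscopy", "polypectomy", "gfobt_test", "fit_test", "staging",
              "medication_uicc_iv", "followup_longterm_per_5y",
              "complication_surgical", "complication_inpatient", "program_divisor")) {
    chk_nonneg(co[[f]], paste0("costs.", f))
  }
  chk_nonneg(co$inpatient_by_stage, "costs.inpatient_by_stage")
  if (length(co$inpatient_by_stage) != 4)
    stop("validation error: costs.inpatient_by_stage needs 4 values")
  chk_nonneg(co$followup_by_year, "costs.followup_by_year")
  if (length(co$followup_by_year) != 5)
    stop("validation error: costs.followup_by_year needs 5 values")
  chk_nonneg(co$end_of_life, "costs.end_of_life")
  chk_nonneg(co$program_cost, "costs.program_cost")
  chk_prob(params$complications$per_colonoscopy_admission,
           "complications.per_colonoscopy_admission")
  chk_prob(params$complications$surgical_fraction, "complications.surgical_fraction")
  invisible(params)
}

#' @export
print.crc_params <- function(x, ...) {
  cat("<crc_params> parameter bundle\n")
  cat("  label:", x$meta$label %||% "(none)", " index year:", x$meta$index_year %||% NA, "\n")
  cat(sprintf("  adenoma onset at 50: %.4f/y (slope %.3f/y)\n",
              x$natural_history$onset_base, x$natural_history$onset_slope))
  cat(sprintf("  FIT sens adv/CRC: %.3f/%.3f spec %.3f; gFOBT %.3f/%.3f spec %.3f\n",
              x$tests$FIT$sensitivity_advanced_adenoma, x$tests$FIT$sensitivity_crc,
              x$tests$FIT$specificity,
              x$tests$gFOBT$sensitivity_advanced_adenoma, x$tests$gFOBT$sensitivity_crc,
              x$tests$gFOBT$specificity))
  cat(sprintf("  life table ages %d-%d\n", min(x$mortality$life_table$age),
              max(x$mortality$life_table$age)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Size-pooled test sensitivity
#'
#' Pools size- or location-specific sensitivities into a single value using
#' the prevalence weights of the strata, e.g. the gFOBT adenoma sensitivity
#' pooled over 1-5 mm and 6-9 mm lesions, or the CRC sensitivity pooled over
#' proximal and distal colon.
#'
#' @param s_small,s_medium stratum-specific sensitivities (probabilities)
#' @param w_small,w_medium stratum weights, must sum to 1
#' @return the weighted sensitivity `w_small*s_small + w_medium*s_medium`.
#' @examples
#' pooled_sensitivity(0.075, 0.124, 0.603, 0.397)  # ~0.0945
#' @export
pooled_sensitivity <- function(s_small, s_medium, w_small, w_medium) {
  chk_prob(c(s_small, s_medium), "sensitivity")
  if (abs(w_small + w_medium - 1) > 1e-9) stop("weights must sum to 1")
  w_small * s_small + w_medium * s_medium
}

#' Screening strategy definition
#'
#' @param name display name
#' @param index_test one of `"none"`, `"FIT"`, `"gFOBT"`, `"colonoscopy"`
#' @param start_age,stop_age first and last age (inclusive) at which the
#'   index test is offered
#' @param interval years between index tests
#' @param surveillance_stop_age last age at which any surveillance
#'   examination is performed (default 75)
#' @param participation fraction of the cohort entering the program
#'   (all-or-none at program entry)
#' @return a `crc_strategy` list.
#' @export
new_strategy <- function(name, index_test, start_age = NA, stop_age = NA,
                         interval = NA, surveillance_stop_age = 75,
                         participation = 1) {
  index_test <- match.arg(index_test, c("none", "FIT", "gFOBT", "colonoscopy"))
  if (index_test != "none") {
    stopifnot(is.numeric(start_age), is.numeric(stop_age), is.numeric(interval))
    if (!(start_age < stop_age)) stop("start_age must be < stop_age")
    if (interval < 1) stop("interval must be >= 1 year")
  }
  if (!(participation > 0 && participation <= 1))
    stop("participation must be in (0, 1]")
  structure(list(name = name, index_test = index_test, start_age = start_age,
                 stop_age = stop_age, interval = interval,
                 surveillance_stop_age = surveillance_stop_age,
                 participation = participation),
            class = "crc_strategy")
}

#' The four evaluated screening strategies
#'
#' No screening; annual FIT at ages 40-75; annual gFOBT at ages 40-75;
#' 10-yearly colonoscopy at ages 50, 60, 70. Age windows are closed on both
#' ends; surveillance runs until age 75 in all strategies.
#'
#' @return named list of `crc_strategy` objects.
#' @export
default_strategies <- function() {
  list(
    no_screening = new_strategy("No Screening", "none"),
    COL = new_strategy("10-yearly Colonoscopy", "colonoscopy", 50, 70, 10),
    gFOBT = new_strategy("Annual gFOBT", "gFOBT", 40, 75, 1),
    FIT = new_strategy("Annual FIT", "FIT", 40, 75, 1)
  )
}

#' @export
print.crc_strategy <- function(x, ...) {
  if (x$index_test == "none") {
    cat("<crc_strategy>", x$name, "\n")
  } else {
    cat(sprintf("<crc_strategy> %s: %s every %dy at ages %d-%d (surveillance to %d)\n",
                x$name, x$index_test, x$interval, x$start_age, x$stop_age,
                x$surveillance_stop_age))
  }
  invisible(x)
}
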