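#' Is an examination due?
#'
#' Regular-track examinations follow the strategy schedule: the index test
#' is offered at `start_age, start_age + interval, ..., stop_age` (closed
#' age window). Surveillance tracks are colonoscopy-based: `colo10y` every
#' 10 years, `surv3y` every 3, `surv5y` every 5, counted from the last
#' examination, and no surveillance examination is performed after the
#' surveillance stop age (75).
#'
#' @param strategy a `crc_strategy`
#' @param track one of `"regular"`, `"colo10y"`, `"surv3y"`, `"surv5y"`
#' @param age current age in years
#' @param last_event_age age at the last examination on the track (ignored
#'   for the regular track)
#' @return list with `due` (logical) and `test` (`NA`, the strategy's index
#'   test, or `"colonoscopy"` for surveillance exams).
#' @export
is_screening_due <- function(strategy, track, age, last_event_age = NA) {
  caps <- track_phase_caps()
  if (track == "regular") {
    if (strategy$index_test == "none") return(list(due = FALSE, test = NA))
    due <- age >= strategy$start_age && age <= strategy$stop_age &&
      (age - strategy$start_age) %% strategy$interval == 0
    return(list(due = due, test = if (due) strategy$index_test else NA))
  }
  interval <- caps[[track]]
  due <- !is.na(last_event_age) &&
    (age - last_event_age) >= interval &&
    age <= strategy$surveillance_stop_age
  list(due = due, test = if (due) "colonoscopy" else NA)
}

#' Screening test result probabilities by health state
#'
#' For a living, undiagnosed state, returns the probability of a positive
#' test: `1 - specificity` for healthy individuals, the lesion-class
#' sensitivity otherwise (CRC sensitivity is stage-invariant).
#'
#' @param state_class one of `"H"`, `"A"`, `"AA"`, `"P1"`..`"P4"`
#' @param acc accuracy block for one test (fields `sensitivity_adenoma`,
#'   `sensitivity_advanced_adenoma`, `sensitivity_crc`, `specificity`)
#' @return list with `positive` and `negative` probabilities.
#' @export
apply_test <- function(state_class, acc) {
  if (state_class %in% c("DX", "death_crc", "death_other"))
    stop("apply_test is defined for living, undiagnosed states only")
  p <- switch(state_class,
              H = 1 - acc$specificity,
              A = acc$sensitivity_adenoma,
              AA = acc$sensitivity_advanced_adenoma,
              P1 = , P2 = , P3 = , P4 = acc$sensitivity_crc,
              stop("unknown state class: ", state_class))
  list(positive = p, negative = 1 - p)
}

# Track reassignment after a colonoscopy, by finding.
# A clean or non-advanced finding on the 3-yearly track de-escalates to the
# 5-yearly track; an advanced-adenoma finding always (re)starts the 3-yearly
# track; on the regular/10-yearly tracks a clean or non-advanced finding
# continues the same 10-yearly schedule.
next_track <- function(track, finding, stool_regular = FALSE) {
  if (finding == "crc") return(NA_character_)
  if (finding == "advanced") return("surv3y")
  if (track == "regular") {
    if (finding == "adenoma" && stool_regular) return("colo10y")
    return("regular")
  }
  if (track == "colo10y") return("colo10y")
  "surv5y"  # surv3y and surv5y both continue/de-escalate to surv5y
}

#' Resolve a positive screening examination
#'
#' Maps a colonoscopy finding (direct, or confirmatory after a positive
#' stool test) to the new health state and surveillance track: detected
#' non-advanced adenomas are removed (back to healthy; under a stool-test
#' strategy the individual switches to 10-yearly colonoscopy), detected
#' advanced adenomas are removed and start 3-yearly surveillance, detected
#' cancers move to the screen-detected diagnosed state, and a false-positive
#' stool test (nothing found at colonoscopy) leaves state and track
#' unchanged.
#'
#' @param finding one of `"none"`, `"adenoma"`, `"advanced"`, `"crc"`
#' @param track surveillance track under which the examination happened
#' @param stool_regular was this a regular-track examination of a stool-test
#'   strategy (i.e. a confirmatory colonoscopy)?
#' @return list with `new_class` (`"H"` for removals, `NA` = unchanged,
#'   `"DX"` for cancer) and `new_track`.
#' @export
resolve_positive <- function(finding, track,
                             stool_regular = FALSE) {
  finding <- match.arg(finding, c("none", "adenoma", "advanced", "crc"))
  if (finding == "none" && stool_regular) {
    # false-positive stool test: one confirmatory colonoscopy, no change
    return(list(new_class = NA_character_, new_track = track))
  }
  nt <- next_track(track, finding, stool_regular)
  new_class <- switch(finding,
                      none = NA_character_,
                      adenoma = "H", advanced = "H", crc = "DX")
  list(new_class = new_class, new_track = nt)
}

#' Expected colonoscopy complications
#'
#' In cohort mode the expected number of complication-related hospital
#' admissions is linear in the number of colonoscopies.
#'
#' @param n_colonoscopies expected number of colonoscopies
#' @param per_colo_complication_prob admission probability per colonoscopy
#' @return expected number of admissions.
#' @export
complication_risk <- function(n_colonoscopies, per_colo_complication_prob) {
  chk_prob(per_colo_complication_prob, "per_colo_complication_prob")
  n_colonoscopies * per_colo_complication_prob
}

#' Cumulative sensitivity of repeated testing
#'
#' Probability that at least one of `k` independent applications of a test
#' with per-application sensitivity `s1` detects a persistent lesion:
#' `1 - (1 - s1)^k`.
#'
#' @param s1 per-application sensitivity
#' @param k number of applications (>= 1)
#' @return cumulative sensitivity.
#' @export
ten_year_sensitivity <- function(s1, k = 10) {
  chk_prob(s1, "s1")
  if (k < 1) stop("k must be >= 1")
  1 - (1 - s1)^k
}

# colonoscopy detection probability by lesion class
colo_detect <- function(acc, class) {
  switch(class,
         H = 1 - acc$specificity,  # fixed at 0 (specificity 1)
         A = acc$sensitivity_adenoma,
         AA = acc$sensitivity_advanced_adenoma,
         P1 = , P2 = , P3 = , P4 = acc$sensitivity_crc)
}

# --- per-cycle screening kernel --------------------------------------------

# Build the screening operator for one cycle: a redistribution matrix P over
# the state space plus per-state expected-event weights. Applied at the
# start of a cycle, before natural-history transitions. Returns NULL when no
# examination is due at this age.
#
# Counting rule for "positive test results": every positive index stool
# test, and every screening/surveillance colonoscopy with any finding.
# Findings of a confirmatory colonoscopy after a positive stool test are not
# counted again.
screening_kernel <- function(strategy, age, params, states) {
  if (strategy$index_test == "none") return(NULL)
  caps <- track_phase_caps()
  living <- states[states$alive & !states$diagnosed, ]
  reg_due <- is_screening_due(strategy, "regular", age)$due
  surv_due <- vapply(c("colo10y", "surv3y", "surv5y"), function(tr) {
    age <= strategy$surveillance_stop_age
  }, TRUE)
  if (!reg_due && !any(surv_due)) return(NULL)

  n <- nrow(states)
  cnt_names <- c("stool_tests", "colonoscopies", "positive_tests",
                 "polypectomies", paste0("screen_dx_", 1:4))
  P <- diag(n)
  W <- matrix(0, n, length(cnt_names), dimnames = list(states$name, cnt_names))
  any_exam <- FALSE

  colo_acc <- params$tests$colonoscopy
  for (r in seq_len(nrow(living))) {
    cl <- living$class[r]; tr <- living$track[r]; ph <- living$phase[r]
    i <- living$id[r]
    if (tr == "regular") {
      if (!reg_due) next
      test <- strategy$index_test
    } else {
      if (ph < caps[[tr]] || age > strategy$surveillance_stop_age) next
      test <- "colonoscopy"
    }
    any_exam <- TRUE
    stage <- if (startsWith(cl, "P")) as.integer(substring(cl, 2)) else NA
    if (test %in% c("FIT", "gFOBT")) {
      pos <- apply_test(cl, params$tests[[test]])$positive
      det <- pos * colo_detect(colo_acc, cl)
      W[i, "stool_tests"] <- 1
      W[i, "positive_tests"] <- pos
      W[i, "colonoscopies"] <- pos
      P[i, i] <- 1 - det
      if (cl %in% c("A", "AA")) {
        res <- resolve_positive(if (cl == "A") "adenoma" else "advanced",
                                tr, stool_regular = TRUE)
        j <- lu_id(states, "H", res$new_track, 0L)
        P[i, j] <- P[i, j] + det
        W[i, "polypectomies"] <- det
      } else if (!is.na(stage)) {
        j <- dx_id(states, stage, "screen", 1L)
        P[i, j] <- P[i, j] + det
        W[i, paste0("screen_dx_", stage)] <- det
      } else {
        P[i, i] <- 1  # healthy: nothing to find at confirmatory colonoscopy
      }
    } else {
      det <- colo_detect(colo_acc, cl)
      W[i, "colonoscopies"] <- 1
      W[i, "positive_tests"] <- det
      # undetected (or healthy): track update follows the "no finding" rule,
      # phase resets because the examination did take place
      tr_none <- next_track(tr, "none")
      j_none <- lu_id(states, cl, tr_none, 0L)
      P[i, i] <- 0
      P[i, j_none] <- 1 - det
      if (cl %in% c("A", "AA")) {
        res <- resolve_positive(if (cl == "A") "adenoma" else "advanced", tr)
        j <- lu_id(states, "H", res$new_track, 0L)
        P[i, j] <- P[i, j] + det
        W[i, "polypectomies"] <- det
      } else if (!is.na(stage)) {
        j <- dx_id(states, stage, "screen", 1L)
        P[i, j] <- P[i, j] + det
        W[i, paste0("screen_dx_", stage)] <- det
      } else {
        P[i, j_none] <- 1  # healthy, nothing found
      }
    }
  }
  if (!any_exam) return(NULL)
  list(P = P, W = W)
}
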