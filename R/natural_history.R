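#' Age-specific adenoma onset probability
#'
#' Annual probability that a healthy individual develops a (non-advanced)
#' adenoma, modelled log-linearly in age:
#' `onset_base * exp(onset_slope * (age - 50))`, zero before age 20 and
#' capped at `onset_cap`; ages beyond 100 use the age-100 value.
#'
#' @param nh `natural_history` block of a `crc_params` bundle
#' @param age age(s) in years
#' @return vector of annual probabilities.
#' @export
onset_probability <- function(nh, age) {
  a <- pmin(age, 100)
  p <- nh$onset_base * exp(nh$onset_slope * (a - 50))
  p <- pmin(p, nh$onset_cap)
  p[age < 20] <- 0
  p
}

#' Extrapolate a life table beyond age 100
#'
#' Continues annual other-cause death probabilities log-linearly
#' (exponential hazard growth, Gompertz-like), fitted to the oldest
#' observed ages, and enforces monotone non-decreasing rates capped at 1.
#'
#' @param life_table data frame with columns `age`, `qx` covering ages
#'   through 100
#' @param max_age last age to extrapolate to
#' @param fit_ages how many of the oldest observed ages to fit (uses all
#'   available if fewer)
#' @return the extended life table.
#' @export
extrapolate_mortality <- function(life_table, max_age = 110, fit_ages = 6) {
  lt <- life_table[order(life_table$age), ]
  if (nrow(lt) < 2) stop("need at least 2 ages to extrapolate")
  top <- utils::tail(lt, min(fit_ages, nrow(lt)))
  if (any(top$qx <= 0)) stop("cannot fit log-linear extrapolation to zero rates")
  fit <- stats::lm(log(qx) ~ age, data = top)
  slope <- max(0, unname(stats::coef(fit)["age"]))  # rates must not decline with age
  if (slope < 1e-10) slope <- 0  # constant-rate tables continue exactly constant
  a_max <- max(lt$age)
  if (max_age <= a_max) return(lt)
  new_ages <- (a_max + 1):max_age
  q_last <- lt$qx[lt$age == a_max]
  new_qx <- pmin(1, q_last * exp(slope * (new_ages - a_max)))
  new_qx <- cummax(new_qx)
  out <- rbind(lt, data.frame(age = new_ages, qx = new_qx))
  rownames(out) <- NULL
  out
}

#' Annual colorectal-cancer death probability after diagnosis
#'
#' Baseline annual death probabilities are tabulated by UICC stage and year
#' since diagnosis (years 1-5, then a long-term band) for symptom-detected
#' cancers. Screen-detected cancers apply the stage-specific detection-mode
#' hazard ratio on the hazard scale:
#' `p_screen = 1 - (1 - p_symptom)^HR`.
#'
#' @param stage UICC stage 1-4
#' @param mode `"screen"` or `"symptom"`
#' @param year_since_dx years since diagnosis (>= 0; values above 5 use the
#'   long-term band)
#' @param mort `mortality` block of a `crc_params` bundle
#' @return annual death probability.
#' @export
crc_death_prob <- function(stage, mode, year_since_dx, mort) {
  if (!stage %in% 1:4) stop("unknown stage: ", stage)
  mode <- match.arg(mode, c("screen", "symptom"))
  if (year_since_dx < 0) stop("year_since_dx must be >= 0")
  band <- min(max(1, ceiling(year_since_dx)), 6)
  sv <- mort$crc_survival
  p <- sv$annual_death_prob[sv$stage == stage & sv$year == band]
  if (length(p) != 1) stop("survival table lookup failed for stage ", stage, " year ", band)
  if (mode == "screen") p <- 1 - (1 - p)^mort$hazard_ratios[[stage]]
  p
}

# --- per-cycle natural-history kernel --------------------------------------

# Precompute the sparse layout of natural-history transitions for a state
# table: (i, j) index pairs plus a `kind` label from which the probability is
# computed. Conditional on surviving other-cause death; rows sum to 1.
nh_plan <- function(states) {
  key <- attr(states, "track_key")
  if (!is.null(key)) {
    cached <- .crc_cache$plans[[key]]
    if (!is.null(cached)) return(cached)
  }
  caps <- track_phase_caps()
  living <- states[states$alive & !states$diagnosed, ]
  slots <- unique(living[, c("track", "phase")])
  i <- integer(0); j <- integer(0); kind <- character(0); stage <- integer(0)
  add <- function(ii, jj, kk, ss = NA_integer_) {
    i <<- c(i, ii); j <<- c(j, jj); kind <<- c(kind, kk); stage <<- c(stage, ss)
  }
  for (r in seq_len(nrow(slots))) {
    tr <- slots$track[r]; ph <- slots$phase[r]
    ph2 <- min(ph + 1L, caps[[tr]])
    id <- function(cl, p = ph2) lu_id(states, cl, tr, p)
    H <- lu_id(states, "H", tr, ph); A <- lu_id(states, "A", tr, ph)
    AA <- lu_id(states, "AA", tr, ph)
    P <- vapply(1:4, function(s) lu_id(states, paste0("P", s), tr, ph), 1L)
    dxs <- vapply(1:4, function(s) dx_id(states, s, "symptom", 1), 1L)
    add(H, id("H"), "stay_H"); add(H, id("A"), "onset")
    add(A, id("A"), "stay_A"); add(A, id("AA"), "to_AA")
    add(AA, id("AA"), "stay_AA")
    add(AA, id("P1"), "AA_to_P_undet"); add(AA, dxs[1], "AA_to_P_det")
    for (s in 1:3) {
      add(P[s], id(paste0("P", s)), "P_stay_undet", s)
      add(P[s], dxs[s], "P_stay_det", s)
      add(P[s], id(paste0("P", s + 1L)), "P_prog_undet", s)
      add(P[s], dxs[s + 1L], "P_prog_det", s)
    }
    add(P[4], id("P4"), "P4_stay_undet", 4L)
    add(P[4], dxs[4], "P4_det", 4L)
  }
  dxrows <- states[states$diagnosed, ]
  death_crc <- state_id(states, "death_crc")
  for (r in seq_len(nrow(dxrows))) {
    s <- dxrows$stage[r]; m <- dxrows$mode[r]; b <- dxrows$band[r]
    ii <- dxrows$id[r]
    add(ii, death_crc, sprintf("dx_death|%d|%s|%d", s, m, b))
    add(ii, dx_id(states, s, m, min(b + 1L, 6L)), sprintf("dx_stay|%d|%s|%d", s, m, b))
  }
  plan <- list(i = i, j = j, kind = kind, stage = stage,
               death_other = state_id(states, "death_other"),
               death_crc = death_crc,
               living_ids = living$id,
               dx_ids = dxrows$id)
  if (!is.null(key)) .crc_cache$plans[[key]] <- plan
  plan
}

# Probability values for each plan entry; only stay_H/onset depend on age.
nh_values <- function(params, plan, age, mort = params$mortality) {
  nh <- params$natural_history
  pa <- nh$adenoma_to_advanced
  pp <- nh$advanced_to_preclinical
  g <- nh$stage_progression      # I>II, II>III, III>IV
  d <- nh$symptomatic_detection  # stages I-IV
  if (any(c(pa, pp, g, d) < 0) || any(c(pa, pp, g, d) > 1))
    stop("parameter inconsistency: natural-history probabilities outside [0,1]")
  ons <- onset_probability(nh, age)
  k <- plan$kind
  v <- numeric(length(k))
  v[k == "stay_H"] <- 1 - ons
  v[k == "onset"] <- ons
  v[k == "stay_A"] <- 1 - pa
  v[k == "to_AA"] <- pa
  v[k == "stay_AA"] <- 1 - pp
  v[k == "AA_to_P_undet"] <- pp * (1 - d[1])
  v[k == "AA_to_P_det"] <- pp * d[1]
  for (s in 1:3) {
    sel <- plan$stage == s & !is.na(plan$stage)
    v[sel & k == "P_stay_undet"] <- (1 - g[s]) * (1 - d[s])
    v[sel & k == "P_stay_det"] <- (1 - g[s]) * d[s]
    v[sel & k == "P_prog_undet"] <- g[s] * (1 - d[s + 1])
    v[sel & k == "P_prog_det"] <- g[s] * d[s + 1]
  }
  v[k == "P4_stay_undet"] <- 1 - d[4]
  v[k == "P4_det"] <- d[4]
  dxk <- startsWith(k, "dx_")
  if (any(dxk)) {
    parts <- strsplit(k[dxk], "|", fixed = TRUE)
    pd <- vapply(parts, function(z) {
      crc_death_prob(as.integer(z[2]), z[3], as.integer(z[4]), mort)
    }, 1.0)
    stayers <- startsWith(k[dxk], "dx_stay")
    v[dxk] <- ifelse(stayers, 1 - pd, pd)
  }
  v
}

#' Build the per-cycle natural-history transition matrix
#'
#' Assembles the row-stochastic transition matrix at a given age over the
#' supplied state table. Event ordering within a cycle is fixed: other-cause
#' death first (life-table probability applied uniformly to all living
#' states), then natural-history progression (one step at most), then
#' symptomatic detection from the resulting preclinical stage into the
#' matching diagnosed state (mode `symptom`, year-1 band). Adenomas never
#' regress. Diagnosed states face other-cause death first, then the stage-,
#' mode- and year-specific cancer death probability, otherwise advance one
#' year-since-diagnosis band (capped at the long-term band).
#'
#' @param params a `crc_params` bundle (life table must cover the age)
#' @param age cycle age in years, 20-110
#' @param states state table from [make_state_table()]
#' @return row-stochastic matrix with state names on both dimensions.
#' @export
build_transition_matrix <- function(params, age,
                                    states = make_state_table()) {
  if (age < 20 || age > 110) stop("age out of supported range 20-110: ", age)
  plan <- nh_plan(states)
  kernel_matrix(params, age, states, plan)
}

kernel_matrix <- function(params, age, states, plan, qx_lookup = NULL) {
  n <- nrow(states)
  q <- if (is.null(qx_lookup)) {
    lt <- params$mortality$life_table
    qa <- lt$qx[match(floor(age), lt$age)]
    if (is.na(qa)) stop("life table does not cover age ", age)
    qa
  } else qx_lookup[[as.character(floor(age))]]
  v <- nh_values(params, plan, age)
  if (any(v < -1e-12 | v > 1 + 1e-12))
    stop("parameter inconsistency: a transition row would exceed probability 1")
  M <- matrix(0, n, n, dimnames = list(states$name, states$name))
  M[cbind(plan$i, plan$j)] <- (1 - q) * v
  alive_ids <- c(plan$living_ids, plan$dx_ids)
  M[alive_ids, plan$death_other] <- M[alive_ids, plan$death_other] + q
  M[plan$death_other, plan$death_other] <- 1
  M[plan$death_crc, plan$death_crc] <- 1
  M
}

# Fast factory: precompute plan, per-age qx and the age-independent value
# vector; rebuild only onset entries per age.
nh_kernel_factory <- function(params, states) {
  plan <- nh_plan(states)
  lt <- params$mortality$life_table
  qx <- lt$qx[match(20:110, lt$age)]
  if (anyNA(qx)) stop("life table must cover ages 20-110 (extrapolate first)")
  names(qx) <- 20:110
  v50 <- nh_values(params, plan, 50)
  if (any(v50 < -1e-12 | v50 > 1 + 1e-12))
    stop("parameter inconsistency: a transition row would exceed probability 1")
  n <- nrow(states)
  stayH <- plan$kind == "stay_H"; onsK <- plan$kind == "onset"
  nh <- params$natural_history
  ij <- cbind(plan$i, plan$j)
  alive_ids <- c(plan$living_ids, plan$dx_ids)
  function(age) {
    q <- qx[[as.character(age)]]
    v <- v50
    ons <- onset_probability(nh, age)
    v[stayH] <- 1 - ons
    v[onsK] <- ons
    M <- matrix(0, n, n)
    M[ij] <- (1 - q) * v
    M[alive_ids, plan$death_other] <- M[alive_ids, plan$death_other] + q
    M[plan$death_other, plan$death_other] <- 1
    M[plan$death_crc, plan$death_crc] <- 1
    dimnames(M) <- list(states$name, states$name)
    M
  }
}
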