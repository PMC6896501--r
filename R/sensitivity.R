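#' Apply scenario overrides to a parameter bundle
#'
#' Named overrides used by the deterministic sensitivity and scenario
#' analyses:
#' \describe{
#'   \item{stool_sens_multiplier}{multiplies all lesion-class sensitivities
#'     of both stool tests (FIT and gFOBT) jointly}
#'   \item{colonoscopy_sens_multiplier}{multiplies all colonoscopy
#'     sensitivities}
#'   \item{colonoscopy_cost, polypectomy_cost}{replace the unit costs}
#'   \item{colonoscopy_cost_multiplier}{scales colonoscopy and polypectomy
#'     unit costs jointly}
#'   \item{uicc_iv_inpatient_multiplier}{scales the UICC-IV inpatient cost}
#'   \item{survival_unadjusted}{if `TRUE`, cancer survival is independent
#'     of the mode of detection (all hazard ratios set to 1)}
#' }
#' Sensitivities are capped at 1 after scaling.
#'
#' @param params a `crc_params` bundle
#' @param overrides named list; an empty list returns the bundle unchanged
#' @return the modified bundle.
#' @export
apply_overrides <- function(params, overrides = list()) {
  known <- c("stool_sens_multiplier", "colonoscopy_sens_multiplier",
             "colonoscopy_cost", "polypectomy_cost",
             "colonoscopy_cost_multiplier", "uicc_iv_inpatient_multiplier",
             "survival_unadjusted")
  bad <- setdiff(names(overrides), known)
  if (length(bad)) stop("unknown override(s): ", paste(bad, collapse = ", "))
  p <- params
  ov <- function(nm) if (nm %in% names(overrides)) overrides[[nm]] else NULL
  scale_sens <- function(acc, m) {
    for (f in c("sensitivity_adenoma", "sensitivity_advanced_adenoma",
                "sensitivity_crc")) {
      acc[[f]] <- min(1, acc[[f]] * m)
    }
    acc
  }
  if (!is.null(ov("stool_sens_multiplier"))) {
    m <- ov("stool_sens_multiplier")
    p$tests$FIT <- scale_sens(p$tests$FIT, m)
    p$tests$gFOBT <- scale_sens(p$tests$gFOBT, m)
  }
  if (!is.null(ov("colonoscopy_sens_multiplier"))) {
    p$tests$colonoscopy <- scale_sens(p$tests$colonoscopy,
                                      ov("colonoscopy_sens_multiplier"))
  }
  if (!is.null(ov("colonoscopy_cost"))) p$costs$colonoscopy <- ov("colonoscopy_cost")
  if (!is.null(ov("polypectomy_cost"))) p$costs$polypectomy <- ov("polypectomy_cost")
  if (!is.null(ov("colonoscopy_cost_multiplier"))) {
    m <- ov("colonoscopy_cost_multiplier")
    p$costs$colonoscopy <- p$costs$colonoscopy * m
    p$costs$polypectomy <- p$costs$polypectomy * m
  }
  if (!is.null(ov("uicc_iv_inpatient_multiplier"))) {
    p$costs$inpatient_by_stage[4] <- p$costs$inpatient_by_stage[4] *
      ov("uicc_iv_inpatient_multiplier")
  }
  if (isTRUE(ov("survival_unadjusted"))) {
    p$mortality$hazard_ratios[] <- 1
  }
  validate_parameters(p)
  p
}

# ICER of FIT vs COL (the paper's headline comparison); returns the ratio,
# or a dominance label when one strategy is both cheaper and more effective.
fit_vs_col_icer <- function(econ) {
  tab <- econ$table
  fit <- tab[tab$name == "Annual FIT", ]
  col <- tab[tab$name == "10-yearly Colonoscopy", ]
  dc <- fit$disc_cost - col$disc_cost
  de <- fit$disc_lyg - col$disc_lyg
  if (de > 0 && dc <= 0) return(list(icer = NA_real_, label = "FIT dominant"))
  if (de <= 0 && dc >= 0) return(list(icer = NA_real_, label = "COL dominant"))
  list(icer = dc / de, label = "ICER")
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full four-strategy pipeline for each value of one varied
#' quantity and records the FIT-vs-colonoscopy comparison and the frontier
#' dominance classification.
#'
#' @param parameter one of `"discount_rate"`, `"stool_sens_multiplier"`,
#'   `"colonoscopy_sens_multiplier"`, `"colonoscopy_cost_multiplier"`,
#'   `"uicc_iv_inpatient_multiplier"`
#' @param values grid of parameter values
#' @param params a `crc_params` bundle
#' @param strategies strategy list
#' @return data frame with one row per grid point: `value`,
#'   `icer_fit_vs_col`, `comparison` label, `dominated` (comma-separated
#'   dominated strategies).
#' @export
one_way <- function(parameter, values, params,
                    strategies = default_strategies()) {
  parameter <- match.arg(parameter,
                         c("discount_rate", "stool_sens_multiplier",
                           "colonoscopy_sens_multiplier",
                           "colonoscopy_cost_multiplier",
                           "uicc_iv_inpatient_multiplier"))
  rows <- lapply(values, function(val) {
    if (parameter == "discount_rate") {
      econ <- strategy_economics(params, strategies, discount_rate = val)
    } else {
      p <- apply_overrides(params, stats::setNames(list(val), parameter))
      econ <- strategy_economics(p, strategies)
    }
    cmp <- fit_vs_col_icer(econ)
    dom <- econ$frontier$name[econ$frontier$classification != "frontier"]
    data.frame(parameter = parameter, value = val,
               icer_fit_vs_col = if (is.na(cmp$icer)) NA_real_ else cmp$icer,
               comparison = cmp$label,
               dominated = paste(dom, collapse = ","))
  })
  do.call(rbind, rows)
}

#' Two-way deterministic sensitivity analysis
#'
#' Full-factorial evaluation over two parameter grids (same parameter names
#' as [one_way()], plus `"participation"` where the value is a named vector
#' of per-strategy participation rates applied as all-or-none mixtures).
#'
#' @param spec1,spec2 lists with `parameter` and `values`
#' @param params a `crc_params` bundle
#' @param strategies strategy list
#' @return long data frame over the grid with the FIT-vs-COL comparison.
#' @export
two_way <- function(spec1, spec2, params, strategies = default_strategies()) {
  grid <- expand.grid(i = seq_along(spec1$values), j = seq_along(spec2$values))
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    ov <- stats::setNames(list(spec1$values[[grid$i[k]]], spec2$values[[grid$j[k]]]),
                          c(spec1$parameter, spec2$parameter))
    res <- scenario(ov, params, strategies)
    cmp <- fit_vs_col_icer(res$econ)
    data.frame(value1 = unlist(spec1$values[grid$i[k]])[1],
               value2 = unlist(spec2$values[grid$j[k]])[1],
               icer_fit_vs_col = cmp$icer, comparison = cmp$label)
  })
  out <- do.call(rbind, rows)
  names(out)[1:2] <- c(spec1$parameter, spec2$parameter)
  out
}

#' Scenario analysis
#'
#' Runs the four-strategy pipeline under a named set of overrides. In
#' addition to the bundle overrides of [apply_overrides()], accepts
#' `discount_rate` and `participation` (named vector of rates for `FIT`,
#' `gFOBT`, `COL`; non-participants follow no-screening natural history,
#' mixed all-or-none). An empty override set reproduces the base case.
#'
#' @param overrides named list
#' @param params a `crc_params` bundle
#' @param strategies strategy list
#' @return list with `econ` (see [strategy_economics()]) and `overrides`.
#' @export
scenario <- function(overrides = list(), params,
                     strategies = default_strategies()) {
  discount_rate <- overrides$discount_rate %||% 0.03
  participation <- overrides$participation
  overrides$discount_rate <- NULL
  overrides$participation <- NULL
  p <- apply_overrides(params, overrides)
  if (!is.null(participation)) {
    for (nm in names(participation)) {
      if (!nm %in% names(strategies)) stop("unknown strategy in participation: ", nm)
      strategies[[nm]]$participation <- participation[[nm]]
    }
  }
  econ <- strategy_economics(p, strategies, discount_rate = discount_rate,
                             apply_participation = !is.null(participation))
  list(econ = econ, overrides = overrides, discount_rate = discount_rate,
       participation = participation)
}

#' Summary table of the packaged one-way sensitivity analyses
#'
#' Convenience wrapper reproducing the standard set of deterministic
#' analyses: discount rate 0 and 10%, stool-test sensitivity reduction,
#' alternative examination costs, UICC-IV treatment cost increase, and
#' survival unadjusted for detection mode.
#'
#' @param params a `crc_params` bundle
#' @return long data frame (`analysis`, `setting`, `icer_fit_vs_col`,
#'   `comparison`).
#' @export
sensitivity_table <- function(params) {
  run1 <- function(analysis, setting, ov) {
    res <- scenario(ov, params)
    cmp <- fit_vs_col_icer(res$econ)
    data.frame(analysis = analysis, setting = setting,
               icer_fit_vs_col = cmp$icer, comparison = cmp$label)
  }
  rbind(
    run1("base case", "", list()),
    run1("discount rate", "0%", list(discount_rate = 0)),
    run1("discount rate", "10%", list(discount_rate = 0.10)),
    run1("stool-test sensitivity", "-60%", list(stool_sens_multiplier = 0.4)),
    run1("examination costs", "colonoscopy 352 / polypectomy 98",
         list(colonoscopy_cost = 352, polypectomy_cost = 98)),
    run1("examination costs", "+100%", list(colonoscopy_cost_multiplier = 2)),
    run1("UICC IV inpatient costs", "+50%", list(uicc_iv_inpatient_multiplier = 1.5)),
    run1("survival", "unadjusted for mode of detection",
         list(survival_unadjusted = TRUE)),
    run1("participation", "COL 20% / FIT 38.9% / gFOBT 31.1%",
         list(participation = c(COL = 0.20, FIT = 0.389, gFOBT = 0.311))),
    run1("participation", "COL 28% / FIT 38.9% / gFOBT 31.1%",
         list(participation = c(COL = 0.28, FIT = 0.389, gFOBT = 0.311)))
  )
}
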