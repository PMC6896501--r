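#' Cost ledger of a cohort trace
#'
#' Maps per-cycle expected event counts to undiscounted costs by category
#' (index year 2017 EUR): stool tests and colonoscopies (screening,
#' surveillance, confirmatory, and diagnostic colonoscopies of symptomatic
#' patients), polypectomies, complication admissions (inpatient stay plus a
#' surgical-procedure share), program-level fixed costs (annual program cost
#' amortized per eligible person via a documented divisor), staging and
#' stage-specific inpatient care at diagnosis, one-time UICC-IV medication
#' at diagnosis, year-since-diagnosis follow-up (the long-term band charges
#' one 5-yearly examination fee per 5 years), and one-time end-of-life
#' costs at cancer death (tabulated for stages I/II and III).
#'
#' @param trace a `cohort_trace`
#' @param params a `crc_params` bundle (its `costs` block is used)
#' @return matrix (accumulation ages 40-110) x (cost category), EUR per
#'   cohort member, undiscounted.
#' @export
program_costs <- function(trace, params) {
  stopifnot(inherits(trace, "cohort_trace"))
  co <- params$costs
  ev <- trace$events[as.character(40:110), , drop = FALSE]
  strategy <- trace$strategy
  stool_unit <- switch(strategy$index_test, FIT = co$fit_test,
                       gFOBT = co$gfobt_test, 0)
  program_annual <- switch(strategy$index_test,
                           colonoscopy = co$program_cost[["colonoscopy_program"]],
                           FIT = , gFOBT = co$program_cost[["stool_program"]],
                           0)
  admission_unit <- co$complication_inpatient +
    params$complications$surgical_fraction * co$complication_surgical

  new_dx <- sapply(1:4, function(s) {
    ev[, paste0("screen_dx_", s)] + ev[, paste0("sym_dx_", s)]
  })
  ledger <- cbind(
    stool_tests = ev[, "stool_tests"] * stool_unit,
    colonoscopy = (ev[, "colonoscopies"] + ev[, "sym_colonoscopies"]) * co$colonoscopy,
    polypectomy = ev[, "polypectomies"] * co$polypectomy,
    complications = ev[, "complications"] * admission_unit,
    program_fixed = ev[, "in_program"] * program_annual / co$program_divisor,
    staging = rowSums(new_dx) * co$staging,
    inpatient = as.numeric(new_dx %*% co$inpatient_by_stage),
    medication_iv = new_dx[, 4] * co$medication_uicc_iv,
    followup = as.numeric(
      ev[, paste0("followup_band_", 1:5)] %*% co$followup_by_year) +
      ev[, "followup_band_6"] * co$followup_longterm_per_5y / 5,
    end_of_life = (ev[, "crc_deaths_1"] + ev[, "crc_deaths_2"]) *
      co$end_of_life[["I_II"]] +
      ev[, "crc_deaths_3"] * co$end_of_life[["III"]]
  )
  rownames(ledger) <- rownames(ev)
  ledger
}

#' Present value of a yearly stream
#'
#' @param values per-year amounts; the first element is year 0 (the
#'   decision age)
#' @param rate annual discount rate (>= 0)
#' @return sum of `values[t] * (1 + rate)^-t`.
#' @export
discount_stream <- function(values, rate) {
  if (rate < 0) stop("discount rate must be >= 0")
  t <- seq_along(values) - 1
  sum(values * (1 + rate)^-t)
}

#' Cost-effectiveness frontier with (extended) dominance
#'
#' Orders strategies by discounted effect, removes strongly dominated
#' strategies (less effect at equal-or-higher cost), iteratively removes
#' extended-dominated strategies (those whose incremental ICER exceeds that
#' of the next more effective frontier member), and reports pairwise ICERs
#' between adjacent frontier members.
#'
#' @param strategies data frame with columns `name`, `cost`, `effect`
#'   (discounted values)
#' @return a `frontier_result` data frame: inputs plus `classification`
#'   (`frontier`, `dominated`, `extended-dominated`), `dominator`,
#'   `incr_cost`, `incr_effect`, `icer` (NA for the least effective
#'   frontier member and non-frontier rows), and a `tie` flag for pairs
#'   identical in both cost and effect.
#' @export
icer_frontier <- function(strategies) {
  df <- as.data.frame(strategies)
  stopifnot(all(c("name", "cost", "effect") %in% names(df)), nrow(df) >= 2)
  n <- nrow(df)
  df$classification <- "frontier"
  df$dominator <- NA_character_
  df$tie <- FALSE
  # exact ties in both dimensions: kept, flagged, mutually undefined ICER
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && df$cost[i] == df$cost[j] && df$effect[i] == df$effect[j]) {
      df$tie[i] <- TRUE
    }
  }
  # strong dominance
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$effect[j] >= df$effect[i] && df$cost[j] <= df$cost[i] &&
          (df$effect[j] > df$effect[i] || df$cost[j] < df$cost[i])) {
        df$classification[i] <- "dominated"
        df$dominator[i] <- df$name[j]
        break
      }
    }
  }
  # extended dominance on the remaining set, sorted by effect
  repeat {
    keep <- which(df$classification == "frontier")
    ord <- keep[order(df$effect[keep], df$cost[keep])]
    if (length(ord) < 3) break
    icers <- diff(df$cost[ord]) / diff(df$effect[ord])
    bad <- which(diff(icers) < 0)
    if (length(bad) == 0) break
    drop <- ord[bad[1] + 1]
    df$classification[drop] <- "extended-dominated"
    df$dominator[drop] <- paste(df$name[ord[bad[1]]], "+", df$name[ord[bad[1] + 2]])
  }
  df$incr_cost <- NA_real_
  df$incr_effect <- NA_real_
  df$icer <- NA_real_
  keep <- which(df$classification == "frontier")
  ord <- keep[order(df$effect[keep], df$cost[keep])]
  if (length(ord) >= 2) {
    for (k in 2:length(ord)) {
      i <- ord[k]; j <- ord[k - 1]
      df$incr_cost[i] <- df$cost[i] - df$cost[j]
      df$incr_effect[i] <- df$effect[i] - df$effect[j]
      df$icer[i] <- df$incr_cost[i] / df$incr_effect[i]
    }
  }
  class(df) <- c("frontier_result", "data.frame")
  df
}

#' @export
print.frontier_result <- function(x, ...) {
  cat("<frontier_result>\n")
  y <- as.data.frame(x)
  y$cost <- round(y$cost)
  y$effect <- round(y$effect, 3)
  y$icer <- round(y$icer)
  print(y[order(y$effect), c("name", "cost", "effect", "classification", "icer")],
        row.names = FALSE)
  invisible(x)
}

#' Economics table across strategies
#'
#' Runs every strategy, summarizes outcomes at the given discount rate and
#' assembles the health-economic comparison (life-years gained vs no
#' screening, discounted and undiscounted costs) plus the ICER frontier.
#'
#' @param params a `crc_params` bundle
#' @param strategies named list of `crc_strategy` objects; must include a
#'   no-screening strategy named `no_screening`
#' @param discount_rate annual discount rate
#' @param apply_participation if `TRUE`, strategies with participation < 1
#'   are participation-weighted mixtures with the no-screening cohort
#' @return list with `summaries`, `table` (per-strategy economics) and
#'   `frontier`.
#' @export
strategy_economics <- function(params, strategies = default_strategies(),
                               discount_rate = 0.03,
                               apply_participation = FALSE) {
  stopifnot("no_screening" %in% names(strategies))
  summaries <- lapply(strategies, function(s) {
    summarize_cohort(run_cohort(s, params), params, discount_rate)
  })
  if (apply_participation) {
    base <- summaries$no_screening
    summaries <- lapply(names(summaries), function(nm) {
      s <- strategies[[nm]]
      if (s$index_test == "none" || s$participation >= 1) return(summaries[[nm]])
      mix_summaries(summaries[[nm]], base, s$participation)
    })
    names(summaries) <- names(strategies)
  }
  base <- summaries$no_screening
  tab <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    data.frame(name = s$strategy,
               lyg = s$life_years - base$life_years,
               disc_lyg = s$disc_life_years - base$disc_life_years,
               cost = s$cost, disc_cost = s$disc_cost)
  }))
  frontier <- icer_frontier(data.frame(name = tab$name, cost = tab$disc_cost,
                                       effect = tab$disc_lyg))
  list(summaries = summaries, table = tab, frontier = frontier)
}

#' Cost-effectiveness plane plot
#'
#' Discounted cost vs discounted life-years gained, dominated strategies
#' marked; the frontier is drawn through the non-dominated strategies.
#'
#' @param frontier a `frontier_result`
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_frontier <- function(frontier) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_frontier requires the ggplot2 package")
  }
  df <- as.data.frame(frontier)
  on_front <- df[df$classification == "frontier", ]
  on_front <- on_front[order(on_front$effect), ]
  ggplot2::ggplot(df, ggplot2::aes(x = effect, y = cost)) +
    ggplot2::geom_line(data = on_front, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = classification), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = name), vjust = -1, size = 3) +
    ggplot2::labs(x = "Discounted life-years gained",
                  y = "Discounted lifetime cost (EUR)",
                  shape = NULL) +
    ggplot2::theme_minimal()
}
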