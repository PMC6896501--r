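#' Incremental harm-benefit ratio
#'
#' Ratio of the incremental harm (e.g. additional positive test results) to
#' the incremental benefit (e.g. additional life-years gained) when moving
#' from a less to a more beneficial strategy. Computed on undiscounted
#' outcomes; invariant to a common per-person vs per-1000 scaling.
#'
#' @param a outcome of the less beneficial strategy (an `outcome_summary`,
#'   or a named list/vector holding the two fields)
#' @param b outcome of the more beneficial strategy
#' @param harm name of the harm field (default `"positive_tests"`)
#' @param benefit name of the benefit field (default `"life_years"`).
#'   For averted-event benefits (`crc_deaths`, `crc_cases`) the benefit is
#'   the reduction, i.e. `a - b`.
#' @return the ratio `(harm_b - harm_a) / incremental_benefit`; zero when
#'   the incremental harm is zero.
#' @export
ihbr <- function(a, b, harm = "positive_tests", benefit = "life_years") {
  dh <- b[[harm]] - a[[harm]]
  db <- if (benefit %in% c("crc_deaths", "crc_cases")) {
    a[[benefit]] - b[[benefit]]  # fewer events = benefit
  } else {
    b[[benefit]] - a[[benefit]]
  }
  if (db <= 0) {
    stop("incremental benefit must be positive (dominance situation: ratio undefined)")
  }
  if (dh == 0) return(0)
  dh / db
}

#' Benefit-harm fact box
#'
#' Side-by-side comparison of two screening strategies against a common
#' no-screening baseline: life-years gained, CRC deaths and cases averted,
#' additional colonoscopy complications and total positive test results,
#' with an exact difference column (`b - a`). The population box is per
#' 1000 40-year-olds; the individual box is per person with the gain in
#' life expectancy expressed in weeks (365.25/7 weeks per year) and
#' lifetime CRC risks as probabilities in percent.
#'
#' @param baseline no-screening `outcome_summary`
#' @param a,b `outcome_summary` objects for the two compared strategies
#'   (conventionally colonoscopy and FIT)
#' @param scale `"per1000"` or `"individual"`
#' @return a `fact_box` data frame (unrounded values; the print method
#'   applies display rounding).
#' @export
render_fact_box <- function(baseline, a, b, scale = c("per1000", "individual")) {
  scale <- match.arg(scale)
  for (s in list(baseline, a, b)) stopifnot(inherits(s, "outcome_summary"))
  if (length(unique(c(baseline$discount_rate, a$discount_rate, b$discount_rate))) != 1) {
    stop("summaries come from mismatched analyses")
  }
  row <- function(outcome, va, vb, digits) {
    data.frame(outcome = outcome, a = va, b = vb, difference = vb - va,
               digits = digits, stringsAsFactors = FALSE)
  }
  if (scale == "per1000") {
    f <- 1000
    box <- rbind(
      row("Life-years gained", f * (a$life_years - baseline$life_years),
          f * (b$life_years - baseline$life_years), 0),
      row("CRC-related deaths averted", f * (baseline$crc_deaths - a$crc_deaths),
          f * (baseline$crc_deaths - b$crc_deaths), 0),
      row("CRC cases averted", f * (baseline$crc_cases - a$crc_cases),
          f * (baseline$crc_cases - b$crc_cases), 0),
      row("Additional complications due to colonoscopy (hospital admissions)",
          f * (a$complications - baseline$complications),
          f * (b$complications - baseline$complications), 1),
      row("Total positive test results", f * a$positive_tests,
          f * b$positive_tests, 0)
    )
  } else {
    wk <- 365.25 / 7
    box <- rbind(
      row("Life-weeks gained", wk * (a$life_years - baseline$life_years),
          wk * (b$life_years - baseline$life_years), 0),
      row("Probability of dying from CRC (%)", 100 * a$crc_deaths,
          100 * b$crc_deaths, 1),
      row("Probability of developing CRC (%)", 100 * a$crc_cases,
          100 * b$crc_cases, 1),
      row("Mean number of complications due to colonoscopy (hospital admissions)",
          a$complications, b$complications, 4),
      row("Mean number of positive test results", a$positive_tests,
          b$positive_tests, 1)
    )
  }
  names(box)[2:3] <- make.names(c(a$strategy, b$strategy))
  attr(box, "strategies") <- c(a$strategy, b$strategy)
  attr(box, "scale") <- scale
  class(box) <- c("fact_box", "data.frame")
  box
}

#' @export
print.fact_box <- function(x, ...) {
  cat(sprintf("<fact_box> %s vs %s (%s)\n", attr(x, "strategies")[1],
              attr(x, "strategies")[2],
              if (attr(x, "scale") == "per1000") "per 1000 persons" else "per person"))
  y <- as.data.frame(x)
  for (i in seq_len(nrow(y))) {
    y[i, 2:4] <- round(as.numeric(y[i, 2:4]), y$digits[i])
  }
  y$digits <- NULL
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a fact box to CSV or Markdown
#'
#' @param box a `fact_box`
#' @param path output file
#' @param format `"csv"` or `"markdown"`
#' @return `path`, invisibly.
#' @export
write_fact_box <- function(box, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  y <- as.data.frame(box)
  for (i in seq_len(nrow(y))) y[i, 2:4] <- round(as.numeric(y[i, 2:4]), y$digits[i])
  y$digits <- NULL
  if (format == "csv") {
    utils::write.csv(y, path, row.names = FALSE)
  } else {
    hdr <- c("Outcome", attr(box, "strategies"), "Difference")
    lines <- c(paste("|", paste(hdr, collapse = " | "), "|"),
               paste("|", paste(rep("---", 4), collapse = " | "), "|"),
               vapply(seq_len(nrow(y)), function(i) {
                 paste("|", paste(c(y$outcome[i], y[i, 2], y[i, 3], y[i, 4]),
                                  collapse = " | "), "|")
               }, ""))
    writeLines(lines, path)
  }
  invisible(path)
}
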