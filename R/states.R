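#' Health-state space of the screening model
#'
#' The model distinguishes living, undiagnosed states along the
#' adenoma-carcinoma sequence (healthy, non-advanced adenoma, advanced
#' adenoma, preclinical cancer UICC I-IV), diagnosed cancer states stratified
#' by UICC stage, mode of detection (screen vs symptom) and years since
#' diagnosis (annual bands 1-5 plus a long-term band), and two absorbing
#' death states (colorectal-cancer death, death from other causes).
#'
#' Living undiagnosed states additionally carry a surveillance track with a
#' phase counter (years since the last examination on that track):
#' \describe{
#'   \item{regular}{the strategy's own schedule (calendar-age driven, phase 0)}
#'   \item{colo10y}{10-yearly colonoscopy after removal of a non-advanced
#'     adenoma found under a stool-test strategy}
#'   \item{surv3y}{3-yearly surveillance colonoscopy after removal of an
#'     advanced adenoma}
#'   \item{surv5y}{5-yearly surveillance colonoscopy after a 3-yearly exam
#'     that found no advanced adenoma}
#' }
#'
#' @param tracks character vector of surveillance tracks to include. The
#'   full set is used for screening strategies; `"regular"` alone gives the
#'   reduced state space sufficient for natural-history (no-screening) runs,
#'   which calibration uses for speed.
#' @return A data frame with one row per state: `name`, `class` (one of
#'   `H`, `A`, `AA`, `P1`..`P4`, `DX`, `death_crc`, `death_other`), `track`,
#'   `phase`, `stage`, `mode`, `band`, and logical `alive`, `diagnosed`.
#' @export
make_state_table <- function(tracks = c("regular", "colo10y", "surv3y", "surv5y")) {
  tracks <- match.arg(tracks, several.ok = TRUE)
  key <- paste(tracks, collapse = "+")
  cached <- .crc_cache$states[[key]]
  if (!is.null(cached)) return(cached)
  caps <- track_phase_caps()
  classes <- c("H", "A", "AA", "P1", "P2", "P3", "P4")
  rows <- list()
  for (tr in tracks) {
    for (ph in 0:caps[[tr]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("%s|%s|%d", classes, tr, ph),
        class = classes, track = tr, phase = ph,
        stage = NA_integer_, mode = NA_character_, band = NA_integer_,
        alive = TRUE, diagnosed = FALSE, stringsAsFactors = FALSE)
    }
  }
  for (s in 1:4) for (m in c("screen", "symptom")) for (b in 1:6) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("DX%d|%s|b%d", s, m, b),
      class = "DX", track = NA_character_, phase = NA_integer_,
      stage = s, mode = m, band = b,
      alive = TRUE, diagnosed = TRUE, stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    name = c("death_crc", "death_other"),
    class = c("death_crc", "death_other"),
    track = NA_character_, phase = NA_integer_,
    stage = NA_integer_, mode = NA_character_, band = NA_integer_,
    alive = FALSE, diagnosed = FALSE, stringsAsFactors = FALSE)
  st <- do.call(rbind, rows)
  rownames(st) <- NULL
  st$id <- seq_len(nrow(st))
  class(st) <- c("crc_states", "data.frame")
  attr(st, "track_key") <- key
  .crc_cache$states[[key]] <- st
  st
}

# deterministic lookup structures are memoised per state-table layout
.crc_cache <- new.env(parent = emptyenv())
.crc_cache$states <- list()
.crc_cache$plans <- list()

# surveillance-exam intervals, in years; phase counts years since last exam
track_phase_caps <- function() {
  list(regular = 0L, colo10y = 10L, surv3y = 3L, surv5y = 5L)
}

state_id <- function(states, name) {
  i <- match(name, states$name)
  if (anyNA(i)) stop("unknown state name(s): ", paste(name[is.na(i)], collapse = ", "))
  i
}

# id of a living undiagnosed state
lu_id <- function(states, class, track, phase) {
  state_id(states, sprintf("%s|%s|%d", class, track, phase))
}

dx_id <- function(states, stage, mode, band) {
  state_id(states, sprintf("DX%d|%s|b%d", stage, mode, band))
}

#' @export
print.crc_states <- function(x, ...) {
  cat(sprintf("<crc_states> %d health states (%d living undiagnosed, %d diagnosed, 2 absorbing)\n",
              nrow(x), sum(x$alive & !x$diagnosed), sum(x$diagnosed)))
  cat("tracks:", paste(unique(stats::na.omit(x$track)), collapse = ", "), "\n")
  invisible(x)
}
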