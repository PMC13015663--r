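#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a global seed
#'
#' All stochastic stages of the pipeline draw their seed from one global seed
#' through fixed offsets, so a single integer reproduces an entire run.
#'
#' @param seed integer global seed.
#' @param offset integer stage offset.
#' @return an integer seed in \[0, 2^31).
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + 97 * as.numeric(offset)) %% 2147483647)
}

## grid constants: CGM sampling interval and minutes per day
GRID_MIN <- 5L
DAY_MIN <- 1440L

HORIZONS <- c(60L, 90L, 120L, 150L, 180L, 210L)

#' Snap a time in minutes to the 5-minute CGM grid
#'
#' Ties (2.5 min) round down, so the mapping is deterministic.
#'
#' @param t numeric vector of times in minutes.
#' @return integer times on the 5-minute grid.
#' @export
snap_to_grid <- function(t) {
  as.integer(GRID_MIN * floor(t / GRID_MIN + 0.5))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## fixed calendar origin used when serializing integer minutes as timestamps
TIME_ORIGIN <- "2026-01-05 00:00:00"

minutes_to_timestamp <- function(t) {
  format(as.POSIXct(TIME_ORIGIN, tz = "UTC") + 60 * t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

timestamp_to_minutes <- function(ts) {
  origin <- as.POSIXct(TIME_ORIGIN, tz = "UTC")
  as.integer(round(as.numeric(difftime(
    as.POSIXct(ts, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"), origin, units = "mins"))))
}

#' Format a p-value the way mediation tables print it
#'
#' @param p numeric p-values.
#' @param digits rounding for values at or above 0.001.
#' @return character vector, with values below 0.001 rendered `"<0.001"`.
#' @export
format_p <- function(p, digits = 3) {
  ifelse(p < 0.001, "<0.001", formatC(round(p, digits), format = "g"))
}
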