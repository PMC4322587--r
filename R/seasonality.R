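# Breeding/birth peak detection from monthly litter-event counts on the
# 12-month circle. Peaks use ranks and thresholds only: the month with the
# most events, extended to sequential neighbours holding at least a third as
# many events as the peak month or at least 20% of all events.

#' Monthly event histogram
#'
#' Tabulates litter events (not individuals) into a 12-bin month histogram.
#'
#' @param months Integer vector of event months (1-12).
#' @return Integer vector of length 12, named `"1"`..`"12"`.
#' @export
month_histogram <- function(months) {
  stopifnot(all(months %in% 1:12))
  counts <- tabulate(months, nbins = 12)
  names(counts) <- as.character(1:12)
  counts
}

circ_idx <- function(i) ((i - 1) %% 12) + 1

#' Peak event month
#'
#' The month holding the most events. Ties are broken by the month whose two
#' circular neighbours hold the most events, then by the smallest month
#' number.
#'
#' @param counts 12-vector of nonnegative event counts (month 1-12).
#' @return Integer month 1-12.
#' @export
peak_month <- function(counts) {
  stopifnot(length(counts) == 12, all(counts >= 0))
  if (sum(counts) == 0) stop("peak_month undefined for an all-zero histogram")
  cand <- which(counts == max(counts))
  if (length(cand) > 1) {
    nb <- vapply(cand, function(i) {
      counts[circ_idx(i - 1)] + counts[circ_idx(i + 1)]
    }, numeric(1))
    cand <- cand[nb == max(nb)]
  }
  as.integer(min(cand))
}

#' Peak event season
#'
#' Starting at the peak month, expands one month at a time in each circular
#' direction. A month is included iff its count is at least a third of the
#' peak month's count or at least 20% of all events; expansion in a direction
#' stops at the first failing month. The thresholds deliberately trim sparse
#' tails so that a single early or late event cannot stretch the season.
#'
#' @param counts 12-vector of nonnegative event counts.
#' @return Ascending integer vector of months in the season (contiguous on
#'   the 12-month circle, always containing the peak month).
#' @export
peak_season <- function(counts) {
  p <- peak_month(counts)
  total <- sum(counts)
  peak_n <- counts[p]
  ok <- function(m) counts[m] >= peak_n / 3 || counts[m] >= 0.20 * total
  season <- p
  for (step in c(-1L, 1L)) {
    m <- p
    for (k in seq_len(11)) {
      m <- circ_idx(m + step)
      if (m %in% season || !ok(m)) break
      season <- c(season, m)
    }
  }
  sort(as.integer(season))
}

#' Format a peak season for the life-history table
#'
#' Dot-joined ascending month numbers; non-seasonal taxa print `"0"`.
#'
#' @param months Integer months from [peak_season()].
#' @param pattern Breeding pattern, `"S"` or `"NS"`.
#' @return Character scalar, e.g. `"4.5.6"` or `"0"`.
#' @export
format_season <- function(months, pattern = c("S", "NS")) {
  pattern <- match.arg(pattern)
  if (pattern == "NS") return("0")
  paste(sort(as.integer(months)), collapse = ".")
}
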