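# Run-theory drought events: maximal runs of consecutive months at or below
# an SPEI threshold, kept when they last at least `min_duration` months.
# Per event: duration DD (months), severity DS (sum of SPEI, negative) and
# intensity DI = DS / DD. Period aggregates: MDN (events per year) and the
# arithmetic means MDD / MDS / MDI.

#' Identify drought events in one SPEI series
#'
#' Scans a single time-ordered SPEI series for maximal runs of consecutive
#' months with `spei <= threshold`. Runs shorter than `min_duration` are
#' discarded; missing values terminate runs (continuity cannot be
#' certified across a gap). The end index is exclusive, so
#' `DD = end - start` equals the month count.
#'
#' @param spei Numeric SPEI series in time order (may contain `NA`).
#' @param threshold Drought threshold (must be negative); a month is in
#'   drought when `spei <= threshold`, so the threshold value itself counts
#'   as drought (the classification bands are half-open on the dry side).
#' @param min_duration Minimum run length in months (default 3).
#' @return Tibble with one row per event: `start` and `end` (month indices
#'   into `spei`, end exclusive), `DD`, `DS`, `DI`.
#' @examples
#' identify_events(c(-0.6, -0.7, -0.8, 0.1), threshold = -0.5)
#' @export
identify_events <- function(spei, threshold = -0.5, min_duration = 3L) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold >= 0) {
    abort_invalid("`threshold` must be a single negative value.")
  }
  min_duration <- stop_if_not_scalar_count(min_duration, "min_duration")
  dry <- !is.na(spei) & spei <= threshold
  r <- rle(dry)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  if (!any(keep)) {
    return(tibble(start = integer(), end = integer(),
                  DD = integer(), DS = double(), DI = double()))
  }
  s <- starts[keep]; e <- ends[keep]
  DS <- purrr::map2_dbl(s, e, ~ sum(spei[.x:.y]))
  DD <- e - s + 1L
  tibble(start = s, end = e + 1L, DD = DD, DS = DS, DI = DS / DD)
}

#' Identify drought events across a gridded SPEI table
#'
#' Applies [identify_events()] per `cell_id` x `scale` (and any scenario or
#' model columns present) for one or more thresholds. Series are ordered by
#' `(year, month)`; a non-contiguous series is an error.
#'
#' @param spei Tibble with `cell_id`, `scale`, `year`, `month`, `spei`.
#' @param thresholds Negative thresholds (default the light and mid drought
#'   thresholds `c(-0.5, -1)`).
#' @param min_duration Minimum run length in months.
#' @return Tibble of events with grouping keys plus `threshold`,
#'   `start_year`, `start_month`, `DD`, `DS`, `DI`.
#' @export
drought_events <- function(spei, thresholds = c(-0.5, -1), min_duration = 3L) {
  require_columns(spei, c("cell_id", "scale", "year", "month", "spei"), "spei")
  group_cols <- intersect(c("cell_id", "scale", "scenario", "model_tag"), names(spei))
  spei %>%
    group_by(across(all_of(group_cols))) %>%
    group_split() %>%
    purrr::map(function(ss) {
      ss <- arrange(ss, .data$year, .data$month)
      midx <- 12L * ss$year + ss$month
      if (any(diff(midx) != 1L)) {
        abort_invalid("SPEI series must be contiguous in (year, month) within each cell.")
      }
      purrr::map(thresholds, function(th) {
        ev <- identify_events(ss$spei, th, min_duration)
        if (nrow(ev) == 0L) return(NULL)
        tibble(!!!ss[1, group_cols], threshold = th,
               start_year = ss$year[ev$start], start_month = ss$month[ev$start],
               DD = ev$DD, DS = ev$DS, DI = ev$DI)
      }) %>% bind_rows()
    }) %>%
    bind_rows()
}

#' Aggregate drought events into per-period characteristics
#'
#' Assigns each event to the period containing its start month (events are
#' never cut at period boundaries) and computes, per grouping key and period:
#' the mean annual number of events `MDN = n / y`, and the arithmetic means
#' `MDD`, `MDS`, `MDI` of per-event duration, severity and intensity.
#' Cells with no events in a period receive 0 for all four characteristics
#' (the "no drought" end of both sign conventions), flagged via `n = 0`.
#'
#' @param events Event tibble from [drought_events()].
#' @param periods Tibble with `period`, `start_year`, `end_year` (inclusive,
#'   non-empty, e.g. from [study_periods()]).
#' @param cells Vector of all cell ids that must appear in the output (zero
#'   -event cells are filled); defaults to the cells present in `events`.
#' @return Tibble keyed by grouping columns, `threshold`, `period`, with
#'   `n`, `years`, `MDN`, `MDD`, `MDS`, `MDI`.
#' @export
summarize_period <- function(events, periods, cells = NULL) {
  require_columns(periods, c("period", "start_year", "end_year"), "periods")
  if (any(periods$end_year < periods$start_year)) {
    abort_invalid("each period must satisfy start_year <= end_year.")
  }
  require_columns(events, c("cell_id", "threshold", "start_year", "DD", "DS", "DI"),
                  "events")
  if (is.null(cells)) cells <- unique(events$cell_id)
  periods <- mutate(periods, years = .data$end_year - .data$start_year + 1L)
  key_cols <- intersect(c("scale", "scenario", "model_tag", "threshold"), names(events))

  assigned <- purrr::map(seq_len(nrow(periods)), function(i) {
    p <- periods[i, ]
    events %>%
      filter(.data$start_year >= p$start_year, .data$start_year <= p$end_year) %>%
      mutate(period = p$period, years = p$years)
  }) %>% bind_rows()

  agg <- assigned %>%
    group_by(across(all_of(c("cell_id", key_cols, "period", "years")))) %>%
    summarise(n = dplyr::n(), MDD = mean(.data$DD), MDS = mean(.data$DS),
              MDI = mean(.data$DI), .groups = "drop") %>%
    mutate(MDN = .data$n / .data$years)

  # complete the cell x key x period universe with zero fills
  keys <- distinct(events[, key_cols, drop = FALSE])
  frame <- tidyr::expand_grid(cell_id = cells, keys,
                              periods[, c("period", "years")])
  frame %>%
    left_join(agg, by = c("cell_id", key_cols, "period", "years")) %>%
    mutate(n = tidyr::replace_na(.data$n, 0L),
           MDN = tidyr::replace_na(.data$MDN, 0),
           MDD = tidyr::replace_na(.data$MDD, 0),
           MDS = tidyr::replace_na(.data$MDS, 0),
           MDI = tidyr::replace_na(.data$MDI, 0)) %>%
    select(all_of(c("cell_id", key_cols, "period", "years", "n",
                    "MDN", "MDD", "MDS", "MDI")))
}

#' Study period definitions
#'
#' The period layout used throughout the package: a 20-year historical
#' calibration window, a 2-year holdout test window, and near-, medium- and
#' long-term future windows.
#'
#' @return Tibble with `period`, `start_year`, `end_year`.
#' @export
study_periods <- function() {
  tibble(period = c("historical", "test", "near", "medium", "long"),
         start_year = c(2000L, 2020L, 2022L, 2041L, 2080L),
         end_year = c(2019L, 2021L, 2040L, 2060L, 2099L))
}
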