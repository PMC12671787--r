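# Observed fire-occurrence probability from point records, and probability
# -forecast verification: ROC/AUC via the Mann-Whitney statistic, the Brier
# score, and a bundled holdout evaluation report.

#' Estimate observed fire-occurrence probability per grid cell
#'
#' Bins point fire records to cells (half-open cells
#' `[west, east) x [south, north)` so the plane is partitioned without double
#' counting) and computes, per cell, the fraction of years in `years` with
#' at least one fire. Records outside the grid extent or outside `years` are
#' dropped, with a message counting them; records with missing coordinates
#' are likewise dropped at load.
#'
#' @param records Tibble with `lon`, `lat`, `year`.
#' @param grid Grid tibble from [gen_grid()] (or with the same columns).
#' @param years Integer vector of years defining the period.
#' @param cell_size Cell edge length in degrees.
#' @return Tibble `cell_id`, `n_years`, `n_fire_years`, `fp`.
#' @export
estimate_fp <- function(records, grid, years, cell_size = 0.5) {
  require_columns(records, c("lon", "lat", "year"), "records")
  if (length(years) == 0L) abort_invalid("`years` must be non-empty.")
  no_coord <- is.na(records$lon) | is.na(records$lat)
  if (any(no_coord)) {
    message(sum(no_coord), " record(s) without coordinates dropped.")
    records <- records[!no_coord, ]
  }
  west <- min(grid$lon) - cell_size / 2
  south <- min(grid$lat) - cell_size / 2
  n_lon <- length(unique(grid$col))
  n_lat <- length(unique(grid$row))
  col <- floor((records$lon - west) / cell_size) + 1L
  row <- floor((records$lat - south) / cell_size) + 1L
  inside <- col >= 1L & col <= n_lon & row >= 1L & row <= n_lat &
    records$year %in% years
  if (any(!inside)) {
    message(sum(!inside), " record(s) outside the grid extent or period dropped.")
  }
  hits <- tibble(col = col[inside], row = row[inside],
                 year = records$year[inside]) %>%
    inner_join(grid[, c("cell_id", "col", "row")], by = c("col", "row")) %>%
    distinct(.data$cell_id, .data$year) %>%
    count(.data$cell_id, name = "n_fire_years")
  grid %>%
    select("cell_id") %>%
    left_join(hits, by = "cell_id") %>%
    mutate(n_fire_years = tidyr::replace_na(.data$n_fire_years, 0L),
           n_years = length(years),
           fp = .data$n_fire_years / .data$n_years) %>%
    select("cell_id", "n_years", "n_fire_years", "fp")
}

#' ROC area under the curve via the Mann-Whitney statistic
#'
#' Computes AUC with midrank tie handling,
#' `AUC = (R1 - n1 (n1 + 1) / 2) / (n1 n0)`, identical to pair counting with
#' half-credit for ties, plus a two-sided p-value from the tie-corrected
#' normal approximation of the Mann-Whitney U statistic.
#'
#' @param labels Binary outcomes (0/1 or logical), both classes present.
#' @param scores Numeric scores or probabilities, higher = more positive.
#' @return Tibble `auc`, `p_value`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    abort_invalid("`labels` and `scores` must have the same length.")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) abort_invalid("`labels` must be binary.")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort_invalid("both classes must be present to compute AUC.")
  }
  r <- rank(scores)  # midranks
  U <- sum(r[labels == 1L]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n0)
  n <- n1 + n0
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n0 / 12 * ((n + 1) - tie_term)
  p <- if (sigma2 <= 0) 1 else 2 * pnorm(-abs(U - n1 * n0 / 2) / sqrt(sigma2))
  tibble(auc = auc, p_value = p, n_pos = n1, n_neg = n0)
}

#' Brier score
#'
#' Mean squared difference between forecast probabilities and binary
#' outcomes; 0 for a perfect forecast, 0.25 for a constant 1/2 forecast.
#'
#' @param probabilities Forecast probabilities in `[0, 1]`.
#' @param outcomes Binary outcomes (0/1 or logical).
#' @return The Brier score.
#' @export
brier_score <- function(probabilities, outcomes) {
  if (length(probabilities) != length(outcomes)) {
    abort_invalid("`probabilities` and `outcomes` must have the same length.")
  }
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE)) {
    abort_invalid("`probabilities` must lie in [0, 1].")
  }
  mean((probabilities - as.numeric(outcomes))^2)
}

#' Evaluate a fitted model on a held-out period
#'
#' Scores a model trained on the historical fire-year fractions against
#' a disjoint test window: the test label of a cell is 1 if any fire fell in
#' it during the test years (a short window makes fractional probabilities
#' nearly binary), the score is the model's predicted occurrence
#' probability. Reports AUC with its Mann-Whitney p-value, the Brier score,
#' and the training AICc. Degenerate (single-class) test labels yield a
#' partial report with AUC omitted and the reason recorded.
#'
#' @param model A fitted `glr` or `gwlr` object.
#' @param newdata Per-cell covariate tibble to predict from (training
#'   normalization applied), including coordinates for `gwlr`.
#' @param records Fire-record tibble (`lon`, `lat`, `year`).
#' @param grid Grid tibble.
#' @param test_years Years of the held-out window (disjoint from training).
#' @param cell_size Cell edge length in degrees.
#' @return One-row tibble `auc`, `p_value`, `brier`, `aicc_train`, `note`.
#' @export
evaluate_holdout <- function(model, newdata, records, grid, test_years,
                             cell_size = 0.5) {
  scores <- stats::predict(model, newdata)
  test_fp <- estimate_fp(records, grid, test_years, cell_size)
  labels <- as.integer(test_fp$n_fire_years > 0L)
  brier <- brier_score(scores, labels)
  if (length(unique(labels)) < 2L) {
    return(tibble(auc = NA_real_, p_value = NA_real_, brier = brier,
                  aicc_train = model$aicc,
                  note = "test labels single-class; AUC undefined"))
  }
  roc <- roc_auc(labels, scores)
  tibble(auc = roc$auc, p_value = roc$p_value, brier = brier,
         aicc_train = model$aicc, note = NA_character_)
}
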