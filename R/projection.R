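# Scenario projection: ensemble-average climate across model members, push
# future drought characteristics through the stored PCA and normalization
# into the fitted model, and summarize forest-masked regional probability
# changes against the historical period.

#' Multi-model ensemble mean of gridded climate
#'
#' Per-cell-per-month arithmetic mean of temperature and precipitation
#' across climate-model members (identified by `model_tag`). Members must
#' cover identical cells and months.
#'
#' @param climate Long climate tibble with `cell_id`, `year`, `month`,
#'   `tas`, `pr`, `model_tag` (and optionally `scenario`, `lon`, `lat`).
#' @return Climate tibble with `model_tag = "MME"`.
#' @export
ensemble_mean <- function(climate) {
  require_columns(climate, c("cell_id", "year", "month", "tas", "pr", "model_tag"),
                  "climate")
  keys <- intersect(c("scenario", "cell_id", "lon", "lat", "year", "month"),
                    names(climate))
  counts <- climate %>% count(.data$model_tag)
  if (length(unique(counts$n)) != 1L) {
    off <- counts$model_tag[counts$n != stats::median(counts$n)]
    abort_invalid(sprintf("member(s) with mismatched coverage: %s.",
                          paste(off, collapse = ", ")))
  }
  per_key <- climate %>% count(across(all_of(keys)))
  if (length(unique(per_key$n)) != 1L) {
    abort_invalid("members do not cover identical cells/months.")
  }
  climate %>%
    group_by(across(all_of(keys))) %>%
    summarise(tas = mean(.data$tas), pr = mean(.data$pr), .groups = "drop") %>%
    mutate(model_tag = "MME")
}

#' Project fire-occurrence probability from future drought characteristics
#'
#' Applies the historical-fit transforms and model to future-period drought
#' characteristics: characteristics -> stored-PCA scores -> stored min-max
#' normalization (clipped to the trained domain) -> local (or global)
#' coefficients -> sigmoid probability. Static covariates are held at their
#' historical (already normalized) values.
#'
#' @param model Fitted `gwlr` or `glr` object.
#' @param future_chars Tibble `cell_id`, `MDN`, `MDD`, `MDS`, `MDI` for one
#'   scenario/period/scale/threshold combination.
#' @param static_covariates Tibble keyed by `cell_id` with the model's
#'   non-drought predictors already normalized, plus coordinates for `gwlr`.
#' @param pca `drought_pca` fitted on the historical characteristics.
#' @param norm `minmax_params` fitted on the historical predictors (must
#'   cover the PC columns; static covariates are assumed pre-normalized).
#' @return Tibble `cell_id`, `fp`.
#' @export
project_fp <- function(model, future_chars, static_covariates, pca, norm) {
  if (is.null(pca)) abort_invalid("missing PCA parameters; fit or load them first.")
  if (is.null(norm)) abort_invalid("missing normalization parameters; fit or load them first.")
  require_columns(future_chars, c("cell_id", pca$vars), "future_chars")
  scored <- pca_apply(pca, future_chars)
  pc_cols <- paste0("PC", seq_len(pca$n_retained))
  pc_norm <- norm %>% filter(.data$variable %in% pc_cols)
  scored <- minmax_apply(scored, pc_norm, clip = TRUE)
  newdata <- static_covariates %>%
    inner_join(scored[, c("cell_id", pc_cols)], by = "cell_id")
  tibble(cell_id = newdata$cell_id,
         fp = as.numeric(stats::predict(model, newdata)))
}

#' Per-cell and regional probability change against the historical period
#'
#' `delta = fp_future - fp_hist` per cell; regional summaries are means over
#' cells whose forest fraction exceeds the mask threshold, reported in
#' percentage points. Regions whose mask is empty are flagged with `NA`.
#'
#' @param fp_future,fp_hist Tibbles `cell_id`, `fp` on the same cells.
#' @param grid Grid tibble with `region` and `forest_fraction`.
#' @param forest_mask_threshold Minimum forest fraction for a cell to enter
#'   the regional mean (default 0.5).
#' @return List of class `fp_delta`: `cells` (per-cell `delta`) and
#'   `regions` (`region`, `n_masked`, `mean_delta_pp`).
#' @export
delta_fp <- function(fp_future, fp_hist, grid, forest_mask_threshold = 0.5) {
  require_columns(fp_future, c("cell_id", "fp"), "fp_future")
  require_columns(fp_hist, c("cell_id", "fp"), "fp_hist")
  cells <- fp_future %>%
    rename(fp_future = "fp") %>%
    inner_join(rename(fp_hist, fp_hist = "fp"), by = "cell_id")
  if (nrow(cells) != nrow(fp_future)) {
    abort_invalid("`fp_future` and `fp_hist` must cover the same cells.")
  }
  cells <- cells %>%
    mutate(delta = .data$fp_future - .data$fp_hist) %>%
    inner_join(grid[, c("cell_id", "region", "forest_fraction")], by = "cell_id")
  regions <- cells %>%
    group_by(.data$region) %>%
    summarise(
      n_masked = sum(.data$forest_fraction >= forest_mask_threshold),
      mean_delta_pp = if (any(.data$forest_fraction >= forest_mask_threshold)) {
        100 * mean(.data$delta[.data$forest_fraction >= forest_mask_threshold])
      } else {
        NA_real_
      },
      .groups = "drop")
  if (any(regions$n_masked == 0L)) {
    warn(sprintf("region(s) with empty forest mask: %s.",
                 paste(regions$region[regions$n_masked == 0L], collapse = ", ")))
  }
  structure(list(cells = select(cells, "cell_id", "region", "forest_fraction",
                                "fp_future", "fp_hist", "delta"),
                 regions = regions,
                 forest_mask_threshold = forest_mask_threshold),
            class = "fp_delta")
}

#' @export
print.fp_delta <- function(x, ...) {
  cat(sprintf("Fire-probability change (forest mask >= %.2f)\n",
              x$forest_mask_threshold))
  print(x$regions)
  invisible(x)
}
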