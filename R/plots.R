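# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an SPEI series with drought thresholds
#'
#' Line plot of one cell's SPEI through time with the light (-0.5) and mid
#' (-1) drought thresholds marked.
#'
#' @param spei SPEI tibble from [compute_spei()].
#' @param cell Cell id to plot (default: the first present).
#' @param scales Scales to facet over (default: all present).
#' @return A ggplot object.
#' @export
plot_spei <- function(spei, cell = NULL, scales = NULL) {
  require_columns(spei, c("cell_id", "scale", "year", "month", "spei"), "spei")
  if (is.null(cell)) cell <- spei$cell_id[1]
  dd <- spei %>%
    filter(.data$cell_id == cell,
           if (is.null(scales)) TRUE else .data$scale %in% scales) %>%
    mutate(date = .data$year + (.data$month - 0.5) / 12)
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$date, y = .data$spei)) +
    ggplot2::geom_hline(yintercept = c(-0.5, -1), linetype = "dashed",
                        colour = c("orange", "red")) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~scale, ncol = 1,
                        labeller = ggplot2::labeller(scale = function(k) paste0("SPEI-", k))) +
    ggplot2::labs(x = "year", y = "SPEI",
                  title = paste("Cell", cell)) +
    ggplot2::theme_minimal()
}

#' Map the local coefficient surfaces of a GWLR fit
#'
#' Tile map of each local coefficient over the grid, one facet per term.
#'
#' @param object A `gwlr` fit.
#' @param terms Terms to map (default: all predictors).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gwlr <- function(object, terms = NULL, ...) {
  if (is.null(terms)) terms <- object$predictors
  dd <- tidy(object) %>% filter(.data$term %in% terms)
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~term) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(x = "longitude", y = "latitude", fill = "local\ncoefficient") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Bar chart of regional fire-probability changes
#'
#' Forest-masked mean probability change (percentage points) per region,
#' the standard summary of a scenario projection.
#'
#' @param object An `fp_delta` result (or a bound tibble of regional rows
#'   with `scenario`/`period` columns).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fp_delta <- function(object, ...) {
  dd <- object$regions
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$region, y = .data$mean_delta_pp,
                                   fill = .data$mean_delta_pp > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "#2166ac")) +
    ggplot2::labs(x = "region", y = "mean ΔFP (percentage points)") +
    ggplot2::theme_minimal()
}
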