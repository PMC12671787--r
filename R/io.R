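# Plain-text external interfaces: every pipeline artifact is a long-format
# CSV; normalization/PCA parameters travel as JSON sidecars (see
# write_transform_params).

#' Read and write pipeline artifacts as long-format CSV
#'
#' Thin readers/writers over `readr` that validate the column contract of
#' each artifact: monthly climate (`cell_id`, `lon`, `lat`, `year`, `month`,
#' `tas`, `pr`), SPEI (`cell_id`, `scale`, `year`, `month`, `spei`), drought
#' events, period summaries, and fire records (`lon`, `lat`, `year`).
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return The tibble (readers) or `path`, invisibly (writers).
#' @name artifact_csv
NULL

artifact_cols <- list(
  climate = c("cell_id", "lon", "lat", "year", "month", "tas", "pr"),
  spei = c("cell_id", "scale", "year", "month", "spei"),
  events = c("cell_id", "threshold", "start_year", "start_month",
             "DD", "DS", "DI"),
  summary = c("cell_id", "threshold", "period", "n", "MDN", "MDD", "MDS", "MDI"),
  fires = c("lon", "lat", "year")
)

write_artifact <- function(x, path, kind) {
  require_columns(x, artifact_cols[[kind]], kind)
  readr::write_csv(x, path)
  invisible(path)
}

read_artifact <- function(path, kind) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(x, artifact_cols[[kind]], kind)
  x
}

#' @rdname artifact_csv
#' @export
write_climate_csv <- function(x, path) write_artifact(x, path, "climate")

#' @rdname artifact_csv
#' @export
read_climate_csv <- function(path) read_artifact(path, "climate")

#' @rdname artifact_csv
#' @export
write_spei_csv <- function(x, path) write_artifact(x, path, "spei")

#' @rdname artifact_csv
#' @export
read_spei_csv <- function(path) read_artifact(path, "spei")

#' @rdname artifact_csv
#' @export
write_events_csv <- function(x, path) write_artifact(x, path, "events")

#' @rdname artifact_csv
#' @export
write_summary_csv <- function(x, path) write_artifact(x, path, "summary")

#' @rdname artifact_csv
#' @export
write_fire_records_csv <- function(x, path) write_artifact(x, path, "fires")

#' @rdname artifact_csv
#' @export
read_fire_records_csv <- function(path) read_artifact(path, "fires")
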