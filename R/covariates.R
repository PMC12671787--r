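# Predictor assembly: terrain and network covariates, min-max normalization
# with stored parameters, variance-inflation-factor collinearity diagnosis,
# and a reusable principal-component transform of the four drought
# characteristics (MDN, MDD, MDS, MDI).

#' Surface roughness of a cell
#'
#' Local elevation difference: `R = max(Z) - min(Z)` over the elevation
#' samples within a cell.
#'
#' @param elevations Numeric elevation samples (m), at least one.
#' @return Roughness in metres (>= 0).
#' @export
surface_roughness <- function(elevations) {
  elevations <- elevations[!is.na(elevations)]
  if (length(elevations) == 0L) abort_invalid("need at least one elevation sample.")
  max(elevations) - min(elevations)
}

#' Road or river network density
#'
#' `delta = L / F`: network length within the cell divided by cell area.
#'
#' @param length_km Network length (km, >= 0).
#' @param area_km2 Cell area (km^2, > 0).
#' @return Density in km per km^2.
#' @export
network_density <- function(length_km, area_km2) {
  if (any(!is.finite(area_km2)) || any(area_km2 <= 0)) {
    abort_invalid("`area_km2` must be strictly positive.")
  }
  if (any(length_km < 0, na.rm = TRUE)) abort_invalid("`length_km` must be >= 0.")
  length_km / area_km2
}

#' Fit min-max normalization parameters
#'
#' Records per-variable `xmin` and `xmax` from a training sample, for
#' `x* = (x - xmin) / (xmax - xmin)`.
#'
#' @param data Data frame of training values.
#' @param vars Variables to normalize (default: all numeric columns except
#'   `cell_id`).
#' @return Tibble `variable`, `xmin`, `xmax` (class `minmax_params`).
#' @export
minmax_fit <- function(data, vars = NULL) {
  if (is.null(vars)) {
    vars <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], "cell_id")
  }
  require_columns(data, vars, "data")
  params <- purrr::map(vars, function(v) {
    x <- data[[v]]
    r <- range(x, na.rm = TRUE)
    if (!all(is.finite(r)) || r[1] == r[2]) {
      abort_invalid(sprintf("variable `%s` is constant; min-max normalization is undefined.", v))
    }
    tibble(variable = v, xmin = r[1], xmax = r[2])
  }) %>% bind_rows()
  class(params) <- c("minmax_params", class(params))
  params
}

#' Apply stored min-max normalization
#'
#' Maps each variable through `(x - xmin) / (xmax - xmin)` using parameters
#' from [minmax_fit()]. Values outside the training range (e.g. future-period
#' data) are clipped to `[0, 1]` so the regression's linear predictor stays
#' inside the trained domain.
#'
#' @param data Data frame containing the variables in `params`.
#' @param params `minmax_params` tibble from [minmax_fit()].
#' @param clip Clip outputs to `[0, 1]` (default `TRUE`).
#' @return `data` with the listed variables replaced by normalized values.
#' @export
minmax_apply <- function(data, params, clip = TRUE) {
  require_columns(data, params$variable, "data")
  for (i in seq_len(nrow(params))) {
    v <- params$variable[i]
    x <- (data[[v]] - params$xmin[i]) / (params$xmax[i] - params$xmin[i])
    if (clip) x <- pmin(pmax(x, 0), 1)
    data[[v]] <- x
  }
  data
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from the least-squares regression of predictor
#' `j` on the remaining predictors. Exact linear dependence is reported as
#' an infinite VIF rather than an error.
#'
#' @param data Data frame of predictors.
#' @param vars Predictor columns (default: all numeric columns except
#'   `cell_id`).
#' @param flag_at Threshold above which `flagged` is set (default 10, the
#'   conventional severe-collinearity cutoff).
#' @return Tibble `variable`, `vif`, `flagged`.
#' @export
vif_table <- function(data, vars = NULL, flag_at = 10) {
  if (is.null(vars)) {
    vars <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], "cell_id")
  }
  require_columns(data, vars, "data")
  if (length(vars) < 2L) abort_invalid("need at least two predictors for VIF.")
  X <- as.data.frame(data[, vars])
  if (nrow(X) < length(vars) + 2L) {
    abort_invalid("need at least p + 2 rows for p predictors.")
  }
  vifs <- vapply(seq_along(vars), function(j) {
    fit <- lm(stats::reformulate(vars[-j], response = vars[j]), data = X)
    # an exact fit is handled below; silence the perfect-fit chatter
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble(variable = vars, vif = vifs, flagged = vifs >= flag_at)
}

#' Fit a principal-component transform of drought characteristics
#'
#' Standardizes the variables (mean 0, SD 1) and eigen-decomposes their
#' correlation structure, retaining components in decreasing-variance order
#' until the cumulative variance proportion reaches `var_threshold`.
#' Eigenvector signs are fixed by making each loading column's
#' largest-magnitude entry positive. Means, SDs and loadings are stored so
#' future-period data can be projected with the identical transform.
#'
#' @param data Data frame with the characteristic columns.
#' @param vars Variables to decompose (default `MDN`, `MDD`, `MDS`, `MDI`).
#' @param var_threshold Cumulative variance proportion to retain (default
#'   0.9).
#' @return Object of class `drought_pca`: `center`, `scale`, `loadings`
#'   (variables x all components), `prop_var` (percent), `cum_var`,
#'   `n_retained`.
#' @export
pca_fit <- function(data, vars = c("MDN", "MDD", "MDS", "MDI"),
                    var_threshold = 0.9) {
  require_columns(data, vars, "data")
  if (nrow(data) < 5L) abort_invalid("need at least 5 rows to fit the PCA.")
  X <- as.matrix(data[, vars])
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort_invalid(sprintf("constant variable(s): %s.",
                          paste(vars[sds == 0], collapse = ", ")))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  L <- pc$rotation
  # sign convention: largest-|loading| entry of each column positive
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  prop <- pc$sdev^2 / sum(pc$sdev^2) * 100
  n_ret <- which(cumsum(prop) >= var_threshold * 100 - 1e-9)[1]
  structure(list(center = pc$center, scale = pc$scale, loadings = L,
                 prop_var = prop, cum_var = cumsum(prop),
                 n_retained = n_ret, vars = vars),
            class = "drought_pca")
}

#' Project data onto a fitted principal-component transform
#'
#' Scores are `t(L) %*% (x - center) / scale` using the stored parameters;
#' projecting the training data reproduces the training scores exactly.
#'
#' @param model `drought_pca` object from [pca_fit()].
#' @param data Data frame containing the model's variables.
#' @param all_components Return all components instead of only the retained
#'   ones (default `FALSE`).
#' @return `data` with score columns `PC1`, `PC2`, ... appended.
#' @export
pca_apply <- function(model, data, all_components = FALSE) {
  if (!inherits(model, "drought_pca")) abort_invalid("`model` must come from pca_fit().")
  require_columns(data, model$vars, "data")
  X <- as.matrix(data[, model$vars])
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  k <- if (all_components) ncol(model$loadings) else model$n_retained
  scores <- Z %*% model$loadings[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  dplyr::bind_cols(data, as_tibble(scores))
}

#' @export
print.drought_pca <- function(x, ...) {
  cat(sprintf("Drought-characteristics PCA (%d of %d components retained, %.1f%% variance)\n",
              x$n_retained, ncol(x$loadings), x$cum_var[x$n_retained]))
  print(round(x$loadings, 3))
  invisible(x)
}

#' @rdname pca_fit
#' @param x A `drought_pca` object.
#' @param ... Unused.
#' @export
tidy.drought_pca <- function(x, ...) {
  L <- x$loadings
  tibble(variable = rep(rownames(L), ncol(L)),
         component = rep(colnames(L), each = nrow(L)),
         loading = as.vector(L))
}

#' @rdname pca_fit
#' @export
glance.drought_pca <- function(x, ...) {
  tibble(component = colnames(x$loadings),
         prop_var = x$prop_var, cum_var = x$cum_var,
         retained = seq_along(x$prop_var) <= x$n_retained)
}

#' Serialize normalization and PCA parameters to JSON
#'
#' Writes the stored parameters as a JSON sidecar so future-period runs can
#' reuse them bit-exactly; [read_transform_params()] restores them.
#'
#' @param norm `minmax_params` from [minmax_fit()] (or `NULL`).
#' @param pca `drought_pca` from [pca_fit()] (or `NULL`).
#' @param path Output file path.
#' @export
write_transform_params <- function(norm, pca, path) {
  payload <- list()
  if (!is.null(norm)) payload$minmax <- as.data.frame(norm)
  if (!is.null(pca)) {
    payload$pca <- list(center = pca$center, scale = pca$scale,
                        loadings = pca$loadings, prop_var = pca$prop_var,
                        n_retained = pca$n_retained, vars = pca$vars)
  }
  # I(17) = 17 significant digits, enough to round-trip doubles bit-exactly
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform_params
#' @export
read_transform_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  if (!is.null(raw$minmax)) {
    out$minmax <- as_tibble(raw$minmax)
    class(out$minmax) <- c("minmax_params", class(out$minmax))
  }
  if (!is.null(raw$pca)) {
    L <- as.matrix(raw$pca$loadings)
    rownames(L) <- raw$pca$vars
    out$pca <- structure(list(center = setNames(unlist(raw$pca$center), raw$pca$vars),
                              scale = setNames(unlist(raw$pca$scale), raw$pca$vars),
                              loadings = L, prop_var = raw$pca$prop_var,
                              cum_var = cumsum(raw$pca$prop_var),
                              n_retained = raw$pca$n_retained,
                              vars = raw$pca$vars),
                         class = "drought_pca")
  }
  out
}
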