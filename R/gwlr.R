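# Global and geographically weighted logistic regression of gridded
# fire-occurrence probability. The response is binomial per cell
# (successes = fire-years, trials = years), so the logit link acts on the
# occurrence probability directly. Local models are fitted at every cell by
# iteratively reweighted least squares (IRLS) with adaptive bi-square kernel
# weights multiplying each observation's likelihood contribution; the kernel
# bandwidth (a neighbour count) is selected by minimizing AICc.

EARTH_RADIUS_KM <- 6371

#' Great-circle distance
#'
#' Haversine distance in kilometres on a sphere of radius 6371 km.
#' Vectorized over coordinate pairs.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in degrees.
#' @return Distance(s) in km.
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE)) {
    abort_invalid("latitudes must lie in [-90, 90].")
  }
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(sqrt(a), 1))
}

dist_matrix_km <- function(lon, lat) {
  m <- length(lon)
  D <- matrix(0, m, m)
  for (i in seq_len(m)) {
    D[i, ] <- great_circle_km(lon[i], lat[i], lon, lat)
  }
  D
}

#' Bi-square kernel
#'
#' `w = (1 - (d / b)^2)^2` for `d < b`, else 0. At `d = 0` the weight is 1;
#' at `d = b/2` it is 0.5625; at the support boundary `d = b` it is 0.
#'
#' @param d Distance(s).
#' @param b Bandwidth (same units as `d`, > 0).
#' @return Weight(s) in `[0, 1]`.
#' @export
bisquare_kernel <- function(d, b) {
  ifelse(d < b, (1 - (d / b)^2)^2, 0)
}

#' Adaptive bi-square kernel weight matrix
#'
#' For each regression location `i` the bandwidth `b_i` is the distance to
#' its `neighbors`-th nearest neighbour (the location itself, at distance 0,
#' counts as the first), and `w_ij = bisquare_kernel(d_ij, b_i)`. The
#' self-weight `w_ii` is always 1.
#'
#' @param distances Square matrix of pairwise distances.
#' @param neighbors Neighbour count defining the adaptive bandwidth
#'   (at most the number of locations).
#' @return Weight matrix, same shape as `distances`.
#' @export
bisquare_weights <- function(distances, neighbors) {
  if (!is.matrix(distances) || nrow(distances) != ncol(distances)) {
    abort_invalid("`distances` must be a square matrix.")
  }
  m <- nrow(distances)
  neighbors <- stop_if_not_scalar_count(neighbors, "neighbors")
  if (neighbors > m) abort_invalid("`neighbors` exceeds the number of locations.")
  W <- matrix(0, m, m)
  for (i in seq_len(m)) {
    b <- sort(distances[i, ], partial = neighbors)[neighbors]
    if (b <= 0) abort_invalid("adaptive bandwidth collapsed to 0 (duplicate locations).")
    W[i, ] <- bisquare_kernel(distances[i, ], b)
  }
  W
}

#' Akaike information criterion with small-sample correction
#'
#' `AIC = -2 ln(L) + 2k`; `AICc = AIC + 2k(k+1) / (m - k - 1)`.
#'
#' @param logL Maximized log-likelihood.
#' @param k (Effective) number of parameters.
#' @param m Number of sample points (must exceed `k + 1`).
#' @return Tibble with columns `aic` and `aicc`.
#' @export
aicc <- function(logL, k, m) {
  if (m <= k + 1) abort_invalid("AICc requires m > k + 1.")
  aic <- -2 * logL + 2 * k
  tibble(aic = aic, aicc = aic + 2 * k * (k + 1) / (m - k - 1))
}

# Binomial log-likelihood (including the combinatorial constant, so values
# are comparable across model families with the same data).
binom_loglik <- function(s, n, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(lchoose(n, s) + s * log(p) + (n - s) * log(1 - p))
}

# Weighted binomial IRLS. `w` are prior (kernel) weights multiplying each
# observation's likelihood contribution. Returns the final coefficient
# vector, fitted probabilities, the final weighted cross-product matrix
# (for hat-trace computations) and convergence flags.
irls_binomial <- function(X, s, n, w = NULL, tol = 1e-8, maxit = 100L) {
  if (is.null(w)) w <- rep(1, length(s))
  beta <- numeric(ncol(X))
  beta[1] <- qlogis(min(max(sum(w * s) / sum(w * n), 1e-4), 1 - 1e-4))
  converged <- FALSE
  ridged <- FALSE
  singular <- FALSE
  A <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- pmin(pmax(plogis(eta), 1e-10), 1 - 1e-10)
    mw <- w * n * p * (1 - p)
    z <- eta + (s / n - p) / (p * (1 - p))
    Xw <- X * mw
    A <- crossprod(Xw, X)
    bvec <- crossprod(Xw, z)
    newbeta <- tryCatch(solve(A, bvec), error = function(e) NULL)
    if (is.null(newbeta) || any(!is.finite(newbeta))) {
      # near-singular weighted design: small ridge jitter, flagged
      ridged <- TRUE
      newbeta <- tryCatch(solve(A + diag(1e-8, ncol(A)), bvec),
                          error = function(e) NULL)
      if (is.null(newbeta) || any(!is.finite(newbeta))) {
        singular <- TRUE
        break
      }
    }
    delta <- max(abs(newbeta - beta))
    beta <- drop(newbeta)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  list(beta = beta, fitted = p, A = A, mw = w * n * pmin(pmax(p, 1e-10), 1 - 1e-10) *
         (1 - pmin(pmax(p, 1e-10), 1 - 1e-10)),
       converged = converged, ridged = ridged, singular = singular)
}

build_design <- function(data, predictors) {
  require_columns(data, predictors, "data")
  X <- cbind(`(Intercept)` = 1, as.matrix(data[, predictors, drop = FALSE]))
  if (any(!is.finite(X))) abort_invalid("predictors contain missing or non-finite values.")
  X
}

check_response <- function(data, successes, trials) {
  require_columns(data, c(successes, trials), "data")
  s <- data[[successes]]
  n <- data[[trials]]
  if (any(s < 0 | s > n)) abort_invalid("need 0 <= successes <= trials.")
  if (all(s == 0) || all(s == n)) {
    abort_invalid("response is all-0 or all-1; the logistic fit is unidentified.")
  }
  list(s = s, n = n)
}

#' Fit a global logistic regression
#'
#' Binomial logistic regression of per-cell fire-years out of total years on
#' normalized covariates, maximized by iteratively reweighted least squares
#' (convergence when the largest coefficient change is below `tol`).
#'
#' @param data Modelling tibble, one row per cell.
#' @param predictors Character vector of predictor column names (normalized
#'   to `[0, 1]`).
#' @param successes,trials Column names of the fire-year count and the year
#'   count per cell.
#' @param tol,maxit IRLS convergence tolerance and iteration cap.
#' @return Object of class `glr`: coefficients, log-likelihood, `k`, `m`,
#'   `aic`, `aicc`, fitted probabilities, convergence flag.
#' @export
fit_glr <- function(data, predictors, successes = "successes", trials = "trials",
                    tol = 1e-8, maxit = 100L) {
  X <- build_design(data, predictors)
  resp <- check_response(data, successes, trials)
  fit <- irls_binomial(X, resp$s, resp$n, tol = tol, maxit = maxit)
  if (!fit$converged) {
    warn("global logistic fit did not converge (possible complete separation); coefficients reported as-is.")
  }
  logL <- binom_loglik(resp$s, resp$n, fit$fitted)
  k <- ncol(X)
  m <- nrow(X)
  ic <- aicc(logL, k, m)
  structure(list(coefficients = setNames(fit$beta, colnames(X)),
                 logL = logL, k = k, m = m,
                 aic = ic$aic, aicc = ic$aicc,
                 fitted = fit$fitted, converged = fit$converged,
                 predictors = predictors, successes = successes,
                 trials = trials),
            class = "glr")
}

#' Fit a geographically weighted logistic regression
#'
#' At every cell a locally weighted binomial IRLS fit is computed, with
#' adaptive bi-square kernel weights (bandwidth = distance to the
#' `bandwidth`-th nearest neighbour) multiplying each observation's
#' likelihood contribution. Only observations with non-zero kernel weight
#' enter each local fit. The model's log-likelihood evaluates every
#' observation at its own local fit; the effective parameter count is the
#' trace of the local hat contributions (each location's leverage in its own
#' weighted least-squares step at convergence), and AIC/AICc follow from
#' those.
#'
#' A local design that stays singular even with ridge jitter is refitted at
#' the smallest enlarged bandwidth that is non-singular, and flagged.
#' `bandwidth = Inf` sets every kernel weight to 1, reproducing the global
#' model at every location.
#'
#' @inheritParams fit_glr
#' @param bandwidth Adaptive bandwidth as a neighbour count (at least
#'   `length(predictors) + 2`), or `Inf` for the global limit.
#' @param coords Names of the longitude and latitude columns.
#' @return Object of class `gwlr`: per-location coefficient tibble,
#'   bandwidth, log-likelihood, effective `k`, `m`, `aic`, `aicc`, fitted
#'   probabilities and per-location convergence flags. The training data is
#'   retained for prediction at new locations.
#' @export
fit_gwlr <- function(data, predictors, successes = "successes", trials = "trials",
                     bandwidth, coords = c("lon", "lat"),
                     tol = 1e-8, maxit = 100L) {
  require_columns(data, coords, "data")
  X <- build_design(data, predictors)
  resp <- check_response(data, successes, trials)
  m <- nrow(X)
  p1 <- ncol(X)
  if (!is.infinite(bandwidth)) {
    bandwidth <- stop_if_not_scalar_count(bandwidth, "bandwidth")
    if (bandwidth < p1 + 1L || bandwidth > m) {
      abort_invalid(sprintf("`bandwidth` must lie in [%d, %d].", p1 + 1L, m))
    }
  }
  D <- dist_matrix_km(data[[coords[1]]], data[[coords[2]]])

  betas <- matrix(NA_real_, m, p1, dimnames = list(NULL, colnames(X)))
  fitted <- numeric(m)
  hat <- numeric(m)
  converged <- logical(m)
  ridged <- logical(m)
  enlarged <- integer(m)

  for (i in seq_len(m)) {
    bw_i <- bandwidth
    repeat {
      if (is.infinite(bw_i)) {
        w <- rep(1, m)
      } else {
        b <- sort(D[i, ], partial = bw_i)[bw_i]
        w <- bisquare_kernel(D[i, ], b)
        w[i] <- 1
      }
      idx <- which(w > 0)
      fit <- irls_binomial(X[idx, , drop = FALSE], resp$s[idx], resp$n[idx],
                           w = w[idx], tol = tol, maxit = maxit)
      if (!fit$singular) break
      if (is.infinite(bw_i) || bw_i >= m) {
        abort_invalid(sprintf("local design singular at location %d even at full bandwidth.", i))
      }
      bw_i <- min(bw_i + max(1L, ceiling(0.2 * m)), m)
      enlarged[i] <- bw_i
    }
    betas[i, ] <- fit$beta
    self <- match(i, idx)
    fitted[i] <- fit$fitted[self]
    # leverage of observation i in its own local weighted LS step
    xi <- X[i, ]
    Ainv_xi <- tryCatch(solve(fit$A, xi), error = function(e)
      tryCatch(solve(fit$A + diag(1e-8 * (mean(diag(fit$A)) + 1), p1), xi),
               error = function(e2) rep(NA_real_, p1)))
    hat[i] <- fit$mw[self] * sum(xi * Ainv_xi)
    if (!is.finite(hat[i])) hat[i] <- 1
    converged[i] <- fit$converged
    ridged[i] <- fit$ridged
  }

  logL <- binom_loglik(resp$s, resp$n, fitted)
  k_eff <- sum(hat)
  if (!is.finite(k_eff) || m <= k_eff + 1) {
    abort_invalid(sprintf(
      "effective parameter count (%.1f) exhausts the sample (m = %d) at bandwidth %s; use a larger bandwidth.",
      k_eff, m, format(bandwidth)))
  }
  ic <- aicc(logL, k_eff, m)
  coef_tbl <- dplyr::bind_cols(
    data[, c(intersect("cell_id", names(data)), coords)],
    as_tibble(betas)
  )
  structure(list(coefficients = coef_tbl, bandwidth = bandwidth,
                 logL = logL, k = k_eff, m = m,
                 aic = ic$aic, aicc = ic$aicc,
                 fitted = fitted, converged = converged, ridged = ridged,
                 enlarged = enlarged,
                 predictors = predictors, successes = successes,
                 trials = trials, coords = coords,
                 training = data, tol = tol, maxit = maxit),
            class = "gwlr")
}

#' Select the GWLR bandwidth by AICc
#'
#' Golden-section search over integer neighbour counts, minimizing the AICc
#' of [fit_gwlr()]; assumes a unimodal AICc profile (a full grid search is
#' available via `method = "grid"` for non-unimodal profiles). Ties break to
#' the smaller bandwidth. Deterministic: repeated runs give identical
#' results.
#'
#' @inheritParams fit_gwlr
#' @param range Integer `c(lower, upper)` neighbour-count search range;
#'   defaults to `c(p + 2, m)`.
#' @param method `"golden"` (default) or `"grid"`.
#' @return List with `bandwidth`, `aicc`, and the evaluated search `trace`
#'   (a tibble of bandwidth/AICc pairs).
#' @export
select_bandwidth <- function(data, predictors, successes = "successes",
                             trials = "trials", coords = c("lon", "lat"),
                             range = NULL, method = c("golden", "grid")) {
  method <- match.arg(method)
  m <- nrow(data)
  p2 <- length(predictors) + 2L
  if (is.null(range)) range <- c(p2, m)
  range <- as.integer(range)
  if (range[1] < p2 || range[2] > m || range[1] > range[2]) {
    abort_invalid(sprintf("`range` must lie within [%d, %d].", p2, m))
  }
  memo <- new.env(parent = emptyenv())
  score <- function(bw) {
    key <- as.character(bw)
    if (!is.null(memo[[key]])) return(memo[[key]])
    # bandwidths whose effective parameters exhaust the sample are infeasible
    val <- tryCatch(
      fit_gwlr(data, predictors, successes, trials,
               bandwidth = bw, coords = coords)$aicc,
      droughtfire_invalid_argument = function(e) Inf)
    memo[[key]] <- val
    val
  }
  lo <- range[1]; hi <- range[2]
  if (method == "grid" || hi - lo <= 4L) {
    for (bw in lo:hi) score(bw)
  } else {
    gr <- (sqrt(5) - 1) / 2
    x1 <- as.integer(round(hi - gr * (hi - lo)))
    x2 <- as.integer(round(lo + gr * (hi - lo)))
    score(lo); score(hi)
    while (hi - lo > 4L) {
      if (x1 == x2) x2 <- x1 + 1L
      if (score(x1) <= score(x2)) {
        hi <- x2
      } else {
        lo <- x1
      }
      x1 <- as.integer(round(hi - gr * (hi - lo)))
      x2 <- as.integer(round(lo + gr * (hi - lo)))
    }
    for (bw in lo:hi) score(bw)
  }
  trace <- tibble(bandwidth = as.integer(ls(memo)),
                  aicc = vapply(ls(memo), function(k) memo[[k]], numeric(1))) %>%
    arrange(.data$bandwidth)
  best <- trace %>% filter(.data$aicc == min(.data$aicc)) %>%
    arrange(.data$bandwidth)
  list(bandwidth = best$bandwidth[1], aicc = best$aicc[1], trace = trace)
}

#' @export
print.glr <- function(x, ...) {
  cat(sprintf("Global logistic regression (m = %d cells)\n", x$m))
  print(round(x$coefficients, 4))
  cat(sprintf("logL = %.3f, k = %d, AIC = %.2f, AICc = %.2f\n",
              x$logL, x$k, x$aic, x$aicc))
  invisible(x)
}

#' @export
print.gwlr <- function(x, ...) {
  cat(sprintf("Geographically weighted logistic regression (m = %d cells, bandwidth = %s neighbours)\n",
              x$m, format(x$bandwidth)))
  cat(sprintf("logL = %.3f, effective k = %.2f, AIC = %.2f, AICc = %.2f\n",
              x$logL, x$k, x$aic, x$aicc))
  cat(sprintf("%d/%d local fits converged\n", sum(x$converged), x$m))
  invisible(x)
}

#' Predict occurrence probabilities from a global logistic model
#'
#' @param object A `glr` fit.
#' @param newdata Tibble containing the model's predictor columns (normalized
#'   with the training parameters).
#' @param ... Unused.
#' @return Probabilities strictly in (0, 1).
#' @export
predict.glr <- function(object, newdata, ...) {
  X <- build_design(newdata, object$predictors)
  check_normalized(X, object$predictors)
  drop(plogis(X %*% object$coefficients))
}

check_normalized <- function(X, predictors) {
  vals <- X[, predictors, drop = FALSE]
  if (any(vals < -1 | vals > 2)) {
    warn("predictor values far outside [0, 1]; did you forget to apply the training normalization?")
  }
}

#' Predict occurrence probabilities from a GWLR model
#'
#' At calibration locations (coordinates matching a training cell) the
#' stored local coefficients are applied to the supplied covariates. At new
#' locations, local coefficients are re-estimated there by a kernel-weighted
#' fit over the calibration observations, using the model's bandwidth.
#'
#' @param object A `gwlr` fit.
#' @param newdata Tibble with the predictor and coordinate columns.
#' @param ... Unused.
#' @return Probabilities strictly in (0, 1).
#' @export
predict.gwlr <- function(object, newdata, ...) {
  coords <- object$coords
  require_columns(newdata, coords, "newdata")
  X <- build_design(newdata, object$predictors)
  check_normalized(X, object$predictors)
  train <- object$training
  B <- as.matrix(object$coefficients[, c("(Intercept)", object$predictors)])
  key <- paste(signif(train[[coords[1]]], 12), signif(train[[coords[2]]], 12))
  new_key <- paste(signif(newdata[[coords[1]]], 12), signif(newdata[[coords[2]]], 12))
  pos <- match(new_key, key)
  eta <- numeric(nrow(newdata))
  known <- !is.na(pos)
  if (any(known)) {
    eta[known] <- rowSums(X[known, , drop = FALSE] * B[pos[known], , drop = FALSE])
  }
  if (any(!known)) {
    Xt <- build_design(train, object$predictors)
    s <- train[[object$successes]]
    n <- train[[object$trials]]
    for (j in which(!known)) {
      d <- great_circle_km(newdata[[coords[1]]][j], newdata[[coords[2]]][j],
                           train[[coords[1]]], train[[coords[2]]])
      if (is.infinite(object$bandwidth)) {
        w <- rep(1, nrow(train))
      } else {
        b <- sort(d, partial = object$bandwidth)[object$bandwidth]
        w <- bisquare_kernel(d, b)
      }
      idx <- which(w > 0)
      fit <- irls_binomial(Xt[idx, , drop = FALSE], s[idx], n[idx], w = w[idx],
                           tol = object$tol, maxit = object$maxit)
      eta[j] <- sum(X[j, ] * fit$beta)
    }
  }
  plogis(eta)
}

#' @rdname fit_glr
#' @param x A fitted `glr` object.
#' @param ... Unused.
#' @export
tidy.glr <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @rdname fit_glr
#' @export
glance.glr <- function(x, ...) {
  tibble(logLik = x$logL, k = x$k, m = x$m, AIC = x$aic, AICc = x$aicc,
         converged = x$converged)
}

#' @rdname fit_gwlr
#' @param x A fitted `gwlr` object.
#' @param ... Unused.
#' @export
tidy.gwlr <- function(x, ...) {
  x$coefficients %>%
    tidyr::pivot_longer(all_of(c("(Intercept)", x$predictors)),
                        names_to = "term", values_to = "estimate")
}

#' @rdname fit_gwlr
#' @export
glance.gwlr <- function(x, ...) {
  tibble(logLik = x$logL, k = x$k, m = x$m, AIC = x$aic, AICc = x$aicc,
         bandwidth = x$bandwidth, n_converged = sum(x$converged))
}

#' Regional means of local coefficients
#'
#' Arithmetic mean of each local coefficient over the cells of each region,
#' the standard summary of spatially varying effects by geographic division.
#'
#' @param model A `gwlr` fit whose training data has a `region` column (or
#'   supply `regions`).
#' @param regions Optional vector of region labels, one per training cell.
#' @return Tibble `region`, `term`, `mean_coef`.
#' @export
regional_coefficients <- function(model, regions = NULL) {
  if (!inherits(model, "gwlr")) abort_invalid("`model` must be a gwlr fit.")
  if (is.null(regions)) {
    require_columns(model$training, "region", "model$training")
    regions <- model$training$region
  }
  tidy(model) %>%
    mutate(region = rep(regions, each = length(model$predictors) + 1L)) %>%
    group_by(.data$region, .data$term) %>%
    summarise(mean_coef = mean(.data$estimate), .groups = "drop")
}
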