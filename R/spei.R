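# Multi-scale Standardized Precipitation Evapotranspiration Index (SPEI):
# Thornthwaite PET -> climatic water balance -> k-month accumulation ->
# per-calendar-month log-logistic standardization by probability-weighted
# moments, reported as a standard-normal deviate.

MID_MONTH_DOY <- c(15L, 46L, 74L, 105L, 135L, 166L, 196L, 227L, 258L, 288L, 319L, 349L)
DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

# Day-length / month-length correction factor of the Thornthwaite formula.
# Solar declination at mid-month; sunset hour angle clipped for polar cases.
thornthwaite_K <- function(lat, month) {
  phi <- lat * pi / 180
  delta <- 0.4093 * sin(2 * pi * MID_MONTH_DOY[month] / 365 - 1.405)
  x <- pmin(pmax(-tan(phi) * tan(delta), -1), 1)
  N <- 24 / pi * acos(x)
  (N / 12) * (DAYS_IN_MONTH[month] / 30)
}

#' Thornthwaite potential evapotranspiration
#'
#' Estimates monthly potential evapotranspiration (PET, mm/month) from monthly
#' mean temperature alone. For each calendar year the annual heat index
#' `I = sum((T/5)^1.514)` is accumulated over months with `T > 0`, the
#' exponent `a` is the standard cubic polynomial in `I`, and
#' `PET = 16 * K(lat, month) * (10 T / I)^a`, with `K` the day-length and
#' month-length correction from solar declination. Months with `T <= 0` get
#' `PET = 0`; a fully frozen year yields an all-zero year (not an error).
#'
#' @param tas Numeric vector of monthly mean temperature (degrees C), starting
#'   in January and covering whole calendar years (length a multiple of 12,
#'   at least 12).
#' @param lat Latitude in degrees, strictly inside (-90, 90).
#' @return Numeric vector of PET (mm/month), same length as `tas`.
#' @examples
#' thornthwaite_pet(rep(10, 12), lat = 45)
#' @export
thornthwaite_pet <- function(tas, lat) {
  if (!is.numeric(lat) || length(lat) != 1L || is.na(lat) || abs(lat) >= 90) {
    abort_invalid("`lat` must be a single value strictly between -90 and 90.")
  }
  n <- length(tas)
  if (n < 12L || n %% 12L != 0L) {
    abort_invalid("`tas` must cover whole calendar years: length >= 12 and a multiple of 12.")
  }
  tmat <- matrix(tas, nrow = 12L)  # months x years
  pet <- matrix(0, nrow = 12L, ncol = ncol(tmat))
  K <- thornthwaite_K(lat, 1:12)
  for (y in seq_len(ncol(tmat))) {
    ty <- tmat[, y]
    warm <- !is.na(ty) & ty > 0
    I <- sum((ty[warm] / 5)^1.514)
    if (I > 0) {
      a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
      pet[warm, y] <- 16 * K[warm] * (10 * ty[warm] / I)^a
    }
    pet[is.na(ty), y] <- NA_real_
  }
  as.vector(pet)
}

#' Climatic water balance
#'
#' Elementwise difference `D = P - PET` (mm/month), the quantity accumulated
#' and standardized by the SPEI.
#'
#' @param pr Monthly precipitation (mm).
#' @param pet Monthly potential evapotranspiration (mm).
#' @return Numeric vector `pr - pet`.
#' @export
water_balance <- function(pr, pet) {
  if (length(pr) != length(pet)) {
    abort_invalid("`pr` and `pet` must have the same length.")
  }
  pr - pet
}

#' k-month backward accumulation
#'
#' Rolling sum over the trailing `k` months: `Dk(t) = sum(D[(t-k+1):t])`.
#' The first `k - 1` entries are undefined and returned as `NA` (never 0,
#' since 0 is a meaningful water balance).
#'
#' @param d Numeric series (e.g. monthly water balance).
#' @param k Accumulation window in months (`k >= 1`).
#' @return Numeric vector, same length as `d`, first `k - 1` entries `NA`.
#' @export
accumulate_balance <- function(d, k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != floor(k)) {
    abort_invalid("`k` must be a single integer >= 1.")
  }
  k <- as.integer(k)
  n <- length(d)
  if (n < k) abort_invalid("series shorter than accumulation window `k`.")
  if (k == 1L) return(d)
  cs <- cumsum(ifelse(is.na(d), 0, d))
  out <- cs - dplyr::lag(cs, k, default = 0)
  # propagate NA through any window containing a missing month
  nas <- cumsum(is.na(d))
  bad <- (nas - dplyr::lag(nas, k, default = 0)) > 0
  out[bad] <- NA_real_
  out[seq_len(k - 1L)] <- NA_real_
  out
}

# Unbiased probability-weighted moments b0, b1, b2 (ascending order statistics).
pwm_unbiased <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  i <- seq_len(n)
  c(mean(xs),
    sum((i - 1) / (n - 1) * xs) / n,
    sum((i - 1) * (i - 2) / ((n - 1) * (n - 2)) * xs) / n)
}

# Three-parameter log-logistic fit by unbiased PWMs. CDF parametrization:
# F(x) = (1 + (alpha / (x - gamma))^beta)^(-1) on (gamma, Inf).
# If the fitted origin exceeds min(x) the support would exclude observed
# values; gamma is clamped to min(x) - eps as a standard guard.
fit_loglogistic_pwm <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 4L || sd(x) == 0) {
    return(list(alpha = NA_real_, beta = NA_real_, gamma = NA_real_, ok = FALSE))
  }
  b <- pwm_unbiased(x)
  w0 <- b[1]; w1 <- b[1] - b[2]; w2 <- b[1] - 2 * b[2] + b[3]
  den <- 6 * w1 - w0 - 6 * w2
  if (!is.finite(den) || den == 0) {
    return(list(alpha = NA_real_, beta = NA_real_, gamma = NA_real_, ok = FALSE))
  }
  beta <- (2 * w1 - w0) / den
  if (!is.finite(beta) || beta <= 1) {
    # beta <= 1: the mean of the fitted distribution does not exist, so the
    # PWM system is inconsistent with the data; flag as degenerate.
    return(list(alpha = NA_real_, beta = NA_real_, gamma = NA_real_, ok = FALSE))
  }
  g <- gamma(1 + 1 / beta) * gamma(1 - 1 / beta)
  alpha <- (w0 - 2 * w1) * beta / g
  gam <- w0 - alpha * g
  if (!is.finite(alpha) || alpha <= 0) {
    return(list(alpha = NA_real_, beta = NA_real_, gamma = NA_real_, ok = FALSE))
  }
  if (gam >= min(x)) gam <- min(x) - 1e-8 * max(1, abs(min(x)))
  list(alpha = alpha, beta = beta, gamma = gam, ok = TRUE)
}

# Standard-normal deviate of a cumulative probability via the classic
# Abramowitz-Stegun rational approximation used throughout the SPI/SPEI
# literature. Probabilities are clamped away from {0, 1}.
as_normal_deviate <- function(p) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  c0 <- 2.515517; c1 <- 0.802853; c2 <- 0.010328
  d1 <- 1.432788; d2 <- 0.189269; d3 <- 0.001308
  lower <- p <= 0.5
  q <- ifelse(lower, p, 1 - p)
  w <- sqrt(-2 * log(q))
  z <- w - (c0 + c1 * w + c2 * w^2) / (1 + d1 * w + d2 * w^2 + d3 * w^3)
  ifelse(lower, -z, z)
}

loglogistic_cdf <- function(x, fit) {
  u <- pmax(x - fit$gamma, 1e-12)
  1 / (1 + (fit$alpha / u)^fit$beta)
}

#' Standardize an accumulated water-balance series into SPEI
#'
#' Per calendar month, fits a three-parameter log-logistic distribution to the
#' calibration values of `dk` by unbiased probability-weighted moments, then
#' maps every value through the fitted CDF to a standard-normal deviate.
#' The transform is strictly monotone in `dk` within each calendar month.
#'
#' @param dk Accumulated water balance (mm), `NA` where undefined.
#' @param month Calendar month (1-12) of each entry.
#' @param calibration Logical vector marking entries used to fit the
#'   distribution; defaults to all defined entries (self-calibration).
#' @return Numeric SPEI vector; `NA` where `dk` is `NA` or where a calendar
#'   month's fit is degenerate (flagged with a warning).
#' @export
spei_standardize <- function(dk, month, calibration = NULL) {
  if (length(dk) != length(month)) {
    abort_invalid("`dk` and `month` must have the same length.")
  }
  if (is.null(calibration)) calibration <- !is.na(dk)
  out <- rep(NA_real_, length(dk))
  bad_months <- integer(0)
  for (m in sort(unique(month[!is.na(dk)]))) {
    sel <- month == m & !is.na(dk)
    cal <- dk[sel & calibration]
    fit <- fit_loglogistic_pwm(cal)
    if (!fit$ok) {
      bad_months <- c(bad_months, m)
      next
    }
    out[sel] <- as_normal_deviate(loglogistic_cdf(dk[sel], fit))
  }
  if (length(bad_months) > 0) {
    warn(sprintf("degenerate log-logistic fit; SPEI undefined for calendar month(s) %s.",
                 paste(bad_months, collapse = ", ")))
  }
  out
}

#' Multi-scale SPEI for a gridded monthly climate table
#'
#' Runs the full index chain per cell: Thornthwaite PET from temperature and
#' latitude, climatic water balance `P - PET`, k-month accumulation, and
#' per-calendar-month log-logistic standardization. Each cell's series must
#' cover whole calendar years in time order.
#'
#' @param climate Tibble with columns `cell_id`, `lat`, `year`, `month`,
#'   `tas` (degrees C) and `pr` (mm/month). Extra grouping columns
#'   (`scenario`, `model_tag`) are honoured if present.
#' @param scales Integer accumulation scales, subset of `c(1, 3, 6, 12)`.
#' @param calibration Optional `c(first_year, last_year)` window used to fit
#'   the standardization; default `NULL` self-calibrates on each series' full
#'   span.
#' @return Tibble `cell_id` (plus any scenario/model columns), `scale`,
#'   `year`, `month`, `spei`. The first `k - 1` months of each series are
#'   `NA` by construction.
#' @export
compute_spei <- function(climate, scales = c(1L, 3L, 6L, 12L), calibration = NULL) {
  require_columns(climate, c("cell_id", "lat", "year", "month", "tas", "pr"), "climate")
  if (!all(scales %in% c(1L, 3L, 6L, 12L))) {
    abort_invalid("`scales` must be a subset of {1, 3, 6, 12}.")
  }
  if (!is.null(calibration) && (length(calibration) != 2L || calibration[1] > calibration[2])) {
    abort_invalid("`calibration` must be c(first_year, last_year).")
  }
  group_cols <- intersect(c("cell_id", "scenario", "model_tag"), names(climate))
  climate %>%
    group_by(across(all_of(group_cols))) %>%
    group_split() %>%
    purrr::map(function(cc) {
      cc <- arrange(cc, .data$year, .data$month)
      pet <- thornthwaite_pet(cc$tas, lat = cc$lat[1])
      d <- water_balance(cc$pr, pet)
      cal <- if (is.null(calibration)) NULL else
        cc$year >= calibration[1] & cc$year <= calibration[2]
      purrr::map(scales, function(k) {
        dk <- accumulate_balance(d, k)
        calk <- if (is.null(cal)) !is.na(dk) else cal & !is.na(dk)
        tibble(!!!cc[1, group_cols], scale = as.integer(k),
               year = cc$year, month = cc$month,
               spei = spei_standardize(dk, cc$month, calk))
      }) %>% bind_rows()
    }) %>%
    bind_rows()
}
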