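# Seeded synthetic inputs with the statistical structure the analysis
# assumes: a lon/lat grid with contiguous regions, seasonal climate with an
# AR(1) wetness anomaly (so multi-month droughts occur), spatially smooth
# static covariates, spatially varying logistic coefficient surfaces, and
# per-cell-per-year Bernoulli fire occurrence.

# One master seed spawns independent per-stream seeds so stages can be
# regenerated in isolation.
spawn_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Smooth random surface over the grid: a short random trigonometric series in
# normalized coordinates, rescaled to [lo, hi].
smooth_field <- function(grid, seed, lo = 0, hi = 1, waves = 4L) {
  with_seed(seed, {
    u <- (grid$lon - min(grid$lon)) / max(diff(range(grid$lon)), 1e-9)
    v <- (grid$lat - min(grid$lat)) / max(diff(range(grid$lat)), 1e-9)
    f <- rep(0, nrow(grid))
    for (j in seq_len(waves)) {
      a <- rnorm(1)
      w1 <- runif(1, 0.5, 2); w2 <- runif(1, 0.5, 2); ph <- runif(1, 0, 2 * pi)
      f <- f + a * sin(2 * pi * (w1 * u + w2 * v) + ph)
    }
    r <- range(f)
    if (diff(r) < 1e-12) return(rep((lo + hi) / 2, nrow(grid)))
    lo + (f - r[1]) / diff(r) * (hi - lo)
  })
}

#' Generate a synthetic lon/lat grid
#'
#' Builds a regular grid of square cells with contiguous rectangular region
#' blocks (stand-ins for large geographic divisions) and a spatially smooth
#' forest fraction per cell.
#'
#' @param n_lon,n_lat Number of columns / rows (each >= 2).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param lon0,lat0 Western / southern edge of the grid (degrees).
#' @param cell_size Cell edge length (degrees).
#' @param n_regions Target number of contiguous regions (capped at 7).
#' @return Tibble with `cell_id`, `col`, `row`, `lon`, `lat` (cell centres),
#'   `region`, `forest_fraction`.
#' @export
gen_grid <- function(n_lon, n_lat, seed = 1L, lon0 = 100, lat0 = 20,
                     cell_size = 0.5, n_regions = 7L) {
  if (!is.numeric(n_lon) || !is.numeric(n_lat) || n_lon < 2 || n_lat < 2) {
    abort_invalid("`n_lon` and `n_lat` must both be >= 2.")
  }
  n_lon <- as.integer(n_lon); n_lat <- as.integer(n_lat)
  grid <- tidyr::expand_grid(row = seq_len(n_lat), col = seq_len(n_lon)) %>%
    mutate(cell_id = row_number(),
           lon = lon0 + (.data$col - 0.5) * cell_size,
           lat = lat0 + (.data$row - 0.5) * cell_size) %>%
    select("cell_id", "col", "row", "lon", "lat")
  # contiguous rectangular blocks: up to 4 lon chunks x 2 lat chunks,
  # the spare 8th block merged into its vertical neighbour
  ny <- if (n_lat >= 2 && n_regions > 1) 2L else 1L
  nx <- max(1L, min(n_lon, as.integer(ceiling(min(n_regions, 7L) / ny))))
  bx <- pmin(ceiling(grid$col / (n_lon / nx)), nx)
  by <- pmin(ceiling(grid$row / (n_lat / ny)), ny)
  block <- (by - 1L) * nx + bx
  block[block > 7L] <- block[block > 7L] - nx  # merge into vertical neighbour
  grid$region <- factor(paste0("R", block))
  grid$forest_fraction <- smooth_field(grid, spawn_seeds(seed, 2L)[2], 0.05, 0.95)
  grid
}

#' Generate synthetic monthly climate for a grid
#'
#' Temperature is a latitude-dependent baseline plus a sinusoidal seasonal
#' cycle, an optional linear warming trend, and Gaussian noise; northern
#' winters drop below 0 degrees C so the frozen-month PET branch is
#' exercised. Precipitation is drawn from seasonal gamma distributions whose
#' scale is modulated by a per-cell AR(1) wetness anomaly (so multi-month
#' droughts occur), a smooth spatial aridity surface, and an optional drying
#' trend; all precipitation is non-negative.
#'
#' @param grid Grid tibble from [gen_grid()].
#' @param years Number of years to simulate (>= 1; >= 30 recommended when the
#'   output feeds SPEI calibration).
#' @param start_year First calendar year.
#' @param warming Temperature trend (degrees C per decade).
#' @param drying Fractional precipitation decline per decade (negative values
#'   give a wetting trend).
#' @param ar1 Lag-1 autocorrelation of the wetness anomaly.
#' @param seed Integer seed.
#' @return Tibble `cell_id`, `lon`, `lat`, `year`, `month`, `tas`, `pr`,
#'   `wet_anom`.
#' @export
gen_climate <- function(grid, years, start_year = 1990L, warming = 0,
                        drying = 0, ar1 = 0.8, seed = 1L) {
  if (!is.numeric(years) || length(years) != 1L || years < 1) {
    abort_invalid("`years` must be a positive number of years.")
  }
  years <- as.integer(years)
  seeds <- spawn_seeds(seed, 3L)
  n_cells <- nrow(grid)
  n_m <- 12L * years
  month <- rep(1:12, years)
  year <- rep(start_year + seq_len(years) - 1L, each = 12L)
  t_dec <- (seq_len(n_m) - 0.5) / 120  # decades since start
  season <- cos(2 * pi * (month - 7) / 12)

  lat <- grid$lat
  v <- (lat - min(lat)) / max(diff(range(lat)), 1e-9)  # 0 south .. 1 north
  t_base <- 26 - 18 * v            # warm south, cool north
  t_amp <- 6 + 10 * v              # continental north: winters below 0 C
  tas <- with_seed(seeds[1], {
    outer(rep(1, n_m), t_base) + outer(season, t_amp) +
      warming * t_dec + matrix(rnorm(n_m * n_cells, 0, 0.8), n_m, n_cells)
  })

  aridity <- smooth_field(grid, seeds[2], 0.5, 1.4)  # multiplicative wetness
  pr_mu <- outer(55 * (1 + 0.8 * season), aridity)   # mm/month, summer peak
  trend_mult <- (1 - drying)^t_dec

  gen <- with_seed(seeds[3], {
    z <- matrix(0, n_m, n_cells)
    z[1, ] <- rnorm(n_cells)
    innov <- matrix(rnorm(n_m * n_cells, 0, sqrt(1 - ar1^2)), n_m, n_cells)
    for (t in 2:n_m) z[t, ] <- ar1 * z[t - 1, ] + innov[t, ]
    shape <- 4
    pr <- matrix(rgamma(n_m * n_cells, shape = shape,
                        scale = as.vector(pr_mu * exp(0.6 * z) * trend_mult) / shape),
                 n_m, n_cells)
    list(z = z, pr = pr)
  })

  tibble(cell_id = rep(grid$cell_id, each = n_m),
         lon = rep(grid$lon, each = n_m),
         lat = rep(grid$lat, each = n_m),
         year = rep(year, n_cells),
         month = rep(month, n_cells),
         tas = as.vector(tas),
         pr = as.vector(gen$pr),
         wet_anom = as.vector(gen$z))
}

#' Generate smooth static covariates for a grid
#'
#' Elevation, slope, tree cover, terrain roughness, road and river network
#' densities and population density as spatially smooth, positively bounded
#' surfaces.
#'
#' @param grid Grid tibble from [gen_grid()].
#' @param seed Integer seed.
#' @return Tibble keyed by `cell_id` with one column per covariate.
#' @export
gen_covariates <- function(grid, seed = 1L) {
  s <- spawn_seeds(seed, 7L)
  tibble(
    cell_id = grid$cell_id,
    elevation = smooth_field(grid, s[1], 50, 2800),
    slope = smooth_field(grid, s[2], 0.5, 28),
    tree_cover = smooth_field(grid, s[3], 0.05, 0.9),
    roughness = smooth_field(grid, s[4], 5, 900),
    road_density = smooth_field(grid, s[5], 0.02, 1.6),
    river_density = smooth_field(grid, s[6], 0.01, 0.8),
    population_density = smooth_field(grid, s[7], 1, 400)
  )
}

#' Planted spatially varying coefficient surfaces
#'
#' Ground truth for recovery tests of geographically weighted logistic
#' fits. The first predictor's coefficient varies smoothly with latitude and
#' flips sign across the middle of the domain (promoting in the south,
#' inhibiting in the north); remaining predictors get small smooth surfaces.
#'
#' @param grid Grid tibble from [gen_grid()].
#' @param predictors Character vector of predictor names.
#' @param effect_size Magnitude of the first predictor's coefficient at the
#'   domain edges (on normalized predictors).
#' @param intercept Baseline log-odds at predictor value 0.5.
#' @param seed Integer seed (used only for the minor predictor surfaces).
#' @return Tibble `cell_id`, `(Intercept)`, one column per predictor.
#' @export
gen_true_model <- function(grid, predictors, effect_size = 5, intercept = -1,
                           seed = 1L) {
  if (length(predictors) < 1) abort_invalid("need at least one predictor.")
  lat_mid <- mean(range(grid$lat))
  half <- max(diff(range(grid$lat)) / 2, 1e-9)
  beta1 <- effect_size * (lat_mid - grid$lat) / half
  out <- tibble(cell_id = grid$cell_id,
                `(Intercept)` = intercept - 0.5 * beta1)
  out[[predictors[1]]] <- beta1
  if (length(predictors) > 1) {
    s <- spawn_seeds(seed, length(predictors))
    for (j in seq_along(predictors)[-1]) {
      # static-covariate effects on the scale of regional mean local
      # coefficients reported for fire-occurrence GWLR fits (|beta| ~ 3 on
      # normalized predictors)
      out[[predictors[j]]] <- smooth_field(grid, s[j], -3, 3)
    }
  }
  out
}

#' Generate point fire records from per-cell occurrence probabilities
#'
#' Each cell-year is a fire-year with its cell's probability; every fire-year
#' emits at least one point record uniformly placed inside the cell. The
#' empirical per-cell fraction of fire-years converges to `fp_true` as the
#' number of years grows.
#'
#' @param grid Grid tibble from [gen_grid()].
#' @param fp_true Per-cell annual fire probability: a single value or a
#'   vector aligned with `grid$cell_id`, all in `[0, 1]`.
#' @param years Integer vector of calendar years to simulate.
#' @param seed Integer seed.
#' @param cell_size Cell edge length (degrees), matching the grid.
#' @return Tibble `lon`, `lat`, `year`, `month`, `day` (one row per record).
#' @export
gen_fire_records <- function(grid, fp_true, years, seed = 1L, cell_size = 0.5) {
  if (length(fp_true) == 1L) fp_true <- rep(fp_true, nrow(grid))
  if (length(fp_true) != nrow(grid)) {
    abort_invalid("`fp_true` must have one probability per grid cell.")
  }
  if (any(!is.finite(fp_true)) || any(fp_true < 0) || any(fp_true > 1)) {
    abort_invalid("`fp_true` must lie in [0, 1].")
  }
  years <- as.integer(years)
  with_seed(seed, {
    n_cells <- nrow(grid)
    fire <- matrix(rbinom(n_cells * length(years), 1L, rep(fp_true, length(years))),
                   n_cells, length(years))
    idx <- which(fire == 1L, arr.ind = TRUE)
    if (nrow(idx) == 0L) {
      return(tibble(lon = double(), lat = double(), year = integer(),
                    month = integer(), day = integer()))
    }
    n_rec <- 1L + stats::rpois(nrow(idx), 0.6)
    cell <- rep(idx[, 1], n_rec)
    yr <- rep(years[idx[, 2]], n_rec)
    tibble(
      lon = grid$lon[cell] + runif(length(cell), -0.5, 0.5) * cell_size,
      lat = grid$lat[cell] + runif(length(cell), -0.5, 0.5) * cell_size,
      year = yr,
      month = sample(1:12, length(cell), replace = TRUE),
      day = sample(1:28, length(cell), replace = TRUE)
    ) %>% arrange(.data$year, .data$lon, .data$lat)
  })
}
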