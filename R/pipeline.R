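# Orchestration: a validated configuration drives the whole synthetic study
# end to end (simulate -> spei -> drought -> features -> fit -> evaluate ->
# project), with all randomness flowing from the config seed.

#' Build and validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list, fills defaults, and validates
#' the fields every stage relies on: thresholds must be negative, scales a
#' subset of {1, 3, 6, 12}, periods non-overlapping, and any numeric
#' bandwidth at least the predictor count plus two. Validation happens
#' before any computation.
#'
#' @param config Path to a YAML file or a named list of overrides.
#' @return Validated config list of class `fire_config`.
#' @export
fire_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort_invalid("`config` must be a list or a YAML file path.")
  defaults <- list(
    seed = 1L,
    grid = list(n_lon = 8L, n_lat = 8L, lon0 = 100, lat0 = 20, cell_size = 0.5),
    climate_start = 1990L,
    scales = c(1L, 3L, 6L, 12L),
    thresholds = c(-0.5, -1),
    min_duration = 3L,
    calibration = "full",
    response = "binomial",
    bandwidth = "auto",
    effect_size = 6,
    forest_mask_threshold = 0.5,
    scenarios = list(SSP126 = -0.05, SSP245 = 0.0, SSP370 = 0.04, SSP585 = 0.08),
    n_members = 3L,
    periods = NULL
  )
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$periods)) cfg$periods <- study_periods()
  cfg$periods <- as_tibble(cfg$periods)

  if (any(cfg$thresholds >= 0)) abort_invalid("all `thresholds` must be negative.")
  if (!all(cfg$scales %in% c(1L, 3L, 6L, 12L))) {
    abort_invalid("`scales` must be a subset of {1, 3, 6, 12}.")
  }
  p <- cfg$periods[order(cfg$periods$start_year), ]
  if (any(p$end_year < p$start_year)) abort_invalid("period end before start.")
  if (nrow(p) > 1 && any(head(p$end_year, -1) >= tail(p$start_year, -1))) {
    abort_invalid("periods overlap.")
  }
  if (!identical(cfg$bandwidth, "auto")) {
    n_pred <- 7L + 3L  # static covariates + retained PCs (upper bound 3)
    if (!is.numeric(cfg$bandwidth) || cfg$bandwidth < n_pred + 2L) {
      abort_invalid(sprintf("numeric `bandwidth` must be >= %d (predictors + 2).",
                            n_pred + 2L))
    }
  }
  if (!cfg$response %in% c("binomial", "binary")) {
    abort_invalid("`response` must be 'binomial' or 'binary'.")
  }
  structure(cfg, class = c("fire_config", "list"))
}

STATIC_VARS <- c("elevation", "slope", "tree_cover", "roughness",
                 "road_density", "river_density", "population_density")

#' Simulate a complete drought-to-fire study
#'
#' Generates every input of the analysis with known ground truth: grid and
#' static covariates, historical monthly climate, SPEI at one scale, drought
#' events and historical characteristics, PCA scores and min-max
#' normalization, a planted spatially varying coefficient field on the first
#' drought component (promoting in the south, inhibiting in the north), the
#' implied per-cell fire probability, and Bernoulli fire records over the
#' historical plus test years.
#'
#' @param n_lon,n_lat Grid dimensions.
#' @param seed Master seed; per-stream seeds are spawned from it.
#' @param scale SPEI accumulation scale for the planted signal.
#' @param threshold Drought threshold for the planted signal.
#' @param effect_size Magnitude of the planted PC1 coefficient at the
#'   north/south edges.
#' @param train_years,test_years Calendar-year windows for model fitting and
#'   holdout evaluation.
#' @param climate_start First simulated climate year (enough spin-up to
#'   calibrate the SPEI).
#' @return List with the generated `grid`, `covariates`, `climate`, `spei`,
#'   `events`, `chars` (historical characteristics), `pca`, `norm`,
#'   `features` (normalized modelling table), `truth` (coefficient
#'   surfaces), `fp_true`, `records`, and the `predictors` name vector.
#' @export
simulate_fire_study <- function(n_lon = 10L, n_lat = 10L, seed = 1L,
                                scale = 3L, threshold = -0.5, effect_size = 6,
                                train_years = 2000:2019, test_years = 2020:2021,
                                climate_start = 1990L) {
  seeds <- spawn_seeds(seed, 5L)
  grid <- gen_grid(n_lon, n_lat, seed = seeds[1])
  covars <- gen_covariates(grid, seed = seeds[2])
  n_years <- max(test_years) - climate_start + 1L
  climate <- gen_climate(grid, years = n_years, start_year = climate_start,
                         seed = seeds[3])
  spei <- compute_spei(climate, scales = scale)
  events <- drought_events(spei, thresholds = threshold)
  hist_period <- tibble(period = "historical",
                        start_year = min(train_years),
                        end_year = max(train_years))
  chars <- summarize_period(events, hist_period, cells = grid$cell_id)
  pca <- pca_fit(chars)
  pc_cols <- paste0("PC", seq_len(pca$n_retained))
  scored <- pca_apply(pca, chars)
  features <- covars %>%
    inner_join(scored[, c("cell_id", pc_cols)], by = "cell_id")
  norm <- minmax_fit(features, c(STATIC_VARS, pc_cols))
  features <- minmax_apply(features, norm) %>%
    inner_join(grid[, c("cell_id", "lon", "lat", "region")], by = "cell_id")
  predictors <- c(pc_cols, "tree_cover", "population_density", "roughness")
  truth <- gen_true_model(grid, predictors, effect_size = effect_size,
                          intercept = -1, seed = seeds[4])
  Xb <- truth[["(Intercept)"]]
  for (v in predictors) Xb <- Xb + truth[[v]] * features[[v]]
  fp_true <- plogis(Xb)
  records <- gen_fire_records(grid, fp_true,
                              years = c(train_years, test_years),
                              seed = seeds[5])
  list(grid = grid, covariates = covars, climate = climate, spei = spei,
       events = events, chars = chars, pca = pca, norm = norm,
       features = features, truth = truth, fp_true = fp_true,
       records = records, predictors = predictors,
       scale = scale, threshold = threshold,
       train_years = train_years, test_years = test_years)
}

#' Run the full pipeline from a configuration
#'
#' Executes the stages in order on synthetic data: simulate the study, fit
#' the geographically weighted logistic model on historical fire-year
#' fractions, evaluate on the held-out window, then (optionally) generate
#' future-scenario climate ensembles, recompute drought characteristics per
#' scenario and period, and project forest-masked regional probability
#' changes. Rerunning with an unchanged config reproduces every artifact.
#'
#' @param config A `fire_config` (or anything [fire_config()] accepts).
#' @param project Also run the future-scenario projection stage (slower).
#' @return List with `study`, `fp_obs`, `model`, `bandwidth`, `evaluation`,
#'   and (if `project`) `projection` keyed by scenario and period.
#' @export
run_fire_pipeline <- function(config = fire_config(), project = FALSE) {
  cfg <- fire_config(unclass(config))
  study <- simulate_fire_study(
    n_lon = cfg$grid$n_lon, n_lat = cfg$grid$n_lat, seed = cfg$seed,
    scale = cfg$scales[1], threshold = cfg$thresholds[1],
    effect_size = cfg$effect_size, climate_start = cfg$climate_start)

  train_years <- study$train_years
  fp_obs <- estimate_fp(study$records, study$grid, train_years,
                        cell_size = cfg$grid$cell_size)
  mdl_data <- study$features %>% inner_join(fp_obs, by = "cell_id")
  if (cfg$response == "binary") {
    mdl_data <- mutate(mdl_data,
                       n_fire_years = as.integer(.data$n_fire_years > 0L),
                       n_years = 1L)
  }
  if (identical(cfg$bandwidth, "auto")) {
    sel <- select_bandwidth(mdl_data, study$predictors,
                            successes = "n_fire_years", trials = "n_years")
    bw <- sel$bandwidth
  } else {
    bw <- cfg$bandwidth
  }
  model <- fit_gwlr(mdl_data, study$predictors, successes = "n_fire_years",
                    trials = "n_years", bandwidth = bw)
  evaluation <- evaluate_holdout(model, mdl_data, study$records, study$grid,
                                 study$test_years,
                                 cell_size = cfg$grid$cell_size)
  out <- list(config = cfg, study = study, fp_obs = fp_obs, model = model,
              bandwidth = bw, evaluation = evaluation)
  if (!project) return(out)

  fp_hist <- tibble(cell_id = mdl_data$cell_id,
                    fp = as.numeric(stats::predict(model, mdl_data)))
  future_periods <- cfg$periods %>%
    filter(.data$period %in% c("near", "medium", "long"))
  pc_cols <- paste0("PC", seq_len(study$pca$n_retained))
  static <- study$features[, c("cell_id", "lon", "lat",
                               setdiff(study$predictors, pc_cols))]
  member_seeds <- spawn_seeds(cfg$seed + 1L, cfg$n_members)
  projection <- purrr::imap(cfg$scenarios, function(drying, scen) {
    members <- purrr::map(seq_len(cfg$n_members), function(j) {
      gen_climate(study$grid, years = max(future_periods$end_year) - 2022L + 1L,
                  start_year = 2022L, drying = drying,
                  seed = member_seeds[j]) %>%
        mutate(model_tag = paste0("GCM", j))
    }) %>% bind_rows()
    mme <- ensemble_mean(members)
    spei_f <- compute_spei(mme, scales = study$scale)
    events_f <- drought_events(spei_f, thresholds = study$threshold)
    chars_f <- summarize_period(events_f, future_periods,
                                cells = study$grid$cell_id)
    purrr::map(future_periods$period, function(per) {
      fc <- filter(chars_f, .data$period == per)
      fp_fut <- project_fp(model, fc, static, study$pca, study$norm)
      d <- delta_fp(fp_fut, fp_hist, study$grid,
                    forest_mask_threshold = cfg$forest_mask_threshold)
      mutate(d$regions, scenario = scen, period = per)
    }) %>% bind_rows()
  }) %>% bind_rows()
  out$projection <- projection
  out
}
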