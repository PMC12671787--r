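test_that("the multi-model ensemble mean is an elementwise average", {
  g <- gen_grid(3, 3, seed = 1)
  base <- gen_climate(g, 2, seed = 2)
  m1 <- dplyr::mutate(base, model_tag = "A")
  m2 <- dplyr::mutate(base, model_tag = "B")
  mme <- ensemble_mean(dplyr::bind_rows(m1, m2))
  expect_equal(mme$tas, base$tas)                       # identical members
  expect_equal(mme$pr, base$pr)
  expect_true(all(mme$model_tag == "MME"))

  warm <- dplyr::mutate(base, tas = tas + 2, model_tag = "B")
  mme2 <- ensemble_mean(dplyr::bind_rows(m1, warm))
  expect_equal(mme2$tas, base$tas + 1)                  # linearity

  set.seed(44)
  members <- purrr::map(1:5, function(j) {
    dplyr::mutate(base, tas = tas + rnorm(nrow(base)),
                  pr = pmax(pr + rnorm(nrow(base), 0, 5), 0),
                  model_tag = paste0("M", j))
  })
  mme5 <- ensemble_mean(dplyr::bind_rows(members))
  oracle_tas <- Reduce(`+`, purrr::map(members, "tas")) / 5
  expect_equal(mme5$tas, oracle_tas, tolerance = 1e-12)

  short <- dplyr::bind_rows(m1, dplyr::mutate(base[1:12, ], model_tag = "C"))
  expect_error(ensemble_mean(short), regexp = "C",
               class = "droughtfire_invalid_argument")
})

test_that("projection with historical inputs reproduces the fitted model", {
  fit <- small_study_model()
  study <- fit$study
  pc_cols <- paste0("PC", seq_len(study$pca$n_retained))
  static <- fit$data[, c("cell_id", "lon", "lat",
                         setdiff(study$predictors, pc_cols))]
  fp_proj <- project_fp(fit$model, study$chars, static, study$pca, study$norm)
  fp_hist <- tibble::tibble(cell_id = fit$data$cell_id,
                            fp = as.numeric(predict(fit$model, fit$data)))
  expect_identical(fp_proj$fp, fp_hist$fp)              # bit-exact
  expect_true(all(fp_proj$fp > 0 & fp_proj$fp < 1))

  expect_error(project_fp(fit$model, study$chars, static, NULL, study$norm),
               class = "droughtfire_invalid_argument")
})

test_that("raising a positively weighted drought score raises FP", {
  fit <- small_study_model()
  study <- fit$study
  pc_cols <- paste0("PC", seq_len(study$pca$n_retained))
  static <- fit$data[, c("cell_id", "lon", "lat",
                         setdiff(study$predictors, pc_cols))]
  # perturb the characteristics along the PC1 loading direction so only the
  # PC1 score moves, and only where clipping cannot bind
  base_scores <- pca_apply(study$pca, study$chars)
  norm_pc1 <- study$norm[study$norm$variable == "PC1", ]
  headroom <- base_scores$PC1 < norm_pc1$xmax - 0.5 &
    base_scores$PC1 > norm_pc1$xmin + 0.1
  beta_pc1 <- fit$model$coefficients$PC1
  cell <- which(beta_pc1 > 0.2 & headroom)[1]
  skip_if(is.na(cell), "no unclipped cell with positive PC1 coefficient")
  bumped <- study$chars
  dirn <- study$pca$scale * study$pca$loadings[, 1]
  for (v in study$pca$vars) {
    bumped[[v]][cell] <- bumped[[v]][cell] + 0.4 * dirn[v]
  }
  fp0 <- project_fp(fit$model, study$chars, static, study$pca, study$norm)
  fp1 <- project_fp(fit$model, bumped, static, study$pca, study$norm)
  expect_gt(fp1$fp[fp1$cell_id == cell], fp0$fp[fp0$cell_id == cell])
})

test_that("probability deltas aggregate to forest-masked regional means", {
  g <- gen_grid(6, 6, seed = 3)
  fp_hist <- tibble::tibble(cell_id = g$cell_id, fp = runif(36, 0.1, 0.6))
  same <- delta_fp(fp_hist, fp_hist, g, forest_mask_threshold = 0.2)
  expect_true(all(same$cells$delta == 0))
  expect_true(all(same$regions$mean_delta_pp[same$regions$n_masked > 0] == 0))

  shifted <- dplyr::mutate(fp_hist, fp = fp + 0.05)
  d <- delta_fp(shifted, fp_hist, g, forest_mask_threshold = 0.2)
  ok <- d$regions$n_masked > 0
  expect_equal(d$regions$mean_delta_pp[ok], rep(5, sum(ok)), tolerance = 1e-9)
  expect_true(all(abs(d$cells$delta) < 1))
  # regional means bounded by per-cell extrema
  expect_true(all(d$regions$mean_delta_pp[ok] / 100 >= min(d$cells$delta) - 1e-12))
  expect_true(all(d$regions$mean_delta_pp[ok] / 100 <= max(d$cells$delta) + 1e-12))

  expect_warning(empty <- delta_fp(shifted, fp_hist, g, forest_mask_threshold = 1),
                 "empty forest mask")
  expect_true(all(is.na(empty$regions$mean_delta_pp)))
})

test_that("monotone drying across scenarios orders the drought summaries", {
  g <- gen_grid(4, 4, seed = 5)
  mdn <- vapply(c(0, 0.06, 0.12), function(drying) {
    cl <- gen_climate(g, 45, start_year = 1981, drying = drying, seed = 17)
    sp <- suppressWarnings(compute_spei(cl, scales = 1L,
                                        calibration = c(1981, 2000)))
    ev <- drought_events(sp, thresholds = -0.5)
    sm <- summarize_period(ev, tibble::tibble(period = "late",
                                              start_year = 2006L,
                                              end_year = 2025L),
                           cells = g$cell_id)
    mean(sm$MDN)
  }, numeric(1))
  expect_true(all(diff(mdn) > 0))
})
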