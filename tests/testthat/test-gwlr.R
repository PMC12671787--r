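test_that("great-circle distance is a proper haversine metric", {
  expect_equal(great_circle_km(12, 34, 12, 34), 0)
  # 1 degree of longitude at the equator: 2*pi*6371/360
  expect_equal(great_circle_km(0, 0, 1, 0), 2 * pi * 6371 / 360, tolerance = 1e-4)
  set.seed(42)
  lon <- runif(100, -180, 180); lat <- runif(100, -89, 89)
  lon2 <- runif(100, -180, 180); lat2 <- runif(100, -89, 89)
  expect_equal(great_circle_km(lon, lat, lon2, lat2),
               great_circle_km(lon2, lat2, lon, lat))
  skip_if_not_installed("geosphere")
  expect_equal(great_circle_km(lon, lat, lon2, lat2),
               geosphere::distHaversine(cbind(lon, lat), cbind(lon2, lat2),
                                        r = 6371000) / 1000,
               tolerance = 1e-9)
  expect_error(great_circle_km(0, 95, 0, 0), class = "droughtfire_invalid_argument")
})

test_that("the adaptive bi-square kernel has its closed-form shape", {
  expect_equal(bisquare_kernel(0, 10), 1)
  expect_equal(bisquare_kernel(5, 10), 0.5625)
  expect_equal(bisquare_kernel(10, 10), 0)
  D <- dist_matrix_km(c(0, 1, 2, 5), c(0, 0, 0, 0))
  W <- bisquare_weights(D, 3)
  expect_equal(diag(W), rep(1, 4))
  expect_true(all(W >= 0 & W <= 1))
  # the 3rd-nearest neighbour (self included) sits exactly on the kernel
  # boundary, where the weight is 0, so each row has < 3 non-zero weights
  expect_equal(unname(rowSums(W > 0)), c(2, 1, 2, 2))
  expect_error(bisquare_weights(D, 5), class = "droughtfire_invalid_argument")
})

test_that("AIC and its small-sample correction follow the printed formulas", {
  ic <- aicc(-100, 5, 50)
  expect_equal(ic$aic, 210)
  expect_equal(ic$aicc, 210 + 60 / 44)
  expect_equal(aicc(-100, 0, 50)$aicc, aicc(-100, 0, 50)$aic)
  expect_equal(aicc(-100, 5, 1e9)$aicc, aicc(-100, 5, 1e9)$aic, tolerance = 1e-6)
  expect_error(aicc(-100, 5, 6), class = "droughtfire_invalid_argument")
})

glm_oracle <- function(data, predictors, successes = "successes", trials = "trials") {
  f <- stats::reformulate(predictors,
                          response = sprintf("cbind(%s, %s - %s)", successes, trials, successes))
  stats::glm(f, stats::binomial(), data)
}

test_that("global logistic IRLS agrees with an independent fitter", {
  # symmetric balanced design: the intercept must vanish
  sym <- tibble::tibble(x = c(1, 1, -1, -1), successes = c(15L, 15L, 5L, 5L),
                        trials = 20L)
  m <- fit_glr(sym, "x")
  expect_lt(abs(m$coefficients["(Intercept)"]), 1e-6)

  # simulation from known coefficients: recovery within 3 standard errors
  set.seed(7)
  n <- 1000L
  dat <- tibble::tibble(x = runif(n), trials = 20L)
  dat$successes <- rbinom(n, dat$trials, plogis(-1 + 2 * dat$x))
  m <- fit_glr(dat, "x")
  g <- glm_oracle(dat, "x")
  se <- sqrt(diag(vcov(g)))
  expect_lt(abs(m$coefficients[1] - (-1)), 3 * se[1])
  expect_lt(abs(m$coefficients[2] - 2), 3 * se[2])
  expect_equal(unname(m$coefficients), unname(coef(g)), tolerance = 1e-7)
  expect_equal(m$logL, as.numeric(logLik(g)), tolerance = 1e-9)

  # Bernoulli reduction matches glm's deviance
  bern <- tibble::tibble(x = rnorm(400), trials = 1L)
  bern$successes <- rbinom(400, 1L, plogis(0.5 * bern$x))
  mb <- fit_glr(bern, "x")
  gb <- glm_oracle(bern, "x")
  # the saturated Bernoulli log-likelihood is 0, so deviance = -2 logL
  expect_equal(-2 * mb$logL, deviance(gb), tolerance = 1e-6)
  expect_equal(unname(mb$coefficients), unname(coef(gb)), tolerance = 1e-7)

  expect_error(fit_glr(tibble::tibble(x = 1:4, successes = 0L, trials = 5L), "x"),
               class = "droughtfire_invalid_argument")
})

test_that("GWLR at infinite bandwidth collapses to the global model", {
  set.seed(11)
  g <- gen_grid(6, 6, seed = 2)
  dat <- dplyr::mutate(g, x1 = runif(36), trials = 20L,
                       successes = rbinom(36, 20L, plogis(-0.5 + x1)))
  glr <- fit_glr(dat, "x1")
  gw <- fit_gwlr(dat, "x1", bandwidth = Inf)
  B <- as.matrix(gw$coefficients[, c("(Intercept)", "x1")])
  expect_lt(max(abs(sweep(B, 2, glr$coefficients))), 1e-6)
  expect_equal(gw$k, glr$k, tolerance = 1e-6)
})

test_that("local fits are invariant to cell ordering", {
  set.seed(12)
  g <- gen_grid(6, 6, seed = 3)
  dat <- dplyr::mutate(g, x1 = runif(36), trials = 20L,
                       successes = rbinom(36, 20L, plogis(-0.5 + 2 * x1)))
  m1 <- fit_gwlr(dat, "x1", bandwidth = 15)
  perm <- sample(36)
  m2 <- fit_gwlr(dat[perm, ], "x1", bandwidth = 15)
  c1 <- dplyr::arrange(m1$coefficients, cell_id)
  c2 <- dplyr::arrange(m2$coefficients, cell_id)
  expect_equal(c1$x1, c2$x1, tolerance = 1e-10)
  expect_equal(m1$logL, m2$logL, tolerance = 1e-10)
  expect_equal(m1$k, m2$k, tolerance = 1e-8)
})

test_that("GWLR recovers a planted sign-flipping coefficient surface", {
  set.seed(13)
  g <- gen_grid(10, 10, seed = 4)
  truth <- gen_true_model(g, "x1", effect_size = 5, intercept = -1)
  dat <- dplyr::mutate(g, x1 = runif(100), trials = 20L)
  dat$successes <- rbinom(100, 20L, plogis(truth$`(Intercept)` + truth$x1 * dat$x1))
  m <- fit_gwlr(dat, "x1", bandwidth = 30)
  expect_gt(cor(m$coefficients$x1, truth$x1), 0.7)
  expect_gt(mean(sign(m$coefficients$x1) == sign(truth$x1)), 0.85)
  # in-sample likelihood of the local model dominates the global one
  glr <- fit_glr(dat, "x1")
  expect_gte(m$logL, glr$logL)
  # the AICc identity holds exactly for the reported diagnostics
  expect_equal(m$aicc, m$aic + 2 * m$k * (m$k + 1) / (m$m - m$k - 1))
})

test_that("bandwidth selection minimizes AICc deterministically", {
  set.seed(14)
  g <- gen_grid(7, 7, seed = 5)
  n <- nrow(g)
  truth <- gen_true_model(g, "x1", effect_size = 5, intercept = -1)
  dat <- dplyr::mutate(g, x1 = runif(n), trials = 20L)
  dat$successes <- rbinom(n, 20L, plogis(truth$`(Intercept)` + truth$x1 * dat$x1))
  sel <- select_bandwidth(dat, "x1", range = c(8, n))
  expect_lte(sel$aicc, sel$trace$aicc[sel$trace$bandwidth == 8])
  expect_lte(sel$aicc, sel$trace$aicc[sel$trace$bandwidth == n])
  sel2 <- select_bandwidth(dat, "x1", range = c(8, n))
  expect_identical(sel$bandwidth, sel2$bandwidth)

  # spatially homogeneous data prefers the global end of the range
  hom <- dplyr::mutate(g, x1 = runif(n), trials = 20L,
                       successes = rbinom(n, 20L, plogis(-0.5 + 1.5 * x1)))
  sel_h <- select_bandwidth(hom, "x1", range = c(20, n), method = "grid")
  expect_equal(sel_h$bandwidth, n)
})

test_that("predictions invert the logit and honour stored local fits", {
  set.seed(15)
  g <- gen_grid(6, 6, seed = 6)
  dat <- dplyr::mutate(g, x1 = runif(36), trials = 20L,
                       successes = rbinom(36, 20L, plogis(-0.5 + 2 * x1)))
  glr <- fit_glr(dat, "x1")
  p <- predict(glr, dat)
  expect_true(all(p > 0 & p < 1))
  eta <- drop(cbind(1, dat$x1) %*% glr$coefficients)
  expect_equal(qlogis(p), eta, tolerance = 1e-12)
  # a zero linear predictor maps to probability one half
  z <- tibble::tibble(x1 = -glr$coefficients[1] / glr$coefficients[2])
  expect_equal(unname(predict(glr, z)), 0.5, tolerance = 1e-12)

  gw <- fit_gwlr(dat, "x1", bandwidth = 15)
  expect_equal(unname(predict(gw, dat)), gw$fitted, tolerance = 1e-10)
  # off-grid locations are refit locally and stay in (0, 1)
  new <- tibble::tibble(lon = 101.13, lat = 20.87, x1 = 0.5)
  p_new <- predict(gw, new)
  expect_true(p_new > 0 && p_new < 1)
  expect_warning(predict(gw, dplyr::mutate(dat, x1 = x1 * 100)), "outside")
})

test_that("tidiers and regional summaries expose the fit in tidy form", {
  set.seed(16)
  g <- gen_grid(5, 5, seed = 7)
  dat <- dplyr::mutate(g, x1 = runif(25), trials = 20L,
                       successes = rbinom(25, 20L, plogis(-0.5 + x1)))
  gw <- fit_gwlr(dat, "x1", bandwidth = 12)
  td <- tidy(gw)
  expect_equal(nrow(td), 25 * 2)
  expect_setequal(unique(td$term), c("(Intercept)", "x1"))
  gl <- glance(gw)
  expect_equal(gl$bandwidth, 12)
  rc <- regional_coefficients(gw)
  expect_setequal(as.character(unique(rc$region)), as.character(unique(g$region)))
  # regional means are plain arithmetic means of the local coefficients
  r1 <- as.character(g$region[1])
  manual <- mean(gw$coefficients$x1[as.character(g$region) == r1])
  expect_equal(rc$mean_coef[rc$region == r1 & rc$term == "x1"], manual)
})
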