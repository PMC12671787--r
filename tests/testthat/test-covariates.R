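test_that("terrain and network covariates follow their defining formulas", {
  expect_equal(surface_roughness(rep(500, 5)), 0)
  expect_equal(surface_roughness(c(100, 250, 175)), 150)
  expect_equal(surface_roughness(723.5), 0)
  expect_error(surface_roughness(numeric(0)), class = "droughtfire_invalid_argument")

  expect_equal(network_density(0, 4), 0)
  expect_equal(network_density(10, 4), 2.5)
  expect_equal(network_density(7, 7), 1)
  expect_error(network_density(10, 0), class = "droughtfire_invalid_argument")
})

test_that("min-max normalization is affine, order-preserving, and clips", {
  df <- tibble::tibble(x = c(2, 5, 8), y = c(-1, 0, 3))
  par <- minmax_fit(df, c("x", "y"))
  out <- minmax_apply(df, par)
  expect_equal(out$x, c(0, 0.5, 1))
  expect_equal(out$y, c(0, 0.25, 1))
  # order preservation on random data
  set.seed(9)
  z <- tibble::tibble(x = rnorm(50))
  zn <- minmax_apply(z, minmax_fit(z, "x"))
  expect_equal(order(zn$x), order(z$x))
  # future values outside the training range clip to [0, 1]
  fut <- minmax_apply(tibble::tibble(x = c(18, -5), y = c(1, 1)), par)
  expect_equal(fut$x, c(1, 0))

  expect_error(minmax_fit(tibble::tibble(x = rep(4, 3)), "x"),
               regexp = "`x`", class = "droughtfire_invalid_argument")
})

test_that("VIF matches an explicit least-squares oracle", {
  # orthogonal predictors carry no mutual information
  X <- tibble::tibble(a = rep(c(-1, 1), 10), b = rep(c(-1, -1, 1, 1), 5),
                      c = rnorm(20))
  X$c <- resid(lm(c ~ a + b, X))  # orthogonalize the third column
  v <- vif_table(X)
  expect_equal(v$vif, rep(1, 3), tolerance = 1e-10)

  # exact linear dependence reports unbounded VIF, not a crash
  dup <- tibble::tibble(a = rnorm(20), b = rnorm(20))
  dup$c <- dup$a
  vd <- vif_table(dup)
  expect_true(all(is.infinite(vd$vif[c(1, 3)])))
  expect_true(all(vd$flagged[c(1, 3)]))

  # fixed correlated design vs normal-equation oracle
  set.seed(77)
  z <- rnorm(50)
  M <- tibble::tibble(x1 = z + rnorm(50, 0, 0.33),
                      x2 = z + rnorm(50, 0, 0.33),
                      x3 = rnorm(50))
  expect_gt(cor(M$x1, M$x2), 0.85)
  expect_equal(vif_table(M)$vif, normal_equation_vif(as.matrix(M)),
               tolerance = 1e-10)
})

test_that("PCA retains >= 90% variance with orthonormal, sign-fixed loadings", {
  set.seed(55)
  n <- 60
  base <- rnorm(n)
  chars <- tibble::tibble(MDN = rnorm(n),
                          MDD = 3 + 2 * base + rnorm(n, 0, 0.2),
                          MDS = -4 - 3 * base + rnorm(n, 0, 0.2),
                          MDI = -0.8 - 0.2 * base + rnorm(n, 0, 0.1))
  pc <- pca_fit(chars)
  L <- pc$loadings
  expect_equal(crossprod(L), diag(4), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(pc$prop_var), 100, tolerance = 1e-10)
  expect_true(all(diff(pc$prop_var) <= 1e-12))
  expect_gte(pc$cum_var[pc$n_retained], 90)
  for (j in 1:4) expect_gt(L[which.max(abs(L[, j])), j], 0)

  # two perfectly correlated variables: one component carries everything
  two <- tibble::tibble(MDD = base, MDS = -2 * base + 1)
  pc2 <- pca_fit(two, vars = c("MDD", "MDS"))
  expect_equal(pc2$prop_var[1], 100, tolerance = 1e-10)

  expect_error(pca_fit(dplyr::mutate(chars, MDI = 1)),
               class = "droughtfire_invalid_argument")
})

test_that("PCA projection is exact, centred, and invertible", {
  set.seed(56)
  chars <- tibble::tibble(MDN = rnorm(30, 1), MDD = rnorm(30, 5),
                          MDS = rnorm(30, -4), MDI = rnorm(30, -1))
  pc <- pca_fit(chars)
  tr <- pca_apply(pc, chars, all_components = TRUE)
  # training round-trip reproduces prcomp scores exactly (up to fixed signs)
  expect_identical(pca_apply(pc, chars), pca_apply(pc, chars))
  # a row at the stored means scores 0 on every component
  mu <- tibble::tibble(MDN = pc$center["MDN"], MDD = pc$center["MDD"],
                       MDS = pc$center["MDS"], MDI = pc$center["MDI"])
  expect_equal(unlist(pca_apply(pc, mu, all_components = TRUE)[, 5:8]),
               rep(0, 4), ignore_attr = TRUE)
  # reconstruction from all components recovers the standardized input
  S <- as.matrix(tr[, paste0("PC", 1:4)])
  Z <- S %*% t(pc$loadings)
  Z_direct <- scale(as.matrix(chars), center = pc$center, scale = pc$scale)
  expect_equal(Z, Z_direct, tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(pca_apply(pc, tibble::tibble(MDN = 1)),
               class = "droughtfire_invalid_argument")
})

test_that("transform parameters survive a JSON round trip bit-for-bit", {
  set.seed(57)
  chars <- tibble::tibble(MDN = rnorm(30, 1), MDD = rnorm(30, 5),
                          MDS = rnorm(30, -4), MDI = rnorm(30, -1))
  pc <- pca_fit(chars)
  nm <- minmax_fit(chars)
  path <- withr::local_tempfile(fileext = ".json")
  write_transform_params(nm, pc, path)
  back <- read_transform_params(path)
  expect_identical(pca_apply(back$pca, chars), pca_apply(pc, chars))
  expect_identical(minmax_apply(chars, back$minmax), minmax_apply(chars, nm))
})
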