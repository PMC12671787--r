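# Independent oracles and shared fixtures. Oracles are deliberately written
# with different algorithms than the implementation (index-walking scanners,
# all-pairs counting, explicit normal equations) so agreement is evidence,
# not tautology.

# Walk the series index by index and emit every maximal qualifying run.
brute_force_events <- function(spei, threshold, min_duration = 3) {
  n <- length(spei)
  out <- data.frame(start = integer(), end = integer(),
                    DD = integer(), DS = double(), DI = double())
  i <- 1L
  while (i <= n) {
    if (!is.na(spei[i]) && spei[i] <= threshold) {
      j <- i
      while (j + 1L <= n && !is.na(spei[j + 1L]) && spei[j + 1L] <= threshold) {
        j <- j + 1L
      }
      if (j - i + 1L >= min_duration) {
        ds <- sum(spei[i:j])
        out <- rbind(out, data.frame(start = i, end = j + 1L, DD = j - i + 1L,
                                     DS = ds, DI = ds / (j - i + 1L)))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# All-pairs AUC: concordant pairs plus half credit for ties.
pair_counting_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# VIF via explicit normal equations (no lm()).
normal_equation_vif <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    beta <- solve(crossprod(Z), crossprod(Z, y))
    res <- y - Z %*% beta
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    1 / (1 - r2)
  }, numeric(1))
}

# Rolling-window sum by explicit windows.
window_sum_oracle <- function(d, k) {
  n <- length(d)
  out <- rep(NA_real_, n)
  for (t in k:n) out[t] <- sum(d[(t - k + 1):t])
  out
}

# Water-balance sample with frozen PWM log-logistic oracle values
# (computed with an independent numpy implementation before the build).
LL_FIXTURE <- c(13.38, 3.328, -2.737, 15.661, -3.948, 33.738, 17.445, 12.219,
                -27.04, -37.003, -25.284, 19.502, 11.492, -31.043, 19.1,
                -13.486, -13.449, 52.685, 9.138, 15.803, 16.288, -31.393, 18,
                119.718, -23.675, 37.71, 42.719, 41.97, -9.618, -3.017,
                -23.384, 6.073, 66.517, -13.084, -39.565, 9.67, 43.031,
                0.104, 88.522, 2.307)
LL_SPEI_MAX <- 2.2786831
LL_SPEI_MIN <- -1.8310699

# Shared expensive fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

cached_fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

small_study <- function() {
  cached_fixture("small_study", function() {
    suppressWarnings(suppressMessages(simulate_fire_study(seed = 42L)))
  })
}

small_study_model <- function() {
  cached_fixture("small_study_model", function() {
    study <- small_study()
    fp <- suppressMessages(
      estimate_fp(study$records, study$grid, study$train_years))
    mdl_data <- dplyr::inner_join(study$features, fp, by = "cell_id")
    sel <- select_bandwidth(mdl_data, study$predictors,
                            successes = "n_fire_years", trials = "n_years")
    model <- fit_gwlr(mdl_data, study$predictors, successes = "n_fire_years",
                      trials = "n_years", bandwidth = sel$bandwidth)
    list(study = study, data = mdl_data, selection = sel, model = model)
  })
}
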