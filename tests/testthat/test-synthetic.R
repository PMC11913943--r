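test_that("covariate stacks are deterministic and span the elevation range", {
  p <- landscape_params(shape = c(60, 60), seed = 5)
  s1 <- generate_covariates(p)
  s2 <- generate_covariates(p)
  for (nm in names(s1)) expect_identical(s1[[nm]]$values, s2[[nm]]$values)
  expect_equal(min(s1$dem$values), 720, tolerance = 1e-6)
  expect_equal(max(s1$dem$values), 840, tolerance = 1e-6)
  for (nm in names(s1)) expect_true(is_aligned(s1[[nm]], s1$dem))
})

test_that("smoother landscapes have higher lag-1 spatial autocorrelation", {
  moran_lag1 <- function(m) {
    z <- m - mean(m)
    num <- sum(z[-nrow(z), ] * z[-1, ]) + sum(z[, -ncol(z)] * z[, -1])
    num / (2 * sum(z^2)) * length(z) / (length(z) - nrow(z) / 2 - ncol(z) / 2)
  }
  rough <- generate_covariates(landscape_params(shape = c(80, 80),
                                                smoothness = 1, seed = 2))
  smooth <- generate_covariates(landscape_params(shape = c(80, 80),
                                                 smoothness = 20, seed = 2))
  expect_gt(moran_lag1(smooth$dem$values), moran_lag1(rough$dem$values))
})

test_that("initial land cover hits requested class fractions", {
  p <- landscape_params(shape = c(120, 120), seed = 9)
  cov <- generate_covariates(p)
  lc <- generate_initial_landcover(cov, p)
  fr <- as.vector(table(factor(lc$values, levels = 1:3))) / length(lc$values)
  expect_true(all(abs(fr - p$class_fractions) < 0.01))

  # degenerate single-class request
  p1 <- landscape_params(shape = c(30, 30), seed = 9,
                         class_fractions = c(1, 0, 0))
  lc1 <- generate_initial_landcover(generate_covariates(p1), p1)
  expect_true(all(lc1$values == 1))

  # different seeds: different pattern, same marginals
  p2 <- landscape_params(shape = c(120, 120), seed = 10)
  lc2 <- generate_initial_landcover(generate_covariates(p2), p2)
  expect_false(identical(lc$values, lc2$values))
  fr2 <- as.vector(table(factor(lc2$values, levels = 1:3))) / length(lc2$values)
  expect_true(all(abs(fr2 - fr) < 0.02))
})

test_that("frozen dynamics leave the series constant", {
  p <- landscape_params(shape = c(40, 40), seed = 3)
  cov <- generate_covariates(p)
  lc <- generate_initial_landcover(cov, p)
  frozen <- dynamics_params(base_logit = matrix(-Inf, 3, 3),
                            durations = c(5, 5))
  ser <- simulate_series(lc, cov, frozen, seed = 1)
  expect_length(ser, 3L)
  for (m in ser) expect_identical(m$values, lc$values)
})

test_that("expansion-only dynamics give non-decreasing woody area", {
  p <- landscape_params(shape = c(80, 80), seed = 6)
  cov <- generate_covariates(p)
  lc <- generate_initial_landcover(cov, p)
  bl <- matrix(-Inf, 3, 3); bl[2, 1] <- -1   # only grass -> woody enabled
  dyn <- dynamics_params(base_logit = bl, neighbor_coef = 3,
                         durations = c(5, 5, 4))
  ser <- simulate_series(lc, cov, dyn, seed = 2)
  woody <- vapply(ser, function(m) sum(m$values == 1), numeric(1))
  expect_true(all(diff(woody) >= 0))
  expect_gt(woody[4], woody[1])
})

test_that("series are deterministic under a fixed seed and conserve cells", {
  p <- landscape_params(shape = c(50, 50), seed = 8)
  cov <- generate_covariates(p)
  lc <- generate_initial_landcover(cov, p)
  dyn <- bisley_like_dynamics(durations = c(5, 4))
  s1 <- simulate_series(lc, cov, dyn, seed = 21)
  s2 <- simulate_series(lc, cov, dyn, seed = 21)
  for (k in seq_along(s1)) expect_identical(s1[[k]]$values, s2[[k]]$values)
  for (m in s1) {
    expect_false(anyNA(m$values))
    expect_true(all(m$values %in% 1:3))
  }
})

test_that("realized transition frequencies follow the logistic intercepts", {
  # flat covariates, no neighbourhood term: frequency -> plogis(base_logit)
  p <- landscape_params(shape = c(374, 374), seed = 12)
  cov <- generate_covariates(p)
  lc <- generate_initial_landcover(cov, p)
  bl <- matrix(-Inf, 3, 3)
  bl[2, 1] <- qlogis(0.2); bl[1, 2] <- qlogis(0.1)
  dyn <- dynamics_params(base_logit = bl, neighbor_coef = 0,
                         durations = 5,
                         covariate_coefs = array(0, c(3, 3, 5)))
  ser <- simulate_series(lc, cov, dyn, seed = 31)
  a <- as.vector(ser[[1]]$values); b <- as.vector(ser[[2]]$values)
  gw <- mean(b[a == 2] == 1)
  wg <- mean(b[a == 1] == 2)
  expect_equal(gw, 0.2, tolerance = 0.01 / 0.2)  # 1% absolute
  expect_true(abs(gw - 0.2) < 0.01)
  expect_true(abs(wg - 0.1) < 0.01)
})

test_that("per-bin empirical frequencies match the logistic rule", {
  # single enabled transition with a DEM effect; bin cells by DEM and
  # compare frequencies with the specified probabilities
  p <- landscape_params(shape = c(200, 200), seed = 14)
  cov <- generate_covariates(p)
  lc <- generate_initial_landcover(cov, p)
  bl <- matrix(-Inf, 3, 3); bl[2, 1] <- -1
  coefs <- array(0, c(3, 3, 5)); coefs[2, 1, 1] <- 1  # DEM only
  dyn <- dynamics_params(base_logit = bl, covariate_coefs = coefs,
                         neighbor_coef = 0, durations = 5)
  ser <- simulate_series(lc, cov, dyn, seed = 15)
  std <- attr(ser, "standardization")
  x <- (as.vector(cov$dem$values) - std$center["dem"]) / std$scale["dem"]
  a <- as.vector(ser[[1]]$values); b <- as.vector(ser[[2]]$values)
  g <- which(a == 2)
  bins <- cut(x[g], breaks = quantile(x[g], seq(0, 1, 0.2)),
              include.lowest = TRUE)
  for (lv in levels(bins)) {
    idx <- g[bins == lv]
    if (length(idx) < 1000) next
    p_hat <- mean(b[idx] == 1)
    p_true <- mean(plogis(-1 + x[idx]))
    se <- sqrt(p_true * (1 - p_true) / length(idx))
    expect_lt(abs(p_hat - p_true), 3 * se + 1e-12)
  }
})

test_that("a series writes to disk with a faithful manifest", {
  dir <- withr::local_tempdir()
  p <- landscape_params(shape = c(20, 20), seed = 17)
  cov <- generate_covariates(p)
  lc <- generate_initial_landcover(cov, p)
  ser <- simulate_series(lc, cov, bisley_like_dynamics(durations = 5),
                         seed = 4)
  write_series(ser, cov, p, dir)
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 4)
  expect_true(all(file.exists(file.path(dir, man$files))))
  back <- read_grid(file.path(dir, "landcover_t1.tif"), "categorical")
  expect_identical(back$values, ser[[2]]$values)
})
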