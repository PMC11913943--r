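make_small_world <- function(seed = 301, shape = c(90, 90), dem_coef = 2) {
  p <- landscape_params(shape = shape, seed = seed)
  cov <- generate_covariates(p)
  lc0 <- generate_initial_landcover(cov, p)
  ser <- simulate_series(lc0, cov, bisley_like_dynamics(dem_coef = dem_coef),
                         seed = seed + 1)
  list(p = p, cov = cov, ser = ser)
}

test_that("covariate correlation behaves on known cases", {
  w <- make_small_world(seed = 311, shape = c(40, 40))
  r <- covariate_correlation(w$cov)
  expect_equal(diag(r), rep(1, 5), ignore_attr = TRUE)
  expect_true(all(abs(r) <= 1 + 1e-12, na.rm = TRUE))

  neg <- w$cov
  neg$negdem <- grid(-neg$dem$values, neg$dem$pixel_size, neg$dem$origin)
  r2 <- covariate_correlation(neg)
  expect_equal(r2["dem", "negdem"], -1, tolerance = 1e-12)

  const <- w$cov
  const$flat <- grid(matrix(3, 40, 40), const$dem$pixel_size,
                     const$dem$origin)
  r3 <- covariate_correlation(const)
  expect_true(all(is.na(r3["flat", setdiff(colnames(r3), "flat")])))

  set.seed(1)
  n1 <- grid(matrix(rnorm(10000), 100, 100), 10)
  n2 <- grid(matrix(rnorm(10000), 100, 100), 10)
  rn <- covariate_correlation(structure(list(a = n1, b = n2),
                                        class = "covariate_stack"))
  expect_lt(abs(rn["a", "b"]), 0.05)
})

test_that("Markov projection: identity, hand power and conservation", {
  idm <- transition_matrix(diag(c(100, 200, 50)), 5)
  pr <- markov_project(idm, steps = 3)
  expect_true(all(apply(pr$areas, 1, function(r) all(r == c(100, 200, 50)))))

  two <- transition_matrix(matrix(c(90, 10, 0,
                                    0, 100, 0,
                                    0, 0, 10), 3, 3, byrow = TRUE), 5)
  pr2 <- markov_project(two, areas_t = c(100, 0, 0), steps = 2)
  expect_equal(unname(pr2$areas[2, ]), c(90, 10, 0))
  expect_equal(unname(pr2$areas[3, ]), c(81, 19, 0))
  expect_equal(unname(rowSums(pr2$areas)), rep(100, 3), tolerance = 1e-9)

  # zero-area class row treated as persistence
  z <- transition_matrix(matrix(c(10, 0, 0, 0, 10, 0, 0, 0, 0), 3, 3), 5)
  przz <- markov_project(z, areas_t = c(5, 5, 2), steps = 1)
  expect_equal(unname(przz$areas[2, 3]), 2)
})

test_that("largest-remainder targets preserve row totals exactly", {
  set.seed(8)
  for (rep in 1:10) {
    x <- runif(3, 0, 1000)
    total <- round(sum(x))
    r <- encroachr:::largest_remainder(x, total)
    expect_equal(sum(r), total)
    expect_true(all(abs(r - x) < 1))
  }
})

test_that("potential model is deterministic and handles degenerate change", {
  w <- make_small_world(seed = 321, shape = c(60, 60))
  f1 <- fit_transition_potential(w$ser[[1]], w$ser[[2]], w$cov, seed = 5,
                                 n_samples = 3000, maxit = 150, restarts = 2)
  f2 <- fit_transition_potential(w$ser[[1]], w$ser[[2]], w$cov, seed = 5,
                                 n_samples = 3000, maxit = 150, restarts = 2)
  p1 <- predict_potentials(f1, w$ser[[2]], w$cov)
  p2 <- predict_potentials(f2, w$ser[[2]], w$cov)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))

  expect_error(
    fit_transition_potential(w$ser[[1]], w$ser[[1]], w$cov, seed = 5),
    "no cells change")
})

test_that("rare transitions fall back to their empirical base rates", {
  w <- make_small_world(seed = 331, shape = c(60, 60))
  fit <- fit_transition_potential(w$ser[[1]], w$ser[[2]], w$cov, seed = 6,
                                  n_samples = 3000, maxit = 100,
                                  min_samples = 1e6)  # force all fallbacks
  pot <- predict_potentials(fit, w$ser[[1]], w$cov)
  v <- as.vector(w$ser[[1]]$values)
  g <- which(v == 2)
  expect_true(all(pot[g, 1] == fit$base_rate[2, 1]))
})

test_that("CA allocation converts exactly the top-scoring cells", {
  cur <- grid(matrix(c(2, 2, 2, 2,
                       2, 1, 1, 2,
                       2, 1, 1, 2,
                       2, 2, 2, 2), 4, 4, byrow = TRUE), 10,
              kind = "categorical")
  n <- 16
  pot <- matrix(0, n, 3)
  pot[, 1] <- seq(0.01, 0.16, 0.01)  # distinct woody potentials
  targets <- matrix(0L, 3, 3); targets[2, 1] <- 2L
  out <- ca_allocate(cur, pot, targets, w = 0, seed = 1)
  grass <- which(as.vector(cur$values) == 2)
  top2 <- grass[order(-pot[grass, 1])][1:2]
  expect_equal(which(as.vector(out$values) == 1 &
                       as.vector(cur$values) == 2), sort(top2))
  expect_equal(sum(out$values == 1), sum(cur$values == 1) + 2)

  # zero targets: identity
  out0 <- ca_allocate(cur, pot, matrix(0L, 3, 3), w = 1, seed = 1)
  expect_identical(out0$values, cur$values)

  # infeasible demand
  big <- matrix(0L, 3, 3); big[2, 1] <- 100L
  expect_error(ca_allocate(cur, pot, big, seed = 1), "demands")
})

test_that("higher neighbourhood weight pulls conversions toward clusters", {
  set.seed(41)
  vals <- matrix(2, 40, 40)
  vals[15:25, 15:25] <- 1  # one woody cluster
  cur <- grid(vals, 10, kind = "categorical")
  n <- length(vals)
  pot <- matrix(runif(n * 3), n, 3)
  targets <- matrix(0L, 3, 3); targets[2, 1] <- 120L
  fr <- moore_fractions(cur)
  mean_nbr <- function(w) {
    out <- ca_allocate(cur, pot, targets, w = w, seed = 2)
    conv <- as.vector(out$values) == 1 & as.vector(cur$values) == 2
    mean(fr[conv, 1])
  }
  expect_gt(mean_nbr(2), mean_nbr(0))
})

test_that("simulation conserves Markov quantities and is deterministic", {
  w <- make_small_world(seed = 341, shape = c(70, 70))
  fit <- fit_transition_potential(w$ser[[1]], w$ser[[2]], w$cov, seed = 7,
                                  n_samples = 4000, maxit = 200, restarts = 2)
  mk <- crosstab(w$ser[[1]], w$ser[[2]], 5)
  sim <- simulate_landcover(w$ser[[2]], fit, w$cov, mk, steps = 2, w = 1,
                            seed = 9)
  # realized counts match the integer targets derived from the Markov row
  P <- markov_project(mk, steps = 1)$P
  v0 <- as.vector(w$ser[[2]]$values)
  counts0 <- vapply(1:3, function(cd) sum(v0 == cd), numeric(1))
  expected1 <- vapply(1:3, function(j) {
    sum(vapply(1:3, function(i) {
      encroachr:::largest_remainder(counts0[i] * P[i, ], counts0[i])[j]
    }, numeric(1)))
  }, numeric(1))
  v1 <- as.vector(sim[[2]]$values)
  counts1 <- vapply(1:3, function(cd) sum(v1 == cd), numeric(1))
  expect_equal(counts1, expected1)

  sim2 <- simulate_landcover(w$ser[[2]], fit, w$cov, mk, steps = 2, w = 1,
                             seed = 9)
  for (k in 1:3) expect_identical(sim[[k]]$values, sim2[[k]]$values)

  # identity Markov matrix: everything persists
  idm <- transition_matrix(diag(c(10, 10, 10)), 5)
  simi <- simulate_landcover(w$ser[[2]], fit, w$cov, idm, steps = 2, seed = 3)
  expect_identical(simi[[3]]$values, w$ser[[2]]$values)
})

test_that("validation wraps the accuracy module faithfully", {
  m <- toy_map()
  v <- validate_simulation(m, m)
  expect_equal(v$overall, 1)
  expect_equal(v$kappa, 1)
  expect_equal(v$QADI, 0)

  # known 15% disagreement by construction
  set.seed(12)
  vals <- matrix(sample(1:3, 400, TRUE), 20, 20)
  ref <- toy_map(vals)
  simv <- vals
  flip <- sample(400, 60)
  simv[flip] <- (vals[flip] %% 3) + 1
  v2 <- validate_simulation(toy_map(simv), ref)
  expect_equal(v2$overall, 0.85)
})
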