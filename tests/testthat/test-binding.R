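test_that("fraction bound handles limits and matches hand values", {
  expect_equal(fraction_bound(20, 0, 140), 0)
  expect_equal(fraction_bound(20, 20, 0), 1.0)  # stoichiometric limit
  expect_equal(fraction_bound(20, 60, 140), 0.2798467, tolerance = 1e-6)
  expect_error(fraction_bound(0, 10, 140), class = "cspmap_validation_error")
  expect_error(fraction_bound(20, -1, 140), class = "cspmap_validation_error")
})

test_that("fraction bound agrees with a bisection oracle to 1e-10", {
  set.seed(42)
  for (i in 1:1000) {
    P <- stats::runif(1, 1, 500)
    L <- stats::runif(1, 0, 1000)
    Kd <- 10^stats::runif(1, -2, 4)
    expect_lt(abs(fraction_bound(P, L, Kd) - fb_bisect(P, L, Kd)), 1e-10)
  }
})

test_that("fraction bound is monotone in L and in Kd", {
  L <- seq(0, 500, by = 10)
  fb <- fraction_bound(20, L, 140)
  expect_true(all(diff(fb) > 0))
  kds <- c(1, 10, 100, 1000)
  fbk <- vapply(kds, function(k) fraction_bound(20, 60, k), numeric(1))
  expect_true(all(diff(fbk) < 0))
})

test_that("predicted response saturates at delta_max", {
  expect_equal(predict_delta_obs(20, c(0, 50, 500), 140, 0), c(0, 0, 0))
  expect_equal(predict_delta_obs(20, 1e6 * 140, 140, 1), 1, tolerance = 0.01)
  expect_equal(predict_delta_obs(20, 60, 140, 1), 0.2798467,
               tolerance = 1e-6)
})

test_that("noiseless fit recovers Kd at the four-point design", {
  obs <- simulate_binding_series(P = 20, L = c(10, 20, 60, 100),
                                 Kd_true = 140, delta_max_true = 1)
  fit <- fit_kd(obs, P = 20)
  expect_equal(fit$Kd, 140, tolerance = 1e-3)
  expect_equal(fit$delta_max, 1, tolerance = 1e-3)
  expect_false(fit$at_bound)
  expect_lt(fit$rss, 1e-12)
})

test_that("tight binding is flagged or recovered at the box boundary", {
  obs <- simulate_binding_series(P = 20, L = c(10, 20, 60, 100),
                                 Kd_true = 1e-3, delta_max_true = 2)
  fit <- fit_kd(obs, P = 20)
  expect_true(fit$at_bound || abs(fit$Kd - 1e-3) / 1e-3 < 0.5)
  expect_equal(fit$delta_max, 2, tolerance = 0.01)
})

test_that("no point of a brute-force grid beats the returned fit", {
  # independent 2-D grid oracle over (log10 Kd, delta_max)
  set.seed(7)
  for (kd_true in c(5, 140, 2000)) {
    dm_true <- stats::runif(1, 0.5, 3)
    L <- c(10, 20, 60, 100)
    y <- predict_delta_obs(20, L, kd_true, dm_true)
    fit <- fit_kd(data.frame(L = L, delta_obs = y), P = 20)
    grid_kd <- 10^seq(-2, 5, length.out = 120)
    # search the same feasible box as the fit (delta_max <= 10 max|y|)
    grid_dm <- seq(0, 10 * max(abs(y)), length.out = 121)
    rss_grid <- outer(grid_kd, grid_dm, function(k, d) {
      vapply(seq_along(k), function(i)
        sum((y - d[i] * fraction_bound(20, L, k[i]))^2), numeric(1))
    })
    expect_lte(fit$rss, min(rss_grid) + 1e-12)
  }
})

test_that("fit is scale-equivariant in the observable", {
  L <- c(10, 20, 60, 100)
  y <- predict_delta_obs(20, L, 140, 1) + c(0.01, -0.02, 0.015, -0.005)
  f1 <- fit_kd(data.frame(L = L, delta_obs = y), P = 20)
  f2 <- fit_kd(data.frame(L = L, delta_obs = 3.7 * y), P = 20)
  expect_equal(f2$Kd, f1$Kd, tolerance = 1e-6)
  expect_equal(f2$delta_max, 3.7 * f1$delta_max, tolerance = 1e-6)
})

test_that("four-point design recovers Kd within 25% at 2% noise (median)", {
  kds <- vapply(1:200, function(s) {
    obs <- simulate_binding_series(P = 20, L = c(10, 20, 60, 100),
                                   Kd_true = 140, delta_max_true = 1,
                                   noise_sd = 0.02, seed = s)
    fit_kd(obs, P = 20)$Kd
  }, numeric(1))
  expect_lt(abs(stats::median(kds) - 140) / 140, 0.25)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(fit_kd(data.frame(L = c(10, 20, 60),
                                 delta_obs = c(0, 0, 0)), P = 20),
               "degenerate", class = "cspmap_data_error")
  expect_error(fit_kd(data.frame(L = c(10, 20), delta_obs = c(0.1, 0.2)),
                      P = 20), class = "cspmap_validation_error")
  expect_error(fit_kd(data.frame(L = c(10, 10, 10),
                                 delta_obs = c(0.1, 0.1, 0.1)), P = 20),
               "distinct", class = "cspmap_validation_error")
})

test_that("the hyperbolic variant fits ligand-excess data", {
  L <- c(50, 100, 400, 1000, 4000)
  y <- 1.5 * L / (L + 300)
  fit <- fit_kd(data.frame(L = L, delta_obs = y), P = 0.1,
                model = "hyperbolic")
  expect_equal(fit$Kd, 300, tolerance = 1e-3)
  expect_equal(fit$delta_max, 1.5, tolerance = 1e-3)
})
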