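test_that("identical distributions have a zero index", {
  tj <- true_youden(dist_spec("normal", 0, 1), dist_spec("normal", 0, 1))
  expect_equal(tj$j, 0, tolerance = 1e-8)
})

test_that("equal-variance normal pair matches the closed form 2*Phi(mu/2) - 1", {
  for (mu in c(0.5, 1, 2)) {
    tj <- true_youden(dist_spec("normal", 0, 1), dist_spec("normal", mu, 1))
    expect_equal(tj$j, 2 * pnorm(mu / 2) - 1, tolerance = 1e-8)
    expect_equal(tj$cut, mu / 2, tolerance = 1e-6)
  }
})

test_that("published scenario parameterizations round-trip to their target index", {
  # (parameters printed to 4 dp, hence the 5e-3 tolerance)
  normal_cells <- list(
    list(mu = 0.8484, s2 = 0.5, j = 0.4), list(mu = 1.4071, s2 = 0.5, j = 0.6),
    list(mu = 2.1682, s2 = 0.5, j = 0.8), list(mu = 2.7927, s2 = 0.5, j = 0.9),
    list(mu = 1.0489, s2 = 1,   j = 0.4), list(mu = 3.2898, s2 = 1,   j = 0.9),
    list(mu = 1.254,  s2 = 3,   j = 0.4), list(mu = 5.1777, s2 = 5,   j = 0.9))
  for (cell in normal_cells) {
    tj <- true_youden(dist_spec("normal", 0, 1),
                      dist_spec("normal", cell$mu, sqrt(cell$s2)))
    expect_equal(tj$j, cell$j, tolerance = 5e-3)
  }
  gamma_cells <- list(
    list(shape = 1.5, rate = 0.4028, j = 0.4), list(shape = 1.5, rate = 0.0505, j = 0.9),
    list(shape = 2,   rate = 0.3616, j = 0.6), list(shape = 3,   rate = 0.2124, j = 0.9))
  for (cell in gamma_cells) {
    tj <- true_youden(dist_spec("gamma", shape = 1.5, rate = 1),
                      dist_spec("gamma", shape = cell$shape, rate = cell$rate))
    expect_equal(tj$j, cell$j, tolerance = 5e-3)
  }
  # t(5) vs normal and N(1,1) vs gamma(2, rate) mixed settings
  for (cell in list(list(mu = 1.08, j = 0.4), list(mu = 3.62, j = 0.9))) {
    tj <- true_youden(dist_spec("t", df = 5), dist_spec("normal", cell$mu, 1))
    expect_equal(tj$j, cell$j, tolerance = 5e-3)
  }
  for (cell in list(list(rate = 0.749, j = 0.4), list(rate = 0.153, j = 0.9))) {
    tj <- true_youden(dist_spec("normal", 1, 1),
                      dist_spec("gamma", shape = 2, rate = cell$rate))
    expect_equal(tj$j, cell$j, tolerance = 5e-3)
  }
})

test_that("location shifts move the cut but not the index (normal pairs)", {
  for (shift in c(-3, 2)) {
    a <- true_youden(dist_spec("normal", 0, 1), dist_spec("normal", 1.5, 2))
    b <- true_youden(dist_spec("normal", shift, 1),
                     dist_spec("normal", 1.5 + shift, 2))
    expect_equal(a$j, b$j, tolerance = 1e-7)
    expect_equal(a$cut + shift, b$cut, tolerance = 1e-5)
  }
})

test_that("solver reproduces the published calibrations", {
  mu <- solve_target_param(dist_spec("normal", 0, 1),
                           dist_spec("normal", NA, 1), "mean", 0.4)
  expect_equal(mu, 1.0489, tolerance = 2e-4)
  mu <- solve_target_param(dist_spec("normal", 0, 1),
                           dist_spec("normal", NA, sqrt(0.5)), "mean", 0.9)
  expect_equal(mu, 2.7927, tolerance = 2e-4)
  th <- solve_target_param(dist_spec("gamma", shape = 1.5, rate = 1),
                           dist_spec("gamma", shape = 1.5, rate = NA), "rate", 0.6)
  expect_equal(round(th, 4), 0.2295)
})

test_that("solver inverse: solve then evaluate recovers the target to 1e-6", {
  families <- list(
    list(dx = dist_spec("normal", 0, 1), dy = dist_spec("normal", NA, 1), free = "mean"),
    list(dx = dist_spec("gamma", shape = 1.5, rate = 1),
         dy = dist_spec("gamma", shape = 2.5, rate = NA), free = "rate"),
    list(dx = dist_spec("t", df = 5), dy = dist_spec("normal", NA, 1), free = "mean"),
    list(dx = dist_spec("normal", 1, 1),
         dy = dist_spec("gamma", shape = 2, rate = NA), free = "rate"))
  for (fam in families) {
    for (target in c(0.4, 0.6, 0.8, 0.9)) {
      par <- solve_target_param(fam$dx, fam$dy, fam$free, target)
      dy <- fam$dy; dy[[fam$free]] <- par
      expect_equal(true_youden(fam$dx, dy)$j, target, tolerance = 1e-6)
    }
  }
})

test_that("solver targets approaching zero drive the normal mean to zero", {
  mu <- solve_target_param(dist_spec("normal", 0, 1),
                           dist_spec("normal", NA, 1), "mean", 0.001)
  expect_lt(mu, 0.01)
})

test_that("solver reports a useless bracket with diagnostics", {
  expect_error(
    solve_target_param(dist_spec("normal", 0, 1), dist_spec("normal", NA, 1),
                       "mean", 0.9, interval = c(0.01, 0.1)),
    "bracket")
})

test_that("gamma sampling follows the rate parameterization (mean = shape/rate)", {
  set.seed(111)
  spec <- dist_spec("gamma", shape = 1.5, rate = 0.25)
  draws <- youdenci:::dist_rand(spec, 1e5)
  se <- sqrt(1.5 / 0.25^2 / 1e5)       # var of gamma = shape/rate^2
  expect_lt(abs(mean(draws) - 1.5 / 0.25), 3 * se)
  expect_true(all(draws > 0))
})

test_that("scenario sampling is deterministic and respects supports", {
  sc <- scenario_spec(dist_spec("gamma", shape = 1.5, rate = 1),
                      dist_spec("gamma", shape = 1.5, rate = 0.2295),
                      m = 10, n = 12)
  a <- sample_scenario(sc, seed = 5)
  b <- sample_scenario(sc, seed = 5)
  expect_identical(a, b)
  expect_true(all(c(a$x, a$y) > 0))
  expect_length(a$x, 10)
  expect_length(a$y, 12)
})

test_that("a mis-stated pre-defined index is rejected", {
  expect_error(scenario_spec(dist_spec("normal", 0, 1),
                             dist_spec("normal", 1.0489, 1),
                             m = 20, n = 20, true_j = 0.6),
               "disagrees")
})

test_that("large samples concentrate the empirical estimate at the true index", {
  sc <- scenario_spec(dist_spec("normal", 0, 1), dist_spec("normal", 1.0489, 1),
                      m = 1e5, n = 1e5, true_j = 0.4)
  s <- sample_scenario(sc, seed = 31)
  expect_equal(youden_empirical(s)$j_hat, 0.4, tolerance = 0.01)
})
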