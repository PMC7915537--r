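# direct textbook evaluation, written independently of the package
naive_hill <- function(T, A, B, C, T1, T2, k, m) {
  A - (B * T^k) / (T1^k + T^k) - (C * T^m) / (T2^m + T^m)
}

null_params <- function() hill_params(A = 1, B = 0.5, C = 0.5,
                                      T1 = 304, T2 = 359, k = 39, m = 29)
wt_params <- function() hill_params(A = 1, B = 0.5, C = 0.5,
                                    T1 = 289, T2 = 307, k = 120, m = 120)
melt_grid <- function() seq(248.15, 398.15, length.out = 150)

test_that("parameter validation enforces the model constraints", {
  expect_error(hill_params(T1 = 350, T2 = 300, k = 30, m = 30), "T1")
  expect_error(hill_params(A = -1, T1 = 300, T2 = 350, k = 30, m = 30))
  expect_error(hill_model(c(300, -5), null_params()), "positive")
})

test_that("model limits and half-saturation are exact", {
  p <- null_params()
  expect_equal(hill_model(p$T1 / 10, p), p$A, tolerance = 1e-6)
  expect_equal(hill_model(1e6, p), p$A - p$B - p$C, tolerance = 1e-6)
  p0 <- hill_params(A = 1, B = 0.5, C = 0, T1 = 304, T2 = 400,
                    k = 39, m = 29)
  expect_identical(hill_model(304, p0), 1 - 0.5 / 2)
})

test_that("stable evaluation equals the naive form where it is finite", {
  grid <- seq(250, 400, length.out = 301)
  set.seed(7)
  for (i in 1:20) {
    k <- runif(1, 1, 20); m <- runif(1, 1, 20)
    T1 <- runif(1, 260, 320); T2 <- T1 + runif(1, 5, 80)
    B <- runif(1, 0.1, 0.6); C <- runif(1, 0.1, 0.6)
    p <- hill_params(A = 1, B = B, C = C, T1 = T1, T2 = T2, k = k, m = m)
    expect_equal(hill_model(grid, p),
                 naive_hill(grid, 1, B, C, T1, T2, k, m),
                 tolerance = 1e-12)
  }
})

test_that("published parameter sets evaluate against the direct form", {
  # 0.746 at T = T1 for the two-transition set
  expect_equal(hill_model(304, null_params()),
               naive_hill(304, 1, 0.5, 0.5, 304, 359, 39, 29),
               tolerance = 1e-10)
  expect_equal(hill_model(304, null_params()), 0.746, tolerance = 5e-4)
  # no overflow at steep cooperativity where the naive form breaks down
  v <- hill_model(seq(250, 400, by = 1), wt_params())
  expect_true(all(is.finite(v)))
  p_extreme <- hill_params(T1 = 289, T2 = 307, k = 450, m = 450)
  expect_true(all(is.finite(hill_model(seq(250, 400, by = 1), p_extreme))))
})

test_that("the model is monotonically non-increasing in temperature", {
  grid <- seq(200, 450, length.out = 2000)
  set.seed(11)
  for (i in 1:10) {
    p <- hill_params(A = 1, B = runif(1, 0, 0.7), C = runif(1, 0, 0.3),
                     T1 = runif(1, 260, 320), T2 = runif(1, 330, 400),
                     k = runif(1, 2, 150), m = runif(1, 2, 150))
    expect_true(all(diff(hill_model(grid, p)) <= 1e-12))
  }
})

test_that("spline differentiation locates the transitions", {
  cur <- simulate_melting_curve(null_params(), melt_grid(), noise_sd = 0,
                                seed = 1)
  tr <- spline_transitions(cur)
  expect_length(tr, 2)
  expect_equal(tr[1], 304, tolerance = 2)
  expect_equal(tr[2], 359, tolerance = 2)
  # single-transition curve
  p1 <- hill_params(A = 1, B = 0.5, C = 0, T1 = 304, T2 = 400,
                    k = 39, m = 29)
  tr1 <- spline_transitions(simulate_melting_curve(p1, melt_grid(),
                                                   noise_sd = 0, seed = 1))
  expect_length(tr1, 1)
  expect_equal(tr1, 304, tolerance = 2)
  # flat curve: nothing to find
  flat <- tibble::tibble(temperature_K = melt_grid(),
                         birefringence = rep(1, 150))
  expect_length(spline_transitions(flat), 0)
  expect_error(spline_transitions(flat[1:5, ]), "7 points")
})

test_that("noiseless refits recover all parameters with r2 = 1", {
  for (p in list(null_params(), wt_params())) {
    cur <- simulate_melting_curve(p, melt_grid(), noise_sd = 0, seed = 1)
    fit <- fit_melting(cur)
    expect_true(fit$converged)
    expect_equal(fit$params$T1, p$T1, tolerance = 0.5 / p$T1)
    expect_equal(fit$params$T2, p$T2, tolerance = 0.5 / p$T2)
    expect_equal(fit$params$k, p$k, tolerance = 0.05)
    expect_equal(fit$params$m, p$m, tolerance = 0.05)
    expect_equal(fit$params$A, p$A, tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_lte(fit$r_squared, 1)
  }
})

test_that("transition estimates are unbiased over noisy replicates", {
  p <- null_params()
  fits <- vapply(1:50, function(s) {
    f <- fit_melting(simulate_melting_curve(p, melt_grid(),
                                            noise_sd = 0.01, seed = s))
    c(f$params$T1, f$params$T2)
  }, numeric(2))
  expect_lt(abs(mean(fits[1, ]) - p$T1), 1)
  expect_lt(abs(mean(fits[2, ]) - p$T2), 1)
})

test_that("explicit inits and tidy/glance accessors work", {
  p <- null_params()
  cur <- simulate_melting_curve(p, melt_grid(), noise_sd = 0.005, seed = 2)
  fit <- fit_melting(cur, init = hill_params(T1 = 290, T2 = 370,
                                             k = 20, m = 20))
  expect_equal(fit$params$T1, 304, tolerance = 0.01)
  td <- tidy(fit)
  expect_setequal(td$term, c("A", "B", "C", "T1", "T2", "k", "m"))
  gl <- glance(fit)
  expect_gt(gl$r.squared, 0.999)
  expect_true(gl$converged)
  expect_equal(gl$nobs, 150)
})

test_that("melt fraction inverts the model", {
  p0 <- hill_params(A = 1, B = 0.5, C = 0, T1 = 304, T2 = 400,
                    k = 39, m = 29)
  expect_equal(melt_fraction_at(p0, 0.5), 304, tolerance = 1e-6)
  expect_lt(melt_fraction_at(p0, 0.01), 304)
  # independent bisection on the direct form for the two-transition set
  p <- null_params()
  f <- function(T) (1 - naive_hill(T, 1, 0.5, 0.5, 304, 359, 39, 29)) - 0.5
  oracle <- uniroot(f, c(250, 400), tol = 1e-10)$root
  expect_equal(melt_fraction_at(p, 0.5), oracle, tolerance = 1e-8)
  expect_error(
    melt_fraction_at(hill_params(A = 1, B = 0, C = 0, T1 = 300, T2 = 350,
                                 k = 10, m = 10), 0.5),
    "no meltable"
  )
})
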