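test_that("therapy_effect divides by amplitude and propagates missingness", {
  h0 <- c(0.5, 1, 2); d <- c(0.2, 0.5, 0.8)
  S <- matrix(rep(h0, each = 3), nrow = 3, byrow = TRUE)  # S = h0 everywhere
  surf <- toy_surface(S, h0, d)
  expect_true(all(therapy_effect(surf) == 1))

  erad <- matrix(FALSE, 3, 3); erad[2, 3] <- TRUE
  conv <- matrix(TRUE, 3, 3); conv[3, 1] <- FALSE
  surf2 <- toy_surface(S, h0, d, eradicated = erad, converged = conv)
  Y <- therapy_effect(surf2)
  expect_true(is.na(Y[2, 3]) && is.na(Y[3, 1]))
  expect_equal(sum(is.na(Y)), 2)

  expect_error(therapy_effect(toy_surface(S, c(0, 1, 2), d)), "h0 = 0")
})

test_that("peak_duty_cycle takes per-row argmax with smallest-d ties", {
  d <- seq(0.1, 0.9, by = 0.1)
  peaked <- function(dm) 1 - (d - dm)^2  # row maximized at dm
  S <- rbind(peaked(0.3), peaked(0.3), peaked(0.5))
  pk <- peak_duty_cycle(toy_surface(S, c(0.5, 1, 2), d))
  expect_equal(unname(pk$per_row), c(0.3, 0.3, 0.5))
  expect_equal(pk$consensus, 0.3)
  expect_equal(pk$range, c(0.3, 0.5))

  # exact tie inside a row resolves to the smaller d
  S2 <- rbind(c(0, 1, 1, 0, 0, 0, 0, 0, 0))
  pk2 <- peak_duty_cycle(toy_surface(S2, 1, d))
  expect_equal(unname(pk2$per_row), 0.2)

  # modal tie across rows resolves to the smaller d
  S3 <- rbind(peaked(0.3), peaked(0.4))
  expect_equal(peak_duty_cycle(toy_surface(S3, c(1, 2), d))$consensus, 0.3)

  # all-missing row is skipped with a warning
  S4 <- rbind(peaked(0.3), NA * peaked(0.3))
  expect_warning(pk4 <- peak_duty_cycle(toy_surface(S4, c(1, 2), d)),
                 "no finite S")
  expect_equal(pk4$consensus, 0.3)
  expect_error(peak_duty_cycle(toy_surface(S2[, 1:2, drop = FALSE], 1, d[1:2])),
               "3 duty-cycle")
})

test_that("reduce_series max-normalizes each amplitude row", {
  # spec'd single-row example
  d <- c(1 / 3, 2 / 3, 1)  # gives I = h0 * d with T = 1
  surf <- toy_surface(matrix(c(1, 2, 4), 1), 1, d)
  red <- reduce_series(surf)
  expect_equal(red$Y_prime, c(0.25, 0.5, 1))
  expect_equal(red$I_prime, c(1 / 3, 2 / 3, 1))
  expect_identical(attr(red, "n_excluded"), 0L)

  # scale invariance: rows identical up to scale coincide after reduction
  d <- seq(0.1, 0.9, by = 0.1)
  base <- (1:9) / 9 - 0.5 * ((1:9) / 9)^2
  surf2 <- toy_surface(rbind(base, 7 * base, 0.01 * base), c(0.5, 1, 2), d)
  red2 <- reduce_series(surf2)
  for (col in c("I_prime", "Y_prime"))
    expect_equal(red2[[col]][1:9], red2[[col]][10:18], tolerance = 1e-14)
  expect_equal(red2$Y_prime[1:9], red2$Y_prime[19:27], tolerance = 1e-14)

  # a zero row is excluded and counted, not fatal
  surf3 <- toy_surface(rbind(base, 0 * base), c(1, 2), d)
  expect_warning(red3 <- reduce_series(surf3), "excluded")
  expect_identical(attr(red3, "n_excluded"), 1L)
  expect_equal(nrow(red3), 9)
})

test_that("quadratic-through-origin fit interpolates exact data", {
  x <- c(0.2, 0.5, 0.8, 1.0)
  f <- fit_quadratic_origin(x, -2 * x^2 + 1.6 * x)
  expect_equal(f$m, -2, tolerance = 1e-12)
  expect_equal(f$n, 1.6, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$x_star, 0.4, tolerance = 1e-12)
  expect_equal(f$y_star, 0.32, tolerance = 1e-12)
  expect_error(fit_quadratic_origin(rep(0.5, 4), 1:4), "rank-deficient")
  expect_error(fit_quadratic_origin(x[1:2], x[1:2]), ">= 3")
})

test_that("fit agrees with explicit normal equations on random instances", {
  set.seed(101)
  for (rep in 1:100) {
    npt <- sample(5:40, 1)
    x <- runif(npt, 0, 2)
    y <- runif(1, -3, 0) * x^2 + runif(1, 0, 3) * x + rnorm(npt, sd = 0.1)
    f <- fit_quadratic_origin(x, y)
    X <- cbind(x^2, x)
    cf <- solve(crossprod(X), crossprod(X, y))  # normal-equations oracle
    expect_equal(c(f$m, f$n), as.numeric(cf), tolerance = 1e-10)
    resid <- y - X %*% cf
    s2 <- sum(resid^2) / (npt - 2)
    se <- sqrt(diag(s2 * solve(crossprod(X))))
    expect_equal(c(f$stderr_m, f$stderr_n), as.numeric(se),
                 tolerance = 1e-8)
  }
})

test_that("noisy fit recovers the generating coefficients within 2 SE", {
  set.seed(42)
  x <- runif(200, 0, 1)
  y <- -2 * x^2 + 1.6 * x + rnorm(200, sd = 0.05)
  f <- fit_quadratic_origin(x, y)
  expect_lt(abs(f$m - (-2)), 2 * f$stderr_m)
  expect_lt(abs(f$n - 1.6), 2 * f$stderr_n)
})

test_that("fit is idempotent and vertex identities hold exactly", {
  set.seed(5)
  x <- runif(30, 0, 1)
  f <- fit_quadratic_origin(x, 1.3 * x - 2.1 * x^2 + rnorm(30, sd = 0.05))
  refit <- fit_quadratic_origin(x, f$m * x^2 + f$n * x)
  expect_equal(c(refit$m, refit$n), c(f$m, f$n), tolerance = 1e-12)
  expect_equal(f$x_star, -f$n / (2 * f$m), tolerance = 1e-12)
  expect_equal(f$y_star, f$m * f$x_star^2 + f$n * f$x_star,
               tolerance = 1e-12)
  expect_equal(f$y_star, -f$n^2 / (4 * f$m), tolerance = 1e-12)
})

test_that("collapse recovers known generating laws from synthetic surfaces", {
  # symmetric parabola: two identical surfaces pooled
  fx1 <- make_quadratic_surface(m = -1, n = 1)
  fx2 <- make_quadratic_surface(m = -1, n = 1, waveform = "halfsine")
  col <- collapse_surfaces(fx1, fx2)
  truth <- fixture_truth(fx1)
  expect_equal(col$x_star, 0.5, tolerance = 1e-9)
  expect_equal(col$m, truth$m_reduced, tolerance = 1e-9)
  expect_equal(col$n, truth$n_reduced, tolerance = 1e-9)
  expect_equal(col$r_squared, 1, tolerance = 1e-9)
  expect_identical(col$n_excluded, 0L)

  # asymmetric law: end-to-end parameter recovery at sigma = 0
  fx <- make_quadratic_surface(m = -2, n = 1.6)
  col2 <- collapse_surfaces(fx)
  tr <- fixture_truth(fx)
  expect_equal(col2$m, tr$m_reduced, tolerance = 1e-6)
  expect_equal(col2$n, tr$n_reduced, tolerance = 1e-6)
  expect_equal(col2$x_star, 0.4, tolerance = 1e-9)
  expect_error(collapse_surfaces(fx, make_quadratic_surface(
    m = -1, n = 1, h0_grid = c(0.5, 1), d_grid = c(0.2, 0.5, 0.8))),
    "same grids")
})

test_that("vertex-normalization reduction maps every row onto u - u^2", {
  fx <- make_quadratic_surface(m = -2, n = 1.6)
  col <- collapse_surfaces(fx, reduction = "vertex")
  expect_equal(col$m, -1, tolerance = 1e-8)
  expect_equal(col$n, 1, tolerance = 1e-8)
  expect_equal(col$x_star, 0.5, tolerance = 1e-8)
})
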