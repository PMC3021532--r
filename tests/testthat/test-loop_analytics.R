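test_that("shoelace area matches the closed-form ellipse across phase lags", {
  for (phi in (1:11) * pi / 12) {
    fx <- make_ellipse_loop(h0 = 1, x0 = 2, phi = phi, c = 3,
                            n_samples = 2000L)
    truth <- fixture_truth(fx)$area
    expect_lt(abs(loop_area(fx) - truth) / (pi * 1 * 2), 1e-4)
  }
  # quarter-lag ellipse, exact closed form 2*pi
  fx <- make_ellipse_loop(h0 = 1, x0 = 2, phi = pi / 2, c = 3)
  expect_equal(as.numeric(loop_area(fx)), 2 * pi, tolerance = 1e-4)
  # in-phase response: degenerate loop
  fx0 <- make_ellipse_loop(h0 = 1, x0 = 2, phi = 0, c = 3)
  expect_equal(as.numeric(loop_area(fx0)), 0, tolerance = 1e-12)
})

test_that("loop_area handles degenerate, ideal and malformed loops", {
  # constant drive: zero enclosed area whatever the response does
  expect_equal(as.numeric(loop_area(list(h = rep(2, 50), x = sin(1:50)))), 0)
  # ideal rectangular loop: exactly h0 * delta_x
  fx <- make_rect_loop(h0 = 0.8, x_hi = 9, x_lo = 6.5)
  expect_equal(as.numeric(loop_area(fx)), fixture_truth(fx)$area,
               tolerance = 1e-12)
  # orientation flips when the cycle is traversed backwards
  fwd <- make_ellipse_loop(phi = pi / 3)
  rev <- list(h = base::rev(fwd$h), x = base::rev(fwd$x))
  expect_identical(attr(loop_area(fwd), "orientation"),
                   -attr(loop_area(rev), "orientation"))
  expect_error(loop_area(list(h = c(1, 2), x = c(1, 2))), "at least 3")
  expect_error(loop_area(list(h = 1:4)), "equal length")
})

test_that("dose cumulant closed forms are exact and match quadrature", {
  expect_identical(
    dose_cumulant(intervention_spec("rectangular", 0.5, T = 10, d = 0.4)), 2)
  expect_equal(
    dose_cumulant(intervention_spec("halfsine", 1, T = 2 * pi, d = 0.5)), 2)
  expect_identical(dose_cumulant(intervention_spec("none", T = 10)), 0)
  expect_identical(
    dose_cumulant(intervention_spec("rectangular", 0, T = 10, d = 0.4)), 0)

  # closed form vs numerical quadrature over the full default grids
  for (w in c("rectangular", "halfsine")) {
    for (h0 in seq(0.1, 1, by = 0.1)) {
      for (d in seq(0.1, 0.9, by = 0.1)) {
        spec <- intervention_spec(w, h0, T = 1, d = d)
        quad <- integrate(function(t) waveform_value(spec, t),
                          0, spec$T0, rel.tol = 1e-12)$value
        expect_lt(abs(dose_cumulant(spec) - quad) / quad, 1e-9)
      }
    }
  }
})

test_that("cycle_stats computes time-weighted means and excursions", {
  t <- seq(0, 1, length.out = 501)
  expect_equal(cycle_stats(list(t = t, x = rep(5, 501))),
               list(mean_x = 5, delta_x = 0))
  # symmetric sinusoid about c = 3 with amplitude 2
  fx <- make_ellipse_loop(h0 = 1, x0 = 2, phi = pi / 4, c = 3)
  st <- cycle_stats(fx)
  expect_equal(st$mean_x, 3, tolerance = 1e-10)
  expect_equal(st$delta_x, 4, tolerance = 1e-5)
  # uniform ramp
  expect_equal(cycle_stats(list(t = t, x = t)),
               list(mean_x = 0.5, delta_x = 1))
  expect_error(cycle_stats(list(t = numeric(0), x = numeric(0))), "length")
})

test_that("dose-effect derivative: central differences, exact on quadratics", {
  d <- dose_effect_derivative(c(1, 2, 3), c(9, 6, 1))
  expect_equal(d$deriv, c(-3, -4, -5))
  # linear curve: constant derivative everywhere
  I <- seq(0, 2, by = 0.25)
  expect_equal(dose_effect_derivative(I, 7 - 3 * I)$deriv,
               rep(-3, length(I)))
  # interior points are exact for quadratics on a uniform grid
  y <- 2 * I^2 - 5 * I + 1
  der <- dose_effect_derivative(I, y)$deriv
  expect_equal(der[2:(length(I) - 1)], (4 * I - 5)[2:(length(I) - 1)],
               tolerance = 1e-12)
  expect_error(dose_effect_derivative(c(1, 1, 2), c(1, 2, 3)), "duplicate")
  expect_error(dose_effect_derivative(c(1, 3, 2), c(1, 2, 3)), "increasing")
  expect_error(dose_effect_derivative(c(1, 2), c(1, 2)), ">= 3")
})

test_that("optimal dose cumulant implements the flat-tail definition", {
  # sigmoid fixture: ground truth computed by the fixture's direct scan
  fx <- make_sigmoid_curve(midpoint = 3, slope = 2, ceiling = 10,
                           I_grid = seq(0, 8, by = 0.25))
  expect_equal(optimal_dose_cumulant(fx$I, fx$mean_x),
               fixture_truth(fx)$I_O)
  # near-step sigmoid: onset lands just past the midpoint
  fs <- make_sigmoid_curve(midpoint = 3, slope = 50,
                           I_grid = seq(0, 8, by = 0.25))
  expect_equal(optimal_dose_cumulant(fs$I, fs$mean_x),
               fixture_truth(fs)$I_O)
  expect_lt(abs(fixture_truth(fs)$I_O - 3), 0.76)
  # flat curve: derivative identically zero, onset at the first point
  f0 <- make_sigmoid_curve(slope = 0, I_grid = seq(0, 8, by = 0.25))
  expect_identical(optimal_dose_cumulant(f0$I, f0$mean_x), 0)
  # monotone steepening curve never flattens
  I <- seq(0, 4, by = 0.5)
  expect_identical(optimal_dose_cumulant(I, 20 - I^2), NA_real_)
})

test_that("effective duty-cycle uses the same criterion on the d axis", {
  # constructed flat tail: steep drop over the first three points, then flat
  d <- seq(0.1, 0.9, by = 0.1)
  mx <- c(10, 6, 2, 1.99, 1.985, 1.982, 1.980, 1.979, 1.9785)
  onset <- effective_duty_cycle(d, mx)
  # oracle: direct scan of the definition on the same data
  der <- dose_effect_derivative(d, mx)$deriv
  thr <- 0.1 * max(abs(der))
  k <- which(vapply(seq_along(d), function(k) all(abs(der[k:length(d)]) <= thr),
                    logical(1)))[1]
  expect_identical(onset, d[k])
  # strictly linear: never flattens relative to itself
  expect_identical(effective_duty_cycle(d, 5 - 2 * d), NA_real_)
})

test_that("d_e shrinks (or appears) with amplitude on real sweeps", {
  p <- repro_params()
  cfg <- fast_config()
  d_grid <- seq(0.1, 0.9, by = 0.1)
  de <- vapply(c(0.5, 1.0), function(h0) {
    s <- sweep_grid(p, "rectangular", h0, d_grid, T = 1, config = cfg)
    cur <- dose_effect_curve(s, h0)
    effective_duty_cycle(cur$d, cur$mean_x)
  }, numeric(1))
  # small amplitude: d_e absent; large amplitude: present, hence smaller
  de[is.na(de)] <- Inf
  expect_lt(de[2], de[1])
})
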