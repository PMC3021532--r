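# Synthetic fixtures with closed-form ground truth.  These stand in for
# the simulation stage so every analysis operation (loop area, dose-effect
# features, collapse fit) can be tested against known answers without
# integrating the ODE.  All stochastic fixtures are reproducible from
# (parameters, seed) and every fixture carries its ground truth in the
# "truth" attribute; test code must read the truth, never recompute it
# from the functions under test.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Elliptic hysteresis-loop fixture
#'
#' One closed cycle of `h = h0 sin(2 pi t)`, `x = c + x0 sin(2 pi t - phi)`
#' on `t` in `[0, 1]`.  The enclosed area is exactly
#' `pi * h0 * x0 * sin(phi)`: in-phase response (`phi = 0`) gives a
#' degenerate loop of zero area, quarter-lag (`phi = pi/2`) the full
#' ellipse.
#'
#' @param h0 drive amplitude, `> 0`.
#' @param x0 response amplitude, `> 0`.
#' @param phi phase lag in `[0, pi]`.
#' @param c response offset; must satisfy `c >= x0` so the density trace
#'   stays nonnegative.
#' @param n_samples samples per cycle (the trace has `n_samples + 1`
#'   points, endpoints included).
#' @return A `trajectory`-like list `(t, x, h)` with attribute `"truth"`
#'   containing `area`, `phi`, `h0`, `x0`, `c`.
#' @export
make_ellipse_loop <- function(h0 = 1, x0 = 2, phi = pi / 6, c = 3,
                              n_samples = 2000L) {
  stopifnot(h0 > 0, x0 > 0, phi >= 0, phi <= pi, n_samples >= 8)
  if (c < x0)
    stop("make_ellipse_loop: need c >= x0 so x stays nonnegative")
  t <- seq(0, 1, length.out = n_samples + 1L)
  structure(list(t = t,
                 h = h0 * sin(2 * pi * t),
                 x = c + x0 * sin(2 * pi * t - phi)),
            class = "trajectory",
            truth = list(area = pi * h0 * x0 * sin(phi),
                         phi = phi, h0 = h0, x0 = x0, c = c))
}

#' Ideal rectangular hysteresis-loop fixture
#'
#' A four-corner loop with two vertical branches in the `(h, x)` plane:
#' `x` descends from `x_hi` to `x_lo` at `h = h0`, jumps to `h = 0`,
#' ascends back to `x_hi`, and jumps to `h = h0` again — the idealized
#' abrupt-change (rectangular wave) cycle.  Enclosed area is exactly
#' `h0 * (x_hi - x_lo)`.
#'
#' @param h0 drive amplitude, `> 0`.
#' @param x_hi,x_lo top/bottom densities, `x_hi > x_lo >= 0`.
#' @param n_per_edge samples along each vertical branch.
#' @return A `trajectory`-like list with attribute `"truth"` (`area`,
#'   `delta_x`).
#' @export
make_rect_loop <- function(h0 = 1, x_hi = 9, x_lo = 7, n_per_edge = 500L) {
  stopifnot(h0 > 0, x_hi > x_lo, x_lo >= 0, n_per_edge >= 2)
  down <- seq(x_hi, x_lo, length.out = n_per_edge)
  up <- seq(x_lo, x_hi, length.out = n_per_edge)
  x <- c(down, up)
  h <- c(rep(h0, n_per_edge), rep(0, n_per_edge))
  t <- seq(0, 1, length.out = length(x))
  structure(list(t = t, h = h, x = x),
            class = "trajectory",
            truth = list(area = h0 * (x_hi - x_lo), delta_x = x_hi - x_lo))
}

#' Synthetic response surface obeying a known quadratic law
#'
#' Builds a response surface whose collapse answer is known exactly: dose
#' cumulants `I[i, j]` follow the waveform closed form, and loop areas are
#' set to `S[i, j] = h0[i] * (F(I'[i, j]) + sigma * e[i, j])` with
#' `F(u) = m u^2 + n u`, `I'` the per-row max-normalized cumulant, and
#' `e ~ N(0, 1)` seeded noise (`sigma` is stated on the `Y = S/h0` scale so
#' one value perturbs every amplitude row equally).
#'
#' Under the max-normalization reduction the quadratic is identifiable
#' only up to the per-row scale `k = 1 / max_j F(I'[j])` (reduced `Y'`
#' always has row maximum 1), so the emitted ground truth contains both the
#' generating pair (`m`, `n`) and the recoverable pair
#' `(m_reduced, n_reduced) = k * (m, n)`; the peak location
#' `x_star = -n/(2m)` is scale-free.
#'
#' @param m,n generating coefficients with `m < 0 < n` and vertex
#'   `-n/(2m)` in `(0, 1)`.
#' @param h0_grid,d_grid surface grids (defaults: 0.1–1.0 and 0.1–0.9,
#'   step 0.1).
#' @param T cycle period used for the `I` closed form.
#' @param waveform `"rectangular"` or `"halfsine"`.
#' @param noise_sigma Gaussian noise s.d. on the `Y` scale (0 = exact).
#' @param seed RNG seed for the noise; required when `noise_sigma > 0`.
#' @return A `response_surface` with attribute `"truth"` containing
#'   `m`, `n`, `m_reduced`, `n_reduced`, `k`, `x_star`, `y_star_reduced`.
#' @export
make_quadratic_surface <- function(m = -1, n = 1,
                                   h0_grid = seq(0.1, 1.0, by = 0.1),
                                   d_grid = seq(0.1, 0.9, by = 0.1),
                                   T = 1, waveform = "rectangular",
                                   noise_sigma = 0, seed = NULL) {
  stopifnot(m < 0, n > 0, noise_sigma >= 0, T > 0)
  waveform <- match.arg(waveform, c("rectangular", "halfsine"))
  vertex <- -n / (2 * m)
  if (vertex <= 0 || vertex >= 1)
    stop("make_quadratic_surface: vertex -n/(2m) must lie in (0, 1)")
  if (noise_sigma > 0 && is.null(seed))
    stop("make_quadratic_surface: noisy fixtures need a seed")
  wf_scale <- if (waveform == "rectangular") 1 else 2 / pi
  # I' depends only on d (row maxima cancel h0 and the waveform factor)
  i_prime <- d_grid / max(d_grid)
  f_vals <- m * i_prime^2 + n * i_prime
  k <- 1 / max(f_vals)
  noise <- .with_seed(seed, matrix(
    if (noise_sigma > 0) rnorm(length(h0_grid) * length(d_grid)) else 0,
    nrow = length(h0_grid), ncol = length(d_grid)))
  rows <- list()
  idx <- 0L
  for (i in seq_along(h0_grid)) {
    for (j in seq_along(d_grid)) {
      idx <- idx + 1L
      y <- f_vals[j] + noise_sigma * noise[i, j]
      rows[[idx]] <- data.frame(
        waveform = waveform, h0 = h0_grid[i], d = d_grid[j], T = T,
        S = h0_grid[i] * y, I = wf_scale * h0_grid[i] * d_grid[j] * T,
        mean_x = NA_real_, delta_x = NA_real_,
        eradicated = FALSE, converged = TRUE)
    }
  }
  surf <- new_response_surface(do.call(rbind, rows), h0_grid, d_grid,
                               waveform, T)
  attr(surf, "truth") <- list(
    m = m, n = n, k = k, m_reduced = k * m, n_reduced = k * n,
    x_star = vertex, y_star_reduced = k * (-n^2 / (4 * m)),
    noise_sigma = noise_sigma, seed = seed)
  surf
}

#' Sigmoid dose-effect curve fixture
#'
#' Mean-burden curve `mean_x = ceiling / (1 + exp(slope * (I - midpoint)))`
#' on a given dose grid — the canonical sigmoidal dose-effect shape.  The
#' ground-truth optimal dose cumulant is computed by a direct scan of the
#' flat-tail definition (central differences, threshold
#' `flatness_frac * max|deriv|`), written here independently of
#' [optimal_dose_cumulant()].
#'
#' @param midpoint inflection dose.
#' @param slope steepness (`>= 0`; 0 gives a flat curve).
#' @param ceiling untreated burden level, `> 0`.
#' @param I_grid strictly increasing dose grid.
#' @param flatness_frac threshold used for the ground-truth scan.
#' @return data.frame `(I, mean_x)` with attribute `"truth"` containing
#'   `I_O` (may be `NA`) and the generator parameters.
#' @export
make_sigmoid_curve <- function(midpoint = 3, slope = 2, ceiling = 10,
                               I_grid = seq(0, 8, by = 0.25),
                               flatness_frac = 0.1) {
  stopifnot(slope >= 0, ceiling > 0, length(I_grid) >= 3,
            all(diff(I_grid) > 0))
  mean_x <- ceiling / (1 + exp(slope * (I_grid - midpoint)))
  # independent direct scan of the flat-tail definition
  nI <- length(I_grid)
  der <- numeric(nI)
  der[1] <- (mean_x[2] - mean_x[1]) / (I_grid[2] - I_grid[1])
  der[nI] <- (mean_x[nI] - mean_x[nI - 1]) / (I_grid[nI] - I_grid[nI - 1])
  for (i in 2:(nI - 1))
    der[i] <- (mean_x[i + 1] - mean_x[i - 1]) / (I_grid[i + 1] - I_grid[i - 1])
  thr <- flatness_frac * max(abs(der))
  I_O <- NA_real_
  for (kk in seq_len(nI)) {
    if (all(abs(der[kk:nI]) <= thr)) { I_O <- I_grid[kk]; break }
  }
  structure(data.frame(I = I_grid, mean_x = mean_x),
            truth = list(I_O = I_O, midpoint = midpoint, slope = slope,
                         ceiling = ceiling, flatness_frac = flatness_frac))
}

#' Ground truth attached to a fixture
#'
#' @param fixture any fixture object produced by the `make_*` generators.
#' @return The `"truth"` attribute (a list).
#' @export
fixture_truth <- function(fixture) {
  tr <- attr(fixture, "truth")
  if (is.null(tr)) stop("fixture_truth: object carries no ground truth")
  tr
}
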