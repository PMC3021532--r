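#' Area of the dynamic hysteresis loop
#'
#' Area enclosed by the closed curve `(h(t), x(t))` over one steady cycle,
#' computed with the shoelace (Green's theorem) formula on the sampled
#' polygon, wrapping the last sample back to the first.  Reported as an
#' absolute value (the loop's orientation is returned in the
#' `"orientation"` attribute: +1 counter-clockwise, -1 clockwise, 0
#' degenerate); in the continuum limit this equals `|closed integral of x dh|`.
#' The rectangular wave's jumps are handled naturally because the polygon
#' contains both the pre- and post-jump samples.
#'
#' @param traj a [trajectory][integrate_to_limit_cycle()] or any list with
#'   numeric `h` and `x` of equal length `>= 3` covering one closed cycle.
#' @return Nonnegative loop area (density x intervention units).
#' @examples
#' loop_area(make_ellipse_loop(h0 = 1, x0 = 2, phi = pi / 2, c = 3))  # ~ 2*pi
#' @export
loop_area <- function(traj) {
  h <- traj$h; x <- traj$x
  if (is.null(h) || is.null(x) || length(h) != length(x))
    stop("loop_area: need 'h' and 'x' of equal length")
  if (length(h) < 3) stop("loop_area: need at least 3 samples")
  if (anyNA(h) || anyNA(x)) stop("loop_area: NA in trajectory")
  h2 <- c(h[-1], h[1]); x2 <- c(x[-1], x[1])
  signed <- 0.5 * sum(h * x2 - h2 * x)
  structure(abs(signed), orientation = sign(signed))
}

#' Dose cumulant per cycle
#'
#' Total dose delivered in one cycle, `I = integral of h(t) dt` over `[0, T]`,
#' in closed form: `h0 * d * T` for the rectangular pulse,
#' `(2/pi) * h0 * d * T` for the half-sine pulse, 0 for `"none"`.
#'
#' @param spec an [intervention_spec()].
#' @return Scalar dose cumulant (intervention x time units).
#' @examples
#' dose_cumulant(intervention_spec("rectangular", h0 = 0.5, T = 10, d = 0.4))  # 2
#' @export
dose_cumulant <- function(spec) {
  stopifnot(inherits(spec, "intervention_spec"))
  switch(spec$waveform,
         none = 0,
         rectangular = spec$h0 * spec$d * spec$T,
         halfsine = (2 / pi) * spec$h0 * spec$d * spec$T)
}

#' Cycle statistics of a steady trajectory
#'
#' `mean_x` is the time-weighted (trapezoidal) average of `x` over the
#' cycle; `delta_x` is the max-to-min excursion.
#'
#' @param traj a trajectory (list with numeric `t`, `x`).
#' @return List with `mean_x` and `delta_x`.
#' @export
cycle_stats <- function(traj) {
  t <- traj$t; x <- traj$x
  if (is.null(t) || is.null(x) || length(t) < 2 || length(t) != length(x))
    stop("cycle_stats: need 't' and 'x' of equal length >= 2")
  if (anyNA(t) || anyNA(x)) stop("cycle_stats: NA in trajectory")
  span <- t[length(t)] - t[1]
  if (span <= 0) stop("cycle_stats: 't' must span a positive duration")
  mean_x <- sum(diff(t) * (head_(x) + tail_(x)) / 2) / span
  list(mean_x = mean_x, delta_x = max(x) - min(x))
}

head_ <- function(v) v[-length(v)]
tail_ <- function(v) v[-1]

#' Finite-difference slope of the dose-effect curve
#'
#' Derivative of mean tumor burden with respect to an ordinate (dose
#' cumulant `I` or duty-cycle `d`): central differences at interior points,
#' one-sided at the two ends.  Central differences are exact for
#' quadratics on uniform grids, which suits the small raw-point grids these
#' curves live on.
#'
#' @param I strictly increasing ordinate values (`>= 3`).
#' @param mean_x corresponding cycle-averaged densities.
#' @return data.frame with columns `I` and `deriv`.
#' @export
dose_effect_derivative <- function(I, mean_x) {
  if (is.data.frame(I)) { mean_x <- I$mean_x; I <- I$I }
  n <- length(I)
  if (n < 3) stop("dose_effect_derivative: need >= 3 points")
  if (length(mean_x) != n)
    stop("dose_effect_derivative: length mismatch")
  if (anyNA(I) || anyNA(mean_x))
    stop("dose_effect_derivative: NA in input")
  if (any(diff(I) == 0))
    stop("dose_effect_derivative: duplicate ordinate values")
  if (any(diff(I) < 0))
    stop("dose_effect_derivative: ordinate must be strictly increasing")
  deriv <- numeric(n)
  deriv[1] <- (mean_x[2] - mean_x[1]) / (I[2] - I[1])
  deriv[n] <- (mean_x[n] - mean_x[n - 1]) / (I[n] - I[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    deriv[i] <- (mean_x[i + 1] - mean_x[i - 1]) / (I[i + 1] - I[i - 1])
  }
  data.frame(I = I, deriv = deriv)
}

# shared flat-tail detector: smallest ordinate index k such that
# |deriv[i]| <= flatness_frac * max|deriv| for all i >= k
.flat_tail_onset <- function(ord, val, flatness_frac) {
  der <- dose_effect_derivative(ord, val)$deriv
  thr <- flatness_frac * max(abs(der))
  flat <- abs(der) <= thr
  # last index before which some point is not flat
  bad <- which(!flat)
  if (length(bad) == 0) return(ord[1])
  k <- max(bad) + 1L
  if (k > length(ord)) return(NA_real_)
  ord[k]
}

#' Optimal dose cumulant
#'
#' The smallest dose cumulant beyond which the dose-effect curve has
#' flattened: `|d<x>/dI|` stays at or below `flatness_frac` times its
#' maximum for every larger `I`.  Returns `NA` when the curve never
#' flattens (e.g. monotone steepening).  This is a formalization of the
#' "arrow on the sigmoid" reading of dose-effect plots.
#'
#' @param I strictly increasing dose cumulants (or a data.frame with
#'   columns `I`, `mean_x`).
#' @param mean_x corresponding mean densities.
#' @param flatness_frac flatness threshold as a fraction of the peak
#'   absolute slope (default 0.1).
#' @return The optimal dose cumulant, or `NA_real_` if absent.
#' @export
optimal_dose_cumulant <- function(I, mean_x, flatness_frac = 0.1) {
  if (is.data.frame(I)) { mean_x <- I$mean_x; I <- I$I }
  stopifnot(flatness_frac > 0)
  .flat_tail_onset(I, mean_x, flatness_frac)
}

#' Effective duty-cycle of therapy
#'
#' Same flat-tail criterion as [optimal_dose_cumulant()] applied to the
#' `<x>` versus duty-cycle curve at fixed amplitude: the duty-cycle beyond
#' which further dosing barely lowers mean burden.  Can be absent
#' (`NA`) — typically at small amplitudes.
#'
#' @param d strictly increasing duty-cycles (or a data.frame with columns
#'   `d`, `mean_x`).
#' @param mean_x corresponding mean densities.
#' @param flatness_frac flatness threshold fraction (default 0.1).
#' @return The effective duty-cycle, or `NA_real_` if absent.
#' @export
effective_duty_cycle <- function(d, mean_x, flatness_frac = 0.1) {
  if (is.data.frame(d)) { mean_x <- d$mean_x; d <- d$d }
  stopifnot(flatness_frac > 0)
  .flat_tail_onset(d, mean_x, flatness_frac)
}

#' Extract one amplitude row of a response surface as a dose-effect curve
#'
#' @param surface a [response_surface][sweep_grid()].
#' @param h0 amplitude of the row (must match a grid value).
#' @return data.frame `(h0, d, I, S, mean_x, delta_x)` sorted by `I`.
#' @export
dose_effect_curve <- function(surface, h0) {
  stopifnot(inherits(surface, "response_surface"))
  i <- which(abs(surface$h0_grid - h0) < 1e-12)
  if (length(i) != 1)
    stop("dose_effect_curve: h0 = ", h0, " is not on the surface grid")
  rec <- surface$records[surface$records$h0 == surface$h0_grid[i], ]
  rec <- rec[order(rec$I), c("h0", "d", "I", "S", "mean_x", "delta_x")]
  rownames(rec) <- NULL
  rec
}
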