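#' Solver configuration for the limit-cycle integrator
#'
#' @param rtol,atol relative/absolute local error tolerances of the
#'   embedded Dormand-Prince 5(4) stepper.
#' @param n_samples_per_cycle uniform samples per cycle; the reported cycle
#'   has `n + 1` points including both endpoints `t = 0` and `t = T`.
#' @param max_cycles cycles to attempt before giving up on periodicity.
#' @param periodicity_tol absolute tolerance (density units) on
#'   `max |x(t) - x(t + T)|` between consecutive cycles.
#' @param min_transient_cycles minimum number of cycles discarded before
#'   the periodicity test can declare convergence.
#' @param x_floor density below which the state is clamped to 0 and held
#'   there (eradication).
#' @param eradication_threshold a cycle whose minimum density ever drops
#'   below this is flagged `eradicated`.
#' @param x0 initial density; `NULL` means the stable untreated steady
#'   state (treatment-naive tumor).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(rtol = 1e-8, atol = 1e-10,
                          n_samples_per_cycle = 2000L,
                          max_cycles = 200L, periodicity_tol = 1e-6,
                          min_transient_cycles = 5L,
                          x_floor = 1e-8, eradication_threshold = 1e-6,
                          x0 = NULL) {
  stopifnot(rtol > 0, atol > 0, n_samples_per_cycle >= 8,
            max_cycles >= 1, periodicity_tol > 0,
            min_transient_cycles >= 1, x_floor >= 0,
            eradication_threshold >= 0)
  structure(list(rtol = rtol, atol = atol,
                 n_samples_per_cycle = as.integer(n_samples_per_cycle),
                 max_cycles = as.integer(max_cycles),
                 periodicity_tol = periodicity_tol,
                 min_transient_cycles = as.integer(min_transient_cycles),
                 x_floor = x_floor,
                 eradication_threshold = eradication_threshold,
                 x0 = x0),
            class = "solver_config")
}

.default_x0 <- function(params) {
  ss <- untreated_steady_states(params)
  stable <- ss$x[ss$stable & ss$x > 0]
  if (length(stable) == 0)
    stop("no stable positive untreated steady state; supply x0 explicitly")
  max(stable)
}

#' Integrate the forced model to its steady periodic cycle
#'
#' Integrates cycle by cycle with an adaptive Dormand-Prince 5(4) stepper,
#' splitting every cycle at the waveform discontinuity `t = T0` so step
#' transitions never straddle it.  Cycles are discarded until two
#' consecutive cycles agree pointwise to `periodicity_tol` (after at least
#' `min_transient_cycles` transients), or `max_cycles` is reached, in which
#' case `converged = FALSE` is returned rather than an error.  If the
#' density falls below `x_floor` it is clamped to 0 for the remainder
#' (eradication).
#'
#' @param params a [model_params()].
#' @param spec an [intervention_spec()].
#' @param config a [solver_config()].
#' @return An object of class `trajectory`: list with `t`, `x`, `h`
#'   (`n_samples_per_cycle + 1` points over one closed cycle, `h` wraps
#'   periodically so `h[1] == h[n+1]`), `converged`,
#'   `n_transient_cycles`, `eradicated`, `min_x`, `periodicity_gap`, plus
#'   the `params`, `spec` and `config` used.
#' @examples
#' p <- model_params(coupling = "multiplicative")
#' tr <- integrate_to_limit_cycle(p, intervention_spec("rectangular", 0.5, 1, 0.3))
#' tr$converged
#' @export
integrate_to_limit_cycle <- function(params, spec, config = solver_config()) {
  stopifnot(inherits(params, "model_params"),
            inherits(spec, "intervention_spec"),
            inherits(config, "solver_config"))
  x0 <- if (is.null(config$x0)) .default_x0(params) else config$x0
  if (!is.finite(x0) || x0 < 0)
    stop("integrate_to_limit_cycle: x0 must be finite and >= 0")
  res <- cpp_limit_cycle(
    params$a, params$b, params$beta, params$eps,
    .coupling_code(params$coupling),
    .waveform_code(spec$waveform), spec$h0, spec$T, spec$d, x0,
    config$rtol, config$atol, config$n_samples_per_cycle,
    config$max_cycles, config$periodicity_tol,
    config$min_transient_cycles, config$x_floor)
  structure(list(t = res$t, x = res$x, h = res$h,
                 converged = res$converged,
                 n_transient_cycles = res$n_transient_cycles,
                 eradicated = res$min_x < config$eradication_threshold,
                 min_x = res$min_x,
                 periodicity_gap = res$periodicity_gap,
                 params = params, spec = spec, config = config),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %s h0=%g T=%g d=%g | %d samples, converged=%s (%d transients), eradicated=%s\n",
    x$spec$waveform, x$spec$h0, x$spec$T, x$spec$d, length(x$t),
    x$converged, x$n_transient_cycles, x$eradicated))
  invisible(x)
}

#' Sweep an amplitude x duty-cycle grid into a response surface
#'
#' Runs [integrate_to_limit_cycle()] and the per-cycle analytics for every
#' `(h0, d)` combination and assembles the tidy response surface.  The
#' pipeline is fully deterministic; a cell whose integration errors is
#' flagged (`converged = FALSE`, observables `NA`) rather than aborting
#' the sweep.
#'
#' @param params a [model_params()].
#' @param waveform `"rectangular"` or `"halfsine"`.
#' @param h0_values strictly increasing amplitudes (surface rows).
#' @param d_values strictly increasing duty-cycles (surface columns).
#' @param T cycle period.
#' @param config a [solver_config()].
#' @return An object of class `response_surface`: list with `h0_grid`,
#'   `d_grid`, `waveform`, `T`, `params`, `config` and `records`, a
#'   data.frame with one row per cell and columns
#'   `waveform, h0, d, T, S, I, mean_x, delta_x, eradicated, converged`.
#' @seealso [therapy_effect()], [peak_duty_cycle()], [collapse_surfaces()]
#' @export
sweep_grid <- function(params, waveform, h0_values, d_values, T = 1,
                       config = solver_config()) {
  stopifnot(inherits(params, "model_params"))
  waveform <- match.arg(waveform, c("rectangular", "halfsine"))
  .check_grid <- function(g, nm) {
    if (length(g) < 1 || !is.numeric(g) || anyNA(g))
      stop("sweep_grid: '", nm, "' must be a nonempty numeric vector")
    if (length(g) > 1 && any(diff(g) <= 0))
      stop("sweep_grid: '", nm, "' must be strictly increasing")
  }
  .check_grid(h0_values, "h0_values")
  .check_grid(d_values, "d_values")
  # resolve x0 once so every cell shares the same initial condition
  if (is.null(config$x0)) config$x0 <- .default_x0(params)

  rows <- vector("list", length(h0_values) * length(d_values))
  k <- 0L
  for (h0 in h0_values) {
    for (d in d_values) {
      k <- k + 1L
      spec <- intervention_spec(waveform, h0 = h0, T = T, d = d)
      rows[[k]] <- tryCatch({
        tr <- integrate_to_limit_cycle(params, spec, config)
        data.frame(waveform = waveform, h0 = h0, d = d, T = T,
                   S = as.numeric(loop_area(tr)), I = dose_cumulant(spec),
                   mean_x = cycle_stats(tr)$mean_x,
                   delta_x = cycle_stats(tr)$delta_x,
                   eradicated = tr$eradicated, converged = tr$converged)
      }, error = function(e) {
        warning(sprintf("cell (h0=%g, d=%g) failed: %s", h0, d,
                        conditionMessage(e)), call. = FALSE)
        data.frame(waveform = waveform, h0 = h0, d = d, T = T,
                   S = NA_real_, I = NA_real_, mean_x = NA_real_,
                   delta_x = NA_real_, eradicated = NA, converged = FALSE)
      })
    }
  }
  new_response_surface(do.call(rbind, rows), h0_values, d_values,
                       waveform, T, params, config)
}

#' Construct a response surface from tidy records
#'
#' Low-level constructor used by [sweep_grid()], [read_surface()] and the
#' synthetic-surface fixtures.
#'
#' @param records data.frame with one row per `(h0, d)` cell.
#' @param h0_grid,d_grid the grids (rows / columns).
#' @param waveform,T,params,config provenance.
#' @return A `response_surface` object.
#' @keywords internal
#' @export
new_response_surface <- function(records, h0_grid, d_grid, waveform, T,
                                 params = NULL, config = NULL) {
  need <- c("waveform", "h0", "d", "T", "S", "I", "mean_x", "delta_x",
            "eradicated", "converged")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("response surface records missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(records) != length(h0_grid) * length(d_grid))
    stop("response surface records: expected ",
         length(h0_grid) * length(d_grid), " rows, got ", nrow(records))
  structure(list(records = records[need], h0_grid = h0_grid, d_grid = d_grid,
                 waveform = waveform, T = T, params = params,
                 config = config),
            class = "response_surface")
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf(
    "<response_surface> %s: %d amplitudes x %d duty-cycles (T=%g), %d/%d cells converged\n",
    x$waveform, length(x$h0_grid), length(x$d_grid), x$T,
    sum(x$records$converged, na.rm = TRUE), nrow(x$records)))
  invisible(x)
}

# cell lookup as a matrix (rows = h0, cols = d) of one records column
.surface_matrix <- function(surface, col) {
  m <- matrix(surface$records[[col]],
              nrow = length(surface$h0_grid),
              ncol = length(surface$d_grid), byrow = TRUE)
  dimnames(m) <- list(h0 = format(surface$h0_grid, trim = TRUE),
                      d = format(surface$d_grid, trim = TRUE))
  m
}
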