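#' Therapy-effect matrix Y = S / h0
#'
#' Scales each cell's hysteresis-loop area by its row amplitude,
#' `Y[i, j] = S[i, j] / h0_grid[i]` — the per-unit-intensity destructive
#' effect.  Eradicated or unconverged cells propagate as `NA`.
#'
#' @param surface a [response_surface][sweep_grid()].
#' @return Numeric matrix (amplitudes x duty-cycles) with dimnames.
#' @export
therapy_effect <- function(surface) {
  stopifnot(inherits(surface, "response_surface"))
  zero <- which(surface$h0_grid == 0)
  if (length(zero))
    stop("therapy_effect: Y = S/h0 undefined for h0 = 0 (row ",
         paste(zero, collapse = ", "), ")")
  S <- .surface_matrix(surface, "S")
  bad <- .surface_matrix(surface, "eradicated") |
    !.surface_matrix(surface, "converged")
  S[bad | is.na(bad)] <- NA_real_
  sweep(S, 1, surface$h0_grid, "/")
}

#' Duty-cycle of maximal loop area
#'
#' Per amplitude row, the duty-cycle at which the loop area `S` is largest
#' (ties broken to the smallest `d`), plus the consensus over rows: the
#' modal per-row value, ties again broken to the smallest `d`.  Rows with
#' no finite `S` are skipped with a warning.
#'
#' @param surface a [response_surface][sweep_grid()].
#' @return List with `per_row` (named by `h0`), `consensus`, and `range`.
#' @export
peak_duty_cycle <- function(surface) {
  stopifnot(inherits(surface, "response_surface"))
  if (length(surface$d_grid) < 3)
    stop("peak_duty_cycle: need at least 3 duty-cycle columns")
  S <- .surface_matrix(surface, "S")
  per_row <- rep(NA_real_, nrow(S))
  names(per_row) <- rownames(S)
  for (i in seq_len(nrow(S))) {
    if (all(is.na(S[i, ]))) {
      warning("peak_duty_cycle: row h0 = ", surface$h0_grid[i],
              " has no finite S; skipped", call. = FALSE)
      next
    }
    per_row[i] <- surface$d_grid[which.max(S[i, ])]  # which.max: first tie
  }
  ok <- per_row[!is.na(per_row)]
  tab <- table(ok)
  modal <- as.numeric(names(tab)[tab == max(tab)])
  list(per_row = per_row, consensus = min(modal), range = range(ok))
}

#' Reduce a response surface to unit-square points
#'
#' Per amplitude row `i`, max-normalizes both coordinates:
#' `I' = I / max_j I`, `Y' = Y / max_j Y` (finite cells only).  Rows that
#' are all-missing or have a nonpositive maximum are excluded (with a
#' warning) and counted in the `"n_excluded"` attribute.  Pooling the
#' reduced rows of one or more surfaces puts every series on a common
#' unit-square scale regardless of amplitude or waveform.
#'
#' @param surface a [response_surface][sweep_grid()].
#' @param Y therapy-effect matrix; computed via [therapy_effect()] when
#'   `NULL`.
#' @return data.frame `(waveform, h0, d, I, Y, I_prime, Y_prime)` of all
#'   finite cells of the retained rows, with attribute `n_excluded`.
#' @export
reduce_series <- function(surface, Y = NULL) {
  stopifnot(inherits(surface, "response_surface"))
  if (is.null(Y)) Y <- therapy_effect(surface)
  I <- .surface_matrix(surface, "I")
  out <- list()
  n_excluded <- 0L
  for (i in seq_along(surface$h0_grid)) {
    yi <- Y[i, ]; ii <- I[i, ]
    fin <- is.finite(yi) & is.finite(ii)
    if (sum(fin) < 2 || max(yi[fin]) <= 0 || max(ii[fin]) <= 0) {
      warning("reduce_series: row h0 = ", surface$h0_grid[i],
              " excluded (missing or nonpositive maxima)", call. = FALSE)
      n_excluded <- n_excluded + 1L
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      waveform = surface$waveform, h0 = surface$h0_grid[i],
      d = surface$d_grid[fin], I = ii[fin], Y = yi[fin],
      I_prime = ii[fin] / max(ii[fin]), Y_prime = yi[fin] / max(yi[fin]))
  }
  if (length(out) == 0)
    stop("reduce_series: every row was excluded")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Least-squares quadratic through the origin
#'
#' Ordinary least squares for the two-parameter model
#' `y = m x^2 + n x` (no intercept: zero dose implies zero effect).
#' `r_squared` is computed against the no-intercept null,
#' `1 - RSS / sum(y^2)`.
#'
#' @param x,y numeric vectors, `length >= 3`, `x` not all equal.
#' @return An object of class `quad_fit`: list with `m`, `n`, `stderr_m`,
#'   `stderr_n`, `r_squared`, and the vertex `x_star = -n/(2m)`,
#'   `y_star = -n^2/(4m)` (`NA` when `m >= 0`).
#' @examples
#' f <- fit_quadratic_origin(c(0.2, 0.5, 0.8, 1), -2 * c(0.2, 0.5, 0.8, 1)^2 +
#'                             1.6 * c(0.2, 0.5, 0.8, 1))
#' c(f$m, f$n, f$x_star)  # -2, 1.6, 0.4
#' @export
fit_quadratic_origin <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y))
    stop("fit_quadratic_origin: need >= 3 (x, y) pairs")
  if (anyNA(x) || anyNA(y)) stop("fit_quadratic_origin: NA in input")
  if (diff(range(x)) == 0)
    stop("fit_quadratic_origin: design is rank-deficient (all x equal)")
  fit <- stats::lm(y ~ 0 + I(x^2) + x)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("fit_quadratic_origin: design is rank-deficient")
  # SEs straight from the QR factor (summary.lm warns on perfect sigma=0
  # fits, which are routine for the exact fixtures)
  rss <- sum(stats::residuals(fit)^2)
  xtx_inv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(pmax(diag(xtx_inv) * rss / fit$df.residual, 0))
  m <- unname(cf[1]); n <- unname(cf[2])
  structure(list(m = m, n = n,
                 stderr_m = unname(se[1]), stderr_n = unname(se[2]),
                 r_squared = 1 - rss / sum(y^2),
                 x_star = if (m < 0) -n / (2 * m) else NA_real_,
                 y_star = if (m < 0) -n^2 / (4 * m) else NA_real_),
            class = "quad_fit")
}

#' @export
print.quad_fit <- function(x, ...) {
  cat(sprintf(
    "<quad_fit> y = %.6g x^2 + %.6g x  (SE %.3g, %.3g)  R^2 = %.4f\n",
    x$m, x$n, x$stderr_m, x$stderr_n, x$r_squared))
  if (is.finite(x$x_star))
    cat(sprintf("  vertex: x* = %.6g, y* = %.6g\n", x$x_star, x$y_star))
  invisible(x)
}

# vertex-normalization reduction: per-row quadratic fit (I, Y), then
# u = -m_i I / n_i, v = -m_i Y / n_i^2, mapping every row onto v = u - u^2
.vertex_reduce <- function(reduced) {
  out <- list()
  for (key in unique(paste(reduced$waveform, reduced$h0))) {
    r <- reduced[paste(reduced$waveform, reduced$h0) == key, ]
    f <- fit_quadratic_origin(r$I, r$Y)
    if (!is.finite(f$m) || f$m >= 0 || f$n <= 0) {
      warning("vertex reduction: row ", key,
              " has no interior peak; excluded", call. = FALSE)
      next
    }
    r$I_prime <- -f$m * r$I / f$n
    r$Y_prime <- -f$m * r$Y / f$n^2
    out[[length(out) + 1L]] <- r
  }
  if (length(out) == 0) stop("vertex reduction: every row excluded")
  do.call(rbind, out)
}

#' Collapse response surfaces onto the universal quadratic law
#'
#' Reduces each surface with [reduce_series()] (or the vertex-normalization
#' alternative), pools all rows and waveforms, and fits
#' `Y' = m I'^2 + n I'` through the origin — the package's realization of
#' the universal quadratic dose-effectiveness rule.
#'
#' @param ... one or more [response_surface][sweep_grid()] objects computed
#'   on the same grids (typically the half-sine and rectangular sweeps).
#' @param reduction `"max"` (per-row max-normalization of `I` and `Y`,
#'   default) or `"vertex"` (per-row quadratic pre-fit, maps every row onto
#'   `v = u - u^2`; provided for sensitivity analysis).
#' @return An object of class `collapse_result`: list with
#'   `reduced_points`, `m`, `n`, `stderr_m`, `stderr_n`, `r_squared`,
#'   `x_star`, `y_star`, `n_excluded`, `reduction`.
#' @examples
#' fx <- make_quadratic_surface(m = -1, n = 1)
#' collapse_surfaces(fx)$x_star  # 0.5
#' @export
collapse_surfaces <- function(..., reduction = c("max", "vertex")) {
  reduction <- match.arg(reduction)
  surfaces <- list(...)
  if (length(surfaces) == 0) stop("collapse_surfaces: no surfaces given")
  for (s in surfaces) stopifnot(inherits(s, "response_surface"))
  if (length(surfaces) > 1) {
    g1 <- surfaces[[1]]
    for (s in surfaces[-1]) {
      if (!isTRUE(all.equal(s$h0_grid, g1$h0_grid)) ||
          !isTRUE(all.equal(s$d_grid, g1$d_grid)))
        stop("collapse_surfaces: surfaces must share the same grids")
    }
  }
  reduced_list <- lapply(surfaces, reduce_series)
  n_excluded <- sum(vapply(reduced_list, attr, 0L, "n_excluded"))
  pooled <- do.call(rbind, reduced_list)
  if (reduction == "vertex") pooled <- .vertex_reduce(pooled)
  fit <- fit_quadratic_origin(pooled$I_prime, pooled$Y_prime)
  structure(list(reduced_points = pooled,
                 m = fit$m, n = fit$n,
                 stderr_m = fit$stderr_m, stderr_n = fit$stderr_n,
                 r_squared = fit$r_squared,
                 x_star = fit$x_star, y_star = fit$y_star,
                 n_excluded = n_excluded, reduction = reduction),
            class = "collapse_result")
}

#' @export
print.collapse_result <- function(x, ...) {
  cat(sprintf(
    "<collapse_result> %d reduced points (%s reduction, %d rows excluded)\n",
    nrow(x$reduced_points), x$reduction, x$n_excluded))
  cat(sprintf("  Y' = %.4f I'^2 + %.4f I'   R^2 = %.4f\n",
              x$m, x$n, x$r_squared))
  if (is.finite(x$x_star))
    cat(sprintf("  peak at I' = %.4f, Y' = %.4f\n", x$x_star, x$y_star))
  invisible(x)
}
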