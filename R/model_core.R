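#' Tumor-immune model parameters
#'
#' Constants of the autonomous growth law
#' \deqn{dx/dt = a x (1 - b x) - \beta x^2 / (\epsilon + x^2)}
#' i.e. logistic growth (per-capita rate `a`, carrying capacity `1/b`) minus
#' a saturating immunosurveillance term with attack ceiling `beta` and
#' activation threshold `eps`.  `coupling` selects how a therapy waveform
#' `h(t)` enters the forced equation: `"additive"` subtracts `h(t)` directly
#' (a density-independent kill flux), `"multiplicative"` subtracts
#' `h(t) * x` (log-kill, per-capita).
#'
#' Defaults are the reference parameter set `a = 1`, `b = 0.1`,
#' `beta = 1`, `eps = 1`.
#'
#' @param a per-capita linear growth rate (1/time), `> 0`.
#' @param b logistic saturation coefficient (1/density); carrying capacity
#'   is `1/b`. `> 0`.
#' @param beta immune attack strength (density/time), `>= 0`.
#' @param eps immune activation threshold (density^2), `> 0`.
#' @param coupling `"additive"` or `"multiplicative"` intervention coupling.
#' @return An object of class `model_params`.
#' @seealso [rhs()], [untreated_steady_states()], [default_run_config()]
#' @examples
#' p <- model_params()
#' rhs(p, intervention_spec("none"), t = 0, x = 1)  # 0.4
#' @export
model_params <- function(a = 1.0, b = 0.10, beta = 1.0, eps = 1.0,
                         coupling = c("additive", "multiplicative")) {
  coupling <- match.arg(coupling)
  for (nm in c("a", "b", "beta", "eps")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("model_params: '", nm, "' must be a finite numeric scalar")
  }
  if (a <= 0) stop("model_params: 'a' must be > 0")
  if (b <= 0) stop("model_params: 'b' must be > 0")
  if (beta < 0) stop("model_params: 'beta' must be >= 0")
  if (eps <= 0) stop("model_params: 'eps' must be > 0")
  structure(list(a = a, b = b, beta = beta, eps = eps, coupling = coupling),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> a=%g b=%g (capacity 1/b=%g) beta=%g eps=%g coupling=%s\n",
    x$a, x$b, 1 / x$b, x$beta, x$eps, x$coupling))
  invisible(x)
}

#' Periodic intervention specification
#'
#' One cycle of length `T` consists of a drug-taking window `[0, T0)` with
#' `T0 = d * T` followed by a drug-suspension window `[T0, T)`.  The
#' duty-cycle `d` is the drug-taking fraction (papers often quote it as a
#' percentage).  Two pulse shapes are supported: `"rectangular"` (abrupt
#' change, radiotherapy-like) holds `h0` over the window; `"halfsine"`
#' (gradual change, chemotherapy-like) ramps as
#' `h0 * sin(pi * t / T0)` over the window.  `"none"` means no forcing.
#'
#' @param waveform `"rectangular"`, `"halfsine"` or `"none"`.
#' @param h0 intervention amplitude, `>= 0` (forced to 0 for `"none"`).
#' @param T cycle period (time), `> 0`.
#' @param d duty-cycle fraction in `(0, 1]`.
#' @return An object of class `intervention_spec` with fields
#'   `waveform, h0, T, d, T0`.
#' @seealso [waveform_value()], [dose_cumulant()]
#' @export
intervention_spec <- function(waveform = c("rectangular", "halfsine", "none"),
                              h0 = 0, T = 1, d = 0.5) {
  waveform <- match.arg(waveform)
  for (nm in c("h0", "T", "d")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("intervention_spec: '", nm, "' must be a finite numeric scalar")
  }
  if (h0 < 0) stop("intervention_spec: 'h0' must be >= 0")
  if (T <= 0) stop("intervention_spec: 'T' must be > 0")
  if (d <= 0 || d > 1) stop("intervention_spec: 'd' must be in (0, 1]")
  if (waveform == "none") h0 <- 0
  structure(list(waveform = waveform, h0 = h0, T = T, d = d, T0 = d * T),
            class = "intervention_spec")
}

#' @export
print.intervention_spec <- function(x, ...) {
  cat(sprintf("<intervention_spec> %s h0=%g T=%g d=%g (T0=%g)\n",
              x$waveform, x$h0, x$T, x$d, x$T0))
  invisible(x)
}

.waveform_code <- function(waveform)
  c(none = 0L, rectangular = 1L, halfsine = 2L)[[waveform]]
.coupling_code <- function(coupling)
  c(additive = 0L, multiplicative = 1L)[[coupling]]

#' Evaluate the intervention waveform
#'
#' Periodic with period `spec$T`; `t` is reduced mod `T`.  Rectangular:
#' `h0` on `[0, T0)`, 0 on `[T0, T)`.  Half-sine: `h0 sin(pi t / T0)` on
#' `[0, T0)`, 0 after.  Never negative, never exceeds `h0`.
#'
#' @param spec an [intervention_spec()].
#' @param t numeric vector of times (any reals).
#' @return Numeric vector of intervention levels, same length as `t`.
#' @export
waveform_value <- function(spec, t) {
  stopifnot(inherits(spec, "intervention_spec"))
  if (!is.numeric(t)) stop("waveform_value: 't' must be numeric")
  if (spec$waveform == "none" || spec$h0 == 0) return(rep(0, length(t)))
  tm <- t %% spec$T
  on <- tm < spec$T0
  out <- numeric(length(t))
  if (spec$waveform == "rectangular") {
    out[on] <- spec$h0
  } else {
    out[on] <- spec$h0 * sin(pi * tm[on] / spec$T0)
  }
  out
}

#' Right-hand side of the forced tumor-immune ODE
#'
#' `rhs = a x (1 - b x) - beta x^2/(eps + x^2) - c(t)` with
#' `c(t) = h(t)` for additive coupling and `c(t) = h(t) x` for
#' multiplicative coupling.  Vectorized over `t` and `x` (recycled).
#'
#' @param params a [model_params()].
#' @param spec an [intervention_spec()]; use waveform `"none"` for the
#'   unforced law.
#' @param t time(s).
#' @param x tumor population density(ies), `>= 0`.
#' @return Rate(s) of change of `x`.
#' @export
rhs <- function(params, spec, t, x) {
  stopifnot(inherits(params, "model_params"))
  if (any(x < 0)) stop("rhs: 'x' must be >= 0")
  h <- waveform_value(spec, t)
  kill <- if (params$coupling == "additive") h else h * x
  params$a * x * (1 - params$b * x) -
    params$beta * x^2 / (params$eps + x^2) - kill
}

#' Steady states of the unforced model
#'
#' Finds all real nonnegative roots of the autonomous right-hand side
#' (`h == 0`), i.e. `x = 0` plus the nonnegative real roots of the cubic
#' `-a b x^3 + a x^2 - (a b eps + beta) x + a eps = 0`, and classifies each
#' by the sign of `f'(x)` (stable if negative).  Roots from
#' [base::polyroot()] are polished by Newton steps; every returned root has
#' residual `|f(x)| < 1e-9`.
#'
#' @param params a [model_params()].
#' @return A data.frame with columns `x`, `stable` (logical) and `residual`,
#'   sorted by `x`.  Always contains `x = 0`.
#' @examples
#' ss <- untreated_steady_states(model_params())
#' ss$x[ss$stable]  # ~ 8.889
#' @export
untreated_steady_states <- function(params) {
  stopifnot(inherits(params, "model_params"))
  a <- params$a; b <- params$b; beta <- params$beta; eps <- params$eps
  f <- function(x) a * x * (1 - b * x) - beta * x^2 / (eps + x^2)
  fp <- function(x) a * (1 - 2 * b * x) -
    beta * 2 * eps * x / (eps + x^2)^2
  # nontrivial roots: a(1 - b x)(eps + x^2) - beta x = 0
  coefs <- c(a * eps, -(a * b * eps + beta), a, -a * b)  # ascending powers
  z <- polyroot(coefs)
  re <- Re(z)[abs(Im(z)) < 1e-8 * (1 + abs(Re(z)))]
  re <- re[re > 1e-12]
  # Newton polish on the full rhs
  polished <- vapply(re, function(x0) {
    x <- x0
    for (i in 1:60) {
      step <- f(x) / fp(x)
      if (!is.finite(step)) break
      x <- x - step
      if (abs(step) < 1e-14 * (1 + abs(x))) break
    }
    x
  }, numeric(1))
  roots <- c(0, sort(unique(polished)))
  res <- abs(f(roots))
  if (any(res >= 1e-9))
    stop("untreated_steady_states: root polishing failed; residuals = ",
         paste(signif(res, 3), collapse = ", "))
  data.frame(x = roots, stable = fp(roots) < 0, residual = res)
}
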