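# Shared helpers for the dosepulse test suite.

# model constants of the reference parameter set, with the reproduction
# coupling used by the full pipeline (see the package vignette)
repro_params <- function() model_params(coupling = "multiplicative")

# coarse but honest solver settings for unit tests that just need a
# converged cycle quickly; acceptance tests use the full defaults
fast_config <- function(...) {
  solver_config(n_samples_per_cycle = 400L, ...)
}

# small hand-built response surface from explicit S values (matrix rows =
# amplitudes, columns = duty-cycles); I follows the rectangular closed form
toy_surface <- function(S, h0_grid, d_grid, T = 1,
                        eradicated = NULL, converged = NULL) {
  nr <- length(h0_grid); nc <- length(d_grid)
  stopifnot(nrow(S) == nr, ncol(S) == nc)
  if (is.null(eradicated)) eradicated <- matrix(FALSE, nr, nc)
  if (is.null(converged)) converged <- matrix(TRUE, nr, nc)
  rows <- expand.grid(d = d_grid, h0 = h0_grid)[, c("h0", "d")]
  rec <- data.frame(waveform = "rectangular", h0 = rows$h0, d = rows$d,
                    T = T, S = as.vector(t(S)),
                    I = rows$h0 * rows$d * T,
                    mean_x = NA_real_, delta_x = NA_real_,
                    eradicated = as.vector(t(eradicated)),
                    converged = as.vector(t(converged)))
  new_response_surface(rec, h0_grid, d_grid, "rectangular", T)
}
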