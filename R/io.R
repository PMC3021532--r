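# Configuration handling and tabular serialization.  Run configs are JSON
# (human-editable, round-trips exactly through jsonlite); surfaces are tidy
# CSV (one row per (waveform, h0, d) cell, "." decimal, NA marker "NA")
# with a JSON sidecar carrying full provenance, so a run can be reproduced
# bit-for-bit from its outputs.

#' Default run configuration
#'
#' The canonical full-pipeline configuration.  The model constants are the
#' reference set (`a = 1`, `b = 0.1`, `beta = 1`, `eps = 1`); the
#' intervention coupling is `"multiplicative"` and the cycle period
#' `T = 1`, the combination that a sensitivity analysis over
#' (coupling, T) selects as reproducing the reported duty-cycles of
#' maximal loop area (~30% rectangular, ~50% half-sine) — see the package
#' vignette.  Grids are amplitudes 0.1–1.0 and duty-cycles 0.1–0.9, both
#' step 0.1.
#'
#' @param ... named overrides of any top-level field (`model`,
#'   `intervention`, `grids`, `solver`, `analysis`), each itself a list
#'   merged over the defaults.
#' @return An object of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    model = list(a = 1.0, b = 0.10, beta = 1.0, eps = 1.0,
                 coupling = "multiplicative"),
    intervention = list(T = 1.0, waveforms = c("halfsine", "rectangular")),
    # (1:n)/10 rather than seq(): these doubles round-trip decimal JSON/CSV
    grids = list(h0 = (1:10) / 10, d = (1:9) / 10),
    solver = list(rtol = 1e-8, atol = 1e-10, n_samples_per_cycle = 2000L,
                  max_cycles = 200L, periodicity_tol = 1e-6,
                  min_transient_cycles = 5L, x_floor = 1e-8,
                  eradication_threshold = 1e-6),
    analysis = list(flatness_frac = 0.1, reduction = "max"))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg))
      stop("default_run_config: unknown field '", nm, "'")
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
  }
  validate_run_config(structure(cfg, class = "run_config"))
}

#' Validate a run configuration
#'
#' Checks types, grid monotonicity and enum values before any computation.
#'
#' @param config a `run_config` (or a bare list with the same fields).
#' @return The validated `run_config`, invisibly usable.
#' @export
validate_run_config <- function(config) {
  cfg <- unclass(config)
  need <- c("model", "intervention", "grids", "solver", "analysis")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("run config missing section(s): ", paste(miss, collapse = ", "))
  # these constructors do the field-level validation
  do.call(model_params, cfg$model)
  if (length(cfg$grids$h0) == 0 || length(cfg$grids$d) == 0)
    stop("run config: empty grids")
  if (any(diff(cfg$grids$h0) <= 0) || any(diff(cfg$grids$d) <= 0))
    stop("run config: grids must be strictly increasing")
  if (any(cfg$grids$d <= 0) || any(cfg$grids$d > 1))
    stop("run config: duty-cycles must lie in (0, 1]")
  if (!is.numeric(cfg$intervention$T) || cfg$intervention$T <= 0)
    stop("run config: intervention period T must be > 0")
  bad <- setdiff(cfg$intervention$waveforms, c("rectangular", "halfsine"))
  if (length(bad))
    stop("run config: unknown waveform(s): ", paste(bad, collapse = ", "))
  do.call(solver_config, cfg$solver)
  if (!is.numeric(cfg$analysis$flatness_frac) ||
      cfg$analysis$flatness_frac <= 0)
    stop("run config: analysis$flatness_frac must be > 0")
  if (!cfg$analysis$reduction %in% c("max", "vertex"))
    stop("run config: analysis$reduction must be 'max' or 'vertex'")
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration (JSON)
#'
#' @param path file path.
#' @return `read_run_config()` returns the validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg$solver$n_samples_per_cycle <- as.integer(cfg$solver$n_samples_per_cycle)
  cfg$solver$max_cycles <- as.integer(cfg$solver$max_cycles)
  cfg$solver$min_transient_cycles <-
    as.integer(cfg$solver$min_transient_cycles)
  validate_run_config(structure(cfg, class = "run_config"))
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(validate_run_config(config)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# full-precision numeric formatting so CSV round-trips are exact and runs
# are byte-identical
.fmt_num <- function(v) {
  out <- vapply(v, function(z) {
    if (is.na(z)) "NA" else sprintf("%.17g", z)
  }, character(1))
  out
}

#' Write / read a response surface (tidy CSV + JSON sidecar)
#'
#' One row per cell, columns
#' `waveform,h0,d,T,S,I,mean_x,delta_x,eradicated,converged`; numerics are
#' written with 17 significant digits so a write/read round trip
#' reproduces every value exactly, and missing cells survive as `NA`.
#' A `<path>.meta.json` sidecar stores the grids, model parameters and
#' solver configuration.
#'
#' @param surface a [response_surface][sweep_grid()].
#' @param path CSV output path.
#' @return `write_surface()` returns `path` invisibly; `read_surface()`
#'   returns the reconstructed `response_surface`.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "response_surface"))
  rec <- surface$records
  out <- data.frame(waveform = rec$waveform,
                    h0 = .fmt_num(rec$h0), d = .fmt_num(rec$d),
                    T = .fmt_num(rec$T), S = .fmt_num(rec$S),
                    I = .fmt_num(rec$I), mean_x = .fmt_num(rec$mean_x),
                    delta_x = .fmt_num(rec$delta_x),
                    eradicated = rec$eradicated, converged = rec$converged)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  meta <- list(h0_grid = surface$h0_grid, d_grid = surface$d_grid,
               waveform = surface$waveform, T = surface$T,
               params = if (!is.null(surface$params))
                 unclass(surface$params),
               solver = if (!is.null(surface$config))
                 unclass(surface$config))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop("surface file not found: ", path)
  num_cols <- c("h0", "d", "T", "S", "I", "mean_x", "delta_x")
  rec <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("waveform", num_cols, "eradicated", "converged")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("read_surface: ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  for (cl in num_cols) {
    v <- rec[[cl]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      badline <- which(!is.na(v) & is.na(conv))
      if (length(badline))
        stop("read_surface: non-numeric value in column '", cl,
             "' at data line ", badline[1])
      v <- conv
    }
    rec[[cl]] <- v
  }
  meta_path <- paste0(path, ".meta.json")
  params <- NULL; h0_grid <- sort(unique(rec$h0)); d_grid <- sort(unique(rec$d))
  waveform <- rec$waveform[1]; T <- rec$T[1]
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
    h0_grid <- meta$h0_grid; d_grid <- meta$d_grid
    waveform <- meta$waveform; T <- meta$T
    if (!is.null(meta$params)) params <- do.call(model_params, meta$params)
  }
  new_response_surface(rec, h0_grid, d_grid, waveform, T, params)
}

#' Run the full pipeline: sweeps, analytics, collapse
#'
#' Executes [sweep_grid()] for every configured waveform, writes each
#' surface (`surface_<waveform>.csv` + sidecars), pools them through
#' [collapse_surfaces()], and writes `reduced.csv`, `collapse.json`, and
#' the echoed `run_config.json`.  Existing outputs are never silently
#' overwritten: the run refuses unless `force = TRUE`.
#'
#' @param config a [run_config][default_run_config()].
#' @param out_dir output directory (created if absent).
#' @param force overwrite existing outputs.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the `surfaces`, the `collapse` result and
#'   the output `paths`.
#' @export
run_full_pipeline <- function(config = default_run_config(),
                              out_dir = ".", force = FALSE, quiet = FALSE) {
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vapply(config$intervention$waveforms,
           function(w) file.path(out_dir, paste0("surface_", w, ".csv")),
           character(1)),
    reduced = file.path(out_dir, "reduced.csv"),
    collapse = file.path(out_dir, "collapse.json"),
    config = file.path(out_dir, "run_config.json"))
  existing <- paths[file.exists(paths)]
  if (length(existing) && !force)
    stop("run_full_pipeline: output exists (use force = TRUE): ",
         paste(existing, collapse = ", "))

  params <- do.call(model_params, config$model)
  solver <- do.call(solver_config, config$solver)
  surfaces <- list()
  for (w in config$intervention$waveforms) {
    if (!quiet) message("sweeping ", w, " waveform ...")
    surfaces[[w]] <- sweep_grid(params, w, config$grids$h0, config$grids$d,
                                T = config$intervention$T, config = solver)
    write_surface(surfaces[[w]], paths[[w]])
  }
  col <- do.call(collapse_surfaces,
                 c(unname(surfaces),
                   list(reduction = config$analysis$reduction)))
  red <- col$reduced_points
  red_out <- red
  for (cl in c("h0", "d", "I", "Y", "I_prime", "Y_prime"))
    red_out[[cl]] <- .fmt_num(red[[cl]])
  utils::write.csv(red_out, paths[["reduced"]], row.names = FALSE,
                   quote = FALSE, na = "NA")
  jsonlite::write_json(
    list(m = col$m, n = col$n, stderr_m = col$stderr_m,
         stderr_n = col$stderr_n, r_squared = col$r_squared,
         x_star = col$x_star, y_star = col$y_star,
         n_excluded = col$n_excluded, reduction = col$reduction,
         n_points = nrow(red), config = unclass(config)),
    paths[["collapse"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_config(config, paths[["config"]])
  if (!quiet) {
    message(sprintf("collapse: Y' = %.4f I'^2 + %.4f I' (R^2 = %.3f), peak I' = %.3f",
                    col$m, col$n, col$r_squared, col$x_star))
  }
  invisible(list(surfaces = surfaces, collapse = col, paths = paths))
}
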