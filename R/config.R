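#' Build a validated run configuration
#'
#' A run configuration gathers everything needed to reproduce a simulation:
#' parameter source, inflammation specification, solver settings, outputs,
#' optional drug regimen, and the seed. Configurations can be written by
#' hand, loaded from a YAML document ([read_run_config()]), or taken from
#' the shipped presets ([preset_config()]).
#'
#' @param mode one of `"ode"`, `"pde"`, `"treatment"`.
#' @param params `NULL` for package defaults, or a path to a parameter
#'   table for [load_param_table()].
#' @param inflammation list describing the drivers: either uniform
#'   (`R_star`, `Rbar_star` amplitudes, optional multipliers `mult_R`,
#'   `mult_Rbar`) or a map spec (`map = list(n_x, n_y, fractions)`); plus
#'   ramp constants `K` and `gamma`.
#' @param solver list: `t_end`, `sample_interval` (ODE), `grid = list(n_x,
#'   n_y, h)` and `dt`, `snapshot_times` (PDE), `rtol`.
#' @param output list: `dir` (required to write anything), `cadence` for
#'   crossing reports.
#' @param drug optional list with `t0` and optionally `Dstar`, `K_D`,
#'   `mu`, `mu_star`.
#' @param seed integer seed for map generation.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode, params = NULL,
                       inflammation = list(R_star = 1.85e-6,
                                           Rbar_star = 4.13e-10,
                                           K = 100, gamma = 1),
                       solver = list(t_end = 3650),
                       output = list(),
                       drug = NULL,
                       seed = 1L) {
  mode <- match.arg(mode, c("ode", "pde", "treatment"))
  fail <- function(field, msg) {
    stop("invalid run configuration at '", field, "': ", msg, call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!is.null(params) && !is.character(params)) {
    fail("params", "must be NULL or a file path")
  }
  infl <- inflammation
  if (is.null(infl$K)) infl$K <- 100
  if (is.null(infl$gamma)) infl$gamma <- 1
  if (!num1(infl$K) || infl$K <= 0) fail("inflammation.K", "must be > 0")
  if (!num1(infl$gamma) || infl$gamma <= 0) {
    fail("inflammation.gamma", "must be > 0")
  }
  if (!is.null(infl$map)) {
    m <- infl$map
    if (is.null(m$n_x) || is.null(m$n_y) || is.null(m$fractions)) {
      fail("inflammation.map", "needs n_x, n_y and fractions")
    }
    if (length(m$fractions) != 4 || abs(sum(m$fractions) - 1) > 1e-9) {
      fail("inflammation.map.fractions", "must be 4 fractions summing to 1")
    }
  }
  if (is.null(infl$R_star)) infl$R_star <- 1.85e-6
  if (is.null(infl$Rbar_star)) infl$Rbar_star <- 4.13e-10
  if (infl$R_star < 0 || infl$Rbar_star < 0) {
    fail("inflammation.R_star", "amplitudes must be >= 0")
  }
  if (is.null(solver$t_end) || !num1(solver$t_end) || solver$t_end <= 0) {
    fail("solver.t_end", "must be a positive number of days")
  }
  if (!is.null(drug)) {
    if (is.null(drug$t0) || !num1(drug$t0) || drug$t0 < 0) {
      fail("drug.t0", "must be a non-negative start day")
    }
    if (drug$t0 > solver$t_end) {
      fail("drug.t0", "start day lies beyond solver.t_end")
    }
  }
  structure(list(mode = mode, params = params, inflammation = infl,
                 solver = solver, output = output, drug = drug,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML document
#'
#' @param path YAML file with top-level keys `mode`, and optionally
#'   `params`, `inflammation`, `solver`, `output`, `drug`, `seed`.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configurations requires the 'yaml' package")
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc$mode)) stop("configuration must name a 'mode'")
  run_config(mode = doc$mode, params = doc$params,
             inflammation = if (is.null(doc$inflammation)) {
               list(R_star = 1.85e-6, Rbar_star = 4.13e-10, K = 100,
                    gamma = 1)
             } else doc$inflammation,
             solver = if (is.null(doc$solver)) list(t_end = 3650) else doc$solver,
             output = if (is.null(doc$output)) list() else doc$output,
             drug = doc$drug,
             seed = if (is.null(doc$seed)) 1L else doc$seed)
}

#' Shipped preset configurations
#'
#' Ready-made configurations for the package's canonical scenarios:
#' \describe{
#' \item{`"endpoints"`}{10-year well-mixed run at baseline drivers (the
#'   endpoint-table scenario; use `mult_R`/`mult_Rbar` for the biased
#'   columns).}
#' \item{`"profiles"`}{10-year well-mixed run sampled every 10 days.}
#' \item{`"nonbiased-map"`}{2-D run on a 40/40/15/5 pixel map to 500 days.}
#' \item{`"longitudinal"`}{slow-ramp 2-D run on the non-biased map to 3600
#'   days with 100-day snapshots.}
#' \item{`"treatment"`}{slow-ramp treated-vs-untreated comparison with
#'   treatment from day 2000.}
#' }
#'
#' @param name preset name.
#' @param seed map seed where applicable.
#' @return A [run_config()].
#' @export
preset_config <- function(name = c("endpoints", "profiles", "nonbiased-map",
                                   "longitudinal", "treatment"),
                          seed = 1L) {
  name <- match.arg(name)
  base_map <- list(n_x = 10, n_y = 10,
                   fractions = c(0.40, 0.40, 0.15, 0.05))
  switch(name,
    "endpoints" = run_config("ode",
      solver = list(t_end = 3650, sample_interval = 10), seed = seed),
    "profiles" = run_config("ode",
      solver = list(t_end = 3650, sample_interval = 10), seed = seed),
    "nonbiased-map" = run_config("pde",
      inflammation = list(map = base_map, K = 100, gamma = 1),
      solver = list(t_end = 500, grid = list(n_x = 50, n_y = 50),
                    snapshot_times = c(100, 250, 500)),
      seed = seed),
    "longitudinal" = run_config("pde",
      inflammation = list(map = base_map, K = 1000, gamma = 1 / 1.4),
      solver = list(t_end = 3600, grid = list(n_x = 50, n_y = 50),
                    snapshot_times = seq(100, 3600, by = 100)),
      seed = seed),
    "treatment" = run_config("treatment",
      inflammation = list(K = 1000, gamma = 1 / 1.4),
      solver = list(t_end = 3650),
      drug = list(t0 = 2000), seed = seed)
  )
}

config_field <- function(cfg, p) {
  infl <- cfg$inflammation
  if (!is.null(infl$map)) {
    m <- infl$map
    pm <- make_pixel_map(m$n_x, m$n_y, m$fractions, seed = cfg$seed)
    map_to_field(pm, infl$R_star, infl$Rbar_star,
                 K = infl$K, gamma = infl$gamma)
  } else {
    mr <- if (is.null(infl$mult_R)) 1 else infl$mult_R
    mb <- if (is.null(infl$mult_Rbar)) 1 else infl$mult_Rbar
    inflammation_field(mr * infl$R_star, mb * infl$Rbar_star,
                       K = infl$K, gamma = infl$gamma)
  }
}

#' Execute a run configuration
#'
#' Dispatches to the requested engine, optionally writes the outputs
#' (trajectory or snapshot CSVs plus a JSON manifest) under
#' `config$output$dir`, and returns the result object.
#'
#' @param config a [run_config()].
#' @param quiet suppress the one-line progress message.
#' @return The engine result: an `ad_trajectory`, `pde_solution` or
#'   `crossing_report`.
#' @export
run <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  ref <- health_reference()
  p <- if (is.null(config$params)) model_params() else {
    load_param_table(config$params, ref)
  }
  sv <- config$solver
  if (!quiet) {
    message("adsim: running mode '", config$mode, "' to t = ", sv$t_end,
            " d (seed ", config$seed, ")")
  }
  result <- switch(config$mode,
    ode = {
      field <- config_field(config, p)
      integrate_ode(p, ref, field, sv$t_end,
                    sample_interval = if (is.null(sv$sample_interval)) 10
                                      else sv$sample_interval,
                    rtol = if (is.null(sv$rtol)) 1e-8 else sv$rtol)
    },
    pde = {
      g <- sv$grid
      grid <- grid2d(if (is.null(g$n_x)) 50 else g$n_x,
                     if (is.null(g$n_y)) 50 else g$n_y,
                     h = if (is.null(g$h)) 1 / (if (is.null(g$n_x)) 50 else g$n_x)
                         else g$h)
      field <- config_field(config, p)
      integrate_pde(grid, p, ref, field, sv$t_end,
                    snapshot_times = sv$snapshot_times, dt = sv$dt)
    },
    treatment = {
      field <- config_field(config, p)
      regimen <- if (is.null(config$drug)) NULL else {
        d <- config$drug
        do.call(drug_regimen, d[!vapply(d, is.null, TRUE)])
      }
      run_treatment_scenario(p, ref, field, regimen,
                             t_end = sv$t_end,
                             cadence = if (is.null(config$output$cadence)) 100
                                       else config$output$cadence)
    }
  )
  dir <- config$output$dir
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (inherits(result, "ad_trajectory")) {
      write_trajectory(result, file.path(dir, "trajectory.csv"))
    } else if (inherits(result, "pde_solution")) {
      write_snapshots(result, dir)
    } else if (inherits(result, "crossing_report")) {
      utils::write.csv(as.data.frame(result),
                       file.path(dir, "crossings.csv"), row.names = FALSE)
    }
    manifest <- list(
      mode = config$mode, seed = config$seed,
      inflammation = config$inflammation, solver = config$solver,
      drug = config$drug,
      package_version = as.character(utils::packageVersion("adsim"))
    )
    jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
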