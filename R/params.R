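#' Healthy-tissue reference state
#'
#' Densities of the seven model variables in healthy brain tissue, the fixed
#' point of the reaction network when both inflammation drivers are zero.
#' All densities are in g/cm^3. The neuron density corresponds to roughly
#' 10^11 neurons of ~1 ng each in a 1500 cm^3 brain; microglia are taken as
#' 12% of neuronal density and astrocytes as four times the microglia.
#' Protein pools come from clinical gray-matter concentrations converted at
#' 1 g tissue = 1 cm^3 = 1 ml.
#'
#' @param N0 neuron density in health, g/cm^3.
#' @param M0 microglia density in health, g/cm^3.
#' @param A0 astrocyte density in health, g/cm^3.
#' @param Abi_ss intraneural amyloid-beta steady state, g/cm^3.
#' @param Abo_ss extraneural amyloid-beta steady state, g/cm^3.
#' @param tau_ss tau protein steady state, g/cm^3.
#'
#' @return An object of class `health_reference`: a named list of the six
#'   densities. Neurofibrillary tangles are zero at this state by
#'   construction (see [nft_from_tau()]).
#' @export
#' @examples
#' ref <- health_reference()
#' nft_from_tau(ref$tau_ss, ref$tau_ss)  # 0 in health
health_reference <- function(N0 = 6.00e-2,
                             M0 = 7.20e-3,
                             A0 = 2.88e-2,
                             Abi_ss = 1.00e-6,
                             Abo_ss = 1.00e-6,
                             tau_ss = 1.37e-10) {
  ref <- list(N0 = N0, M0 = M0, A0 = A0,
              Abi_ss = Abi_ss, Abo_ss = Abo_ss, tau_ss = tau_ss)
  vals <- unlist(ref)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all health reference densities must be finite and strictly positive")
  }
  structure(ref, class = "health_reference")
}

# Names of the rate/saturation/diffusion constants, in display order.
.param_names <- c(
  "lambda_Abi", "d_Abi",
  "lambda_Abo", "lambda_AboN", "d_AboM", "d_Abo", "lambda_AboA",
  "lambda_tau", "lambda_tauAbi", "d_tau",
  "delta_MAbo", "K_gradAbo", "D_M",
  "lambda_M", "lambda_MAbo", "K_Abo", "lambda_MFi", "K_Fi", "d_M",
  "lambda_A", "lambda_AM", "K_M", "d_A",
  "d_NFi", "d_NAbo",
  "D_Abi", "D_Abo", "D_tau"
)

#' Model rate, saturation and diffusion constants
#'
#' Assemble the full constant set of the reaction-diffusion network. Rates
#' are per day, densities g/cm^3, diffusivities cm^2/day, and the
#' chemotactic coefficient `delta_MAbo` is a speed bound in cm/day.
#'
#' The degradation rates of the fast protein pools (`d_Abi`, `d_tau`) and
#' the tau sensitivity to intraneural amyloid excess (`lambda_tauAbi`)
#' follow from the quasi-steady-state response of those pools to the
#' saturated inflammation drivers, using the published 10-year endpoints of
#' the well-mixed system. Constants not pinned down by those clinical
#' summary values alone (Hill constants, clearance and activation rates,
#' the death-rate split, diffusivities) ship as a documented default set
#' fitted once against the same 10-year endpoint table and the
#' longitudinal average-density series; see the methods vignette. Any value
#' can be overridden here or via [load_param_table()].
#'
#' Production rates (`lambda_Abi`, `lambda_Abo`, `lambda_tau`, `lambda_M`,
#' `lambda_A`) default to `NA` and are filled by
#' [calibrate_health_fixed_point()] so that the healthy state is an exact
#' equilibrium; passing `calibrate = TRUE` (default) does this for you.
#'
#' @param ... named overrides of individual constants.
#' @param ref a [health_reference()] used for calibration.
#' @param calibrate logical; fill the production rates from the health
#'   fixed-point identities (default `TRUE`).
#'
#' @return An object of class `model_params`: a named list of constants.
#' @export
#' @examples
#' p <- model_params()
#' p$d_tau * health_reference()$tau_ss == p$lambda_tau  # calibrated
model_params <- function(..., ref = health_reference(), calibrate = TRUE) {
  p <- list(
    # intraneural amyloid-beta (production calibrated; decay from the
    # quasi-steady response Abi = Abi_ss + R/d_Abi at the saturated driver)
    lambda_Abi = NA_real_, d_Abi = 1.8567123,
    # extraneural amyloid-beta: microglial clearance, baseline clearance,
    # necrosis leak of intraneural amyloid, astrocytic secretion
    lambda_Abo = NA_real_, lambda_AboN = 1.7382993e4, d_AboM = 55.231954,
    d_Abo = 0.67326686, lambda_AboA = 22.477464,
    # tau: production calibrated; amyloid-driven hyperphosphorylation
    lambda_tau = NA_real_, lambda_tauAbi = 7.8358006e-05, d_tau = 1.3885018,
    # microglia: flux-limited chemotaxis toward extraneural amyloid,
    # activation by amyloid excess and by tangles
    delta_MAbo = 2.0e-4, K_gradAbo = 1.0e-4, D_M = 1.0e-5,
    lambda_M = NA_real_, lambda_MAbo = 2.7405005e-02, K_Abo = 5.7566698e-6,
    lambda_MFi = 2.6624754e-02, K_Fi = 2.2304061e-10, d_M = 4.8743745e-2,
    # astrocytes: activation saturating in microglia density
    lambda_A = NA_real_, lambda_AM = 8.8647067e-03, K_M = 8.8573110e-3,
    d_A = 1.0158817e-02,
    # neuron death: tangle-driven and amyloid-driven terms share the Hill
    # constants of the microglial activation terms
    d_NFi = 1.2152498e-04, d_NAbo = 1.1234320e-04,
    # diffusivities, cm^2/day (chosen so 500-day spatial patterns retain
    # pixel-scale contrast on a ~1 cm domain)
    D_Abi = 1.0e-6, D_Abo = 1.0e-5, D_tau = 1.0e-6
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("all parameter overrides must be named")
    }
    unknown <- setdiff(names(dots), .param_names)
    if (length(unknown)) {
      stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  p <- structure(p, class = "model_params")
  validate_model_params(p, allow_na = TRUE)
  if (calibrate) p <- calibrate_health_fixed_point(p, ref)
  p
}

validate_model_params <- function(p, allow_na = FALSE) {
  vals <- unlist(p[.param_names])
  if (length(vals) != length(.param_names)) {
    missing <- setdiff(.param_names, names(p))
    stop("missing model constant(s): ", paste(missing, collapse = ", "))
  }
  bad <- !is.na(vals) & (!is.finite(vals) | vals < 0)
  if (any(bad)) {
    stop("model constants must be non-negative and finite; offending: ",
         paste(names(vals)[bad], collapse = ", "))
  }
  if (!allow_na && anyNA(vals)) {
    stop("uncalibrated production rate(s): ",
         paste(names(vals)[is.na(vals)], collapse = ", "),
         " (run calibrate_health_fixed_point())")
  }
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model constants (rates /day, densities g/cm^3, diffusivities cm^2/day):\n")
  v <- unlist(x[.param_names])
  print(format(v, digits = 6, scientific = TRUE), quote = FALSE)
  invisible(x)
}

#' Published endpoint targets for Alzheimer's disease
#'
#' Average clinical densities reached after the ten-year disease horizon,
#' used as thresholds in longitudinal crossing analyses, together with the
#' horizon itself and the fraction of neurons surviving it.
#'
#' @return A named list: `Abo_AD`, `tau_AD`, `M_AD`, `N_AD` (g/cm^3, average
#'   AD values), `Abo_range`, `tau_range`, `M_range`, `N_range` (clinical
#'   ranges), `horizon` (days) and `survival_fraction`.
#' @export
calibration_targets <- function() {
  ref <- health_reference()
  t <- list(
    Abo_AD = 6.70e-6, tau_AD = 4.90e-10,
    M_AD = 15.84e-3, N_AD = 3.96e-2,
    Abo_range = c(1.1e-6, 2.3e-5),
    tau_range = c(3.0e-10, 1.0e-9),
    M_range = c(9.8e-3, 19.8e-3),
    N_range = c(2.61e-2, 4.87e-2),
    horizon = 3650,
    survival_fraction = 0.66
  )
  stopifnot(t$Abo_AD > ref$Abo_ss, t$tau_AD > ref$tau_ss,
            t$M_AD > ref$M0, t$N_AD < ref$N0)
  t
}

#' Convert a clinical concentration to a tissue density
#'
#' Clinical assays report amyloid-beta in ng per g of gray matter and tau in
#' pg per ml of fluid; the model works in g/cm^3 of tissue. Under the
#' convention that tissue density is 1 g/cm^3 and 1 ml = 1 cm^3, both
#' conversions are linear scalings.
#'
#' @param value concentration, non-negative.
#' @param unit one of `"ng/g"`, `"pg/ml"`, `"g/cm3"`.
#' @return The density in g/cm^3.
#' @export
#' @examples
#' clinical_unit_to_density(1000, "ng/g")   # 1e-6, healthy amyloid
#' clinical_unit_to_density(137, "pg/ml")   # 1.37e-10, healthy tau
clinical_unit_to_density <- function(value, unit = c("ng/g", "pg/ml", "g/cm3")) {
  if (!is.numeric(value) || any(value < 0)) {
    stop("'value' must be a non-negative number")
  }
  if (!is.character(unit) || length(unit) == 0) {
    stop("unknown unit; accepted units: ng/g, pg/ml, g/cm3")
  }
  unit <- unit[1]
  scale <- switch(unit,
    "ng/g"  = 1e-9,  # ng per g tissue; tissue density 1 g/cm^3
    "pg/ml" = 1e-12, # pg per ml; 1 ml = 1 cm^3
    "g/cm3" = 1,
    stop("unknown unit '", unit, "'; accepted units: ng/g, pg/ml, g/cm3")
  )
  value * scale
}

#' Constant neuron death rate from a survival fraction
#'
#' If a fraction `survival_fraction` of neurons survives to `horizon` days
#' under exponential decay, the implied constant death rate is
#' `-log(survival_fraction) / horizon` per day. Scaling the rate by `c`
#' yields survival `survival_fraction^c` at the same horizon, which is how
#' shorter or longer life expectancies at diagnosis map onto the rate.
#'
#' @param survival_fraction fraction in (0, 1) of neurons alive at `horizon`.
#' @param horizon time horizon in days (> 0).
#' @return Death rate per day.
#' @export
#' @examples
#' dN <- neuron_death_rate(0.66, 3650)
#' 6.00e-2 * exp(-dN * 3650)  # 3.96e-2 g/cm^3
neuron_death_rate <- function(survival_fraction, horizon) {
  if (!is.numeric(survival_fraction) || length(survival_fraction) != 1 ||
      survival_fraction <= 0 || survival_fraction >= 1) {
    stop("'survival_fraction' must be a single number in (0, 1)")
  }
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon <= 0) {
    stop("'horizon' must be a single positive number of days")
  }
  -log(survival_fraction) / horizon
}

#' Calibrate production rates to the healthy fixed point
#'
#' Overwrites the five production rates so that the healthy reference state
#' is an exact equilibrium of the reaction network with both inflammation
#' drivers at zero:
#' \deqn{\lambda_{A\beta_i} = d_{A\beta_i} A\beta_i^{ss}, \quad
#'       \lambda_\tau = d_\tau \tau^{ss}, \quad
#'       \lambda_M = d_M M_0,}
#' \deqn{\lambda_A = d_A A_0 - \lambda_{AM} \frac{M_0}{K_M + M_0} A_0, \quad
#'       \lambda_{A\beta_o} = (d_{A\beta_o M} M_0 + d_{A\beta_o})
#'         A\beta_o^{ss} - \lambda_{A\beta_o A} A_0 A\beta_o^{ss}.}
#' At the healthy state the tangle density and all positive-part excesses
#' vanish, so the remaining terms of each equation cancel by construction.
#'
#' @param p a [model_params()] object (production rates may be `NA`).
#' @param ref a [health_reference()].
#' @return `p` with the production rates filled in. Errors if a derived
#'   production rate is negative, which signals inconsistent degradation or
#'   activation inputs.
#' @export
calibrate_health_fixed_point <- function(p, ref = health_reference()) {
  stopifnot(inherits(ref, "health_reference"))
  validate_model_params(p, allow_na = TRUE)
  p$lambda_Abi <- p$d_Abi * ref$Abi_ss
  p$lambda_tau <- p$d_tau * ref$tau_ss
  p$lambda_M <- p$d_M * ref$M0
  p$lambda_A <- p$d_A * ref$A0 -
    p$lambda_AM * (ref$M0 / (p$K_M + ref$M0)) * ref$A0
  p$lambda_Abo <- (p$d_AboM * ref$M0 + p$d_Abo) * ref$Abo_ss -
    p$lambda_AboA * ref$A0 * ref$Abo_ss
  for (nm in c("lambda_A", "lambda_Abo")) {
    if (p[[nm]] < 0) {
      stop("calibration implies negative production rate ", nm,
           "; degradation/activation constants are inconsistent ",
           "with a healthy equilibrium")
    }
  }
  validate_model_params(p, allow_na = FALSE)
  p
}

#' Load model constants from a delimited parameter table
#'
#' Reads a two-or-more-column delimited text file (comma, tab or whitespace
#' separated) whose first two columns are constant name and numeric value;
#' extra columns (units, notes) are ignored. Named constants override the
#' package defaults; the result is re-calibrated to the healthy fixed point.
#'
#' @param path path to the table file.
#' @param ref a [health_reference()] used for re-calibration.
#' @param base optional `model_params` to override instead of the defaults.
#' @return A calibrated `model_params` object.
#' @export
load_param_table <- function(path, ref = health_reference(), base = NULL) {
  if (!file.exists(path)) stop("parameter table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  overrides <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(trimws(lines[i]), "[,\t ]+")[[1]]
    if (length(fields) < 2) {
      stop("line ", lineno[i], ": expected at least 'name value'")
    }
    # skip a header row naming the columns (never a known constant)
    if (i == 1 && !fields[1] %in% .param_names &&
        is.na(suppressWarnings(as.numeric(fields[2])))) next
    val <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(val)) {
      stop("line ", lineno[i], ": malformed number '", fields[2], "'")
    }
    overrides[[fields[1]]] <- val
  }
  unknown <- setdiff(names(overrides), .param_names)
  if (length(unknown)) {
    stop("unknown constant name(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  p <- if (is.null(base)) model_params(ref = ref, calibrate = FALSE) else base
  p[names(overrides)] <- overrides
  validate_model_params(p, allow_na = TRUE)
  calibrate_health_fixed_point(p, ref)
}
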