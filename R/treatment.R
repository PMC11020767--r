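#' Drug regimen for slowing amyloid and tau accumulation
#'
#' Describes an anti-amyloid/anti-tau treatment that begins at day `t0` and
#' whose effect builds up with a saturating time course. From `t0` onward,
#' three production pathways are divided by `1 + w * Dstar * s(t)` with
#' `s(t) = (t - t0) / (K_D + (t - t0))`:
#' \itemize{
#' \item the necrosis leak of intraneural amyloid into the extraneural
#'   pool (weight `w = 1`),
#' \item the astrocytic amyloid secretion term (weight `w = mu`),
#' \item the amyloid-driven tau hyperphosphorylation term (weight
#'   `w = mu_star`).
#' }
#' The drug does not remove the underlying inflammation; it only slows the
#' aggregation of extraneural amyloid and tau.
#'
#' Default `Dstar`, `K_D`, `mu`, `mu_star` were fitted once so that, in the
#' slow-ramp longitudinal scenario, treatment starting at day 2000 delays
#' the amyloid crossing of the average-AD level from day 2500 to day 3100
#' (see the methods vignette), and then frozen.
#'
#' @param t0 treatment start day (>= 0).
#' @param Dstar dimensionless dose (> 0).
#' @param K_D effect saturation time, days (> 0).
#' @param mu,mu_star non-negative modulation weights of the astrocytic and
#'   tau pathways.
#' @return An object of class `drug_regimen`.
#' @export
drug_regimen <- function(t0, Dstar = 6.7949249e-3, K_D = 1874.3247,
                         mu = 8.6752999, mu_star = 133.86615) {
  if (t0 < 0) stop("'t0' must be non-negative")
  if (Dstar <= 0 || K_D <= 0) stop("'Dstar' and 'K_D' must be positive")
  if (mu < 0 || mu_star < 0) stop("'mu' and 'mu_star' must be non-negative")
  structure(list(t0 = t0, Dstar = Dstar, K_D = K_D,
                 mu = mu, mu_star = mu_star),
            class = "drug_regimen")
}

#' Saturating drug attenuation factor
#'
#' `1` before the start day; `1 / (1 + w * Dstar * s(t))` afterwards, with
#' `s(t) = (t - t0) / (K_D + (t - t0))`. Decreasing in `t`, with limit
#' `1 / (1 + w * Dstar)`.
#'
#' @param t time, days (vectorised).
#' @param regimen a [drug_regimen()].
#' @param weight pathway weight `w` (default 1, the necrosis-leak pathway).
#' @return Attenuation factor in (0, 1].
#' @export
#' @examples
#' reg <- drug_regimen(t0 = 2000, Dstar = 2, K_D = 300)
#' drug_factor(2300, reg)  # half saturation: 1 / (1 + Dstar/2)
drug_factor <- function(t, regimen, weight = 1) {
  stopifnot(inherits(regimen, "drug_regimen"))
  s <- pmax(t - regimen$t0, 0)
  1 / (1 + weight * regimen$Dstar * s / (regimen$K_D + s))
}

# Internal: the three pathway factors at time t (all 1 when untreated).
drug_factors <- function(t, regimen = NULL) {
  if (is.null(regimen)) return(list(leak = 1, astro = 1, tau = 1))
  list(leak = drug_factor(t, regimen, 1),
       astro = drug_factor(t, regimen, regimen$mu),
       tau = drug_factor(t, regimen, regimen$mu_star))
}

#' Treated vs untreated longitudinal scenario
#'
#' Runs the well-mixed model twice over a slow-ramp longitudinal horizon —
#' once untreated and once with the drug regimen — and reports the first
#' visit day (on the PET cadence) at which extraneural amyloid and tau
#' reach their average-AD thresholds, together with the treatment delay.
#'
#' @param p a calibrated [model_params()].
#' @param ref a [health_reference()].
#' @param field a spatially uniform [inflammation_field()]; the default is
#'   the baseline-amplitude slow ramp (`K = 1000`, `gamma = 1/1.4`) used
#'   for ten-year longitudinal studies.
#' @param regimen a [drug_regimen()], or `NULL` for an untreated-only run.
#' @param thresholds named numeric vector with elements `Abo` and `tau`;
#'   defaults to the average-AD densities from [calibration_targets()].
#' @param t_end horizon, days.
#' @param cadence visit spacing, days.
#' @return An object of class `crossing_report`: a data frame with one row
#'   per variable and columns `variable`, `threshold`, `untreated`,
#'   `treated`, `delay` (days; `NA` entries where not reached or not run).
#' @export
run_treatment_scenario <- function(p, ref,
                                   field = inflammation_field(
                                     1.85e-6, 4.13e-10,
                                     K = 1000, gamma = 1 / 1.4),
                                   regimen = NULL,
                                   thresholds = NULL,
                                   t_end = 3650, cadence = 100) {
  if (is.null(thresholds)) {
    tg <- calibration_targets()
    thresholds <- c(Abo = tg$Abo_AD, tau = tg$tau_AD)
  }
  if (is.null(names(thresholds)) || !all(nzchar(names(thresholds)))) {
    stop("'thresholds' must be a named vector of variable thresholds")
  }
  untreated <- integrate_ode(p, ref, field, t_end,
                             sample_interval = cadence)
  treated <- if (!is.null(regimen)) {
    integrate_ode(p, ref, field, t_end, sample_interval = cadence,
                  drug = regimen)
  } else NULL
  rows <- lapply(names(thresholds), function(v) {
    thr <- thresholds[[v]]
    cu <- detect_crossing(untreated, v, thr, cadence)
    ct <- if (is.null(treated)) NA_real_ else {
      detect_crossing(treated, v, thr, cadence)
    }
    data.frame(variable = v, threshold = thr,
               untreated = cu, treated = ct, delay = ct - cu)
  })
  rep <- do.call(rbind, rows)
  attr(rep, "regimen") <- regimen
  class(rep) <- c("crossing_report", "data.frame")
  rep
}

#' @export
print.crossing_report <- function(x, ...) {
  reg <- attr(x, "regimen")
  if (is.null(reg)) {
    cat("Untreated longitudinal scenario\n")
  } else {
    cat(sprintf("Treatment from day %g (Dstar = %g, K_D = %g, mu = %g, mu* = %g)\n",
                reg$t0, reg$Dstar, reg$K_D, reg$mu, reg$mu_star))
  }
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-4s reaches %.3g g/cm^3: untreated day %s, treated day %s (delay %s d)\n",
                x$variable[i], x$threshold[i],
                format(x$untreated[i]), format(x$treated[i]),
                format(x$delay[i])))
  }
  invisible(x)
}
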