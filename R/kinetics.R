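#' Positive part
#'
#' `max(x, 0)`, elementwise. Used for the excess-over-health activation
#' terms, which must not act when a density sits below its healthy level.
#'
#' @param x numeric vector or matrix.
#' @return `x` with negative entries replaced by 0.
#' @export
positive_part <- function(x) {
  x[x < 0] <- 0
  x
}

#' Neurofibrillary tangle density from tau
#'
#' Tangles are taken as a fixed 60% of the hyperphosphorylated-tau excess
#' over its healthy level: `F_i = 0.6 * (tau - tau_ss)`, floored at zero
#' (tau below its healthy level cannot produce a negative tangle density).
#' Tangles are an algebraic function of tau, not an integrated state.
#'
#' @param tau tau density, g/cm^3 (vectorised).
#' @param tau_ss healthy tau density, g/cm^3.
#' @return Tangle density, g/cm^3.
#' @export
#' @examples
#' nft_from_tau(4.81e-10, 1.37e-10)  # 2.064e-10
nft_from_tau <- function(tau, tau_ss) {
  if (any(tau < 0) || any(tau_ss < 0)) stop("tau densities must be >= 0")
  positive_part(0.6 * (tau - tau_ss))
}

#' Reaction rates of the seven-variable network
#'
#' Evaluates the non-spatial (reaction) time derivatives shared by the
#' well-mixed and spatial engines. The state is the six integrated
#' densities; the tangle density is derived algebraically via
#' [nft_from_tau()]. All components may be scalars or equal-shaped arrays
#' (one entry per grid cell).
#'
#' The kinetics are:
#' \itemize{
#' \item intraneural amyloid: `(R + lambda_Abi - d_Abi*Abi) * N/N0` — driven
#'   by the amyloid inflammation driver, scaled by the surviving neuron
#'   fraction;
#' \item extraneural amyloid: constitutive production, necrosis leak of
#'   intraneural amyloid proportional to the neuron death rate, microglial
#'   and baseline clearance, astrocytic secretion (bilinear in `A` and
#'   `Abo`);
#' \item tau: `(Rbar + lambda_tau + lambda_tauAbi*(Abi - Abi_ss)^+ -
#'   d_tau*tau) * N/N0`;
#' \item microglia: constitutive turnover plus saturating activation by
#'   extraneural amyloid excess and by tangles;
#' \item astrocytes: activation saturating in microglia density;
#' \item neurons: two death channels (tangle-driven and amyloid-driven),
#'   both saturating; the neuron derivative is computed first and reused in
#'   the necrosis-leak term, so no numerical differentiation is involved.
#' }
#'
#' @param state named list with elements `N`, `M`, `A`, `Abi`, `Abo`, `tau`
#'   (scalars or arrays of a common shape), all non-negative.
#' @param p a calibrated [model_params()].
#' @param ref a [health_reference()].
#' @param R_val,Rbar_val local, already-ramped inflammation driver values,
#'   g/(cm^3 day), scalars or arrays matching the state.
#' @param drug optional list of multiplicative drug factors `leak`, `astro`,
#'   `tau` in (0, 1] (see [drug_factor()]); `NULL` means no treatment.
#' @return Named list of time derivatives `N`, `M`, `A`, `Abi`, `Abo`,
#'   `tau` in g/(cm^3 day), plus `Fi` (the algebraic tangle density used).
#' @export
reaction_rhs <- function(state, p, ref, R_val, Rbar_val, drug = NULL) {
  if (any(unlist(state) < 0)) stop("state densities must be non-negative")
  if (any(R_val < 0) || any(Rbar_val < 0)) {
    stop("inflammation driver values must be non-negative")
  }
  N <- state$N; M <- state$M; A <- state$A
  Abi <- state$Abi; Abo <- state$Abo; tau <- state$tau
  if (is.null(drug)) drug <- list(leak = 1, astro = 1, tau = 1)

  Fi <- nft_from_tau(tau, ref$tau_ss)
  x_Abo <- positive_part(Abo - ref$Abo_ss)
  x_Abi <- positive_part(Abi - ref$Abi_ss)
  sat_Abo <- x_Abo / (p$K_Abo + x_Abo)
  sat_Fi <- Fi / (p$K_Fi + Fi)
  nfrac <- N / ref$N0

  # neuron death first: per-capita rate reused in the necrosis leak
  death_rate <- p$d_NFi * sat_Fi + p$d_NAbo * sat_Abo
  dN <- -death_rate * N

  dAbi <- (R_val + p$lambda_Abi - p$d_Abi * Abi) * nfrac

  dAbo <- p$lambda_Abo +
    p$lambda_AboN * death_rate * (Abi * drug$leak) -
    p$d_AboM * M * Abo - p$d_Abo * Abo +
    p$lambda_AboA * A * (Abo * drug$astro)

  dtau <- (Rbar_val + p$lambda_tau +
             p$lambda_tauAbi * (x_Abi * drug$tau) -
             p$d_tau * tau) * nfrac

  dM <- p$lambda_M +
    M * (p$lambda_MAbo * sat_Abo + p$lambda_MFi * sat_Fi) -
    p$d_M * M

  dA <- p$lambda_A + p$lambda_AM * (M / (p$K_M + M)) * A - p$d_A * A

  list(N = dN, M = dM, A = dA, Abi = dAbi, Abo = dAbo, tau = dtau, Fi = Fi)
}
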