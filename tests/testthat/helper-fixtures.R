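# Shared fixtures: default calibrated constants, health reference and the
# published driver amplitudes used across the suite.
ref <- adsim::health_reference()
par0 <- adsim::model_params()
R_STAR <- 1.85e-6
RBAR_STAR <- 4.13e-10

health_state <- function() {
  list(N = ref$N0, M = ref$M0, A = ref$A0,
       Abi = ref$Abi_ss, Abo = ref$Abo_ss, tau = ref$tau_ss)
}

slow_field <- function(mult_R = 1, mult_Rbar = 1) {
  adsim::inflammation_field(mult_R * R_STAR, mult_Rbar * RBAR_STAR,
                            K = 1000, gamma = 1 / 1.4)
}
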