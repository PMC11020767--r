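---
title: "An inflammation-driven model of amyloid and tau dynamics: model, calibration and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An inflammation-driven model of amyloid and tau dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adsim)
```

## The biological picture

Alzheimer's disease is marked by two protein pathologies visible in PET
scans: extracellular plaques of amyloid-$\beta$ and intraneural
neurofibrillary tangles of hyperphosphorylated tau. Both accumulate for a
decade or more before clinical symptoms. `adsim` implements a compact
dynamical model of this preclinical phase built on one organizing
assumption: early neuroinflammation (reactive oxygen species in neurons)
drives both pathologies, through two separate channels — a driver $R$ that
accelerates intraneural amyloid production and a driver $\bar R$ that
accelerates tau hyperphosphorylation. Because the two channels are
independent and spatially variable, the model can generate the full range
of observed PET patterns: amyloid-dominant, tau-dominant, or balanced.

Seven tissue-level densities (all in g/cm$^3$) are tracked: neurons $N$,
microglia $M$, astrocytes $A$, intraneural amyloid $A\beta_i$, extraneural
amyloid $A\beta_o$, tau $\tau$, and tangles $F_i$. The tissue is treated
as two co-located continua (intraneural and extraneural), in the spirit of
the bidomain models of cardiac electrophysiology: intraneural kinetics are
scaled by the surviving neuron fraction $N/N_0$.

## The reaction network

$$\frac{\partial A\beta_i}{\partial t} - D_{A\beta_i}\nabla^2 A\beta_i
  = \left[R + \lambda_{A\beta_i} - d_{A\beta_i} A\beta_i\right]
    \frac{N}{N_0}$$

$$\frac{\partial A\beta_o}{\partial t} - D_{A\beta_o}\nabla^2 A\beta_o
  = \lambda_{A\beta_o}
    - \lambda_{A\beta_o N}\frac{1}{N}\frac{\partial N}{\partial t} A\beta_i
    - d_{A\beta_o M} M A\beta_o - d_{A\beta_o} A\beta_o
    + \lambda_{A\beta_o A} A\, A\beta_o$$

$$\frac{\partial \tau}{\partial t} - D_\tau\nabla^2 \tau
  = \left[\bar R + \lambda_\tau
     + \lambda_{\tau A\beta_i}(A\beta_i - A\beta_i^{ss})^+
     - d_\tau \tau\right]\frac{N}{N_0},
  \qquad F_i = 0.6\,(\tau - \tau^{ss})$$

$$\frac{\partial M}{\partial t}
  + \delta_{MA\beta_o}\nabla\!\cdot\!\left(M
      \frac{\nabla A\beta_o}{K_{\nabla A\beta_o} + |\nabla A\beta_o|}\right)
  - D_M \nabla^2 M
  = \lambda_M + M\left(
      \frac{\lambda_{MA\beta_o}(A\beta_o - A\beta_o^{ss})^+}
           {K_{A\beta_o} + (A\beta_o - A\beta_o^{ss})^+}
    + \frac{\lambda_{MF_i} F_i}{K_{F_i} + F_i}\right) - d_M M$$

$$\frac{dA}{dt} = \lambda_A + \lambda_{AM}\frac{M}{K_M + M} A - d_A A,
\qquad
\frac{\partial N}{\partial t}
  = -\,d_{NF_i}\frac{F_i}{K_{F_i} + F_i}N
    -\,d_{NA\beta_o}\frac{(A\beta_o - A\beta_o^{ss})^+}
       {K_{A\beta_o} + (A\beta_o - A\beta_o^{ss})^+}N$$

with no-flux (homogeneous Neumann) boundaries for the four mobile species.
The inflammation drivers ramp in time from zero,

$$R(x, y, t) = R(x, y)\,\frac{t/\gamma}{K + t},$$

and likewise for $\bar R$: `K` sets how fast the plateau is approached and
$1/\gamma$ scales the plateau. The fast scenario uses $K = 100$ d,
$\gamma = 1$; the slow longitudinal scenario uses $K = 1000$ d,
$1/\gamma = 1.4$, which reaches AD-range densities only after about seven
years.

Points worth noting, because they are where a re-implementation can go
wrong:

* **Tangles are algebraic, not integrated.** $F_i$ is recomputed from
  $\tau$ at every evaluation, floored at zero. Tau never falls below its
  healthy level along any scenario shipped here, so the floor is inactive
  in practice, but it guards against unphysical negative tangle densities
  in exotic parameter regimes.
* **The necrosis leak uses the analytic death rate.** The
  $-\lambda_{A\beta_o N}\,(1/N)\,\partial N/\partial t\,A\beta_i$ term is
  evaluated by computing the neuron equation first and substituting, so it
  is always non-negative and no numerical differentiation is involved.
* **The astrocytic secretion term is bilinear** in $A$ and $A\beta_o$, as
  written above; the health-state calibration absorbs it into
  $\lambda_{A\beta_o}$ so the healthy state remains an exact equilibrium.
* **The per-capita neuron death rate is state- but not N-dependent**, so
  the $N = 0$ limit of the leak term is well defined.

## Calibration to the healthy fixed point

In health both drivers are zero and the system must sit exactly at the
reference state ($N_0 = 6.00\times10^{-2}$, $M_0 = 7.20\times10^{-3}$,
$A_0 = 2.88\times10^{-2}$, $A\beta_i^{ss} = A\beta_o^{ss} =
1.00\times10^{-6}$, $\tau^{ss} = 1.37\times10^{-10}$ g/cm$^3$; the classic
count of $10^{11}$ neurons of $\sim$1 ng in a 1500 cm$^3$ brain gives the
order of $N_0$, and the protein pools come from clinical assays at
1 g tissue = 1 ml = 1 cm$^3$). `calibrate_health_fixed_point()` enforces
this by solving the five production rates from the degradation and
activation constants:

```{r}
ref <- health_reference()
p <- model_params()   # calibrated on construction
r <- reaction_rhs(list(N = ref$N0, M = ref$M0, A = ref$A0,
                       Abi = ref$Abi_ss, Abo = ref$Abo_ss,
                       tau = ref$tau_ss), p, ref, R_val = 0, Rbar_val = 0)
unlist(r[c("N", "M", "A", "Abi", "Abo", "tau")])  # exact zeros
```

The calibration rejects constant sets that would imply a negative
production rate (e.g. an astrocytic secretion strong enough to outrun all
clearance at the healthy state).

## Where the default constants come from

The driver amplitudes ($R^* = 1.85\times10^{-6}$,
$\bar R^* = 4.13\times10^{-10}$ g/(cm$^3\,$d)), the health references, the
ten-year endpoint table and the longitudinal average-density series are
published values. The remaining rate and saturation constants are not
published in a usable form, so the package ships a default set constructed
in two steps and then frozen:

1. **Quasi-steady-state arithmetic for the fast pools.** $A\beta_i$ and
   $\tau$ relax within days, so their ten-year endpoints pin their
   constants directly: $d_{A\beta_i}$ follows from
   $A\beta_i = A\beta_i^{ss} + R/d_{A\beta_i}$ at the saturated driver,
   and the three endpoint columns (baseline, amyloid-biased, tau-biased)
   overdetermine $(d_\tau, \lambda_{\tau A\beta_i})$ consistently — a
   useful internal-consistency check of the published table.
2. **Endpoint-matching for the slow pools.** The remaining constants
   (microglial activation, astrocyte activation, the two neuron-death
   channels, the four extraneural-amyloid constants and the Hill
   constants) were fitted once, by block-coordinate Levenberg–Marquardt,
   against the three endpoint columns, the slow-ramp trajectory
   checkpoints and the longitudinal average series. The fitted set
   reproduces every endpoint within 1.7%, and places the untreated
   slow-ramp crossings of the average-AD levels
   ($6.70\times10^{-6}$ for amyloid, $4.90\times10^{-10}$ for tau) at
   visit day 2500 on the 100-day scan cadence.

Because the defaults are a fitted set, they are not unique: other constant
sets reproduce the same surface. Users with access to an authoritative
parameter table can load it with `load_param_table()`, which re-runs the
fixed-point calibration after the overrides.

The drug constants (`Dstar`, `K_D`, `mu`, `mu_star`) were fitted the same
way — against the published treated crossing days (3100/2900 for
treatment from day 2000; 2800/2700 from day 2300) — and frozen. The dose
is small because the necrosis-leak pathway carries most of the extraneural
amyloid production, so mild attenuation suffices; the tau pathway weight
is large because amyloid-driven hyperphosphorylation contributes only
$\sim$16% of the tau excess, leaving little leverage.

## Numerics

**Well-mixed engine.** `integrate_ode()` wraps `deSolve::lsoda` with a
relative tolerance of $10^{-8}$ and per-variable absolute tolerances
(the densities span eight decades). Halving the tolerances moves ten-year
endpoints by far less than 0.1%.

**Spatial engine.** `integrate_pde()` uses an IMEX operator split on a
cell-centred grid (default 50$\times$50 on a 1 cm square):

* reactions and chemotaxis advance explicitly with a two-stage Heun step;
* diffusion advances implicitly (backward Euler) with prefactored sparse
  Cholesky solves, one per mobile species, so the diffusive CFL does not
  bind;
* chemotaxis uses face-centred gradients with the flux limiter
  $\nabla A\beta_o / (K_{\nabla A\beta_o} + |\nabla A\beta_o|)$ and
  first-order upwinding of $M$, making the scheme conservative with face
  speeds bounded by $\delta_{MA\beta_o}$;
* the step (default 0.25 d) is capped by an advective CFL bound with
  safety factor 0.5 and by the fastest reaction rate; a step that would
  produce a negative density is retried with halved sub-steps (never
  clamped) and logged.

Correctness is anchored to an equivalence oracle rather than to any
particular published scheme: under a spatially uniform field the PDE has
no gradients, so every cell must reproduce the well-mixed trajectory —
the suite verifies agreement to $\sim10^{-7}$, far inside the 0.5%
contract. Grid refinement changes map-average series by well under 1%.

**Crossing analytics.** Longitudinal studies observe the system only at
scan visits, so `detect_crossing()` reports the first visit day (default
cadence 100 d) at which a variable meets its threshold — deliberately not
a continuous interpolation, because that is what a PET schedule yields.
Trajectories default to 10-day samples; crossing analyses to 100-day
samples.

## The synthetic inflammation maps

`make_pixel_map()` draws a categorical map over map pixels (default
10$\times$10, each spanning a 5$\times$5 block of grid cells, so map and
solver resolution are decoupled): amyloid-biased pixels get amplitudes
$(1.5R^*, 0.5\bar R^*)$, tau-biased the reverse, non-biased $(R^*, \bar
R^*)$, zero-inflammation $(0, 0)$. Class counts are exact
(largest-remainder rounding of the requested fractions) and placement is
a seeded uniform permutation, so fractions are reproduced exactly — the
map composition, not just its expectation, matches the requested
percentages, and two runs with the same seed are bit-identical. A map is
classified amyloid-biased, tau-biased or non-biased by comparing the two
biased-class percentages.

What the generator emulates: the coarse pixel-level heterogeneity of
driver intensity used to produce PET-like patterns, under idealized
no-flux boundaries on a square (or arbitrary masked) domain. What it does
not emulate: anatomically registered geometry, partial-volume effects,
scanner noise, or any feedback of pathology onto the inflammation field
(the drivers are prescribed, not dynamic). Passing tests therefore
validate the solver and the calibrated kinetics, not the model's fidelity
to any individual patient's scan.

## Tunable parameters that matter most

| Parameter | Units | Default | Role |
|---|---|---|---|
| `R_star`, `Rbar_star` | g/(cm$^3$ d) | 1.85e-6, 4.13e-10 | driver amplitudes reaching average AD in 10 y |
| `K`, `gamma` | d, — | 100, 1 (slow: 1000, 1/1.4) | ramp shape |
| `N1`, `N2` | — | 1.5, 0.5 | biased-pixel multipliers ($N_1 > 1 > N_2$) |
| `d_Abi`, `d_tau` | /d | 1.857, 1.389 | fast-pool relaxation; set endpoint response to drivers |
| `d_NFi`, `d_NAbo` | /d | 1.22e-4, 1.12e-4 | death-channel split; both near the aggregate rate $-\ln(0.66)/3650$ |
| `delta_MAbo` | cm/d | 2e-4 | chemotactic speed bound |
| `D_Abo` (`D_Abi`, `D_tau`) | cm$^2$/d | 1e-5 (1e-6) | chosen so 500-day patterns retain pixel contrast on a 1 cm domain |
| `Dstar`, `K_D`, `mu`, `mu_star` | —, d, —, — | 6.8e-3, 1874, 8.68, 133.9 | drug dose, onset time constant, pathway weights |

The aggregate neuron death rate deserves a note: a 34% neuron loss over
ten years corresponds to a constant rate $-\ln(0.66)/3650 =
1.14\times10^{-4}$/d, and scaling that rate by $c$ gives survival
$0.66^c$ — the rule used to span the 5–20 year life-expectancy range
(endpoints $2.61\times10^{-2}$ to $4.87\times10^{-2}$ g/cm$^3$). The
fitted split across the two saturating channels recovers this aggregate
behaviour at the baseline endpoint state.

## Design choices made where the design was open

* **Ramp-constant robustness is qualitative.** Replacing $K = 100$ by 500
  or 1000 lowers the driver value reached within the ten-year horizon by
  9.6% and 21.5% respectively, and the fast pools respond
  quasi-statically, so late endpoints necessarily move by a few percent.
  The suite asserts the defensible quantitative form: endpoint changes
  stay below the driver change (the saturating kinetics damp, but cannot
  cancel, the difference), with the early-time profile carrying most of
  the effect.
* **Death-channel Hill constants are shared** with the corresponding
  microglial activation terms, as the equation symbols indicate.
* **Drug grouping.** The treated equations attenuate three production
  pathways multiplicatively — the necrosis leak (weight 1), the
  astrocytic secretion (weight $\mu$) and the amyloid-driven tau term
  (weight $\mu^*$) — each by $1/(1 + w D^* s(t))$ with
  $s(t) = (t-t_0)/(K_D + t - t_0)$. Where the printed grouping of the
  treated amyloid equation is ambiguous, each factor is read as acting on
  that term's amyloid contribution.
* **Problem sizes.** Spatial runs use the 50$\times$50 grid and 10$\times$10
  map throughout (the sources do not state either resolution); the
  longitudinal spatial check averages three map seeds. These sizes give
  map-average series stable to well under 1% across seeds.
* **Degenerate inputs.** Zero fractions, all-zero maps, empty masks,
  thresholds at or below the initial state, and regimens starting beyond
  the horizon are all handled explicitly (constant fields, rejected
  masks, first-visit crossings, validation errors respectively).

## Known limitations

* The inflammation drivers are prescribed inputs; there is no feedback
  from pathology to inflammation, no mechanistic aggregation kinetics,
  and no pharmacokinetics beyond the saturating dose factor.
* The fitted default constants are one point in a degenerate set; only
  the surface they were fitted to (endpoints, longitudinal series,
  crossing days) should be treated as meaningful.
* The spatial model is two-dimensional with reflective boundaries;
  absolute spatial scales (cm) matter only relative to the diffusivities
  and the chemotactic speed.

## A worked longitudinal example

```{r, eval = FALSE}
ref <- health_reference()
p <- model_params()
slow <- inflammation_field(1.85e-6, 4.13e-10, K = 1000, gamma = 1 / 1.4)

# untreated vs treatment from day 2000
run_treatment_scenario(p, ref, slow, drug_regimen(t0 = 2000))
#> Treatment from day 2000 (Dstar = 0.00679492, K_D = 1874.32, ...)
#>   Abo  reaches 6.7e-06 g/cm^3: untreated day 2500, treated day 3100 (delay 600 d)
#>   tau  reaches 4.9e-10 g/cm^3: untreated day 2500, treated day 2900 (delay 400 d)
```

Starting the same regimen at day 2300 instead yields crossings at
2800/2700 — delays of 300/200 days — illustrating the central trade-off
of preclinical treatment: earlier treatment buys more delay, at the price
of treating patients whose diagnosis is less certain.
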