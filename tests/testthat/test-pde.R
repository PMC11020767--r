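grid_sum <- function(f, g) sum(f[adsim:::grid_mask(g)])

test_that("no-flux Laplacian annihilates constants, conserves mass, and
           converges to the analytic eigenvalue", {
  g <- grid2d(12, 9, h = 0.1)
  expect_true(all(laplacian_noflux(matrix(3.5, 9, 12), g) == 0))
  spike <- matrix(0, 9, 12); spike[5, 6] <- 1
  expect_equal(grid_sum(laplacian_noflux(spike, g), g), 0, tolerance = 1e-14)
  expect_error(laplacian_noflux(matrix(0, 5, 5), g), "do not match")
  # cos(pi x / L) is a Neumann eigenmode with eigenvalue -(pi/L)^2
  n <- 200; L <- 1; h <- L / n
  x <- (seq_len(n) - 0.5) * h
  gf <- grid2d(n, 2, h = h)
  f <- matrix(cos(pi * x / L), nrow = 2, ncol = n, byrow = TRUE)
  lam_num <- laplacian_noflux(f, gf)[1, ] / f[1, ]
  expect_equal(mean(lam_num), -(pi / L)^2, tolerance = 1e-3)
})

test_that("masked cells behave like outer boundary: no flux, no dynamics,
           mask-aware averages", {
  mask <- matrix(TRUE, 8, 8); mask[1:4, 1:4] <- FALSE
  g <- grid2d(8, 8, h = 0.1, mask = mask)
  f <- matrix(runif(64), 8, 8)
  expect_equal(grid_sum(laplacian_noflux(f, g), g), 0, tolerance = 1e-12)
  # averages over active cells only
  f2 <- matrix(1, 8, 8); f2[!mask] <- 99
  expect_equal(spatial_average(f2, g), 1)
  # checkerboard average
  cb <- matrix(rep_len(c(2, 6), 64), 8, 8)
  expect_equal(spatial_average(cb, grid2d(8, 8, h = 0.1)), 4)
})

test_that("flux-limited chemotaxis is conservative, vanishes on uniform
           fields and saturates at the speed bound", {
  g <- grid2d(16, 16, h = 1 / 16)
  M <- matrix(runif(256, 0.5, 2), 16, 16)
  # uniform attractant: zero everywhere
  expect_true(all(chemotaxis_divergence(M, matrix(1, 16, 16), 1e-3, 1e-4,
                                        g) == 0))
  # conservation for arbitrary fields
  Abo <- matrix(runif(256), 16, 16)
  div <- chemotaxis_divergence(M, Abo, 1e-3, 1e-4, g)
  expect_equal(sum(div), 0, tolerance = 1e-15 * max(abs(div)) * 256)
  # steep-gradient limit: face speed approaches the bound delta
  delta <- 2e-4
  steep <- matrix(rep(c(0, 1e6), each = 8), 16, 16, byrow = FALSE)
  Mu <- matrix(1, 16, 16)
  div2 <- chemotaxis_divergence(Mu, t(steep), delta, 1e-4, g)
  # flux through the steep face ~ delta * M; divergence = +-delta/h there
  expect_equal(max(abs(div2)), delta / g$h, tolerance = 1e-3)
  expect_error(chemotaxis_divergence(M, Abo, 1e-3, -1, g), "positive")
})

test_that("diffusion conserves grid totals: driven species follow the
           analytic source integral, undriven species stay constant", {
  # degradation, activation and chemotaxis off; the inflammation map still
  # feeds the intraneural pools, so they become spatially non-uniform and
  # diffuse, but their grid totals must equal the ramp time-integral —
  # any diffusion leak would show up here
  g <- grid2d(20, 20, h = 0.05)
  p <- model_params(calibrate = FALSE)
  for (nm in adsim:::.param_names) p[[nm]] <- 0
  p$K_gradAbo <- 1e-4; p$K_Abo <- 1e-6; p$K_Fi <- 1e-10; p$K_M <- 1e-3
  p$D_Abi <- 1e-3; p$D_Abo <- 2e-3; p$D_tau <- 5e-4; p$D_M <- 1e-3
  p <- adsim:::validate_model_params(p)
  pm <- make_pixel_map(4, 4, c(0.25, 0.25, 0.25, 0.25), 5)
  f <- map_to_field(pm)
  K <- f$K
  R_grid <- adsim:::expand_amplitude(f$R_amp, g)
  Rbar_grid <- adsim:::expand_amplitude(f$Rbar_amp, g)
  sol <- integrate_pde(g, p, ref, f, t_end = 20, snapshot_times = c(10, 20))
  for (i in 1:2) {
    t <- c(10, 20)[i]; snap <- sol$snapshots[[i]]
    ramp_int <- t - K * log((K + t) / K)
    # tolerance reflects the second-order time stepping of the curved
    # ramp source; a diffusion leak would be far larger and systematic
    expect_equal(grid_sum(snap$Abi, g),
                 400 * ref$Abi_ss + sum(R_grid) * ramp_int,
                 tolerance = 1e-4, label = "Abi")
    expect_equal(grid_sum(snap$tau, g),
                 400 * ref$tau_ss + sum(Rbar_grid) * ramp_int,
                 tolerance = 1e-4, label = "tau")
    # no sources at all for the extraneural pools: totals exactly conserved
    expect_equal(grid_sum(snap$Abo, g), 400 * ref$Abo_ss,
                 tolerance = 1e-10, label = "Abo")
    expect_equal(grid_sum(snap$M, g), 400 * ref$M0,
                 tolerance = 1e-10, label = "M")
  }
  # the driven pools really are non-uniform (diffusion is being exercised)
  expect_gt(diff(range(sol$snapshots[[2]]$Abi)), 0)
})

test_that("a zero-inflammation map holds the healthy state everywhere", {
  g <- grid2d(10, 10, h = 0.1)
  f <- map_to_field(make_pixel_map(5, 5, c(0, 0, 0, 1), 1))
  sol <- integrate_pde(g, par0, ref, f, t_end = 50, snapshot_times = 50)
  snap <- sol$snapshots[[1]]
  expect_equal(max(abs(snap$N / ref$N0 - 1)), 0, tolerance = 1e-9)
  expect_equal(max(abs(snap$Abo / ref$Abo_ss - 1)), 0, tolerance = 1e-9)
  # tangles stay at numerical zero (tau holds its healthy level to rounding)
  expect_lt(max(snap$Fi), 1e-9 * ref$tau_ss)
})

test_that("with a uniform field every grid cell tracks the well-mixed
           solution", {
  g <- grid2d(10, 10, h = 0.1)
  f <- inflammation_field(R_STAR, RBAR_STAR)
  times <- c(100, 300, 500)
  sol <- integrate_pde(g, par0, ref, f, t_end = 500, snapshot_times = times)
  tr <- integrate_ode(par0, ref, f, 500, sample_interval = 100)
  for (i in seq_along(times)) {
    row <- tr[tr$time == times[i], ]
    snap <- sol$snapshots[[i]]
    for (v in c("N", "M", "A", "Abi", "Abo", "tau")) {
      expect_lt(max(abs(snap[[v]] / row[[v]] - 1)), 0.005,
                label = sprintf("%s at t=%d", v, times[i]))
    }
  }
})

test_that("masked domains evolve only their active cells and still track
           the well-mixed solution under a uniform field", {
  mask <- matrix(TRUE, 10, 10); mask[1:5, 1:5] <- FALSE  # L-shaped tissue
  g <- grid2d(10, 10, h = 0.1, mask = mask)
  f <- inflammation_field(R_STAR, RBAR_STAR)
  sol <- integrate_pde(g, par0, ref, f, t_end = 200, snapshot_times = 200)
  tr <- integrate_ode(par0, ref, f, 200, sample_interval = 200)
  row <- tr[tr$time == 200, ]
  snap <- sol$snapshots[[1]]
  for (v in c("N", "M", "Abo", "tau")) {
    expect_lt(max(abs(snap[[v]][mask] / row[[v]] - 1)), 0.005, label = v)
    expect_true(all(snap[[v]][!mask] == 0))
  }
  avg <- spatial_average(snap, g)
  expect_equal(avg[["Abo"]], row$Abo, tolerance = 0.005)
})

test_that("mixed maps keep cell values within the pure-class envelope and
           averages between the class extremes", {
  g <- grid2d(20, 20, h = 0.05)
  pm <- make_pixel_map(4, 4, c(0.5, 0.5, 0, 0), seed = 2)
  f <- map_to_field(pm)
  sol <- integrate_pde(g, par0, ref, f, t_end = 300, snapshot_times = 300)
  snap <- sol$snapshots[[1]]
  # pure-class ODE endpoints bracket the spatial field (diffusion smooths
  # inward, never outward)
  hi <- endpoint(integrate_ode(par0, ref,
                               inflammation_field(1.5 * R_STAR, 0.5 * RBAR_STAR),
                               300, sample_interval = 300))
  lo <- endpoint(integrate_ode(par0, ref,
                               inflammation_field(0.5 * R_STAR, 1.5 * RBAR_STAR),
                               300, sample_interval = 300))
  eps <- 1e-6
  expect_gte(min(snap$Abo), lo$Abo * (1 - eps))
  expect_lte(max(snap$Abo), hi$Abo * (1 + eps))
  expect_gte(min(snap$tau), hi$tau * (1 - eps))
  expect_lte(max(snap$tau), lo$tau * (1 + eps))
  avg <- spatial_average(snap, g)
  expect_true(avg[["Abo"]] > lo$Abo && avg[["Abo"]] < hi$Abo)
})

test_that("snapshot export writes matrices, averages and a manifest", {
  g <- grid2d(6, 6, h = 1 / 6)
  f <- inflammation_field(R_STAR, RBAR_STAR)
  sol <- integrate_pde(g, par0, ref, f, t_end = 20, snapshot_times = c(10, 20))
  dir <- tempfile()
  write_snapshots(sol, dir, variables = c("Abo", "tau"))
  expect_true(file.exists(file.path(dir, "Abo_t10.csv")))
  m <- as.matrix(read.csv(file.path(dir, "Abo_t10.csv"), header = FALSE))
  expect_equal(dim(m), c(6, 6))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$grid$n_x, 6)
  expect_equal(unlist(man$times), c(10, 20))
  avg <- read.csv(file.path(dir, "averages.csv"))
  expect_equal(avg$Abo[2], spatial_average(sol$snapshots[[2]], g)[["Abo"]])
})
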