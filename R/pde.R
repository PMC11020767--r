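#' Two-dimensional simulation grid
#'
#' Cell-centered rectangular grid, optionally restricted by a binary mask
#' of active cells (an arbitrary tissue outline). Mask boundaries are
#' treated exactly like the outer boundary: no flux crosses them, and
#' spatial averages run over active cells only.
#'
#' @param n_x,n_y number of cells in x and y (>= 2).
#' @param h cell size, cm (> 0). The default gives a unit-square domain
#'   for a 50 x 50 grid.
#' @param mask optional `n_y` x `n_x` logical (or 0/1) matrix of active
#'   cells; `NULL` means all cells are active.
#' @return An object of class `grid2d`.
#' @export
grid2d <- function(n_x = 50, n_y = 50, h = 1 / n_x, mask = NULL) {
  if (n_x < 2 || n_y < 2) stop("grid must be at least 2 x 2")
  if (h <= 0) stop("'h' must be positive")
  if (!is.null(mask)) {
    mask <- matrix(as.logical(mask), nrow = n_y, ncol = n_x)
    if (nrow(mask) != n_y || ncol(mask) != n_x) {
      stop("mask dimensions must match the grid")
    }
    if (!any(mask)) stop("mask excludes every cell")
  }
  structure(list(n_x = as.integer(n_x), n_y = as.integer(n_y), h = h,
                 mask = mask),
            class = "grid2d")
}

grid_mask <- function(grid) {
  if (is.null(grid$mask)) {
    matrix(TRUE, grid$n_y, grid$n_x)
  } else {
    grid$mask
  }
}

check_grid_field <- function(field, grid) {
  if (!is.matrix(field) || nrow(field) != grid$n_y || ncol(field) != grid$n_x) {
    stop("field dimensions (", paste(dim(field), collapse = " x "),
         ") do not match the grid (", grid$n_y, " x ", grid$n_x, ")")
  }
  invisible(field)
}

# Shift a matrix by one cell, reflecting at boundaries and at mask edges
# (the neighbour value across an inactive face is the cell's own value, so
# the normal difference, and hence the flux, vanishes there).
shift_reflect <- function(f, dr, dc, active) {
  n_y <- nrow(f); n_x <- ncol(f)
  ri <- pmin(pmax(seq_len(n_y) + dr, 1L), n_y)
  ci <- pmin(pmax(seq_len(n_x) + dc, 1L), n_x)
  out <- f[ri, ci, drop = FALSE]
  nb_active <- active[ri, ci, drop = FALSE]
  out[!nb_active] <- f[!nb_active]
  out
}

#' Five-point Laplacian with no-flux boundaries
#'
#' Second-order centred discretisation of the Laplacian with reflecting
#' (zero normal derivative) ghost cells at the outer boundary and at mask
#' edges. Under these boundary conditions the discrete operator conserves
#' the grid sum exactly.
#'
#' @param field `n_y` x `n_x` matrix.
#' @param grid a [grid2d()].
#' @return Matrix of the same shape (zero on inactive cells), units
#'   field-units / cm^2.
#' @export
laplacian_noflux <- function(field, grid) {
  check_grid_field(field, grid)
  active <- grid_mask(grid)
  f <- field
  up <- shift_reflect(f, -1L, 0L, active)
  down <- shift_reflect(f, 1L, 0L, active)
  left <- shift_reflect(f, 0L, -1L, active)
  right <- shift_reflect(f, 0L, 1L, active)
  lap <- (up + down + left + right - 4 * f) / grid$h^2
  lap[!active] <- 0
  lap
}

# Face-centred normal gradients in +x (east) and +y (south, increasing row)
# directions; zero on boundary/mask faces. Returned as matrices of interior
# face values: gx is n_y x (n_x - 1), gy is (n_y - 1) x n_x.
face_gradients <- function(f, grid) {
  h <- grid$h
  gx <- (f[, -1, drop = FALSE] - f[, -ncol(f), drop = FALSE]) / h
  gy <- (f[-1, , drop = FALSE] - f[-nrow(f), , drop = FALSE]) / h
  if (!is.null(grid$mask)) {
    m <- grid$mask
    gx[!(m[, -1, drop = FALSE] & m[, -ncol(m), drop = FALSE])] <- 0
    gy[!(m[-1, , drop = FALSE] & m[-nrow(m), , drop = FALSE])] <- 0
  }
  list(gx = gx, gy = gy)
}

#' Divergence of the flux-limited chemotactic flux
#'
#' Microglia drift up extraneural-amyloid gradients with a flux-limited
#' velocity: the flux is `delta_MAbo * M * grad(Abo) / (K_gradAbo +
#' |grad(Abo)|)`, whose speed saturates at `delta_MAbo` (cm/day) for steep
#' gradients. Discretised with face-centred gradients and first-order
#' upwinding of `M`; no flux crosses outer or mask boundaries, so the grid
#' sum of the divergence is zero to rounding.
#'
#' The microglia equation uses the *negative* of this divergence
#' (`dM/dt = -div(flux) + ...`).
#'
#' @param M,Abo `n_y` x `n_x` density matrices.
#' @param delta_MAbo chemotactic speed bound, cm/day.
#' @param K_gradAbo gradient saturation constant, g/cm^4 (> 0).
#' @param grid a [grid2d()].
#' @return Matrix of `div(flux)` values, g/(cm^3 day).
#' @export
chemotaxis_divergence <- function(M, Abo, delta_MAbo, K_gradAbo, grid) {
  if (K_gradAbo <= 0) stop("'K_gradAbo' must be positive")
  check_grid_field(M, grid)
  check_grid_field(Abo, grid)
  g <- face_gradients(Abo, grid)
  # face velocity, capped in magnitude at delta_MAbo by the limiter
  ux <- delta_MAbo * g$gx / (K_gradAbo + abs(g$gx))
  uy <- delta_MAbo * g$gy / (K_gradAbo + abs(g$gy))
  # upwind M on each face
  Mw <- M[, -ncol(M), drop = FALSE]; Me <- M[, -1, drop = FALSE]
  Mn <- M[-nrow(M), , drop = FALSE]; Ms <- M[-1, , drop = FALSE]
  Fx <- ux * ifelse(ux > 0, Mw, Me)
  Fy <- uy * ifelse(uy > 0, Mn, Ms)
  n_y <- nrow(M); n_x <- ncol(M)
  zx <- matrix(0, n_y, 1); zy <- matrix(0, 1, n_x)
  FxE <- cbind(Fx, zx); FxW <- cbind(zx, Fx)
  FyS <- rbind(Fy, zy); FyN <- rbind(zy, Fy)
  div <- (FxE - FxW + FyS - FyN) / grid$h
  div[!grid_mask(grid)] <- 0
  div
}

# Sparse no-flux Laplacian over active cells (column-major cell order),
# symmetric; used for the implicit diffusion solves.
laplacian_matrix <- function(grid) {
  active <- grid_mask(grid)
  n_y <- grid$n_y; n_x <- grid$n_x
  idx <- matrix(NA_integer_, n_y, n_x)
  idx[active] <- seq_len(sum(active))
  ii <- integer(0); jj <- integer(0)
  add_pairs <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    ii <<- c(ii, a[ok]); jj <<- c(jj, b[ok])
  }
  # east neighbours
  add_pairs(idx[, -n_x], idx[, -1])
  # south neighbours
  add_pairs(idx[-n_y, ], idx[-1, ])
  n <- sum(active)
  off <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                              dims = c(n, n))
  deg <- Matrix::rowSums(off)
  (off - Matrix::Diagonal(n, deg)) / grid$h^2
}

#' Integrate the spatial (PDE) model
#'
#' Solves the reaction-diffusion-chemotaxis system on a 2-D grid from the
#' healthy state everywhere, with no-flux boundaries, using an IMEX
#' operator-split scheme: reactions and upwinded chemotaxis are advanced
#' explicitly with a two-stage (Heun) step, then diffusion of the four
#' mobile species is advanced implicitly (backward Euler, prefactored
#' sparse Cholesky solves). The step size respects an advective CFL bound
#' with safety factor 0.5 and an explicit reaction-rate bound; if a step
#' produces a negative density it is retried with a halved step (clamping
#' is never applied), and retries are reported in the solution's `log`.
#'
#' @param grid a [grid2d()].
#' @param p a calibrated [model_params()].
#' @param ref a [health_reference()].
#' @param field an [inflammation_field()]; matrix amplitudes must tile the
#'   grid (grid dimensions an integer multiple of the map's), and each map
#'   pixel then spans a block of grid cells.
#' @param t_end horizon, days.
#' @param snapshot_times times (days) at which to store full fields;
#'   defaults to `t_end` only. Averages over active cells are recorded at
#'   every snapshot.
#' @param drug optional [drug_regimen()].
#' @param dt requested step size, days; the default applies the stability
#'   bounds to 0.25 d.
#' @return An object of class `pde_solution`: list with `snapshots` (each
#'   a `field_snapshot`: list of `time` and `n_y` x `n_x` matrices `N`,
#'   `M`, `A`, `Abi`, `Abo`, `tau`, `Fi`), `averages` (data frame of
#'   spatial means per snapshot), `grid`, and `log`.
#' @export
integrate_pde <- function(grid, p, ref, field, t_end,
                          snapshot_times = NULL, drug = NULL, dt = NULL) {
  stopifnot(inherits(grid, "grid2d"), inherits(field, "inflammation_field"))
  validate_model_params(p)
  if (t_end <= 0) stop("'t_end' must be positive")
  if (is.null(snapshot_times)) snapshot_times <- t_end
  snapshot_times <- sort(unique(snapshot_times))
  if (any(snapshot_times <= 0) || max(snapshot_times) > t_end) {
    stop("'snapshot_times' must lie in (0, t_end]")
  }
  if (!is.null(drug)) stopifnot(inherits(drug, "drug_regimen"))

  R_amp <- expand_amplitude(field$R_amp, grid)
  Rbar_amp <- expand_amplitude(field$Rbar_amp, grid)
  active <- grid_mask(grid)
  R_amp[!active] <- 0; Rbar_amp[!active] <- 0

  # stability-bounded default step
  rate_bound <- max(p$d_Abi, p$d_tau, p$d_AboM * 3 * ref$M0 + p$d_Abo,
                    p$d_M, p$d_A)
  dt_react <- 1 / rate_bound
  dt_cfl <- 0.5 * grid$h / max(p$delta_MAbo, 1e-300)
  dt0 <- min(if (is.null(dt)) 0.25 else dt, dt_react, dt_cfl)

  n_act <- sum(active)
  ident <- Matrix::Diagonal(n_act)
  L <- laplacian_matrix(grid)
  diff_species <- c(Abi = p$D_Abi, Abo = p$D_Abo, tau = p$D_tau, M = p$D_M)

  state <- list(
    N = matrix(ref$N0, grid$n_y, grid$n_x),
    M = matrix(ref$M0, grid$n_y, grid$n_x),
    A = matrix(ref$A0, grid$n_y, grid$n_x),
    Abi = matrix(ref$Abi_ss, grid$n_y, grid$n_x),
    Abo = matrix(ref$Abo_ss, grid$n_y, grid$n_x),
    tau = matrix(ref$tau_ss, grid$n_y, grid$n_x)
  )
  for (nm in names(state)) state[[nm]][!active] <- 0

  explicit_rhs <- function(st, t) {
    fac <- drug_factors(t, drug)
    m <- ramp(t, field$K, field$gamma)
    r <- reaction_rhs(st, p, ref, R_amp * m, Rbar_amp * m, drug = fac)
    r$M <- r$M - chemotaxis_divergence(st$M, st$Abo, p$delta_MAbo,
                                       p$K_gradAbo, grid)
    for (nm in c("N", "M", "A", "Abi", "Abo", "tau")) r[[nm]][!active] <- 0
    r
  }

  factor_cache <- list()
  diffuse <- function(st, h_dt) {
    key <- format(h_dt, digits = 15)
    if (is.null(factor_cache[[key]])) {
      fac <- lapply(diff_species, function(D) {
        if (D <= 0) return(NULL)
        Matrix::Cholesky(Matrix::forceSymmetric(ident - h_dt * D * L),
                         LDL = FALSE)
      })
      factor_cache[[key]] <<- fac
    }
    fac <- factor_cache[[key]]
    for (nm in names(diff_species)) {
      if (is.null(fac[[nm]])) next
      v <- st[[nm]][active]
      v <- as.numeric(Matrix::solve(fac[[nm]], v, system = "A"))
      st[[nm]][active] <- v
    }
    st
  }

  heun_imex_step <- function(st, t, h_dt) {
    k1 <- explicit_rhs(st, t)
    st1 <- st
    for (nm in names(st)) st1[[nm]] <- st[[nm]] + h_dt * k1[[nm]]
    if (min(vapply(st1, min, 0)) < 0) return(NULL)
    k2 <- explicit_rhs(st1, t + h_dt)
    st2 <- st
    for (nm in names(st)) {
      st2[[nm]] <- st[[nm]] + (h_dt / 2) * (k1[[nm]] + k2[[nm]])
    }
    if (min(vapply(st2, min, 0)) < 0) return(NULL)
    diffuse(st2, h_dt)
  }

  halvings <- 0L
  advance_to <- function(st, t_from, t_to) {
    n_steps <- max(1L, ceiling((t_to - t_from) / dt0))
    h_dt <- (t_to - t_from) / n_steps
    t <- t_from
    for (k in seq_len(n_steps)) {
      nxt <- heun_imex_step(st, t, h_dt)
      if (is.null(nxt)) {
        # negativity: redo this step in halved sub-steps (up to 20 levels)
        sub <- h_dt; depth <- 0L; t_sub <- t; target <- t + h_dt
        while (t_sub < target - 1e-12) {
          cand <- heun_imex_step(st, t_sub, sub)
          if (is.null(cand)) {
            sub <- sub / 2; depth <- depth + 1L; halvings <<- halvings + 1L
            if (depth > 20L) {
              stop("PDE step size underflow at t = ", t_sub,
                   ": the solution appears to diverge")
            }
          } else {
            st <- cand; t_sub <- t_sub + sub
          }
        }
        nxt <- st
      }
      st <- nxt
      t <- t_from + k * h_dt
    }
    st
  }

  snapshots <- vector("list", length(snapshot_times))
  avgs <- vector("list", length(snapshot_times))
  t_prev <- 0
  for (i in seq_along(snapshot_times)) {
    state <- advance_to(state, t_prev, snapshot_times[i])
    t_prev <- snapshot_times[i]
    snap <- state
    snap$Fi <- nft_from_tau(pmax(state$tau, 0), ref$tau_ss)
    snap$Fi[!active] <- 0
    snap <- c(list(time = t_prev), snap)
    class(snap) <- "field_snapshot"
    snapshots[[i]] <- snap
    avgs[[i]] <- data.frame(time = t_prev,
                            t(vapply(snap[c("N", "M", "A", "Abi", "Abo",
                                            "tau", "Fi")],
                                     function(f) mean(f[active]), 0)))
  }
  structure(list(snapshots = snapshots,
                 averages = do.call(rbind, avgs),
                 grid = grid,
                 log = list(dt = dt0, step_halvings = halvings)),
            class = "pde_solution")
}

# Expand a map-resolution amplitude matrix (or scalar) onto the grid; each
# map pixel spans an integer block of grid cells.
expand_amplitude <- function(amp, grid) {
  if (!is.matrix(amp)) return(matrix(amp, grid$n_y, grid$n_x))
  by <- grid$n_y / nrow(amp); bx <- grid$n_x / ncol(amp)
  if (by != round(by) || bx != round(bx)) {
    stop("grid dimensions (", grid$n_y, " x ", grid$n_x,
         ") must be integer multiples of the amplitude map's (",
         nrow(amp), " x ", ncol(amp), ")")
  }
  amp[rep(seq_len(nrow(amp)), each = by),
      rep(seq_len(ncol(amp)), each = bx), drop = FALSE]
}

#' Spatial average of a field snapshot
#'
#' Arithmetic mean of each variable over the grid's active cells.
#'
#' @param snapshot a `field_snapshot` from [integrate_pde()], or a bare
#'   matrix.
#' @param grid the [grid2d()] the snapshot lives on.
#' @return For a snapshot, a named numeric vector over the seven
#'   variables; for a bare matrix, a single number.
#' @export
spatial_average <- function(snapshot, grid) {
  active <- grid_mask(grid)
  if (!any(active)) stop("mask excludes every cell")
  if (is.matrix(snapshot)) {
    check_grid_field(snapshot, grid)
    return(mean(snapshot[active]))
  }
  stopifnot(inherits(snapshot, "field_snapshot"))
  vapply(snapshot[c("N", "M", "A", "Abi", "Abo", "tau", "Fi")],
         function(f) mean(f[active]), 0)
}

#' @export
print.pde_solution <- function(x, ...) {
  cat(sprintf("PDE solution on %d x %d grid (h = %g cm), %d snapshot(s), dt = %g d\n",
              x$grid$n_x, x$grid$n_y, x$grid$h, length(x$snapshots),
              x$log$dt))
  print(utils::tail(x$averages, 3), digits = 4)
  invisible(x)
}

#' Export snapshots as CSV matrices plus a JSON manifest
#'
#' Writes one CSV matrix per variable per snapshot time
#' (`<var>_t<time>.csv`, row-major cell order) and a `manifest.json`
#' recording grid, times, step statistics and the writing package version.
#'
#' @param sol a `pde_solution`.
#' @param dir output directory (created if needed).
#' @param variables variables to export.
#' @return The manifest path, invisibly.
#' @export
write_snapshots <- function(sol, dir,
                            variables = c("Abo", "tau")) {
  stopifnot(inherits(sol, "pde_solution"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (snap in sol$snapshots) {
    for (v in variables) {
      fn <- file.path(dir, sprintf("%s_t%g.csv", v, snap$time))
      utils::write.table(snap[[v]], fn, sep = ",",
                         row.names = FALSE, col.names = FALSE)
      files <- c(files, basename(fn))
    }
  }
  avg_path <- file.path(dir, "averages.csv")
  utils::write.csv(sol$averages, avg_path, row.names = FALSE)
  manifest <- list(
    grid = list(n_x = sol$grid$n_x, n_y = sol$grid$n_y, h = sol$grid$h,
                masked = !is.null(sol$grid$mask)),
    times = vapply(sol$snapshots, `[[`, 0, "time"),
    dt = sol$log$dt,
    step_halvings = sol$log$step_halvings,
    files = files,
    package_version = as.character(utils::packageVersion("adsim"))
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
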