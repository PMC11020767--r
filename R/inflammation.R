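#' Temporal inflammation ramp
#'
#' Multiplier applied to the spatial amplitude of an inflammation driver:
#' `(t / gamma) / (K + t)`. It is zero at onset, increases monotonically,
#' and saturates at `1 / gamma` as `t` grows. `K` sets how quickly the ramp
#' approaches its plateau (with `gamma = 1`, half the plateau is reached at
#' `t = K`); `gamma < 1` raises the plateau above the nominal amplitude.
#'
#' @param t time in days, non-negative (vectorised).
#' @param K ramp half-time constant, days (> 0).
#' @param gamma ramp speed divisor (> 0).
#' @return The dimensionless multiplier, same length as `t`.
#' @export
#' @examples
#' ramp(100, K = 100)                # 0.5: half saturation
#' ramp(1000, K = 1000, gamma = 1/1.4)  # 0.7
ramp <- function(t, K = 100, gamma = 1) {
  if (any(t < 0)) stop("'t' must be non-negative")
  if (K <= 0 || gamma <= 0) stop("'K' and 'gamma' must be positive")
  (t / gamma) / (K + t)
}

.pixel_classes <- c("Abeta", "tau", "nonbiased", "zero")

#' Generate a seeded random pixel-class inflammation map
#'
#' Divides an `n_x` by `n_y` grid of map pixels into four classes —
#' amyloid-biased, tau-biased, non-biased and zero-inflammation — with
#' exact class counts obtained from the requested fractions by
#' largest-remainder rounding, placed by a uniform random permutation under
#' the given seed. The same seed always yields the same map.
#'
#' @param n_x,n_y map dimensions in pixels.
#' @param fractions length-4 non-negative vector of class fractions
#'   (amyloid-biased, tau-biased, non-biased, zero), summing to 1.
#' @param seed integer seed for the placement permutation.
#' @return An object of class `pixel_map`: list with `classes` (an
#'   `n_y` x `n_x` integer matrix with values 1-4), `fractions`, `counts`,
#'   and `seed`.
#' @export
#' @examples
#' pm <- make_pixel_map(20, 20, c(0.40, 0.40, 0.15, 0.05), seed = 1)
#' pm$counts  # 160 160 60 20
make_pixel_map <- function(n_x, n_y, fractions, seed) {
  if (n_x < 1 || n_y < 1) stop("map dimensions must be at least 1")
  if (length(fractions) != 4 || any(fractions < 0)) {
    stop("'fractions' must be 4 non-negative numbers")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("'fractions' must sum to 1 (got ", format(sum(fractions)), ")")
  }
  n <- as.integer(n_x) * as.integer(n_y)
  counts <- largest_remainder_counts(fractions, n)
  codes <- rep.int(seq_len(4L), counts)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  codes <- sample(codes, n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(
    classes = matrix(codes, nrow = n_y, ncol = n_x),
    fractions = fractions,
    counts = counts,
    seed = as.integer(seed)
  ), class = "pixel_map")
}

# Apportion n among length(frac) classes with exact totals: floor each
# ideal count, then distribute the leftover units to the largest remainders
# (ties broken by class order).
largest_remainder_counts <- function(frac, n) {
  ideal <- frac * n
  base <- floor(ideal)
  left <- as.integer(round(n - sum(base)))
  if (left > 0) {
    ord <- order(ideal - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' @export
print.pixel_map <- function(x, ...) {
  d <- dim(x$classes)
  cat(sprintf("Inflammation pixel map %d x %d (seed %d)\n", d[2], d[1], x$seed))
  cat(sprintf("  %s: %d pixels (%.1f%%)\n", .pixel_classes, x$counts,
              100 * x$counts / sum(x$counts)), sep = "")
  cat("  bias classification:", bias_classification(x), "\n")
  invisible(x)
}

#' Classify the overall bias of an inflammation map
#'
#' A map is amyloid-biased if amyloid-biased pixels outnumber tau-biased
#' pixels, tau-biased in the opposite case, and non-biased on a tie.
#'
#' @param map a [make_pixel_map()] object.
#' @return `"Abeta"`, `"tau"` or `"nonbiased"`.
#' @export
bias_classification <- function(map) {
  stopifnot(inherits(map, "pixel_map"))
  if (map$counts[1] > map$counts[2]) "Abeta"
  else if (map$counts[2] > map$counts[1]) "tau"
  else "nonbiased"
}

#' Build an inflammation field from amplitudes or a pixel map
#'
#' An inflammation field couples the spatial amplitude maps of the two
#' drivers — `R` (amyloid pathway) and `Rbar` (tau pathway), in
#' g/(cm^3 day) — with the temporal ramp constants `K` and `gamma`. The
#' local driver value at time `t` is `amplitude * ramp(t, K, gamma)`.
#'
#' `inflammation_field()` builds a spatially uniform field;
#' [map_to_field()] expands a pixel-class map into per-pixel amplitudes.
#'
#' @param R_amp,Rbar_amp scalar amplitudes (uniform field) or matrices.
#' @param K,gamma temporal ramp constants (see [ramp()]).
#' @return An object of class `inflammation_field`: list with `R_amp`,
#'   `Rbar_amp`, `K`, `gamma`, and `uniform` flag.
#' @export
#' @examples
#' f <- inflammation_field(1.85e-6, 4.13e-10)       # baseline drivers
#' f$R_amp * ramp(3650, f$K, f$gamma)               # driver value at 10 y
inflammation_field <- function(R_amp, Rbar_amp, K = 100, gamma = 1) {
  if (any(R_amp < 0) || any(Rbar_amp < 0)) {
    stop("inflammation amplitudes must be non-negative")
  }
  if (K <= 0 || gamma <= 0) stop("'K' and 'gamma' must be positive")
  if (is.matrix(R_amp) || is.matrix(Rbar_amp)) {
    if (!identical(dim(R_amp), dim(Rbar_amp))) {
      stop("'R_amp' and 'Rbar_amp' must have identical dimensions")
    }
  }
  structure(list(R_amp = R_amp, Rbar_amp = Rbar_amp, K = K, gamma = gamma,
                 uniform = !is.matrix(R_amp)),
            class = "inflammation_field")
}

#' Expand a pixel map into an inflammation field
#'
#' Assigns per-pixel driver amplitudes from the pixel class: amyloid-biased
#' pixels get `(N1 * R_star, N2 * Rbar_star)`, tau-biased pixels the
#' reverse weighting, non-biased pixels `(R_star, Rbar_star)`, and
#' zero-inflammation pixels `(0, 0)`. The default multipliers are
#' `N1 = 1.5`, `N2 = 0.5`; any pair with `N1 > 1 > N2` defines the same
#' bias classification.
#'
#' @param map a [make_pixel_map()] object.
#' @param R_star,Rbar_star reference amplitudes, g/(cm^3 day).
#' @param K,gamma temporal ramp constants.
#' @param N1,N2 bias multipliers, `N1 > 1 > N2 >= 0`.
#' @return An `inflammation_field` whose amplitude matrices have the map's
#'   dimensions (one entry per map pixel).
#' @export
map_to_field <- function(map, R_star = 1.85e-6, Rbar_star = 4.13e-10,
                         K = 100, gamma = 1, N1 = 1.5, N2 = 0.5) {
  stopifnot(inherits(map, "pixel_map"))
  if (R_star < 0 || Rbar_star < 0) stop("reference amplitudes must be >= 0")
  if (!(N1 > 1 && N2 < 1 && N2 >= 0)) {
    stop("bias multipliers must satisfy N1 > 1 > N2 >= 0")
  }
  mult_R <- c(N1, N2, 1, 0)[map$classes]
  mult_Rbar <- c(N2, N1, 1, 0)[map$classes]
  R_amp <- matrix(mult_R * R_star, nrow = nrow(map$classes))
  Rbar_amp <- matrix(mult_Rbar * Rbar_star, nrow = nrow(map$classes))
  inflammation_field(R_amp, Rbar_amp, K = K, gamma = gamma)
}

#' Evaluate both drivers of a field at a time point
#'
#' @param field an `inflammation_field`.
#' @param t time, days.
#' @return List with components `R` and `Rbar` (scalars or matrices).
#' @export
field_at <- function(field, t) {
  stopifnot(inherits(field, "inflammation_field"))
  m <- ramp(t, field$K, field$gamma)
  list(R = field$R_amp * m, Rbar = field$Rbar_amp * m)
}

#' Write / read a pixel map as a CSV grid of class codes
#'
#' @param map a `pixel_map`.
#' @param path output CSV path.
#' @return `write_pixel_map` returns `path` invisibly; `read_pixel_map`
#'   returns a `pixel_map` (seed recorded as `NA`).
#' @export
write_pixel_map <- function(map, path) {
  stopifnot(inherits(map, "pixel_map"))
  utils::write.table(map$classes, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pixel_map
#' @export
read_pixel_map <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  if (any(!m %in% 1:4)) stop("pixel map codes must be integers 1-4")
  counts <- as.integer(tabulate(m, nbins = 4))
  structure(list(classes = m, fractions = counts / length(m),
                 counts = counts, seed = NA_integer_),
            class = "pixel_map")
}
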