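# Occupancy grids and inverse-Boltzmann free-energy landscapes.
#
# Sighting counts n_c per conformational cell are converted to relative
# free energies E_c = -kT ln(n_c / n_max); cells never sighted carry no
# energy (mask), and the deepest observable state in an ensemble of N
# particles lies kT ln N above the minimum.

#' Boltzmann constant times temperature, in kcal/mol
#'
#' @param temperature Temperature in Kelvin (default 298.15).
#' @return kT in kcal/mol (0.593 at 298.15 K).
#' @export
kT_kcal <- function(temperature = 298.15) 0.0019872043 * temperature

#' Histogram global coordinates into an occupancy grid
#'
#' Cells are half-open `[lo, hi)` with the top edge closed, so a point on
#' an interior edge belongs to the higher cell and `cc = 1` to the last
#' cell. Rows index `cc1`, columns `cc2`.
#'
#' @param coords data.frame with `cc1`, `cc2` in `[0, 1]` (a
#'   `global_coordinates` object's `coords`, or any such frame); rows with
#'   `NA` are dropped.
#' @param dims Grid dimensions `c(n1, n2)` (each >= 2); a single number is
#'   used for both axes.
#' @param condition Optional label stored with the grid.
#' @return Object of class `occupancy_grid`: `counts` (n1 x n2 integer
#'   matrix), `N`, `dims`, `condition`, cell-center axes `centers1`,
#'   `centers2`.
#' @export
occupancy_grid <- function(coords, dims = c(50, 50), condition = NA) {
  if (inherits(coords, "global_coordinates")) coords <- coords$coords
  if (length(dims) == 1) dims <- c(dims, dims)
  if (any(dims < 2)) stop("grid dims must be >= 2 per axis")
  ok <- stats::complete.cases(coords[, c("cc1", "cc2")])
  cc1 <- coords$cc1[ok]; cc2 <- coords$cc2[ok]
  if (any(cc1 < 0 | cc1 > 1 | cc2 < 0 | cc2 > 1))
    stop("coordinates outside [0, 1]")
  i1 <- pmin(dims[1], floor(cc1 * dims[1]) + 1L)
  i2 <- pmin(dims[2], floor(cc2 * dims[2]) + 1L)
  counts <- matrix(0L, dims[1], dims[2])
  t <- table(factor(i1, levels = seq_len(dims[1])),
             factor(i2, levels = seq_len(dims[2])))
  counts[] <- as.integer(t)
  structure(list(counts = counts, N = sum(counts), dims = as.integer(dims),
                 condition = condition,
                 centers1 = (seq_len(dims[1]) - 0.5) / dims[1],
                 centers2 = (seq_len(dims[2]) - 0.5) / dims[2]),
            class = "occupancy_grid")
}

#' Build an occupancy grid directly from counts
#'
#' @param counts Nonnegative integer matrix.
#' @param condition Optional label.
#' @return An `occupancy_grid`.
#' @export
occupancy_from_counts <- function(counts, condition = NA) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  dims <- dim(counts)
  structure(list(counts = counts, N = sum(counts), dims = dims,
                 condition = condition,
                 centers1 = (seq_len(dims[1]) - 0.5) / dims[1],
                 centers2 = (seq_len(dims[2]) - 0.5) / dims[2]),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("occupancy_grid [%s]: %dx%d cells, N = %d (%d occupied)\n",
              as.character(x$condition), x$dims[1], x$dims[2], x$N,
              sum(x$counts > 0)))
  invisible(x)
}

#' Observability limit on free energies
#'
#' The highest energy observable in an ensemble of `N` particles: a state
#' sighted once lies `kT ln N` above the ensemble minimum (natural
#' logarithm).
#'
#' @param N Ensemble size (>= 1).
#' @param kT Energy unit (kT in the unit you want the answer in; e.g.
#'   [kT_kcal()] for kcal/mol).
#' @return `kT * ln(N)`.
#' @export
delta_g_max <- function(N, kT = 1) {
  if (N < 1) stop("N must be >= 1")
  kT * log(N)
}

#' Inverse-Boltzmann energy landscape from an occupancy grid
#'
#' `E_c = -kT ln(n_c / n_max)` for occupied cells, so the most-populated
#' cell sits at exactly 0 (only relative free energies are defined since
#' the partition sum is unknown). Zero-count cells are masked as
#' unobserved, not given a pseudo-count. The conversion assumes the
#' coarse-graining degeneracy varies negligibly across cells (energy
#' variance dominates the entropy variance); this assumption is recorded
#' in the object's metadata as an analysis caveat.
#'
#' @param grid An [occupancy_grid()].
#' @param kT Energy unit for the output (default 1, i.e. kT units).
#' @return Object of class `energy_landscape`: `energy` (matrix, `NA` on
#'   masked cells), `mask` (TRUE = unobserved), `kT`, `N`,
#'   `delta_g_max`, `dims`, `condition`, cell centers.
#' @export
energy_from_occupancy <- function(grid, kT = 1) {
  stopifnot(inherits(grid, "occupancy_grid"))
  if (all(grid$counts == 0)) stop("all-zero occupancy grid")
  n_max <- max(grid$counts)
  E <- matrix(NA_real_, grid$dims[1], grid$dims[2])
  occ <- grid$counts > 0
  E[occ] <- -kT * log(grid$counts[occ] / n_max)
  structure(list(energy = E, mask = !occ, kT = kT, N = grid$N,
                 delta_g_max = delta_g_max(grid$N, kT),
                 dims = grid$dims, condition = grid$condition,
                 centers1 = grid$centers1, centers2 = grid$centers2,
                 caveat = paste("assumes coarse-graining degeneracy",
                                "variance is negligible")),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf(
    "energy_landscape [%s]: %dx%d cells, N = %d, kT = %.4g\n",
    as.character(x$condition), x$dims[1], x$dims[2], x$N, x$kT))
  cat(sprintf("  occupied: %d cells, E in [0, %.3g]; dGmax = %.3g\n",
              sum(!x$mask), max(x$energy, na.rm = TRUE), x$delta_g_max))
  invisible(x)
}

#' Probability mass of a cell region
#'
#' Fraction of all snapshots whose conformation falls in a set of cells —
#' e.g. the occupancy of a window around a transition hotspot.
#'
#' @param grid An [occupancy_grid()].
#' @param region Either a logical matrix of the grid's dimensions or a
#'   two-column matrix of (row, col) cell indices.
#' @return `sum(n_c in region) / N`.
#' @export
region_fraction <- function(grid, region) {
  stopifnot(inherits(grid, "occupancy_grid"))
  if (is.logical(region)) {
    stopifnot(all(dim(region) == grid$dims))
    sel <- region
  } else {
    region <- matrix(as.integer(region), ncol = 2)
    if (nrow(region) == 0) stop("region must be nonempty")
    if (any(region[, 1] < 1 | region[, 1] > grid$dims[1] |
            region[, 2] < 1 | region[, 2] > grid$dims[2]))
      stop("region contains invalid cells")
    sel <- matrix(FALSE, grid$dims[1], grid$dims[2])
    sel[region] <- TRUE
  }
  sum(grid$counts[sel]) / grid$N
}

#' Cells of a rectangular window around a center cell
#'
#' @param dims Grid dimensions.
#' @param center c(row, col).
#' @param half_width Window half-width in cells.
#' @return Two-column matrix of cell indices (clipped to the grid).
#' @export
cell_window <- function(dims, center, half_width = 1) {
  r <- max(1, center[1] - half_width):min(dims[1], center[1] + half_width)
  c <- max(1, center[2] - half_width):min(dims[2], center[2] + half_width)
  as.matrix(expand.grid(row = r, col = c))
}

#' Contour plot of an energy landscape
#'
#' Filled image with contour lines; unobserved cells are blank.
#'
#' @param x An `energy_landscape`.
#' @param nlevels Number of contour levels.
#' @param ... Passed to [graphics::image()].
#' @export
plot.energy_landscape <- function(x, nlevels = 10, ...) {
  graphics::image(x$centers1, x$centers2, x$energy,
                  col = grDevices::hcl.colors(64, "viridis",
                                              rev = TRUE),
                  xlab = "CC1", ylab = "CC2",
                  main = sprintf("free energy [%s] (kT = %.3g)",
                                 as.character(x$condition), x$kT), ...)
  graphics::contour(x$centers1, x$centers2, x$energy,
                    nlevels = nlevels, add = TRUE, col = "grey30")
  invisible(x)
}

#' Export a landscape (or occupancy grid) as a tidy data.frame / CSV
#'
#' @param x An `energy_landscape` or `occupancy_grid`.
#' @param path Optional CSV path; when given the frame is also written.
#' @return data.frame with cell indices, centers and value.
#' @export
landscape_to_df <- function(x, path = NULL) {
  v <- if (inherits(x, "energy_landscape")) x$energy else x$counts
  df <- data.frame(
    i1 = rep(seq_len(x$dims[1]), x$dims[2]),
    i2 = rep(seq_len(x$dims[2]), each = x$dims[1]),
    cc1 = rep(x$centers1, x$dims[2]),
    cc2 = rep(x$centers2, each = x$dims[1]),
    value = as.vector(v))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
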