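# Interlandscape ligand-association transition maps from a master-equation
# model. At early times, with all probability on the apo (minus) landscape
# at equilibrium and iso-conformational binding at mass-action rates whose
# association constant follows the bound-landscape Arrhenius factor, the
# gain of each bound state is proportional to the product of the two
# conformational spectra: hotspots are the maxima of that product.

#' Conformational spectrum of a condition
#'
#' Per-cell occupancy probability `P_c = n_c / N`.
#'
#' @param grid An [occupancy_grid()].
#' @return Object of class `conformational_spectrum` with `P` (matrix
#'   summing to 1), `dims`, `condition`.
#' @export
conformational_spectrum <- function(grid) {
  stopifnot(inherits(grid, "occupancy_grid"))
  if (grid$N == 0) stop("empty occupancy grid")
  structure(list(P = grid$counts / grid$N, dims = grid$dims,
                 condition = grid$condition),
            class = "conformational_spectrum")
}

#' Interlandscape transition-probability map
#'
#' `T_c = P_c^+ P_c^- / sum_c P_c^+ P_c^-`: the normalized early-time gain
#' of each bound conformational state. Cells unoccupied in either
#' condition get 0.
#'
#' @param occ_minus,occ_plus [occupancy_grid()]s on identical grids.
#' @return Object of class `transition_map` with `T` (matrix summing to
#'   1), `dims`, cell centers.
#' @export
transition_map <- function(occ_minus, occ_plus) {
  stopifnot(inherits(occ_minus, "occupancy_grid"),
            inherits(occ_plus, "occupancy_grid"))
  if (!all(occ_minus$dims == occ_plus$dims))
    stop("occupancy grids have different dimensions")
  prod <- (occ_minus$counts / occ_minus$N) * (occ_plus$counts / occ_plus$N)
  s <- sum(prod)
  if (s == 0)
    stop("no iso-conformational overlap: the two conditions occupy ",
         "disjoint cells")
  structure(list(T = prod / s, dims = occ_minus$dims,
                 centers1 = occ_minus$centers1,
                 centers2 = occ_minus$centers2),
            class = "transition_map")
}

#' @export
print.transition_map <- function(x, ...) {
  am <- which(x$T == max(x$T), arr.ind = TRUE)[1, ]
  cat(sprintf(
    "transition_map: %dx%d, max %.3g at cell (%d, %d), %d nonzero\n",
    x$dims[1], x$dims[2], max(x$T), am[1], am[2], sum(x$T > 0)))
  invisible(x)
}

#' Hotspots of a transition map
#'
#' Local maxima over the 8-neighbourhood (a cell is a hotspot when its
#' value is >= every neighbour's and >= `rel_threshold * max(T)`), sorted
#' by value descending with ties broken by row-major cell index.
#'
#' @param tmap A [transition_map()].
#' @param rel_threshold Fraction of the global maximum below which local
#'   maxima are dropped (default 0.5).
#' @return data.frame with `row`, `col`, `value`, ordered.
#' @export
find_hotspots <- function(tmap, rel_threshold = 0.5) {
  T <- tmap$T
  n1 <- nrow(T); n2 <- ncol(T)
  pad <- matrix(-Inf, n1 + 2, n2 + 2)
  pad[2:(n1 + 1), 2:(n2 + 1)] <- T
  is_max <- matrix(TRUE, n1, n2)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max &
      (T >= pad[(2 + dr):(n1 + 1 + dr), (2 + dc):(n2 + 1 + dc)])
  }
  keep <- which(is_max & T >= rel_threshold * max(T) & T > 0)
  rows <- ((keep - 1) %% n1) + 1
  cols <- ((keep - 1) %/% n1) + 1
  rowmajor <- (rows - 1) * n2 + cols
  out <- data.frame(row = rows, col = cols, value = T[keep],
                    rowmajor = rowmajor)
  out <- out[order(-out$value, out$rowmajor), ]
  rownames(out) <- NULL
  out$rowmajor <- NULL
  out
}

# ---- Rate model ----

neighbor_offsets_8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                            dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Build the dual-landscape rate model
#'
#' Intra-landscape moves connect 8-neighbouring occupied cells at
#' Metropolis rates `A * min(1, exp(-(E_j - E_i)/kT))`, which guarantees
#' the inverse-Boltzmann density of each landscape is stationary for its
#' own block. Ligand association connects iso-conformational cells only
#' (diagonal in conformation space) at the mass-action rate
#' `L * A * exp(-(E_c^+ - E_min^+)/kT)`, i.e. proportional to the bound
#' spectrum. Dissociation defaults to zero, matching an initial-time
#' analysis with no bound receptors; a detailed-balance-consistent
#' dissociation rate is available behind `dissociation =
#' "detailed_balance"` (with binding constant `K_b`), with the caveat that
#' association-only maps offer an incomplete description of the reversible
#' binding pathway.
#'
#' @param E_minus,E_plus [energy_from_occupancy()] landscapes on a shared
#'   grid.
#' @param L Free-ligand concentration (arbitrary units; scales association
#'   rates only).
#' @param A Arrhenius prefactor.
#' @param kT Energy unit matching the landscapes.
#' @param dissociation `"none"` (default) or `"detailed_balance"`.
#' @param K_b Binding constant used by the detailed-balance dissociation.
#' @return Object of class `rate_model`: sparse intra-landscape rate
#'   matrices `Wmm`, `Wpp` (entry `[c, c']` is the rate from `c'` to `c`),
#'   association/dissociation vectors `wmp`, `wpm`, and metadata.
#' @export
build_rate_model <- function(E_minus, E_plus, L = 1, A = 1, kT = 1,
                             dissociation = c("none", "detailed_balance"),
                             K_b = 1) {
  stopifnot(inherits(E_minus, "energy_landscape"),
            inherits(E_plus, "energy_landscape"))
  if (!all(E_minus$dims == E_plus$dims))
    stop("landscapes have different grid dimensions")
  if (L < 0) stop("ligand concentration must be >= 0")
  if (A <= 0) stop("prefactor must be positive")
  dissociation <- match.arg(dissociation)
  dims <- E_minus$dims
  intra <- function(E) {
    n1 <- dims[1]; n2 <- dims[2]
    from <- integer(0); to <- integer(0); rate <- numeric(0)
    occ <- which(!is.na(E), arr.ind = TRUE)
    for (k in seq_len(nrow(neighbor_offsets_8))) {
      r2 <- occ[, 1] + neighbor_offsets_8[k, 1]
      c2 <- occ[, 2] + neighbor_offsets_8[k, 2]
      ok <- r2 >= 1 & r2 <= n1 & c2 >= 1 & c2 <= n2
      i <- occ[ok, , drop = FALSE]
      j <- cbind(r2[ok], c2[ok])
      Ej <- E[j]
      okj <- !is.na(Ej)    # masked-cell adjacency: zero rate
      i <- i[okj, , drop = FALSE]; j <- j[okj, , drop = FALSE]
      if (nrow(i) == 0) next
      w <- A * pmin(1, exp(-(E[j] - E[i]) / kT))
      from <- c(from, i[, 1] + (i[, 2] - 1) * n1)
      to <- c(to, j[, 1] + (j[, 2] - 1) * n1)
      rate <- c(rate, w)
    }
    Matrix::sparseMatrix(i = to, j = from, x = rate,
                         dims = c(n1 * n2, n1 * n2))
  }
  both <- !E_minus$mask & !E_plus$mask
  wmp <- numeric(prod(dims))
  wmp[both] <- L * A * exp(-E_plus$energy[both] / kT)
  wpm <- numeric(prod(dims))
  if (dissociation == "detailed_balance")
    wpm[both] <- (A / K_b) * exp(-E_minus$energy[both] / kT)
  structure(list(dims = dims, Wmm = intra(E_minus$energy),
                 Wpp = intra(E_plus$energy), wmp = wmp, wpm = wpm,
                 L = L, A = A, kT = kT, dissociation = dissociation,
                 mask_minus = E_minus$mask, mask_plus = E_plus$mask),
            class = "rate_model")
}

#' Full generator matrix of a rate model
#'
#' State ordering: all minus-landscape cells, then all plus-landscape
#' cells. Entry `[to, from]` holds the rate; diagonal entries are minus
#' the column sums, so columns sum to zero and total probability is
#' conserved.
#'
#' @param model A [build_rate_model()].
#' @return Sparse `2n x 2n` generator matrix.
#' @export
rate_generator <- function(model) {
  n <- prod(model$dims)
  G <- rbind(cbind(model$Wmm, Matrix::Diagonal(n, model$wpm)),
             cbind(Matrix::Diagonal(n, model$wmp), model$Wpp))
  Matrix::diag(G) <- Matrix::diag(G) - Matrix::colSums(G)
  G
}

#' Integrate the coupled master equations
#'
#' Solves the linear system `dp/dt = G p` for the concatenated
#' (minus, plus) probability vector with deSolve. Total probability must
#' be conserved to 1e-8 along the trajectory and probabilities must not go
#' below -1e-8 (otherwise a step-size failure error is raised).
#'
#' @param model A [build_rate_model()].
#' @param p0 Initial probability vector of length `2 * prod(dims)`,
#'   nonnegative, summing to 1. The standard initial condition puts all
#'   probability on the minus landscape at its equilibrium.
#' @param times Output time grid (must start at 0).
#' @return Object of class `me_trajectory`: `times`, `p` (length(times) x
#'   2n matrix).
#' @export
integrate_master_equation <- function(model, p0, times) {
  n2 <- 2 * prod(model$dims)
  stopifnot(length(p0) == n2)
  if (any(p0 < 0)) stop("p0 must be nonnegative")
  if (abs(sum(p0) - 1) > 1e-10) stop("p0 must sum to 1")
  G <- rate_generator(model)
  deriv <- function(t, p, parms) list(as.vector(G %*% p))
  sol <- deSolve::ode(y = p0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  p <- unname(sol[, -1, drop = FALSE])
  if (max(abs(rowSums(p) - 1)) > 1e-8)
    stop("probability not conserved along the trajectory")
  if (min(p) < -1e-8)
    stop("step-size failure: negative probabilities beyond tolerance")
  structure(list(times = times, p = p, dims = model$dims),
            class = "me_trajectory")
}

#' Image plot of a transition map
#'
#' @param x A `transition_map`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.transition_map <- function(x, ...) {
  graphics::image(x$centers1, x$centers2, x$T,
                  col = grDevices::hcl.colors(64, "inferno",
                                              rev = TRUE),
                  xlab = "CC1", ylab = "CC2",
                  main = "interlandscape transition probability", ...)
  hs <- find_hotspots(x)
  if (nrow(hs) > 0)
    graphics::points(x$centers1[hs$row], x$centers2[hs$col], pch = 4,
                     col = "white", cex = 1.2)
  invisible(x)
}

#' Tidy a master-equation trajectory
#'
#' Long-format time series, one row per (time, landscape side, cell),
#' convenient for CSV export.
#'
#' @param x An `me_trajectory`.
#' @param ... Unused.
#' @return data.frame with `time`, `side`, `cell`, `p`.
#' @export
as.data.frame.me_trajectory <- function(x, ...) {
  n <- prod(x$dims)
  nt <- length(x$times)
  data.frame(time = rep(x$times, each = 2 * n),
             side = rep(rep(c("minus", "plus"), each = n), nt),
             cell = rep(seq_len(n), 2 * nt),
             p = as.vector(t(x$p)))
}

#' Boltzmann equilibrium of a single landscape
#'
#' `exp(-E/kT) / Z` over occupied cells (0 on masked cells).
#'
#' @param landscape An [energy_from_occupancy()] landscape.
#' @return Vector of length `prod(dims)` summing to 1.
#' @export
boltzmann_density <- function(landscape) {
  p <- numeric(prod(landscape$dims))
  occ <- !landscape$mask
  p[occ] <- exp(-landscape$energy[occ] / landscape$kT)
  p / sum(p)
}

#' Initial interlandscape flux
#'
#' Early-time gain of each bound state: the iso-conformational association
#' rate times the apo equilibrium probability, `W^{-+}(c) p_c^-`. After
#' normalization over the grid this equals the [transition_map()] exactly.
#'
#' @param model A [build_rate_model()].
#' @param p_minus_eq Apo equilibrium probabilities (matrix or vector over
#'   cells, summing to 1).
#' @return Matrix of per-cell fluxes (same shape as the grid).
#' @export
initial_flux <- function(model, p_minus_eq) {
  p <- as.vector(p_minus_eq)
  stopifnot(length(p) == prod(model$dims))
  matrix(model$wmp * p, model$dims[1], model$dims[2])
}
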