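# Least-energy functional paths over the dual landscapes: grid Dijkstra
# with a trapezoidal energy line-integral (or minimax) cost, START -> HOT
# -> FINISH concatenation, arc-length resampling into movie frames with
# per-frame snapshot sets, and a toy real-space back-projector.

cell_index <- function(cells, n1) cells[, 1] + (cells[, 2] - 1) * n1

# neighbours in row-major order of the neighbouring cell
path_neighbor_offsets <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                               dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Least-action path between two cells of an energy landscape
#'
#' Shortest path on the 8-connected graph of occupied cells. In
#' `"integral"` mode (default) each step costs its length times the mean
#' of the two endpoint energies (a trapezoidal line integral of energy
#' along the route); `"minimax"` mode minimizes the maximum energy visited,
#' with ties resolved by the integral cost. Tie-breaking is deterministic:
#' nodes are settled lowest-index first and neighbours scanned in
#' row-major order, so equal-cost routes resolve identically on every run.
#' Masked (never-observed) cells are impassable by default; with
#' `allow_masked = TRUE` they can be crossed at energy `delta_g_max`.
#'
#' @param landscape An [energy_from_occupancy()] landscape.
#' @param start,end Cells as `c(row, col)`.
#' @param mode `"integral"` or `"minimax"`.
#' @param allow_masked Allow crossing unobserved cells at the
#'   observability-limit energy.
#' @return List with `cells` (k x 2 matrix), `energy` (per cell), `action`
#'   (integral cost), `bottleneck` (max energy), `mode`.
#' @export
least_action_path <- function(landscape, start, end,
                              mode = c("integral", "minimax"),
                              allow_masked = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(landscape, "energy_landscape"))
  n1 <- landscape$dims[1]; n2 <- landscape$dims[2]
  E <- landscape$energy
  if (allow_masked) E[is.na(E)] <- landscape$delta_g_max
  chk <- function(cell, what) {
    if (cell[1] < 1 || cell[1] > n1 || cell[2] < 1 || cell[2] > n2)
      stop(what, " cell out of range")
    if (is.na(E[cell[1], cell[2]]))
      stop(what, " cell (", cell[1], ",", cell[2], ") is unobserved; ",
           "set allow_masked = TRUE to cross the mask")
  }
  chk(start, "start"); chk(end, "end")
  n1n2 <- n1 * n2
  s <- start[1] + (start[2] - 1) * n1
  e <- end[1] + (end[2] - 1) * n1
  Ev <- as.vector(E)

  # deterministic O(V^2) Dijkstra; `kind` selects the accumulated cost:
  # "sum" for the trapezoidal action, "max" for the bottleneck energy
  dijkstra <- function(Euse, kind) {
    d <- rep(Inf, n1n2)
    prev <- rep(NA_integer_, n1n2)
    done <- rep(FALSE, n1n2)
    d[s] <- if (kind == "max") Euse[s] else 0
    repeat {
      cand <- which(!done & is.finite(d))
      if (length(cand) == 0) break
      u <- cand[which.min(d[cand])]   # lowest index on ties
      if (u == e) break
      done[u] <- TRUE
      ur <- ((u - 1) %% n1) + 1
      uc <- ((u - 1) %/% n1) + 1
      for (k in seq_len(8)) {
        vr <- ur + path_neighbor_offsets[k, 1]
        vc <- uc + path_neighbor_offsets[k, 2]
        if (vr < 1 || vr > n1 || vc < 1 || vc > n2) next
        v <- vr + (vc - 1) * n1
        if (done[v] || is.na(Euse[v])) next
        nd <- if (kind == "max") max(d[u], Euse[v]) else
          d[u] + sqrt((vr - ur)^2 + (vc - uc)^2) *
            (Euse[u] + Euse[v]) / 2
        if (nd < d[v]) { d[v] <- nd; prev[v] <- u }
      }
    }
    list(d = d, prev = prev)
  }

  if (mode == "minimax") {
    # phase 1: minimal achievable bottleneck; phase 2: minimal action on
    # the subgraph of cells not exceeding it (every route there attains
    # exactly the optimal bottleneck)
    bot <- dijkstra(Ev, "max")
    if (!is.finite(bot$d[e]))
      stop("no route between the requested cells: the unobserved-cell ",
           "mask disconnects them")
    Esub <- Ev
    Esub[!is.na(Esub) & Esub > bot$d[e] + 1e-12] <- NA
    res <- dijkstra(Esub, "sum")
  } else {
    res <- dijkstra(Ev, "sum")
  }
  if (!is.finite(res$d[e]))
    stop("no route between the requested cells: the unobserved-cell mask ",
         "disconnects them")
  cells <- e
  while (cells[1] != s) cells <- c(res$prev[cells[1]], cells)
  cells_rc <- cbind(row = ((cells - 1) %% n1) + 1,
                    col = ((cells - 1) %/% n1) + 1)
  energy <- Ev[cells]
  list(cells = cells_rc, energy = energy,
       action = path_action_cells(cells_rc, Ev, n1),
       bottleneck = max(energy), mode = mode)
}

path_action_cells <- function(cells, Ev, n1) {
  if (nrow(cells) < 2) return(0)
  i <- cell_index(cells, n1)
  len <- sqrt(diff(cells[, 1])^2 + diff(cells[, 2])^2)
  sum(len * (Ev[i[-length(i)]] + Ev[i[-1]]) / 2)
}

#' Action of an arbitrary cell path on a landscape
#'
#' Trapezoidal energy line integral along a given route (used e.g. to
#' compare the optimum against a straight-line interpolation).
#'
#' @param landscape An energy landscape.
#' @param cells k x 2 matrix of cells.
#' @param allow_masked Treat unobserved cells at `delta_g_max`.
#' @return Numeric action.
#' @export
path_action <- function(landscape, cells, allow_masked = FALSE) {
  E <- landscape$energy
  if (allow_masked) E[is.na(E)] <- landscape$delta_g_max
  path_action_cells(as.matrix(cells), as.vector(E), landscape$dims[1])
}

#' Bresenham straight-line cell interpolation
#'
#' @param start,end Cells as `c(row, col)`.
#' @return k x 2 matrix of cells from start to end.
#' @export
bresenham_path <- function(start, end) {
  x0 <- start[1]; y0 <- start[2]; x1 <- end[1]; y1 <- end[2]
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- sign(x1 - x0); sy <- sign(y1 - y0)
  if (sx == 0) sx <- 1
  if (sy == 0) sy <- 1
  err <- dx + dy
  out <- matrix(c(x0, y0), 1, 2)
  while (!(x0 == x1 && y0 == y1)) {
    e2 <- 2 * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
    out <- rbind(out, c(x0, y0))
  }
  colnames(out) <- c("row", "col")
  out
}

landscape_argmin <- function(landscape) {
  E <- landscape$energy
  m <- min(E, na.rm = TRUE)
  w <- which(!is.na(E) & E == m)
  # lowest row-major index on ties
  rows <- ((w - 1) %% landscape$dims[1]) + 1
  cols <- ((w - 1) %/% landscape$dims[1]) + 1
  rm <- (rows - 1) * landscape$dims[2] + cols
  k <- which.min(rm)
  c(rows[k], cols[k])
}

#' Functional path across the dual landscapes
#'
#' Concatenates the least-action route on the apo landscape from its
#' minimum (START) to the transition hotspot (HOT) with the route on the
#' bound landscape from the hotspot to its minimum (FINISH). The crossing
#' is iso-conformational: the same grid cell on both landscapes. Reports
#' two occupancy summaries: the apo probability mass in a window around
#' the hotspot (how often the transition zone is visited before binding)
#' and the normalized transition probability at the hotspot cell.
#'
#' @param E_minus,E_plus Landscapes on a shared grid.
#' @param tmap A [transition_map()].
#' @param hotspot Optional `c(row, col)`; defaults to the top-ranked
#'   [find_hotspots()] cell.
#' @param occ_minus Optional apo [occupancy_grid()] used for the window
#'   summary.
#' @param window_half_width Hotspot window half-width in cells (default 1).
#' @param mode Path mode, see [least_action_path()].
#' @param allow_masked Allow crossing unobserved cells.
#' @return Object of class `functional_path`: `cells`, `side`
#'   ("minus"/"plus" per cell), `switch_index`, `energy`, `action`,
#'   `hotspot`, `summaries`.
#' @export
dual_landscape_path <- function(E_minus, E_plus, tmap, hotspot = NULL,
                                occ_minus = NULL, window_half_width = 1,
                                mode = "integral", allow_masked = FALSE) {
  if (is.null(hotspot)) {
    hs <- find_hotspots(tmap)
    if (nrow(hs) == 0) stop("transition map has no hotspot")
    hotspot <- c(hs$row[1], hs$col[1])
  }
  if (is.na(E_minus$energy[hotspot[1], hotspot[2]]) ||
      is.na(E_plus$energy[hotspot[1], hotspot[2]]))
    stop("hotspot cell must be occupied on both landscapes")
  start <- landscape_argmin(E_minus)
  finish <- landscape_argmin(E_plus)
  p1 <- least_action_path(E_minus, start, hotspot, mode = mode,
                          allow_masked = allow_masked)
  p2 <- least_action_path(E_plus, hotspot, finish, mode = mode,
                          allow_masked = allow_masked)
  k1 <- nrow(p1$cells)
  cells <- rbind(p1$cells, p2$cells[-1, , drop = FALSE])
  side <- c(rep("minus", k1), rep("plus", nrow(p2$cells) - 1))
  energy <- c(p1$energy, p2$energy[-1])
  summaries <- list(hotspot_transition_prob = tmap$T[hotspot[1],
                                                     hotspot[2]])
  if (!is.null(occ_minus)) {
    win <- cell_window(occ_minus$dims, hotspot, window_half_width)
    summaries$hotspot_window_fraction_minus <-
      region_fraction(occ_minus, win)
  }
  structure(list(cells = cells, side = side, switch_index = k1,
                 energy = energy, action = p1$action + p2$action,
                 hotspot = hotspot, mode = mode, summaries = summaries),
            class = "functional_path")
}

#' @export
print.functional_path <- function(x, ...) {
  cat(sprintf(
    "functional_path: %d cells, switch at %d (hotspot %d,%d), action %.3g\n",
    nrow(x$cells), x$switch_index, x$hotspot[1], x$hotspot[2], x$action))
  if (!is.null(x$summaries$hotspot_window_fraction_minus))
    cat(sprintf("  apo occupancy of hotspot window: %.3g%%\n",
                100 * x$summaries$hotspot_window_fraction_minus))
  cat(sprintf("  transition probability at hotspot: %.3g%%\n",
              100 * x$summaries$hotspot_transition_prob))
  invisible(x)
}

#' Resample a functional path into movie frames with snapshot sets
#'
#' The path polyline (cell centers in coordinate units) is resampled by
#' arc length into `n_frames` equidistant frame centers. Each frame
#' collects the snapshots of its landscape side whose coordinates fall in
#' a rectangular window around the frame center (half-width in cells).
#' Optional endpoint excursions extend the route along CC1 beyond the two
#' minima (increasing CC1 on the apo side, decreasing CC1 on the bound
#' side) to ease distance measurements near the endpoints.
#'
#' @param path A [dual_landscape_path()] result.
#' @param coords Per-snapshot coordinates (data.frame `cc1`, `cc2`).
#' @param condition Per-snapshot condition labels.
#' @param dims Grid dimensions the path lives on.
#' @param n_frames Number of frames (>= 2; default 50).
#' @param half_width Window half-width in cells (default 1).
#' @param excursions Extend endpoints along CC1 by this many cells
#'   (default 0 = off).
#' @return Object of class `frame_set`: per-frame `center` (cc units),
#'   `cell`, `side`, `members` (list of snapshot indices).
#' @export
path_frames <- function(path, coords, condition, dims, n_frames = 50,
                        half_width = 1, excursions = 0) {
  stopifnot(n_frames >= 2)
  if (inherits(coords, "global_coordinates")) coords <- coords$coords
  cells <- path$cells
  side <- path$side
  if (excursions > 0) {
    pre_r <- seq(cells[1, 1] + excursions, cells[1, 1] + 1)
    pre_r <- pre_r[pre_r >= 1 & pre_r <= dims[1]]
    if (length(pre_r) > 0) {
      cells <- rbind(cbind(pre_r, cells[1, 2]), cells)
      side <- c(rep("minus", length(pre_r)), side)
    }
    post_r <- seq(cells[nrow(cells), 1] - 1,
                  cells[nrow(cells), 1] - excursions)
    post_r <- post_r[post_r >= 1 & post_r <= dims[1]]
    if (length(post_r) > 0) {
      side <- c(side, rep("plus", length(post_r)))
      cells <- rbind(cells, cbind(post_r, cells[nrow(cells), 2]))
    }
  }
  h1 <- 1 / dims[1]; h2 <- 1 / dims[2]
  pts <- cbind((cells[, 1] - 0.5) * h1, (cells[, 2] - 0.5) * h2)
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  targets <- seq(0, total, length.out = n_frames)
  frames <- lapply(targets, function(s) {
    k <- max(which(arc <= s + 1e-12))
    if (k == nrow(pts)) {
      ctr <- pts[k, ]; vertex <- k
    } else {
      f <- (s - arc[k]) / (arc[k + 1] - arc[k])
      ctr <- (1 - f) * pts[k, ] + f * pts[k + 1, ]
      vertex <- if (f < 0.5) k else k + 1
    }
    list(center = ctr, side = side[vertex],
         cell = c(round(ctr[1] / h1 + 0.5), round(ctr[2] / h2 + 0.5)))
  })
  members <- vector("list", n_frames)
  w1 <- (half_width + 0.5) * h1
  w2 <- (half_width + 0.5) * h2
  for (f in seq_len(n_frames)) {
    fr <- frames[[f]]
    sel <- which(condition == fr$side &
                   abs(coords$cc1 - fr$center[1]) <= w1 &
                   abs(coords$cc2 - fr$center[2]) <= w2)
    if (length(sel) == 0)
      warning("frame ", f, " has no member snapshots")
    members[[f]] <- sel
  }
  structure(list(centers = t(vapply(frames, `[[`, numeric(2), "center")),
                 cells = t(vapply(frames, function(f) as.numeric(f$cell),
                                  numeric(2))),
                 side = vapply(frames, `[[`, character(1), "side"),
                 members = members, n_frames = n_frames,
                 half_width = half_width),
            class = "frame_set")
}

#' Toy real-space back-projection of an image subset
#'
#' Adjoint of the nearest-voxel line projection: each image value is
#' smeared back along its beam, accumulated over images, and normalized by
#' per-voxel hit counts. Intended for blob phantoms, not for quantitative
#' reconstruction.
#'
#' @param images `H x W x m` array (or matrix `npix x m`).
#' @param orientations data.frame with `rot`, `tilt`, `psi` per image.
#' @param volume_size Output cubic volume side.
#' @return `volume_size^3` array.
#' @export
backproject_frame <- function(images, orientations, volume_size) {
  if (is.matrix(images)) {
    W <- as.integer(sqrt(nrow(images)))
    images <- array(images, dim = c(W, W, ncol(images)))
  }
  d <- dim(images)
  m <- d[3]
  if (m < 1) stop("empty image subset")
  W <- d[1]
  s <- volume_size
  ax <- voxel_axis(s)
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  acc <- numeric(s^3)
  hits <- numeric(s^3)
  half <- (W + 1) / 2
  for (i in seq_len(m)) {
    A <- euler_to_matrix(orientations$rot[i], orientations$tilt[i],
                         orientations$psi[i])
    q <- pts %*% t(A)
    px <- round(q[, 1] + half)
    py <- round(q[, 2] + half)
    ok <- px >= 1 & px <= W & py >= 1 & py <= W
    idx <- px[ok] + (py[ok] - 1) * W
    img <- images[, , i]
    acc[ok] <- acc[ok] + img[idx]
    hits[ok] <- hits[ok] + 1
  }
  out <- numeric(s^3)
  nz <- hits > 0
  out[nz] <- acc[nz] / hits[nz]
  array(out, dim = c(s, s, s))
}
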