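# Shared fixtures built in code at test time.

# small occupancy grid from explicit counts
occ2 <- function(counts, condition = "minus") {
  occupancy_from_counts(matrix(as.integer(counts), nrow = 2), condition)
}

# random energy landscape on a grid: counts ~ Poisson, all occupied
random_landscape <- function(n1, n2, seed, kT = 1, lambda = 50) {
  set.seed(seed)
  counts <- matrix(stats::rpois(n1 * n2, lambda) + 1L, n1, n2)
  energy_from_occupancy(occupancy_from_counts(counts), kT = kT)
}

# tiny deterministic PDB text (CA-only chains); coords is a data.frame
# with chain, resno, x, y, z and optional alt, occ
write_tiny_pdb <- function(path, coords, atom = "CA", resid = "ALA") {
  lines <- character(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    r <- coords[i, ]
    alt <- if (!is.null(r$alt)) r$alt else ""
    occ <- if (!is.null(r$occ)) r$occ else 1.0
    lines[i] <- sprintf(
      "ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      i, atom, alt, resid, r$chain, r$resno, r$x, r$y, r$z, occ, 0.0)
  }
  writeLines(c(lines, "END"), path)
  path
}

# brute-force least-action oracle: depth-first enumeration of simple
# paths on the 8-connected occupied-cell graph with cost pruning
oracle_path_cost <- function(E, start, end, mode = "integral") {
  n1 <- nrow(E); n2 <- ncol(E)
  offs <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1),
                c(-1, 0, 1, -1, 1, -1, 0, 1))
  best <- list(primary = Inf, secondary = Inf)
  visited <- matrix(FALSE, n1, n2)
  rec <- function(cell, primary, secondary) {
    if (primary > best$primary ||
        (primary == best$primary && secondary >= best$secondary)) return()
    if (all(cell == end)) {
      best <<- list(primary = primary, secondary = secondary)
      return()
    }
    visited[cell[1], cell[2]] <<- TRUE
    for (k in 1:8) {
      r <- cell[1] + offs[k, 1]; c <- cell[2] + offs[k, 2]
      if (r < 1 || r > n1 || c < 1 || c > n2) next
      if (visited[r, c] || is.na(E[r, c])) next
      len <- sqrt(offs[k, 1]^2 + offs[k, 2]^2)
      step <- len * (E[cell[1], cell[2]] + E[r, c]) / 2
      if (mode == "integral") rec(c(r, c), primary + step, 0)
      else rec(c(r, c), max(primary, E[r, c]), secondary + step)
    }
    visited[cell[1], cell[2]] <<- FALSE
  }
  p0 <- if (mode == "minimax") E[start[1], start[2]] else 0
  rec(start, p0, 0)
  best
}

# small noise-free ensemble rendered once per test session (a direction
# set small enough for fast embedding tests)
tiny_ensemble <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pair <- define_dual_landscape("shifted_double_well")
      cache <<- simulate_ensemble(pair, n_per_condition = 300,
                                  n_directions = 6, seed = 42)
    }
    cache
  }
})
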