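# Synthetic two-degree-of-freedom validation ensembles: a deformable
# Gaussian-blob phantom, analytic dual energy landscapes, Boltzmann
# conformational sampling, and noisy projection rendering.

# ---- Analytic landscapes ----

#' Construct an analytic energy landscape on the unit square
#'
#' Wraps a scalar energy function of two conformational coordinates
#' (`cc1`, `cc2`), each in `[0, 1]`, in kT units. The function is evaluated
#' on a fine grid to verify finiteness and to locate the global minimum;
#' energies are offset so the minimum is exactly 0.
#'
#' @param fn function(cc1, cc2) returning energy (vectorized).
#' @param grid_n Evaluation-grid resolution used for validation.
#' @return Object of class `analytic_landscape` with elements `fn`,
#'   `offset`, `minimum` (c(cc1, cc2) of the grid argmin).
#' @export
analytic_landscape <- function(fn, grid_n = 201) {
  g <- seq(0, 1, length.out = grid_n)
  E <- outer(g, g, fn)
  if (any(!is.finite(E))) {
    bad <- which(!is.finite(E), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite energy at (cc1=%.3f, cc2=%.3f)",
                 g[bad[1]], g[bad[2]]))
  }
  off <- min(E)
  am <- which(E == off, arr.ind = TRUE)[1, ]
  structure(list(fn = fn, offset = off,
                 minimum = c(g[am[1]], g[am[2]])),
            class = "analytic_landscape")
}

#' Evaluate an analytic landscape
#'
#' @param ls An [analytic_landscape()].
#' @param cc1,cc2 Coordinates in `[0, 1]` (vectorized).
#' @return Energies in kT, with global minimum 0.
#' @export
landscape_energy <- function(ls, cc1, cc2) ls$fn(cc1, cc2) - ls$offset

smooth_double_well <- function(m1, m2, depth2 = 1.5, width = 0.13,
                               trans_sigma = 0.25) {
  force(m1); force(m2); force(depth2); force(width); force(trans_sigma)
  function(cc1, cc2) {
    q1 <- (cc1 - m1)^2 / (2 * width^2)
    q2 <- (cc1 - m2)^2 / (2 * width^2)
    -log(exp(-q1) + exp(-depth2) * exp(-q2)) +
      (cc2 - 0.5)^2 / (2 * trans_sigma^2)
  }
}

#' Define a dual (apo / ligand-bound) analytic landscape pair
#'
#' @param spec Either a preset name (`"shifted_double_well"`,
#'   `"shifted_bowls"`) or a list with elements `minus` and `plus`, each a
#'   vectorized function(cc1, cc2) in kT units.
#' @param grid_n Validation-grid resolution.
#' @return Object of class `landscape_pair` with `minus`, `plus`
#'   ([analytic_landscape()]s) and `name`.
#' @details
#' Preset `"shifted_double_well"` is separable: a smooth double well along
#' `cc1` (wells at 0.3 and 0.7, the minor well 1.5 kT above the major one)
#' plus harmonic confinement of `cc2` around 0.5. The apo (`minus`) global
#' minimum sits at `cc1 = 0.3` and the ligand-bound (`plus`) minimum at
#' `cc1 = 0.7`, so the start and end states of a functional transition
#' live at different conformations. Separability makes the two degrees of
#' freedom statistically independent, which keeps the validation
#' interpretable per coordinate. Preset `"shifted_bowls"` is a pair of
#' quadratic bowls (curvature 8 kT) with shifted minima, useful when broad
#' coverage of the unit square is wanted.
#' @export
define_dual_landscape <- function(spec, grid_n = 201) {
  if (is.character(spec)) {
    spec <- switch(spec,
      shifted_double_well = list(
        minus = smooth_double_well(0.3, 0.7),
        plus = smooth_double_well(0.7, 0.3),
        name = "shifted_double_well"),
      shifted_bowls = list(
        minus = function(cc1, cc2) 8 * ((cc1 - 0.35)^2 + (cc2 - 0.4)^2),
        plus = function(cc1, cc2) 8 * ((cc1 - 0.65)^2 + (cc2 - 0.6)^2),
        name = "shifted_bowls"),
      stop("unknown landscape preset: ", spec))
  }
  stopifnot(is.function(spec$minus), is.function(spec$plus))
  structure(list(minus = analytic_landscape(spec$minus, grid_n),
                 plus = analytic_landscape(spec$plus, grid_n),
                 name = if (!is.null(spec$name)) spec$name else "custom"),
            class = "landscape_pair")
}

#' @export
print.landscape_pair <- function(x, ...) {
  cat(sprintf("landscape_pair '%s'\n", x$name))
  cat(sprintf("  minus minimum at (%.3f, %.3f)\n",
              x$minus$minimum[1], x$minus$minimum[2]))
  cat(sprintf("  plus  minimum at (%.3f, %.3f)\n",
              x$plus$minimum[1], x$plus$minimum[2]))
  invisible(x)
}

# ---- Boltzmann sampling of conformations ----

#' Sample conformations from an analytic landscape
#'
#' Draws (`cc1`, `cc2`) pairs from the Boltzmann density
#' `exp(-E/kT)` on the unit square. The default `"grid"` method computes
#' cell probabilities on a fine grid, draws multinomial counts, and jitters
#' points uniformly within their cell; `"rejection"` draws uniform
#' proposals accepted with probability `exp(-E/kT)` (valid because the
#' landscape minimum is 0) and aborts if the acceptance rate falls below
#' 1e-4, suggesting the grid method.
#'
#' @param ls An [analytic_landscape()].
#' @param n Number of samples.
#' @param kT Energy unit (landscapes are in kT, so usually 1).
#' @param seed RNG seed (required: no silent entropy).
#' @param method `"grid"` or `"rejection"`.
#' @param grid_n Sampling-grid resolution for the grid method.
#' @return data.frame with columns `cc1`, `cc2`.
#' @export
sample_conformations <- function(ls, n, kT = 1, seed,
                                 method = c("grid", "rejection"),
                                 grid_n = 200) {
  stopifnot(inherits(ls, "analytic_landscape"), n >= 1)
  if (missing(seed)) stop("seed must be supplied")
  method <- match.arg(method)
  set.seed(seed)
  if (method == "grid") {
    h <- 1 / grid_n
    centers <- (seq_len(grid_n) - 0.5) * h
    E <- outer(centers, centers, function(a, b) landscape_energy(ls, a, b))
    p <- exp(-E / kT)
    p <- p / sum(p)
    counts <- as.vector(stats::rmultinom(1, n, as.vector(p)))
    idx <- rep.int(seq_along(counts), counts)
    i1 <- ((idx - 1) %% grid_n) + 1
    i2 <- ((idx - 1) %/% grid_n) + 1
    out <- data.frame(cc1 = (i1 - 1) * h + stats::runif(n) * h,
                      cc2 = (i2 - 1) * h + stats::runif(n) * h)
    # shuffle so consecutive rows are not sorted by cell
    out[sample.int(n), , drop = FALSE]
  } else {
    got <- 0L; tried <- 0L
    acc1 <- numeric(n); acc2 <- numeric(n)
    while (got < n) {
      m <- max(1000L, as.integer((n - got) * 2))
      x <- stats::runif(m); y <- stats::runif(m)
      keep <- stats::runif(m) < exp(-landscape_energy(ls, x, y) / kT)
      tried <- tried + m
      k <- which(keep)
      if (length(k) > 0) {
        take <- k[seq_len(min(length(k), n - got))]
        acc1[got + seq_along(take)] <- x[take]
        acc2[got + seq_along(take)] <- y[take]
        got <- got + length(take)
      }
      if (tried >= 1e4 && (got / tried) < 1e-4)
        stop("rejection acceptance rate below 1e-4; use method = 'grid'")
    }
    data.frame(cc1 = acc1, cc2 = acc2)
  }
}

# ---- Phantom ----

#' Deformable Gaussian-blob phantom
#'
#' A 3D density on a cubic voxel grid, parameterized by two conformational
#' degrees of freedom in `[0, 1]`: `cc1` translates a satellite blob and
#' `cc2` grows/shrinks a second blob. Density is a sum of isotropic
#' Gaussians evaluated at arbitrary points, so projections can be computed
#' as exact beam-line Riemann sums; at (`cc1` = 0, `cc2` = 0) the voxelized
#' phantom is the base map.
#'
#' The default deformation amplitudes are chosen so a full sweep of either
#' coordinate produces a comparable image-space (L2) displacement; this
#' keeps the two degrees of freedom at similar scales in the embedding
#' metric, as for a molecule whose two dominant motions have comparable
#' mass-weighted amplitude.
#'
#' @param size Cubic grid side in voxels (default 32).
#' @param blobs Optional list overriding the default blob set; each element
#'   is a list with functions `center(cc1, cc2)` -> length-3 vector,
#'   `sigma(cc1, cc2)` and `amp(cc1, cc2)` -> scalars.
#' @return Object of class `phantom`.
#' @export
phantom_default <- function(size = 32, blobs = NULL) {
  stopifnot(size >= 8)
  s <- size
  if (is.null(blobs)) {
    u <- s / 32
    blobs <- list(
      core = list(center = function(cc1, cc2) c(0, 0, 0),
                  sigma = function(cc1, cc2) 4.5 * u,
                  amp = function(cc1, cc2) 1),
      mover = list(center = function(cc1, cc2)
                     c(-6 * u + 12 * u * cc1, 8 * u, 2 * u),
                   sigma = function(cc1, cc2) 2.5 * u,
                   amp = function(cc1, cc2) 1.3),
      breather = list(center = function(cc1, cc2)
                        c(2 * u, -8 * u, -5 * u),
                      sigma = function(cc1, cc2) 2.0 * u + 2.2 * u * cc2,
                      amp = function(cc1, cc2) 1.1 + 0.4 * cc2))
  }
  structure(list(size = as.integer(size), blobs = blobs),
            class = "phantom")
}

#' Evaluate phantom density at arbitrary 3D points
#'
#' @param phantom A [phantom_default()] object.
#' @param pts N x 3 matrix of coordinates (voxel units, origin at grid
#'   center).
#' @param cc1,cc2 Degree-of-freedom values in `[0, 1]`.
#' @return Numeric vector of densities (nonnegative).
#' @export
phantom_density <- function(phantom, pts, cc1, cc2) {
  stopifnot(cc1 >= 0, cc1 <= 1, cc2 >= 0, cc2 <= 1)
  dens <- numeric(nrow(pts))
  for (b in phantom$blobs) {
    ctr <- b$center(cc1, cc2)
    sg <- b$sigma(cc1, cc2)
    d2 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 +
      (pts[, 3] - ctr[3])^2
    dens <- dens + b$amp(cc1, cc2) * exp(-d2 / (2 * sg^2))
  }
  dens
}

voxel_axis <- function(size) seq_len(size) - (size + 1) / 2

#' Voxelize a phantom at given degree-of-freedom values
#'
#' @inheritParams phantom_density
#' @return A `size^3` array of densities (the base map when both
#'   coordinates are 0).
#' @export
phantom_volume <- function(phantom, cc1 = 0, cc2 = 0) {
  s <- phantom$size
  ax <- voxel_axis(s)
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  array(phantom_density(phantom, pts, cc1, cc2), dim = c(s, s, s))
}

# ---- Projection ----

# image/beam sampling points for one orientation, mapped to map frame
beam_points <- function(image_size, depth, rot, tilt, psi) {
  A <- euler_to_matrix(rot, tilt, psi)
  axi <- voxel_axis(image_size)
  axz <- voxel_axis(depth)
  q <- as.matrix(expand.grid(x = axi, y = axi, z = axz))
  q %*% A   # rows q_i mapped by t(A) %*% q_i
}

#' Project a voxel volume along an orientation
#'
#' Line-integral (beam-sum) projection of a voxel array: for every image
#' pixel the volume is sampled along the beam (image-frame z axis) at unit
#' steps and summed. At the identity orientation this reduces exactly to
#' the axis sum of the array.
#'
#' @param vol Cubic 3D array.
#' @param rot,tilt,psi ZYZ Euler angles in degrees.
#' @param image_size Output image side in pixels (default volume side).
#' @param interp `"nearest"` or `"trilinear"` volume sampling.
#' @return `image_size` x `image_size` matrix.
#' @export
project_volume <- function(vol, rot = 0, tilt = 0, psi = 0,
                           image_size = dim(vol)[1],
                           interp = c("nearest", "trilinear")) {
  interp <- match.arg(interp)
  s <- dim(vol)[1]
  stopifnot(length(unique(dim(vol))) == 1)
  if (image_size < s)
    stop("image size ", image_size,
         " smaller than phantom silhouette; need at least ", s)
  pts <- beam_points(image_size, s, rot, tilt, psi)
  idx <- pts + (s + 1) / 2   # voxel index space, 1-based
  val <- if (interp == "nearest") {
    i <- round(idx)
    ok <- i[, 1] >= 1 & i[, 1] <= s & i[, 2] >= 1 & i[, 2] <= s &
      i[, 3] >= 1 & i[, 3] <= s
    v <- numeric(nrow(idx))
    v[ok] <- vol[cbind(i[ok, 1], i[ok, 2], i[ok, 3])]
    v
  } else {
    trilinear_sample(vol, idx)
  }
  npix <- image_size^2
  matrix(rowSums(matrix(val, nrow = npix)), image_size, image_size)
}

trilinear_sample <- function(vol, idx) {
  s <- dim(vol)[1]
  v <- numeric(nrow(idx))
  f <- floor(idx)
  w <- idx - f
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- f[, 1] + dx; iy <- f[, 2] + dy; iz <- f[, 3] + dz
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
      (if (dy) w[, 2] else 1 - w[, 2]) *
      (if (dz) w[, 3] else 1 - w[, 3])
    ok <- ix >= 1 & ix <= s & iy >= 1 & iy <= s & iz >= 1 & iz <= s & wt > 0
    if (any(ok))
      v[ok] <- v[ok] + wt[ok] * vol[cbind(ix[ok], iy[ok], iz[ok])]
  }
  v
}

#' Render snapshot images for a table of ground-truth states
#'
#' Each image is the beam-line projection of the phantom deformed to that
#' snapshot's (`cc1`, `cc2`), at its orientation, plus i.i.d. Gaussian
#' noise. Projections of the continuous blob density are computed
#' analytically along the sampled beams (unit steps over the phantom
#' depth), which at the identity orientation coincides exactly with the
#' axis sum of the voxelized phantom.
#'
#' @param phantom A [phantom_default()].
#' @param states data.frame with columns `condition`, `cc1`, `cc2`, `rot`,
#'   `tilt`, `psi` (one row per snapshot).
#' @param image_size Image side in pixels (>= phantom size).
#' @param noise_sigma Gaussian noise standard deviation (0 = exact
#'   projections).
#' @param seed RNG seed for the noise realization.
#' @param pixel_size Pixel size metadata (Angstrom).
#' @return A [snapshot_stack()] carrying `states[, c("cc1","cc2")]` as
#'   ground truth.
#' @export
render_snapshots <- function(phantom, states, image_size = phantom$size,
                             noise_sigma = 0, seed = 1, pixel_size = 1.0) {
  stopifnot(inherits(phantom, "phantom"),
            all(c("condition", "cc1", "cc2", "rot", "tilt", "psi") %in%
                  names(states)))
  if (noise_sigma < 0) stop("noise sigma must be >= 0")
  s <- phantom$size
  if (image_size < s)
    stop("image size ", image_size,
         " smaller than phantom silhouette; need at least ", s)
  n <- nrow(states)
  npix <- image_size^2
  imgs <- matrix(0, npix, n)
  okey <- paste(states$rot, states$tilt, states$psi)
  for (key in unique(okey)) {
    rows <- which(okey == key)
    r1 <- rows[1]
    pts <- beam_points(image_size, s, states$rot[r1], states$tilt[r1],
                       states$psi[r1])
    for (i in rows) {
      dens <- phantom_density(phantom, pts, states$cc1[i], states$cc2[i])
      imgs[, i] <- rowSums(matrix(dens, nrow = npix))
    }
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    imgs <- imgs + stats::rnorm(length(imgs), sd = noise_sigma)
  }
  snapshot_stack(array(imgs, dim = c(image_size, image_size, n)),
                 states[, c("rot", "tilt", "psi")],
                 as.character(states$condition),
                 pixel_size = pixel_size,
                 ground_truth = states[, c("cc1", "cc2")])
}

# ---- Whole-ensemble convenience generator ----

#' Generate a full dual-condition synthetic ensemble
#'
#' Draws conformations for both conditions from a dual landscape pair,
#' assigns quasi-uniform viewing directions (Fibonacci lattice, equal
#' occupancy per direction, optional angular jitter), and renders the
#' images. These are the validation conditions used throughout the
#' package's tests: a two-degree-of-freedom system imaged over many
#' projection directions, with and without noise.
#'
#' @param pair A [define_dual_landscape()] pair.
#' @param n_per_condition Snapshots per condition.
#' @param n_directions Number of viewing directions.
#' @param phantom Phantom (default [phantom_default()]).
#' @param noise_sigma Additive Gaussian noise sd.
#' @param jitter Angular jitter (radians) applied to each snapshot's
#'   direction within its assigned direction (default 0).
#' @param seed RNG seed controlling sampling, direction assignment, jitter
#'   and noise.
#' @param image_size Image side (default phantom size).
#' @return A [snapshot_stack()] with ground truth.
#' @export
simulate_ensemble <- function(pair, n_per_condition = 2000,
                              n_directions = 50,
                              phantom = phantom_default(),
                              noise_sigma = 0, jitter = 0, seed = 1,
                              image_size = phantom$size) {
  stopifnot(inherits(pair, "landscape_pair"))
  conf_m <- sample_conformations(pair$minus, n_per_condition, seed = seed)
  conf_p <- sample_conformations(pair$plus, n_per_condition,
                                 seed = seed + 1)
  n <- 2 * n_per_condition
  dirs <- fibonacci_sphere(n_directions)
  set.seed(seed + 2)
  dir_idx <- sample(rep_len(seq_len(n_directions), n))
  d <- dirs[dir_idx, , drop = FALSE]
  if (jitter > 0) {
    d <- jitter_directions(d, jitter)
  }
  eul <- direction_to_euler(d)
  states <- data.frame(
    condition = rep(c("minus", "plus"), each = n_per_condition),
    cc1 = c(conf_m$cc1, conf_p$cc1),
    cc2 = c(conf_m$cc2, conf_p$cc2),
    rot = eul$rot, tilt = eul$tilt, psi = eul$psi)
  render_snapshots(phantom, states, image_size = image_size,
                   noise_sigma = noise_sigma, seed = seed + 3)
}

jitter_directions <- function(d, jitter) {
  n <- nrow(d)
  # small random rotation: add tangent-plane noise and renormalize
  noise <- matrix(stats::rnorm(3 * n, sd = jitter), n, 3)
  noise <- noise - d * rowSums(noise * d)
  out <- d + noise
  out / sqrt(rowSums(out^2))
}

#' Noise level giving a target signal-to-noise ratio
#'
#' Signal power is measured as the mean per-pixel variance of the
#' (noise-free) images across the ensemble; the returned sigma satisfies
#' `SNR = signal_power / sigma^2`.
#'
#' @param stack A noise-free [snapshot_stack()].
#' @param snr Target SNR (default 1).
#' @return Gaussian noise standard deviation.
#' @export
noise_sigma_for_snr <- function(stack, snr = 1) {
  d <- dim(stack$images)
  m <- matrix(stack$images, d[1] * d[2], d[3])
  mu <- rowMeans(m)
  signal_power <- mean(rowMeans((m - mu)^2))
  sqrt(signal_power / snr)
}

#' Add Gaussian noise to an existing stack
#'
#' @param stack A [snapshot_stack()].
#' @param noise_sigma Noise standard deviation.
#' @param seed RNG seed.
#' @return A new [snapshot_stack()] with noisy images.
#' @export
add_noise <- function(stack, noise_sigma, seed) {
  set.seed(seed)
  imgs <- stack$images + stats::rnorm(length(stack$images),
                                      sd = noise_sigma)
  snapshot_stack(imgs, stack$orientations, stack$condition,
                 pixel_size = stack$pixel_size,
                 ground_truth = stack$ground_truth)
}
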