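# ---- Euler angles and sphere geometry (RELION ZYZ convention) ----

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

#' Rotation matrix from RELION ZYZ Euler angles
#'
#' Returns the matrix `A = Rz(psi) %*% Ry(tilt) %*% Rz(rot)` mapping map-frame
#' coordinates to image-frame coordinates, with angles in degrees (RELION
#' `rlnAngleRot`/`rlnAngleTilt`/`rlnAnglePsi`). The beam travels along the
#' image-frame z axis, so the viewing direction in the map frame is the third
#' row of `A` and does not depend on `psi`.
#'
#' @param rot,tilt,psi Euler angles in degrees.
#' @return A 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(rot, tilt, psi) {
  rot_z(deg2rad(psi)) %*% rot_y(deg2rad(tilt)) %*% rot_z(deg2rad(rot))
}

#' Viewing direction from Euler angles
#'
#' In-plane rotation (`psi`) does not affect the direction; projection bins
#' live on the orientation sphere spanned by (`rot`, `tilt`) alone.
#'
#' @param rot,tilt Euler angles in degrees (vectorized).
#' @return An n x 3 matrix of unit vectors.
#' @export
view_direction <- function(rot, tilt) {
  r <- deg2rad(rot); t <- deg2rad(tilt)
  cbind(-sin(t) * cos(r), sin(t) * sin(r), cos(t))
}

#' Euler angles whose viewing direction is a given unit vector
#'
#' Inverse of [view_direction()]; `psi` is set to 0.
#'
#' @param dirs An n x 3 matrix of unit vectors.
#' @return A data.frame with columns `rot`, `tilt`, `psi` (degrees).
#' @export
direction_to_euler <- function(dirs) {
  dirs <- matrix(dirs, ncol = 3)
  z <- pmin(1, pmax(-1, dirs[, 3]))
  tilt <- acos(z)
  st <- sin(tilt)
  rot <- ifelse(st < 1e-12, 0, atan2(dirs[, 2], -dirs[, 1]))
  data.frame(rot = rad2deg(rot), tilt = rad2deg(tilt), psi = 0)
}

#' Quasi-uniform unit vectors on the sphere (Fibonacci lattice)
#'
#' @param n Number of points.
#' @return An n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# ---- Snapshot stacks ----

#' Construct a snapshot stack
#'
#' Container for an ensemble of aligned, centered particle images with
#' per-image orientations and a condition label (ligand-free `"minus"` or
#' ligand-bound `"plus"`), optionally carrying ground-truth conformational
#' coordinates from the synthetic generator.
#'
#' @param images Array of dimension H x W x n (square images required by the
#'   MRC writer used here).
#' @param orientations data.frame with columns `rot`, `tilt`, `psi` (ZYZ
#'   Euler angles, degrees).
#' @param condition Character/factor of length n with values in
#'   `c("minus", "plus")`.
#' @param pixel_size Pixel size in Angstrom (metadata only).
#' @param ground_truth Optional data.frame with columns `cc1`, `cc2` in
#'   `[0, 1]`.
#' @return An object of class `snapshot_stack`.
#' @export
snapshot_stack <- function(images, orientations, condition,
                           pixel_size = 1.0, ground_truth = NULL) {
  stopifnot(is.array(images), length(dim(images)) == 3)
  n <- dim(images)[3]
  stopifnot(n >= 1)
  stopifnot(is.data.frame(orientations),
            all(c("rot", "tilt", "psi") %in% names(orientations)),
            nrow(orientations) == n)
  if (!all(is.finite(as.matrix(orientations[, c("rot", "tilt", "psi")]))))
    stop("non-finite Euler angles in orientations")
  condition <- as.character(condition)
  if (length(condition) == 1) condition <- rep(condition, n)
  stopifnot(length(condition) == n)
  if (!all(condition %in% c("minus", "plus")))
    stop("condition labels must be 'minus' or 'plus'")
  if (!is.null(ground_truth)) {
    stopifnot(is.data.frame(ground_truth), nrow(ground_truth) == n,
              all(c("cc1", "cc2") %in% names(ground_truth)))
  }
  structure(list(images = images,
                 orientations = orientations,
                 condition = condition,
                 pixel_size = pixel_size,
                 ground_truth = ground_truth),
            class = "snapshot_stack")
}

#' @export
print.snapshot_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("snapshot_stack: %d images of %dx%d px (%.3f A/px)\n",
              d[3], d[1], d[2], x$pixel_size))
  cat(sprintf("  conditions: %s\n",
              paste(sprintf("%s=%d", names(table(x$condition)),
                            table(x$condition)), collapse = ", ")))
  if (!is.null(x$ground_truth)) cat("  ground truth: present\n")
  invisible(x)
}

#' @export
length.snapshot_stack <- function(x) dim(x$images)[3]

# ---- MRC/MRCS I/O (mode 2, little-endian) ----

#' Write a 3D array as an MRC/MRCS file (mode 2 float)
#'
#' @param vol Array (2D or 3D); for image stacks the third dimension indexes
#'   images (sections).
#' @param path Output file path.
#' @param pixel_size Voxel/pixel size in Angstrom, stored in the cell header.
#' @export
write_mrc <- function(vol, path, pixel_size = 1.0) {
  if (length(dim(vol)) == 2) dim(vol) <- c(dim(vol), 1L)
  d <- dim(vol)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                       # NX NY NZ
  wi(2)                       # MODE 2 = float32
  wi(c(0, 0, 0))              # NXSTART..
  wi(d)                       # MX MY MZ
  wf(d * pixel_size)          # CELLA
  wf(c(90, 90, 90))           # CELLB
  wi(c(1, 2, 3))              # MAPC MAPR MAPS
  wf(c(min(vol), max(vol), mean(vol)))  # DMIN DMAX DMEAN
  wi(c(0, 0))                 # ISPG NSYMBT
  wi(rep(0L, 25))             # EXTRA (words 26-50)
  wi(c(0, 0, 0))              # ORIGIN (words 50-52)
  writeBin(charToRaw("MAP "), con)              # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machine stamp (LE)
  wf(stats::sd(vol))          # RMS
  wi(0)                       # NLABL
  writeBin(raw(800), con)     # labels
  wf(as.numeric(vol))         # data, x fastest
  invisible(path)
}

#' Read an MRC/MRCS file (mode 2)
#'
#' @param path File path.
#' @return A list with `data` (array NX x NY x NZ) and `pixel_size`.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2L)
    stop("unsupported MRC mode ", mode, " (only mode 2 float is supported)")
  ri(3)                 # nstart
  mx <- ri(3)
  cella <- rf(3)
  rf(3); ri(3); rf(3)   # cellb, map order, dmin/max/mean
  ri(1)                 # ispg
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  data <- rf(prod(d))
  if (length(data) != prod(d)) stop("truncated MRC data in ", path)
  dim(data) <- d
  px <- if (mx[1] > 0 && cella[1] > 0) cella[1] / mx[1] else 1.0
  list(data = data, pixel_size = px)
}

# ---- STAR I/O (RELION dialect) ----

star_cols <- c(rot = "_rlnAngleRot", tilt = "_rlnAngleTilt",
               psi = "_rlnAnglePsi")

#' Write a data.frame as a single-block RELION STAR file
#'
#' @param df data.frame; column names must already be STAR tags
#'   (leading underscore).
#' @param path Output path.
#' @param block Data block name.
#' @export
write_star <- function(df, path, block = "particles") {
  lines <- c(paste0("data_", block), "", "loop_",
             sprintf("%s #%d", names(df), seq_along(df)))
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) format(col, digits = 10, trim = TRUE,
                                scientific = FALSE)
    else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1) fmt <- matrix(fmt, nrow = 1)
  rows <- apply(fmt, 1, paste, collapse = "  ")
  writeLines(c(lines, rows, ""), path)
  invisible(path)
}

#' Read a single-block RELION STAR file
#'
#' @param path File path.
#' @return data.frame with STAR tags as column names; numeric columns are
#'   converted.
#' @export
read_star <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  loop <- which(lines == "loop_")
  if (length(loop) == 0) stop("no loop_ block in STAR file ", path)
  i <- loop[1] + 1
  tags <- character(0)
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    tags <- c(tags, sub("\\s+#\\d+$", "", lines[i]))
    i <- i + 1
  }
  body <- lines[i:length(lines)]
  body <- body[nzchar(body) & !startsWith(body, "data_")]
  if (length(body) == 0) stop("empty STAR table in ", path)
  fields <- strsplit(body, "\\s+")
  nf <- lengths(fields)
  if (any(nf != length(tags)))
    stop("STAR row with ", nf[which(nf != length(tags))[1]],
         " fields, expected ", length(tags))
  m <- do.call(rbind, fields)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- tags
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(v)) df[[j]] <- v
  }
  df
}

#' Write a snapshot stack as MRCS + STAR
#'
#' Writes `<path>` as an MRCS image stack (mode 2 float) and a sibling STAR
#' table (same path, `.star` extension) with RELION Euler-angle columns,
#' condition labels and, when present, ground-truth coordinates in
#' namespaced custom columns.
#'
#' @param stack A [snapshot_stack()].
#' @param path Output `.mrcs` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "snapshot_stack"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  write_mrc(stack$images, path, pixel_size = stack$pixel_size)
  n <- length(stack)
  df <- data.frame(check.names = FALSE,
    `_rlnImageName` = sprintf("%06d@%s", seq_len(n), basename(path)),
    `_rlnAngleRot` = stack$orientations$rot,
    `_rlnAngleTilt` = stack$orientations$tilt,
    `_rlnAnglePsi` = stack$orientations$psi,
    `_cryofelCondition` = stack$condition)
  if (!is.null(stack$ground_truth)) {
    df$`_cryofelCC1` <- stack$ground_truth$cc1
    df$`_cryofelCC2` <- stack$ground_truth$cc2
  }
  write_star(df, star_path(path))
  invisible(path)
}

star_path <- function(path) sub("\\.[^.]+$", ".star", path)

#' Read a snapshot stack from MRCS + STAR
#'
#' @param path `.mrcs` path written by [write_stack()] (the sibling `.star`
#'   table is read alongside).
#' @return A [snapshot_stack()].
#' @export
read_stack <- function(path) {
  mrc <- read_mrc(path)
  if (dim(mrc$data)[1] != dim(mrc$data)[2])
    stop("non-square images in ", path)
  df <- read_star(star_path(path))
  for (tag in star_cols) {
    if (!tag %in% names(df))
      stop("STAR table is missing required column ", tag)
  }
  cond_tag <- "_cryofelCondition"
  condition <- if (cond_tag %in% names(df)) as.character(df[[cond_tag]])
               else rep("minus", nrow(df))
  gt <- NULL
  if (all(c("_cryofelCC1", "_cryofelCC2") %in% names(df))) {
    gt <- data.frame(cc1 = df$`_cryofelCC1`, cc2 = df$`_cryofelCC2`)
  }
  snapshot_stack(mrc$data,
                 data.frame(rot = df$`_rlnAngleRot`,
                            tilt = df$`_rlnAngleTilt`,
                            psi = df$`_rlnAnglePsi`),
                 condition, pixel_size = mrc$pixel_size, ground_truth = gt)
}

# ---- Projection-direction binning ----

#' Shannon-angle aperture
#'
#' The Shannon angle is the spatial resolution divided by the particle
#' diameter; projection-direction bins subtend a semi-cone of a small
#' multiple of it (conventionally two).
#'
#' @param resolution Spatial resolution (same length unit as `diameter`).
#' @param diameter Particle diameter.
#' @param multiplier Number of Shannon angles in the semi-cone (default 2).
#' @return Aperture in radians.
#' @export
shannon_aperture <- function(resolution, diameter, multiplier = 2) {
  if (resolution <= 0 || diameter <= 0 || multiplier <= 0)
    stop("resolution, diameter and multiplier must all be positive")
  multiplier * (resolution / diameter)
}

#' Number of tessellation centers for a given aperture
#'
#' Chooses the count of quasi-uniform bin centers so that neighbouring
#' centers are roughly `2 * aperture` apart (each cap of semi-angle
#' `2 * aperture` tiles the sphere).
#'
#' @param aperture Semi-cone aperture in radians.
#' @return Integer number of centers.
#' @export
aperture_bin_count <- function(aperture) {
  s <- min(2 * aperture, pi)
  max(1L, as.integer(round(2 / (1 - cos(s)))))
}

#' Bin snapshots into projection directions
#'
#' Bin centers come from a deterministic Fibonacci tessellation of the full
#' sphere with angular spacing of roughly twice the aperture; each snapshot
#' is assigned to the nearest center (ties to the lowest bin id). In-plane
#' rotation (`psi`) is ignored: bins live on the spherical shell of viewing
#' directions. Bins with fewer than `min_members` snapshots are flagged
#' (kept for occupancy counts, excluded from embedding).
#'
#' @param stack A [snapshot_stack()].
#' @param aperture Semi-cone aperture in radians, in `(0, pi]`.
#' @param min_members Minimum occupancy before a bin is flagged.
#' @return An object of class `projection_bins`: list of bins, each with
#'   `id`, `center`, `aperture`, `members` (snapshot indices), `flagged`.
#' @export
bin_orientations <- function(stack, aperture, min_members = 20) {
  stopifnot(inherits(stack, "snapshot_stack"))
  if (!is.finite(aperture) || aperture <= 0 || aperture > pi)
    stop("aperture must be in (0, pi]")
  dirs <- view_direction(stack$orientations$rot, stack$orientations$tilt)
  m <- aperture_bin_count(aperture)
  centers <- fibonacci_sphere(m)
  # nearest center by maximal dot product; which.max takes the lowest index
  dots <- dirs %*% t(centers)
  assign <- apply(dots, 1, which.max)
  ids <- sort(unique(assign))
  bins <- lapply(ids, function(id) {
    members <- which(assign == id)
    list(id = id, center = centers[id, ], aperture = aperture,
         members = members, flagged = length(members) < min_members)
  })
  structure(list(bins = bins, n_centers = m, aperture = aperture,
                 assignment = assign),
            class = "projection_bins")
}

#' @export
print.projection_bins <- function(x, ...) {
  occ <- vapply(x$bins, function(b) length(b$members), integer(1))
  cat(sprintf(
    "projection_bins: %d occupied of %d centers (aperture %.4f rad)\n",
    length(x$bins), x$n_centers, x$aperture))
  cat(sprintf("  occupancy: min %d / median %d / max %d; %d flagged\n",
              min(occ), as.integer(stats::median(occ)), max(occ),
              sum(vapply(x$bins, `[[`, logical(1), "flagged"))))
  invisible(x)
}
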