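# Per-projection-direction diffusion-map embedding and the assembly of
# global conformational coordinates: coordinate selection above the noise
# plateau, propagation of coordinate identity/sign across neighbouring
# directions, and rank-based metric homogenization.

# ---- Diffusion map ----

pairwise_sqdist <- function(X) {
  # rows = observations
  g <- rowSums(X^2)
  d2 <- outer(g, g, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}

#' Kernel bandwidth from pairwise distances
#'
#' Default rule: the median of the nonzero pairwise squared distances. An
#' alternative log-log kernel-sum sweep picks the bandwidth at the point of
#' steepest slope of `log sum_ij exp(-d2/(2 eps))` versus `log eps`, the
#' region where the kernel resolves the data's intrinsic scale.
#'
#' @param d2 Matrix of pairwise squared distances.
#' @param method `"median"` or `"sweep"`.
#' @return Bandwidth epsilon (squared-distance units).
#' @export
estimate_bandwidth <- function(d2, method = c("median", "sweep")) {
  method <- match.arg(method)
  nz <- d2[upper.tri(d2)]
  nz <- nz[nz > 0]
  if (length(nz) == 0) stop("all pairwise distances are zero")
  if (method == "median") return(stats::median(nz))
  eps_grid <- exp(seq(log(min(nz)), log(max(nz)) + log(10),
                      length.out = 40))
  logsum <- vapply(eps_grid, function(e) log(sum(exp(-d2 / (2 * e)))),
                   numeric(1))
  slope <- diff(logsum) / diff(log(eps_grid))
  eps_grid[which.max(slope)]
}

#' Diffusion-map embedding of one projection direction
#'
#' Builds a Gaussian kernel `exp(-d2 / (2 eps))` on pairwise squared
#' Euclidean image distances, normalizes it into a Markov operator
#' (symmetric normalization, so eigenvalues are real), and returns the
#' leading eigenpairs. The top eigenvalue is 1 with a constant
#' eigenvector; subsequent eigenvectors are the candidate conformational
#' coordinates of the direction. Eigenvector sign is fixed by making the
#' first component of magnitude above 1e-12 positive.
#'
#' @param images Either an `H x W x m` array or an `npix x m` matrix of
#'   member images.
#' @param eps Kernel bandwidth (default: [estimate_bandwidth()] median
#'   rule).
#' @param k Number of eigenpairs to return (including the trivial first).
#' @param bin_id Optional identifier carried through.
#' @return Object of class `bin_embedding` with `eigenvalues` (length k,
#'   descending), `vectors` (m x k), `epsilon`, `bin_id`, `n_members`.
#' @export
diffusion_embed <- function(images, eps = NULL, k = 10, bin_id = NA) {
  X <- if (is.matrix(images)) t(images) else {
    d <- dim(images)
    t(matrix(images, d[1] * d[2], d[3]))
  }
  m <- nrow(X)
  if (m < k + 1)
    stop("bin has ", m, " members; need at least k + 1 = ", k + 1)
  d2 <- pairwise_sqdist(X)
  if (is.null(eps)) eps <- estimate_bandwidth(d2)
  if (eps <= 0) stop("bandwidth must be positive")
  K <- exp(-d2 / (2 * eps))
  if (max(K[upper.tri(K)]) < 1e-12)
    stop("degenerate kernel: all off-diagonal weights ~0; increase eps")
  D <- rowSums(K)
  Dn <- 1 / sqrt(D)
  S <- K * tcrossprod(Dn)           # D^-1/2 K D^-1/2
  es <- eigen(S, symmetric = TRUE)
  lam <- es$values[seq_len(k)]
  psi <- es$vectors[, seq_len(k), drop = FALSE] * Dn   # right eigenvectors
  for (j in seq_len(k)) {
    nz <- which(abs(psi[, j]) > 1e-12)
    if (length(nz) > 0 && psi[nz[1], j] < 0) psi[, j] <- -psi[, j]
  }
  structure(list(bin_id = bin_id, epsilon = eps, eigenvalues = lam,
                 vectors = psi, n_members = m, n_retained = NA_integer_),
            class = "bin_embedding")
}

#' @export
print.bin_embedding <- function(x, ...) {
  cat(sprintf("bin_embedding (bin %s): %d members, eps = %.4g\n",
              as.character(x$bin_id), x$n_members, x$epsilon))
  cat("  eigenvalues:",
      paste(sprintf("%.4f", utils::head(x$eigenvalues, 8)),
            collapse = " "), "\n")
  invisible(x)
}

#' Embed every usable projection bin
#'
#' Runs [diffusion_embed()] on each non-flagged bin of a tessellation.
#'
#' @param stack A [snapshot_stack()].
#' @param bins A [bin_orientations()] result.
#' @param k Eigenpairs per bin.
#' @param eps Optional fixed bandwidth (default per-bin median rule).
#' @return List parallel to `bins$bins`; flagged bins give `NULL`.
#' @export
embed_bins <- function(stack, bins, k = 10, eps = NULL) {
  d <- dim(stack$images)
  M <- matrix(stack$images, d[1] * d[2], d[3])
  lapply(bins$bins, function(b) {
    if (b$flagged || length(b$members) < k + 1) return(NULL)
    emb <- diffusion_embed(M[, b$members, drop = FALSE], eps = eps,
                           k = k, bin_id = b$id)
    emb$members <- b$members
    emb
  })
}

#' Persist / restore per-bin embeddings
#'
#' Embeddings are stored in a single container file keyed by bin id.
#'
#' @param embeddings List from [embed_bins()].
#' @param path File path.
#' @return `path` (save) or the embeddings list (load).
#' @export
save_embeddings <- function(embeddings, path) {
  keyed <- embeddings[!vapply(embeddings, is.null, logical(1))]
  names(keyed) <- vapply(keyed, function(e) as.character(e$bin_id),
                         character(1))
  saveRDS(keyed, path)
  invisible(path)
}

#' @rdname save_embeddings
#' @export
load_embeddings <- function(path) readRDS(path)

#' Append pooled coordinates to a STAR table
#'
#' Adds the global conformational coordinates as namespaced custom
#' columns (`_cryofelPooledCC1`, `_cryofelPooledCC2`) to an existing
#' particle STAR file.
#'
#' @param star_path Path to a STAR file with one row per snapshot.
#' @param coords A `global_coordinates` object (or its `coords` frame).
#' @return `star_path`, invisibly.
#' @export
append_coordinates_star <- function(star_path, coords) {
  if (inherits(coords, "global_coordinates")) coords <- coords$coords
  df <- read_star(star_path)
  if (nrow(df) != nrow(coords))
    stop("STAR table has ", nrow(df), " rows but coordinates have ",
         nrow(coords))
  df$`_cryofelPooledCC1` <- coords$cc1
  df$`_cryofelPooledCC2` <- coords$cc2
  write_star(df, star_path)
}

# ---- Coordinate selection above the noise plateau ----

#' Count conformational coordinates above the noise plateau
#'
#' For each bin's eigenvalue spectrum (leading trivial eigenvalue
#' included), the plateau level is the median of the trailing half of the
#' non-trivial eigenvalues; coordinate k is retained when
#' `lambda_k > plateau * (1 + tau)`. The global retained count is the
#' median of the per-bin counts, capped at `cap` (the landscape analysis
#' uses only the two strongest coordinates).
#'
#' @param spectra List of numeric eigenvalue vectors (descending, first
#'   entry the trivial eigenvalue 1).
#' @param tau Relative margin above the plateau (default 0.5).
#' @param cap Maximum global retained count (default 2).
#' @return List with `per_bin` (integer counts), `indices` (list of
#'   retained coordinate indices per bin), `plateau` (per-bin levels),
#'   `retained` (global count).
#' @export
coordinates_above_noise <- function(spectra, tau = 0.5, cap = 2) {
  if (!is.list(spectra)) spectra <- list(spectra)
  res <- lapply(spectra, function(sp) {
    lam <- sp[-1]
    K <- length(lam)
    if (K < 8)
      stop("need at least 8 eigenvalues beyond the trivial one, got ", K)
    plateau <- stats::median(lam[(floor(K / 2) + 1):K])
    keep <- which(lam > plateau * (1 + tau))
    list(count = length(keep), indices = keep, plateau = plateau)
  })
  per_bin <- vapply(res, `[[`, numeric(1), "count")
  list(per_bin = as.integer(per_bin),
       indices = lapply(res, `[[`, "indices"),
       plateau = vapply(res, `[[`, numeric(1), "plateau"),
       retained = min(cap, as.integer(floor(stats::median(per_bin) + 0.5))))
}

# ---- Coordinate propagation across projection directions ----

#' Rotate a square image in-plane
#'
#' Bilinear resampling about the image center; samples falling outside
#' get 0.
#'
#' @param img Square matrix.
#' @param theta Rotation angle in degrees.
#' @return Rotated matrix of the same size.
#' @export
rotate_image <- function(img, theta) {
  if (theta %% 360 == 0) return(img)
  W <- nrow(img)
  ctr <- (W + 1) / 2
  th <- theta * pi / 180
  g <- seq_len(W) - ctr
  X <- matrix(g, W, W); Y <- matrix(g, W, W, byrow = TRUE)
  xs <- cos(th) * X - sin(th) * Y + ctr
  ys <- sin(th) * X + cos(th) * Y + ctr
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  out <- matrix(0, W, W)
  for (dx in 0:1) for (dy in 0:1) {
    xi <- x0 + dx; yi <- y0 + dy
    ok <- xi >= 1 & xi <= W & yi >= 1 & yi <= W
    wt <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy)
    out[ok] <- out[ok] + wt[ok] * img[cbind(xi[ok], yi[ok])]
  }
  out
}

block_average <- function(img, f) {
  if (f <= 1) return(img)
  W <- nrow(img); H <- ncol(img)
  bw <- W %/% f; bh <- H %/% f
  img <- img[seq_len(bw * f), seq_len(bh * f), drop = FALSE]
  g1 <- rep(seq_len(bw), each = f)
  g2 <- rep(seq_len(bh), each = f)
  t(rowsum(t(rowsum(img, g1)), g2)) / f^2
}

# windowed mean images of a bin, ordered by one coordinate
window_means <- function(M, members, coord, n_windows) {
  ord <- members[order(coord)]
  m <- length(ord)
  win <- cut(seq_len(m), breaks = n_windows, labels = FALSE)
  vapply(seq_len(n_windows), function(w) {
    cols <- ord[win == w]
    if (length(cols) == 1) M[, cols] else rowMeans(M[, cols, drop = FALSE])
  }, numeric(nrow(M)))
}

# flatten window means into a comparison trajectory: optional in-plane
# rotation (to undo the camera-frame offset between bins), per-pixel
# centering across windows (removes the static average), and a low-pass
# block average so the pattern tolerates the small viewing-angle
# difference between neighbouring bins
flat_trajectory <- function(wm, side, lowpass, theta = 0) {
  if (theta %% 360 != 0)
    wm <- apply(wm, 2, function(col)
      as.vector(rotate_image(matrix(col, side, side), theta)))
  wm <- wm - rowMeans(wm)
  out <- apply(wm, 2, function(col)
    as.vector(block_average(matrix(col, side, side), lowpass)))
  as.vector(out)
}

#' Propagate coordinate identity and sign across projection directions
#'
#' Diffusion-map coordinates are defined per bin only up to order and
#' sign, and a strong coordinate's spectral harmonic can displace a weaker
#' genuine coordinate in the eigenvalue ranking. Starting from the
#' most-populated bin, a maximum-correlation spanning tree over the bin
#' adjacency graph (k-nearest neighbours of bin centers on the orientation
#' sphere) is traversed; on each edge, every injective assignment of
#' `n_candidates` child coordinates to the parent's `n_coords` aligned
#' coordinates, with either sign, is scored by the correlation of
#' coordinate-ordered windowed mean-image trajectories, and the assignment
#' with the highest total absolute correlation is applied. Before
#' trajectories are compared, the two bins' camera frames are registered
#' by maximizing the static mean-image correlation over in-plane rotation
#' (the image-plane basis is not continuous across the orientation
#' sphere). Edges whose best absolute correlation falls below `min_corr`
#' are flagged ambiguous (their bins are excluded from pooling);
#' processing continues.
#'
#' @param embeddings List from [embed_bins()].
#' @param bins The [bin_orientations()] tessellation.
#' @param stack The [snapshot_stack()] (images are needed for scoring).
#' @param n_coords Number of global coordinates to align (default 2).
#' @param n_candidates Leading non-trivial eigenvectors considered as
#'   candidates in each bin (default 4).
#' @param n_windows Windows per trajectory (default 8).
#' @param min_corr Ambiguity threshold on the edge score (default 0.2).
#' @param knn Neighbour count for the adjacency graph (default 6).
#' @param lowpass Block-averaging factor applied to window mean images
#'   before correlation (default 4); tolerates the viewing-angle offset
#'   between neighbouring bins.
#' @return Object of class `coord_map`: per-bin `perm` (selected
#'   eigenvector indices), `sign`, `score`, `ambiguous` flags, and the
#'   spanning-tree edge list with scores.
#' @export
propagate_coordinates <- function(embeddings, bins, stack, n_coords = 2,
                                  n_candidates = 4, n_windows = 8,
                                  min_corr = 0.2, knn = 6, lowpass = 4) {
  usable <- which(!vapply(embeddings, is.null, logical(1)))
  nb <- length(bins$bins)
  maps <- vector("list", nb)
  ambiguous <- rep(FALSE, nb)
  scores <- rep(NA_real_, nb)
  edges <- NULL
  if (length(usable) == 0) stop("no usable bins to propagate over")
  if (length(usable) == 1) {
    maps[[usable]] <- list(perm = seq_len(n_coords),
                           sign = rep(1, n_coords))
    return(structure(list(maps = maps, ambiguous = ambiguous,
                          scores = scores, edges = edges,
                          usable = usable),
                     class = "coord_map"))
  }
  n_candidates <- min(n_candidates,
                      min(vapply(embeddings[usable], function(e)
                        length(e$eigenvalues), integer(1))) - 1)
  centers <- t(vapply(bins$bins[usable], `[[`, numeric(3), "center"))
  d <- dim(stack$images)
  side <- d[1]
  M <- matrix(stack$images, d[1] * d[2], d[3])
  nu <- length(usable)

  # how much of candidate j is a (possibly non-monotone) function of a
  # stronger candidate i: R^2 of a piecewise-constant regression on
  # deciles of psi_i; spectral harmonics of a strong coordinate score
  # high and are penalized as coordinate candidates
  harmonic_r2 <- function(vecs) {
    nc <- ncol(vecs)
    m <- nrow(vecs)
    nq <- max(2, min(10, floor(m / 10)))
    pen <- numeric(nc)
    for (j in seq_len(nc)) {
      if (j == 1) next
      r2 <- 0
      for (i in seq_len(j - 1)) {
        g <- cut(rank(vecs[, i], ties.method = "first"), nq,
                 labels = FALSE)
        res <- vecs[, j] - stats::ave(vecs[, j], g)
        r2 <- max(r2, 1 - stats::var(res) / stats::var(vecs[, j]))
      }
      pen[j] <- r2
    }
    pen
  }

  # per-bin features: static mean image, per-candidate window means,
  # harmonic penalties
  binfeat <- lapply(seq_len(nu), function(i) {
    emb <- embeddings[[usable[i]]]
    static <- matrix(rowMeans(M[, emb$members, drop = FALSE]), side, side)
    wm <- lapply(seq_len(n_candidates), function(j)
      window_means(M, emb$members, emb$vectors[, 1 + j], n_windows))
    traj0 <- lapply(wm, flat_trajectory, side = side, lowpass = lowpass)
    pen <- harmonic_r2(emb$vectors[, 1 + seq_len(n_candidates),
                                   drop = FALSE])
    list(static = static, wm = wm, traj0 = traj0, pen = pen)
  })

  # in-plane frame registration per edge, then a first-pass 2x2 score on
  # the leading candidates to weight the spanning tree
  theta_grid <- seq(0, 355, by = 5)
  dots <- tcrossprod(centers)
  kk <- min(knn, nu - 1)
  el <- unique(do.call(rbind, lapply(seq_len(nu), function(i) {
    nbrs <- setdiff(order(dots[i, ], decreasing = TRUE), i)[seq_len(kk)]
    cbind(pmin(i, nbrs), pmax(i, nbrs))
  })))
  # per edge: in-plane registration, then the full candidate-candidate
  # correlation matrix (rows: bin a's candidates, cols: bin b's
  # rotation-registered candidates); the edge weight for the spanning
  # tree is the best injective two-coordinate match in that matrix
  edge_theta <- numeric(nrow(el))
  w <- numeric(nrow(el))
  edge_C <- vector("list", nrow(el))
  for (e in seq_len(nrow(el))) {
    a <- el[e, 1]; b <- el[e, 2]
    Sa <- as.vector(binfeat[[a]]$static)
    rc <- vapply(theta_grid, function(th)
      stats::cor(Sa, as.vector(rotate_image(binfeat[[b]]$static, th))),
      numeric(1))
    edge_theta[e] <- theta_grid[which.max(rc)]
    tb <- lapply(binfeat[[b]]$wm, flat_trajectory, side = side,
                 lowpass = lowpass, theta = edge_theta[e])
    C <- matrix(0, n_candidates, n_candidates)
    for (i in seq_len(n_candidates)) for (j in seq_len(n_candidates))
      C[i, j] <- stats::cor(binfeat[[a]]$traj0[[i]], tb[[j]])
    C[!is.finite(C)] <- 0
    edge_C[[e]] <- C
    # greedy: strongest entry, then strongest in a different row and col
    A <- abs(C)
    m1 <- which(A == max(A), arr.ind = TRUE)[1, ]
    A2 <- A[-m1[1], -m1[2], drop = FALSE]
    w[e] <- if (length(A2) > 0) max(A2) else max(A)
  }
  # incident edges per vertex, with orientation (C or t(C))
  inc <- vector("list", nu)
  for (e in seq_len(nrow(el))) {
    a <- el[e, 1]; b <- el[e, 2]
    inc[[a]] <- c(inc[[a]], list(list(other = b, C = edge_C[[e]])))
    inc[[b]] <- c(inc[[b]], list(list(other = a, C = t(edge_C[[e]]))))
  }

  # injective assignments of candidates onto the coordinate slots
  combs <- utils::combn(n_candidates, n_coords, simplify = FALSE)
  assigns <- list()
  for (cb in combs) {
    assigns <- c(assigns, list(cb))
    if (n_coords == 2 && cb[1] != cb[2]) assigns <- c(assigns,
                                                      list(rev(cb)))
  }

  # best assignment for vertex v given its currently-assigned neighbours:
  # per slot k the neighbour votes S_k(j) = sum_u sign_u[k] *
  # C_uv[perm_u[k], j]; a sign flip reverses the window order, which for
  # a progression-like trajectory is approximately a negation
  best_assignment <- function(v, mp) {
    S <- matrix(0, n_coords, n_candidates)
    nn <- 0
    for (ed in inc[[v]]) {
      mu <- mp[[ed$other]]
      if (is.null(mu)) next
      nn <- nn + 1
      for (k in seq_len(n_coords))
        S[k, ] <- S[k, ] + mu$sign[k] * ed$C[mu$perm[k], ]
    }
    if (nn == 0) return(NULL)
    Sp <- sweep(S, 2, 1 - binfeat[[v]]$pen, `*`)
    tot <- vapply(assigns, function(aa)
      sum(abs(Sp[cbind(seq_len(n_coords), aa)])), numeric(1))
    best <- assigns[[which.max(tot)]]
    sv <- S[cbind(seq_len(n_coords), best)]
    sg <- sign(sv); sg[sg == 0] <- 1
    list(perm = best, sign = sg, score = min(abs(sv)) / nn)
  }

  # init: maximum-score spanning tree from the most-populated bin
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  mst <- igraph::mst(g, weights = -w)
  occ <- vapply(bins$bins[usable], function(b) length(b$members),
                integer(1))
  root <- which.max(occ)
  mp <- vector("list", nu)
  roots <- integer(0)
  for (comp in igraph::groups(igraph::components(mst))) {
    comp <- as.integer(comp)
    r <- if (root %in% comp) root else comp[which.max(occ[comp])]
    roots <- c(roots, r)
    mp[[r]] <- list(perm = seq_len(n_coords), sign = rep(1, n_coords),
                    score = NA_real_)
    bf <- igraph::bfs(mst, root = r, unreachable = FALSE, father = TRUE)
    ord <- as.integer(bf$order)
    ord <- ord[!is.na(ord)]
    parent <- as.integer(bf$father)
    for (v in ord) {
      if (v == r) next
      mp[[v]] <- best_assignment(v, mp)
      edges <- rbind(edges, c(usable[parent[v]], usable[v],
                              mp[[v]]$score))
    }
  }
  # refinement sweeps: revisit every non-root bin against all its
  # neighbours until assignments stabilize
  sweep_order <- setdiff(order(occ, decreasing = TRUE), roots)
  for (it in 1:5) {
    changed <- FALSE
    for (v in sweep_order) {
      new <- best_assignment(v, mp)
      if (is.null(new)) next
      if (is.null(mp[[v]]) || !identical(new$perm, mp[[v]]$perm) ||
          !identical(new$sign, mp[[v]]$sign)) changed <- TRUE
      mp[[v]] <- new
    }
    if (!changed) break
  }

  # global sign synchronization per slot: local sign votes can freeze
  # into internally-consistent but mutually-opposed domains; the leading
  # eigenvector of the signed edge-consistency matrix recovers the global
  # two-colouring (Z2 synchronization), which is robust to such domains
  for (k in seq_len(n_coords)) {
    A <- matrix(0, nu, nu)
    for (e in seq_len(nrow(el))) {
      a <- el[e, 1]; b <- el[e, 2]
      if (is.null(mp[[a]]) || is.null(mp[[b]])) next
      val <- edge_C[[e]][mp[[a]]$perm[k], mp[[b]]$perm[k]]
      A[a, b] <- A[b, a] <- val
    }
    x <- eigen(A, symmetric = TRUE)$vectors[, 1]
    anchor <- roots[1]
    if (x[anchor] < 0) x <- -x
    for (v in seq_len(nu)) {
      if (is.null(mp[[v]])) next
      mp[[v]]$sign[k] <- if (x[v] >= 0) 1 else -1
    }
  }

  # final consistency scores under the synchronized assignment
  for (v in seq_len(nu)) {
    if (is.null(mp[[v]])) next
    S <- numeric(n_coords)
    nn <- 0
    for (ed in inc[[v]]) {
      mu <- mp[[ed$other]]
      if (is.null(mu)) next
      nn <- nn + 1
      for (k in seq_len(n_coords))
        S[k] <- S[k] + mu$sign[k] * mp[[v]]$sign[k] *
          ed$C[mu$perm[k], mp[[v]]$perm[k]]
    }
    mp[[v]]$score <- if (nn > 0) min(S) / nn else NA_real_
  }

  for (v in seq_len(nu)) {
    if (is.null(mp[[v]])) next
    maps[[usable[v]]] <- mp[[v]][c("perm", "sign")]
    scores[usable[v]] <- mp[[v]]$score
    ambiguous[usable[v]] <- !is.na(mp[[v]]$score) &&
      mp[[v]]$score < min_corr
  }
  structure(list(maps = maps, ambiguous = ambiguous, scores = scores,
                 edges = edges, usable = usable),
            class = "coord_map")
}

# ---- Metric homogenization and pooling ----

rank_unit <- function(x) {
  r <- rank(x, ties.method = "average")
  if (max(r) == min(r)) return(rep(0.5, length(x)))
  (r - min(r)) / (max(r) - min(r))
}

#' Homogenize per-bin coordinates and pool into global coordinates
#'
#' Within each non-flagged, unambiguous bin, each aligned coordinate is
#' rank-transformed to `[0, 1]` (empirical CDF; average ranks for ties;
#' all-tied collapses to 0.5), the propagation order/sign map is applied,
#' and values are pooled over bins so that every snapshot receives
#' (`cc1`, `cc2`). Snapshots in excluded bins get `NA`.
#'
#' @param embeddings List from [embed_bins()].
#' @param cmap A [propagate_coordinates()] result.
#' @param n_snapshots Total ensemble size.
#' @param n_coords Number of coordinates (default 2).
#' @return Object of class `global_coordinates`: data.frame `coords`
#'   (cc1, cc2 per snapshot) plus provenance (`bandwidths`, `n_bins_used`).
#' @export
homogenize_and_pool <- function(embeddings, cmap, n_snapshots,
                                n_coords = 2) {
  coords <- matrix(NA_real_, n_snapshots, n_coords)
  used <- 0L
  eps <- numeric(0)
  for (i in cmap$usable) {
    if (cmap$ambiguous[i]) next
    emb <- embeddings[[i]]
    map <- cmap$maps[[i]]
    if (is.null(emb) || is.null(map)) next
    al <- sweep(emb$vectors[, 1 + map$perm, drop = FALSE], 2,
                map$sign, `*`)
    for (j in seq_len(n_coords)) coords[emb$members, j] <- rank_unit(al[, j])
    used <- used + 1L
    eps <- c(eps, emb$epsilon)
  }
  df <- as.data.frame(coords)
  names(df) <- paste0("cc", seq_len(n_coords))
  structure(list(coords = df, n_bins_used = used, bandwidths = eps),
            class = "global_coordinates")
}

#' @export
print.global_coordinates <- function(x, ...) {
  ok <- stats::complete.cases(x$coords)
  cat(sprintf("global_coordinates: %d/%d snapshots from %d bins\n",
              sum(ok), nrow(x$coords), x$n_bins_used))
  invisible(x)
}

#' One-call global coordinates from a stack
#'
#' Convenience driver: bins orientations, embeds every usable bin, selects
#' the retained-coordinate count, propagates and homogenizes.
#'
#' @param stack A [snapshot_stack()].
#' @param aperture Binning aperture in radians.
#' @param k Eigenpairs per bin.
#' @param tau Noise-plateau margin.
#' @param min_members Minimum bin occupancy.
#' @return List with `coords` ([homogenize_and_pool()] result), `bins`,
#'   `embeddings`, `selection` ([coordinates_above_noise()] result),
#'   `cmap`.
#' @export
global_coordinates <- function(stack, aperture, k = 10, tau = 0.5,
                               min_members = max(20, k + 1)) {
  bins <- bin_orientations(stack, aperture, min_members = min_members)
  embeddings <- embed_bins(stack, bins, k = k)
  spectra <- lapply(embeddings[!vapply(embeddings, is.null, logical(1))],
                    `[[`, "eigenvalues")
  selection <- coordinates_above_noise(spectra, tau = tau)
  cmap <- propagate_coordinates(embeddings, bins, stack)
  coords <- homogenize_and_pool(embeddings, cmap, length(stack))
  list(coords = coords, bins = bins, embeddings = embeddings,
       selection = selection, cmap = cmap)
}
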