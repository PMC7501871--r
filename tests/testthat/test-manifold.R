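test_that("diffusion embedding of identical images gives a rank-1 spectrum", {
  imgs <- array(rep(matrix(1:16, 4, 4), 6), c(4, 4, 6))
  emb <- diffusion_embed(imgs, eps = 1, k = 5)
  expect_equal(emb$eigenvalues[1], 1, tolerance = 1e-8)
  expect_true(all(abs(emb$eigenvalues[-1]) < 1e-8))
})

test_that("embedding a dense ring recovers the circle", {
  set.seed(77)
  n <- 240
  t <- sort(runif(n, 0, 2 * pi))
  X <- cbind(cos(t), sin(t)) %*% matrix(rnorm(2 * 12), 2, 12)  # lift
  emb <- diffusion_embed(t(X), k = 5)
  r <- sqrt(emb$vectors[, 2]^2 + emb$vectors[, 3]^2)
  expect_lt(sd(r) / mean(r), 0.05)
})

test_that("one-bin embedding tracks a single degree of freedom monotonically", {
  ph <- phantom_default()
  set.seed(78)
  cc1 <- runif(200)
  st <- render_snapshots(ph, data.frame(condition = "minus", cc1 = cc1,
                                        cc2 = 0.5, rot = 40, tilt = 70,
                                        psi = 0))
  emb <- diffusion_embed(st$images, k = 10)
  expect_gt(abs(cor(emb$vectors[, 2], cc1, method = "spearman")), 0.99)
  expect_error(diffusion_embed(st$images[, , 1:5], k = 10), "k \\+ 1")
})

test_that("bandwidth estimation uses nonzero median and matches brute force", {
  d2 <- matrix(c(0, 4, 4, 0), 2, 2)
  expect_equal(estimate_bandwidth(d2), 4)
  # duplicated points: zeros ignored
  d2b <- matrix(0, 3, 3); d2b[1, 3] <- d2b[3, 1] <- 2
  expect_equal(estimate_bandwidth(d2b), 2)
  expect_error(estimate_bandwidth(matrix(0, 3, 3)), "zero")
  set.seed(79)
  X <- matrix(rnorm(50 * 4), 50, 4)
  d2c <- as.matrix(dist(X))^2
  expect_equal(estimate_bandwidth(d2c),
               median(d2c[upper.tri(d2c)][d2c[upper.tri(d2c)] > 0]))
})

test_that("Markov operator rows sum to one and the top eigenpair is trivial", {
  set.seed(80)
  imgs <- array(rnorm(8 * 8 * 30), c(8, 8, 30))
  X <- t(matrix(imgs, 64, 30))
  d2 <- as.matrix(dist(X))^2
  eps <- estimate_bandwidth(d2)
  K <- exp(-d2 / (2 * eps))
  P <- K / rowSums(K)
  expect_true(max(abs(rowSums(P) - 1)) < 1e-10)
  emb <- diffusion_embed(imgs, k = 10)
  expect_equal(emb$eigenvalues[1], 1, tolerance = 1e-8)
  expect_true(all(abs(emb$eigenvalues) <= 1 + 1e-8))
  expect_lt(sd(emb$vectors[, 1]), 1e-8)   # constant trivial eigenvector
})

test_that("embedding is equivariant under image permutation", {
  set.seed(81)
  imgs <- array(rnorm(6 * 6 * 50), c(6, 6, 50))
  emb <- diffusion_embed(imgs, eps = 30, k = 6)
  perm <- sample(50)
  emb_p <- diffusion_embed(imgs[, , perm], eps = 30, k = 6)
  # same spectrum; eigenvectors permuted identically (up to fixed sign)
  expect_equal(emb_p$eigenvalues, emb$eigenvalues, tolerance = 1e-10)
  for (j in 2:6) {
    a <- emb$vectors[perm, j]; b <- emb_p$vectors[, j]
    expect_true(max(abs(a - b)) < 1e-8 || max(abs(a + b)) < 1e-8)
  }
})

test_that("noise-plateau rule retains coordinates above the trailing-half median", {
  sel <- coordinates_above_noise(list(c(1, .9, .8, .1, .1, .1, .1, .1,
                                        .1)))
  expect_equal(sel$per_bin, 2L)
  expect_equal(sel$indices[[1]], 1:2)
  flat <- coordinates_above_noise(list(c(1, rep(0.3, 8))))
  expect_equal(flat$per_bin, 0L)
  expect_error(coordinates_above_noise(list(c(1, .5, .4))), "8")
  # global count: median across bins, capped at 2
  many <- coordinates_above_noise(list(
    c(1, .9, .8, .7, .1, .1, .1, .1, .1),
    c(1, .9, .8, .1, .1, .1, .1, .1, .1),
    c(1, .9, .8, .1, .1, .1, .1, .1, .1)))
  expect_equal(many$retained, 2L)
})

test_that("rank homogenization maps coordinates to the unit interval", {
  expect_equal(cryofel:::rank_unit(c(3, 1, 2)), c(1, 0, 0.5))
  expect_equal(cryofel:::rank_unit(c(5, 5, 5)), c(0.5, 0.5, 0.5))
  expect_equal(cryofel:::rank_unit(c(2, 2, 1, 3)),
               c(0.5, 0.5, 0, 1))
})

test_that("propagation aligns co-directional bins and detects sign flips", {
  # two bins over the same viewing direction, disjoint member halves:
  # the cleanest case, where assignment must be the identity and an
  # artificial sign flip of one eigenvector must be detected exactly
  ph <- phantom_default()
  set.seed(90)
  n <- 200
  cc1 <- runif(n); cc2 <- runif(n)
  st <- render_snapshots(ph, data.frame(condition = "minus", cc1 = cc1,
                                        cc2 = cc2, rot = 40, tilt = 70,
                                        psi = 0))
  mk_bin <- function(id, members)
    list(id = id, center = c(0, 0, 1), aperture = 0.1,
         members = members, flagged = FALSE)
  bins <- structure(list(bins = list(mk_bin(1, 1:100),
                                     mk_bin(2, 101:200)),
                         n_centers = 2, aperture = 0.1),
                    class = "projection_bins")
  embs <- embed_bins(st, bins, k = 10)
  cmap <- propagate_coordinates(embs, bins, st)
  expect_s3_class(cmap, "coord_map")
  expect_false(any(cmap$ambiguous))
  expect_gt(min(cmap$scores, na.rm = TRUE), 0.4)
  # both bins see the same manifold: each aligned slot must track the
  # same ground-truth coordinate with the same orientation
  aligned <- function(cm, emb) sweep(emb$vectors[, 1 + cm$perm],
                                     2, cm$sign, `*`)
  al1 <- aligned(cmap$maps[[1]], embs[[1]])
  al2 <- aligned(cmap$maps[[2]], embs[[2]])
  gt <- list(cc1, cc2)
  for (k in 1:2) {
    r1 <- vapply(gt, function(g)
      cor(al1[, k], g[1:100], method = "spearman"), numeric(1))
    g <- which.max(abs(r1))
    r2 <- cor(al2[, k], gt[[g]][101:200], method = "spearman")
    expect_gt(abs(r1[g]), 0.9)
    expect_gt(abs(r2), 0.9)
    expect_equal(sign(r2), sign(r1[g]))
  }

  # flip bin 2's first eigenvector: the flip must be detected, leaving
  # the aligned coordinates unchanged
  embs2 <- embs
  embs2[[2]]$vectors[, 2] <- -embs2[[2]]$vectors[, 2]
  cmap2 <- propagate_coordinates(embs2, bins, st)
  expect_equal(cmap2$maps[[2]]$perm, cmap$maps[[2]]$perm)
  al2b <- aligned(cmap2$maps[[2]], embs2[[2]])
  expect_equal(al2b, al2, tolerance = 1e-12)

  # single usable bin: identity map
  bins1 <- structure(list(bins = list(mk_bin(1, 1:100)), n_centers = 1,
                          aperture = 0.1),
                     class = "projection_bins")
  cmap1 <- propagate_coordinates(list(embs[[1]]), bins1, st)
  expect_equal(cmap1$maps[[1]]$perm, 1:2)
  expect_equal(cmap1$maps[[1]]$sign, c(1, 1))
})

test_that("pooled coordinates cover every snapshot of unflagged bins", {
  st <- tiny_ensemble()
  res <- global_coordinates(st, aperture_for_bins(6), k = 10)
  cc <- res$coords$coords
  expect_equal(nrow(cc), length(st))
  used_members <- unlist(lapply(res$embeddings[res$cmap$usable],
                                `[[`, "members"))
  amb_members <- unlist(lapply(which(res$cmap$ambiguous), function(i)
    res$embeddings[[i]]$members))
  expect_true(all(complete.cases(cc[setdiff(used_members,
                                            amb_members), ])))
  ok <- complete.cases(cc)
  expect_true(all(cc$cc1[ok] >= 0 & cc$cc1[ok] <= 1))
  expect_true(all(cc$cc2[ok] >= 0 & cc$cc2[ok] <= 1))
})
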