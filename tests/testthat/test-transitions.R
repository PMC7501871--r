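test_that("transition map is the normalized product of the two spectra", {
  # delta overlapping delta
  a <- occupancy_from_counts(matrix(c(5L, 0L, 0L, 0L), 2, 2), "minus")
  b <- occupancy_from_counts(matrix(c(3L, 0L, 0L, 0L), 2, 2), "plus")
  tm <- transition_map(a, b)
  expect_equal(tm$T, matrix(c(1, 0, 0, 0), 2, 2))

  # uniform over k cells
  u <- occupancy_from_counts(matrix(2L, 3, 3))
  expect_equal(transition_map(u, u)$T, matrix(1 / 9, 3, 3))

  # hand arithmetic
  nm <- occupancy_from_counts(matrix(c(2L, 1L, 0L, 1L), 2, 2))
  np <- occupancy_from_counts(matrix(c(1L, 0L, 1L, 2L), 2, 2))
  expect_equal(transition_map(nm, np)$T,
               matrix(c(0.5, 0, 0, 0.5), 2, 2))

  # disjoint supports
  d1 <- occupancy_from_counts(matrix(c(1L, 0L), 1, 2))
  d2 <- occupancy_from_counts(matrix(c(0L, 1L), 1, 2))
  expect_error(transition_map(d1, d2), "iso-conformational")
  expect_error(transition_map(nm, occupancy_from_counts(matrix(1L, 3, 3))),
               "dimensions")
})

test_that("transition maps and spectra are normalized", {
  set.seed(31)
  for (i in 1:20) {
    a <- occupancy_from_counts(matrix(rpois(25, 4), 5, 5))
    b <- occupancy_from_counts(matrix(rpois(25, 4) + 1L, 5, 5))
    expect_equal(sum(conformational_spectrum(a)$P), 1, tolerance = 1e-12)
    tm <- transition_map(a, b)
    expect_equal(sum(tm$T), 1, tolerance = 1e-12)
    expect_true(all(tm$T >= 0))
    pr <- (a$counts / a$N) * (b$counts / b$N)
    expect_equal(which.max(tm$T), which.max(pr))
  }
})

test_that("hotspot detection matches a brute-force local-maxima scan", {
  # single peak
  one <- occupancy_from_counts(matrix(c(9L, 1L, 1L, 1L), 2, 2))
  hs <- find_hotspots(transition_map(one, one))
  expect_equal(c(hs$row[1], hs$col[1]), c(1, 1))

  # two equal peaks: both reported, lower row-major index first
  m <- matrix(1L, 5, 5); m[2, 2] <- 10L; m[4, 4] <- 10L
  occ <- occupancy_from_counts(m)
  hs2 <- find_hotspots(transition_map(occ, occ))
  expect_equal(hs2$row[1:2], c(2, 4))
  expect_equal(hs2$col[1:2], c(2, 4))

  set.seed(33)
  for (rep in 1:10) {
    a <- occupancy_from_counts(matrix(rpois(100, 6) + 1L, 10, 10))
    b <- occupancy_from_counts(matrix(rpois(100, 6) + 1L, 10, 10))
    tm <- transition_map(a, b)
    hs3 <- find_hotspots(tm, rel_threshold = 0.3)
    # exhaustive scan oracle
    ora <- NULL
    for (r in 1:10) for (c in 1:10) {
      nb <- expand.grid(r = r + (-1:1), c = c + (-1:1))
      nb <- nb[!(nb$r == r & nb$c == c) & nb$r >= 1 & nb$r <= 10 &
                 nb$c >= 1 & nb$c <= 10, ]
      if (all(tm$T[r, c] >= tm$T[cbind(nb$r, nb$c)]) &&
          tm$T[r, c] >= 0.3 * max(tm$T) && tm$T[r, c] > 0)
        ora <- rbind(ora, c(r, c))
    }
    expect_equal(nrow(hs3), nrow(ora))
    expect_setequal(paste(hs3$row, hs3$col), paste(ora[, 1], ora[, 2]))
  }
})

test_that("Metropolis intra-landscape rates have the stated closed forms", {
  flat <- energy_from_occupancy(occupancy_from_counts(matrix(4L, 3, 3)))
  rm <- build_rate_model(flat, flat, L = 1, A = 2, kT = 1)
  offdiag <- rm$Wmm[Matrix::which(rm$Wmm != 0)]
  expect_true(all(abs(offdiag - 2) < 1e-12))

  # two-cell landscape with energy gap kT ln 2: forward A/2, reverse A
  occ <- occupancy_from_counts(matrix(c(10L, 5L), 1, 2))
  E <- energy_from_occupancy(occ, kT = 1)
  r2 <- build_rate_model(E, E, A = 1, kT = 1)
  expect_equal(r2$Wmm[2, 1], 0.5, tolerance = 1e-12)  # up in energy
  expect_equal(r2$Wmm[1, 2], 1, tolerance = 1e-12)    # downhill

  # association rate ratio equals the bound-spectrum ratio (k_c prop P+)
  set.seed(41)
  cnt <- matrix(rpois(16, 20) + 1L, 4, 4)
  Ep <- energy_from_occupancy(occupancy_from_counts(cnt), kT = 1)
  rm3 <- build_rate_model(Ep, Ep, L = 2, A = 3, kT = 1)
  w <- matrix(rm3$wmp, 4, 4)
  expect_equal(w[1, 2] / w[3, 3], cnt[1, 2] / cnt[3, 3],
               tolerance = 1e-12)
})

test_that("master-equation integration conserves probability and finds equilibria", {
  # all rates zero: p stays put
  z <- energy_from_occupancy(occupancy_from_counts(matrix(5L, 2, 2)))
  rm0 <- build_rate_model(z, z, L = 0, A = 1e-300, kT = 1)
  p0 <- rep(1 / 8, 8)
  tr <- integrate_master_equation(rm0, p0, c(0, 1, 5))
  expect_equal(tr$p[3, ], p0, tolerance = 1e-9)

  # symmetric two-state system relaxes to (1/2, 1/2)
  occ2c <- occupancy_from_counts(matrix(c(5L, 5L), 1, 2))
  E2 <- energy_from_occupancy(occ2c)
  rm2 <- build_rate_model(E2, E2, L = 0, A = 1, kT = 1)
  p2 <- c(1, 0, 0, 0)
  tr2 <- integrate_master_equation(rm2, p2, c(0, 50))
  expect_equal(tr2$p[2, 1:2], c(0.5, 0.5), tolerance = 1e-6)
  expect_true(max(abs(rowSums(tr2$p) - 1)) < 1e-8)
})

test_that("Metropolis stationary state is the Boltzmann density (null-space oracle)", {
  set.seed(47)
  counts <- matrix(rpois(400, 30) + 1L, 20, 20)
  E <- energy_from_occupancy(occupancy_from_counts(counts), kT = 1)
  model <- build_rate_model(E, E, L = 0, A = 1, kT = 1)
  # oracle: null-space eigenvector of the single-landscape generator
  W <- as.matrix(model$Wmm)
  G <- W - diag(colSums(W))
  es <- eigen(G)
  k <- which.min(abs(es$values))
  stat <- Re(es$vectors[, k])
  stat <- stat / sum(stat)
  boltz <- boltzmann_density(E)
  expect_lt(0.5 * sum(abs(stat - boltz)), 1e-4)   # total variation
})

test_that("normalized initial flux equals the transition map exactly", {
  set.seed(53)
  for (rep in 1:20) {
    nm <- occupancy_from_counts(matrix(rpois(36, 8) + 1L, 6, 6), "minus")
    np <- occupancy_from_counts(matrix(rpois(36, 8) + 1L, 6, 6), "plus")
    Em <- energy_from_occupancy(nm)
    Ep <- energy_from_occupancy(np)
    model <- build_rate_model(Em, Ep, L = runif(1, 0.1, 5),
                              A = runif(1, 0.1, 5))
    flux <- initial_flux(model, conformational_spectrum(nm)$P)
    tm <- transition_map(nm, np)
    expect_lt(max(abs(flux / sum(flux) - tm$T)), 1e-12)
    expect_equal(which.max(flux), which.max((nm$counts / nm$N) *
                                              (np$counts / np$N)))
  }
  # flux proportional to p- under uniform association rates
  flatp <- energy_from_occupancy(occupancy_from_counts(matrix(3L, 3, 3)))
  mu <- build_rate_model(flatp, flatp, L = 1, A = 1)
  pm <- matrix(runif(9), 3, 3); pm <- pm / sum(pm)
  expect_equal(initial_flux(mu, pm) / sum(initial_flux(mu, pm)),
               pm, tolerance = 1e-12)
  # delta input: flux supported on one cell
  d <- matrix(0, 3, 3); d[2, 2] <- 1
  expect_equal(sum(initial_flux(mu, d) > 0), 1)
})

test_that("trajectories tidy into long-format time series", {
  z <- energy_from_occupancy(occupancy_from_counts(matrix(2L, 2, 2)))
  rm0 <- build_rate_model(z, z, L = 0, A = 1)
  tr <- integrate_master_equation(rm0, rep(1 / 8, 8), c(0, 1))
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 2 * 8)
  expect_equal(sum(df$p[df$time == 0]), 1, tolerance = 1e-10)
  expect_setequal(unique(df$side), c("minus", "plus"))
})

test_that("detailed-balance dissociation makes the dual-landscape density stationary", {
  set.seed(59)
  nm <- occupancy_from_counts(matrix(rpois(25, 20) + 1L, 5, 5))
  np <- occupancy_from_counts(matrix(rpois(25, 20) + 1L, 5, 5))
  Em <- energy_from_occupancy(nm); Ep <- energy_from_occupancy(np)
  model <- build_rate_model(Em, Ep, L = 1, A = 1,
                            dissociation = "detailed_balance", K_b = 1)
  wm <- exp(-as.vector(Em$energy))
  wp <- exp(-as.vector(Ep$energy))
  pi_full <- c(wm, wp) / sum(c(wm, wp))
  G <- as.matrix(rate_generator(model))
  expect_lt(max(abs(G %*% pi_full)), 1e-10)
})
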