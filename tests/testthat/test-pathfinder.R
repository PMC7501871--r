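test_that("trivial paths behave: flat landscape, single-cell path", {
  flat <- energy_from_occupancy(occupancy_from_counts(matrix(3L, 4, 4)))
  p <- least_action_path(flat, c(1, 1), c(4, 4))
  expect_equal(p$action, 0)
  expect_equal(p$cells[1, ], c(row = 1, col = 1))
  expect_equal(p$cells[nrow(p$cells), ], c(row = 4, col = 4))
  # 8-adjacency between consecutive cells
  expect_true(all(abs(diff(p$cells[, 1])) <= 1 &
                    abs(diff(p$cells[, 2])) <= 1))
  same <- least_action_path(flat, c(2, 3), c(2, 3))
  expect_equal(nrow(same$cells), 1)
  expect_equal(same$action, 0)
})

test_that("a ridge with a gap forces the path through the gap", {
  counts <- matrix(50L, 4, 4)
  counts[2, c(1, 2, 4)] <- 1L   # high ridge on row 2 except column 3
  E <- energy_from_occupancy(occupancy_from_counts(counts))
  p <- least_action_path(E, c(1, 1), c(4, 1))
  ridge_cols <- p$cells[p$cells[, 1] == 2, 2]
  expect_true(all(ridge_cols == 3))
  ora <- oracle_path_cost(E$energy, c(1, 1), c(4, 1))
  expect_equal(p$action, ora$primary, tolerance = 1e-12)
})

test_that("least-action paths match exhaustive enumeration on small grids", {
  set.seed(61)
  for (rep in 1:60) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    counts <- matrix(rpois(n1 * n2, 15), n1, n2)
    counts[sample(n1 * n2, round(0.2 * n1 * n2))] <- 0L  # masked cells
    counts[1, 1] <- max(counts[1, 1], 1L)
    counts[n1, n2] <- max(counts[n1, n2], 1L)
    E <- energy_from_occupancy(occupancy_from_counts(counts))
    reachable <- !is.na(E$energy)
    if (!reachable[1, 1] || !reachable[n1, n2]) next
    for (mode in c("integral", "minimax")) {
      p <- tryCatch(least_action_path(E, c(1, 1), c(n1, n2), mode = mode),
                    error = function(e) NULL)
      ora <- oracle_path_cost(E$energy, c(1, 1), c(n1, n2), mode = mode)
      if (is.null(p)) {
        expect_false(is.finite(ora$primary))
      } else if (mode == "integral") {
        expect_equal(p$action, ora$primary, tolerance = 1e-10)
      } else {
        expect_equal(p$bottleneck, ora$primary, tolerance = 1e-10)
        expect_equal(p$action, ora$secondary, tolerance = 1e-10)
      }
    }
  }
})

test_that("optimal action never exceeds the straight-line interpolation action", {
  set.seed(67)
  for (rep in 1:30) {
    counts <- matrix(rpois(49, 20) + 1L, 7, 7)
    E <- energy_from_occupancy(occupancy_from_counts(counts))
    s <- c(sample(7, 1), sample(7, 1)); e <- c(sample(7, 1), sample(7, 1))
    p <- least_action_path(E, s, e)
    bres <- bresenham_path(s, e)
    expect_lte(p$action, path_action(E, bres) + 1e-12)
  }
})

test_that("the dual-landscape functional path runs START -> HOT -> FINISH", {
  # shifted occupancy peaks with overlap in the middle
  g <- expand.grid(r = 1:9, c = 1:9)
  nm <- matrix(as.integer(200 * exp(-((g$r - 3)^2 + (g$c - 3)^2) / 6)) +
                 1L, 9, 9)
  np <- matrix(as.integer(200 * exp(-((g$r - 7)^2 + (g$c - 7)^2) / 6)) +
                 1L, 9, 9)
  om <- occupancy_from_counts(nm, "minus")
  op <- occupancy_from_counts(np, "plus")
  Em <- energy_from_occupancy(om); Ep <- energy_from_occupancy(op)
  tm <- transition_map(om, op)
  fp <- dual_landscape_path(Em, Ep, tm, occ_minus = om)
  expect_equal(unname(fp$cells[1, ]), c(3, 3))
  expect_equal(unname(fp$cells[nrow(fp$cells), ]), c(7, 7))
  # exactly one switch, iso-conformational at the hotspot
  expect_equal(sum(diff(fp$side == "plus") == 1), 1)
  expect_equal(unname(fp$cells[fp$switch_index, ]), fp$hotspot)
  expect_equal(fp$side[fp$switch_index], "minus")
  expect_equal(fp$side[fp$switch_index + 1], "plus")
  # consecutive cells 8-adjacent across the whole route
  expect_true(all(abs(diff(fp$cells[, 1])) <= 1 &
                    abs(diff(fp$cells[, 2])) <= 1))
  # reported summaries recomputed by direct summation
  win <- cell_window(c(9, 9), fp$hotspot, 1)
  expect_equal(fp$summaries$hotspot_window_fraction_minus,
               sum(nm[win]) / sum(nm), tolerance = 1e-12)
  expect_equal(fp$summaries$hotspot_transition_prob,
               tm$T[fp$hotspot[1], fp$hotspot[2]], tolerance = 1e-12)

  # identical landscapes with hotspot at the shared minimum: single cell
  tmi <- transition_map(om, om)
  fpi <- dual_landscape_path(Em, Em, tmi, hotspot = c(3, 3))
  expect_equal(nrow(fpi$cells), 1)
})

test_that("frames resample the path and collect only in-window members", {
  g <- expand.grid(r = 1:9, c = 1:9)
  nm <- matrix(as.integer(100 * exp(-((g$r - 3)^2 + (g$c - 5)^2) / 8)) +
                 1L, 9, 9)
  np <- matrix(as.integer(100 * exp(-((g$r - 7)^2 + (g$c - 5)^2) / 8)) +
                 1L, 9, 9)
  om <- occupancy_from_counts(nm, "minus")
  op <- occupancy_from_counts(np, "plus")
  fp <- dual_landscape_path(energy_from_occupancy(om),
                            energy_from_occupancy(op),
                            transition_map(om, op), occ_minus = om)
  set.seed(71)
  n <- 500
  coords <- data.frame(cc1 = runif(n), cc2 = runif(n))
  cond <- sample(c("minus", "plus"), n, replace = TRUE)
  fs <- suppressWarnings(path_frames(fp, coords, cond, c(9, 9),
                                     n_frames = 10, half_width = 1))
  expect_equal(fs$n_frames, 10)
  # frame centers start and end at the path endpoints
  expect_equal(unname(fs$centers[1, ]),
               unname((fp$cells[1, ] - 0.5) / 9), tolerance = 1e-12)
  expect_equal(unname(fs$centers[10, ]),
               unname((fp$cells[nrow(fp$cells), ] - 0.5) / 9),
               tolerance = 1e-12)
  # brute-force membership check
  w <- 1.5 / 9
  for (f in seq_len(10)) {
    inwin <- which(cond == fs$side[f] &
                     abs(coords$cc1 - fs$centers[f, 1]) <= w &
                     abs(coords$cc2 - fs$centers[f, 2]) <= w)
    expect_setequal(fs$members[[f]], inwin)
  }
  # two frames degenerate to the endpoints
  fs2 <- suppressWarnings(path_frames(fp, coords, cond, c(9, 9),
                                      n_frames = 2))
  expect_equal(nrow(fs2$centers), 2)
  # a window covering the whole grid collects every same-side snapshot
  fs3 <- suppressWarnings(path_frames(fp, coords, cond, c(9, 9),
                                      n_frames = 3, half_width = 9))
  expect_setequal(fs3$members[[1]], which(cond == fs3$side[1]))
})

test_that("back-projection is the adjoint smear and recovers blob phantoms", {
  # single axis-aligned view of a point: a line through the point
  pv <- array(0, c(9, 9, 9)); pv[5, 5, 5] <- 1
  img <- project_volume(pv)
  vol <- backproject_frame(array(img, c(9, 9, 1)),
                           data.frame(rot = 0, tilt = 0, psi = 0), 9)
  expect_true(all(vol[5, 5, ] == 1))
  expect_equal(sum(vol != 0), 9)

  # duplicated image at the same orientation changes nothing (hit
  # normalization)
  vol2 <- backproject_frame(array(rep(img, 2), c(9, 9, 2)),
                            data.frame(rot = c(0, 0), tilt = c(0, 0),
                                       psi = c(0, 0)), 9)
  expect_equal(vol2, vol, tolerance = 1e-12)

  # 100 noise-free views of the base phantom correlate with ground truth
  ph <- phantom_default(24)
  dirs <- fibonacci_sphere(100)
  eul <- direction_to_euler(dirs)
  st <- render_snapshots(ph, data.frame(condition = "minus", cc1 = 0.0,
                                        cc2 = 0.0, rot = eul$rot,
                                        tilt = eul$tilt, psi = eul$psi))
  rec <- backproject_frame(st$images, st$orientations, 24)
  truth <- phantom_volume(ph, 0, 0)
  expect_gt(cor(as.vector(rec), as.vector(truth)), 0.8)
  expect_error(backproject_frame(array(0, c(4, 4, 0)),
                                 data.frame(rot = 1, tilt = 1, psi = 1)[0, ],
                                 4), "empty")
})
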