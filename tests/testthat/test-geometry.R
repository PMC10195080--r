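dfr <- direction_frame()

test_that("sector assignment honours axes and half-open boundaries", {
  expect_equal(as.character(assign_sector(c(1, 0, 0), dfr)), "DL")
  expect_equal(as.character(assign_sector(c(0, 1, 0), dfr)), "DM")
  expect_equal(as.character(assign_sector(c(-1, 0, 0), dfr)), "VM")
  expect_equal(as.character(assign_sector(c(0, -1, 0), dfr)), "VL")
  # boundaries: 45 -> DM, 135 -> VM, 225 -> VL, 315 -> DL
  expect_equal(as.character(assign_sector(c(1, 1, 0), dfr)), "DM")
  expect_equal(as.character(assign_sector(c(-1, 1, 0), dfr)), "VM")
  expect_equal(as.character(assign_sector(c(-1, -1, 0), dfr)), "VL")
  expect_equal(as.character(assign_sector(c(1, -1, 0), dfr)), "DL")
  # anterior component is ignored (projection onto DL-DM plane)
  expect_equal(as.character(assign_sector(c(1, 0, 5), dfr)), "DL")
  expect_error(assign_sector(c(0, 0, 3), dfr), "degenerate")
})

test_that("sector labels match the independent atan2 oracle on random points", {
  set.seed(11)
  pts <- matrix(rnorm(3000), ncol = 3)
  expect_identical(as.character(assign_sector(pts, dfr)), sector_oracle(pts, dfr))
  # in a rotated, translated frame
  th <- 0.7
  d2 <- direction_frame(origin = c(3, -2, 5),
                        axis_dl = c(cos(th), sin(th), 0),
                        axis_dm = c(-sin(th), cos(th), 0))
  pts2 <- sweep(matrix(rnorm(3000), ncol = 3), 2, c(3, -2, 5), "+")
  expect_identical(as.character(assign_sector(pts2, d2)),
                   sector_oracle(pts2, d2))
})

test_that("sector assignment is rotation-consistent and partitions the plane", {
  set.seed(12)
  pts <- matrix(rnorm(900), ncol = 3)
  lab0 <- assign_sector(pts, dfr)
  # rotate frame and points together about the anterior axis
  for (th in c(0.3, 1.2, 2.9)) {
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    d2 <- direction_frame(axis_dl = drop(R %*% c(1, 0, 0)),
                          axis_dm = drop(R %*% c(0, 1, 0)))
    expect_identical(assign_sector(pts %*% t(R), d2), lab0)
  }
  # sweeping theta yields the cyclic sequence DL, DM, VM, VL, 90 deg each
  th <- seq(0, 359.5, by = 0.5)
  pts_th <- cbind(cos(th * pi / 180), sin(th * pi / 180), 0)
  lab <- assign_sector(pts_th, dfr)
  expect_equal(as.vector(table(lab)[c("DL", "DM", "VM", "VL")]),
               rep(180L, 4))
  expect_identical(as.character(lab[th == 0]), "DL")
  expect_identical(as.character(lab[th == 90]), "DM")
  expect_identical(as.character(lab[th == 44.5]), "DL")
  # off the exact bin boundaries (where the oracle's radians-to-degrees
  # conversion rounds while the comparison-based assignment does not) the
  # sweep agrees with the angle oracle everywhere
  off <- th %% 45 != 0
  expect_identical(as.character(lab)[off], sector_oracle(pts_th, dfr)[off])
})

test_that("cable metrics match closed forms and brute-force sums", {
  # single edge, length 3, radii 1,1: a cylinder of volume 3*pi
  cyl <- chain_frame(rbind(c(0, 0, 0), c(3, 0, 0)), radius = 1)
  m <- cable_metrics(cyl)
  expect_equal(m$length, 3)
  expect_equal(m$volume, 3 * pi, tolerance = 1e-12)
  # 3-4-5 chain: path length 7
  expect_equal(cable_metrics(chain_frame(rbind(c(0, 0, 0), c(3, 0, 0),
                                               c(3, 4, 0))))$length, 7)
  # random trees against an edge-by-edge oracle
  for (seed in 1:5) {
    fr <- random_tree_frame(n = 40, seed = seed)
    n <- fr$nodes
    L <- V <- 0
    for (i in seq_len(nrow(n))) {
      p <- n$parent_id[i]
      if (p == -1) next
      j <- which(n$node_id == p)
      len <- sqrt(sum((c(n$x[i], n$y[i], n$z[i]) -
                         c(n$x[j], n$y[j], n$z[j]))^2))
      L <- L + len
      V <- V + pi / 3 * len * (n$radius[i]^2 + n$radius[i] * n$radius[j] +
                                 n$radius[j]^2)
    }
    m <- cable_metrics(fr)
    expect_equal(m$length, L, tolerance = 1e-12)
    expect_equal(m$volume, V, tolerance = 1e-12)
  }
})

test_that("cable metrics are additive over edge-disjoint subtrees", {
  a <- chain_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)))
  b <- chain_frame(rbind(c(5, 5, 5), c(5, 6, 5)))
  both <- skeleton_frame(node_df(
    c(1, 3, 0, 0, 0, 0.5, -1), c(2, 3, 1, 0, 0, 0.5, 1),
    c(3, 3, 2, 1, 0, 0.5, 2), c(4, 3, 5, 5, 5, 0.5, 1),
    c(5, 3, 5, 6, 5, 0.5, 4)
  ))
  # total = sum of parts plus the bridging edge 1->4
  bridge <- sqrt(sum(c(5, 5, 5)^2))
  expect_equal(cable_metrics(both)$length,
               cable_metrics(a)$length + cable_metrics(b)$length + bridge,
               tolerance = 1e-12)
})

test_that("exploring volume: closed forms, degeneracy, monotonicity, oracle", {
  tet <- chain_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_equal(exploring_volume(tet), 1 / 6, tolerance = 1e-12)
  # collinear points: 0 with a warning, not an error
  expect_warning(v <- exploring_volume(chain_frame(cbind(0:5, 0, 0))),
                 "degenerate|fewer")
  expect_equal(v, 0)
  # soma/axon-typed nodes excluded by default
  f <- four_arm_frame()
  expect_warning(exploring_volume(f), "degenerate")  # arms are coplanar
  expect_gt(suppressWarnings(exploring_volume(f, exclude_axon = FALSE)), 0)
  # frozen oracle: scipy.spatial.ConvexHull volume on this exact seeded set
  set.seed(42)
  pts <- matrix(round(runif(600, -10, 10), 6), ncol = 3)
  expect_equal(convex_hull_volume(pts), 6766.644347801685, tolerance = 1e-9)
  # known polytopes
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_hull_volume(cube), 1, tolerance = 1e-12)
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  expect_equal(convex_hull_volume(oct), 4 / 3, tolerance = 1e-12)
  # monotone under adding points; interior points change nothing
  set.seed(13)
  base <- matrix(rnorm(150), ncol = 3)
  v0 <- convex_hull_volume(base)
  expect_gte(convex_hull_volume(rbind(base, matrix(rnorm(30), ncol = 3))), v0)
  expect_equal(convex_hull_volume(rbind(base, colMeans(base))), v0,
               tolerance = 1e-9)
})

test_that("terminal branch counts equal a brute-force degree scan", {
  expect_equal(count_terminal_branches(chain_frame(cbind(0:5, 0, 0))), 1L)
  # binary tree of depth 2: 4 leaves
  bt <- skeleton_frame(node_df(
    c(1, 1, 0, 0, 0, 1, -1),
    c(2, 3, -1, 1, 0, 0.5, 1), c(3, 3, 1, 1, 0, 0.5, 1),
    c(4, 3, -2, 2, 0, 0.5, 2), c(5, 3, -1, 2, 0, 0.5, 2),
    c(6, 3, 1, 2, 0, 0.5, 3), c(7, 3, 2, 2, 0, 0.5, 3)
  ))
  expect_equal(count_terminal_branches(bt), 4L)
  for (seed in 1:10) {
    fr <- random_tree_frame(n = 25, seed = seed)
    n <- fr$nodes
    leaves <- sum(vapply(n$node_id, function(id) {
      sum(n$parent_id == id) == 0 && n$parent_id[n$node_id == id] != -1
    }, logical(1)))
    expect_equal(count_terminal_branches(fr), leaves)
  }
})

test_that("mass center: symmetry, single edge, weighted oracle", {
  sym <- skeleton_frame(node_df(
    c(1, 3, 0, 0, 0, 0.5, -1),
    c(2, 3, 2, 0, 0, 0.5, 1), c(3, 3, -2, 0, 0, 0.5, 1)
  ))
  expect_equal(mass_center(sym), c(0, 0, 0), tolerance = 1e-12)
  one <- chain_frame(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(mass_center(one), c(1, 0, 0), tolerance = 1e-12)
  expect_error(mass_center(one, node_ids = integer(0)), "empty subset")
  for (seed in 1:5) {
    fr <- random_tree_frame(n = 30, seed = seed)
    n <- fr$nodes
    wsum <- c(0, 0, 0); wtot <- 0
    for (i in seq_len(nrow(n))) {
      p <- n$parent_id[i]
      if (p == -1) next
      j <- which(n$node_id == p)
      len <- sqrt(sum((c(n$x[i], n$y[i], n$z[i]) -
                         c(n$x[j], n$y[j], n$z[j]))^2))
      w <- pi / 3 * len * (n$radius[i]^2 + n$radius[i] * n$radius[j] +
                             n$radius[j]^2)
      mid <- (c(n$x[i], n$y[i], n$z[i]) + c(n$x[j], n$y[j], n$z[j])) / 2
      wsum <- wsum + w * mid; wtot <- wtot + w
    }
    expect_equal(mass_center(fr), wsum / wtot, tolerance = 1e-10)
  }
})

test_that("core overlap: identity, disjointness, translated brute force", {
  arbor <- random_tree_frame(n = 30, seed = 3, spread = 8)
  expect_equal(core_overlap(arbor, arbor), 1.0)
  far <- arbor
  far$nodes$x <- far$nodes$x + 1000
  expect_equal(core_overlap(arbor, far, voxel = 1), 0.0)
  # translated copy: brute-force voxel set intersection oracle
  shift <- far
  shift$nodes$x <- arbor$nodes$x + 5
  vox <- 2
  rast <- function(fr, anchor) {
    n <- fr$nodes
    keys <- character(0); lens <- numeric(0)
    for (i in seq_len(nrow(n))) {
      p <- n$parent_id[i]
      if (p == -1) next
      j <- which(n$node_id == p)
      a <- c(n$x[j], n$y[j], n$z[j]); b <- c(n$x[i], n$y[i], n$z[i])
      L <- sqrt(sum((b - a)^2))
      if (L == 0) next
      k <- max(1, ceiling(L / (vox / 2)))
      for (s in seq_len(k)) {
        m <- a + (s - 0.5) / k * (b - a)
        keys <- c(keys, paste(floor((m - anchor) / vox), collapse = "_"))
        lens <- c(lens, L / k)
      }
    }
    tapply(lens, keys, sum)
  }
  core <- function(d, q) {
    d <- sort(d, decreasing = TRUE)
    names(d)[seq_len(which(cumsum(d) / sum(d) >= q)[1])]
  }
  anchor <- apply(rbind(as.matrix(arbor$nodes[, c("x", "y", "z")]),
                        as.matrix(shift$nodes[, c("x", "y", "z")])), 2, min)
  ca <- core(rast(arbor, anchor), 0.5)
  cb <- core(rast(shift, anchor), 0.5)
  expect_equal(core_overlap(arbor, shift, voxel = vox),
               length(intersect(ca, cb)) / min(length(ca), length(cb)))
})
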