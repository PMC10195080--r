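dfr <- direction_frame()

test_that("terminal branches are leaf-to-junction walks", {
  # unbranched cable of length 10 from root: one branch, full length
  cab <- chain_frame(cbind(seq(0, 10, by = 2.5), 0, 0))
  tb <- extract_terminals(cab)
  expect_equal(nrow(tb), 1L)
  expect_equal(tb$path_length, 10)
  # Y-shape: arms 3 and 4 after a junction
  y <- skeleton_frame(node_df(
    c(1, 3, 0, 0, 0, 0.5, -1), c(2, 3, 0, 1, 0, 0.5, 1),
    c(3, 3, 3, 1, 0, 0.5, 2), c(4, 3, 0, 5, 0, 0.5, 2)
  ))
  tb <- extract_terminals(y)
  expect_equal(sort(tb$path_length), c(3, 4))
  expect_equal(tb$base_id, c(2L, 2L))
  # random trees: brute-force leaf-to-junction oracle
  for (seed in 1:8) {
    fr <- random_tree_frame(n = 30, seed = seed)
    n <- fr$nodes
    nchild <- vapply(n$node_id, function(id) sum(n$parent_id == id), integer(1))
    leaves <- n$node_id[nchild == 0 & n$parent_id != -1]
    oracle <- vapply(leaves, function(leaf) {
      len <- 0; cur <- leaf
      repeat {
        i <- which(n$node_id == cur); p <- n$parent_id[i]
        if (p == -1) break
        j <- which(n$node_id == p)
        len <- len + sqrt((n$x[i] - n$x[j])^2 + (n$y[i] - n$y[j])^2 +
                            (n$z[i] - n$z[j])^2)
        if (nchild[j] >= 2) break
        cur <- p
      }
      len
    }, numeric(1))
    tb <- extract_terminals(fr)
    expect_equal(sort(tb$tip_id), sort(leaves))
    expect_equal(tb$path_length[match(leaves, tb$tip_id)], oracle,
                 tolerance = 1e-10)
  }
})

test_that("tracking follows drifting tips and never swaps distant ones", {
  mkframe <- function(tips, t) {
    rows <- list(node_df(c(1, 1, 0, 0, -10, 1, -1), c(2, 2, 0, 0, 0, 0.5, 1)))
    for (k in seq_len(nrow(tips))) {
      rows[[k + 1]] <- node_df(c(k + 2, 3, tips[k, 1], tips[k, 2], tips[k, 3],
                                 0.3, 2))
    }
    skeleton_frame(do.call(rbind, rows), time = t)
  }
  # one tip drifting 0.5 um/frame over 5 frames: one track
  frames <- lapply(0:4, function(i) mkframe(rbind(c(5 + 0.5 * i, 0, 0)), i * 0.5))
  tr <- track_terminals(skeleton_series(frames))
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(nrow(tr), 5L)
  # two tips 20 um apart each drifting 0.5 um/frame: two tracks, no swap
  frames <- lapply(0:4, function(i) {
    mkframe(rbind(c(5 + 0.5 * i, 0, 0), c(5 + 0.5 * i, 20, 0)), i * 0.5)
  })
  tr <- track_terminals(skeleton_series(frames))
  expect_equal(length(unique(tr$track_id)), 2L)
  by_track <- split(tr$tip_y, tr$track_id)
  expect_true(all(vapply(by_track, function(y) length(unique(y)) == 1,
                         logical(1))))
  # displacement beyond the gate closes the track and opens a new one
  frames <- list(mkframe(rbind(c(5, 0, 0)), 0), mkframe(rbind(c(15, 0, 0)), 0.5))
  tr <- track_terminals(skeleton_series(frames))
  expect_equal(length(unique(tr$track_id)), 2L)
  # a missing frame always breaks the track (no resurrection)
  frames <- list(mkframe(rbind(c(5, 0, 0)), 0), NULL, mkframe(rbind(c(5, 0, 0)), 1))
  s <- skeleton_series(frames, times = c(0, 0.5, 1),
                       missing = c(FALSE, TRUE, FALSE))
  tr <- track_terminals(s)
  expect_equal(length(unique(tr$track_id)), 2L)
})

test_that("tracking recovers ground-truth identities on sparse series", {
  cfg <- synth_config(seed = 8, lambda = c(DL = 0.15, DM = 0.15, VM = 0.15,
                                           VL = 0.15),
                      tau = c(DL = 20, DM = 20, VM = 20, VL = 20),
                      jitter_sd = 0.05)
  res <- simulate_series(cfg)
  tr <- track_terminals(res$series, dframe = dfr)
  obs <- res$truth$observations
  m <- merge(tr[c("track_id", "frame", "tip_id")],
             obs[c("branch_id", "frame", "tip_node_id")],
             by.x = c("frame", "tip_id"), by.y = c("frame", "tip_node_id"))
  expect_equal(nrow(m), nrow(obs))  # every true tip observation was tracked
  # per true branch, the majority track; count observations assigned to it
  hits <- 0
  for (b in unique(m$branch_id)) {
    tb <- m$track_id[m$branch_id == b]
    hits <- hits + max(table(tb))
  }
  expect_gte(hits / nrow(m), 0.99)
  # and each track maps to a single true branch (no chimeras)
  purity <- vapply(split(m$branch_id, m$track_id), function(b) {
    max(table(b)) / length(b)
  }, numeric(1))
  expect_gte(mean(purity == 1), 0.95)
})

test_that("classification matches the four-case oracle over all contiguous masks", {
  for (n_frames in 2:8) {
    masks <- list()
    for (first in seq_len(n_frames)) for (last in first:n_frames) {
      mask <- rep(FALSE, n_frames); mask[first:last] <- TRUE
      masks[[length(masks) + 1]] <- mask
    }
    spec <- lapply(masks, function(m) {
      list(frames = which(m), lengths = rep(5, sum(m)))
    })
    tr <- tracks_from_lengths(spec, n_frames = n_frames)
    cls <- classify_tracks(tr, n_frames = n_frames)
    oracle <- vapply(masks, category_oracle, character(1))
    expect_identical(as.character(cls$category), oracle)
    # the four categories are exhaustive and mutually exclusive
    expect_false(anyNA(cls$category))
    if (n_frames >= 3) {
      expect_setequal(unique(oracle),
                      c("stable", "transient", "emerging", "retracting"))
    }
  }
  # the canonical examples: 30-frame window
  tr <- tracks_from_lengths(list(
    list(frames = 1:30, lengths = rep(5, 30)),
    list(frames = 4:11, lengths = rep(5, 8)),
    list(frames = 1:11, lengths = rep(5, 11)),
    list(frames = 4:30, lengths = rep(5, 27))
  ), n_frames = 30)
  cls <- classify_tracks(tr, n_frames = 30)
  expect_identical(as.character(cls$category),
                   c("stable", "transient", "retracting", "emerging"))
  # non-contiguous masks violate the tracker contract
  bad <- tracks_from_lengths(list(list(frames = c(1, 3), lengths = c(5, 5))),
                             n_frames = 4)
  expect_error(classify_tracks(bad, n_frames = 4), "non-contiguous")
})

test_that("tip speeds are signed path-length differences per minute", {
  tr <- tracks_from_lengths(list(list(frames = 1:3, lengths = c(5, 5.5, 5.5))))
  sp <- tip_speeds(tr)
  expect_equal(sp$speed, c(1, 0))  # +0.5 um over 0.5 min, then constant
  # speed antisymmetry under time reversal
  set.seed(31)
  lens <- cumsum(rnorm(10))
  tr <- tracks_from_lengths(list(list(frames = 1:10, lengths = lens)))
  tr_rev <- tracks_from_lengths(list(list(frames = 1:10, lengths = rev(lens))))
  expect_equal(tip_speeds(tr)$speed, -rev(tip_speeds(tr_rev)$speed),
               tolerance = 1e-12)
})

test_that("motion labels are strict at 0.5 um/min and threshold-monotone", {
  expect_identical(as.character(label_motion(c(0.6, -0.7, 0.2))),
                   c("extending", "retracting", "stationary"))
  # exactly the threshold is stationary ("exceeded" is strict)
  expect_identical(as.character(label_motion(c(0.5, -0.5))),
                   c("stationary", "stationary"))
  set.seed(32)
  sp <- rnorm(500, 0, 1)
  lab <- label_motion(sp)
  oracle <- ifelse(sp > 0.5, "extending",
                   ifelse(sp < -0.5, "retracting", "stationary"))
  expect_identical(as.character(lab), oracle)
  n_stat <- vapply(seq(0.1, 2, by = 0.1), function(thr) {
    sum(label_motion(sp, analysis_params(speed_threshold = thr)) == "stationary")
  }, numeric(1))
  expect_true(all(diff(n_stat) >= 0))
})

test_that("tip observations are conserved between frames and tracks", {
  res <- simulate_series(synth_preset("uniform", seed = 9))
  tr <- track_terminals(res$series, dframe = dfr)
  for (i in seq_along(res$series$frames)) {
    n_tips <- nrow(extract_terminals(res$series$frames[[i]]))
    expect_equal(sum(tr$frame == i), n_tips)
  }
  expect_equal(nrow(tr), sum(vapply(res$series$frames, function(f) {
    nrow(extract_terminals(f))
  }, integer(1))))
})

test_that("branch dynamics summary aggregates by direction and category", {
  # all stable branches in DL
  tr <- tracks_from_lengths(list(
    list(frames = 1:6, lengths = rep(5, 6), sector = "DL"),
    list(frames = 1:6, lengths = rep(4, 6), sector = "DL"),
    list(frames = 2:5, lengths = rep(3, 4), sector = "VM")
  ), n_frames = 6)
  s <- summarize_branch_dynamics(tr)
  expect_equal(s$by_direction$stable_pct, c(100, 0, 0, 0))
  # direction without stable branches reports NA speed, not 0
  expect_true(is.na(s$by_direction$mean_abs_speed[3]))
  # one stable branch alternating +1.5/-1.5 um/min
  lens <- 5 + c(0, 0.75, 0, 0.75, 0, 0.75, 0)  # 0.5-min cadence
  tr2 <- tracks_from_lengths(list(list(frames = 1:7, lengths = lens,
                                       sector = "DM")), n_frames = 7)
  s2 <- summarize_branch_dynamics(tr2)
  expect_equal(s2$by_direction$mean_abs_speed[2], 1.5)
  bc <- s2$by_category
  expect_equal(bc$frac_extending[bc$category == "stable"], 0.5)
  expect_equal(bc$frac_retracting[bc$category == "stable"], 0.5)
  expect_equal(bc$frac_stationary[bc$category == "stable"], 0)
})

test_that("motion raster lays out tracks by interval", {
  tr <- tracks_from_lengths(list(
    list(frames = 1:4, lengths = c(5, 6, 6, 5)),
    list(frames = 2:4, lengths = c(3, 3, 3))
  ), n_frames = 4)
  m <- motion_raster(tr)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(m[1, ], c(1L, 0L, -1L), ignore_attr = TRUE)
  expect_true(is.na(m[2, 1]))
  expect_equal(m[2, 2:3], c(0L, 0L), ignore_attr = TRUE)
})
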