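# Fixture builders shared across the test files. Everything is generated in
# code; no binary fixtures.

# quick node-table constructor: m is a matrix-like of rows
# (node_id, structure, x, y, z, radius, parent_id)
node_df <- function(...) {
  m <- rbind(...)
  data.frame(node_id = as.integer(m[, 1]), structure = as.integer(m[, 2]),
             x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
             parent_id = as.integer(m[, 7]))
}

# a chain frame along given 3-D points, uniform radius
chain_frame <- function(pts, radius = 0.5, structure = 3L, time = 0) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  skeleton_frame(data.frame(
    node_id = seq_len(n), structure = structure,
    x = pts[, 1], y = pts[, 2], z = pts[, 3], radius = radius,
    parent_id = c(-1L, seq_len(n - 1L))
  ), time = time)
}

# random valid skeleton tree: node i's parent is uniform among 1..(i-1)
random_tree_frame <- function(n = 20, seed = 1, spread = 10, time = 0) {
  set.seed(seed)
  parent <- c(-1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  skeleton_frame(data.frame(
    node_id = seq_len(n), structure = 3L,
    x = runif(n, -spread, spread), y = runif(n, -spread, spread),
    z = runif(n, -spread, spread), radius = runif(n, 0.1, 1),
    parent_id = parent
  ), time = time)
}

# write SWC text lines to a temp file, return the path
swc_tmp <- function(lines) {
  path <- tempfile(fileext = ".swc")
  writeLines(lines, path)
  path
}

# a series of identical static frames at the given cadence
static_series <- function(frame, n = 10, dt = 20) {
  frames <- lapply(seq_len(n) - 1L, function(i) {
    f <- frame
    f$time <- i * dt
    f
  })
  skeleton_series(frames)
}

# canonical frame used in direction tests: one segment per direction with
# controllable extents, hanging off a typed main process
four_arm_frame <- function(extents = c(DL = 10, DM = 8, VM = 6, VL = 4),
                           radius = 0.3, time = 0) {
  axes <- rbind(DL = c(1, 0, 0), DM = c(0, 1, 0),
                VM = c(-1, 0, 0), VL = c(0, -1, 0))
  base <- node_df(
    c(1, 1, 0, 0, -20, 2, -1),
    c(2, 2, 0, 0, -10, 0.6, 1),
    c(3, 2, 0, 0, 0, 0.6, 2)
  )
  rows <- list(base)
  nid <- 3L
  for (d in names(extents)) {
    if (extents[[d]] <= 0) next
    tip <- axes[d, ] * extents[[d]]
    rows[[length(rows) + 1L]] <- node_df(
      c(nid + 1, 3, tip[1], tip[2], tip[3], radius, 3)
    )
    nid <- nid + 1L
  }
  skeleton_frame(do.call(rbind, rows), time = time)
}

# independent sector oracle via atan2 (degrees measured from DL towards DM)
sector_oracle <- function(points, dframe) {
  v <- sweep(as.matrix(points), 2, dframe$origin)
  pdl <- drop(v %*% dframe$axis_dl)
  pdm <- drop(v %*% dframe$axis_dm)
  theta <- (atan2(pdm, pdl) * 180 / pi) %% 360
  ifelse(theta >= 315 | theta < 45, "DL",
         ifelse(theta < 135, "DM", ifelse(theta < 225, "VM", "VL")))
}

# brute-force four-case category rule on a contiguous presence mask
category_oracle <- function(mask) {
  n <- length(mask)
  first <- which(mask)[1]
  last <- rev(which(mask))[1]
  if (first == 1 && last == n) return("stable")
  if (first > 1 && last == n) return("emerging")
  if (first == 1 && last < n) return("retracting")
  "transient"
}

# build a minimal track table from a list of per-track (frames, lengths)
tracks_from_lengths <- function(spec, dt = 0.5, n_frames = NULL) {
  rows <- lapply(seq_along(spec), function(k) {
    s <- spec[[k]]
    data.frame(track_id = k, frame = s$frames,
               time_min = (s$frames - 1) * dt,
               tip_id = s$frames, tip_x = 0, tip_y = 0, tip_z = 0,
               path_length = s$lengths,
               sector = factor(if (is.null(s$sector)) "DL" else s$sector,
                               levels = c("DL", "DM", "VM", "VL")))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_frames") <- if (is.null(n_frames)) max(out$frame) else n_frames
  out
}
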