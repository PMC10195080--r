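#' Antennal-lobe direction frame
#'
#' The coordinate frame in which dendritic mass is partitioned into the four
#' directional sectors DL (dorsolateral), DM (dorsomedial), VM (ventromedial)
#' and VL (ventrolateral). The frame is anchored at an apex (by default the
#' point where the neuron's main process enters the neuropil), with two
#' orthonormal in-plane axes; the anterior axis is their cross product.
#' Sectors live in the frontal DL-DM plane: points are projected onto it
#' before the angular assignment.
#'
#' @param origin 3-vector, micrometres: sector apex.
#' @param axis_dl unit 3-vector pointing dorsolaterally.
#' @param axis_dm unit 3-vector pointing dorsomedially; must be orthogonal to
#'   `axis_dl` (both checked to 1e-9).
#' @return an object of class `direction_frame`.
#' @export
direction_frame <- function(origin = c(0, 0, 0),
                            axis_dl = c(1, 0, 0),
                            axis_dm = c(0, 1, 0)) {
  origin <- as.numeric(origin); axis_dl <- as.numeric(axis_dl)
  axis_dm <- as.numeric(axis_dm)
  stopifnot(length(origin) == 3L, length(axis_dl) == 3L, length(axis_dm) == 3L)
  if (abs(sqrt(sum(axis_dl^2)) - 1) > 1e-9 ||
      abs(sqrt(sum(axis_dm^2)) - 1) > 1e-9) {
    stop("direction axes must be unit length (within 1e-9)")
  }
  if (abs(sum(axis_dl * axis_dm)) > 1e-9) {
    stop("axis_DL and axis_DM must be orthogonal (within 1e-9)")
  }
  axis_ant <- c(axis_dl[2] * axis_dm[3] - axis_dl[3] * axis_dm[2],
                axis_dl[3] * axis_dm[1] - axis_dl[1] * axis_dm[3],
                axis_dl[1] * axis_dm[2] - axis_dl[2] * axis_dm[1])
  structure(list(origin = origin, axis_dl = axis_dl, axis_dm = axis_dm,
                 axis_ant = axis_ant),
            class = "direction_frame")
}

#' @export
print.direction_frame <- function(x, ...) {
  cat("<direction_frame> origin (", paste(signif(x$origin, 4), collapse = ", "),
      ") um\n", sep = "")
  invisible(x)
}

#' Write/read a direction frame as JSON
#'
#' Serializes `origin`, `axis_dl` and `axis_dm`; the anterior axis is always
#' re-derived as the cross product on read.
#' @param dframe a [direction_frame()].
#' @param path file path.
#' @return `write_direction_frame` returns `path` invisibly;
#'   `read_direction_frame` a [direction_frame()].
#' @export
write_direction_frame <- function(dframe, path) {
  stopifnot(inherits(dframe, "direction_frame"))
  jsonlite::write_json(
    list(origin = dframe$origin, axis_dl = dframe$axis_dl,
         axis_dm = dframe$axis_dm),
    path, digits = NA
  )
  invisible(path)
}

#' @rdname write_direction_frame
#' @export
read_direction_frame <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  direction_frame(x$origin, x$axis_dl, x$axis_dm)
}

#' Assign points to directional sectors
#'
#' Each point is projected onto the DL-DM plane of the frame; the sector is
#' determined by the in-plane angle theta measured from the DL axis rotating
#' towards DM: DL for theta in \[315, 45), DM in \[45, 135), VM in \[135, 225),
#' VL in \[225, 315) (half-open, degrees). VM is thus antiparallel to DL and
#' VL antiparallel to DM. The assignment is implemented by sign/magnitude
#' comparisons of the two projections, not by explicit angles, so boundary
#' ties are exact.
#'
#' @param points numeric matrix (n x 3) or a 3-vector, micrometres.
#' @param dframe a [direction_frame()].
#' @return factor of sector labels with levels `DL, DM, VM, VL`.
#' @export
assign_sector <- function(points, dframe) {
  stopifnot(inherits(dframe, "direction_frame"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  points <- as.matrix(points)
  v <- sweep(points, 2L, dframe$origin)
  pdl <- drop(v %*% dframe$axis_dl)
  pdm <- drop(v %*% dframe$axis_dm)
  r <- sqrt(pdl^2 + pdm^2)
  if (any(r < 1e-9)) {
    stop("degenerate point: in-plane projection within 1e-9 um of the origin")
  }
  lab <- character(length(pdl))
  lab[pdl > 0 & pdm < pdl & pdm >= -pdl] <- "DL"
  lab[pdm > 0 & pdl <= pdm & pdl > -pdm] <- "DM"
  lab[pdl < 0 & pdm <= -pdl & pdm > pdl] <- "VM"
  lab[pdm < 0 & pdl >= pdm & pdl < -pdm] <- "VL"
  factor(lab, levels = DIRECTIONS)
}

# ---- edge table -------------------------------------------------------------

# One row per parent->child edge: endpoints, radii, length, frustum volume,
# midpoint. The frustum volume of an edge of length L with end radii ra, rb is
# (pi/3) L (ra^2 + ra rb + rb^2), the standard SWC cable-volume proxy.
edge_table <- function(frame) {
  n <- frame$nodes
  child <- which(n$parent_id != -1L)
  pidx <- match(n$parent_id[child], n$node_id)
  a <- as.matrix(n[pidx, c("x", "y", "z")])
  b <- as.matrix(n[child, c("x", "y", "z")])
  len <- sqrt(rowSums((b - a)^2))
  ra <- n$radius[pidx]; rb <- n$radius[child]
  data.frame(
    child_id = n$node_id[child], parent_id = n$node_id[pidx],
    ax = a[, 1L], ay = a[, 2L], az = a[, 3L],
    bx = b[, 1L], by = b[, 2L], bz = b[, 3L],
    r_a = ra, r_b = rb, length = len,
    volume = (pi / 3) * len * (ra^2 + ra * rb + rb^2),
    mx = (a[, 1L] + b[, 1L]) / 2, my = (a[, 2L] + b[, 2L]) / 2,
    mz = (a[, 3L] + b[, 3L]) / 2,
    child_structure = n$structure[child]
  )
}

# Nodes on the main process: the path from the soma to the node nearest the
# frame origin (the neuropil entry point). Returned as node ids.
main_process_path <- function(frame, dframe) {
  n <- frame$nodes
  d2 <- (n$x - dframe$origin[1])^2 + (n$y - dframe$origin[2])^2 +
    (n$z - dframe$origin[3])^2
  entry <- n$node_id[which.min(d2)]
  path <- integer(0)
  cur <- entry
  repeat {
    path <- c(path, cur)
    p <- n$parent_id[match(cur, n$node_id)]
    if (p == -1L) break
    cur <- p
  }
  path
}

# Edge table restricted to dendritic cable. Drops edges whose child is
# soma/axon-typed (structure 1 or 2) and, when a direction frame is given,
# edges along the soma-to-entry main-process path.
dendrite_edges <- function(frame, dframe = NULL, exclude_axon = TRUE) {
  e <- edge_table(frame)
  if (!exclude_axon) return(e)
  keep <- !(e$child_structure %in% c(1L, 2L))
  if (!is.null(dframe)) {
    main <- main_process_path(frame, dframe)
    keep <- keep & !(e$child_id %in% main)
  }
  e[keep, , drop = FALSE]
}

# Dendritic node positions (matrix) under the same exclusion rule.
dendrite_points <- function(frame, dframe = NULL, exclude_axon = TRUE) {
  n <- frame$nodes
  keep <- rep(TRUE, nrow(n))
  if (exclude_axon) {
    keep <- !(n$structure %in% c(1L, 2L))
    if (!is.null(dframe)) {
      keep <- keep & !(n$node_id %in% main_process_path(frame, dframe))
    }
  }
  as.matrix(n[keep, c("x", "y", "z"), drop = FALSE])
}

#' Total cable length and frustum volume of a frame
#'
#' Sums Euclidean edge lengths and per-edge conical-frustum volumes
#' \eqn{(\pi/3) L (r_a^2 + r_a r_b + r_b^2)} over all edges. Used as the
#' skeleton-based proxy for dendritic volume.
#'
#' @param frame a [skeleton_frame()].
#' @return list with `length` (um) and `volume` (um^3).
#' @export
cable_metrics <- function(frame) {
  e <- edge_table(frame)
  list(length = sum(e$length), volume = sum(e$volume))
}

#' Exploring volume (convex hull) of a dendritic arbor
#'
#' Volume of the 3-D convex hull of the dendrite node positions — a measure
#' of the territory the arbor surveys. Fewer than four points, or a
#' degenerate (coplanar/collinear) set, yields 0 with a warning rather than
#' an error.
#'
#' @param frame a [skeleton_frame()].
#' @param exclude_axon drop soma- and axon-typed nodes (structure 1 or 2)
#'   before the hull; default `TRUE`.
#' @return hull volume in um^3.
#' @export
exploring_volume <- function(frame, exclude_axon = TRUE) {
  pts <- dendrite_points(frame, dframe = NULL, exclude_axon = exclude_axon)
  convex_hull_volume(pts)
}

#' Convex hull volume of a 3-D point set
#'
#' Incremental convex hull: seeds a non-degenerate tetrahedron, then inserts
#' each remaining point, replacing the faces it sees with a fan over the
#' horizon edges. The volume is the sum of signed tetrahedra from an interior
#' point. Degenerate inputs (under 4 points, or all points within `tol` of a
#' plane) return 0 with a warning.
#'
#' @param pts numeric matrix (n x 3).
#' @param tol degeneracy tolerance on signed volumes.
#' @return volume.
#' @export
convex_hull_volume <- function(pts, tol = 1e-9) {
  pts <- unique(as.matrix(pts))
  if (nrow(pts) < 4L) {
    warning("fewer than 4 distinct points: hull volume 0")
    return(0)
  }
  orient <- function(a, b, c, d) {
    u <- b - a; v <- c - a; w <- d - a
    u[1] * (v[2] * w[3] - v[3] * w[2]) -
      u[2] * (v[1] * w[3] - v[3] * w[1]) +
      u[3] * (v[1] * w[2] - v[2] * w[1])
  }
  n <- nrow(pts)
  # seed tetrahedron: two extreme points, then the point farthest from their
  # line, then the point farthest from their plane
  i1 <- which.min(pts[, 1L]); i2 <- which.max(pts[, 1L])
  if (i1 == i2) i2 <- which.max(rowSums(sweep(pts, 2L, pts[i1, ])^2))
  ab <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2L, pts[i1, ])
  cr <- cbind(rel[, 2L] * ab[3L] - rel[, 3L] * ab[2L],
              rel[, 3L] * ab[1L] - rel[, 1L] * ab[3L],
              rel[, 1L] * ab[2L] - rel[, 2L] * ab[1L])
  i3 <- which.max(rowSums(cr^2))
  vols <- vapply(seq_len(n), function(i) {
    orient(pts[i1, ], pts[i2, ], pts[i3, ], pts[i, ])
  }, numeric(1))
  i4 <- which.max(abs(vols))
  if (abs(vols[i4]) <= tol) {
    warning("degenerate (coplanar or collinear) point set: hull volume 0")
    return(0)
  }
  # faces stored as index triples oriented outward: the interior point lies
  # on the negative side of every face
  interior <- colMeans(pts[c(i1, i2, i3, i4), , drop = FALSE])
  orient_face <- function(f) {
    if (orient(pts[f[1L], ], pts[f[2L], ], pts[f[3L], ], interior) > 0) {
      f[c(1L, 3L, 2L)]
    } else f
  }
  faces <- lapply(list(c(i1, i2, i3), c(i1, i4, i2), c(i2, i4, i3),
                       c(i3, i4, i1)), orient_face)
  for (p in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    vis <- vapply(faces, function(f) {
      orient(pts[f[1L], ], pts[f[2L], ], pts[f[3L], ], pts[p, ]) > tol
    }, logical(1))
    if (!any(vis)) next
    # horizon: edges of visible faces shared with an invisible face
    edges_of <- function(f) list(f[c(1L, 2L)], f[c(2L, 3L)], f[c(3L, 1L)])
    vis_edges <- do.call(c, lapply(faces[vis], edges_of))
    keys <- vapply(vis_edges, function(e) {
      paste(sort(e), collapse = "_")
    }, character(1))
    # an edge appearing once among the visible faces is on the horizon
    horizon <- vis_edges[table(keys)[keys] == 1L]
    faces <- faces[!vis]
    for (e in horizon) {
      faces[[length(faces) + 1L]] <- orient_face(c(e[1L], e[2L], p))
    }
  }
  vol <- 0
  for (f in faces) {
    vol <- vol + abs(orient(interior, pts[f[1L], ], pts[f[2L], ], pts[f[3L], ]))
  }
  unname(vol / 6)
}

#' Number of terminal branches in a frame
#'
#' Terminal branches end at the skeleton's leaves: nodes of degree 1 that are
#' not the root.
#'
#' @param frame a [skeleton_frame()].
#' @return integer count.
#' @export
count_terminal_branches <- function(frame) {
  n <- frame$nodes
  has_child <- n$node_id %in% n$parent_id
  sum(!has_child & n$parent_id != -1L)
}

#' Frustum-volume-weighted centre of dendritic mass
#'
#' Weighted centroid of edge midpoints, with each edge weighted by its
#' frustum volume. With uniform radii this reduces to the length-weighted
#' centroid; if all volumes are zero (zero-radius tracing) lengths are used.
#'
#' @param frame a [skeleton_frame()].
#' @param node_ids optional subset: only edges whose child node is in this
#'   set contribute.
#' @return 3-vector, micrometres.
#' @export
mass_center <- function(frame, node_ids = NULL) {
  e <- edge_table(frame)
  if (!is.null(node_ids)) e <- e[e$child_id %in% node_ids, , drop = FALSE]
  if (nrow(e) == 0L) stop("empty subset: no edges to average")
  w <- e$volume
  if (sum(w) <= 0) w <- e$length
  if (sum(w) <= 0) w <- rep(1, nrow(e))
  c(sum(w * e$mx), sum(w * e$my), sum(w * e$mz)) / sum(w)
}

# Rasterize a frame's cable length onto an integer voxel grid anchored at
# `anchor`. Segments are split into pieces no longer than voxel/2; each piece
# deposits its length in the voxel containing its midpoint. Returns a named
# numeric vector: names are "i_j_k" voxel keys, values summed cable length.
rasterize_cable <- function(frame, voxel, anchor) {
  e <- edge_table(frame)
  keys <- character(0); lens <- numeric(0)
  for (i in seq_len(nrow(e))) {
    L <- e$length[i]
    if (L == 0) next
    k <- max(1L, ceiling(L / (voxel / 2)))
    t_mid <- (seq_len(k) - 0.5) / k
    px <- e$ax[i] + t_mid * (e$bx[i] - e$ax[i])
    py <- e$ay[i] + t_mid * (e$by[i] - e$ay[i])
    pz <- e$az[i] + t_mid * (e$bz[i] - e$az[i])
    keys <- c(keys, paste(floor((px - anchor[1]) / voxel),
                          floor((py - anchor[2]) / voxel),
                          floor((pz - anchor[3]) / voxel), sep = "_"))
    lens <- c(lens, rep(L / k, k))
  }
  if (!length(keys)) return(numeric(0))
  tapply(lens, keys, sum)
}

# Voxel keys holding the top `quantile` fraction of an arbor's cable length
# (greedy from the densest voxel down).
core_voxels <- function(density, quantile) {
  if (!length(density)) stop("empty core: arbor has no cable")
  d <- sort(density, decreasing = TRUE)
  cum <- cumsum(d) / sum(d)
  k <- which(cum >= quantile)[1L]
  names(d)[seq_len(k)]
}

#' Overlap of two arbors' core targeting regions
#'
#' Both arbors' cable lengths are rasterized into one shared voxel grid. The
#' "core" of each arbor is the smallest set of voxels (densest first) holding
#' at least `density_quantile` of its total cable length. The overlap is
#' `|core_a intersect core_b| / min(|core_a|, |core_b|)`, in \[0, 1\].
#'
#' @param frame_a,frame_b [skeleton_frame()] objects in a shared coordinate
#'   system.
#' @param voxel voxel edge length, micrometres (default 1).
#' @param density_quantile fraction of cable length defining the core
#'   (default 0.5).
#' @return overlap fraction.
#' @export
core_overlap <- function(frame_a, frame_b, voxel = 1, density_quantile = 0.5) {
  stopifnot(voxel > 0, density_quantile > 0, density_quantile < 1)
  pa <- as.matrix(frame_a$nodes[, c("x", "y", "z")])
  pb <- as.matrix(frame_b$nodes[, c("x", "y", "z")])
  anchor <- apply(rbind(pa, pb), 2L, min)
  da <- rasterize_cable(frame_a, voxel, anchor)
  db <- rasterize_cable(frame_b, voxel, anchor)
  ca <- core_voxels(da, density_quantile)
  cb <- core_voxels(db, density_quantile)
  length(intersect(ca, cb)) / min(length(ca), length(cb))
}
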