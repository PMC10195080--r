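#' @keywords internal
"_PACKAGE"

DIRECTIONS <- c("DL", "DM", "VM", "VL")

#' Construct a skeleton frame
#'
#' A skeleton frame is one traced arbor at one time point: a rooted tree of
#' nodes with 3-D positions (micrometres) and radii, as produced by neurite
#' tracing tools in SWC form. Structural validity (unique ids, a single root,
#' connectivity, acyclicity, non-negative radii) is enforced at construction.
#'
#' @param nodes data.frame with columns `node_id`, `structure`, `x`, `y`, `z`,
#'   `radius`, `parent_id`. `parent_id` is -1 for the root. `structure` is the
#'   SWC type column (1 soma, 2 axon/main process, 3+ dendrite); it is carried
#'   through unmodified and only consulted when excluding non-dendritic cable.
#' @param time acquisition time in minutes since series start.
#' @return an object of class `skeleton_frame` with elements `nodes`, `time`
#'   and `soma_id` (the root's node id).
#' @export
skeleton_frame <- function(nodes, time = 0) {
  required <- c("node_id", "structure", "x", "y", "z", "radius", "parent_id")
  if (!is.data.frame(nodes) || !all(required %in% names(nodes))) {
    stop("`nodes` must be a data.frame with columns: ",
         paste(required, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[, required]
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$structure <- as.integer(nodes$structure)
  nodes$parent_id <- as.integer(nodes$parent_id)
  for (col in c("x", "y", "z", "radius")) nodes[[col]] <- as.numeric(nodes[[col]])
  validate_skeleton_nodes(nodes)
  structure(
    list(nodes = nodes, time = as.numeric(time),
         soma_id = nodes$node_id[nodes$parent_id == -1L]),
    class = "skeleton_frame"
  )
}

validate_skeleton_nodes <- function(nodes) {
  if (nrow(nodes) == 0L) stop("structural error: frame has no nodes")
  if (anyNA(nodes)) stop("structural error: NA values in node table")
  if (any(nodes$node_id <= 0L)) stop("structural error: node_id must be positive")
  if (anyDuplicated(nodes$node_id)) {
    stop("structural error: duplicate node_id ",
         nodes$node_id[duplicated(nodes$node_id)][1L])
  }
  if (any(nodes$radius < 0)) stop("structural error: negative radius")
  roots <- which(nodes$parent_id == -1L)
  if (length(roots) == 0L) stop("structural error: no root (parent_id -1) found")
  if (length(roots) > 1L) {
    stop("structural error: multiple roots (nodes ",
         paste(nodes$node_id[roots], collapse = ", "), ")")
  }
  idx <- match(nodes$parent_id, nodes$node_id)
  dangling <- nodes$parent_id != -1L & is.na(idx)
  if (any(dangling)) {
    stop("structural error: node ", nodes$node_id[which(dangling)[1L]],
         " has dangling parent_id ", nodes$parent_id[which(dangling)[1L]])
  }
  if (any(nodes$parent_id == nodes$node_id)) {
    stop("structural error: node is its own parent")
  }
  # connectivity / acyclicity: BFS from the root over child lists
  n <- nrow(nodes)
  children <- split(seq_len(n)[nodes$parent_id != -1L],
                    idx[nodes$parent_id != -1L])
  visited <- logical(n)
  queue <- roots
  while (length(queue)) {
    visited[queue] <- TRUE
    queue <- unlist(children[as.character(queue)], use.names = FALSE)
    if (any(visited[queue])) stop("structural error: cycle detected")
  }
  if (!all(visited)) {
    stop("structural error: frame is disconnected (node ",
         nodes$node_id[which(!visited)[1L]], " unreachable from root)")
  }
  invisible(nodes)
}

#' @export
print.skeleton_frame <- function(x, ...) {
  cat("<skeleton_frame> ", nrow(x$nodes), " nodes, t = ", x$time,
      " min, root = ", x$soma_id, "\n", sep = "")
  invisible(x)
}

#' Read an SWC morphology file
#'
#' Parses standard whitespace-delimited 7-column SWC
#' (id, type, x, y, z, radius, parent), with `#` comment lines allowed.
#' Node order is preserved. Coordinates are interpreted as micrometres.
#'
#' @param path path to an SWC file.
#' @param time acquisition time (minutes) to attach to the frame.
#' @return a [skeleton_frame()].
#' @export
read_swc <- function(path, time = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("parse error: no data lines in ", path)
  fields <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    bad <- which(nf != 7L)[1L]
    stop("parse error at line ", keep[bad], " of ", path,
         ": expected 7 whitespace-delimited columns, found ", nf[bad])
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))[1L]
    stop("parse error at line ", keep[bad], " of ", path,
         ": non-numeric field")
  }
  nodes <- data.frame(
    node_id = as.integer(m[, 1L]), structure = as.integer(m[, 2L]),
    x = m[, 3L], y = m[, 4L], z = m[, 5L], radius = m[, 6L],
    parent_id = as.integer(m[, 7L])
  )
  skeleton_frame(nodes, time = time)
}

#' Write a skeleton frame to SWC
#'
#' Writes the standard 7 columns in stored node order, values at full
#' precision and without any clamping, so that read/write round-trips are
#' structurally exact.
#'
#' @param frame a [skeleton_frame()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_swc <- function(frame, path) {
  stopifnot(inherits(frame, "skeleton_frame"))
  n <- frame$nodes
  num <- function(v) {
    out <- formatC(v, format = "g", digits = 15)
    trimws(out)
  }
  rows <- paste(n$node_id, n$structure, num(n$x), num(n$y), num(n$z),
                num(n$radius), n$parent_id)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(rows, con)
  invisible(path)
}

#' Construct a skeleton time series
#'
#' An ordered sequence of skeleton frames sharing one coordinate system.
#' Missing frames (gaps in acquisition) are represented explicitly: they keep
#' their time slot but carry no frame, and downstream event detection never
#' spans them. The cadence class is inferred from the median inter-frame
#' interval: at most 1 minute means a branch-scale (fast) recording, anything
#' longer a bulk-scale recording.
#'
#' @param frames list of [skeleton_frame()] objects, or `NULL` entries for
#'   missing frames (then `times` must be supplied).
#' @param times frame times in minutes; defaults to the frames' own times.
#' @param missing logical vector flagging missing frames.
#' @param frame_kind `"branch"` or `"bulk"`; inferred from cadence if `NULL`.
#' @return an object of class `skeleton_series`.
#' @export
skeleton_series <- function(frames, times = NULL, missing = NULL,
                            frame_kind = NULL) {
  if (is.null(times)) {
    times <- vapply(frames, function(f) {
      if (is.null(f)) NA_real_ else f$time
    }, numeric(1))
  }
  times <- as.numeric(times)
  if (is.null(missing)) missing <- vapply(frames, is.null, logical(1))
  if (anyNA(times)) stop("missing frames must be given explicit times")
  if (length(frames) != length(times) || length(missing) != length(times)) {
    stop("frames, times and missing must have equal length")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  present_bad <- which(missing & !vapply(frames, is.null, logical(1)))
  if (length(present_bad)) stop("frame flagged missing but supplied")
  intervals <- diff(times)
  nominal <- stats::median(intervals)
  if (is.null(frame_kind)) {
    frame_kind <- if (isTRUE(nominal <= 1)) "branch" else "bulk"
  }
  frame_kind <- match.arg(frame_kind, c("branch", "bulk"))
  if (length(intervals)) {
    # tolerate 10% jitter around the nominal cadence next to present frames
    off <- abs(intervals - nominal) / nominal > 0.1
    gap_ok <- missing[-length(missing)] | missing[-1L]
    if (any(off & !gap_ok)) {
      stop("irregular cadence: interval ", which(off & !gap_ok)[1L],
           " deviates from the nominal ", signif(nominal, 4),
           " min by more than 10% and is not flagged missing")
    }
  }
  structure(
    list(frames = frames, times = times, missing = missing,
         frame_interval = nominal, frame_kind = frame_kind),
    class = "skeleton_series"
  )
}

#' @export
print.skeleton_series <- function(x, ...) {
  cat("<skeleton_series> ", length(x$frames), " frames (",
      sum(x$missing), " missing), ", x$frame_kind, " cadence, interval ",
      signif(x$frame_interval, 4), " min\n", sep = "")
  invisible(x)
}

#' @export
length.skeleton_series <- function(x) length(x$frames)

#' Read a skeleton time series from a manifest
#'
#' The manifest is a CSV with columns `path` (SWC file, relative to the
#' manifest's directory), `time_min` (acquisition time in minutes; a
#' `time_s` column in seconds is accepted instead and converted at this
#' boundary) and optionally `missing` (0/1). Frames are loaded in time order.
#'
#' @param manifest path to the manifest CSV.
#' @param frame_kind optional override of the inferred cadence class.
#' @return a [skeleton_series()].
#' @export
read_series <- function(manifest, frame_kind = NULL) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!"time_min" %in% names(tab)) {
    if ("time_s" %in% names(tab)) {
      tab$time_min <- tab$time_s / 60
    } else {
      stop("manifest must have a time_min (or time_s) column")
    }
  }
  if (!"path" %in% names(tab)) stop("manifest must have a path column")
  if (!"missing" %in% names(tab)) tab$missing <- 0L
  tab$missing <- as.logical(tab$missing)
  if (any(diff(tab$time_min) <= 0)) {
    stop("manifest times are not strictly increasing")
  }
  base <- dirname(manifest)
  frames <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (tab$missing[i]) next
    p <- file.path(base, tab$path[i])
    if (!file.exists(p)) {
      stop("frame file not found and not flagged missing: ", tab$path[i])
    }
    frames[[i]] <- read_swc(p, time = tab$time_min[i])
  }
  skeleton_series(frames, times = tab$time_min, missing = tab$missing,
                  frame_kind = frame_kind)
}

#' Write a skeleton series as SWC files plus a manifest
#'
#' Emits `frame_%04d.swc` per present frame and a `manifest.csv` in the same
#' layout [read_series()] consumes. Output is byte-deterministic for a given
#' series.
#'
#' @param series a [skeleton_series()].
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest path.
#' @export
write_series <- function(series, dir) {
  stopifnot(inherits(series, "skeleton_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(series$frames)
  paths <- sprintf("frame_%04d.swc", seq_len(n))
  for (i in seq_len(n)) {
    if (!series$missing[i]) write_swc(series$frames[[i]], file.path(dir, paths[i]))
  }
  man <- data.frame(path = paths, time_min = series$times,
                    missing = as.integer(series$missing))
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
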