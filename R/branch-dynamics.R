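#' Extract terminal branches from a frame
#'
#' A terminal branch runs from a leaf tip back to the nearest node of degree
#' at least 3 (a branch point) or to the root, junction included. Its path
#' length is the summed edge length along that walk. Branches near the main
#' process are typically too dense to resolve in vivo; terminal branches are
#' the unit of all branch-level dynamics here.
#'
#' @param frame a [skeleton_frame()].
#' @param dframe optional [direction_frame()]; if given, each branch's tip
#'   sector is attached.
#' @return data.frame with one row per leaf: `tip_id`, `tip_x/y/z`,
#'   `path_length`, `n_nodes`, `base_id` (the junction node), `sector`
#'   (factor or `NA` without `dframe`), and a list column `node_ids` (tip
#'   first, junction last).
#' @export
extract_terminals <- function(frame, dframe = NULL) {
  n <- frame$nodes
  nchild <- table(factor(n$parent_id, levels = n$node_id))
  degree_high <- n$node_id[nchild >= 2L]  # junctions: >= 2 children
  # a bare main-process end (soma/axon-typed leaf) is not a dendritic branch
  leaves <- n$node_id[nchild == 0L & n$parent_id != -1L &
                        !(n$structure %in% c(1L, 2L))]
  idx <- match(n$node_id, n$node_id)  # identity; positions by id below
  pos <- function(id) match(id, n$node_id)
  out <- vector("list", length(leaves))
  for (k in seq_along(leaves)) {
    cur <- leaves[k]
    path <- cur
    len <- 0
    repeat {
      p <- n$parent_id[pos(cur)]
      if (p == -1L) break
      len <- len + sqrt((n$x[pos(cur)] - n$x[pos(p)])^2 +
                          (n$y[pos(cur)] - n$y[pos(p)])^2 +
                          (n$z[pos(cur)] - n$z[pos(p)])^2)
      path <- c(path, p)
      # stop at a branch point or on reaching the main process (soma/axon)
      if (p %in% degree_high || n$structure[pos(p)] %in% c(1L, 2L)) break
      cur <- p
    }
    tp <- pos(leaves[k])
    out[[k]] <- list(tip_id = leaves[k], tip_x = n$x[tp], tip_y = n$y[tp],
                     tip_z = n$z[tp], path_length = len,
                     n_nodes = length(path), base_id = path[length(path)],
                     node_ids = path)
  }
  res <- data.frame(
    tip_id = vapply(out, `[[`, integer(1), "tip_id"),
    tip_x = vapply(out, `[[`, numeric(1), "tip_x"),
    tip_y = vapply(out, `[[`, numeric(1), "tip_y"),
    tip_z = vapply(out, `[[`, numeric(1), "tip_z"),
    path_length = vapply(out, `[[`, numeric(1), "path_length"),
    n_nodes = vapply(out, `[[`, integer(1), "n_nodes"),
    base_id = vapply(out, `[[`, integer(1), "base_id")
  )
  res$node_ids <- lapply(out, `[[`, "node_ids")
  if (!is.null(dframe) && nrow(res)) {
    res$sector <- assign_sector(cbind(res$tip_x, res$tip_y, res$tip_z), dframe)
  } else {
    res$sector <- factor(rep(NA_character_, nrow(res)), levels = DIRECTIONS)
  }
  res
}

#' Track terminal branches across a fast time series
#'
#' Links branch tips between consecutive present frames by greedy nearest-
#' neighbour matching: candidate pairs within `match_gate` micrometres are
#' accepted in order of increasing distance (ties broken by smaller previous
#' then smaller new tip node id). Unmatched old tips close their track;
#' unmatched new tips open new tracks; a track never resurrects after an
#' absence, and no matching is attempted across a missing frame.
#'
#' The default 3-um gate comfortably exceeds one frame interval of tip travel
#' at the ~1.5 um/min speeds typical of developing terminal branches sampled
#' every 30 s.
#'
#' @param series a branch-cadence [skeleton_series()].
#' @param params an [analysis_params()].
#' @param dframe optional [direction_frame()] for per-observation sectors.
#' @return data.frame (one row per track x present frame): `track_id`,
#'   `frame`, `time_min`, `tip_id`, `tip_x/y/z`, `path_length`, `sector`.
#' @export
track_terminals <- function(series, params = analysis_params(),
                            dframe = NULL) {
  stopifnot(inherits(series, "skeleton_series"))
  gate <- params$match_gate
  rows <- list()
  next_track <- 1L
  prev <- NULL  # data.frame of previous frame's terminals with track ids
  for (i in seq_along(series$frames)) {
    if (series$missing[i]) { prev <- NULL; next }
    term <- extract_terminals(series$frames[[i]], dframe)
    term$track_id <- rep(NA_integer_, nrow(term))
    if (!is.null(prev) && nrow(prev) && nrow(term)) {
      dx <- outer(prev$tip_x, term$tip_x, "-")
      dy <- outer(prev$tip_y, term$tip_y, "-")
      dz <- outer(prev$tip_z, term$tip_z, "-")
      d <- sqrt(dx^2 + dy^2 + dz^2)
      cand <- which(d <= gate, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(d[cand], prev$tip_id[cand[, 1L]], term$tip_id[cand[, 2L]])
        cand <- cand[ord, , drop = FALSE]
        used_prev <- logical(nrow(prev)); used_new <- logical(nrow(term))
        for (r in seq_len(nrow(cand))) {
          pi_ <- cand[r, 1L]; ni_ <- cand[r, 2L]
          if (used_prev[pi_] || used_new[ni_]) next
          used_prev[pi_] <- TRUE; used_new[ni_] <- TRUE
          term$track_id[ni_] <- prev$track_id[pi_]
        }
      }
    }
    fresh <- which(is.na(term$track_id))
    if (length(fresh)) {
      term$track_id[fresh] <- seq.int(next_track, length.out = length(fresh))
      next_track <- next_track + length(fresh)
    }
    if (nrow(term)) {
      rows[[i]] <- data.frame(
        track_id = term$track_id, frame = i, time_min = series$times[i],
        tip_id = term$tip_id, tip_x = term$tip_x, tip_y = term$tip_y,
        tip_z = term$tip_z, path_length = term$path_length,
        sector = term$sector
      )
    }
    prev <- term
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(track_id = integer(), frame = integer(), time_min = numeric(),
               tip_id = integer(), tip_x = numeric(), tip_y = numeric(),
               tip_z = numeric(), path_length = numeric(),
               sector = factor(character(), levels = DIRECTIONS))
  }
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  attr(out, "n_frames") <- length(series$frames)
  out
}

#' Classify branch tracks into the four lifetime categories
#'
#' Over an observation window of `n_frames` frames, a branch is *stable* if
#' present in every frame; *transient* if it both appeared after the first
#' frame and disappeared before the last; *emerging* if it appeared after the
#' first frame and was still present at the last; *retracting* if present at
#' the first frame but gone before the last. The four categories are
#' exhaustive and mutually exclusive over contiguous presence masks.
#'
#' @param tracks track table from [track_terminals()].
#' @param n_frames length of the observation window (defaults to the track
#'   table's own series length).
#' @return data.frame `track_id`, `first_frame`, `last_frame`, `n_present`,
#'   `category` (factor: stable, transient, emerging, retracting).
#' @export
classify_tracks <- function(tracks, n_frames = attr(tracks, "n_frames")) {
  if (is.null(n_frames)) stop("n_frames must be supplied")
  ids <- unique(tracks$track_id)
  first <- tapply(tracks$frame, tracks$track_id, min)
  last <- tapply(tracks$frame, tracks$track_id, max)
  npres <- tapply(tracks$frame, tracks$track_id, length)
  if (any(npres != last - first + 1)) {
    bad <- names(npres)[npres != last - first + 1][1L]
    stop("track ", bad, " has a non-contiguous presence mask ",
         "(tracker contract violated)")
  }
  first <- first[as.character(ids)]; last <- last[as.character(ids)]
  category <- ifelse(
    first == 1L & last == n_frames, "stable",
    ifelse(first > 1L & last == n_frames, "emerging",
           ifelse(first == 1L & last < n_frames, "retracting", "transient"))
  )
  data.frame(track_id = ids, first_frame = as.integer(first),
             last_frame = as.integer(last),
             n_present = as.integer(npres[as.character(ids)]),
             category = factor(category, levels = c("stable", "transient",
                                                    "emerging", "retracting")))
}

#' Signed tip speeds per track interval
#'
#' For each track and each pair of consecutive present frames, the signed
#' speed is the change in branch path length divided by the elapsed time
#' (um/min); positive speeds are extension, negative retraction.
#'
#' @param tracks track table from [track_terminals()].
#' @return data.frame `track_id`, `from_frame`, `to_frame`, `dt_min`,
#'   `speed` (um/min).
#' @export
tip_speeds <- function(tracks) {
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  g <- split(seq_len(nrow(tracks)), tracks$track_id)
  out <- lapply(g, function(ix) {
    if (length(ix) < 2L) return(NULL)
    i0 <- ix[-length(ix)]; i1 <- ix[-1L]
    data.frame(track_id = tracks$track_id[i0],
               from_frame = tracks$frame[i0], to_frame = tracks$frame[i1],
               dt_min = tracks$time_min[i1] - tracks$time_min[i0],
               speed = (tracks$path_length[i1] - tracks$path_length[i0]) /
                 (tracks$time_min[i1] - tracks$time_min[i0]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(track_id = integer(), from_frame = integer(),
                      to_frame = integer(), dt_min = numeric(),
                      speed = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Label per-interval branch motion
#'
#' An interval is *extending* when the signed speed strictly exceeds the
#' speed threshold, *retracting* when it is strictly below its negative, and
#' *stationary* otherwise (a speed of exactly 0.5 um/min at the default
#' threshold is stationary: "exceeds" is strict).
#'
#' @param speeds numeric vector of signed speeds (um/min), or the data.frame
#'   from [tip_speeds()].
#' @param params an [analysis_params()].
#' @return factor with levels `extending`, `stationary`, `retracting`
#'   (same length as the input speeds; if a data.frame was given, it is
#'   returned with a `motion` column added).
#' @export
label_motion <- function(speeds, params = analysis_params()) {
  thr <- params$speed_threshold
  if (is.data.frame(speeds)) {
    speeds$motion <- label_motion(speeds$speed, params)
    return(speeds)
  }
  lab <- ifelse(speeds > thr, "extending",
                ifelse(speeds < -thr, "retracting", "stationary"))
  factor(lab, levels = c("extending", "stationary", "retracting"))
}

# Modal sector of each track over its present frames (ties -> first level in
# DL, DM, VM, VL order; configurable to the first-frame sector).
track_sectors <- function(tracks, rule = c("modal", "first")) {
  rule <- match.arg(rule)
  g <- split(tracks$sector, tracks$track_id)
  sec <- vapply(g, function(s) {
    s <- s[!is.na(s)]
    if (!length(s)) return(NA_character_)
    if (rule == "first") return(as.character(s[1L]))
    tab <- table(s)
    names(tab)[which.max(tab)]
  }, character(1))
  data.frame(track_id = as.integer(names(g)),
             sector = factor(sec, levels = DIRECTIONS))
}

#' Per-direction and per-category summary of branch dynamics
#'
#' Combines classification, sectors and motion labels into the two summary
#' tables used to compare directions: the per-direction abundance of stable
#' branches (as a percentage of the cell's stable branches) with their mean
#' absolute speed, and the per-category mean fractions of intervals spent
#' extending, retracting and stationary.
#'
#' @param tracks track table from [track_terminals()] (with sectors).
#' @param n_frames observation window length; defaults to the table's own.
#' @param params an [analysis_params()].
#' @param sector_rule how a track's direction is assigned when its tip
#'   wanders across a sector boundary: `"modal"` (default) or `"first"`.
#' @return list with `by_direction` (direction, n_stable, stable_pct,
#'   mean_abs_speed — `NA`, not 0, where a direction has no stable branch),
#'   `by_category` (category, n_tracks, frac_extending, frac_retracting,
#'   frac_stationary) and the per-track table `tracks_summary`.
#' @export
summarize_branch_dynamics <- function(tracks,
                                      n_frames = attr(tracks, "n_frames"),
                                      params = analysis_params(),
                                      sector_rule = "modal") {
  if (!nrow(tracks)) stop("no tracks to summarize")
  cls <- classify_tracks(tracks, n_frames)
  sec <- track_sectors(tracks, sector_rule)
  per_track <- merge(cls, sec, by = "track_id")
  sp <- label_motion(tip_speeds(tracks), params)
  mot <- lapply(split(sp, sp$track_id), function(s) {
    data.frame(track_id = s$track_id[1L],
               mean_abs_speed = mean(abs(s$speed)),
               frac_extending = mean(s$motion == "extending"),
               frac_retracting = mean(s$motion == "retracting"),
               frac_stationary = mean(s$motion == "stationary"))
  })
  mot <- do.call(rbind, mot)
  per_track <- merge(per_track, mot, by = "track_id", all.x = TRUE)

  stable <- per_track[per_track$category == "stable", , drop = FALSE]
  n_stable <- vapply(DIRECTIONS, function(d) {
    sum(stable$sector == d, na.rm = TRUE)
  }, numeric(1))
  by_direction <- data.frame(
    direction = DIRECTIONS,
    n_stable = as.integer(n_stable),
    stable_pct = if (nrow(stable)) 100 * n_stable / nrow(stable) else
      rep(NA_real_, 4L),
    mean_abs_speed = vapply(DIRECTIONS, function(d) {
      v <- stable$mean_abs_speed[stable$sector == d]
      v <- v[!is.na(v)]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  )
  rownames(by_direction) <- NULL
  by_category <- do.call(rbind, lapply(levels(per_track$category), function(k) {
    s <- per_track[per_track$category == k & !is.na(per_track$frac_extending), ]
    data.frame(category = k,
               n_tracks = sum(per_track$category == k),
               frac_extending = if (nrow(s)) mean(s$frac_extending) else NA_real_,
               frac_retracting = if (nrow(s)) mean(s$frac_retracting) else NA_real_,
               frac_stationary = if (nrow(s)) mean(s$frac_stationary) else NA_real_)
  }))
  list(by_direction = by_direction, by_category = by_category,
       tracks_summary = per_track)
}

#' Motion raster matrix
#'
#' Track-by-interval matrix of motion labels (+1 extending, -1 retracting,
#' 0 stationary, NA absent) for kymograph-style plots. Rows are ordered by
#' track id.
#'
#' @param tracks track table from [track_terminals()].
#' @param params an [analysis_params()].
#' @return integer matrix (n_tracks x n_intervals).
#' @export
motion_raster <- function(tracks, params = analysis_params()) {
  n_frames <- attr(tracks, "n_frames")
  if (is.null(n_frames)) n_frames <- max(tracks$frame)
  sp <- label_motion(tip_speeds(tracks), params)
  ids <- sort(unique(tracks$track_id))
  m <- matrix(NA_integer_, nrow = length(ids), ncol = n_frames - 1L,
              dimnames = list(ids, seq_len(n_frames - 1L)))
  if (nrow(sp)) {
    m[cbind(match(sp$track_id, ids), sp$from_frame)] <-
      ifelse(sp$motion == "extending", 1L,
             ifelse(sp$motion == "retracting", -1L, 0L))
  }
  m
}
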