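#' Analysis parameters
#'
#' Bundles the thresholds used across the pipeline. The two scientific
#' constants are `bulk_threshold` (a bulk extension/retraction event requires
#' a per-direction extent change of strictly more than 2 um between two
#' consecutive frames) and `speed_threshold` (a terminal branch is extending
#' or retracting only when its signed tip speed strictly exceeds 0.5 um/min
#' in magnitude). The remainder are pipeline settings.
#'
#' @param bulk_threshold um; default 2.
#' @param speed_threshold um/min; default 0.5.
#' @param occupancy_threshold minimal volume fraction for a direction to
#'   count as occupied; default 0.05 (must stay below 0.25, the uniform
#'   four-way share).
#' @param phase_smoothing frames of identical occupancy class required before
#'   a phase boundary is declared; default 3 (one hour at 20-min cadence).
#' @param match_gate um; maximal tip displacement accepted when linking
#'   terminal branches across consecutive fast frames; default 3.
#' @param voxel um; voxel size for core-overlap rasterization; default 1.
#' @param density_quantile cable-length fraction defining an arbor's core;
#'   default 0.5.
#' @return a list of class `analysis_params`.
#' @export
analysis_params <- function(bulk_threshold = 2, speed_threshold = 0.5,
                            occupancy_threshold = 0.05, phase_smoothing = 3,
                            match_gate = 3, voxel = 1,
                            density_quantile = 0.5) {
  p <- list(bulk_threshold = bulk_threshold, speed_threshold = speed_threshold,
            occupancy_threshold = occupancy_threshold,
            phase_smoothing = as.integer(phase_smoothing),
            match_gate = match_gate, voxel = voxel,
            density_quantile = density_quantile)
  if (any(unlist(p) <= 0)) stop("all analysis parameters must be positive")
  if (occupancy_threshold >= 0.25) {
    stop("occupancy_threshold must be below 0.25")
  }
  structure(p, class = "analysis_params")
}

#' Per-direction volume fractions and extents over time
#'
#' For every present frame, each dendritic segment contributes its frustum
#' volume (or its length, with `weighting = "length"`) to the sector of its
#' midpoint; fractions are normalized within the frame. The extent of a
#' direction is the largest in-plane radial distance (projection onto the
#' DL-DM plane) of any dendritic node assigned to that sector, 0 if the
#' sector is empty. Frames with zero dendritic cable get `NA` fractions and
#' are flagged in the `undefined` column rather than propagating NaN.
#'
#' @param series a [skeleton_series()].
#' @param dframe a [direction_frame()].
#' @param weighting `"volume"` (default) or `"length"`.
#' @param params an [analysis_params()].
#' @param exclude_axon drop the main process and axon-typed cable
#'   (default `TRUE`).
#' @return data.frame with one row per present frame x direction:
#'   `frame`, `time_min`, `direction`, `weight`, `fraction`, `extent`,
#'   `undefined`.
#' @export
direction_profile <- function(series, dframe,
                              weighting = c("volume", "length"),
                              params = analysis_params(),
                              exclude_axon = TRUE) {
  stopifnot(inherits(series, "skeleton_series"), inherits(dframe, "direction_frame"))
  weighting <- match.arg(weighting)
  rows <- vector("list", length(series$frames))
  for (i in seq_along(series$frames)) {
    if (series$missing[i]) next
    fr <- series$frames[[i]]
    e <- dendrite_edges(fr, dframe, exclude_axon = exclude_axon)
    w_by_dir <- stats::setNames(numeric(4), DIRECTIONS)
    if (nrow(e)) {
      sec <- assign_sector(cbind(e$mx, e$my, e$mz), dframe)
      w <- if (weighting == "volume") e$volume else e$length
      agg <- tapply(w, sec, sum, default = 0)
      w_by_dir[names(agg)] <- agg
    }
    total <- sum(w_by_dir)
    pts <- dendrite_points(fr, dframe, exclude_axon = exclude_axon)
    ext <- stats::setNames(numeric(4), DIRECTIONS)
    if (nrow(pts)) {
      v <- sweep(pts, 2L, dframe$origin)
      pdl <- drop(v %*% dframe$axis_dl)
      pdm <- drop(v %*% dframe$axis_dm)
      r <- sqrt(pdl^2 + pdm^2)
      ok <- r >= 1e-9
      if (any(ok)) {
        sec_n <- assign_sector(pts[ok, , drop = FALSE], dframe)
        mx <- tapply(r[ok], sec_n, max, default = 0)
        ext[names(mx)] <- mx
      }
    }
    rows[[i]] <- data.frame(
      frame = i, time_min = series$times[i], direction = DIRECTIONS,
      weight = unname(w_by_dir),
      fraction = if (total > 0) unname(w_by_dir) / total else NA_real_,
      extent = unname(ext),
      undefined = total <= 0
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "weighting") <- weighting
  attr(out, "n_frames") <- length(series$frames)
  out
}

#' Detect bulk extension and retraction events
#'
#' For every direction and every pair of consecutive present frames, the
#' extent change `delta = extent[i+1] - extent[i]` is an extension event when
#' `delta > bulk_threshold` and a retraction event when
#' `delta < -bulk_threshold` (strict: a change of exactly the threshold is
#' not an event). Pairs spanning a missing frame are never compared.
#'
#' @param profile output of [direction_profile()].
#' @param params an [analysis_params()].
#' @return data.frame with columns `direction`, `from_frame`, `to_frame`,
#'   `time_from`, `time_to`, `kind` (`extension`/`retraction`),
#'   `magnitude` (um, positive).
#' @export
detect_bulk_events <- function(profile, params = analysis_params()) {
  thr <- params$bulk_threshold
  out <- list()
  for (d in DIRECTIONS) {
    p <- profile[profile$direction == d, , drop = FALSE]
    p <- p[order(p$frame), , drop = FALSE]
    if (nrow(p) < 2L) next
    consec <- which(diff(p$frame) == 1L)
    if (!length(consec)) next
    delta <- p$extent[consec + 1L] - p$extent[consec]
    hit <- abs(delta) > thr
    if (!any(hit)) next
    out[[d]] <- data.frame(
      direction = d,
      from_frame = p$frame[consec][hit], to_frame = p$frame[consec + 1L][hit],
      time_from = p$time_min[consec][hit], time_to = p$time_min[consec + 1L][hit],
      kind = ifelse(delta[hit] > 0, "extension", "retraction"),
      magnitude = abs(delta[hit])
    )
  }
  if (!length(out)) {
    return(data.frame(direction = character(), from_frame = integer(),
                      to_frame = integer(), time_from = numeric(),
                      time_to = numeric(), kind = character(),
                      magnitude = numeric()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$from_frame, match(res$direction, DIRECTIONS)), ]
  rownames(res) <- NULL
  res
}

#' Count events in the initial and final observation windows
#'
#' Restricts events to the first and last `n_frames` frames of the recording
#' (default 6 windows, the convention for comparing pre- and post-targeting
#' dynamics); an event is counted only when its whole frame interval lies
#' inside the window.
#'
#' @param events output of [detect_bulk_events()].
#' @param profile the profile the events came from (supplies series length).
#' @param n_frames window size in frames; default 6.
#' @return data.frame with `window`, `direction`, `kind`, `n` (complete grid,
#'   zeros included).
#' @export
event_counts_by_window <- function(events, profile, n_frames = 6) {
  n_total <- attr(profile, "n_frames")
  if (is.null(n_total)) n_total <- max(profile$frame)
  if (n_total < 2 * n_frames) {
    stop("series too short: ", n_total, " frames < 2 x ", n_frames)
  }
  grid <- expand.grid(window = c("initial", "final"), direction = DIRECTIONS,
                      kind = c("extension", "retraction"),
                      stringsAsFactors = FALSE)
  grid$n <- 0L
  if (nrow(events)) {
    in_initial <- events$to_frame <= n_frames
    in_final <- events$from_frame >= n_total - n_frames + 1L
    for (j in seq_len(nrow(grid))) {
      sel <- (if (grid$window[j] == "initial") in_initial else in_final) &
        events$direction == grid$direction[j] & events$kind == grid$kind[j]
      grid$n[j] <- sum(sel)
    }
  }
  grid
}

#' Event raster matrix
#'
#' Direction-by-interval matrix with +1 for an extension event, -1 for a
#' retraction event and 0 otherwise — the layout used for kymograph-style
#' event plots.
#'
#' @param events output of [detect_bulk_events()].
#' @param profile the corresponding [direction_profile()].
#' @return integer matrix (4 x n_intervals) with dimnames.
#' @export
event_raster <- function(events, profile) {
  n_total <- attr(profile, "n_frames")
  if (is.null(n_total)) n_total <- max(profile$frame)
  m <- matrix(0L, nrow = 4L, ncol = n_total - 1L,
              dimnames = list(DIRECTIONS, seq_len(n_total - 1L)))
  if (nrow(events)) {
    m[cbind(match(events$direction, DIRECTIONS), events$from_frame)] <-
      ifelse(events$kind == "extension", 1L, -1L)
  }
  m
}
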