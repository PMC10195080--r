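#' Occupied directions of a frame
#'
#' A direction counts as occupied when it holds at least
#' `occupancy_threshold` (default 5%) of the frame's dendritic volume — the
#' threshold separates genuine occupancy from tracing noise. Undefined
#' fractions (zero-cable frames) yield an empty set.
#'
#' @param fractions named numeric vector of per-direction fractions (names
#'   among DL, DM, VM, VL), or an unnamed length-4 vector in that order.
#' @param params an [analysis_params()].
#' @return character vector of occupied directions (subset of DL, DM, VM, VL).
#' @export
occupied_directions <- function(fractions, params = analysis_params()) {
  if (is.null(names(fractions))) {
    stopifnot(length(fractions) == 4L)
    names(fractions) <- DIRECTIONS
  }
  f <- fractions[DIRECTIONS]
  f[is.na(f)] <- 0
  DIRECTIONS[f >= params$occupancy_threshold]
}

# occupancy class of a count of occupied directions
occupancy_class <- function(n_occ) {
  ifelse(n_occ >= 3L, "initial", ifelse(n_occ == 2L, "transitional", "final"))
}

#' Segment a recording into targeting phases
#'
#' Classifies every frame by how many directions its dendrites occupy —
#' *initial* (3 or 4 directions: undirected exploration), *transitional*
#' (exactly 2) and *final* (at most 1: targeting complete) — then smooths:
#' a run of frames shorter than `phase_smoothing` never starts a phase and is
#' absorbed into its predecessor. Runs are finally merged into the admissible
#' order initial -> transitional -> final; frames whose class would move
#' backwards in that order are absorbed into the preceding phase and counted
#' in `n_flagged`.
#'
#' @param profile output of [direction_profile()] at bulk cadence.
#' @param params an [analysis_params()].
#' @return data.frame of class `phase_segmentation`: `phase`, `start_frame`,
#'   `end_frame`, `start_min`, `end_min`, `occupied` (modal occupied set,
#'   comma-separated), `n_flagged`. Attribute `frame_phase` holds the
#'   per-frame phase assignment.
#' @export
segment_phases <- function(profile, params = analysis_params()) {
  frames <- sort(unique(profile$frame))
  if (length(frames) < 3L * params$phase_smoothing) {
    stop("series too short for phase segmentation: ", length(frames),
         " frames < 3 x phase_smoothing")
  }
  occ_sets <- lapply(frames, function(i) {
    p <- profile[profile$frame == i, ]
    occupied_directions(stats::setNames(p$fraction, p$direction), params)
  })
  n_occ <- lengths(occ_sets)
  cls <- occupancy_class(n_occ)

  # smoothing: absorb runs shorter than phase_smoothing into the previous run
  r <- rle(cls)
  repeat {
    short <- which(r$lengths < params$phase_smoothing)
    short <- short[short > 1L]
    if (!length(short)) break
    k <- short[1L]
    r$values[k] <- r$values[k - 1L]
    r <- rle(inverse.rle(r))
  }
  smoothed <- inverse.rle(r)

  # admissible order: initial -> transitional -> final; backward moves are
  # absorbed into the preceding phase and flagged
  rank <- c(initial = 1L, transitional = 2L, final = 3L)
  flagged <- logical(length(smoothed))
  cur <- smoothed[1L]
  for (i in seq_along(smoothed)) {
    if (rank[smoothed[i]] < rank[cur]) {
      flagged[i] <- TRUE
      smoothed[i] <- cur
    } else {
      cur <- smoothed[i]
    }
  }

  r2 <- rle(smoothed)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1L
  occ_string <- vapply(seq_along(r2$values), function(k) {
    sets <- vapply(occ_sets[starts[k]:ends[k]], paste, character(1),
                   collapse = ",")
    tab <- table(sets)
    names(tab)[which.max(tab)]
  }, character(1))
  time_by_frame <- tapply(profile$time_min, profile$frame, min)[as.character(frames)]
  out <- data.frame(
    phase = factor(r2$values, levels = c("initial", "transitional", "final")),
    start_frame = frames[starts], end_frame = frames[ends],
    start_min = as.numeric(time_by_frame[starts]),
    end_min = as.numeric(time_by_frame[ends]),
    occupied = occ_string,
    n_flagged = vapply(seq_along(starts), function(k) {
      sum(flagged[starts[k]:ends[k]])
    }, integer(1))
  )
  attr(out, "frame_phase") <- stats::setNames(smoothed, frames)
  class(out) <- c("phase_segmentation", "data.frame")
  out
}

#' Two-group and multi-group comparisons
#'
#' The two tests used for group comparisons throughout: a two-sided Welch
#' t-test for two groups and a one-way fixed-effects ANOVA for two or more.
#' Degenerate inputs (zero variance within every group) do not produce NaN:
#' equal means give statistic 0 and p = 1 by convention; distinct means give
#' p = 0 with the `degenerate` flag set.
#'
#' @param values list of numeric vectors, one per group (each of length >= 2;
#'   exactly two groups for `t_test`).
#' @param test `"t_test"` or `"anova"`.
#' @return list of class `group_comparison`: `test`, `statistic`, `df`,
#'   `p_value`, `degenerate`.
#' @export
compare_groups <- function(values, test = c("t_test", "anova")) {
  test <- match.arg(test)
  stopifnot(is.list(values))
  if (any(lengths(values) < 2L)) stop("each group needs at least 2 values")
  vars <- vapply(values, stats::var, numeric(1))
  means <- vapply(values, mean, numeric(1))
  if (all(vars == 0)) {
    if (max(means) - min(means) == 0) {
      res <- list(test = test, statistic = 0, df = NA_real_, p_value = 1,
                  degenerate = TRUE)
    } else {
      res <- list(test = test, statistic = Inf, df = NA_real_, p_value = 0,
                  degenerate = TRUE)
    }
    class(res) <- "group_comparison"
    return(res)
  }
  if (test == "t_test") {
    if (length(values) != 2L) stop("t_test requires exactly 2 groups")
    ht <- stats::t.test(values[[1L]], values[[2L]], var.equal = FALSE)
    res <- list(test = "t_test", statistic = unname(ht$statistic),
                df = unname(ht$parameter), p_value = ht$p.value,
                degenerate = FALSE)
  } else {
    if (length(values) < 2L) stop("anova requires at least 2 groups")
    y <- unlist(values, use.names = FALSE)
    g <- factor(rep(seq_along(values), lengths(values)))
    ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
    res <- list(test = "anova", statistic = unname(ht$statistic),
                df = unname(ht$parameter), p_value = ht$p.value,
                degenerate = FALSE)
  }
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$test, ": statistic = ",
      signif(x$statistic, 6), ", df = ", paste(signif(x$df, 6), collapse = ", "),
      ", p = ", signif(x$p_value, 6),
      if (x$degenerate) " (degenerate: zero within-group variance)" else "",
      "\n", sep = "")
  invisible(x)
}
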