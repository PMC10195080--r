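#' Configuration for the synthetic skeleton simulator
#'
#' Defines a birth-death model of terminal-branch dynamics around a static
#' main process entering an ellipsoidal neuropil. Branches nucleate per
#' direction as independent Poisson processes, live exponentially distributed
#' lifetimes, and while alive their path length follows a two-state
#' extend/retract process whose speed magnitudes centre on the ~1.5 um/min
#' scale typical of developing terminal branches. Selective stabilization of
#' a direction is expressed as a longer mean lifetime there; destabilization
#' as a shorter one.
#'
#' @param seed integer RNG seed; all randomness flows from it.
#' @param duration minutes of recorded time (window starts at 0).
#' @param frame_interval minutes between frames (0.5 for branch cadence,
#'   20 for bulk cadence).
#' @param lambda named per-direction nucleation rates, branches/min.
#' @param tau named per-direction mean lifetimes, min (exponential).
#' @param speed_mean,speed_sd mean and sd of per-interval tip speed
#'   magnitude, um/min (defaults 1.5 and 0.4).
#' @param flip_prob per-minute probability that a branch switches between
#'   extending and retracting (default 0.3).
#' @param dwell_prob per-interval probability of a stationary interval
#'   (default 0.1).
#' @param jitter_sd sd of Gaussian tip-position jitter, um (default 0.1;
#'   set 0 for exact-recovery experiments).
#' @param neuropil_radius um; branch lengths are capped here (default 30).
#' @param burn_in minutes of pre-window simulation so a stationary branch
#'   population exists at frame 1 (default `4 * max(tau)`, capped at 150).
#' @param midpoint_nodes add a midpoint node to each branch (default FALSE).
#' @param dframe the [direction_frame()] the series is generated in.
#' @param scripted_extents optional n_frames x 4 matrix of per-direction
#'   extents (um); switches the generator to the deterministic bulk-drift
#'   mode in which each direction is rendered as one radial branch of the
#'   scripted extent.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, duration = 15, frame_interval = 0.5,
                         lambda = c(DL = 0.5, DM = 0.5, VM = 0.5, VL = 0.5),
                         tau = c(DL = 5, DM = 5, VM = 5, VL = 5),
                         speed_mean = 1.5, speed_sd = 0.4,
                         flip_prob = 0.3, dwell_prob = 0.1,
                         jitter_sd = 0.1, neuropil_radius = 30,
                         burn_in = NULL, midpoint_nodes = FALSE,
                         dframe = direction_frame(),
                         scripted_extents = NULL) {
  lambda <- lambda[DIRECTIONS]; tau <- tau[DIRECTIONS]
  names(lambda) <- DIRECTIONS; names(tau) <- DIRECTIONS
  stopifnot(all(lambda >= 0), all(tau > 0), duration > 0, frame_interval > 0,
            speed_mean > 0)
  if (is.null(burn_in)) burn_in <- min(4 * max(tau), 150)
  structure(list(seed = as.integer(seed), duration = duration,
                 frame_interval = frame_interval, lambda = lambda, tau = tau,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 flip_prob = flip_prob, dwell_prob = dwell_prob,
                 jitter_sd = jitter_sd, neuropil_radius = neuropil_radius,
                 burn_in = burn_in, midpoint_nodes = midpoint_nodes,
                 dframe = dframe, scripted_extents = scripted_extents),
            class = "synth_config")
}

#' Named simulation presets
#'
#' * `uniform` — no directional bias: identical nucleation rate (0.5/min)
#'   and mean lifetime (5 min) in all four directions, 15 min at 30 s
#'   cadence. Null condition for direction comparisons.
#' * `vm_destabilized` — branches in VM live a quarter as long as elsewhere
#'   (tau_VM = tau/4); base lifetime 30 min and rate 0.8/min chosen so a
#'   cell carries on the order of 15 stable branches per unbiased direction
#'   over the 15-min window. The selective-destabilization condition.
#' * `stepwise_targeting` — bulk cadence (20 min, 63 frames ~ 21 h) with
#'   scripted per-direction extents: all four directions occupied, then only
#'   DL plus one of DM/VL (never VM), then DL alone; large extent jumps are
#'   scripted into the first phase so pre-targeting dynamics carry bulk
#'   events.
#' * `static` — one immobile branch per direction, no noise: an end-to-end
#'   null in which every event detector must stay silent.
#'
#' @param name preset name.
#' @param seed RNG seed (default 1).
#' @return a [synth_config()].
#' @export
synth_preset <- function(name = c("uniform", "vm_destabilized",
                                  "stepwise_targeting", "static"),
                         seed = 1L) {
  name <- match.arg(name)
  switch(name,
    uniform = synth_config(seed = seed),
    vm_destabilized = synth_config(
      seed = seed,
      lambda = c(DL = 0.8, DM = 0.8, VM = 0.8, VL = 0.8),
      tau = c(DL = 30, DM = 30, VM = 7.5, VL = 30)
    ),
    stepwise_targeting = {
      cfg <- synth_config(seed = seed, duration = 62 * 20, frame_interval = 20,
                          lambda = c(DL = 0, DM = 0, VM = 0, VL = 0),
                          jitter_sd = 0)
      cfg$scripted_extents <- scripted_targeting_extents(seed)
      cfg
    },
    static = {
      cfg <- synth_config(seed = seed, lambda = c(DL = 0, DM = 0, VM = 0, VL = 0),
                          jitter_sd = 0)
      cfg$static_branches <- TRUE
      cfg
    }
  )
}

# Scripted per-direction extents for the stepwise-targeting scenario:
# 63 frames at 20 min. Frames 1-27 all four directions occupied with
# scripted jumps (every 4th interval, magnitude 2.3-3.2 um, alternating
# sign) that constitute bulk events; frames 28-39 only DL and a partner
# (DM or VL, never VM); frames 40-63 DL alone.
scripted_targeting_extents <- function(seed) {
  rng_scope(seed + 211L)
  n <- 63L
  partner <- sample(c("DM", "VL"), 1L)
  ext <- matrix(0, nrow = n, ncol = 4L, dimnames = list(NULL, DIRECTIONS))
  start <- c(DL = 10, DM = 9, VM = 8, VL = 9) + stats::runif(4, -1, 1)
  ext[1L, ] <- start[DIRECTIONS]
  sign_state <- c(1, -1, 1, -1)
  for (k in 2:27) {
    step <- stats::rnorm(4, 0, 0.4)
    if (k %% 4L == 2L) {
      step <- sign_state * stats::runif(4, 2.3, 3.2)
      sign_state <- -sign_state
    }
    ext[k, ] <- pmin(15, pmax(5, ext[k - 1L, ] + step))
  }
  keep2 <- c("DL", partner)
  for (k in 28:39) {
    ext[k, keep2] <- pmin(15, pmax(5, ext[k - 1L, keep2] +
                                     stats::rnorm(2, 0, 0.4)))
  }
  for (k in 40:63) {
    ext[k, "DL"] <- pmin(15, pmax(5, ext[k - 1L, "DL"] +
                                    stats::rnorm(1, 0, 0.25)))
  }
  attr(ext, "partner") <- partner
  ext
}

# All generator randomness flows from one seed set at entry.
rng_scope <- function(seed) {
  set.seed(seed)
  invisible(seed)
}

# unit direction for azimuth theta (deg from DL axis towards DM) and
# elevation phi (deg towards anterior)
sector_unit <- function(theta_deg, phi_deg, dframe) {
  th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
  outer(cos(ph) * cos(th), dframe$axis_dl) +
    outer(cos(ph) * sin(th), dframe$axis_dm) +
    outer(sin(ph), dframe$axis_ant)
}

#' Simulate a skeleton time series with ground truth
#'
#' Runs the birth-death branch model of [synth_config()] and renders each
#' frame as a valid SWC tree: a static main process (soma and trunk, SWC
#' type 2, ending at the neuropil entry point = the direction-frame origin)
#' with one straight radial branch (type 3) per live terminal branch.
#' Identical seeds give bit-identical series and ground truth.
#'
#' The ground truth records, per branch: birth/death times, direction, the
#' lifetime category implied by its presence in the observation window, its
#' per-frame rendered tip positions and path lengths, and its scripted
#' per-interval speeds; per frame: the true occupied-direction set; and, in
#' scripted bulk mode, the true bulk event log obtained by scanning the
#' scripted extents with the 2-um threshold.
#'
#' @param config a [synth_config()].
#' @param params an [analysis_params()] (supplies the bulk threshold for the
#'   scripted event log).
#' @return list of class `synth_result` with `series` ([skeleton_series()]),
#'   `truth` (list of data.frames: `branches`, `observations`, `speeds`,
#'   `occupancy`, `events`) and `config`.
#' @export
simulate_series <- function(config, params = analysis_params()) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$scripted_extents)) {
    return(simulate_scripted_bulk(config, params))
  }
  rng_scope(config$seed)
  dfr <- config$dframe
  dt <- config$frame_interval
  times <- seq(0, config$duration, by = dt)
  n_frames <- length(times)

  expected <- sum(config$lambda) * (config$burn_in + config$duration)
  if (sum(config$lambda * config$tau) > 1e5 || expected > 5e5) {
    stop("configuration would produce more than 1e5 concurrent branches")
  }

  branches <- list()
  if (isTRUE(config$static_branches)) {
    for (j in seq_along(DIRECTIONS)) {
      branches[[j]] <- list(direction = DIRECTIONS[j],
                            theta = (j - 1) * 90, phi = 0, b0 = 4,
                            birth = -config$burn_in, death = Inf,
                            lengths = rep(8, n_frames),
                            speeds = rep(0, n_frames - 1L))
    }
  } else {
    centers <- c(DL = 0, DM = 90, VM = 180, VL = 270)
    # nucleation: Poisson per direction over [-burn_in, duration]
    proto <- list()
    for (d in DIRECTIONS) {
      span <- config$burn_in + config$duration
      n_d <- stats::rpois(1L, config$lambda[[d]] * span)
      if (n_d == 0L) next
      births <- sort(stats::runif(n_d, -config$burn_in, config$duration))
      for (b in births) {
        proto[[length(proto) + 1L]] <- list(direction = d, birth = b)
      }
    }
    if (length(proto)) {
      ord <- order(vapply(proto, `[[`, numeric(1), "birth"))
      proto <- proto[ord]
    }
    # grid including burn-in so pre-window branches have evolved lengths;
    # the burn-in is rounded to a whole number of intervals so that t = 0
    # lies exactly on the grid
    burn <- round(config$burn_in / dt) * dt
    grid <- seq(-burn, config$duration, by = dt)
    for (pb in proto) {
      d <- pb$direction
      theta <- centers[[d]] + stats::runif(1, -45, 45)
      phi <- stats::runif(1, -40, 40)
      # each branch sprouts from its own base point along the ray, as real
      # terminal branches sprout from distinct positions on the arbor
      b0 <- stats::runif(1, 3, 10)
      life <- stats::rexp(1, 1 / config$tau[[d]])
      death <- pb$birth + life
      first_g <- which(grid >= pb$birth)[1L]
      if (is.na(first_g)) next
      s0 <- max(0.05, stats::rnorm(1, config$speed_mean, config$speed_sd))
      l <- max(0.2, (grid[first_g] - pb$birth) * s0)
      state <- 1
      pflip <- 1 - (1 - config$flip_prob)^dt
      lens <- rep(NA_real_, length(grid))
      spds <- rep(NA_real_, length(grid))  # speed over interval g -> g+1
      g <- first_g
      while (g <= length(grid) && grid[g] < death) {
        lens[g] <- l
        if (g == length(grid)) break
        v <- if (stats::runif(1) < config$dwell_prob) 0 else {
          state * max(0.05, stats::rnorm(1, config$speed_mean, config$speed_sd))
        }
        l_next <- l + v * dt
        if (l_next > config$neuropil_radius) {
          l_next <- config$neuropil_radius
          v <- (l_next - l) / dt
          state <- -1
        }
        if (l_next <= 0) {  # full retraction eliminates the branch
          spds[g] <- v
          death <- min(death, grid[g + 1L])
          break
        }
        spds[g] <- v
        l <- l_next
        if (stats::runif(1) < pflip) state <- -state
        g <- g + 1L
      }
      win <- which(grid >= -1e-9)
      wl <- lens[win]
      if (all(is.na(wl))) {
        # died before the window: keep for the truth table only
        branches[[length(branches) + 1L]] <- list(
          direction = d, theta = theta, phi = phi, b0 = b0, birth = pb$birth,
          death = min(death, pb$birth + life),
          lengths = rep(NA_real_, n_frames), speeds = rep(NA_real_, n_frames - 1L))
        next
      }
      branches[[length(branches) + 1L]] <- list(
        direction = d, theta = theta, phi = phi, b0 = b0, birth = pb$birth,
        death = min(death, pb$birth + life),
        lengths = wl, speeds = spds[win][-n_frames])
    }
  }

  build_truth_and_frames(branches, times, config, params,
                         scripted = NULL)
}

# Scripted bulk-drift mode: each direction with positive extent is one
# straight in-plane branch whose tip sits exactly at the scripted extent.
simulate_scripted_bulk <- function(config, params) {
  rng_scope(config$seed)
  ext <- config$scripted_extents
  n_frames <- nrow(ext)
  dt <- config$frame_interval
  times <- seq(0, by = dt, length.out = n_frames)
  centers <- c(DL = 0, DM = 90, VM = 180, VL = 270)
  branches <- list()
  for (j in seq_along(DIRECTIONS)) {
    d <- DIRECTIONS[j]
    lens <- ext[, d]
    lens[lens <= 0] <- NA_real_
    pres <- which(!is.na(lens))
    if (!length(pres)) next
    spds <- diff(ifelse(is.na(lens), 0, lens)) / dt
    spds[is.na(lens[-1L]) | is.na(lens[-n_frames])] <- NA_real_
    branches[[length(branches) + 1L]] <- list(
      direction = d, theta = centers[[d]], phi = 0, b0 = 0,
      birth = times[pres[1L]] - dt, death = times[pres[length(pres)]] + dt / 2,
      lengths = lens, speeds = spds)
  }
  res <- build_truth_and_frames(branches, times, config, params,
                                scripted = ext)
  res
}

# Shared renderer: builds SWC frames, the ground-truth tables and the series.
build_truth_and_frames <- function(branches, times, config, params, scripted) {
  dfr <- config$dframe
  n_frames <- length(times)
  origin <- dfr$origin
  # main process: soma 25 um posterior of the entry point, two trunk nodes
  trunk_pos <- rbind(origin - 25 * dfr$axis_ant,
                     origin - 15 * dfr$axis_ant,
                     origin - 5 * dfr$axis_ant,
                     origin)
  n_branch <- length(branches)
  units <- if (n_branch) {
    sector_unit(vapply(branches, `[[`, numeric(1), "theta"),
                vapply(branches, `[[`, numeric(1), "phi"), dfr)
  } else matrix(numeric(0), ncol = 3L)

  # jittered tip positions fixed per branch x frame (recorded in the truth
  # table and rendered in the SWC frames identically)
  obs <- list()
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    live <- if (n_branch) {
      which(vapply(branches, function(b) !is.na(b$lengths[i]), logical(1)))
    } else integer(0)
    tips <- bases <- matrix(numeric(0), ncol = 3L)
    b0s <- numeric(0)
    if (length(live)) {
      L <- vapply(branches[live], function(b) b$lengths[i], numeric(1))
      b0s <- vapply(branches[live], `[[`, numeric(1), "b0")
      og <- matrix(rep(origin, each = length(live)), ncol = 3L)
      bases <- og + units[live, , drop = FALSE] * b0s
      tips <- og + units[live, , drop = FALSE] * (b0s + L)
      if (config$jitter_sd > 0) {
        tips <- tips + matrix(stats::rnorm(length(tips), 0, config$jitter_sd),
                              ncol = 3L)
      }
    }
    # node table: 1 soma (type 1), 2-3 trunk, 4 entry (type 2), branches
    nid <- 4L
    rows <- data.frame(
      node_id = 1:4, structure = c(1L, 2L, 2L, 2L),
      x = trunk_pos[, 1L], y = trunk_pos[, 2L], z = trunk_pos[, 3L],
      radius = c(2, 0.6, 0.6, 0.6), parent_id = c(-1L, 1L, 2L, 3L)
    )
    if (length(live)) {
      extra <- list()
      for (k in seq_along(live)) {
        b <- live[k]
        parent <- 4L
        if (b0s[k] > 0) {  # distinct sprouting point along the ray
          extra[[length(extra) + 1L]] <- data.frame(
            node_id = nid + 1L, structure = 3L,
            x = bases[k, 1L], y = bases[k, 2L], z = bases[k, 3L],
            radius = 0.3, parent_id = parent)
          parent <- nid + 1L
          nid <- nid + 1L
        }
        if (config$midpoint_nodes) {
          mid <- (bases[k, ] + tips[k, ]) / 2
          extra[[length(extra) + 1L]] <- data.frame(
            node_id = nid + 1L, structure = 3L,
            x = mid[1L], y = mid[2L], z = mid[3L], radius = 0.3,
            parent_id = parent)
          parent <- nid + 1L
          nid <- nid + 1L
        }
        extra[[length(extra) + 1L]] <- data.frame(
          node_id = nid + 1L, structure = 3L,
          x = tips[k, 1L], y = tips[k, 2L], z = tips[k, 3L], radius = 0.3,
          parent_id = parent)
        tip_id <- nid + 1L
        nid <- nid + 1L
        # path length the tracer sees: base offset plus rendered tip-base run
        plen <- b0s[k] + sqrt(sum((tips[k, ] - bases[k, ])^2))
        obs[[length(obs) + 1L]] <- data.frame(
          branch_id = b, frame = i, time_min = times[i],
          length = plen,
          tip_x = tips[k, 1L], tip_y = tips[k, 2L], tip_z = tips[k, 3L],
          tip_node_id = tip_id)
      }
      rows <- rbind(rows, do.call(rbind, extra))
    }
    frames[[i]] <- skeleton_frame(rows, time = times[i])
  }

  observations <- if (length(obs)) do.call(rbind, obs) else {
    data.frame(branch_id = integer(), frame = integer(), time_min = numeric(),
               length = numeric(), tip_x = numeric(), tip_y = numeric(),
               tip_z = numeric(), tip_node_id = integer())
  }
  rownames(observations) <- NULL

  branch_tbl <- if (n_branch) {
    do.call(rbind, lapply(seq_len(n_branch), function(b) {
      br <- branches[[b]]
      pres <- which(!is.na(br$lengths))
      first <- if (length(pres)) pres[1L] else NA_integer_
      last <- if (length(pres)) pres[length(pres)] else NA_integer_
      cat <- if (!length(pres)) NA_character_ else if (first == 1L && last == n_frames) {
        "stable"
      } else if (first > 1L && last == n_frames) {
        "emerging"
      } else if (first == 1L && last < n_frames) {
        "retracting"
      } else "transient"
      data.frame(branch_id = b, direction = br$direction,
                 birth_min = br$birth,
                 death_min = ifelse(is.finite(br$death), br$death, NA_real_),
                 first_frame = first, last_frame = last,
                 true_category = cat)
    }))
  } else {
    data.frame(branch_id = integer(), direction = character(),
               birth_min = numeric(), death_min = numeric(),
               first_frame = integer(), last_frame = integer(),
               true_category = character())
  }

  speeds_tbl <- if (n_branch) {
    do.call(rbind, lapply(seq_len(n_branch), function(b) {
      sp <- branches[[b]]$speeds
      k <- which(!is.na(sp))
      if (!length(k)) return(NULL)
      data.frame(branch_id = b, from_frame = k, to_frame = k + 1L,
                 speed = sp[k])
    }))
  } else NULL
  if (is.null(speeds_tbl)) {
    speeds_tbl <- data.frame(branch_id = integer(), from_frame = integer(),
                             to_frame = integer(), speed = numeric())
  }
  rownames(speeds_tbl) <- NULL

  # true occupancy: directions holding a live branch in the frame (scripted
  # mode: extent > 0)
  occupancy <- do.call(rbind, lapply(seq_len(n_frames), function(i) {
    occ <- if (!is.null(scripted)) {
      DIRECTIONS[scripted[i, ] > 0]
    } else if (nrow(observations)) {
      o <- observations[observations$frame == i, ]
      sort(unique(branch_tbl$direction[match(o$branch_id, branch_tbl$branch_id)]))
    } else character(0)
    data.frame(frame = i, time_min = times[i], n_occupied = length(occ),
               occupied = paste(intersect(DIRECTIONS, occ), collapse = ","))
  }))

  events <- NULL
  if (!is.null(scripted)) {
    thr <- params$bulk_threshold
    ev <- list()
    for (d in DIRECTIONS) {
      delta <- diff(scripted[, d])
      hit <- which(abs(delta) > thr)
      if (length(hit)) {
        ev[[d]] <- data.frame(direction = d, from_frame = hit,
                              to_frame = hit + 1L,
                              kind = ifelse(delta[hit] > 0, "extension",
                                            "retraction"),
                              magnitude = abs(delta[hit]))
      }
    }
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(direction = character(), from_frame = integer(),
                 to_frame = integer(), kind = character(),
                 magnitude = numeric())
    events <- events[order(events$from_frame, match(events$direction,
                                                    DIRECTIONS)), ]
    rownames(events) <- NULL
  }

  series <- skeleton_series(frames, times = times,
                            missing = rep(FALSE, n_frames))
  structure(list(series = series,
                 truth = list(branches = branch_tbl,
                              observations = observations,
                              speeds = speeds_tbl,
                              occupancy = occupancy,
                              events = events,
                              scripted_extents = scripted),
                 config = config),
            class = "synth_result")
}

#' @export
print.synth_result <- function(x, ...) {
  cat("<synth_result> ", length(x$series$frames), " frames, ",
      nrow(x$truth$branches), " true branches\n", sep = "")
  invisible(x)
}
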