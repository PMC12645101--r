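# Synthetic-data generator: jittered receiver grids, coupled
# Ornstein-Uhlenbeck pair movement with leader/follower role switching, and
# distance- and height-dependent detection emission. Gives every downstream
# stage (localization, coverage, home range, cohesion) a known ground truth.

#' Generate a jittered rectangular receiver array
#'
#' @param nx,ny grid dimensions (>= 1).
#' @param spacing grid spacing in meters (> 0).
#' @param jitter_sd per-coordinate Gaussian jitter sd in meters (default 0).
#' @param seed integer seed; fixing it fixes the array.
#' @param origin coordinates of the (1,1) receiver before jitter.
#' @return data frame (`node_id`, `x_m`, `y_m`) with a `bounds` attribute
#'   (xmin, xmax, ymin, ymax of the unjittered grid).
#' @export
generate_receiver_array <- function(nx, ny, spacing, jitter_sd = 0, seed = 1L,
                                    origin = c(0, 0)) {
  if (nx < 1 || ny < 1) stopf("generate_receiver_array: nx and ny must be >= 1")
  if (!is.finite(spacing) || spacing <= 0)
    stopf("generate_receiver_array: spacing must be > 0")
  set.seed(seed)
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  x <- origin[1L] + (g$ix - 1L) * spacing
  y <- origin[2L] + (g$iy - 1L) * spacing
  if (jitter_sd > 0) {
    x <- x + stats::rnorm(nrow(g), 0, jitter_sd)
    y <- y + stats::rnorm(nrow(g), 0, jitter_sd)
  }
  out <- data.frame(
    node_id = sprintf("N%03d", seq_len(nrow(g))),
    x_m = x, y_m = y,
    stringsAsFactors = FALSE
  )
  attr(out, "bounds") <- c(xmin = origin[1L], xmax = origin[1L] + (nx - 1L) * spacing,
                           ymin = origin[2L], ymax = origin[2L] + (ny - 1L) * spacing)
  out
}

#' Movement configuration for a simulated pair
#'
#' The pair moves as two coupled Ornstein-Uhlenbeck (OU) processes. The
#' current leader reverts to its territory center with stationary sd
#' `home_range_sd` and timescale `ou_timescale`; at each step the partner,
#' with probability `coupling`, relaxes toward the leader's current position
#' over `follow_lag_mean` (plus small local noise `follow_noise_sd`),
#' otherwise it follows its own OU dynamics. Roles swap via a symmetric
#' Markov chain at `role_switch_per_min`, so either bird initiates moves.
#'
#' `periods` optionally rescales `home_range_sd` and `coupling` over time
#' (e.g. breeding vs post-breeding): a data frame with columns `start_s`,
#' `home_range_sd`, `coupling`; each step uses the latest period started.
#'
#' @param centers list of two length-2 numeric vectors: territory centers (m)
#'   of the two pair members.
#' @param home_range_sd OU stationary sd in meters (> 0); default 30, the
#'   scale of a breeding-season territory.
#' @param ou_timescale OU relaxation time in seconds (> 0).
#' @param coupling follow probability in [0, 1].
#' @param follow_lag_mean relaxation time toward the leader when following (s).
#' @param follow_noise_sd local per-step noise while following (m).
#' @param step_interval beacon/step interval in seconds (default 15).
#' @param role_switch_per_min probability per minute that leader/follower
#'   roles swap.
#' @param periods optional period schedule (see Details).
#' @return a `movement_config` list.
#' @export
movement_config <- function(centers = list(c(0, 0), c(0, 0)),
                            home_range_sd = 30,
                            ou_timescale = 300,
                            coupling = 0.8,
                            follow_lag_mean = 60,
                            follow_noise_sd = 5,
                            step_interval = 15,
                            role_switch_per_min = 0.1,
                            periods = NULL) {
  if (coupling < 0 || coupling > 1) stopf("coupling must lie in [0, 1]")
  if (home_range_sd <= 0 || ou_timescale <= 0 || follow_lag_mean <= 0 ||
      step_interval <= 0)
    stopf("sds, timescales and step interval must be > 0")
  if (!is.null(periods))
    assert_cols(periods, c("start_s", "home_range_sd", "coupling"), "periods")
  structure(list(centers = centers, home_range_sd = home_range_sd,
                 ou_timescale = ou_timescale, coupling = coupling,
                 follow_lag_mean = follow_lag_mean,
                 follow_noise_sd = follow_noise_sd,
                 step_interval = step_interval,
                 role_switch_per_min = role_switch_per_min,
                 periods = periods),
            class = "movement_config")
}

#' Simulate a coupled pair of movement tracks
#'
#' Discretized with the exact OU transition (mean-reversion factor
#' exp(-dt/tau), innovation sd sigma * sqrt(1 - exp(-2 dt/tau))), so long
#' runs stay at the stationary distribution. Beacon times lie on the shared
#' epoch grid at `step_interval`.
#'
#' @param config a [movement_config()].
#' @param duration track duration in seconds (>= 2 * step_interval).
#' @param seed integer seed.
#' @param start_time epoch start (s); snapped to the step grid.
#' @param ids,sexes,pair_id identifiers for the two individuals.
#' @return data frame with one row per (individual, step): `individual_id`,
#'   `pair_id`, `sex`, `time_s`, `x_m`, `y_m`, `role` ("leader"/"follower").
#' @export
simulate_pair_tracks <- function(config, duration, seed = 1L, start_time = 0,
                                 ids = c("A", "B"), sexes = c("F", "M"),
                                 pair_id = "P1") {
  stopifnot(inherits(config, "movement_config"))
  dt <- config$step_interval
  if (duration < 2 * dt)
    stopf("simulate_pair_tracks: duration must cover at least 2 steps")
  set.seed(seed)
  n <- floor(duration / dt)
  t0 <- floor(start_time / dt) * dt
  times <- t0 + (seq_len(n) - 1L) * dt

  lookup_period <- function(t) {
    if (is.null(config$periods)) return(c(config$home_range_sd, config$coupling))
    i <- findInterval(t, config$periods$start_s)
    if (i == 0L) return(c(config$home_range_sd, config$coupling))
    c(config$periods$home_range_sd[i], config$periods$coupling[i])
  }

  phi  <- exp(-dt / config$ou_timescale)
  phif <- exp(-dt / config$follow_lag_mean)
  p_switch <- min(1, config$role_switch_per_min * dt / 60)

  pos <- matrix(NA_real_, nrow = n, ncol = 4L)  # x1 y1 x2 y2
  role1 <- logical(n)                           # TRUE when individual 1 leads
  ctr <- rbind(config$centers[[1L]], config$centers[[2L]])

  sd0 <- lookup_period(times[1L])[1L]
  cur <- ctr + matrix(stats::rnorm(4L, 0, sd0), 2L, 2L)
  leader <- 1L
  for (i in seq_len(n)) {
    par <- lookup_period(times[i])
    sdp <- par[1L]; coup <- par[2L]
    if (i > 1L) {
      if (stats::runif(1L) < p_switch) leader <- 3L - leader
      follower <- 3L - leader
      inn <- sdp * sqrt(1 - phi^2)
      # leader: own OU around its territory center
      cur[leader, ] <- ctr[leader, ] +
        (cur[leader, ] - ctr[leader, ]) * phi + stats::rnorm(2L, 0, inn)
      if (stats::runif(1L) < coup) {
        # follower relaxes toward the leader's current position
        cur[follower, ] <- cur[leader, ] +
          (cur[follower, ] - cur[leader, ]) * phif +
          stats::rnorm(2L, 0, config$follow_noise_sd)
      } else {
        cur[follower, ] <- ctr[follower, ] +
          (cur[follower, ] - ctr[follower, ]) * phi + stats::rnorm(2L, 0, inn)
      }
    }
    pos[i, ] <- c(cur[1L, ], cur[2L, ])
    role1[i] <- leader == 1L
  }

  data.frame(
    individual_id = rep(ids, each = n),
    pair_id = pair_id,
    sex = rep(sexes, each = n),
    time_s = rep(times, 2L),
    x_m = c(pos[, 1L], pos[, 3L]),
    y_m = c(pos[, 2L], pos[, 4L]),
    role = c(ifelse(role1, "leader", "follower"),
             ifelse(role1, "follower", "leader")),
    stringsAsFactors = FALSE
  )
}

#' Detection-emission configuration
#'
#' Governs how simulated beacons turn into receiver detections: detection
#' probability is a logistic decay in distance with a hard cutoff at
#' `max_detect_distance`, multiplied by `ground_height_penalty` for tags at
#' ground level; RSS is the inverse calibration law at the true distance
#' plus Gaussian noise.
#'
#' @param curve a [calibration_curve()]; default [reference_curve()].
#' @param rss_noise_sd RSS noise sd in dB.
#' @param max_detect_distance hard detection cutoff in meters.
#' @param p_max detection probability at zero distance, in (0, 1].
#' @param d50 distance (m) at which probability halves (logistic midpoint).
#' @param logistic_width logistic scale (m).
#' @param ground_height_penalty multiplicative penalty in (0, 1] for
#'   ground-level tags; default 1/8.3, the scale of the field-observed drop.
#' @param min_distance clamp (m) applied before inverting the curve.
#' @return an `emission_config` list.
#' @export
emission_config <- function(curve = reference_curve(),
                            rss_noise_sd = 2,
                            max_detect_distance = 250,
                            p_max = 0.9,
                            d50 = 90,
                            logistic_width = 30,
                            ground_height_penalty = 1 / 8.3,
                            min_distance = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (ground_height_penalty <= 0 || ground_height_penalty > 1)
    stopf("ground_height_penalty must lie in (0, 1]")
  if (p_max <= 0 || p_max > 1) stopf("p_max must lie in (0, 1]")
  structure(list(curve = curve, rss_noise_sd = rss_noise_sd,
                 max_detect_distance = max_detect_distance,
                 p_max = p_max, d50 = d50, logistic_width = logistic_width,
                 ground_height_penalty = ground_height_penalty,
                 min_distance = min_distance),
            class = "emission_config")
}

#' Detection probability at a given distance and tag height
#'
#' @param emission an [emission_config()].
#' @param d distance in meters (vectorized).
#' @param height_class "elevated" or "ground".
#' @return probability in [0, 1]; 0 beyond the hard cutoff.
#' @export
detection_probability <- function(emission, d, height_class = "elevated") {
  stopifnot(inherits(emission, "emission_config"))
  p <- emission$p_max *
    stats::plogis((emission$d50 - d) / emission$logistic_width)
  p[d > emission$max_detect_distance] <- 0
  mult <- ifelse(height_class == "ground", emission$ground_height_penalty, 1)
  p * mult
}

#' Emit noisy detections from truth tracks over a receiver array
#'
#' For each beacon (one per track row) and each receiver within the hard
#' cutoff, a detection is emitted with probability
#' [detection_probability()]; its RSS is the inverse calibration law at the
#' (clamped) true distance plus Gaussian(0, rss_noise_sd) dB.
#'
#' @param tracks data frame with `individual_id`, `time_s`, `x_m`, `y_m`,
#'   optionally `height_class` (default "elevated").
#' @param array receiver data frame (`node_id`, `x_m`, `y_m`).
#' @param emission an [emission_config()].
#' @param seed integer seed.
#' @return data frame of detections (`tag_id`, `node_id`, `time_s`,
#'   `rss_db`), sorted by time then tag then receiver; empty for an empty
#'   array.
#' @export
emit_detections <- function(tracks, array, emission, seed = 1L) {
  stopifnot(inherits(emission, "emission_config"))
  empty <- data.frame(tag_id = character(0), node_id = character(0),
                      time_s = numeric(0), rss_db = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(array) == 0L || nrow(tracks) == 0L) return(empty)
  assert_cols(tracks, c("individual_id", "time_s", "x_m", "y_m"), "tracks")
  if (any(!is.finite(tracks$x_m)) || any(!is.finite(tracks$y_m)))
    stopf("emit_detections: track positions must be finite")
  set.seed(seed)
  hc <- if (is.null(tracks$height_class)) rep("elevated", nrow(tracks))
        else tracks$height_class

  # distance matrix: track rows x receivers
  dx <- outer(tracks$x_m, array$x_m, "-")
  dy <- outer(tracks$y_m, array$y_m, "-")
  d <- sqrt(dx * dx + dy * dy)
  d_clamped <- pmax(d, emission$min_distance)
  p <- emission$p_max *
    stats::plogis((emission$d50 - d_clamped) / emission$logistic_width)
  p[d_clamped > emission$max_detect_distance] <- 0
  p <- p * ifelse(hc == "ground", emission$ground_height_penalty, 1)

  hit <- which(matrix(stats::runif(length(p)), nrow(p), ncol(p)) < p,
               arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  dd <- d_clamped[hit]
  out <- data.frame(
    tag_id = tracks$individual_id[hit[, 1L]],
    node_id = array$node_id[hit[, 2L]],
    time_s = tracks$time_s[hit[, 1L]],
    rss_db = distance_to_rss(emission$curve, dd) +
      stats::rnorm(length(dd), 0, emission$rss_noise_sd),
    stringsAsFactors = FALSE
  )
  out[order(out$time_s, out$tag_id, out$node_id), , drop = FALSE]
}

#' Simulate a calibration walk
#'
#' Emulates the field protocol: tags held at a ladder of set distances from
#' several receivers; each (tag, receiver, distance) yields one RSS drawn
#' from the inverse calibration law plus noise.
#'
#' @param curve generating [calibration_curve()].
#' @param distances distance ladder in meters; default the 18-step 1-200 m
#'   ladder used in the field.
#' @param n_tags,n_receivers numbers of tags and receivers.
#' @param rss_noise_sd RSS noise sd in dB.
#' @param seed integer seed.
#' @return data frame (`tag_id`, `node_id`, `true_distance_m`, `rss_db`,
#'   `height_class`).
#' @export
simulate_calibration_walk <- function(curve = reference_curve(),
                                      distances = c(1, 2, 3, 4, 5, 7.5, 10,
                                                    12.5, 15, 20, 25, 30, 40,
                                                    50, 75, 100, 150, 200),
                                      n_tags = 6, n_receivers = 4,
                                      rss_noise_sd = 2, seed = 1L) {
  set.seed(seed)
  g <- expand.grid(tag = seq_len(n_tags), node = seq_len(n_receivers),
                   d = distances)
  data.frame(
    tag_id = sprintf("T%02d", g$tag),
    node_id = sprintf("N%03d", g$node),
    true_distance_m = g$d,
    rss_db = distance_to_rss(curve, g$d) +
      stats::rnorm(nrow(g), 0, rss_noise_sd),
    height_class = "elevated",
    stringsAsFactors = FALSE
  )
}

#' Simulate a ground-vs-elevated test-point trial
#'
#' Stationary tags at test points near a single receiver, each beaconing
#' `beacons_per_point` times at both heights; detection uses the emission
#' config so the ground penalty propagates to realized detection rates.
#'
#' @param emission an [emission_config()].
#' @param n_points number of test points.
#' @param beacons_per_point beacons per (point, height) trial.
#' @param distance tag-receiver distance (m) for all points.
#' @param seed integer seed.
#' @return data frame suitable for [point_detection_metrics()] plus the
#'   trial enumeration in attribute `all_points`.
#' @export
simulate_height_trial <- function(emission, n_points = 86,
                                  beacons_per_point = 8, distance = 95,
                                  seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (h in c("elevated", "ground")) {
    p <- detection_probability(emission, distance, h)
    for (pt in seq_len(n_points)) {
      det <- which(stats::runif(beacons_per_point) < p)
      if (length(det) > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          test_point_id = sprintf("TP%03d", pt),
          height_class = h,
          time_s = (det - 1L) * 15,
          node_id = "N001",
          rss_db = distance_to_rss(emission$curve, distance) +
            stats::rnorm(length(det), 0, emission$rss_noise_sd),
          stringsAsFactors = FALSE
        )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "all_points") <- expand.grid(
    test_point_id = sprintf("TP%03d", seq_len(n_points)),
    height_class = c("elevated", "ground"),
    stringsAsFactors = FALSE
  )
  out
}

#' Build a per-date daylight table
#'
#' @param start_date first date ("YYYY-MM-DD", UTC).
#' @param n_days number of consecutive days.
#' @param sunrise_hour,sunset_hour clock hours of sunrise and sunset.
#' @return data frame (`date`, `sunrise_s`, `sunset_s`) in epoch seconds.
#' @export
daylight_table <- function(start_date = "2023-09-07", n_days = 1,
                           sunrise_hour = 6, sunset_hour = 20) {
  d0 <- as.numeric(as.POSIXct(paste0(start_date, " 00:00:00"), tz = "UTC"))
  day <- d0 + (seq_len(n_days) - 1L) * 86400
  data.frame(
    date = epoch_date(day),
    sunrise_s = day + sunrise_hour * 3600,
    sunset_s = day + sunset_hour * 3600,
    stringsAsFactors = FALSE
  )
}
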