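# Dyadic cohesion: pairwise separation against a day-shifted null,
# movement-event and following-event detection on strongest-method series,
# percentile lag thresholding, following rates, and initiation attribution.

#' Cohesion configuration
#'
#' @param day_shift_days day offset of the proximity null (default 1: the
#'   partner's track from the next day at the same time of day).
#' @param lag_percentile percentile of candidate lags used as the
#'   following-event threshold (default 90).
#' @param confidence_cutoff RSS confidence cutoff in dB for movement-event
#'   endpoints (default -80).
#' @param window_s matching window in seconds (default 15).
#' @param staleness_s how long before a departure the follower's last fix
#'   at the shared location may lie and still count as "present"; NULL
#'   (default) means use the lag threshold once computed.
#' @return a `cohesion_config` list.
#' @export
cohesion_config <- function(day_shift_days = 1, lag_percentile = 90,
                            confidence_cutoff = -80, window_s = 15,
                            staleness_s = NULL) {
  if (lag_percentile <= 0 || lag_percentile > 100)
    stopf("lag_percentile must lie in (0, 100]")
  if (day_shift_days < 1) stopf("day_shift_days must be >= 1")
  structure(list(day_shift_days = day_shift_days,
                 lag_percentile = lag_percentile,
                 confidence_cutoff = confidence_cutoff,
                 window_s = window_s, staleness_s = staleness_s),
            class = "cohesion_config")
}

#' Pairwise separation series (true or day-shifted null)
#'
#' In `true` mode the two individuals' estimates are matched on identical
#' windows and the Euclidean separation recorded. In `null` mode individual
#' a's window at (day x, time of day) is matched to b's at (day x +
#' day_shift, same time of day) — the separation expected if the partners
#' moved independently, preserving each bird's time-of-day routine.
#'
#' @param locs_a,locs_b per-window estimates of the same method (`tag_id`,
#'   `window_start`, `x_m`, `y_m`, optionally `node_id`).
#' @param config a [cohesion_config()].
#' @param mode "true" or "null".
#' @return data frame (`window_start` of a, `distance_m`, `same_receiver`
#'   where both carry receiver ids, `kind`). Empty with a warning when no
#'   windows match.
#' @export
separation_series <- function(locs_a, locs_b, config = cohesion_config(),
                              mode = c("true", "null")) {
  mode <- match.arg(mode)
  for (l in list(locs_a, locs_b))
    assert_cols(l, c("window_start", "x_m", "y_m"), "estimates")
  shift <- if (mode == "null") config$day_shift_days * 86400 else 0
  b <- locs_b
  b$match_window <- b$window_start - shift
  idx <- match(locs_a$window_start, b$match_window)
  ok <- !is.na(idx)
  if (!any(ok)) {
    warning("separation_series: no overlapping matched windows")
    return(data.frame(window_start = numeric(0), distance_m = numeric(0),
                      same_receiver = logical(0), kind = character(0)))
  }
  a <- locs_a[ok, , drop = FALSE]
  b <- b[idx[ok], , drop = FALSE]
  same <- if (!is.null(a$node_id) && !is.null(b$node_id))
    a$node_id == b$node_id else NA
  data.frame(window_start = a$window_start,
             distance_m = sqrt((a$x_m - b$x_m)^2 + (a$y_m - b$y_m)^2),
             same_receiver = same,
             kind = mode, stringsAsFactors = FALSE)
}

#' Extract movement events from a strongest-method series
#'
#' A movement event is a change of strongest-detection receiver between
#' consecutive localized windows (unlocalized gaps are skipped), with both
#' endpoint detections above the confidence cutoff. Departure time is the
#' last window at the origin receiver, arrival time the first window at
#' the destination.
#'
#' @param locs strongest-method estimates for one individual (`tag_id`,
#'   `window_start`, `node_id`, `rss_db`).
#' @param config a [cohesion_config()].
#' @return data frame (`individual_id`, `from_node`, `to_node`,
#'   `depart_time`, `arrive_time`).
#' @export
extract_movement_events <- function(locs, config = cohesion_config()) {
  assert_cols(locs, c("tag_id", "window_start", "node_id", "rss_db"),
              "strongest-method estimates")
  empty <- data.frame(individual_id = character(0), from_node = character(0),
                      to_node = character(0), depart_time = numeric(0),
                      arrive_time = numeric(0), stringsAsFactors = FALSE)
  locs <- locs[locs$rss_db >= config$confidence_cutoff, , drop = FALSE]
  if (nrow(locs) < 2L) return(empty)
  locs <- locs[order(locs$window_start), , drop = FALSE]
  prev <- seq_len(nrow(locs) - 1L)
  moved <- locs$node_id[prev + 1L] != locs$node_id[prev]
  if (!any(moved)) return(empty)
  data.frame(
    individual_id = locs$tag_id[1L],
    from_node = locs$node_id[prev][moved],
    to_node = locs$node_id[prev + 1L][moved],
    depart_time = locs$window_start[prev][moved],
    arrive_time = locs$window_start[prev + 1L][moved],
    stringsAsFactors = FALSE
  )
}

#' Candidate following events for a leader's movement events
#'
#' For each leader movement event A -> B, a candidate following event
#' exists when (i) the follower's most recent localization at or before the
#' leader's departure was at A (within a staleness limit), and (ii) the
#' follower's own first movement event departing A at or after the leader's
#' departure also arrives at B. The lag is follower arrival minus leader
#' arrival (clamped at 0 when the follower arrives first); no threshold is
#' applied at this stage.
#'
#' @param events_leader movement events of the leader
#'   ([extract_movement_events()]).
#' @param locs_follower strongest-method estimates of the partner.
#' @param config a [cohesion_config()]; `staleness_s = NULL` means
#'   unlimited at this stage (thresholding happens later).
#' @return data frame (`leader_id`, `follower_id`, `from_node`, `to_node`,
#'   `leader_depart`, `leader_arrive`, `follower_arrive`, `lag_s`).
#' @export
extract_following_events <- function(events_leader, locs_follower,
                                     config = cohesion_config()) {
  empty <- data.frame(leader_id = character(0), follower_id = character(0),
                      from_node = character(0), to_node = character(0),
                      leader_depart = numeric(0), leader_arrive = numeric(0),
                      follower_arrive = numeric(0), lag_s = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(events_leader) == 0L || nrow(locs_follower) < 2L) return(empty)
  f_locs <- locs_follower[locs_follower$rss_db >= config$confidence_cutoff, ,
                          drop = FALSE]
  f_locs <- f_locs[order(f_locs$window_start), , drop = FALSE]
  f_events <- extract_movement_events(f_locs, config)
  out <- list()
  for (i in seq_len(nrow(events_leader))) {
    ev <- events_leader[i, ]
    # follower's most recent fix at or before the leader's departure
    j <- findInterval(ev$depart_time, f_locs$window_start)
    if (j == 0L) next
    if (f_locs$node_id[j] != ev$from_node) next
    if (!is.null(config$staleness_s) &&
        ev$depart_time - f_locs$window_start[j] > config$staleness_s) next
    # follower's first own departure from A at or after the leader's
    cand <- f_events[f_events$from_node == ev$from_node &
                     f_events$depart_time >= ev$depart_time, , drop = FALSE]
    if (nrow(cand) == 0L) next
    cand <- cand[which.min(cand$depart_time), ]
    if (cand$to_node != ev$to_node) next
    out[[length(out) + 1L]] <- data.frame(
      leader_id = ev$individual_id, follower_id = f_locs$tag_id[1L],
      from_node = ev$from_node, to_node = ev$to_node,
      leader_depart = ev$depart_time, leader_arrive = ev$arrive_time,
      follower_arrive = cand$arrive_time,
      lag_s = max(0, cand$arrive_time - ev$arrive_time),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Lag threshold at the configured percentile
#'
#' Nearest-rank percentile of candidate following-event lags; extreme lags
#' caused by long detection gaps fall above it and are discarded
#' downstream. By construction at least `lag_percentile`% of candidates
#' fall at or below the returned value.
#'
#' @param candidates candidate events from [extract_following_events()],
#'   or a numeric vector of lags.
#' @param config a [cohesion_config()].
#' @return threshold in seconds.
#' @export
lag_threshold <- function(candidates, config = cohesion_config()) {
  lags <- if (is.data.frame(candidates)) candidates$lag_s else candidates
  if (length(lags) == 0L)
    stopf("lag_threshold: no candidate following events")
  nearest_rank_percentile(lags, config$lag_percentile)
}

#' Following rate over a leader's movement events
#'
#' Denominator: leader movement events where both birds carry at least one
#' localization within `threshold` seconds of the event (its
#' [depart - threshold, arrive + threshold] envelope) — events where either
#' bird was effectively unobserved are excluded. Numerator: those events
#' matched by a candidate following event with lag <= threshold. Undefined
#' (zero-denominator) rates are NA, never 0.
#'
#' @param events_leader leader movement events.
#' @param candidates candidate following events for those events.
#' @param threshold lag threshold in seconds (>= 0; 0 admits only
#'   same-window arrivals), from [lag_threshold()].
#' @param locs_leader,locs_follower the two birds' strongest-method
#'   estimates (used for the observed-within-threshold exclusion).
#' @return list: `rate`, `n_events` (eligible denominator), `n_followed`.
#' @export
following_rate <- function(events_leader, candidates, threshold,
                           locs_leader, locs_follower) {
  if (!is.numeric(threshold) || threshold < 0)
    stopf("following_rate: threshold must be >= 0")
  if (nrow(events_leader) == 0L)
    return(list(rate = NA_real_, n_events = 0L, n_followed = 0L))
  observed_near <- function(locs, lo, hi) {
    w <- locs$window_start
    vapply(seq_along(lo), function(i) any(w >= lo[i] & w <= hi[i]),
           logical(1L))
  }
  lo <- events_leader$depart_time - threshold
  hi <- events_leader$arrive_time + threshold
  eligible <- observed_near(locs_leader, lo, hi) &
              observed_near(locs_follower, lo, hi)
  ev <- events_leader[eligible, , drop = FALSE]
  if (nrow(ev) == 0L)
    return(list(rate = NA_real_, n_events = 0L, n_followed = 0L))
  ok_cand <- candidates[candidates$lag_s <= threshold, , drop = FALSE]
  key <- function(d, depart) paste(d$from_node, d$to_node, depart)
  followed <- key(ev, ev$depart_time) %in% key(ok_cand, ok_cand$leader_depart)
  list(rate = mean(followed), n_events = nrow(ev),
       n_followed = sum(followed))
}

#' Attribute movement initiations within co-location episodes
#'
#' An episode is a maximal run of windows in which both pair members are
#' localized at the same receiver. At its end, whichever bird is first
#' localized at a different receiver initiated the departure; identical
#' departure windows count as simultaneous. Episodes where neither bird is
#' seen elsewhere afterwards are skipped. Shares sum to 1 over attributed
#' episodes.
#'
#' @param locs_a,locs_b strongest-method estimates of the two pair members.
#' @param config a [cohesion_config()].
#' @return list: `shares` (named: a_first, b_first, simultaneous),
#'   `n_episodes`.
#' @export
initiation_attribution <- function(locs_a, locs_b,
                                   config = cohesion_config()) {
  for (l in list(locs_a, locs_b))
    assert_cols(l, c("window_start", "node_id"), "estimates")
  a <- locs_a[order(locs_a$window_start), , drop = FALSE]
  b <- locs_b[order(locs_b$window_start), , drop = FALSE]
  idx <- match(a$window_start, b$window_start)
  shared <- !is.na(idx) & a$node_id == b$node_id[ifelse(is.na(idx), 1L, idx)]
  if (!any(shared))
    return(list(shares = c(a_first = NA_real_, b_first = NA_real_,
                           simultaneous = NA_real_), n_episodes = 0L))
  r <- rle(shared)
  ends <- cumsum(r$lengths)
  counts <- c(a_first = 0L, b_first = 0L, simultaneous = 0L)
  first_departure <- function(locs, t_end, node) {
    later <- locs[locs$window_start > t_end & locs$node_id != node, ,
                  drop = FALSE]
    if (nrow(later) == 0L) NA_real_ else later$window_start[1L]
  }
  for (k in which(r$values)) {
    i_end <- ends[k]
    t_end <- a$window_start[i_end]
    node <- a$node_id[i_end]
    da <- first_departure(a, t_end, node)
    db <- first_departure(b, t_end, node)
    if (is.na(da) && is.na(db)) next
    if (is.na(db) || (!is.na(da) && da < db)) {
      counts["a_first"] <- counts["a_first"] + 1L
    } else if (is.na(da) || db < da) {
      counts["b_first"] <- counts["b_first"] + 1L
    } else {
      counts["simultaneous"] <- counts["simultaneous"] + 1L
    }
  }
  n <- sum(counts)
  list(shares = if (n > 0L) counts / n else counts * NA_real_,
       n_episodes = n)
}
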