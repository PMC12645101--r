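# Localization: raw detections -> per-15-s-window location estimates by the
# strongest-detection and multilateration methods, plus localization-rate
# and gap diagnostics.

#' Localization configuration
#'
#' @param window_s window length in seconds (default 15, the beacon
#'   interval).
#' @param rss_cutoff signal cutoff in dB; windows whose strongest detection
#'   is below it are discarded (default -80 dB, a 23.5 m radius under the
#'   field calibration).
#' @param min_receivers minimum receivers for multilateration (default 3).
#' @param n_resamples distance resamples per multilateration fix
#'   (default 100).
#' @param max_drop_frac maximum fraction of non-converged resamples before
#'   the fix is abandoned.
#' @param seed integer seed for the resampling.
#' @return a `localization_config` list.
#' @export
localization_config <- function(window_s = 15, rss_cutoff = -80,
                                min_receivers = 3, n_resamples = 100,
                                max_drop_frac = 0.5, seed = 1L) {
  if (window_s <= 0) stopf("window_s must be > 0")
  if (n_resamples < 2) stopf("n_resamples must be >= 2")
  structure(list(window_s = window_s, rss_cutoff = rss_cutoff,
                 min_receivers = min_receivers, n_resamples = n_resamples,
                 max_drop_frac = max_drop_frac, seed = seed),
            class = "localization_config")
}

#' Collapse detections into epoch-aligned windows
#'
#' Windows are half-open intervals [k*window_s, (k+1)*window_s) on the
#' shared epoch grid, so windows coincide across tags. Within a window each
#' receiver keeps only its strongest (maximum RSS) detection. Exact
#' duplicate records are removed first (count reported via a message);
#' unsorted input is sorted.
#'
#' @param detections data frame (`tag_id`, `node_id`, `time_s`, `rss_db`).
#' @param config a [localization_config()].
#' @return data frame (`tag_id`, `window_start`, `node_id`, `rss_db`), one
#'   row per (tag, window, receiver).
#' @export
window_detections <- function(detections, config = localization_config()) {
  assert_cols(detections, c("tag_id", "node_id", "time_s", "rss_db"),
              "detections")
  if (nrow(detections) == 0L)
    return(data.frame(tag_id = character(0), window_start = numeric(0),
                      node_id = character(0), rss_db = numeric(0)))
  if (any(!is.finite(detections$time_s)) || any(!is.finite(detections$rss_db)))
    stopf("window_detections: times and RSS must be finite")
  dt <- data.table::as.data.table(detections)
  ndup <- nrow(dt) - data.table::uniqueN(dt)
  if (ndup > 0L) {
    message(sprintf("window_detections: removed %d duplicate record(s)", ndup))
    dt <- unique(dt)
  }
  dt[, window_start := floor(time_s / config$window_s) * config$window_s]
  agg <- dt[, .(rss_db = max(rss_db)), by = .(tag_id, window_start, node_id)]
  data.table::setorder(agg, tag_id, window_start, node_id)
  as.data.frame(agg)
}

#' Strongest-detection localization
#'
#' Each window's location is the coordinates of the receiver with the
#' strongest detection, provided that detection meets the RSS cutoff. Ties
#' at the maximum RSS break deterministically to the lowest receiver id.
#'
#' @param windows windowed detections from [window_detections()].
#' @param array receiver data frame (`node_id`, `x_m`, `y_m`).
#' @param config a [localization_config()].
#' @return data frame of estimates (`tag_id`, `window_start`, `x_m`, `y_m`,
#'   `node_id`, `method` = "strongest", `n_receivers`, `rss_db` of the
#'   winning detection); windows failing the cutoff are absent.
#' @export
localize_strongest <- function(windows, array, config = localization_config()) {
  assert_cols(windows, c("tag_id", "window_start", "node_id", "rss_db"),
              "windowed detections")
  unknown <- setdiff(unique(windows$node_id), array$node_id)
  if (length(unknown) > 0L)
    stopf("localize_strongest: receiver(s) absent from array: %s",
          paste(unknown, collapse = ", "))
  dt <- data.table::as.data.table(windows)
  data.table::setorder(dt, tag_id, window_start, -rss_db, node_id)
  best <- dt[, .(node_id = node_id[1L], rss_db = rss_db[1L],
                 n_receivers = .N), by = .(tag_id, window_start)]
  best <- best[rss_db >= config$rss_cutoff]
  out <- merge(best, data.table::as.data.table(array), by = "node_id")
  out[, method := "strongest"]
  data.table::setorder(out, tag_id, window_start)
  as.data.frame(out[, .(tag_id, window_start, x_m, y_m, node_id, method,
                        n_receivers, rss_db)])
}

# One multilateration fix: resample per-receiver distances on the
# log10-meter scale, solve the nonlinear least-squares range problem per
# resample, and summarize the cloud of fits.
multilaterate_window <- function(rx, ry, rss, curve, config, bounds) {
  k <- length(rx)
  mu <- curve$intercept + curve$slope * rss       # log10 mean distance
  d_hat <- 10^mu
  w <- 1 / pmax(d_hat, 1)
  x0 <- c(sum(rx * w) / sum(w), sum(ry * w) / sum(w))
  obj <- function(p, d) {
    dx <- p[1L] - rx; dy <- p[2L] - ry
    r <- sqrt(dx * dx + dy * dy)
    sum((r - d)^2)
  }
  grad <- function(p, d) {
    dx <- p[1L] - rx; dy <- p[2L] - ry
    r <- pmax(sqrt(dx * dx + dy * dy), 1e-9)
    f <- 2 * (r - d) / r
    c(sum(f * dx), c(sum(f * dy)))
  }
  fits <- matrix(NA_real_, config$n_resamples, 2L)
  for (j in seq_len(config$n_resamples)) {
    d_j <- 10^(mu + stats::rnorm(k, 0, curve$residual_se))
    res <- tryCatch(
      stats::optim(x0, obj, gr = grad, d = d_j, method = "L-BFGS-B",
                   lower = bounds[c(1L, 3L)], upper = bounds[c(2L, 4L)]),
      error = function(e) NULL)
    if (!is.null(res) && res$convergence == 0L) fits[j, ] <- res$par
  }
  ok <- stats::complete.cases(fits)
  if (mean(ok) < 1 - config$max_drop_frac) return(NULL)
  fits <- fits[ok, , drop = FALSE]
  ctr <- colMeans(fits)
  if (nrow(fits) >= 2L) {
    cv <- stats::cov(fits)
    ev <- eigen(cv, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    a <- sqrt(2) * sqrt(lam[1L])
    b <- sqrt(2) * sqrt(lam[2L])
    th <- atan2(ev$vectors[2L, 1L], ev$vectors[1L, 1L])
  } else {
    a <- b <- 0; th <- 0
  }
  list(x = ctr[1L], y = ctr[2L], ellipse_a = a, ellipse_b = b,
       ellipse_theta = th, n_used = nrow(fits))
}

#' Multilateration localization with resampled error ellipses
#'
#' A window is localized only when at least `min_receivers` receivers heard
#' the tag and the strongest detection meets the RSS cutoff. Per-receiver
#' distances are drawn `n_resamples` times as 10^Normal(a + b*RSS,
#' residual_se) (Gaussian on the log10-meter scale, the scale of the fitted
#' calibration law); each draw is solved by bounded nonlinear least squares
#' on sum_i (||p - r_i|| - d_i)^2, initialized at the proximity-weighted
#' receiver centroid and bounded by the array bounding box expanded by
#' 200 m. The reported location is the mean of the converged fits; the
#' error ellipse is the sqrt(2)-scaled eigendecomposition of their sample
#' covariance.
#'
#' @param windows windowed detections from [window_detections()].
#' @param array receiver data frame (`node_id`, `x_m`, `y_m`).
#' @param curve a [calibration_curve()].
#' @param config a [localization_config()].
#' @return data frame of estimates (`tag_id`, `window_start`, `x_m`, `y_m`,
#'   `method` = "multilateration", `n_receivers`, `ellipse_a_m`,
#'   `ellipse_b_m`, `ellipse_theta_rad`).
#' @export
localize_multilateration <- function(windows, array, curve,
                                     config = localization_config()) {
  assert_cols(windows, c("tag_id", "window_start", "node_id", "rss_db"),
              "windowed detections")
  stopifnot(inherits(curve, "calibration_curve"))
  unknown <- setdiff(unique(windows$node_id), array$node_id)
  if (length(unknown) > 0L)
    stopf("localize_multilateration: receiver(s) absent from array: %s",
          paste(unknown, collapse = ", "))
  set.seed(config$seed)
  bounds <- c(min(array$x_m) - 200, max(array$x_m) + 200,
              min(array$y_m) - 200, max(array$y_m) + 200)
  coords <- array[match(windows$node_id, array$node_id), c("x_m", "y_m")]
  dt <- data.table::data.table(
    tag_id = windows$tag_id, window_start = windows$window_start,
    node_id = windows$node_id, rss_db = windows$rss_db,
    rx = coords$x_m, ry = coords$y_m)
  data.table::setorder(dt, tag_id, window_start)
  keys <- unique(dt[, .(tag_id, window_start)])
  grp <- split(dt, by = c("tag_id", "window_start"), sorted = TRUE)
  out <- vector("list", length(grp))
  for (i in seq_along(grp)) {
    g <- grp[[i]]
    if (nrow(g) < config$min_receivers) next
    if (max(g$rss_db) < config$rss_cutoff) next
    fix <- multilaterate_window(g$rx, g$ry, g$rss_db, curve, config, bounds)
    if (is.null(fix)) next
    out[[i]] <- data.frame(
      tag_id = g$tag_id[1L], window_start = g$window_start[1L],
      x_m = fix$x, y_m = fix$y, method = "multilateration",
      n_receivers = nrow(g), ellipse_a_m = fix$ellipse_a,
      ellipse_b_m = fix$ellipse_b, ellipse_theta_rad = fix$ellipse_theta,
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L)
    return(data.frame(tag_id = character(0), window_start = numeric(0),
                      x_m = numeric(0), y_m = numeric(0),
                      method = character(0), n_receivers = integer(0),
                      ellipse_a_m = numeric(0), ellipse_b_m = numeric(0),
                      ellipse_theta_rad = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$tag_id, res$window_start), , drop = FALSE]
}

# Enumerate daylight window-start slots intersected with [span_lo, span_hi].
daylight_slots <- function(daylight, span_lo, span_hi, window_s) {
  slots <- numeric(0)
  for (i in seq_len(nrow(daylight))) {
    lo <- max(daylight$sunrise_s[i], span_lo)
    hi <- min(daylight$sunset_s[i], span_hi)
    if (hi <= lo) next
    # half-open [lo, hi): slots are window starts in that range
    first_idx <- ceiling(lo / window_s)
    last_idx <- ceiling(hi / window_s) - 1
    if (last_idx < first_idx) next
    slots <- c(slots, (first_idx:last_idx) * window_s)
  }
  slots
}

#' Realized localization rate per tag
#'
#' Fraction of daylight window slots between a tag's first and last
#' estimate that carry a localization, the standard yield metric for an
#' automated array.
#'
#' @param estimates estimate data frame (any method) with `tag_id`,
#'   `window_start`.
#' @param daylight per-date daylight table ([daylight_table()]).
#' @param window_s window length in seconds.
#' @return data frame (`tag_id`, `n_localized`, `n_slots`, `rate`).
#' @export
localization_rate <- function(estimates, daylight, window_s = 15) {
  if (is.null(daylight) || nrow(daylight) == 0L)
    stopf("localization_rate: daylight table must be non-empty")
  assert_cols(daylight, c("sunrise_s", "sunset_s"), "daylight table")
  assert_cols(estimates, c("tag_id", "window_start"), "estimates")
  out <- lapply(split(estimates, estimates$tag_id), function(e) {
    slots <- daylight_slots(daylight, min(e$window_start),
                            max(e$window_start) + window_s, window_s)
    n_loc <- sum(slots %in% e$window_start)
    data.frame(tag_id = e$tag_id[1L], n_localized = n_loc,
               n_slots = length(slots),
               rate = if (length(slots) > 0L) n_loc / length(slots) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Distribution of localization gaps
#'
#' Gaps are maximal runs of unlocalized daylight slots between a tag's
#' first and last estimate; runs never bridge nights (slots are enumerated
#' per daylight interval, so a gap reaching sunset ends there and a new gap
#' starts at the next sunrise).
#'
#' @inheritParams localization_rate
#' @return list with `gaps` (data frame `tag_id`, `start_s`, `length_s`)
#'   and `summary` (fractions of gaps < 30 s and < 10 min).
#' @export
gap_distribution <- function(estimates, daylight, window_s = 15) {
  assert_cols(estimates, c("tag_id", "window_start"), "estimates")
  gaps <- list()
  for (e in split(estimates, estimates$tag_id)) {
    span_lo <- min(e$window_start); span_hi <- max(e$window_start) + window_s
    for (i in seq_len(nrow(daylight))) {
      slots <- daylight_slots(daylight[i, , drop = FALSE], span_lo, span_hi,
                              window_s)
      if (length(slots) == 0L) next
      miss <- !(slots %in% e$window_start)
      r <- rle(miss)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values))
        gaps[[length(gaps) + 1L]] <- data.frame(
          tag_id = e$tag_id[1L], start_s = slots[starts[k]],
          length_s = r$lengths[k] * window_s, stringsAsFactors = FALSE)
    }
  }
  gaps <- if (length(gaps) > 0L) do.call(rbind, gaps)
          else data.frame(tag_id = character(0), start_s = numeric(0),
                          length_s = numeric(0))
  list(gaps = gaps,
       summary = c(frac_lt_30s = if (nrow(gaps)) mean(gaps$length_s < 30) else NA_real_,
                   frac_lt_10min = if (nrow(gaps)) mean(gaps$length_s < 600) else NA_real_,
                   n_gaps = nrow(gaps)))
}
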