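# RSS-distance calibration: the power law linking received signal strength
# (RSS, negative dB) to tag-receiver distance, fitted from calibration walks,
# plus per-test-point detection metrics used to quantify the effect of tag
# height above ground.

#' Construct a calibration curve
#'
#' The curve is the log-linear law distance(m) = 10^(a + b * RSS), with RSS in
#' dB (negative; closer to 0 = stronger). `residual_se` is the residual
#' standard error of the fitted regression on the log10-meter scale and drives
#' the distance resampling used by the multilateration localizer.
#'
#' @param intercept a, log10-meters at RSS = 0.
#' @param slope b, log10-meters per dB; must be negative so that weaker
#'   signals map to larger distances.
#' @param residual_se residual standard error on the log10-meter scale (>= 0).
#' @param n_obs number of observations behind the fit (informational).
#' @return an object of class `calibration_curve`.
#' @export
calibration_curve <- function(intercept, slope, residual_se = 0, n_obs = NA_integer_) {
  if (!is.finite(intercept) || !is.finite(slope))
    stopf("calibration_curve: coefficients must be finite")
  if (slope >= 0)
    stopf("calibration_curve: slope must be negative (distance must grow as RSS drops)")
  if (!is.finite(residual_se) || residual_se < 0)
    stopf("calibration_curve: residual_se must be >= 0")
  structure(list(intercept = intercept, slope = slope,
                 residual_se = residual_se, n_obs = n_obs),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("RSS-distance calibration: distance(m) = 10^(%.5f %+.5f * RSS)\n",
              x$intercept, x$slope))
  cat(sprintf("  residual SE (log10 m): %.4f   n = %s\n",
              x$residual_se, format(x$n_obs)))
  invisible(x)
}

#' The field-calibrated reference curve
#'
#' Convenience constructor for the field-calibrated law
#' distance(m) = 10^(-1.27009 - 0.03302 * RSS), under which an RSS of -80 dB
#' corresponds to a 23.5 m detection radius.
#'
#' @param residual_se residual spread on the log10-meter scale; default 0.
#' @return a `calibration_curve`.
#' @export
reference_curve <- function(residual_se = 0) {
  calibration_curve(-1.27009, -0.03302, residual_se = residual_se)
}

#' Fit the RSS-distance law from calibration-walk observations
#'
#' Ordinary least squares of log10(true distance) on observed RSS, pooling
#' tags and receivers into one global curve. The response is distance (not
#' RSS) so that the fitted coefficients plug directly into
#' [rss_to_distance()].
#'
#' @param obs data frame with columns `true_distance_m` (> 0) and `rss_db`;
#'   extra columns (tag_id, node_id, height_class, ...) are ignored.
#' @return a `calibration_curve`.
#' @export
fit_calibration <- function(obs) {
  assert_cols(obs, c("true_distance_m", "rss_db"), "calibration observations")
  ok <- is.finite(obs$true_distance_m) & is.finite(obs$rss_db)
  obs <- obs[ok, , drop = FALSE]
  if (nrow(obs) < 3L)
    stopf("fit_calibration: need at least 3 observations")
  if (any(obs$true_distance_m <= 0))
    stopf("fit_calibration: true distances must be > 0")
  if (length(unique(obs$rss_db)) < 2L)
    stopf("fit_calibration: singular design (all RSS values identical)")
  fit <- stats::lm(log10(true_distance_m) ~ rss_db, data = obs)
  co <- stats::coef(fit)
  sigma <- suppressWarnings(summary(fit)$sigma)  # warns on noiseless input
  calibration_curve(unname(co[1L]), unname(co[2L]),
                    residual_se = sigma,
                    n_obs = nrow(obs))
}

#' Convert RSS to distance under a calibration curve
#'
#' @param curve a `calibration_curve`.
#' @param rss RSS in dB (vectorized).
#' @return distance in meters.
#' @export
rss_to_distance <- function(curve, rss) {
  stopifnot(inherits(curve, "calibration_curve"))
  10^(curve$intercept + curve$slope * rss)
}

#' Convert distance to RSS (inverse of the calibration law)
#'
#' @param curve a `calibration_curve`.
#' @param d distance in meters, > 0 (vectorized).
#' @return RSS in dB.
#' @export
distance_to_rss <- function(curve, d) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(!is.finite(d)) || any(d <= 0))
    stopf("distance_to_rss: distances must be finite and > 0")
  (log10(d) - curve$intercept) / curve$slope
}

#' Per-test-point detection metrics from a calibration trial
#'
#' Summarizes stationary test-point trials (tags held at fixed points, e.g.
#' at ground level and elevated on poles): rate of detected beacons, number
#' of distinct receivers, mean and maximum RSS per (test point, height
#' class). A beacon counts as detected if at least one receiver heard it;
#' RSS summaries at undetected points are NA, never 0.
#'
#' @param detections data frame with columns `test_point_id`, `height_class`,
#'   `time_s` (beacon time, epoch s) and `rss_db`, plus `node_id`.
#' @param expected_beacons expected beacon count per (point, height) trial
#'   (scalar >= 1), from trial duration / beacon interval.
#' @param all_points optional data frame (`test_point_id`, `height_class`)
#'   enumerating trials, so points with zero detections appear with rate 0.
#' @return data frame with one row per (test_point_id, height_class):
#'   `detection_rate`, `n_receivers`, `mean_rss`, `max_rss`.
#' @export
point_detection_metrics <- function(detections, expected_beacons, all_points = NULL) {
  if (!is.numeric(expected_beacons) || length(expected_beacons) != 1L ||
      expected_beacons < 1)
    stopf("point_detection_metrics: expected_beacons must be a scalar >= 1")
  assert_cols(detections, c("test_point_id", "height_class", "time_s",
                            "node_id", "rss_db"), "test-point detections")
  dt <- data.table::as.data.table(detections)
  agg <- dt[, .(
    detection_rate = min(length(unique(time_s)) / expected_beacons, 1),
    n_receivers    = length(unique(node_id)),
    mean_rss       = mean(rss_db),
    max_rss        = max(rss_db)
  ), by = .(test_point_id, height_class)]
  out <- as.data.frame(agg)
  if (!is.null(all_points)) {
    all_points <- unique(all_points[, c("test_point_id", "height_class")])
    out <- merge(all_points, out, all.x = TRUE,
                 by = c("test_point_id", "height_class"))
    none <- is.na(out$detection_rate)
    out$detection_rate[none] <- 0
    out$n_receivers[none] <- 0L
  }
  out[order(out$test_point_id, out$height_class), , drop = FALSE]
}
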