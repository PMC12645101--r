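# I/O edge: CSV readers/writers with schema checks, ISO-8601 UTC parsing,
# and the end-to-end pipeline driver with a reproducibility manifest.
# Coordinates are planar meters throughout; geographic inputs must be
# projected before ingestion.

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stopf("%s: file not found: %s", what, path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(df, required, what)
  df
}

#' Read a detection table
#'
#' Expects columns `tag_id`, `node_id`, `time_utc` (ISO-8601), `rss_db`.
#' Rows with unparseable timestamps or non-finite RSS are dropped and
#' counted in a message.
#'
#' @param path CSV path.
#' @return data frame (`tag_id`, `node_id`, `time_s` epoch seconds,
#'   `rss_db`).
#' @export
read_detections <- function(path) {
  df <- read_csv_checked(path, c("tag_id", "node_id", "time_utc", "rss_db"),
                         "detections file")
  if (nrow(df) == 0L) {
    warning("read_detections: empty detections file")
    return(data.frame(tag_id = character(0), node_id = character(0),
                      time_s = numeric(0), rss_db = numeric(0)))
  }
  t <- suppressWarnings(parse_utc(df$time_utc))
  rss <- suppressWarnings(as.numeric(df$rss_db))
  ok <- is.finite(t) & is.finite(rss)
  if (any(!ok))
    message(sprintf("read_detections: dropped %d unparseable row(s)",
                    sum(!ok)))
  data.frame(tag_id = as.character(df$tag_id[ok]),
             node_id = as.character(df$node_id[ok]),
             time_s = t[ok], rss_db = rss[ok], stringsAsFactors = FALSE)
}

#' Read a receiver-array table
#'
#' @param path CSV path with columns `node_id`, `x_m`, `y_m`.
#' @return receiver data frame.
#' @export
read_receivers <- function(path) {
  df <- read_csv_checked(path, c("node_id", "x_m", "y_m"), "receivers file")
  if (anyDuplicated(df$node_id)) stopf("read_receivers: duplicate node ids")
  if (any(!is.finite(df$x_m)) || any(!is.finite(df$y_m)))
    stopf("read_receivers: coordinates must be finite")
  df
}

#' Read a calibration-walk table
#'
#' @param path CSV path with columns `tag_id`, `node_id`, `true_distance_m`,
#'   `rss_db`, `height_class`.
#' @return data frame ready for [fit_calibration()].
#' @export
read_calibration_walk <- function(path) {
  read_csv_checked(path, c("tag_id", "node_id", "true_distance_m", "rss_db",
                           "height_class"), "calibration file")
}

#' Write detections with ISO-8601 timestamps
#'
#' @param detections data frame with `time_s`.
#' @param path output CSV path.
#' @export
write_detections <- function(detections, path) {
  out <- data.frame(tag_id = detections$tag_id,
                    node_id = detections$node_id,
                    time_utc = format_utc(detections$time_s),
                    rss_db = detections$rss_db)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a calibration curve to a small text file
#'
#' @param curve a [calibration_curve()].
#' @param path output path (key: value lines).
#' @export
write_calibration_curve <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  writeLines(c(
    sprintf("intercept_log10m: %.10f", curve$intercept),
    sprintf("slope_log10m_per_db: %.10f", curve$slope),
    sprintf("residual_se_log10m: %.10f", curve$residual_se),
    sprintf("n_obs: %s", format(curve$n_obs))
  ), path)
  invisible(path)
}

#' Read a serialized calibration curve
#'
#' @param path path written by [write_calibration_curve()].
#' @return a [calibration_curve()].
#' @export
read_calibration_curve <- function(path) {
  kv <- utils::read.table(path, sep = ":", strip.white = TRUE,
                          col.names = c("key", "value"),
                          stringsAsFactors = FALSE)
  get <- function(k) as.numeric(kv$value[kv$key == k])
  calibration_curve(get("intercept_log10m"), get("slope_log10m_per_db"),
                    residual_se = get("residual_se_log10m"),
                    n_obs = suppressWarnings(as.integer(get("n_obs"))))
}

#' Run the full analysis pipeline
#'
#' Executes calibrate -> localize (strongest and/or multilateration) ->
#' coverage -> home range/overlap -> cohesion on the supplied input files
#' and writes every product plus a manifest (file list with MD5 hashes,
#' seed, config) under `out_dir`. Rerunning with identical inputs and seed
#' reproduces identical outputs.
#'
#' @param detections_csv,receivers_csv,calibration_csv input CSV paths.
#' @param metadata data frame (`tag_id`, `sex`, `pair_id`).
#' @param daylight per-date daylight table ([daylight_table()]).
#' @param out_dir output directory (created if needed).
#' @param week1_start,breeding_end epoch-second period anchors; defaults
#'   span the data.
#' @param methods estimate methods to run: subset of
#'   c("strongest", "multilateration").
#' @param loc_config a [localization_config()].
#' @param coh_config a [cohesion_config()].
#' @param seed integer seed recorded in the manifest and used for the
#'   multilateration resampling.
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(detections_csv, receivers_csv, calibration_csv,
                         metadata, daylight, out_dir,
                         week1_start = NULL, breeding_end = NULL,
                         methods = c("strongest", "multilateration"),
                         loc_config = localization_config(),
                         coh_config = cohesion_config(),
                         seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  det <- stage("read", read_detections(detections_csv))
  array <- stage("read", read_receivers(receivers_csv))
  walk <- stage("read", read_calibration_walk(calibration_csv))

  curve <- stage("calibrate", fit_calibration(walk))
  cp <- file.path(out_dir, "calibration_curve.txt")
  write_calibration_curve(curve, cp)
  outputs <- c(outputs, cp)

  loc_config$seed <- seed
  windows <- stage("localize", window_detections(det, loc_config))
  est <- list()
  if ("strongest" %in% methods) {
    est$strongest <- stage("localize",
                           localize_strongest(windows, array, loc_config))
    emit(est$strongest, "estimates_strongest.csv")
  }
  if ("multilateration" %in% methods) {
    est$multilateration <- stage("localize",
      localize_multilateration(windows, array, curve, loc_config))
    emit(est$multilateration, "estimates_multilateration.csv")
  }
  primary <- est$strongest %||% est$multilateration

  rates <- stage("localize", do.call(rbind, lapply(names(est), function(m) {
    r <- localization_rate(est[[m]], daylight, loc_config$window_s)
    r$method <- m
    r
  })))
  emit(rates, "localization_rates.csv")

  radius <- rss_to_distance(curve, loc_config$rss_cutoff)
  cov <- stage("coverage", coverage_report(
    array, radius = radius,
    array_area_km2 = diff(range(array$x_m)) * diff(range(array$y_m)) / 1e6))
  cov_rows <- data.frame(metric = names(cov),
                         value = unlist(cov, use.names = FALSE))
  mcp_rows <- do.call(rbind, lapply(split(primary, primary$tag_id),
    function(e) {
      if (nrow(e) < 3L) return(NULL)
      m <- tryCatch(minimum_convex_polygon(e, 100), error = function(x) NULL)
      if (is.null(m)) return(NULL)
      data.frame(tag_id = e$tag_id[1L], mcp_km2 = m$area_km2,
                 expected_fraction_pct =
                   expected_localization_fraction(array, m, radius))
    }))
  emit(cov_rows, "coverage_report.csv")
  if (!is.null(mcp_rows)) emit(mcp_rows, "coverage_per_individual.csv")

  if (is.null(week1_start)) week1_start <- min(primary$window_start)
  if (is.null(breeding_end)) breeding_end <- max(primary$window_start) + 1
  hr <- stage("homerange", split_and_summarize(
    primary, metadata, daylight, week1_start, breeding_end))
  emit(hr$areas, "homerange_areas.csv")
  emit(hr$dyads, "dyad_overlap.csv")

  pairs <- split(metadata$tag_id, metadata$pair_id)
  pairs <- pairs[lengths(pairs) == 2L]
  sep_rows <- list(); cand_all <- list(); rate_rows <- list()
  for (pid in names(pairs)) {
    ids <- sort(pairs[[pid]])
    la <- primary[primary$tag_id == ids[1L], , drop = FALSE]
    lb <- primary[primary$tag_id == ids[2L], , drop = FALSE]
    if (nrow(la) == 0L || nrow(lb) == 0L) next
    for (md in c("true", "null")) {
      s <- suppressWarnings(separation_series(la, lb, coh_config, md))
      if (nrow(s) > 0L) { s$pair_id <- pid; sep_rows[[paste(pid, md)]] <- s }
    }
    if (!is.null(la$node_id)) {
      ev <- extract_movement_events(la, coh_config)
      cand <- extract_following_events(ev, lb, coh_config)
      if (nrow(cand) > 0L) cand_all[[pid]] <- cbind(pair_id = pid, cand,
                                                    stringsAsFactors = FALSE)
    }
  }
  seps <- stage("cohesion", do.call(rbind, sep_rows))
  if (!is.null(seps)) emit(seps, "separation_series.csv")
  cands <- do.call(rbind, cand_all)
  if (!is.null(cands) && nrow(cands) > 0L) {
    thr <- lag_threshold(cands, coh_config)
    emit(cands, "following_candidates.csv")
    for (pid in names(pairs)) {
      ids <- sort(pairs[[pid]])
      la <- primary[primary$tag_id == ids[1L], , drop = FALSE]
      lb <- primary[primary$tag_id == ids[2L], , drop = FALSE]
      ev <- extract_movement_events(la, coh_config)
      cd <- cands[cands$pair_id == pid, , drop = FALSE]
      fr <- following_rate(ev, cd, thr, la, lb)
      rate_rows[[pid]] <- data.frame(pair_id = pid, leader_id = ids[1L],
                                     rate = fr$rate, n_events = fr$n_events,
                                     n_followed = fr$n_followed,
                                     lag_threshold_s = thr)
    }
    emit(do.call(rbind, rate_rows), "following_rates.csv")
  }

  manifest <- list(
    seed = seed,
    inputs = c(detections_csv, receivers_csv, calibration_csv),
    input_md5 = unname(tools::md5sum(c(detections_csv, receivers_csv,
                                       calibration_csv))),
    outputs = basename(outputs),
    output_md5 = unname(tools::md5sum(outputs)),
    config = list(localization = unclass(loc_config),
                  cohesion = unclass(coh_config),
                  methods = methods,
                  week1_start = week1_start, breeding_end = breeding_end)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
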