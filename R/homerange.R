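# Utilization distributions and overlap: grid kernel density estimates per
# individual/period, 95% home-range areas, Bhattacharyya overlap between
# dyads, and the weekly x section-of-day splitting of estimates.

#' Construct a utilization distribution from a mass matrix
#'
#' @param mass nx x ny matrix of non-negative cell masses; normalized to
#'   sum 1.
#' @param origin length-2 lower-left corner of cell (1,1), meters.
#' @param cell cell size in meters (> 0).
#' @return object of class `ud`.
#' @export
ud <- function(mass, origin = c(0, 0), cell = 10) {
  mass <- as.matrix(mass)
  if (any(!is.finite(mass)) || any(mass < 0))
    stopf("ud: masses must be finite and >= 0")
  s <- sum(mass)
  if (s <= 0) stopf("ud: total mass must be positive")
  structure(list(mass = mass / s, origin = as.numeric(origin), cell = cell),
            class = "ud")
}

#' @export
print.ud <- function(x, ...) {
  cat(sprintf("utilization distribution: %d x %d cells of %.1f m, origin (%.1f, %.1f)\n",
              nrow(x$mass), ncol(x$mass), x$cell, x$origin[1L], x$origin[2L]))
  invisible(x)
}

#' A common grid specification covering a set of points
#'
#' @param points data frame(s) with `x_m`, `y_m` (a list is row-bound).
#' @param cell cell size in meters.
#' @param pad padding in meters added on every side (e.g. 3 bandwidths).
#' @return list (`origin`, `cell`, `nx`, `ny`).
#' @export
ud_grid <- function(points, cell = 10, pad = 100) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, lapply(points, function(p) p[, c("x_m", "y_m")]))
  xr <- range(points$x_m) + c(-pad, pad)
  yr <- range(points$y_m) + c(-pad, pad)
  origin <- c(floor(xr[1L] / cell) * cell, floor(yr[1L] / cell) * cell)
  list(origin = origin, cell = cell,
       nx = ceiling((xr[2L] - origin[1L]) / cell),
       ny = ceiling((yr[2L] - origin[2L]) / cell))
}

#' Estimate a gridded utilization distribution by kernel density
#'
#' Gaussian product-kernel density on a regular grid (via MASS::kde2d),
#' converted to per-cell mass and renormalized to sum 1. The default
#' per-axis bandwidth is Silverman's rule-of-thumb (stats::bw.nrd). This is
#' a fixed-bandwidth stand-in for autocorrelation-adjusted estimators: it
#' preserves the overlap statistic and area extraction exactly while
#' keeping bandwidth selection simple.
#'
#' @param points data frame with `x_m`, `y_m`; at least 10 points.
#' @param bandwidth per-axis kernel sd in meters (scalar or length 2);
#'   default Silverman per axis.
#' @param grid grid spec from [ud_grid()]; default covers the points padded
#'   by 3 bandwidths.
#' @param cell cell size (m) when `grid` is NULL.
#' @return a [ud()].
#' @export
estimate_ud <- function(points, bandwidth = NULL, grid = NULL, cell = 10) {
  assert_cols(points, c("x_m", "y_m"), "points")
  points <- points[stats::complete.cases(points[, c("x_m", "y_m")]), ,
                   drop = FALSE]
  if (nrow(points) < 10L)
    stopf("estimate_ud: need at least 10 points")
  x <- points$x_m; y <- points$y_m
  if (is.null(bandwidth)) {
    bw_axis <- function(v) {
      b <- tryCatch(stats::bw.nrd(v), error = function(e) 0)
      if (!is.finite(b) || b <= 0) b <- cell  # degenerate spread fallback
      b
    }
    bandwidth <- c(bw_axis(x), bw_axis(y))
  }
  bandwidth <- rep(bandwidth, length.out = 2L)
  if (any(bandwidth <= 0)) stopf("estimate_ud: bandwidth must be > 0")
  if (is.null(grid))
    grid <- ud_grid(points, cell = cell, pad = 3 * max(bandwidth))
  # kde2d's h is 4x the Gaussian kernel sd
  lims <- c(grid$origin[1L] + grid$cell / 2,
            grid$origin[1L] + (grid$nx - 0.5) * grid$cell,
            grid$origin[2L] + grid$cell / 2,
            grid$origin[2L] + (grid$ny - 0.5) * grid$cell)
  kd <- MASS::kde2d(x, y, h = 4 * bandwidth, n = c(grid$nx, grid$ny),
                    lims = lims)
  out <- ud(kd$z, origin = grid$origin, cell = grid$cell)
  out$bandwidth <- bandwidth
  out
}

#' Home-range area at a utilization level
#'
#' Area of the smallest set of grid cells (filled greedily in descending
#' mass order) whose cumulative mass reaches `level` — the `level`
#' isopleth area of the UD.
#'
#' @param x a [ud()].
#' @param level utilization level in (0, 1]; default 0.95.
#' @return area in km^2.
#' @export
home_range_area <- function(x, level = 0.95) {
  stopifnot(inherits(x, "ud"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level > 1)
    stopf("home_range_area: level must lie in (0, 1]")
  m <- sort(x$mass[x$mass > 0], decreasing = TRUE)
  k <- which(cumsum(m) >= level - 1e-12)[1L]
  if (is.na(k)) k <- length(m)
  k * x$cell^2 / 1e6
}

#' Bhattacharyya coefficient between two utilization distributions
#'
#' BC = sum over cells of sqrt(p * q), from 0 (disjoint space use) to 1
#' (identical). The two UDs must live on aligned grids of equal cell size;
#' differing extents are reconciled over the union of cells (missing cells
#' carry zero mass).
#'
#' @param ud_a,ud_b [ud()] objects.
#' @return coefficient in [0, 1].
#' @export
bhattacharyya <- function(ud_a, ud_b) {
  stopifnot(inherits(ud_a, "ud"), inherits(ud_b, "ud"))
  if (abs(ud_a$cell - ud_b$cell) > 1e-9)
    stopf("bhattacharyya: grids have different cell sizes; regrid first")
  off <- (ud_b$origin - ud_a$origin) / ud_a$cell
  if (max(abs(off - round(off))) > 1e-6)
    stopf("bhattacharyya: grid origins are not aligned; regrid first")
  off <- round(off)
  # index ranges of b's cells in a's frame
  ai <- seq_len(nrow(ud_a$mass)); aj <- seq_len(ncol(ud_a$mass))
  bi <- seq_len(nrow(ud_b$mass)) + off[1L]
  bj <- seq_len(ncol(ud_b$mass)) + off[2L]
  ii <- intersect(ai, bi); jj <- intersect(aj, bj)
  if (length(ii) == 0L || length(jj) == 0L) return(0)
  pa <- ud_a$mass[ii, jj, drop = FALSE]
  pb <- ud_b$mass[ii - off[1L], jj - off[2L], drop = FALSE]
  min(sum(sqrt(pa * pb)), 1)
}

#' Refine a utilization distribution to a finer grid
#'
#' Splits every cell into `factor`^2 subcells with equal mass; used to put
#' UDs on a common finer grid. BC is invariant to common refinement.
#'
#' @param x a [ud()].
#' @param factor integer refinement factor (>= 1).
#' @return a [ud()] on the finer grid.
#' @export
regrid_ud <- function(x, factor) {
  stopifnot(inherits(x, "ud"))
  factor <- as.integer(factor)
  if (factor < 1L) stopf("regrid_ud: factor must be >= 1")
  if (factor == 1L) return(x)
  m <- x$mass[rep(seq_len(nrow(x$mass)), each = factor),
              rep(seq_len(ncol(x$mass)), each = factor)] / factor^2
  ud(m, origin = x$origin, cell = x$cell / factor)
}

#' Assign estimates to week, section of day, and breeding period
#'
#' Sections of day partition [0, 14) hours post sunrise into [0,3), [3,6),
#' [6,9), [9,14); later times fall in section 4 with a warning, earlier
#' (pre-sunrise) in section 1 with a warning. Weeks are 7-day blocks from
#' `week1_start`; estimates before it get week 0 and are flagged, not
#' dropped. The period is "breeding" strictly before `breeding_end` and
#' "post_breeding" from it on.
#'
#' @param estimates estimate data frame with `tag_id`, `window_start`.
#' @param daylight per-date daylight table ([daylight_table()]).
#' @param week1_start epoch second of the first day of week 1.
#' @param breeding_end epoch second of the breeding/post-breeding split.
#' @return `estimates` with columns `week`, `section`, `period` added.
#' @export
assign_periods <- function(estimates, daylight, week1_start, breeding_end) {
  assert_cols(estimates, c("tag_id", "window_start"), "estimates")
  assert_cols(daylight, c("date", "sunrise_s"), "daylight table")
  date <- epoch_date(estimates$window_start)
  sunrise <- daylight$sunrise_s[match(date, daylight$date)]
  if (any(is.na(sunrise)))
    stopf("assign_periods: daylight table does not cover all estimate dates")
  hps <- (estimates$window_start - sunrise) / 3600  # hours post sunrise
  section <- findInterval(hps, c(0, 3, 6, 9, 14), rightmost.closed = FALSE)
  if (any(section == 5L))
    warning("assign_periods: estimates beyond 14 h post sunrise assigned to section 4")
  if (any(section == 0L))
    warning("assign_periods: pre-sunrise estimates assigned to section 1")
  section <- pmin(pmax(section, 1L), 4L)
  week <- floor((estimates$window_start - week1_start) / (7 * 86400)) + 1L
  if (any(week < 1L))
    warning("assign_periods: estimates before week-1 start flagged as week 0")
  week[week < 1L] <- 0L
  estimates$week <- week
  estimates$section <- section
  estimates$period <- ifelse(estimates$window_start < breeding_end,
                             "breeding", "post_breeding")
  estimates
}

#' Enumerate all dyads among tagged individuals
#'
#' @param metadata data frame with `tag_id` and `pair_id`.
#' @return data frame (`id_a`, `id_b`, `dyad_type`), one row per unordered
#'   pair; `dyad_type` is "pair_bonded" when the two share a `pair_id`.
#' @export
enumerate_dyads <- function(metadata) {
  assert_cols(metadata, c("tag_id", "pair_id"), "metadata")
  ids <- sort(unique(metadata$tag_id))
  if (length(ids) < 2L) stopf("enumerate_dyads: need at least 2 individuals")
  cmb <- utils::combn(ids, 2L)
  pid <- metadata$pair_id[match(ids, metadata$tag_id)]
  names(pid) <- ids
  data.frame(
    id_a = cmb[1L, ], id_b = cmb[2L, ],
    dyad_type = ifelse(pid[cmb[1L, ]] == pid[cmb[2L, ]],
                       "pair_bonded", "not_pair_bonded"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Weekly/section home-range areas and per-period dyad overlap
#'
#' The two summary products of the space-use stage: (1) a 95% home-range
#' area per (individual, week, section of day) with at least `min_points`
#' estimates; (2) per breeding period, a pooled UD per individual on one
#' common grid and the Bhattacharyya coefficient for every dyad.
#'
#' @param estimates estimate data frame (`tag_id`, `window_start`, `x_m`,
#'   `y_m`), any one method.
#' @param metadata data frame (`tag_id`, `sex`, `pair_id`).
#' @param daylight per-date daylight table.
#' @param week1_start,breeding_end epoch-second period anchors.
#' @param cell UD cell size in meters.
#' @param level home-range utilization level.
#' @param min_points minimum estimates per split cell (default 10, the KDE
#'   minimum).
#' @return list with `areas` (individual, week, section, period, n,
#'   area_km2) and `dyads` (id_a, id_b, dyad_type, period, bc).
#' @export
split_and_summarize <- function(estimates, metadata, daylight,
                                week1_start, breeding_end,
                                cell = 10, level = 0.95, min_points = 10) {
  est <- assign_periods(estimates, daylight, week1_start, breeding_end)
  est <- est[order(est$tag_id, est$window_start), , drop = FALSE]

  dt <- data.table::as.data.table(est)
  grp <- split(dt, by = c("tag_id", "week", "section", "period"),
               sorted = TRUE, drop = TRUE)
  areas <- lapply(grp, function(g) {
    if (nrow(g) < min_points) return(NULL)
    u <- estimate_ud(as.data.frame(g), cell = cell)
    data.frame(individual_id = g$tag_id[1L], week = g$week[1L],
               section = g$section[1L], period = g$period[1L],
               n = nrow(g), area_km2 = home_range_area(u, level),
               stringsAsFactors = FALSE)
  })
  areas <- do.call(rbind, areas[!vapply(areas, is.null, logical(1L))])
  rownames(areas) <- NULL

  dyads_all <- enumerate_dyads(metadata)
  dyad_rows <- list()
  for (per in unique(est$period)) {
    ep <- est[est$period == per, , drop = FALSE]
    grid <- ud_grid(ep[, c("x_m", "y_m")], cell = cell, pad = 150)
    uds <- lapply(split(ep, ep$tag_id), function(g) {
      if (nrow(g) < min_points) return(NULL)
      estimate_ud(g, grid = grid)
    })
    for (k in seq_len(nrow(dyads_all))) {
      ua <- uds[[dyads_all$id_a[k]]]; ub <- uds[[dyads_all$id_b[k]]]
      if (is.null(ua) || is.null(ub)) next
      dyad_rows[[length(dyad_rows) + 1L]] <- data.frame(
        id_a = dyads_all$id_a[k], id_b = dyads_all$id_b[k],
        dyad_type = dyads_all$dyad_type[k], period = per,
        bc = bhattacharyya(ua, ub), stringsAsFactors = FALSE)
    }
  }
  dyads <- if (length(dyad_rows) > 0L) do.call(rbind, dyad_rows)
           else data.frame(id_a = character(0), id_b = character(0),
                           dyad_type = character(0), period = character(0),
                           bc = numeric(0))
  list(areas = areas, dyads = dyads)
}
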