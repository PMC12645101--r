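# Internal helpers shared across modules. Coordinates are planar meters,
# times numeric epoch seconds (UTC); conversion happens only at the I/O edge.

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stopf("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  invisible(df)
}

#' Nearest-rank empirical percentile
#'
#' The p-th percentile of `x` under the nearest-rank convention: the k-th
#' smallest value with k = ceiling(p/100 * n). Guarantees that at least p%
#' of the sample is <= the returned value, which downstream thresholding
#' relies on.
#'
#' @param x numeric vector, at least one finite value.
#' @param p percentile in (0, 100].
#' @return a single element of `x`.
#' @export
nearest_rank_percentile <- function(x, p) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stopf("nearest_rank_percentile: no finite values")
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 100)
    stopf("percentile must lie in (0, 100]")
  sort(x)[ceiling(p / 100 * length(x))]
}

# Shoelace area of a simple polygon given as a two-column matrix of vertices
# (closed implicitly). Returns absolute area in the input units squared.
polygon_area <- function(xy) {
  if (nrow(xy) < 3L) return(0)
  x <- xy[, 1L]; y <- xy[, 2L]
  j <- c(seq_len(nrow(xy))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Sutherland-Hodgman clipping of polygon `subject` against a *convex*
# polygon `clip` (both counter-clockwise two-column matrices).
clip_polygon_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0L) return(out)
    a <- clip[i, ]; b <- clip[if (i == nc) 1L else i + 1L, ]
    # signed side of edge a->b; >=0 keeps (inside for CCW clip polygon)
    side <- (b[1L] - a[1L]) * (out[, 2L] - a[2L]) -
            (b[2L] - a[2L]) * (out[, 1L] - a[1L])
    inp <- out; ins <- side >= 0
    nxt <- c(seq_len(nrow(inp))[-1L], 1L)
    res <- matrix(numeric(0), ncol = 2L)
    for (k in seq_len(nrow(inp))) {
      p <- inp[k, ]; q <- inp[nxt[k], ]
      pin <- ins[k]; qin <- ins[nxt[k]]
      if (pin) res <- rbind(res, p)
      if (xor(pin, qin)) {
        # intersection of segment p->q with infinite line a->b
        d1 <- (b[1L] - a[1L]) * (p[2L] - a[2L]) - (b[2L] - a[2L]) * (p[1L] - a[1L])
        d2 <- (b[1L] - a[1L]) * (q[2L] - a[2L]) - (b[2L] - a[2L]) * (q[1L] - a[1L])
        t <- d1 / (d1 - d2)
        res <- rbind(res, p + t * (q - p))
      }
    }
    out <- res
  }
  out
}

# Counter-clockwise orientation of a polygon (positive signed area).
ensure_ccw <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  j <- c(seq_len(nrow(xy))[-1L], 1L)
  if (sum(x * y[j] - x[j] * y) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

# Regular n-gon approximating a disk; vertices CCW.
disk_polygon <- function(cx, cy, r, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Epoch seconds -> "YYYY-MM-DDTHH:MM:SS" (UTC) and back.
format_utc <- function(t) {
  format(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"), "%Y-%m-%dT%H:%M:%S")
}

parse_utc <- function(s) {
  s <- sub("T", " ", s, fixed = TRUE)
  t <- as.numeric(strptime(s, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  fallback <- is.na(t)
  if (any(fallback))
    t[fallback] <- as.numeric(strptime(s[fallback], "%Y-%m-%d %H:%M",
                                       tz = "UTC"))
  t  # NA where unparseable
}

# Calendar date string of an epoch second under a fixed UTC offset (hours).
epoch_date <- function(t, utc_offset = 0) {
  format(as.POSIXct(t + utc_offset * 3600, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%d")
}
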