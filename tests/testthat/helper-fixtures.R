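# Shared fixture builders. Everything is generated in code; no stored data.

# Small receiver arrays with exact coordinates.
tiny_array <- function(coords, ids = sprintf("N%03d", seq_len(nrow(coords)))) {
  data.frame(node_id = ids, x_m = coords[, 1L], y_m = coords[, 2L],
             stringsAsFactors = FALSE)
}

# A strongest-method estimate frame at given windows/receivers.
strongest_locs <- function(tag, windows, nodes, array, rss = -70) {
  i <- match(nodes, array$node_id)
  data.frame(tag_id = tag, window_start = windows,
             x_m = array$x_m[i], y_m = array$y_m[i],
             node_id = nodes, method = "strongest",
             n_receivers = 1L, rss_db = rep(rss, length.out = length(windows)),
             stringsAsFactors = FALSE)
}

# Raw detection rows.
det_rows <- function(tag, node, t, rss) {
  data.frame(tag_id = tag, node_id = node, time_s = t, rss_db = rss,
             stringsAsFactors = FALSE)
}

# Uniform-mass UD over an index rectangle of a nx x ny grid.
uniform_ud <- function(nx, ny, rows, cols, origin = c(0, 0), cell = 10) {
  m <- matrix(0, nx, ny)
  m[rows, cols] <- 1
  ud(m, origin = origin, cell = cell)
}
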