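# Windowing, the two localizers, and the yield diagnostics.

test_that("windows are epoch-aligned, half-open, and keep per-receiver maxima", {
  det <- rbind(det_rows("A", "N001", c(2, 9), c(-75, -70)),
               det_rows("A", "N001", 14.9, -68),
               det_rows("A", "N001", 15.0, -66))
  w <- window_detections(det)
  expect_equal(w$window_start, c(0, 15))
  expect_equal(w$rss_db, c(-68, -66))  # max kept; 14.9 and 15.0 split

  # randomized fixture: member count equals brute-force distinct keys, <= n
  set.seed(11)
  det2 <- det_rows(sample(c("A", "B"), 200, TRUE),
                   sample(sprintf("N%03d", 1:5), 200, TRUE),
                   runif(200, 0, 300), runif(200, -90, -50))
  w2 <- window_detections(det2)
  brute <- nrow(unique(data.frame(det2$tag_id, det2$node_id,
                                  floor(det2$time_s / 15))))
  expect_equal(nrow(w2), brute)
  expect_lte(nrow(w2), nrow(det2))
  # shuffling input order changes nothing
  w3 <- window_detections(det2[sample(nrow(det2)), ])
  expect_equal(w2, w3)
})

test_that("duplicate detection records are removed with a message", {
  det <- det_rows("A", "N001", c(1, 1), c(-70, -70))
  expect_message(w <- window_detections(det), "1 duplicate")
  expect_equal(nrow(w), 1L)
})

test_that("strongest-detection localization applies cutoff and tie-breaks", {
  arr <- tiny_array(rbind(c(0, 0), c(100, 0)), c("N001", "N002"))
  w1 <- data.frame(tag_id = "A", window_start = 0, node_id = "N001",
                   rss_db = -79)
  e1 <- localize_strongest(w1, arr)
  expect_equal(c(e1$x_m, e1$y_m), c(0, 0))
  expect_equal(e1$method, "strongest")

  # below cutoff: no estimate
  w2 <- transform(w1, rss_db = -81)
  expect_equal(nrow(localize_strongest(w2, arr)), 0L)

  # exact tie at max RSS resolves to the lowest receiver id, whatever the
  # input order
  wt <- data.frame(tag_id = "A", window_start = 0,
                   node_id = c("N002", "N001"), rss_db = c(-70, -70))
  for (perm in list(1:2, 2:1)) {
    et <- localize_strongest(wt[perm, ], arr)
    expect_equal(et$node_id, "N001")
  }
  expect_error(localize_strongest(transform(w1, node_id = "N099"), arr),
               "absent")
})

test_that("strongest estimates sit on receiver coordinates", {
  sc <- simulate_scenario(n_pairs = 1, n_days = 1, day_hours = 1, seed = 21)
  est <- localize_strongest(window_detections(sc$detections), sc$array)
  i <- match(est$node_id, sc$array$node_id)
  expect_equal(est$x_m, sc$array$x_m[i])
  expect_equal(est$y_m, sc$array$y_m[i])
})

test_that("multilateration recovers a noiseless geometric fix exactly", {
  # equilateral triangle, side 30 m; target at the centroid
  s <- 30
  verts <- rbind(c(0, 0), c(s, 0), c(s / 2, s * sqrt(3) / 2))
  arr <- tiny_array(verts)
  ctr <- colMeans(verts)
  d <- sqrt(sum((verts[1, ] - ctr)^2))
  curve0 <- reference_curve(residual_se = 0)
  w <- data.frame(tag_id = "A", window_start = 0, node_id = arr$node_id,
                  rss_db = distance_to_rss(curve0, d))
  est <- localize_multilateration(w, arr, curve0, localization_config(seed = 2))
  expect_equal(nrow(est), 1L)
  expect_lt(sqrt((est$x_m - ctr[1])^2 + (est$y_m - ctr[2])^2), 0.01)
  # zero residual spread collapses the resampling: degenerate ellipse
  expect_lt(est$ellipse_a_m, 1e-6)
  expect_lt(est$ellipse_b_m, 1e-6)
})

test_that("multilateration enforces the receiver-count and cutoff gates", {
  arr <- tiny_array(rbind(c(0, 0), c(100, 0), c(50, 80)))
  curve0 <- reference_curve(residual_se = 0.05)
  cfg <- localization_config(seed = 3)
  # only 2 receivers above nothing: window skipped
  w2 <- data.frame(tag_id = "A", window_start = 0,
                   node_id = c("N001", "N002"), rss_db = c(-60, -65))
  expect_equal(nrow(localize_multilateration(w2, arr, curve0, cfg)), 0L)
  # 3 receivers but strongest below -80: skipped
  w3 <- data.frame(tag_id = "A", window_start = 0, node_id = arr$node_id,
                   rss_db = c(-85, -88, -90))
  expect_equal(nrow(localize_multilateration(w3, arr, curve0, cfg)), 0L)
})

test_that("multilateration error shrinks with RSS noise and stays field-scale", {
  sc <- simulate_scenario(n_pairs = 1, n_days = 1, day_hours = 1, seed = 33)
  w <- window_detections(sc$detections)
  w <- w[w$tag_id == "P1F", ]
  tr <- sc$tracks[sc$tracks$individual_id == "P1F", ]
  med_err <- function(noise_sd, seed) {
    curve <- reference_curve(residual_se = abs(-0.03302) * noise_sd)
    est <- localize_multilateration(w, sc$array, curve,
                                    localization_config(seed = seed))
    i <- match(est$window_start, floor(tr$time_s / 15) * 15)
    stats::median(sqrt((est$x_m - tr$x_m[i])^2 + (est$y_m - tr$y_m[i])^2),
                  na.rm = TRUE)
  }
  e_lo <- median(vapply(1:3, function(s) med_err(0.5, s), numeric(1)))
  e_hi <- median(vapply(1:3, function(s) med_err(4, s), numeric(1)))
  expect_lt(e_lo, e_hi)
  expect_lt(med_err(2, 1), 60)
})

test_that("localization rate counts daylight slots between first and last fix", {
  day <- daylight_table("2023-09-07", 1, 6, 7)  # one 1-h daylight interval
  arr <- tiny_array(cbind(0, 0))
  sunrise <- day$sunrise_s[1]
  all_slots <- seq(sunrise, sunrise + 3600 - 15, by = 15)
  # every slot localized
  full <- strongest_locs("A", all_slots, "N001", arr)
  expect_equal(localization_rate(full, day)$rate, 1.0)
  # a 40% deterministic subset: rate recovers the constructed fraction
  keep <- all_slots[seq_along(all_slots) %% 5 %in% c(1, 2)]
  part <- strongest_locs("A", keep, "N001", arr)
  r <- localization_rate(part, day)
  expect_equal(r$rate, 0.40, tolerance = 0.02)
  # invariant to input order
  expect_equal(localization_rate(part[sample(nrow(part)), ], day)$rate, r$rate)
  expect_error(localization_rate(full, day[0, ]), "daylight")
})

test_that("gap distribution splits at night and summarizes durations", {
  arr <- tiny_array(cbind(0, 0))
  day <- daylight_table("2023-09-07", 2, 6, 7)
  # alternating localized/unlocalized slots in day 1: all gaps 15 s
  s1 <- seq(day$sunrise_s[1], day$sunset_s[1] - 15, by = 30)
  g1 <- gap_distribution(strongest_locs("A", s1, "N001", arr), day)
  expect_true(all(g1$gaps$length_s == 15))
  expect_equal(unname(g1$summary["frac_lt_30s"]), 1)

  # one fix near the end of day 1 and one early on day 2: the overnight gap
  # is split at sunset/sunrise into two daylight gaps
  locs <- strongest_locs("A", c(day$sunrise_s[1], day$sunset_s[1] - 300,
                                day$sunrise_s[2] + 300), "N001", arr)
  g2 <- gap_distribution(locs, day)
  expect_equal(nrow(g2$gaps), 3L)
  # no gap longer than remaining daylight; none spans the 23-h night
  expect_true(all(g2$gaps$length_s <= 3600))

  # fully localized: no gaps
  full <- strongest_locs("A", seq(day$sunrise_s[1], day$sunset_s[1] - 15, 15),
                         "N001", arr)
  expect_equal(nrow(gap_distribution(full, day)$gaps), 0L)
})
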