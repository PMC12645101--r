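# Separation series vs the day-shift null, movement/following events, lag
# thresholding, following rates, and initiation attribution.

arr5 <- tiny_array(rbind(c(0, 0), c(100, 0), c(200, 0), c(0, 100), c(100, 100)),
                   c("A1", "B1", "C1", "D1", "E1"))

test_that("true-mode separation of identical tracks is zero at shared receivers", {
  locs <- strongest_locs("F", seq(0, 150, 15), "A1", arr5)
  locs2 <- locs; locs2$tag_id <- "M"
  s <- separation_series(locs, locs2, mode = "true")
  expect_equal(nrow(s), nrow(locs))
  expect_true(all(s$distance_m == 0))
  expect_true(all(s$same_receiver))
})

test_that("the day-shift null is zero for a day-stationary track", {
  w1 <- seq(0, 150, 15)
  locs_a <- strongest_locs("F", w1, "A1", arr5)
  # partner at the same position at the same time of day on both days
  locs_b <- strongest_locs("M", c(w1, w1 + 86400), "A1", arr5)
  s <- separation_series(locs_a, locs_b, mode = "null")
  expect_equal(nrow(s), length(w1))
  expect_true(all(s$distance_m == 0))
  # non-overlapping windows yield an empty series with a warning
  expect_warning(
    s0 <- separation_series(locs_a, strongest_locs("M", w1 + 7 * 86400, "A1",
                                                   arr5)),
    "no overlapping")
  expect_equal(nrow(s0), 0L)
})

test_that("coupled pairs are closer than their day-shift null", {
  # truth tracks over two daylight periods, 20 replicate seeds: the paired
  # (true) separation is below the null in every replicate
  n_true_below <- 0L
  for (s in 1:20) {
    cfg <- movement_config(centers = list(c(0, 0), c(15, 0)), coupling = 0.8)
    day <- daylight_table("2023-09-07", 2, 6, 9)
    tr <- rbind(
      simulate_pair_tracks(cfg, 3 * 3600, seed = 700 + s,
                           start_time = day$sunrise_s[1], ids = c("F", "M")),
      simulate_pair_tracks(cfg, 3 * 3600, seed = 900 + s,
                           start_time = day$sunrise_s[2], ids = c("F", "M")))
    to_locs <- function(id) {
      t <- tr[tr$individual_id == id, ]
      data.frame(tag_id = id, window_start = t$time_s, x_m = t$x_m,
                 y_m = t$y_m)
    }
    st <- separation_series(to_locs("F"), to_locs("M"), mode = "true")
    sn <- separation_series(to_locs("F"), to_locs("M"), mode = "null")
    if (mean(st$distance_m) < mean(sn$distance_m))
      n_true_below <- n_true_below + 1L
  }
  # sign test: 20/20 (or 19/20) successes rejects equality at p << 0.01
  expect_gte(n_true_below, 19L)
})

test_that("movement events are receiver changes between localized windows", {
  # constant receiver: no events
  locs <- strongest_locs("F", seq(0, 60, 15), "A1", arr5)
  expect_equal(nrow(extract_movement_events(locs)), 0L)

  # A,A,B,B,C gives exactly A->B and B->C
  locs2 <- strongest_locs("F", seq(0, 60, 15), c("A1", "A1", "B1", "B1", "C1"),
                          arr5)
  ev <- extract_movement_events(locs2)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$from_node, c("A1", "B1"))
  expect_equal(ev$to_node, c("B1", "C1"))
  expect_equal(ev$depart_time, c(15, 45))
  expect_equal(ev$arrive_time, c(30, 60))

  # unlocalized gap between A and B: still one event, at observed windows
  locs3 <- strongest_locs("F", c(0, 15, 120, 135), c("A1", "A1", "B1", "B1"),
                          arr5)
  ev3 <- extract_movement_events(locs3)
  expect_equal(nrow(ev3), 1L)
  expect_equal(c(ev3$depart_time, ev3$arrive_time), c(15, 120))

  # low-confidence endpoints are excluded
  locs4 <- strongest_locs("F", seq(0, 45, 15), c("A1", "A1", "B1", "B1"), arr5,
                          rss = c(-70, -70, -85, -85))
  expect_equal(nrow(extract_movement_events(locs4)), 0L)
})

test_that("following candidates require presence at A and arrival at B", {
  # lockstep: partner mirrors every move one window later
  lead <- strongest_locs("F", seq(0, 90, 15),
                         c("A1", "A1", "B1", "B1", "C1", "C1", "C1"), arr5)
  foll <- strongest_locs("M", seq(0, 90, 15),
                         c("A1", "A1", "A1", "B1", "B1", "C1", "C1"), arr5)
  ev <- extract_movement_events(lead)
  cand <- extract_following_events(ev, foll)
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$lag_s, c(15, 15))
  expect_lte(nrow(cand), nrow(ev))

  # partner moves A->C instead: no candidate
  foll2 <- strongest_locs("M", seq(0, 90, 15),
                          c("A1", "A1", "A1", "D1", "D1", "D1", "D1"), arr5)
  expect_equal(nrow(extract_following_events(ev[1, ], foll2)), 0L)

  # hand-traced 6-window fixture: one A->B pair move, lag 30 s
  lead3 <- strongest_locs("F", seq(0, 75, 15),
                          c("A1", "B1", "B1", "B1", "B1", "B1"), arr5)
  foll3 <- strongest_locs("M", seq(0, 75, 15),
                          c("A1", "A1", "A1", "B1", "B1", "B1"), arr5)
  ev3 <- extract_movement_events(lead3)
  cand3 <- extract_following_events(ev3, foll3)
  expect_equal(nrow(cand3), 1L)
  # leader arrives at 15, follower at 45
  expect_equal(cand3$lag_s, 30)

  # a stale presence at A is rejected under a staleness limit
  cfgs <- cohesion_config(staleness_s = 30)
  foll4 <- strongest_locs("M", c(0, 600, 615), c("A1", "B1", "B1"), arr5)
  ev4 <- extract_movement_events(
    strongest_locs("F", c(540, 555, 570), c("A1", "A1", "B1"), arr5))
  expect_equal(nrow(extract_following_events(ev4, foll4, cfgs)), 0L)
})

test_that("lag threshold uses the nearest-rank 90th percentile", {
  expect_equal(nearest_rank_percentile(1:10, 90), 9)
  expect_equal(nearest_rank_percentile(rep(7, 5), 90), 7)
  expect_equal(lag_threshold(data.frame(lag_s = as.numeric(1:10))), 9)
  expect_error(lag_threshold(data.frame(lag_s = numeric(0))), "no candidate")
  expect_error(nearest_rank_percentile(1:10, 0), "percentile")
  # by construction, at least 90% of lags fall at or below the threshold
  set.seed(3)
  lags <- rexp(137, 1 / 120)
  thr <- lag_threshold(data.frame(lag_s = lags))
  expect_gte(mean(lags <= thr), 0.9)
})

test_that("following rate is 1 in lockstep and near chance when uncoupled", {
  lead <- strongest_locs("F", seq(0, 90, 15),
                         c("A1", "A1", "B1", "B1", "C1", "C1", "C1"), arr5)
  foll <- strongest_locs("M", seq(0, 90, 15),
                         c("A1", "A1", "A1", "B1", "B1", "C1", "C1"), arr5)
  ev <- extract_movement_events(lead)
  cand <- extract_following_events(ev, foll)
  fr <- following_rate(ev, cand, lag_threshold(cand), lead, foll)
  expect_equal(fr$rate, 1.0)
  expect_equal(fr$n_events, 2L)

  # independent pairs on the sparse array: rate stays at chance level
  rates <- vapply(1:10, function(s) {
    mv <- movement_config(coupling = 0)
    sc <- simulate_scenario(n_pairs = 1, n_days = 1, day_hours = 6,
                            movement = mv, seed = 1100 + s)
    est <- localize_strongest(window_detections(sc$detections), sc$array)
    la <- est[est$tag_id == "P1F", ]; lb <- est[est$tag_id == "P1M", ]
    ev <- extract_movement_events(la)
    cd <- extract_following_events(ev, lb)
    if (nrow(cd) == 0L) return(0)
    following_rate(ev, cd, max(lag_threshold(cd), 15), la, lb)$rate
  }, numeric(1))
  expect_lt(mean(rates), 0.2)

  # zero eligible events: rate is undefined, not 0
  fr0 <- following_rate(ev[0, ], cand[0, ], 600, lead, foll)
  expect_true(is.na(fr0$rate))
})

test_that("following events never outnumber leader movement events and are reproducible", {
  mv <- movement_config(coupling = 0.8)
  sc <- simulate_scenario(n_pairs = 1, n_days = 1, day_hours = 4,
                          movement = mv, seed = 77)
  est <- localize_strongest(window_detections(sc$detections), sc$array)
  la <- est[est$tag_id == "P1F", ]; lb <- est[est$tag_id == "P1M", ]
  ev <- extract_movement_events(la)
  cand <- extract_following_events(ev, lb)
  expect_lte(nrow(cand), nrow(ev))
  expect_identical(cand, extract_following_events(ev, lb))
  # relabeling receivers leaves the rate unchanged
  relabel <- setNames(sprintf("Z%02d", seq_len(nrow(sc$array))),
                      sc$array$node_id)
  la2 <- la; la2$node_id <- unname(relabel[la$node_id])
  lb2 <- lb; lb2$node_id <- unname(relabel[lb$node_id])
  ev2 <- extract_movement_events(la2)
  cand2 <- extract_following_events(ev2, lb2)
  thr <- max(lag_threshold(cand), 15)
  expect_equal(following_rate(ev2, cand2, thr, la2, lb2)$rate,
               following_rate(ev, cand, thr, la, lb)$rate)
})

test_that("initiation attribution is exact on constructed episodes and symmetric", {
  # a departs first from the only shared episode
  la <- strongest_locs("F", seq(0, 45, 15), c("A1", "A1", "B1", "B1"), arr5)
  lb <- strongest_locs("M", seq(0, 45, 15), c("A1", "A1", "A1", "B1"), arr5)
  ia <- initiation_attribution(la, lb)
  expect_equal(unname(ia$shares), c(1, 0, 0))
  # swapping the labels swaps the shares exactly
  ib <- initiation_attribution(lb, la)
  expect_equal(unname(ib$shares[c(2, 1, 3)]), unname(ia$shares))

  # simultaneous departures
  lc <- strongest_locs("F", seq(0, 45, 15), c("A1", "A1", "B1", "B1"), arr5)
  ld <- strongest_locs("M", seq(0, 45, 15), c("A1", "A1", "C1", "C1"), arr5)
  ic <- initiation_attribution(lc, ld)
  expect_equal(unname(ic$shares), c(0, 0, 1))

  # symmetric generator: neither bird initiates systematically more
  shares <- t(vapply(1:20, function(s) {
    mv <- movement_config(coupling = 0.8, role_switch_per_min = 0.5)
    sc <- simulate_scenario(n_pairs = 1, n_days = 1, day_hours = 4,
                            movement = mv, seed = 1300 + s)
    est <- localize_strongest(window_detections(sc$detections), sc$array)
    ia <- initiation_attribution(est[est$tag_id == "P1F", ],
                                 est[est$tag_id == "P1M", ])
    ia$shares
  }, numeric(3)))
  pooled <- colMeans(shares, na.rm = TRUE)
  expect_lt(abs(pooled[1] - pooled[2]), 0.05)
  expect_gt(pooled[3], 0)
  expect_equal(sum(pooled), 1, tolerance = 1e-9)
})
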