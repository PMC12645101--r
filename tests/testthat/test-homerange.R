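# Utilization distributions, home-range areas, Bhattacharyya overlap, and
# the weekly/section/period splitting.

test_that("UDs are normalized and concentrate correctly", {
  set.seed(5)
  pts <- data.frame(x_m = rnorm(200, 0, 40), y_m = rnorm(200, 0, 40))
  u <- estimate_ud(pts)
  expect_s3_class(u, "ud")
  expect_equal(sum(u$mass), 1, tolerance = 1e-9)
  expect_true(all(u$mass >= 0))

  # identical points with bandwidth at the cell scale: one dominant cell
  same <- data.frame(x_m = rep(55, 20), y_m = rep(55, 20))
  u1 <- estimate_ud(same, bandwidth = 2, cell = 10)
  expect_gte(max(u1$mass), 0.99)

  expect_error(estimate_ud(pts[1:5, ]), "at least 10")
  expect_error(estimate_ud(pts, bandwidth = -1), "bandwidth")
})

test_that("the 95% area of a Gaussian UD matches the chi-square closed form", {
  set.seed(8)
  sigma <- 50
  pts <- data.frame(x_m = rnorm(5000, 0, sigma), y_m = rnorm(5000, 0, sigma))
  u <- estimate_ud(pts, cell = 5)
  a95 <- home_range_area(u, 0.95)
  closed <- pi * sigma^2 * stats::qchisq(0.95, 2) / 1e6
  expect_lt(abs(a95 - closed) / closed, 0.15)
  # monotone in level
  levels <- c(0.5, 0.8, 0.95, 1.0)
  areas <- vapply(levels, function(l) home_range_area(u, l), numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("home-range area handles uniform and degenerate levels", {
  u <- uniform_ud(10, 10, 1:4, 1:5)  # 20 equal cells of 100 m^2
  expect_equal(home_range_area(u, 0.95), ceiling(0.95 * 20) * 100 / 1e6)
  expect_equal(home_range_area(u, 1.0), 20 * 100 / 1e6)
  expect_error(home_range_area(u, 0), "level")
  expect_error(home_range_area(u, 1.5), "level")
})

test_that("Bhattacharyya endpoints and symmetry", {
  set.seed(9)
  pts <- data.frame(x_m = runif(300, 0, 200), y_m = runif(300, 0, 200))
  u <- estimate_ud(pts, cell = 10)
  expect_equal(bhattacharyya(u, u), 1.0, tolerance = 1e-12)

  # disjoint supports
  ua <- uniform_ud(20, 20, 1:5, 1:5)
  ub <- uniform_ud(20, 20, 10:14, 10:14)
  expect_equal(bhattacharyya(ua, ub), 0)

  # two uniform squares overlapping on half their area: BC = 0.5
  u1 <- uniform_ud(30, 10, 1:10, 1:10)
  u2 <- uniform_ud(30, 10, 6:15, 1:10)
  expect_equal(bhattacharyya(u1, u2), 0.5, tolerance = 1e-12)
  expect_equal(bhattacharyya(u2, u1), bhattacharyya(u1, u2))

  # misaligned grids are rejected
  ushift <- ud(u1$mass, origin = c(3.5, 0), cell = 10)
  expect_error(bhattacharyya(u1, ushift), "aligned")
  ucell <- ud(u1$mass, origin = c(0, 0), cell = 5)
  expect_error(bhattacharyya(u1, ucell), "cell")
})

test_that("BC is invariant to common grid refinement", {
  set.seed(10)
  pa <- data.frame(x_m = rnorm(400, 0, 30), y_m = rnorm(400, 0, 30))
  pb <- data.frame(x_m = rnorm(400, 25, 30), y_m = rnorm(400, 0, 30))
  grid <- ud_grid(list(pa, pb), cell = 20, pad = 90)
  ua <- estimate_ud(pa, grid = grid); ub <- estimate_ud(pb, grid = grid)
  bc1 <- bhattacharyya(ua, ub)
  bc2 <- bhattacharyya(regrid_ud(ua, 4), regrid_ud(ub, 4))
  expect_lt(abs(bc1 - bc2), 1e-3)
  expect_true(bc1 >= 0 && bc1 <= 1)
})

test_that("period assignment follows the half-open section boundaries", {
  day <- daylight_table("2023-09-07", 10, 6, 20)
  arr <- tiny_array(cbind(0, 0))
  sunrise <- day$sunrise_s[1]
  est <- strongest_locs("A", sunrise + c(0, 3, 6, 9, 13.9) * 3600, "N001", arr)
  est$x_m <- est$y_m <- 0
  out <- assign_periods(est, day, week1_start = day$sunrise_s[1] - 6 * 3600,
                        breeding_end = day$sunrise_s[3])
  expect_equal(out$section, c(1, 2, 3, 4, 4))
  expect_equal(out$week, rep(1L, 5))
  expect_equal(out$period, rep("breeding", 5))
  # a fix in week 2, after breeding end
  est2 <- strongest_locs("A", day$sunrise_s[8] + 3600, "N001", arr)
  out2 <- assign_periods(est2, day, day$sunrise_s[1] - 6 * 3600,
                         day$sunrise_s[3])
  expect_equal(out2$week, 2L)
  expect_equal(out2$period, "post_breeding")
  # beyond 14 h post sunrise: warned into section 4
  expect_warning(
    assign_periods(strongest_locs("A", sunrise + 15 * 3600, "N001", arr),
                   daylight_table("2023-09-07", 2, 6, 22), 0, 1e12),
    "section 4")
})

test_that("12 individuals form 66 dyads with pair bonds from metadata", {
  md <- data.frame(tag_id = sprintf("B%02d", 1:12), sex = rep(c("F", "M"), 6),
                   pair_id = rep(sprintf("P%d", 1:6), each = 2))
  dy <- enumerate_dyads(md)
  expect_equal(nrow(dy), 66L)
  expect_equal(sum(dy$dyad_type == "pair_bonded"), 6L)
  expect_equal(sum(dy$dyad_type == "not_pair_bonded"), 60L)
})

test_that("coupled pairs overlap far more than non-pair dyads", {
  sc <- simulate_scenario(n_pairs = 3, n_days = 2, day_hours = 4, seed = 42)
  est <- localize_strongest(window_detections(sc$detections), sc$array)
  res <- split_and_summarize(est, sc$metadata, sc$daylight,
                             sc$week1_start, sc$breeding_end)
  bc_pair <- mean(res$dyads$bc[res$dyads$dyad_type == "pair_bonded"])
  bc_non <- mean(res$dyads$bc[res$dyads$dyad_type == "not_pair_bonded"])
  expect_gt(bc_pair, bc_non + 0.3)
  expect_true(all(res$dyads$bc >= 0 & res$dyads$bc <= 1))
  expect_true(all(res$areas$n >= 10))
})

test_that("mean pair BC does not decrease with coupling", {
  # truth-track UDs across 20 replicate pairs per coupling level
  mean_bc <- function(coupling) {
    bcs <- vapply(1:20, function(s) {
      cfg <- movement_config(centers = list(c(0, 0), c(15, 0)),
                             coupling = coupling)
      tr <- simulate_pair_tracks(cfg, duration = 15 * 500, seed = 600 + s)
      a <- tr[tr$individual_id == "A", c("x_m", "y_m")]
      b <- tr[tr$individual_id == "B", c("x_m", "y_m")]
      names(a) <- names(b) <- c("x_m", "y_m")
      grid <- ud_grid(list(a, b), cell = 10, pad = 60)
      bhattacharyya(estimate_ud(a, grid = grid), estimate_ud(b, grid = grid))
    }, numeric(1))
    mean(bcs)
  }
  bc_by_coupling <- vapply(c(0, 0.5, 1), mean_bc, numeric(1))
  expect_true(all(diff(bc_by_coupling) >= 0))
})
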