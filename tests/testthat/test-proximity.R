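test_that("dynamic threshold is linear in the gap and anchored at 30 m", {
  p <- together_params()
  expect_equal(dynamic_threshold(0, p), 30)
  expect_equal(dynamic_threshold(5, p), 90)
  g <- sort(runif(50, 0, 10))
  expect_true(all(diff(dynamic_threshold(g, p)) >= 0))
  expect_error(dynamic_threshold(-1, p), "non-negative")
})

test_that("fix pairing is greedy one-to-one by ascending gap", {
  ctr <- study_site_center()
  t0 <- as.POSIXct("2019-06-10 00:00:00", tz = "UTC")
  mk <- function(id, times_min, x) {
    ll <- aeqd_unproject(x, rep(0, length(x)), ctr)
    data.table::data.table(id = id, sex = "M", timestamp = t0 + 60 * times_min,
                           lon = ll$lon, lat = ll$lat)
  }
  # synchronous grids: every slot paired at gap 0
  a <- mk("A", seq(0, 90, by = 10), rep(0, 10))
  b <- mk("B", seq(0, 90, by = 10), rep(10, 10))
  obs <- pair_fixes(a, b)
  expect_identical(nrow(obs), 10L)
  expect_true(all(obs$gap_min == 0))
  expect_equal(obs$dist_m, rep(10, 10), tolerance = 1e-6)
  # a fix with no counterpart within 10 min is dropped
  b2 <- mk("B", c(0, 10, 40), rep(10, 3))
  obs2 <- pair_fixes(a[1:4], b2)
  expect_identical(nrow(obs2), 3L)
  expect_true(all(obs2$gap_min <= 10))
  # one-to-one: no fix used twice
  a3 <- mk("A", c(0, 1), c(0, 0))
  b3 <- mk("B", 0.5, 5)
  obs3 <- pair_fixes(a3, b3)
  expect_identical(nrow(obs3), 1L)
  expect_equal(obs3$gap_min, 0.5)
})

test_that("three-rule classification follows the stated rules", {
  p <- together_params()
  # all close -> together
  o <- classify_together(mk_obs(c(10, 20, 25), 1), p)
  expect_true(all(o$together))
  # bout under the dynamic threshold but never < 30 m -> not together
  o2 <- classify_together(mk_obs(c(40, 45), 5), p)
  expect_true(all(o2$candidate))
  expect_false(any(o2$together))
  # confirmed bout ending above 30 m: final observation relabelled
  o3 <- classify_together(mk_obs(c(10, 20, 80), c(1, 1, 6)), p)
  expect_identical(o3$together, c(TRUE, TRUE, FALSE))
  # a final distance of exactly 30 m stays together (strict >)
  o4 <- classify_together(mk_obs(c(10, 30), 1), p)
  expect_identical(o4$together, c(TRUE, TRUE))
})

test_that("classification equals the brute-force reference on random tracks", {
  set.seed(7)
  for (rep in 1:200) {
    tr <- random_track(sample(1:50, 1))
    obs <- classify_together(mk_obs(tr$dist, tr$gaps))
    expect_identical(obs$together, oracle_together(tr$dist, tr$gaps))
  }
})

test_that("labels are symmetric in the two members", {
  set.seed(8)
  tr <- random_track(40)
  obs <- mk_obs(tr$dist, tr$gaps)
  swapped <- data.table::copy(obs)
  data.table::setnames(swapped, c("x_a", "y_a", "x_b", "y_b", "t_a", "t_b"),
                       c("x_b", "y_b", "x_a", "y_a", "t_b", "t_a"))
  expect_identical(classify_together(obs)$together,
                   classify_together(swapped)$together)
})

test_that("daily proportions conserve counts and use local civil days", {
  # 144 slots, half together
  d <- rep(c(5, 500), 72)
  obs <- classify_together(mk_obs(d, 0,
    t0 = as.POSIXct("2019-06-10 08:00:00", tz = "UTC")))
  s <- daily_proportions(obs, as.Date("2019-06-10"), "P1")
  expect_identical(nrow(s), 1L)
  expect_identical(s$n_slots, 144L)
  expect_equal(s$prop_together, 0.5)
  expect_identical(s$day_rel, 0L)
  # UTC time 07:50 on June 10 belongs to local (UTC-8) June 9
  obs2 <- classify_together(mk_obs(5, 0,
    t0 = as.POSIXct("2019-06-10 07:50:00", tz = "UTC")))
  s2 <- daily_proportions(obs2, as.Date("2019-06-10"), "P1")
  expect_identical(s2$day_rel, -1L)
  expect_identical(nrow(daily_proportions(obs[0], as.Date("2019-06-10"))), 0L)
})

test_that("window mean weights by slots with pair-clustered SE", {
  s <- data.table::data.table(
    pair_id = c("P1", "P2"), day_rel = -3L, date = as.Date("2019-06-10"),
    n_slots = c(100L, 100L), n_together = c(60L, 80L))
  wm <- window_mean(s, -5:-1)
  expect_equal(wm$prop, 0.7)
  expect_equal(wm$prop_by_pair, 0.7)
  # single pair constant -> SE 0
  s1 <- s[1]
  expect_equal(window_mean(s1, -5:-1)$se, 0)
  expect_error(window_mean(s, 5:8), "no data")
})
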