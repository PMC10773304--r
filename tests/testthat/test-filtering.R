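ctr <- study_site_center()

# fixes at given planar offsets from the study centre, 10 min apart
mk_fixes <- function(x, y, id = "A", t0 = as.POSIXct("2019-06-10 12:00:00", tz = "UTC"),
                     dt_s = 600) {
  ll <- aeqd_unproject(x, y, ctr)
  data.table::data.table(id = id, sex = "M",
                         timestamp = t0 + dt_s * (seq_along(x) - 1),
                         lon = ll$lon, lat = ll$lat)
}

test_that("deployment clipping uses a closed interval and preserves order", {
  f <- mk_fixes(1:10, rep(0, 10))
  out <- clip_to_deployment(f, f$timestamp[3], f$timestamp[8])
  expect_identical(out$timestamp, f$timestamp[3:8])
  expect_identical(clip_to_deployment(f[0], f$timestamp[1], f$timestamp[2]),
                   f[0])
  expect_error(clip_to_deployment(f, f$timestamp[5], f$timestamp[2]),
               "release_time")
})

test_that("distance-from-capture rule is strict at 500 km", {
  f <- mk_fixes(c(0, 600e3, 500e3, 5e3), c(0, 0, 0, 0))
  res <- filter_far(f, ctr)
  expect_identical(res$removed, 2L)
  # exactly-500km fix retained: strict inequality (allow float slack)
  d <- gc_dist_m(f$lon[3], f$lat[3], ctr[["lon"]], ctr[["lat"]])
  expect_lt(abs(d - 500e3), 1)
  expect_true(3L %in% which(!seq_len(4) %in% res$removed))
})

test_that("speed rule removes the arriving fix, sequentially", {
  # 20 km in 10 min = 120 km/h -> second fix removed
  f <- mk_fixes(c(0, 20e3), c(0, 0))
  expect_identical(filter_speed(f)$removed, 2L)
  # constant slow track unchanged
  slow <- mk_fixes(seq(0, 900, by = 100), rep(0, 10))
  expect_length(filter_speed(slow)$removed, 0)
  # A -> B at 200 km/h, but A -> C slow: only B removed
  f3 <- mk_fixes(c(0, 33e3, 1000), c(0, 0, 0))
  res <- filter_speed(f3)
  expect_identical(res$removed, 2L)
  expect_identical(res$fixes$timestamp, f3$timestamp[c(1, 3)])
  expect_error(filter_speed(mk_fixes(c(0, 1), c(0, 0), dt_s = 0)),
               "duplicate")
})

test_that("speed-filtered output never contains an over-speed leg", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(3:6, 1)
    f <- mk_fixes(cumsum(runif(n, 0, 30e3)), runif(n, 0, 1000))
    out <- filter_speed(f)$fixes
    expect_lte(max_leg_speed(out), 105 / 3.6 + 1e-9)
    # removed fixes are a subset of the input
    expect_true(all(out$timestamp %in% f$timestamp))
  }
})

test_that("single-outlier rule needs close temporal neighbours", {
  f <- mk_fixes(c(0, 3000, 50), c(0, 0, 0))
  expect_identical(filter_single_outlier(f)$removed, 2L)
  # neighbours 500 m apart: retained
  f2 <- mk_fixes(c(0, 3000, 500), c(0, 0, 0))
  expect_length(filter_single_outlier(f2)$removed, 0)
  # endpoints never removed
  f3 <- mk_fixes(c(5000, 0, 10, 5000), c(0, 0, 0, 0))
  rem <- filter_single_outlier(f3)$removed
  expect_false(1L %in% rem)
  expect_false(4L %in% rem)
})

test_that("run_filters is idempotent, conservative and audited per rule", {
  # one planted violation per rule
  x <- c(0, 10, 20, 600e3, 30, 40, 33e3, 50, 60, 3000, 70, 80)
  f <- mk_fixes(x, rep(0, length(x)))
  res <- run_filters(f, ctr)
  rep1 <- res$report
  expect_identical(rep1$removed_far, 1L)
  expect_identical(rep1$removed_speed, 1L)
  expect_identical(rep1$removed_single_outlier, 1L)
  expect_identical(rep1$n_retained,
                   rep1$n_input - rep1$removed_far - rep1$removed_speed -
                     rep1$removed_single_outlier - rep1$removed_clip)
  # idempotent
  res2 <- run_filters(res$fixes, ctr)
  expect_identical(nrow(res2$fixes), nrow(res$fixes))
  expect_identical(res2$report$n_retained, res2$report$n_input)
  # clean track untouched
  clean <- run_filters(mk_fixes(seq(0, 1100, by = 100), rep(0, 12)), ctr)
  expect_identical(clean$report$n_retained, clean$report$n_input)
})

test_that("filter report conservation identity is enforced", {
  expect_error(filter_report(100, 0, 10, 5, 5, n_retained = 99), "conservation")
  expect_silent(r <- filter_report(100, 0, 10, 5, 5))
  expect_identical(r$n_retained, 80)
})
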