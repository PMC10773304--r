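test_that("config validation rejects bad probabilities and lengths", {
  expect_error(sim_config(together_prob_by_day = c(`0` = 1.2)), "probabilities")
  expect_error(sim_config(epp_rate = -0.1), "probabilities")
  expect_error(sim_config(fix_interval_min = 0), "positive")
  expect_error(sim_config(n_pairs = 0), "n_pairs")
})

test_that("identical config and seed give identical output", {
  cfg <- sim_config(n_pairs = 2, days_rel = -2:1, rng_seed = 5,
                    outlier_rates = c(far = 0.01, speed = 0.005, single = 0.005))
  s1 <- simulate_pair_tracks(cfg)
  s2 <- simulate_pair_tracks(cfg)
  expect_identical(s1$fixes, s2$fixes)
  expect_identical(s1$truth$slots, s2$truth$slots)
  expect_identical(s1$nests, s2$nests)
  s3 <- simulate_pair_tracks(sim_config(n_pairs = 2, days_rel = -2:1,
                                        rng_seed = 6))
  expect_false(identical(s1$fixes$lon, s3$fixes$lon))
})

test_that("degenerate config: always together, no noise, no outliers", {
  cfg <- sim_config(n_pairs = 2, days_rel = 0:1, rng_seed = 3,
                    together_prob_by_day = c(`0` = 1, `1` = 1),
                    gps_noise_sd = 1e-9,
                    nest_attendance_by_day_sex = list(
                      male = c(`0` = 0, `1` = 0), female = c(`0` = 0, `1` = 0)))
  sim <- simulate_pair_tracks(cfg)
  expect_true(all(sim$truth$slots$together))
  expect_identical(nrow(sim$truth$separations), 0L)
  for (p in 1:2) {
    fa <- sim$fixes[sim$fixes$id == sprintf("M%03d", p), ]
    fb <- sim$fixes[sim$fixes$id == sprintf("F%03d", p), ]
    obs <- pair_fixes(fa, fb)
    expect_true(all(obs$dist_m < 30))
    expect_true(all(classify_together(obs)$together))
  }
})

test_that("realised per-day together fractions are binomially calibrated", {
  sim <- simulate_pair_tracks(sim_config(n_pairs = 20, rng_seed = 13))
  cfg <- sim$config
  tr <- sim$truth$slots
  agg <- tr[, .(p_hat = mean(together), n = .N), by = day_rel]
  p_cfg <- cfg$together_prob_by_day[as.character(agg$day_rel)]
  se <- sqrt(p_cfg * (1 - p_cfg) / agg$n)
  expect_true(all(abs(agg$p_hat - p_cfg) < 3 * se))
})

test_that("no outliers configured means nothing to remove, and filters agree", {
  sim <- small_sim() # outlier_rates all zero
  expect_true(all(is.na(sim$truth$fixes$corrupt_rule)))
  res <- run_filters(sim$fixes, sim$config$center)
  expect_identical(res$report$n_retained, res$report$n_input)
})

test_that("planted corruptions are recalled perfectly and no clean fix lost", {
  cfg <- sim_config(n_pairs = 10, rng_seed = 17,
                    outlier_rates = c(far = 0.003, speed = 0.001, single = 0.001))
  sim <- simulate_pair_tracks(cfg)
  planted <- sim$truth$fixes[!is.na(corrupt_rule)]
  expect_gt(nrow(planted), 50)
  res <- run_filters(sim$fixes, cfg$center)
  kept_key <- paste(res$fixes$id, res$fixes$timestamp)
  tf <- sim$truth$fixes
  removed <- !paste(tf$id, tf$timestamp) %in% kept_key
  expect_true(all(removed[!is.na(tf$corrupt_rule)]))
  expect_false(any(removed[is.na(tf$corrupt_rule)]))
  # per-rule audit matches the planted counts
  expect_identical(res$report$removed_far,
                   as.integer(sum(tf$corrupt_rule == "far", na.rm = TRUE)))
  expect_identical(res$report$removed_speed,
                   as.integer(sum(tf$corrupt_rule == "speed", na.rm = TRUE)))
  expect_identical(res$report$removed_single_outlier,
                   as.integer(sum(tf$corrupt_rule == "single", na.rm = TRUE)))
})

test_that("pairing gaps have a median near 2.6 min", {
  sim <- simulate_pair_tracks(sim_config(n_pairs = 20, rng_seed = 19))
  gaps <- c()
  for (p in seq_len(20)) {
    fa <- sim$fixes[sim$fixes$id == sprintf("M%03d", p), ]
    fb <- sim$fixes[sim$fixes$id == sprintf("F%03d", p), ]
    gaps <- c(gaps, pair_fixes(fa, fb)$gap_min)
  }
  expect_lt(abs(stats::median(gaps) - 2.6), 0.5)
  expect_gt(mean(gaps <= 5), 0.9)
})

test_that("toy fixtures reproduce their frozen expectations", {
  fx <- make_toy_fixture("single-outlier")
  res <- filter_single_outlier(fx$fixes)
  expect_identical(res$removed, fx$expected$removed_idx)
  fx2 <- make_toy_fixture("last-fix-separation")
  fa <- fx2$fixes[fx2$fixes$sex == "M", ]; fb <- fx2$fixes[fx2$fixes$sex == "F", ]
  expect_identical(classify_together(pair_fixes(fa, fb))$together,
                   fx2$expected$together)
  fx3 <- make_toy_fixture("all-close")
  fa <- fx3$fixes[fx3$fixes$sex == "M", ]; fb <- fx3$fixes[fx3$fixes$sex == "F", ]
  expect_identical(classify_together(pair_fixes(fa, fb))$together,
                   fx3$expected$together)
  fx4 <- make_toy_fixture("three-rule-together")
  fa <- fx4$fixes[fx4$fixes$sex == "M", ]; fb <- fx4$fixes[fx4$fixes$sex == "F", ]
  expect_identical(classify_together(pair_fixes(fa, fb))$together,
                   fx4$expected$together)
  expect_error(make_toy_fixture("nope"), "unknown")
})

test_that("fix tables and configs survive a CSV / YAML round trip", {
  sim <- small_sim()
  tmp <- tempfile(fileext = ".csv")
  write_fixes_csv(sim$fixes[1:200, ], tmp)
  back <- read_fixes_csv(tmp)
  expect_equal(nrow(back), 200)
  expect_equal(back$lon, sim$fixes$lon[1:200], tolerance = 1e-9)
  expect_lt(max(abs(as.numeric(back$timestamp) -
                      as.numeric(sim$fixes$timestamp[1:200]))), 1)
  cfgf <- tempfile(fileext = ".yaml")
  cfg <- sim_config(n_pairs = 3, rng_seed = 2)
  write_sim_config_yaml(cfg, cfgf)
  cfg2 <- read_sim_config_yaml(cfgf)
  expect_equal(cfg2$together_prob_by_day, cfg$together_prob_by_day)
  expect_identical(cfg2$n_pairs, cfg$n_pairs)
  expect_identical(simulate_pair_tracks(cfg2)$fixes,
                   simulate_pair_tracks(cfg)$fixes)
})
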