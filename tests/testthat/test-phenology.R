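mk_evidence <- function(...) {
  base <- list(nest_id = "N1", discovery_date = as.Date(NA),
               n_eggs_at_discovery = NA_integer_, found_during_laying = FALSE,
               hatch_date = as.Date(NA), hatch_context = NA_character_,
               flotation_age_days = NA_real_, clutch_size = 4L,
               manual_override_date = as.Date(NA), male_visit_onset = as.Date(NA))
  args <- list(...)
  base[names(args)] <- args
  data.table::as.data.table(base)
}

test_that("clutch initiation cascade: back-count, hatch, flotation, override", {
  # found during laying with 2 eggs on June 15 -> June 14
  e1 <- mk_evidence(discovery_date = as.Date("2019-06-15"),
                    n_eggs_at_discovery = 2L, found_during_laying = TRUE)
  r1 <- estimate_clutch_initiation(e1)
  expect_identical(r1$clutch_init_date, as.Date("2019-06-14"))
  expect_identical(r1$method, 1L)
  # incubator hatch July 10, clutch of 4 -> July 10 - 3 - 17 = June 20
  e2 <- mk_evidence(hatch_date = as.Date("2019-07-10"),
                    hatch_context = "incubator")
  r2 <- estimate_clutch_initiation(e2)
  expect_identical(r2$clutch_init_date, as.Date("2019-06-20"))
  expect_identical(r2$method, 2L)
  # naturally incubated uses 19 days
  e2n <- mk_evidence(hatch_date = as.Date("2019-07-10"),
                     hatch_context = "natural")
  expect_identical(estimate_clutch_initiation(e2n)$clutch_init_date,
                   as.Date("2019-06-18"))
  # flotation: discovery - age - (eggs - 1)
  e3 <- mk_evidence(discovery_date = as.Date("2019-06-25"),
                    n_eggs_at_discovery = 4L, flotation_age_days = 5)
  r3 <- estimate_clutch_initiation(e3)
  expect_identical(r3$clutch_init_date, as.Date("2019-06-17"))
  expect_identical(r3$method, 3L)
  # manual override wins over everything else
  e4 <- mk_evidence(discovery_date = as.Date("2019-06-15"),
                    n_eggs_at_discovery = 2L, found_during_laying = TRUE,
                    manual_override_date = as.Date("2019-06-12"))
  r4 <- suppressWarnings(estimate_clutch_initiation(e4))
  expect_identical(r4$clutch_init_date, as.Date("2019-06-12"))
  expect_identical(r4$method, 4L)
  # no usable channel errors
  expect_error(estimate_clutch_initiation(mk_evidence()), "no usable")
  # divergent channels warn
  expect_warning(estimate_clutch_initiation(
    mk_evidence(found_during_laying = TRUE,
                discovery_date = as.Date("2019-06-15"), n_eggs_at_discovery = 1L,
                hatch_date = as.Date("2019-07-20"), hatch_context = "incubator")),
    "diverge")
})

test_that("round trip: simulated evidence recovers the generator's dates", {
  sim <- small_sim()
  ev <- simulate_nest_evidence(sim$nests, flotation_noise_sd = 1, seed = 3)
  est <- estimate_clutch_initiation(ev)
  err <- as.numeric(est$clutch_init_date - sim$nests$clutch_init_date)
  exact <- est$method %in% c(1L, 2L, 4L)
  expect_true(all(err[exact] == 0))
  expect_true(all(abs(err[est$method == 3L]) <= 2))
  expect_identical(est$method, ev$true_method)
})

test_that("standardised initiation dates centre at zero within year", {
  d <- as.Date(c("2019-06-10", "2019-06-14", "2018-06-20"))
  y <- c(2019L, 2019L, 2018L)
  s <- standardize_init_date(d, y)
  expect_equal(s, c(-2, 2, 0))
  expect_equal(standardize_init_date(d[3], 2018L), 0)
})

test_that("clutch order ranks by date within female", {
  cl <- data.table::data.table(
    nest_id = c("N1", "N2", "N3"),
    female_id = c("F1", "F1", "F2"),
    clutch_init_date = as.Date(c("2019-06-25", "2019-06-12", "2019-06-20")))
  out <- assign_clutch_order(cl)
  expect_identical(out[nest_id == "N2", clutch_number], 1L)
  expect_identical(out[nest_id == "N1", clutch_number], 2L)
  expect_identical(out[nest_id == "N3", clutch_number], 1L)
  cl2 <- cl[c(1, 1)]; cl2$nest_id <- c("N1", "N2")
  expect_warning(assign_clutch_order(cl2), "tied")
})
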