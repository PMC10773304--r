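# Clutch initiation dates from nest evidence, via a fixed decision cascade,
# plus season covariates. Egg-count convention: one egg per day, the first egg
# laid on day 0, so a nest discovered during laying with k eggs was initiated
# k - 1 days before discovery.

#' Phenology parameters
#'
#' @param incubation_incubator,incubation_natural Mean incubation period in
#'   days for incubator-hatched (17) and naturally incubated (19) clutches.
#' @param conflict_warn_days Warn when usable evidence channels disagree by
#'   more than this many days (default 3).
#' @return List of class `pg_phenology_params`.
#' @export
phenology_params <- function(incubation_incubator = 17,
                             incubation_natural = 19,
                             conflict_warn_days = 3) {
  structure(list(incubation_incubator = incubation_incubator,
                 incubation_natural = incubation_natural,
                 conflict_warn_days = conflict_warn_days),
            class = "pg_phenology_params")
}

estimate_one_nest <- function(ev, params) {
  est <- list()
  if (!is.na(ev$manual_override_date))
    est$m4 <- as.Date(ev$manual_override_date)
  if (isTRUE(ev$found_during_laying) && !is.na(ev$discovery_date) &&
      !is.na(ev$n_eggs_at_discovery))
    est$m1 <- as.Date(ev$discovery_date) - (ev$n_eggs_at_discovery - 1)
  if (!is.na(ev$hatch_date) && !is.na(ev$clutch_size)) {
    inc <- if (identical(ev$hatch_context, "natural"))
      params$incubation_natural else params$incubation_incubator
    est$m2 <- as.Date(ev$hatch_date) - (ev$clutch_size - 1) - inc
  }
  if (!is.na(ev$flotation_age_days) && !is.na(ev$discovery_date) &&
      !is.na(ev$n_eggs_at_discovery))
    est$m3 <- as.Date(ev$discovery_date) - round(ev$flotation_age_days) -
      (ev$n_eggs_at_discovery - 1)
  if (!is.na(ev$male_visit_onset))
    est$m5 <- as.Date(ev$male_visit_onset)
  if (!length(est))
    stop("nest ", ev$nest_id, ": no usable evidence channel", call. = FALSE)
  prio <- c("m4", "m1", "m2", "m3", "m5")
  chosen <- prio[prio %in% names(est)][1]
  dates <- do.call(c, est)
  if (length(dates) > 1 &&
      as.numeric(max(dates) - min(dates)) > params$conflict_warn_days)
    warning(sprintf("nest %s: evidence channels diverge by %d days; using method %s",
                    ev$nest_id, as.integer(max(dates) - min(dates)),
                    sub("m", "", chosen)))
  list(date = est[[chosen]], method = as.integer(sub("m", "", chosen)))
}

#' Estimate clutch initiation dates from nest evidence
#'
#' Decision cascade, highest priority first: (4) a manual override from
#' reliable field observations; (1) back-count for nests found during laying
#' (`discovery - (eggs - 1)`, one egg per day, first egg = day 0); (2) hatch
#' date minus `(clutch_size - 1)` laying days minus the mean incubation period
#' (17 d incubator-hatched, 19 d natural); (3) discovery minus the flotation
#' developmental age minus `(eggs - 1)`; (5) the male's first sustained
#' nest-visit day, used as-is.
#'
#' @param evidence data.frame with one row per nest; columns `nest_id,
#'   discovery_date, n_eggs_at_discovery, found_during_laying, hatch_date,
#'   hatch_context` (`"incubator"`/`"natural"`), `flotation_age_days,
#'   clutch_size, manual_override_date, male_visit_onset` (unused channels
#'   NA).
#' @param params A [phenology_params()] object.
#' @return data.table: `nest_id, clutch_init_date, method` (1-5).
#' @export
estimate_clutch_initiation <- function(evidence, params = phenology_params()) {
  ev <- data.table::as.data.table(evidence)
  res <- lapply(seq_len(nrow(ev)), function(i) estimate_one_nest(ev[i], params))
  data.table::data.table(
    nest_id = ev$nest_id,
    clutch_init_date = as.Date(vapply(res, function(r) as.character(r$date), "")),
    method = vapply(res, function(r) r$method, integer(1)))
}

#' Standardise clutch initiation dates within year
#'
#' Subtracts the within-year mean initiation date, giving a real-valued
#' covariate in days centred at zero for every year cohort.
#'
#' @param dates Vector of Dates.
#' @param year Vector of years (same length; defaults to the calendar year of
#'   each date).
#' @return Numeric vector of standardised dates (days).
#' @export
standardize_init_date <- function(dates, year = as.integer(format(dates, "%Y"))) {
  num <- as.numeric(dates)
  stats::ave(num, year, FUN = function(x) x - mean(x))
}

#' Order a female's clutches within season
#'
#' Ranks clutches of each female by clutch initiation date (first, second,
#' third); date ties are broken by nest id with a warning.
#'
#' @param clutches data.frame with `nest_id, female_id, clutch_init_date`.
#' @return The input with an added integer column `clutch_number`.
#' @export
assign_clutch_order <- function(clutches) {
  cl <- data.table::as.data.table(clutches)
  if (any(cl[, .(dup = anyDuplicated(clutch_init_date)), by = female_id]$dup > 0))
    warning("tied clutch initiation dates within a female; ordering by nest_id")
  data.table::setorder(cl, female_id, clutch_init_date, nest_id)
  cl[, clutch_number := seq_len(.N), by = female_id]
  cl[]
}
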