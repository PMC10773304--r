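# Dyadic proximity: pair near-simultaneous fixes of two individuals, classify
# each paired observation as together / not together with the three-rule
# dynamic-threshold scheme, and aggregate to daily proportions.

#' Together-classification parameters
#'
#' @param fixed_threshold Fixed threshold (m): a bout of candidate-together
#'   observations is confirmed only if at least one distance is strictly below
#'   this (default 30 m).
#' @param base_threshold Dynamic threshold at zero time gap (m; default 30).
#' @param gap_allowance_rate Extra distance allowed per minute of time gap
#'   between the two fixes (m/min; default 12). The dynamic threshold is
#'   `base_threshold + gap_allowance_rate * gap`.
#' @param max_pairing_gap_min Maximum time gap for two fixes to count as
#'   simultaneous (min; default 10).
#' @param tz_offset_hours Offset of local civil time from UTC used for day
#'   boundaries (default -8, Alaska daylight time).
#' @return List of class `pg_together_params`.
#' @export
together_params <- function(fixed_threshold = 30,
                            base_threshold = 30,
                            gap_allowance_rate = 12,
                            max_pairing_gap_min = 10,
                            tz_offset_hours = -8) {
  p <- list(fixed_threshold = fixed_threshold, base_threshold = base_threshold,
            gap_allowance_rate = gap_allowance_rate,
            max_pairing_gap_min = max_pairing_gap_min,
            tz_offset_hours = tz_offset_hours)
  if (fixed_threshold <= 0 || base_threshold <= 0 || gap_allowance_rate < 0 ||
      max_pairing_gap_min <= 0)
    stop("together parameters must be positive", call. = FALSE)
  class(p) <- "pg_together_params"
  p
}

#' Dynamic together threshold
#'
#' Linear in the time gap between the two paired fixes: equals the base
#' threshold (30 m) at zero gap and grows by `gap_allowance_rate` metres per
#' minute, allowing for movement during the gap.
#'
#' @param gap_min Time gap(s) in minutes (must be >= 0).
#' @param params A [together_params()] object.
#' @return Threshold(s) in metres.
#' @export
dynamic_threshold <- function(gap_min, params = together_params()) {
  if (any(gap_min < 0)) stop("gap must be non-negative", call. = FALSE)
  params$base_threshold + params$gap_allowance_rate * gap_min
}

#' Pair near-simultaneous fixes of a dyad
#'
#' Greedy one-to-one matching by ascending time gap: candidate matches are all
#' fix pairs within `max_pairing_gap_min` of each other; pairs are accepted in
#' order of increasing gap, each fix being used at most once. Distances are
#' computed in the local planar projection.
#'
#' @param fixes_a,fixes_b Filtered, time-sorted fix tables of the two members
#'   (conventionally a = male, b = female).
#' @param params A [together_params()] object.
#' @param center Projection centre, named vector `c(lon=, lat=)`.
#' @return data.table of paired observations sorted by `slot_time` (midpoint
#'   of the two fix times): `t_a, t_b, slot_time, gap_min, x_a, y_a, x_b, y_b,
#'   dist_m`.
#' @export
pair_fixes <- function(fixes_a, fixes_b, params = together_params(),
                       center = study_site_center()) {
  fixes_a <- fixes_a[order(fixes_a$timestamp), ]
  fixes_b <- fixes_b[order(fixes_b$timestamp), ]
  na <- nrow(fixes_a); nb <- nrow(fixes_b)
  empty <- data.table::data.table(
    t_a = as.POSIXct(character(), tz = "UTC"),
    t_b = as.POSIXct(character(), tz = "UTC"),
    slot_time = as.POSIXct(character(), tz = "UTC"),
    gap_min = numeric(), x_a = numeric(), y_a = numeric(),
    x_b = numeric(), y_b = numeric(), dist_m = numeric())
  if (na == 0 || nb == 0) return(empty)
  ta <- as.numeric(fixes_a$timestamp); tb <- as.numeric(fixes_b$timestamp)
  gap_s <- params$max_pairing_gap_min * 60
  lo <- findInterval(ta - gap_s, tb) + 1L   # first b with tb >= ta - gap
  hi <- findInterval(ta + gap_s, tb)        # last b with tb <= ta + gap
  cnt <- pmax(0L, hi - lo + 1L)
  ii <- rep.int(seq_len(na), cnt)
  jj <- unlist(lapply(seq_len(na), function(i) if (cnt[i] > 0) lo[i]:hi[i] else integer(0)))
  if (!length(ii)) return(empty)
  gap <- abs(ta[ii] - tb[jj])
  ord <- order(gap, ii, jj)
  used_a <- logical(na); used_b <- logical(nb)
  pick <- logical(length(ord))
  for (k in ord) {
    if (!used_a[ii[k]] && !used_b[jj[k]]) {
      pick[k] <- TRUE
      used_a[ii[k]] <- TRUE; used_b[jj[k]] <- TRUE
    }
  }
  ii <- ii[pick]; jj <- jj[pick]
  pa <- aeqd_project(fixes_a$lon[ii], fixes_a$lat[ii], center)
  pb <- aeqd_project(fixes_b$lon[jj], fixes_b$lat[jj], center)
  obs <- data.table::data.table(
    t_a = fixes_a$timestamp[ii], t_b = fixes_b$timestamp[jj],
    slot_time = fixes_a$timestamp[ii] + (tb[jj] - ta[ii]) / 2,
    gap_min = abs(ta[ii] - tb[jj]) / 60,
    x_a = pa$x, y_a = pa$y, x_b = pb$x, y_b = pb$y,
    dist_m = planar_dist(pa$x, pa$y, pb$x, pb$y))
  data.table::setorder(obs, slot_time)
  obs
}

#' Classify paired observations as together / not together
#'
#' Three rules: (1) an observation is candidate-together when its distance is
#' strictly below the dynamic threshold for its time gap; (2) a maximal run
#' (bout) of candidate observations is confirmed only if it contains at least
#' one distance strictly below the fixed 30 m threshold, otherwise the whole
#' bout is not together; (3) if the final observation of a confirmed bout has
#' distance strictly above 30 m (the separating flight), that final
#' observation is relabelled not together.
#'
#' @param obs Paired observations from [pair_fixes()], time-sorted.
#' @param params A [together_params()] object.
#' @return `obs` with added columns `candidate` (rule 1), `bout_id` (index of
#'   the candidate run, NA outside runs) and `together` (final label).
#' @export
classify_together <- function(obs, params = together_params()) {
  obs <- data.table::as.data.table(obs)
  n <- nrow(obs)
  if (n == 0) {
    obs[, `:=`(candidate = logical(0), bout_id = integer(0), together = logical(0))]
    return(obs)
  }
  cand <- obs$dist_m < dynamic_threshold(obs$gap_min, params)
  r <- rle(cand)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  bout_id <- rep(NA_integer_, n)
  together <- rep(FALSE, n)
  bid <- 0L
  for (b in seq_along(r$values)) {
    if (!r$values[b]) next
    bid <- bid + 1L
    idx <- starts[b]:ends[b]
    bout_id[idx] <- bid
    if (any(obs$dist_m[idx] < params$fixed_threshold)) {
      together[idx] <- TRUE
      last <- ends[b]
      if (obs$dist_m[last] > params$fixed_threshold) together[last] <- FALSE
    }
  }
  obs[, `:=`(candidate = cand, bout_id = bout_id, together = together)]
  obs
}

local_date <- function(time, tz_offset_hours) {
  as.Date(time + tz_offset_hours * 3600, tz = "UTC")
}

#' Aggregate together labels to daily proportions
#'
#' Days are local civil days (`tz_offset_hours` from the classification
#' parameters); `day_rel` is the day relative to clutch initiation (first-egg
#' day = 0), left NA when `clutch_init_date` is missing.
#'
#' @param obs Labelled observations from [classify_together()].
#' @param clutch_init_date Date of the first egg (or NULL).
#' @param pair_id Identifier copied into the output.
#' @param params A [together_params()] object (for the day convention).
#' @return data.table: `pair_id, date, day_rel, n_slots, n_together,
#'   prop_together`, one row per day with data.
#' @export
daily_proportions <- function(obs, clutch_init_date = NULL, pair_id = NA_character_,
                              params = together_params()) {
  obs <- data.table::as.data.table(obs)
  if (nrow(obs) == 0)
    return(data.table::data.table(pair_id = character(), date = as.Date(character()),
                                  day_rel = integer(), n_slots = integer(),
                                  n_together = integer(), prop_together = numeric()))
  obs[, date := local_date(slot_time, params$tz_offset_hours)]
  out <- obs[, .(n_slots = .N, n_together = sum(together)), by = date]
  out[, `:=`(pair_id = pair_id,
             day_rel = if (is.null(clutch_init_date)) NA_integer_
                       else as.integer(date - as.Date(clutch_init_date)),
             prop_together = n_together / n_slots)]
  data.table::setcolorder(out, c("pair_id", "date", "day_rel", "n_slots",
                                 "n_together", "prop_together"))
  data.table::setorder(out, date)
  out[]
}

#' Slot-weighted window mean with pair-clustered SE
#'
#' Model-free descriptive summary over a window of days relative to clutch
#' initiation: the pooled proportion (total together slots / total slots) with
#' a cluster-robust (by pair) linearised standard error, plus the unweighted
#' mean of per-pair proportions.
#'
#' @param summaries Day summaries ([daily_proportions()] rows, possibly many
#'   pairs) with columns `pair_id, day_rel, n_slots, n_together`.
#' @param day_rel_window Integer vector of days to include, e.g. `-5:-1`.
#' @return List: `prop` (slot-weighted), `se` (pair-clustered), `prop_by_pair`
#'   (mean of pair-level proportions), `n_pairs`, `n_slots`.
#' @export
window_mean <- function(summaries, day_rel_window) {
  s <- data.table::as.data.table(summaries)[day_rel %in% day_rel_window]
  if (nrow(s) == 0) stop("no data in the requested window", call. = FALSE)
  byp <- s[, .(tog = sum(n_together), n = sum(n_slots)), by = pair_id]
  p <- sum(byp$tog) / sum(byp$n)
  m <- nrow(byp)
  se <- if (m > 1)
    sqrt(m / (m - 1) * sum((byp$tog - p * byp$n)^2)) / sum(byp$n)
  else 0
  list(prop = p, se = se, prop_by_pair = mean(byp$tog / byp$n),
       n_pairs = m, n_slots = sum(byp$n))
}

#' Pair, classify and summarise one dyad
#'
#' Convenience wrapper: [pair_fixes()] then [classify_together()] then
#' [daily_proportions()].
#'
#' @inheritParams pair_fixes
#' @inheritParams daily_proportions
#' @return List with `obs` (labelled observations) and `days` (daily summary).
#' @export
label_dyad <- function(fixes_a, fixes_b, params = together_params(),
                       center = study_site_center(), clutch_init_date = NULL,
                       pair_id = NA_character_) {
  obs <- classify_together(pair_fixes(fixes_a, fixes_b, params, center), params)
  list(obs = obs,
       days = daily_proportions(obs, clutch_init_date, pair_id, params))
}
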