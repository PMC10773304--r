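# Nest attendance: a member is "at the nest" when its own position is within
# 15 m of the nest, or when it is together with its partner and the partner is
# within 15 m (both rules inclusive at the boundary).

#' Classify paired observations as at-nest per member
#'
#' @param obs Labelled observations from [classify_together()] (member a =
#'   male, b = female).
#' @param nest One-row nest record with `lon`, `lat` (or `x`, `y` already in
#'   the projection).
#' @param radius_m At-nest radius (m; default 15, inclusive).
#' @param center Projection centre used for the observations.
#' @return `obs` with added columns `nest_dist_a, nest_dist_b, at_nest_a,
#'   at_nest_b`.
#' @export
classify_at_nest <- function(obs, nest, radius_m = 15,
                             center = study_site_center()) {
  obs <- data.table::as.data.table(obs)
  if (!is.null(nest$x) && !is.null(nest$y)) {
    nx <- nest$x; ny <- nest$y
  } else if (!is.null(nest$lon) && !is.null(nest$lat) &&
             !is.na(nest$lon) && !is.na(nest$lat)) {
    p <- aeqd_project(nest$lon, nest$lat, center)
    nx <- p$x; ny <- p$y
  } else stop("nest has no coordinates", call. = FALSE)
  da <- planar_dist(obs$x_a, obs$y_a, nx, ny)
  db <- planar_dist(obs$x_b, obs$y_b, nx, ny)
  near_a <- da <= radius_m; near_b <- db <= radius_m
  obs[, `:=`(nest_dist_a = da, nest_dist_b = db,
             at_nest_a = near_a | (together & near_b),
             at_nest_b = near_b | (together & near_a))]
  obs
}

#' Daily nest-attendance summary per sex
#'
#' Four proportions per sex-day over the recorded paired slots: at the nest
#' overall, at the nest with the mate (at nest and together), at the nest
#' alone, and alone away from the nest (neither together nor at the nest).
#' `at_nest = at_nest_with_mate + at_nest_alone` by construction.
#'
#' @param obs Output of [classify_at_nest()].
#' @param clutch_init_date Optional Date for `day_rel`.
#' @param pair_id Identifier copied into the output.
#' @param params A [together_params()] object (day convention).
#' @return data.table: `pair_id, sex, date, day_rel, n_slots, at_nest,
#'   at_nest_with_mate, at_nest_alone, alone_away` (proportions).
#' @export
attendance_day_summary <- function(obs, clutch_init_date = NULL,
                                   pair_id = NA_character_,
                                   params = together_params()) {
  obs <- data.table::as.data.table(obs)
  obs[, date := local_date(slot_time, params$tz_offset_hours)]
  agg <- function(flag_col, sexlab) {
    f <- obs[[flag_col]]
    dt <- data.table::data.table(date = obs$date, f = f, tog = obs$together)
    out <- dt[, .(n_slots = .N, at_nest = mean(f),
                  at_nest_with_mate = mean(f & tog),
                  at_nest_alone = mean(f & !tog),
                  alone_away = mean(!f & !tog)), by = date]
    out[, sex := sexlab]
    out
  }
  res <- rbind(agg("at_nest_a", "M"), agg("at_nest_b", "F"))
  res[, `:=`(pair_id = pair_id,
             day_rel = if (is.null(clutch_init_date)) NA_integer_
                       else as.integer(date - as.Date(clutch_init_date)))]
  data.table::setcolorder(res, c("pair_id", "sex", "date", "day_rel", "n_slots",
                                 "at_nest", "at_nest_with_mate",
                                 "at_nest_alone", "alone_away"))
  data.table::setorder(res, sex, date)
  res[]
}

#' Day of the first nest visit
#'
#' Returns the day relative to clutch initiation of the first at-nest slot of
#' either pair member, plus the number of distinct data days strictly before
#' that day (population summaries should include only pairs with at least one
#' prior day of data).
#'
#' @param obs Output of [classify_at_nest()].
#' @param clutch_init_date Date of the first egg.
#' @param params A [together_params()] object (day convention).
#' @return List: `day_rel` (integer, NA when the pair was never at the nest),
#'   `n_days_before` (distinct days with data before the first visit day).
#' @export
first_nest_visit_day <- function(obs, clutch_init_date,
                                 params = together_params()) {
  obs <- data.table::as.data.table(obs)
  obs[, date := local_date(slot_time, params$tz_offset_hours)]
  at <- obs[at_nest_a | at_nest_b]
  if (!nrow(at)) return(list(day_rel = NA_integer_, n_days_before = NA_integer_))
  first_date <- min(at$date)
  list(day_rel = as.integer(first_date - as.Date(clutch_init_date)),
       n_days_before = length(unique(obs$date[obs$date < first_date])))
}
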