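# Separation events: together -> not-together transitions in the labelled
# observation sequence, attributed to the member that moved farthest between
# the two bracketing observations.

#' Detect and attribute separation events
#'
#' One event per together -> not-together transition between consecutive
#' paired observations. Each member's displacement is the straight-line
#' distance between its own fixes at the two bracketing observations; the
#' mover is the member with the strictly larger displacement (`"tie"`
#' otherwise), and the partner is "stationary" when the non-mover moved at
#' most 30 m.
#'
#' @param obs Labelled observations from [classify_together()] (members a/b;
#'   conventionally a = male, b = female).
#' @param pair_id Identifier copied into the output.
#' @param clutch_init_date Optional Date for `day_rel`.
#' @param params A [together_params()] object (day convention, 30 m rule).
#' @return data.table of events: `pair_id, event_time, date, day_rel,
#'   disp_a, disp_b, mover` (`"a"`, `"b"` or `"tie"`), `partner_stationary`.
#' @export
detect_separations <- function(obs, pair_id = NA_character_,
                               clutch_init_date = NULL,
                               params = together_params()) {
  obs <- data.table::as.data.table(obs)
  n <- nrow(obs)
  empty <- data.table::data.table(
    pair_id = character(), event_time = as.POSIXct(character(), tz = "UTC"),
    date = as.Date(character()), day_rel = integer(),
    disp_a = numeric(), disp_b = numeric(), mover = character(),
    partner_stationary = logical())
  if (n < 2) return(empty)
  i <- which(obs$together[-n] & !obs$together[-1])
  if (!length(i)) return(empty)
  j <- i + 1L
  disp_a <- planar_dist(obs$x_a[i], obs$y_a[i], obs$x_a[j], obs$y_a[j])
  disp_b <- planar_dist(obs$x_b[i], obs$y_b[i], obs$x_b[j], obs$y_b[j])
  mover <- ifelse(disp_a > disp_b, "a", ifelse(disp_b > disp_a, "b", "tie"))
  nonmover_disp <- pmin(disp_a, disp_b)
  ev_time <- obs$slot_time[j]
  d <- local_date(ev_time, params$tz_offset_hours)
  data.table::data.table(
    pair_id = pair_id, event_time = ev_time, date = d,
    day_rel = if (is.null(clutch_init_date)) NA_integer_
              else as.integer(d - as.Date(clutch_init_date)),
    disp_a = disp_a, disp_b = disp_b, mover = mover,
    partner_stationary = nonmover_disp <= 30)
}

#' Per-day separation counts and female share
#'
#' @param events Events from [detect_separations()] for one or more pairs,
#'   with mover codes `"a"` = male, `"b"` = female.
#' @param windows Named list of day_rel windows for the summary (default the
#'   pre-laying and laying windows).
#' @return List with `by_day` (per pair-day counts: `n_events, n_female,
#'   n_male, n_tie`) and `by_window` (pooled counts and female share of
#'   attributed, non-tie events).
#' @export
separation_day_stats <- function(events,
                                 windows = list(prelaying = -5:-1, laying = 0:3)) {
  ev <- data.table::as.data.table(events)
  by_day <- ev[, .(n_events = .N,
                   n_female = sum(mover == "b"),
                   n_male = sum(mover == "a"),
                   n_tie = sum(mover == "tie")),
               by = .(pair_id, date, day_rel)]
  by_window <- data.table::rbindlist(lapply(names(windows), function(w) {
    e <- ev[day_rel %in% windows[[w]] & mover != "tie"]
    nf <- sum(e$mover == "b"); nm <- sum(e$mover == "a")
    data.table::data.table(window = w, n_events = nrow(e),
                           n_female = nf, n_male = nm,
                           female_share = if (nrow(e)) nf / (nf + nm) else NA_real_)
  }))
  list(by_day = by_day, by_window = by_window)
}

#' Mover displacement summaries by sex and period
#'
#' @param events Attributed events (non-tie) with `day_rel` known.
#' @param windows Named list of day_rel windows.
#' @return data.table: window, mover sex, n, mean / median / SE of the mover's
#'   displacement (m). Empty when there are no attributable events.
#' @export
separation_distance_table <- function(events,
                                      windows = list(prelaying = -5:-1,
                                                     laying = 0:3)) {
  ev <- data.table::as.data.table(events)[mover %in% c("a", "b")]
  ev[, `:=`(mover_sex = ifelse(mover == "a", "M", "F"),
            mover_disp = ifelse(mover == "a", disp_a, disp_b))]
  out <- data.table::rbindlist(lapply(names(windows), function(w) {
    e <- ev[day_rel %in% windows[[w]]]
    if (!nrow(e)) return(NULL)
    e[, .(window = w, n = .N, mean_m = mean(mover_disp),
          median_m = stats::median(mover_disp),
          se_m = stats::sd(mover_disp) / sqrt(.N)), by = mover_sex]
  }))
  if (is.null(out) || !nrow(out))
    return(data.table::data.table(mover_sex = character(), window = character(),
                                  n = integer(), mean_m = numeric(),
                                  median_m = numeric(), se_m = numeric()))
  out
}
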