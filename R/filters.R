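# Plausibility filtering of raw fix streams. Three rules, applied per
# individual in a fixed order: (1) fixes too far from the capture site,
# (2) fixes implying an impossible flight speed, (3) single spatial outliers
# bracketed by near-identical neighbours. All thresholds are strict (">").

#' Filter parameters
#'
#' @param max_dist_from_capture Remove fixes farther than this from the
#'   capture site (m; default 500 km).
#' @param max_speed_kmh Remove fixes whose arrival leg implies a speed above
#'   this (km/h; default 105, the fastest speed seen in a continuous track).
#' @param outlier_jump Single-outlier displacement threshold (m; default
#'   2.5 km).
#' @param outlier_neighbor_window Maximum distance between the temporal
#'   neighbours of a single outlier (m; default 100).
#' @return List of class `pg_filter_params`.
#' @export
filter_params <- function(max_dist_from_capture = 500e3,
                          max_speed_kmh = 105,
                          outlier_jump = 2500,
                          outlier_neighbor_window = 100) {
  p <- list(max_dist_from_capture = max_dist_from_capture,
            max_speed_kmh = max_speed_kmh,
            outlier_jump = outlier_jump,
            outlier_neighbor_window = outlier_neighbor_window)
  if (any(unlist(p) <= 0)) stop("filter parameters must be strictly positive",
                                call. = FALSE)
  class(p) <- "pg_filter_params"
  p
}

check_fixes <- function(fixes) {
  need <- c("id", "timestamp", "lon", "lat")
  if (!all(need %in% names(fixes)))
    stop("fixes must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (any(fixes$lat < -90 | fixes$lat > 90, na.rm = TRUE) ||
      any(fixes$lon < -180 | fixes$lon > 180, na.rm = TRUE))
    stop("coordinates out of range", call. = FALSE)
  invisible(fixes)
}

#' Clip fixes to the deployment interval
#'
#' Retains fixes with `release_time <= timestamp <= end_time` (closed
#' interval), preserving order.
#'
#' @param fixes Fix table (one individual or many; clipping is row-wise).
#' @param release_time,end_time POSIXct bounds of the deployment.
#' @return The retained fixes.
#' @export
clip_to_deployment <- function(fixes, release_time, end_time) {
  if (release_time > end_time) stop("release_time must be <= end_time",
                                    call. = FALSE)
  fixes[fixes$timestamp >= release_time & fixes$timestamp <= end_time, ]
}

#' Remove fixes far from the capture site
#'
#' Removes fixes whose great-circle distance to `capture_site` exceeds
#' `max_dist_from_capture` (strictly).
#'
#' @param fixes Fix table.
#' @param capture_site Named vector `c(lon=, lat=)`.
#' @param params A [filter_params()] object.
#' @return List with `fixes` (retained) and `removed` (row indices removed).
#' @export
filter_far <- function(fixes, capture_site, params = filter_params()) {
  d <- gc_dist_m(fixes$lon, fixes$lat, capture_site[["lon"]], capture_site[["lat"]])
  removed <- which(d > params$max_dist_from_capture)
  list(fixes = if (length(removed)) fixes[-removed, ] else fixes,
       removed = removed)
}

# Forward sequential speed scan for one time-sorted track: a fix is removed
# when the leg from the previous *retained* fix implies speed > max; the
# retained sequence therefore contains no over-speed leg.
speed_scan <- function(lon, lat, t, max_speed_ms) {
  n <- length(t)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1L
  for (i in seq_len(n)[-1]) {
    dt <- as.numeric(difftime(t[i], t[last], units = "secs"))
    d <- gc_dist_m(lon[last], lat[last], lon[i], lat[i])
    if (d / dt <= max_speed_ms) { keep[i] <- TRUE; last <- i }
  }
  keep
}

#' Remove fixes implying implausible speeds
#'
#' Per individual, scans the time-sorted track forward and removes any fix
#' whose arrival leg from the previous retained fix implies a speed strictly
#' above `max_speed_kmh`.
#'
#' @inheritParams filter_far
#' @return List with `fixes` and `removed` (row indices in the input).
#' @export
filter_speed <- function(fixes, params = filter_params()) {
  ms <- params$max_speed_kmh / 3.6
  keep <- rep(TRUE, nrow(fixes))
  for (ind in unique(fixes$id)) {
    idx <- which(fixes$id == ind)
    tt <- fixes$timestamp[idx]
    if (is.unsorted(tt)) stop("fixes must be time-sorted within individual",
                              call. = FALSE)
    if (anyDuplicated(tt)) stop("duplicate timestamps for individual ", ind,
                                call. = FALSE)
    if (length(idx) > 1)
      keep[idx] <- speed_scan(fixes$lon[idx], fixes$lat[idx], tt, ms)
  }
  removed <- which(!keep)
  list(fixes = if (length(removed)) fixes[-removed, ] else fixes,
       removed = removed)
}

#' Remove single spatial outliers
#'
#' Per individual, removes any interior fix farther than `outlier_jump` from
#' both temporal neighbours when those neighbours are within
#' `outlier_neighbor_window` of each other. First and last fixes of a track
#' are never removed.
#'
#' @inheritParams filter_far
#' @return List with `fixes` and `removed` (row indices in the input).
#' @export
filter_single_outlier <- function(fixes, params = filter_params()) {
  removed <- integer(0)
  for (ind in unique(fixes$id)) {
    idx <- which(fixes$id == ind)
    n <- length(idx)
    if (n < 3) next
    lon <- fixes$lon[idx]; lat <- fixes$lat[idx]
    d_prev <- gc_dist_m(lon[-n], lat[-n], lon[-1], lat[-1]) # leg i -> i+1
    d_skip <- gc_dist_m(lon[1:(n - 2)], lat[1:(n - 2)], lon[3:n], lat[3:n])
    bad <- which(d_prev[1:(n - 2)] > params$outlier_jump &
                   d_prev[2:(n - 1)] > params$outlier_jump &
                   d_skip <= params$outlier_neighbor_window) + 1L
    removed <- c(removed, idx[bad])
  }
  removed <- sort(removed)
  list(fixes = if (length(removed)) fixes[-removed, ] else fixes,
       removed = removed)
}

#' Run all plausibility filters
#'
#' Applies, in order: deployment clipping (if `deployments` given), the
#' distance-from-capture rule, the speed rule, and the single-outlier rule,
#' and returns the retained fixes plus a per-rule audit report. Re-running on
#' the output removes nothing.
#'
#' @param fixes Fix table (columns `id, timestamp, lon, lat`, any extras kept).
#' @param capture_site Named vector `c(lon=, lat=)`.
#' @param params A [filter_params()] object.
#' @param deployments Optional data.frame `id, release_time, end_time`.
#' @return List with `fixes` and `report` (class `pg_filter_report`: counts
#'   `n_input, removed_clip, removed_far, removed_speed,
#'   removed_single_outlier, n_retained`).
#' @export
run_filters <- function(fixes, capture_site, params = filter_params(),
                        deployments = NULL) {
  check_fixes(fixes)
  fixes <- fixes[order(fixes$id, fixes$timestamp), ]
  n_input <- nrow(fixes)
  n_clip <- 0L
  if (!is.null(deployments)) {
    kept <- lapply(seq_len(nrow(deployments)), function(i) {
      f <- fixes[fixes$id == deployments$id[i], ]
      clip_to_deployment(f, deployments$release_time[i], deployments$end_time[i])
    })
    others <- fixes[!fixes$id %in% deployments$id, ]
    fixes <- rbind(data.table::rbindlist(kept), others)
    fixes <- fixes[order(fixes$id, fixes$timestamp), ]
    n_clip <- n_input - nrow(fixes)
  }
  f1 <- filter_far(fixes, capture_site, params)
  f2 <- filter_speed(f1$fixes, params)
  f3 <- filter_single_outlier(f2$fixes, params)
  report <- filter_report(n_input = n_input,
                          removed_clip = n_clip,
                          removed_far = length(f1$removed),
                          removed_speed = length(f2$removed),
                          removed_single_outlier = length(f3$removed))
  list(fixes = f3$fixes, report = report)
}

#' Construct and validate a filter report
#'
#' Enforces the conservation identity
#' `n_retained = n_input - removed_clip - removed_far - removed_speed -
#' removed_single_outlier`.
#'
#' @param n_input,removed_clip,removed_far,removed_speed,removed_single_outlier
#'   Counts.
#' @param n_retained Optional; computed from the identity when missing, and
#'   checked against it when supplied.
#' @return List of class `pg_filter_report`.
#' @export
filter_report <- function(n_input, removed_clip = 0L, removed_far = 0L,
                          removed_speed = 0L, removed_single_outlier = 0L,
                          n_retained = NULL) {
  expect <- n_input - removed_clip - removed_far - removed_speed -
    removed_single_outlier
  if (is.null(n_retained)) n_retained <- expect
  if (n_retained != expect)
    stop("filter report violates the conservation identity", call. = FALSE)
  structure(list(n_input = n_input, removed_clip = removed_clip,
                 removed_far = removed_far, removed_speed = removed_speed,
                 removed_single_outlier = removed_single_outlier,
                 n_retained = n_retained),
            class = "pg_filter_report")
}

#' @export
print.pg_filter_report <- function(x, ...) {
  cat(sprintf(
    "Fix filter report: %d input; removed %d (deployment clip), %d (>dist), %d (>speed), %d (single outlier); %d retained\n",
    x$n_input, x$removed_clip, x$removed_far, x$removed_speed,
    x$removed_single_outlier, x$n_retained))
  invisible(x)
}
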