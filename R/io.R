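# Plain-text I/O: fix and nest CSVs (ISO-8601 UTC timestamps) and YAML
# simulation configs.

#' Read a fix CSV
#'
#' Expects columns `id, sex, timestamp, lon, lat` (extra columns kept);
#' timestamps are parsed as ISO-8601 UTC.
#'
#' @param path File path.
#' @return data.table of fixes sorted by id and time.
#' @export
read_fixes_csv <- function(path) {
  f <- data.table::fread(path)
  f[, timestamp := as.POSIXct(timestamp, tz = "UTC")]
  data.table::setorder(f, id, timestamp)
  check_fixes(f)
  f
}

#' Write a fix CSV
#'
#' Writes the standard columns `id, sex, timestamp, lon, lat` with ISO-8601
#' UTC timestamps.
#'
#' @param fixes Fix table.
#' @param path File path.
#' @export
write_fixes_csv <- function(fixes, path) {
  f <- data.table::as.data.table(fixes)[, .(id, sex, timestamp, lon, lat)]
  f[, timestamp := format(timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")]
  data.table::fwrite(f, path)
  invisible(path)
}

#' Read / write a nest CSV
#'
#' @param path File path.
#' @return data.table with `clutch_init_date` parsed as Date.
#' @export
read_nests_csv <- function(path) {
  n <- data.table::fread(path)
  if ("clutch_init_date" %in% names(n))
    n[, clutch_init_date := as.Date(clutch_init_date)]
  n
}

#' @rdname read_nests_csv
#' @param nests Nest table.
#' @export
write_nests_csv <- function(nests, path) {
  data.table::fwrite(data.table::as.data.table(nests), path)
  invisible(path)
}

#' Read / write a simulation config as YAML
#'
#' @param path File path.
#' @return A [sim_config()] object.
#' @export
read_sim_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  for (d in c("season_start", "clutch_init_dates"))
    if (!is.null(y[[d]])) y[[d]] <- as.Date(y[[d]])
  for (m in c("together_prob_by_day", "separation_rate_by_day",
              "mover_female_prob_by_day"))
    if (!is.null(y[[m]])) y[[m]] <- unlist(y[[m]])
  if (!is.null(y$nest_attendance_by_day_sex))
    y$nest_attendance_by_day_sex <- lapply(y$nest_attendance_by_day_sex, unlist)
  if (!is.null(y$outlier_rates)) y$outlier_rates <- unlist(y$outlier_rates)
  if (!is.null(y$center)) y$center <- unlist(y$center)
  do.call(sim_config, y)
}

#' @rdname read_sim_config_yaml
#' @param config A [sim_config()] object.
#' @export
write_sim_config_yaml <- function(config, path) {
  y <- unclass(config)
  y$season_start <- as.character(y$season_start)
  if (!is.null(y$clutch_init_dates))
    y$clutch_init_dates <- as.character(y$clutch_init_dates)
  # reassemble constructor-shaped fields
  y$nest_attendance_by_day_sex <- list(male = as.list(y$nest_attendance_male),
                                       female = as.list(y$nest_attendance_female))
  y$nest_attendance_male <- NULL; y$nest_attendance_female <- NULL
  y$together_prob_by_day <- as.list(y$together_prob_by_day)
  y$separation_rate_by_day <- as.list(y$separation_rate_by_day)
  y$mover_female_prob_by_day <- as.list(y$mover_female_prob_by_day)
  y$outlier_rates <- as.list(y$outlier_rates)
  y$center <- as.list(y$center)
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}
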