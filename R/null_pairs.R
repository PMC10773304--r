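# Random non-breeding pair null model: which opposite-sex dyads are a valid
# comparison for a focal breeding pair on a given day, and a seeded sampler.

#' Eligible random (non-breeding) dyads for one date
#'
#' A dyad is eligible on a date when (1) it has paired location data covering
#' at least half of that day, (2) it was together for at least one paired slot
#' at some point in the data (dyads never in each other's neighbourhood are
#' not a meaningful comparison), and (3) it is not a breeding pair.
#'
#' @param dyad_days Daily summaries for candidate dyads (rows as from
#'   [daily_proportions()], `pair_id` identifying the dyad as
#'   `"<male>:<female>"`).
#' @param date The calendar date (local) of interest.
#' @param breeding_dyads Character vector of dyad ids that bred together.
#' @param full_day_slots Number of slots in a fully covered day (default 144,
#'   10-min fixes).
#' @return Character vector of eligible dyad ids.
#' @export
eligible_random_pairs <- function(dyad_days, date, breeding_dyads = character(),
                                  full_day_slots = 144) {
  dd <- data.table::as.data.table(dyad_days)
  on_date <- as.Date(date)
  ever_tog <- dd[, .(ever = sum(n_together) > 0), by = pair_id]
  day_cov <- dd[date == on_date & n_slots >= full_day_slots / 2, pair_id]
  ok <- intersect(day_cov, ever_tog[ever == TRUE, pair_id])
  setdiff(ok, breeding_dyads)
}

#' Sample a null-pair set
#'
#' Uniform sample without replacement of up to `n` dyads; when fewer
#' candidates exist, all are returned with a warning.
#'
#' @param candidates Character vector of eligible dyad ids.
#' @param n Sample size (default 50).
#' @param seed Integer seed.
#' @return Character vector of sampled dyad ids (possibly empty).
#' @export
sample_null <- function(candidates, n = 50, seed = 1L) {
  set.seed(seed)
  if (!length(candidates)) {
    warning("no eligible candidates; returning empty sample")
    return(character(0))
  }
  if (length(candidates) < n) {
    warning(sprintf("only %d candidates for requested %d; taking all",
                    length(candidates), n))
    return(sample(candidates))
  }
  sample(candidates, n)
}

#' Stack breeding and null summaries for window models
#'
#' Combines per-day summaries of breeding pairs and sampled null dyads into
#' one table with a `pair_type` factor, restricted to the requested day_rel
#' windows, ready for the beta-binomial comparison models.
#'
#' @param summaries_breeding,summaries_null Day summaries with `pair_id,
#'   day_rel, n_slots, n_together`.
#' @param windows Named list of integer day_rel windows.
#' @return data.table with columns of the inputs plus `pair_type`
#'   (`"breeding"` / `"random"`) and `window`.
#' @export
null_comparison <- function(summaries_breeding, summaries_null,
                            windows = list(prelaying = -5:-1, laying = 0:3,
                                           post = 4:10)) {
  b <- data.table::as.data.table(summaries_breeding)
  r <- data.table::as.data.table(summaries_null)
  b[, pair_type := "breeding"]; r[, pair_type := "random"]
  all <- rbind(b, r, fill = TRUE)
  out <- data.table::rbindlist(lapply(names(windows), function(w) {
    x <- all[day_rel %in% windows[[w]]]
    if (nrow(x)) x[, window := w]
    x
  }), fill = TRUE)
  out
}
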