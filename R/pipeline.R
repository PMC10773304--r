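# End-to-end orchestration: simulate (or ingest) -> filter -> pair & classify
# -> separations -> nest attendance -> phenology round trip -> null pairs ->
# mixed models -> machine-readable results.

#' Analysis windows
#'
#' Single source of truth for the day_rel windows used across modules:
#' pre-laying (-5..-1), laying (0..3), the fertile part of laying (0..2,
#' excluding the last laying day of a four-egg clutch), and post-laying
#' (4..10).
#' @return Named list of integer vectors.
#' @export
default_windows <- function() {
  list(prelaying = -5:-1, laying = 0:3, fertile_laying = 0:2, post = 4:10)
}

#' Run the full mate-guarding analysis on simulated or supplied data
#'
#' Executes every stage of the analysis and returns all intermediate artifacts
#' plus model fits and a flat numeric summary. With only a `config`, the data
#' are simulated; alternatively pass `fixes` and `nests` read from CSV.
#'
#' @param config A [sim_config()]; used to simulate when `fixes` is NULL and
#'   for the projection centre and seed.
#' @param fixes,nests Optional pre-loaded fix and nest tables (as produced by
#'   [simulate_pair_tracks()] or [read_fixes_csv()]/[read_nests_csv()]).
#' @param tparams A [together_params()] object.
#' @param fparams A [filter_params()] object.
#' @param windows Named list of day_rel windows (see [default_windows()]).
#' @param n_null_dyads Number of random opposite-sex non-breeding dyads to
#'   label for the null comparison (0 skips the stage).
#' @param out_dir Optional directory: CSV artifacts, a JSON summary and (if
#'   ggplot2 is installed) figures are written there.
#' @return List of class `pg_run`: `filter_report`, `pair_days` (daily
#'   together summaries with covariates), `events`, `attendance`, `fits`
#'   (model fits), `marginals`, `descriptives`, `null` (or NULL), `phenology`,
#'   `truth` (when simulated), `summary` (flat named numerics).
#' @export
run_pipeline <- function(config = sim_config(), fixes = NULL, nests = NULL,
                         tparams = together_params(),
                         fparams = filter_params(),
                         windows = default_windows(),
                         n_null_dyads = 0, out_dir = NULL) {
  truth <- NULL
  if (is.null(fixes)) {
    sim <- simulate_pair_tracks(config)
    fixes <- sim$fixes; nests <- sim$nests; truth <- sim$truth
  }
  stopifnot(!is.null(nests))
  filt <- run_filters(fixes, capture_site = config$center, params = fparams)
  ffix <- data.table::as.data.table(filt$fixes)

  nests <- data.table::as.data.table(nests)
  nests[, std_init_date := standardize_init_date(clutch_init_date)]

  # --- per-pair labelling ---
  obs_l <- list(); days_l <- list(); ev_l <- list(); att_l <- list()
  fvd_l <- list(); gaps <- list()
  for (i in seq_len(nrow(nests))) {
    nst <- nests[i]
    fa <- ffix[id == nst$male_id]; fb <- ffix[id == nst$female_id]
    if (!nrow(fa) || !nrow(fb)) next
    lab <- label_dyad(fa, fb, tparams, config$center,
                      clutch_init_date = nst$clutch_init_date,
                      pair_id = nst$pair_id)
    obs <- classify_at_nest(lab$obs, nst, center = config$center)
    days <- lab$days
    days[, `:=`(nest_id = nst$nest_id, epp = nst$epp,
                std_init_date = nst$std_init_date)]
    ev <- detect_separations(obs, nst$pair_id, nst$clutch_init_date, tparams)
    ev[, `:=`(nest_id = nst$nest_id, epp = nst$epp,
              std_init_date = nst$std_init_date)]
    att <- attendance_day_summary(obs, nst$clutch_init_date, nst$pair_id, tparams)
    att[, `:=`(nest_id = nst$nest_id, std_init_date = nst$std_init_date)]
    obs_l[[nst$pair_id]] <- obs
    days_l[[i]] <- days; ev_l[[i]] <- ev; att_l[[i]] <- att
    fvd_l[[i]] <- first_nest_visit_day(obs, nst$clutch_init_date, tparams)
    gaps[[i]] <- obs$gap_min
  }
  pair_days <- data.table::rbindlist(days_l)
  events <- data.table::rbindlist(ev_l)
  attendance <- data.table::rbindlist(att_l)
  median_gap <- stats::median(unlist(gaps))

  # --- models ---
  fits <- list(); marginals <- list()
  bb_terms <- c("day_rel", "I(day_rel^2)", "std_init_date", "I(std_init_date^2)")
  for (w in c("prelaying", "laying")) {
    sq <- select_quadratic(pair_days,
                           model_spec("beta_binomial",
                                      c(successes = "n_together", totals = "n_slots"),
                                      bb_terms, random = "slope",
                                      window = windows[[w]]))
    fits[[paste0("together_", w)]] <- sq$fit
    nd <- data.frame(day_rel = windows[[w]], std_init_date = 0)
    marginals[[paste0("together_", w)]] <- marginal_mean(sq$fit, nd)
  }
  ev_mod <- events[mover != "tie"]
  ev_mod[, female_move := as.integer(mover == "b")]
  for (w in c("prelaying", "laying")) {
    if (nrow(ev_mod[day_rel %in% windows[[w]]]) >= 10) {
      sq <- select_quadratic(ev_mod,
                             model_spec("binomial", "female_move", bb_terms,
                                        random = "slope", window = windows[[w]]))
      fits[[paste0("mover_", w)]] <- sq$fit
      nd <- data.frame(day_rel = round(mean(windows[[w]])), std_init_date = 0)
      marginals[[paste0("mover_", w)]] <- marginal_mean(sq$fit, nd)
    }
  }
  att_mod <- data.table::copy(attendance)
  att_mod[, n_at_nest := as.integer(round(at_nest * n_slots))]
  for (s in c("M", "F")) {
    d <- att_mod[sex == s]
    sq <- select_quadratic(d,
                           model_spec("beta_binomial",
                                      c(successes = "n_at_nest", totals = "n_slots"),
                                      bb_terms, random = "slope",
                                      window = windows$laying))
    fits[[paste0("attendance_", s)]] <- sq$fit
    nd <- data.frame(day_rel = windows$laying, std_init_date = 0)
    marginals[[paste0("attendance_", s)]] <- marginal_mean(sq$fit, nd)
  }
  dist_mod <- data.table::copy(ev_mod)
  dist_mod[, `:=`(mover_disp = ifelse(mover == "a", disp_a, disp_b),
                  mover_sex = ifelse(mover == "a", "M", "F"))]
  for (w in c("prelaying", "laying")) {
    d <- dist_mod[day_rel %in% windows[[w]]]
    if (nrow(d) >= 10) {
      fits[[paste0("sepdist_", w)]] <-
        fit_glmm(d, model_spec("gaussian", "mover_disp",
                               c("day_rel", "std_init_date", "mover_sex"),
                               random = "intercept"))
    }
  }

  # --- descriptives ---
  descr <- list(
    together = lapply(windows, function(w)
      tryCatch(window_mean(pair_days, w), error = function(e) NULL)),
    separations = separation_day_stats(events,
                                       windows[c("prelaying", "laying")]),
    sep_distance = separation_distance_table(events,
                                             windows[c("prelaying", "laying")]),
    median_pairing_gap_min = median_gap,
    sep_rate = list(
      prelaying = nrow(events[day_rel %in% windows$prelaying]) /
        max(1, nrow(pair_days[day_rel %in% windows$prelaying])),
      laying = nrow(events[day_rel %in% windows$laying]) /
        max(1, nrow(pair_days[day_rel %in% windows$laying]))),
    first_visit = {
      fv <- Filter(function(x) !is.na(x$day_rel) && x$n_days_before >= 1, fvd_l)
      if (length(fv)) mean(vapply(fv, `[[`, numeric(1), "day_rel")) else NA_real_
    })

  # --- phenology round trip (simulated evidence) ---
  phen <- NULL
  if (!is.null(truth)) {
    evd <- simulate_nest_evidence(nests, seed = config$rng_seed + 1L)
    est <- estimate_clutch_initiation(evd)
    cmp <- merge(est, nests[, .(nest_id, clutch_init_date)], by = "nest_id",
                 suffixes = c("_est", "_true"))
    phen <- list(estimates = est,
                 mean_abs_error_days =
                   mean(abs(as.numeric(cmp$clutch_init_date_est -
                                         cmp$clutch_init_date_true))))
  }

  # --- null pairs ---
  nullres <- NULL
  if (n_null_dyads > 0)
    nullres <- null_pair_analysis(ffix, nests, pair_days, tparams, config,
                                  windows, n_null_dyads)

  summary <- build_summary(descr, marginals, filt$report, nullres, phen)
  res <- structure(list(filter_report = filt$report, pair_days = pair_days,
                        events = events, attendance = attendance, fits = fits,
                        marginals = marginals, descriptives = descr,
                        null = nullres, phenology = phen, truth = truth,
                        nests = nests, obs = obs_l, summary = summary,
                        windows = windows),
                   class = "pg_run")
  if (!is.null(out_dir)) write_run_artifacts(res, out_dir)
  res
}

# Label a seeded sample of non-breeding opposite-sex dyads and summarise their
# time together per window.
null_pair_analysis <- function(ffix, nests, pair_days, tparams, config,
                               windows, n_dyads) {
  set.seed(config$rng_seed + 2L)
  males <- nests$male_id; females <- nests$female_id
  combos <- data.table::CJ(m = males, f = females)
  breeding <- paste(nests$male_id, nests$female_id, sep = ":")
  combos <- combos[!paste(m, f, sep = ":") %in% breeding]
  combos <- combos[sample(.N, min(n_dyads, .N))]
  # day_rel of a null dyad follows the focal female's clutch
  init_by_f <- stats::setNames(as.list(nests$clutch_init_date), nests$female_id)
  dl <- list()
  for (k in seq_len(nrow(combos))) {
    fa <- ffix[id == combos$m[k]]; fb <- ffix[id == combos$f[k]]
    if (!nrow(fa) || !nrow(fb)) next
    lab <- label_dyad(fa, fb, tparams, config$center,
                      clutch_init_date = init_by_f[[combos$f[k]]],
                      pair_id = paste(combos$m[k], combos$f[k], sep = ":"))
    dl[[k]] <- lab$days
  }
  dyad_days <- data.table::rbindlist(dl)
  # eligibility: ever together at least once, >= 50% coverage on the day
  ever <- dyad_days[, .(ever = sum(n_together) > 0), by = pair_id]
  elig <- dyad_days[pair_id %in% ever[ever == TRUE, pair_id] & n_slots >= 72]
  win_means <- lapply(windows, function(w)
    tryCatch(window_mean(elig, w), error = function(e) NULL))
  list(dyad_days = dyad_days, eligible_days = elig, window_means = win_means,
       n_dyads_labelled = length(unique(dyad_days$pair_id)),
       n_dyads_eligible = length(unique(elig$pair_id)))
}

#' Extrapair-paternity contrast models
#'
#' Fits, for both fertile windows (pre-laying -5..-1 and laying days 0..2),
#' the daily time-together beta-binomial model and the separation mover-sex
#' binomial model with extrapair paternity (yes/no) as a covariate alongside
#' day and standardised clutch initiation date.
#'
#' @param pair_days Daily summaries with `epp` and `std_init_date`.
#' @param events Separation events with `epp` (non-tie rows are used).
#' @param windows Named list; `prelaying` and `fertile_laying` are used.
#' @return List per window: `together` fit, `mover` fit (NULL when
#'   inestimable), and marginal means by EPP group.
#' @export
epp_contrast <- function(pair_days, events,
                         windows = default_windows()) {
  pd <- data.table::as.data.table(pair_days)
  ev <- data.table::as.data.table(events)[mover != "tie"]
  ev[, female_move := as.integer(mover == "b")]
  out <- list()
  for (w in c("prelaying", "fertile_laying")) {
    win <- windows[[w]]
    res <- list(together = NULL, mover = NULL, marginals = NULL)
    d <- pd[day_rel %in% win]
    if (length(unique(d$epp)) < 2) {
      res$note <- "EPP contrast inestimable: single EPP class"
    } else {
      res$together <- fit_glmm(d, model_spec(
        "beta_binomial", c(successes = "n_together", totals = "n_slots"),
        c("epp", "day_rel", "std_init_date"), random = "slope"))
      nd <- data.frame(epp = c(FALSE, TRUE), day_rel = round(mean(win)),
                       std_init_date = 0)
      res$marginals <- marginal_mean(res$together, nd)
      de <- ev[day_rel %in% win]
      if (nrow(de) >= 10 && length(unique(de$epp)) == 2)
        res$mover <- fit_glmm(de, model_spec(
          "binomial", "female_move", c("epp", "day_rel", "std_init_date"),
          random = "intercept"))
    }
    out[[w]] <- res
  }
  out
}

build_summary <- function(descr, marginals, report, nullres, phen) {
  pick_marg <- function(name, day) {
    m <- marginals[[name]]
    if (is.null(m)) return(NA_real_)
    m$estimate[match(day, m$day_rel)]
  }
  s <- c(
    filtered_retention_pct = 100 * report$n_retained / report$n_input,
    median_pairing_gap_min = descr$median_pairing_gap_min,
    together_prelaying_pct = 100 * descr$together$prelaying$prop,
    together_laying_pct = 100 * descr$together$laying$prop,
    together_post_pct = if (!is.null(descr$together$post))
      100 * descr$together$post$prop else NA_real_,
    together_day0_model_pct = 100 * pick_marg("together_laying", 0),
    together_day3_model_pct = 100 * pick_marg("together_laying", 3),
    male_nest_day0_model_pct = 100 * pick_marg("attendance_M", 0),
    male_nest_day3_model_pct = 100 * pick_marg("attendance_M", 3),
    sep_per_pairday_prelaying = descr$sep_rate$prelaying,
    sep_per_pairday_laying = descr$sep_rate$laying,
    female_mover_share_prelaying_pct =
      100 * descr$separations$by_window[window == "prelaying", female_share],
    female_mover_share_laying_pct =
      100 * descr$separations$by_window[window == "laying", female_share],
    first_nest_visit_mean_day = descr$first_visit)
  if (!is.null(nullres) && !is.null(nullres$window_means$post))
    s["null_together_post_pct"] <- 100 * nullres$window_means$post$prop
  if (!is.null(phen))
    s["phenology_mean_abs_error_days"] <- phen$mean_abs_error_days
  s
}

write_run_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(res$pair_days, file.path(out_dir, "pair_days.csv"))
  data.table::fwrite(res$events, file.path(out_dir, "separation_events.csv"))
  data.table::fwrite(res$attendance, file.path(out_dir, "attendance.csv"))
  jsonlite::write_json(as.list(res$summary),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(res$pair_days,
                         ggplot2::aes(day_rel, prop_together, group = day_rel)) +
      ggplot2::geom_boxplot(outlier.size = 0.4) +
      ggplot2::labs(x = "day relative to clutch initiation",
                    y = "proportion of time together")
    ggplot2::ggsave(file.path(out_dir, "together_profile.png"), p,
                    width = 7, height = 4, dpi = 150)
  }
  invisible(out_dir)
}
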