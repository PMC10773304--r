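# Synthetic paired-track generator.
#
# Emulates a season of dyadic GPS tracking on an arctic tundra plot: each pair
# follows a two-state process (together around a shared correlated-random-walk
# centroid vs. apart after a scripted separation flight), visits shared
# foraging sites and its own nest, and is sampled on jittered 10-min grids with
# GPS noise and optional planted implausible positions. Every stochastic
# element is logged so downstream classifiers can be scored against ground
# truth.

#' Simulation configuration for paired GPS tracks
#'
#' Defaults reproduce the study conditions the analysis targets: ~90% of slots
#' together in the five days before clutch initiation decaying to ~28% on
#' laying day 3, a median pairing gap of ~2.6 min, separation flights with a
#' median around 160 m, and male nest attendance rising from 20% on day 0 to
#' 66% on day 3.
#'
#' @param n_pairs Number of breeding pairs.
#' @param season_start First calendar date of the season (Date or string).
#' @param clutch_init_dates Optional vector of per-pair clutch initiation
#'   dates; if `NULL`, dates are drawn around `season_start + 14` (SD 4 days).
#' @param days_rel Integer vector of days relative to clutch initiation to
#'   simulate for every pair (first-egg day = 0).
#' @param fix_interval_min Scheduled fix interval, minutes.
#' @param pair_gap_median_min Target median (min) of the within-pair fix-time
#'   gap. Each pair's members are offset by a Weibull-distributed amount
#'   (shape 3.5, light-tailed) calibrated so that, with the per-fix jitter,
#'   gaps have this median with ~95% below 5 min, mirroring the tag
#'   asynchrony of the field data.
#' @param fix_jitter_min Half-width (min) of the uniform per-fix time jitter.
#' @param gps_noise_sd GPS noise SD per coordinate, metres.
#' @param together_prob_by_day Named numeric vector: day (as character of the
#'   integer day_rel) -> probability a slot is truly together.
#' @param separation_rate_by_day Named numeric vector: expected
#'   together-to-apart transitions per day.
#' @param mover_female_prob_by_day Named numeric vector: probability the
#'   female is the scripted mover of a separation starting that day.
#' @param separation_dist_logmean,separation_dist_logsd Log-normal parameters
#'   (log-metres) of the separation flight length.
#' @param nest_attendance_by_day_sex List with elements `male` and `female`,
#'   each a named numeric vector day -> per-slot probability of being at the
#'   nest. When the pair is together the male's draw drives both members;
#'   when apart each member uses its own draw.
#' @param step_speed_together,step_speed_apart Mean CRW step speed, m/min.
#' @param n_sites Number of shared foraging sites on the plot; co-visits of
#'   these sites by different individuals generate the random-pair baseline.
#' @param site_radius Confinement radius of within-site movement, metres.
#' @param site_switch_prob Per-slot probability of relocating to another site.
#' @param plot_size Side of the square study plot, metres.
#' @param within_pair_scatter_sd SD (m) of each member's offset from the
#'   shared centroid while together.
#' @param nest_scatter_sd SD (m) of the position while sitting on the nest.
#' @param outlier_rates Named numeric vector `c(far=, speed=, single=)`:
#'   per-fix corruption probabilities exercising the three plausibility
#'   filters.
#' @param diurnal_amplitude Optional amplitude (probability scale) of a
#'   sinusoidal within-day modulation of the together probability, peaking at
#'   local midday; `0` disables it and uses day-level bout construction.
#' @param epp_rate Probability that a clutch contains extrapair young.
#' @param center Named vector `c(lon=, lat=)`: plot centre for the projection.
#' @param rng_seed Integer seed; identical config + seed gives identical
#'   output.
#' @return Object of class `pg_sim_config` (a validated list).
#' @export
sim_config <- function(n_pairs = 40,
                       season_start = as.Date("2019-06-01"),
                       clutch_init_dates = NULL,
                       days_rel = -7:10,
                       fix_interval_min = 10,
                       pair_gap_median_min = 2.6,
                       fix_jitter_min = 0.5,
                       gps_noise_sd = 5,
                       together_prob_by_day = NULL,
                       separation_rate_by_day = NULL,
                       mover_female_prob_by_day = NULL,
                       separation_dist_logmean = log(160),
                       separation_dist_logsd = 0.6,
                       nest_attendance_by_day_sex = NULL,
                       step_speed_together = 0.8,
                       step_speed_apart = 1.2,
                       n_sites = 6,
                       site_radius = 25,
                       site_switch_prob = 0.05,
                       plot_size = 1600,
                       within_pair_scatter_sd = 3,
                       nest_scatter_sd = 2,
                       outlier_rates = c(far = 0, speed = 0, single = 0),
                       diurnal_amplitude = 0,
                       epp_rate = 0.11,
                       center = study_site_center(),
                       rng_seed = 1L) {
  days_rel <- as.integer(days_rel)
  dn <- as.character(days_rel)
  fill_by_day <- function(x, default) {
    out <- default
    if (!is.null(x)) {
      stopifnot(!is.null(names(x)))
      out[names(x)] <- x
    }
    out[dn]
  }
  def_together <- stats::setNames(rep(0.10, length(days_rel)), dn)
  def_together[dn %in% as.character(-7:-6)] <- 0.80
  def_together[dn %in% as.character(-5:-1)] <- 0.90
  for (d in c("0", "1", "2", "3"))
    if (d %in% dn) def_together[d] <- c(`0` = 0.84, `1` = 0.69, `2` = 0.48, `3` = 0.28)[d]
  def_rate <- stats::setNames(rep(2.5, length(days_rel)), dn)
  def_rate[dn %in% as.character(-7:-1)] <- 1.9
  def_rate[dn %in% as.character(0:3)] <- 4.6
  def_mover <- stats::setNames(rep(0.50, length(days_rel)), dn)
  def_mover[dn %in% as.character(-7:-1)] <- 0.45
  def_mover[dn %in% as.character(0:3)] <- 0.52
  def_att_m <- stats::setNames(rep(0, length(days_rel)), dn)
  def_att_m[dn %in% as.character(4:10)] <- 0.85
  for (d in c("-3", "-2", "-1", "0", "1", "2", "3"))
    if (d %in% dn) def_att_m[d] <- c(`-3` = 0.05, `-2` = 0.08, `-1` = 0.10,
                                     `0` = 0.20, `1` = 0.35, `2` = 0.50, `3` = 0.66)[d]
  def_att_f <- stats::setNames(rep(0, length(days_rel)), dn)
  def_att_f[dn %in% as.character(4:10)] <- 0.02
  for (d in c("-3", "-2", "-1", "0", "1", "2", "3"))
    if (d %in% dn) def_att_f[d] <- c(`-3` = 0.04, `-2` = 0.06, `-1` = 0.10,
                                     `0` = 0.08, `1` = 0.07, `2` = 0.07, `3` = 0.07)[d]
  att <- nest_attendance_by_day_sex
  cfg <- list(
    n_pairs = as.integer(n_pairs),
    season_start = as.Date(season_start),
    clutch_init_dates = if (!is.null(clutch_init_dates)) as.Date(clutch_init_dates),
    days_rel = days_rel,
    fix_interval_min = fix_interval_min,
    pair_gap_median_min = pair_gap_median_min,
    fix_jitter_min = fix_jitter_min,
    gps_noise_sd = gps_noise_sd,
    together_prob_by_day = fill_by_day(together_prob_by_day, def_together),
    separation_rate_by_day = fill_by_day(separation_rate_by_day, def_rate),
    mover_female_prob_by_day = fill_by_day(mover_female_prob_by_day, def_mover),
    separation_dist_logmean = separation_dist_logmean,
    separation_dist_logsd = separation_dist_logsd,
    nest_attendance_male = fill_by_day(att$male, def_att_m),
    nest_attendance_female = fill_by_day(att$female, def_att_f),
    step_speed_together = step_speed_together,
    step_speed_apart = step_speed_apart,
    n_sites = as.integer(n_sites),
    site_radius = site_radius,
    site_switch_prob = site_switch_prob,
    plot_size = plot_size,
    within_pair_scatter_sd = within_pair_scatter_sd,
    nest_scatter_sd = nest_scatter_sd,
    outlier_rates = outlier_rates[c("far", "speed", "single")],
    diurnal_amplitude = diurnal_amplitude,
    epp_rate = epp_rate,
    center = center,
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "pg_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$together_prob_by_day, cfg$mover_female_prob_by_day,
             cfg$nest_attendance_male, cfg$nest_attendance_female,
             cfg$outlier_rates, cfg$epp_rate, cfg$site_switch_prob)
  if (anyNA(probs) || any(probs < 0 | probs > 1))
    stop("sim_config: all probabilities must lie in [0, 1]", call. = FALSE)
  pos <- c(cfg$fix_interval_min, cfg$pair_gap_median_min, cfg$gps_noise_sd,
           cfg$step_speed_together, cfg$step_speed_apart, cfg$site_radius,
           cfg$plot_size, cfg$within_pair_scatter_sd, cfg$nest_scatter_sd,
           cfg$separation_rate_by_day)
  if (any(pos < 0) || cfg$fix_interval_min <= 0 || cfg$plot_size <= 0 ||
      cfg$step_speed_together <= 0 || cfg$step_speed_apart <= 0)
    stop("sim_config: durations, lengths and speeds must be positive",
         call. = FALSE)
  if (cfg$n_pairs < 1) stop("sim_config: n_pairs must be >= 1", call. = FALSE)
  invisible(cfg)
}

# Random composition of n into m positive integer parts.
rand_composition <- function(n, m) {
  if (m == 1) return(n)
  cuts <- sort(sample.int(n - 1, m - 1))
  diff(c(0L, cuts, n))
}

# Lay out one day's slot states: n1 together slots among n, with ~k
# together->apart transitions, arranged as alternating runs.
arrange_day_states <- function(n, n1, k) {
  n0 <- n - n1
  if (n1 <= 0) return(rep(FALSE, n))
  if (n0 <= 0) return(rep(TRUE, n))
  if (k <= 0) return(c(rep(FALSE, n0), rep(TRUE, n1)))
  kk <- min(k, n1, n0)
  # variants: (start, end) in {T,A}; T->A transitions = kk in all of them
  variants <- list(c(kk, kk, TRUE),          # T ... A
                   c(kk + 1, kk, TRUE),      # T ... T (needs n1 >= kk+1)
                   c(kk, kk + 1, FALSE),     # A ... A (needs n0 >= kk+1)
                   c(kk + 1, kk + 1, FALSE)) # A ... T
  ok <- vapply(variants, function(v) n1 >= v[1] && n0 >= v[2], logical(1))
  v <- variants[ok][[sample.int(sum(ok), 1)]]
  mT <- v[1]; mA <- v[2]; start_T <- as.logical(v[3])
  runsT <- rand_composition(n1, mT)
  runsA <- rand_composition(n0, mA)
  out <- logical(0)
  i <- 1; j <- 1; cur_T <- start_T
  while (i <= mT || j <= mA) {
    if (cur_T && i <= mT) { out <- c(out, rep(TRUE, runsT[i])); i <- i + 1 }
    else if (!cur_T && j <= mA) { out <- c(out, rep(FALSE, runsA[j])); j <- j + 1 }
    cur_T <- !cur_T
  }
  out
}

rnorm2 <- function(sd) stats::rnorm(2, 0, sd)

# One CRW step confined to a disc of radius `rad` around `anchor`.
crw_step <- function(pos, heading, anchor, rad, step_mean, turn_sd = 1.2) {
  heading <- heading + stats::rnorm(1, 0, turn_sd)
  step <- stats::rgamma(1, shape = 2, scale = step_mean / 2)
  pos <- pos + step * c(cos(heading), sin(heading))
  d <- sqrt(sum((pos - anchor)^2))
  if (d > rad) {
    pos <- anchor + (pos - anchor) * rad / d
    heading <- atan2(anchor[2] - pos[2], anchor[1] - pos[1]) +
      stats::rnorm(1, 0, 0.5)
  }
  list(pos = pos, heading = heading)
}

# Rejection-sample `n` points in the plot with pairwise separation >= min_sep
# and distance >= min_from from every row of `from` (matrix or NULL).
scatter_points <- function(n, half, min_sep, from = NULL, min_from = 0) {
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(pts) < n && tries < 20000) {
    p <- stats::runif(2, -half, half)
    ok <- (nrow(pts) == 0 || min(sqrt(colSums((t(pts) - p)^2))) >= min_sep) &&
      (is.null(from) || nrow(from) == 0 ||
         min(sqrt(colSums((t(from) - p)^2))) >= min_from)
    if (ok) pts <- rbind(pts, p)
    tries <- tries + 1
  }
  if (nrow(pts) < n) stop("could not place points; plot too small")
  pts
}

#' Simulate paired GPS tracks with ground truth
#'
#' Generates a full tracking season for `config$n_pairs` breeding pairs on a
#' shared plot, returning raw fix tables (with planted implausible positions if
#' configured), nest records, and a truth log for scoring classifiers.
#'
#' @param config A [sim_config()] object.
#' @return List with elements:
#'   \describe{
#'     \item{fixes}{data.table of fixes: `id, sex, pair_id, slot, timestamp,
#'       lon, lat` (slot indexes the season-long 10-min grid of the pair).}
#'     \item{nests}{data.table of nest records (coordinates, members,
#'       `clutch_init_date`, `epp`, `clutch_size`, `year`).}
#'     \item{truth}{list of data.tables `slots` (true together flag per pair
#'       slot), `fixes` (true at-nest flag and planted corruption rule per
#'       fix), and `separations` (scripted mover and flight length per
#'       together-to-apart transition).}
#'     \item{sites}{matrix of shared foraging-site coordinates (m).}
#'     \item{config}{the input configuration.}
#'   }
#' @export
simulate_pair_tracks <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$rng_seed)
  half <- cfg$plot_size / 2
  n <- cfg$n_pairs
  nests_xy <- scatter_points(n, half - 50, min_sep = 60)
  sites <- scatter_points(cfg$n_sites, half - 50, min_sep = 150,
                          from = nests_xy, min_from = 140)
  init_dates <- cfg$clutch_init_dates
  if (is.null(init_dates))
    init_dates <- cfg$season_start + pmax(8, round(stats::rnorm(n, 14, 4)))
  if (length(init_dates) == 1) init_dates <- rep(init_dates, n)
  epp <- stats::rbinom(n, 1, cfg$epp_rate) == 1

  fixes_l <- list(); slots_l <- list(); tfix_l <- list(); sep_l <- list()
  for (p in seq_len(n)) {
    sim <- simulate_one_pair(cfg, p, nests_xy[p, ], sites, init_dates[p])
    fixes_l[[p]] <- sim$fixes; slots_l[[p]] <- sim$slots
    tfix_l[[p]] <- sim$truth_fixes; sep_l[[p]] <- sim$separations
  }
  fixes <- data.table::rbindlist(fixes_l)
  # corrupt and export to lon/lat
  fixes <- plant_outliers(fixes, cfg)
  ll <- aeqd_unproject(fixes$x, fixes$y, cfg$center)
  fixes[, `:=`(lon = ll$lon, lat = ll$lat)]
  truth_fixes <- fixes[, .(pair_id, id, sex, slot, timestamp, at_nest,
                           corrupt_rule)]
  out_fixes <- fixes[, .(id, sex, pair_id, slot, timestamp, lon, lat)]
  data.table::setorder(out_fixes, id, timestamp)

  nest_ll <- aeqd_unproject(nests_xy[, 1], nests_xy[, 2], cfg$center)
  nests <- data.table::data.table(
    nest_id = sprintf("N%03d", seq_len(n)),
    pair_id = sprintf("P%03d", seq_len(n)),
    male_id = sprintf("M%03d", seq_len(n)),
    female_id = sprintf("F%03d", seq_len(n)),
    lon = nest_ll$lon, lat = nest_ll$lat,
    clutch_init_date = init_dates,
    clutch_number = 1L, clutch_size = 4L, epp = epp,
    year = as.integer(format(init_dates, "%Y")))

  list(fixes = out_fixes,
       nests = nests,
       truth = list(slots = data.table::rbindlist(slots_l),
                    fixes = truth_fixes,
                    separations = data.table::rbindlist(sep_l)),
       sites = sites,
       config = cfg)
}

simulate_one_pair <- function(cfg, p, nest_xy, sites, init_date) {
  pair_id <- sprintf("P%03d", p)
  days <- cfg$days_rel
  nsl <- as.integer(round(1440 / cfg$fix_interval_min))
  nday <- length(days)
  total <- nday * nsl
  day_of <- rep(days, each = nsl)
  hour_of <- rep((seq_len(nsl) - 1) * cfg$fix_interval_min / 60, times = nday)
  dchr <- as.character(day_of)
  p_tog <- cfg$together_prob_by_day[dchr]
  rate <- cfg$separation_rate_by_day[dchr]
  att_m <- cfg$nest_attendance_male[dchr]
  att_f <- cfg$nest_attendance_female[dchr]

  # --- truth together sequence ---
  if (cfg$diurnal_amplitude > 0) {
    p_slot <- pmin(1, pmax(0, p_tog - cfg$diurnal_amplitude * cos(2 * pi * hour_of / 24)))
    tog <- stats::runif(total) < p_slot
  } else {
    tog <- logical(total)
    for (d in seq_len(nday)) {
      idx <- ((d - 1) * nsl + 1):(d * nsl)
      pd <- cfg$together_prob_by_day[as.character(days[d])]
      if (pd >= 1) { tog[idx] <- TRUE; next }
      if (pd <= 0) { tog[idx] <- FALSE; next }
      n1 <- stats::rbinom(1, nsl, pd)
      k <- stats::rpois(1, cfg$separation_rate_by_day[as.character(days[d])])
      tog[idx] <- arrange_day_states(nsl, n1, k)
    }
  }

  # apart bouts and scripted movers
  r <- rle(tog)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  bout_start <- rep(NA_integer_, total)  # first slot of the apart bout
  mover_f <- rep(NA, total)              # TRUE = female moves
  sep_rows <- list()
  for (b in seq_along(r$values)) {
    if (r$values[b]) next
    s <- starts[b]
    fem <- stats::runif(1) < cfg$mover_female_prob_by_day[dchr[s]]
    idx <- s:ends[b]
    bout_start[idx] <- s
    mover_f[idx] <- fem
  }

  # --- per-slot draws for nest attendance ---
  pair_nest <- stats::runif(total) < att_m      # drives both when together
  m_nest <- stats::runif(total) < att_m         # own draw when apart
  f_nest <- stats::runif(total) < att_f

  # --- movement ---
  step_tog <- cfg$step_speed_together * cfg$fix_interval_min
  step_ap <- cfg$step_speed_apart * cfg$fix_interval_min
  cs <- sample.int(nrow(sites), 1)
  cpos <- sites[cs, ] + rnorm2(6); chead <- stats::runif(1, 0, 2 * pi)
  mv_pos <- cpos; mv_head <- 0; mv_anchor <- cpos; mv_site <- cs
  posM <- matrix(0, total, 2); posF <- matrix(0, total, 2)
  flight_len <- rep(NA_real_, total)

  nearest_site <- function(q) which.min((sites[, 1] - q[1])^2 + (sites[, 2] - q[2])^2)
  pick_site <- function(exclude) {
    cand <- setdiff(seq_len(nrow(sites)), exclude)
    if (!length(cand)) cand <- seq_len(nrow(sites))
    cand[sample.int(length(cand), 1)]
  }

  prevM <- cpos + rnorm2(cfg$within_pair_scatter_sd)
  prevF <- cpos + rnorm2(cfg$within_pair_scatter_sd)
  for (t in seq_len(total)) {
    new_bout <- !tog[t] && !is.na(bout_start[t]) && bout_start[t] == t
    # centroid process (frozen in the slot a separation starts)
    if (!new_bout) {
      if (stats::runif(1) < cfg$site_switch_prob) {
        excl <- cs
        if (!tog[t]) excl <- c(excl, nearest_site(mv_pos))
        cs <- pick_site(excl)
        cpos <- sites[cs, ] + rnorm2(6)
        chead <- stats::runif(1, 0, 2 * pi)
      } else {
        st <- crw_step(cpos, chead, sites[cs, ], cfg$site_radius, step_tog)
        cpos <- st$pos; chead <- st$heading
      }
    }
    if (tog[t]) {
      base <- if (pair_nest[t]) nest_xy else cpos
      sdv <- if (pair_nest[t]) cfg$nest_scatter_sd else cfg$within_pair_scatter_sd
      pm <- base + rnorm2(sdv); pf <- base + rnorm2(sdv)
    } else {
      fem <- mover_f[t]
      if (new_bout) {
        # scripted flight by the mover; partner holds position. Flights are
        # floored at 120 m: at a 10-min fix interval a shorter displacement is
        # not distinguishable from joint movement, so a scripted separation
        # always exceeds the dynamic together threshold.
        d <- max(120, stats::rlnorm(1, cfg$separation_dist_logmean,
                                    cfg$separation_dist_logsd))
        ang <- stats::runif(1, 0, 2 * pi)
        from <- if (fem) prevF else prevM
        to <- from + d * c(cos(ang), sin(ang))
        half <- cfg$plot_size / 2 - 20
        if (any(abs(to) > half)) to <- from - d * c(cos(ang), sin(ang))
        to <- pmin(half, pmax(-half, to))
        mv_pos <- to; mv_anchor <- to; mv_head <- stats::runif(1, 0, 2 * pi)
        mv_site <- nearest_site(to)
        flight_len[t] <- sqrt(sum((to - from)^2))
        partner_prev <- if (fem) prevM else prevF
        ppos <- partner_prev + rnorm2(cfg$within_pair_scatter_sd)
        cpos <- ppos; cs <- nearest_site(ppos) # re-anchor pair frame on the stayer
        if (fem) { pf <- mv_pos; pm <- ppos } else { pm <- mv_pos; pf <- ppos }
      } else {
        # mover wanders around its anchor, occasionally relocating
        if (stats::runif(1) < cfg$site_switch_prob) {
          mv_site <- pick_site(c(mv_site, nearest_site(cpos)))
          mv_anchor <- sites[mv_site, ]
          mv_pos <- mv_anchor + rnorm2(6)
        } else {
          st <- crw_step(mv_pos, mv_head, mv_anchor, max(cfg$site_radius, 40), step_ap)
          mv_pos <- st$pos; mv_head <- st$heading
        }
        # only one member sits on the nest at a time while apart (otherwise
        # the pair would de facto be together); the male's draw has priority
        male_at <- m_nest[t]
        female_at <- f_nest[t] && !male_at
        own_nest <- if (fem) female_at else male_at
        mp <- if (own_nest) nest_xy + rnorm2(cfg$nest_scatter_sd) else mv_pos
        partner_nest <- if (fem) male_at else female_at
        pp <- if (partner_nest) nest_xy + rnorm2(cfg$nest_scatter_sd)
              else cpos + rnorm2(cfg$within_pair_scatter_sd)
        # while apart, keep the mover genuinely separated (>= 120 m) from
        # the partner so the apart state has unambiguous geometry
        dmp <- sqrt(sum((mp - pp)^2))
        if (!own_nest && dmp < 120)
          mp <- pp + (mp - pp) * if (dmp > 1e-9) 120 / dmp else c(120, 0)
        if (fem) { pf <- mp; pm <- pp } else { pm <- mp; pf <- pp }
      }
    }
    posM[t, ] <- pm; posF[t, ] <- pf
    prevM <- pm; prevF <- pf
  }

  at_nest_M <- sqrt((posM[, 1] - nest_xy[1])^2 + (posM[, 2] - nest_xy[2])^2) <= 15
  at_nest_F <- sqrt((posF[, 1] - nest_xy[1])^2 + (posF[, 2] - nest_xy[2])^2) <= 15

  # --- timestamps ---
  base_utc <- as.POSIXct(paste(init_date + day_of), tz = "UTC") + 8 * 3600 +
    rep((seq_len(nsl) - 1) * cfg$fix_interval_min * 60, times = nday)
  # between-member grid offset: Weibull with light tail so that cross-slot
  # mismatches in the pairing step stay rare (gap median ~ pair_gap_median_min)
  delta <- stats::rweibull(1, shape = 3.5,
                           scale = 1.115 * cfg$pair_gap_median_min) *
    sample(c(-1, 1), 1)
  offs <- stats::rnorm(1, 0, 1) + c(0, delta)
  tM <- base_utc + 60 * (offs[1] + stats::runif(total, -cfg$fix_jitter_min, cfg$fix_jitter_min))
  tF <- base_utc + 60 * (offs[2] + stats::runif(total, -cfg$fix_jitter_min, cfg$fix_jitter_min))

  noiseM <- matrix(stats::rnorm(2 * total, 0, cfg$gps_noise_sd), ncol = 2)
  noiseF <- matrix(stats::rnorm(2 * total, 0, cfg$gps_noise_sd), ncol = 2)

  ids <- c(sprintf("M%03d", p), sprintf("F%03d", p))
  fixes <- data.table::data.table(
    pair_id = pair_id,
    id = rep(ids, each = total),
    sex = rep(c("M", "F"), each = total),
    slot = rep(seq_len(total), 2),
    day_rel = rep(day_of, 2),
    timestamp = c(tM, tF),
    x = c(posM[, 1] + noiseM[, 1], posF[, 1] + noiseF[, 1]),
    y = c(posM[, 2] + noiseM[, 2], posF[, 2] + noiseF[, 2]),
    at_nest = c(at_nest_M, at_nest_F),
    corrupt_rule = NA_character_)

  slots <- data.table::data.table(
    pair_id = pair_id, slot = seq_len(total), day_rel = day_of,
    slot_time = base_utc, together = tog)

  sep_idx <- which(!is.na(bout_start) & bout_start == seq_len(total) &
                     c(FALSE, tog[-total]))
  separations <- data.table::data.table(
    pair_id = pair_id, slot = sep_idx,
    event_time = base_utc[sep_idx],
    mover_sex = ifelse(mover_f[sep_idx], "F", "M"),
    mover_id = ifelse(mover_f[sep_idx], ids[2], ids[1]),
    flight_m = flight_len[sep_idx],
    day_rel = day_of[sep_idx])

  list(fixes = fixes, slots = slots,
       truth_fixes = NULL, separations = separations)
}

# Inject implausible positions per cfg$outlier_rates; the fixes table carries
# planar x/y at this point. Corruption slots are kept >= 3 fixes apart within
# an individual so each planted fix is caught by exactly its own rule.
plant_outliers <- function(fixes, cfg) {
  rates <- cfg$outlier_rates
  if (all(rates <= 0)) return(fixes)
  data.table::setorder(fixes, id, timestamp)
  fixes[, row_in_track := seq_len(.N), by = id]
  fixes[, n_track := .N, by = id]
  n <- nrow(fixes)
  u <- stats::runif(n)
  rule <- rep(NA_character_, n)
  cum <- cumsum(c(far = rates[["far"]], speed = rates[["speed"]],
                  single = rates[["single"]]))
  rule[u < cum[1]] <- "far"
  rule[u >= cum[1] & u < cum[2]] <- "speed"
  rule[u >= cum[2] & u < cum[3]] <- "single"
  cand <- which(!is.na(rule) & fixes$row_in_track > 1 &
                  fixes$row_in_track < fixes$n_track)
  keep <- integer(0)
  last_by_id <- list()
  for (i in cand) {
    id <- fixes$id[i]
    prev <- last_by_id[[id]]
    if (!is.null(prev) && fixes$row_in_track[i] - prev < 3) next
    if (rule[i] == "single") {
      a <- i - 1L; c <- i + 1L
      if (planar_dist(fixes$x[a], fixes$y[a], fixes$x[c], fixes$y[c]) > 60) next
    }
    keep <- c(keep, i)
    last_by_id[[id]] <- fixes$row_in_track[i]
  }
  for (i in keep) {
    ang <- stats::runif(1, 0, 2 * pi)
    d <- switch(rule[i],
                far = stats::runif(1, 550e3, 900e3),
                speed = stats::runif(1, 25e3, 60e3),
                single = stats::runif(1, 3e3, 8e3))
    data.table::set(fixes, i, "x", fixes$x[i] + d * cos(ang))
    data.table::set(fixes, i, "y", fixes$y[i] + d * sin(ang))
    data.table::set(fixes, i, "corrupt_rule", rule[i])
  }
  fixes[, c("row_in_track", "n_track") := NULL]
  fixes
}

#' Hand-built miniature fixtures with known classifier output
#'
#' Returns a tiny track pair (or single track) plus the exact expected result
#' of the relevant classifier, for frozen regression tests.
#'
#' @param name One of `"single-outlier"`, `"last-fix-separation"`,
#'   `"all-close"`, `"three-rule-together"`.
#' @return List with `fixes` (data.table: id, sex, timestamp, lon, lat) and
#'   `expected` (named list; see each fixture's documentation in the source).
#' @export
make_toy_fixture <- function(name) {
  center <- study_site_center()
  t0 <- as.POSIXct("2019-06-10 12:00:00", tz = "UTC")
  mk <- function(id, sex, times, x, y) {
    ll <- aeqd_unproject(x, y, center)
    data.table::data.table(id = id, sex = sex, timestamp = times,
                           lon = ll$lon, lat = ll$lat)
  }
  switch(name,
    "single-outlier" = {
      fx <- mk("M001", "M", t0 + c(0, 600, 1200), c(0, 3000, 50), c(0, 0, 0))
      list(fixes = fx, expected = list(removed_idx = 2L))
    },
    "last-fix-separation" = {
      tm <- t0 + c(0, 600, 1200)
      m <- mk("M001", "M", tm, c(0, 10, 20), c(0, 0, 0))
      f <- mk("F001", "F", tm, c(10, 22, 100), c(0, 0, 0))
      list(fixes = rbind(m, f), expected = list(together = c(TRUE, TRUE, FALSE)))
    },
    "all-close" = {
      tm <- t0 + 600 * (0:3)
      m <- mk("M001", "M", tm, c(0, 5, 10, 15), c(0, 0, 0, 0))
      f <- mk("F001", "F", tm, c(5, 10, 15, 20), c(0, 0, 0, 0))
      list(fixes = rbind(m, f), expected = list(together = rep(TRUE, 4)))
    },
    "three-rule-together" = {
      # distances 40 and 45 m with 5-min gaps: below the dynamic threshold
      # (30 + 12 * 5 = 90 m) but never below the 30 m fixed threshold
      tm_m <- t0 + c(0, 600)
      tm_f <- t0 + c(300, 900)
      m <- mk("M001", "M", tm_m, c(0, 0), c(0, 0))
      f <- mk("F001", "F", tm_f, c(40, 45), c(0, 0))
      list(fixes = rbind(m, f), expected = list(together = c(FALSE, FALSE)))
    },
    stop("unknown fixture name: ", name, call. = FALSE)
  )
}

#' Simulate nest-evidence records from known clutch initiation dates
#'
#' Produces one evidence row per nest, assigning each nest an evidence channel
#' (found during laying, hatch date, flotation, manual override, or male visit
#' onset) so that [estimate_clutch_initiation()] can be scored against the
#' generator's true dates.
#'
#' @param nests Nest table from [simulate_pair_tracks()].
#' @param method_probs Probabilities of evidence channels 1-5 (recycled and
#'   normalised); defaults mirror a typical field mix.
#' @param flotation_noise_sd SD (days) of the flotation ageing error.
#' @param seed Integer seed.
#' @return data.table of evidence rows (see [estimate_clutch_initiation()]).
#' @export
simulate_nest_evidence <- function(nests,
                                   method_probs = c(0.41, 0.34, 0.12, 0.10, 0.03),
                                   flotation_noise_sd = 1,
                                   seed = 1L) {
  set.seed(seed)
  n <- nrow(nests)
  meth <- sample.int(5, n, replace = TRUE, prob = method_probs / sum(method_probs))
  init <- nests$clutch_init_date
  cs <- nests$clutch_size
  ev <- data.table::data.table(
    nest_id = nests$nest_id,
    discovery_date = as.Date(NA), n_eggs_at_discovery = NA_integer_,
    found_during_laying = FALSE, hatch_date = as.Date(NA),
    hatch_context = NA_character_, flotation_age_days = NA_real_,
    clutch_size = cs, manual_override_date = as.Date(NA),
    male_visit_onset = as.Date(NA), true_method = meth)
  for (i in seq_len(n)) {
    if (meth[i] == 1) {
      k <- sample.int(cs[i], 1)
      ev$discovery_date[i] <- init[i] + (k - 1)
      ev$n_eggs_at_discovery[i] <- k
      ev$found_during_laying[i] <- TRUE
    } else if (meth[i] == 2) {
      ctx <- sample(c("incubator", "natural"), 1)
      inc <- if (ctx == "incubator") 17 else 19
      ev$hatch_date[i] <- init[i] + (cs[i] - 1) + inc
      ev$hatch_context[i] <- ctx
    } else if (meth[i] == 3) {
      disc <- init[i] + (cs[i] - 1) + sample(2:12, 1)
      ev$discovery_date[i] <- disc
      ev$n_eggs_at_discovery[i] <- cs[i]
      ev$flotation_age_days[i] <- as.numeric(disc - init[i]) - (cs[i] - 1) +
        stats::rnorm(1, 0, flotation_noise_sd)
    } else if (meth[i] == 4) {
      ev$manual_override_date[i] <- init[i]
      ev$hatch_date[i] <- init[i] + (cs[i] - 1) + 17 + sample(-2:2, 1)
      ev$hatch_context[i] <- "incubator"
    } else {
      ev$male_visit_onset[i] <- init[i] - sample(0:3, 1)
    }
  }
  ev
}
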