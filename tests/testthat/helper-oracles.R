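# Independent reference implementations and small constructors used across the
# test files. The oracles deliberately use the dumbest possible algorithm so
# they stay independent of the package's vectorised code paths.

# Build a minimal paired-observation table from distances and gaps: member a
# sits at the origin, member b at (dist, 0); slots are 10 min apart.
mk_obs <- function(dists, gaps = 0,
                   t0 = as.POSIXct("2019-06-10 12:00:00", tz = "UTC")) {
  n <- length(dists)
  gaps <- rep_len(gaps, n)
  data.table::data.table(
    t_a = t0 + 600 * (seq_len(n) - 1),
    t_b = t0 + 600 * (seq_len(n) - 1) + 60 * gaps,
    slot_time = t0 + 600 * (seq_len(n) - 1) + 30 * gaps,
    gap_min = gaps,
    x_a = 0, y_a = 0, x_b = dists, y_b = 0, dist_m = dists)
}

# Literal three-rule reference: scan maximal candidate runs with a while loop
# and apply rules 2 and 3 verbatim.
oracle_together <- function(dist, gap, p = together_params()) {
  n <- length(dist)
  cand <- dist < (p$base_threshold + p$gap_allowance_rate * gap)
  lab <- rep(FALSE, n)
  i <- 1
  while (i <= n) {
    if (!cand[i]) { i <- i + 1; next }
    j <- i
    while (j < n && cand[j + 1]) j <- j + 1
    if (any(dist[i:j] < p$fixed_threshold)) {
      lab[i:j] <- TRUE
      if (dist[j] > p$fixed_threshold) lab[j] <- FALSE
    }
    i <- j + 1
  }
  lab
}

# Random dyad track in distance/gap space exercising all three rules.
random_track <- function(n) {
  state <- sample(c("near", "mid", "far"), n, replace = TRUE,
                  prob = c(0.45, 0.25, 0.3))
  dist <- ifelse(state == "near", runif(n, 0, 30),
                 ifelse(state == "mid", runif(n, 30, 120), runif(n, 120, 2000)))
  gaps <- runif(n, 0, 9.9)
  list(dist = dist, gaps = gaps)
}

# Maximum implied speed (m/s) over consecutive fixes of one track.
max_leg_speed <- function(fixes) {
  if (nrow(fixes) < 2) return(0)
  d <- pairguard::gc_dist_m(fixes$lon[-nrow(fixes)], fixes$lat[-nrow(fixes)],
                            fixes$lon[-1], fixes$lat[-1])
  dt <- diff(as.numeric(fixes$timestamp))
  max(d / dt)
}

# Gauss-Hermite nodes/weights (weight exp(-x^2)) via the Golub-Welsch
# eigendecomposition of the Jacobi matrix.
gh_nodes <- function(k) {
  i <- seq_len(k - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

dbetabinom_log <- function(y, n, mu, phi) {
  a <- mu * phi
  b <- (1 - mu) * phi
  lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b)
}

# Marginal log-likelihood of a random-intercept beta-binomial model by
# adaptive Gauss-Hermite quadrature (k nodes), evaluated at given parameters.
agq_betabinom_loglik <- function(y, n, X, group, beta, sd_re, phi, k = 21) {
  gh <- gh_nodes(k)
  eta0 <- as.numeric(X %*% beta)
  ll <- 0
  for (g in unique(group)) {
    idx <- group == g
    f <- function(b)
      sum(dbetabinom_log(y[idx], n[idx], stats::plogis(eta0[idx] + b), phi)) +
        stats::dnorm(b, 0, sd_re, log = TRUE)
    opt <- stats::optimize(f, interval = c(-8, 8) * sd_re, maximum = TRUE)
    mode <- opt$maximum
    h <- 1e-4 * max(1, abs(mode))
    d2 <- (f(mode + h) - 2 * f(mode) + f(mode - h)) / h^2
    s <- sqrt(-1 / d2)
    z <- mode + sqrt(2) * s * gh$x
    vals <- vapply(z, f, numeric(1))
    ll <- ll + log(sum(gh$w * exp(gh$x^2) * exp(vals - opt$objective)) *
                     sqrt(2) * s) + opt$objective
  }
  ll
}

# One small simulated season shared by several test files (kept small: the
# full-size run lives in the acceptance tests).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_pair_tracks(sim_config(n_pairs = 8, rng_seed = 99))
    cache
  }
})
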