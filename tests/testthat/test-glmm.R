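test_that("gaussian fit without random effects matches ordinary least squares", {
  set.seed(31)
  d <- data.frame(y = rnorm(80), x = runif(80), nest_id = "n1", day_rel = 0)
  fit <- fit_glmm(d, model_spec("gaussian", "y", "x", random = "none"))
  ols <- lm(y ~ x, data = d)
  # agreement is limited by the iterative optimiser's convergence tolerance
  expect_equal(unname(fit$coef$estimate), unname(coef(ols)), tolerance = 1e-5)
})

test_that("binomial fit reduces to the contingency-table log odds ratio", {
  d <- data.frame(succ = c(20L, 50L), tot = c(100L, 100L), x = c(0, 1),
                  nest_id = c("n1", "n2"), day_rel = 0)
  fit <- fit_glmm(d, model_spec("binomial",
                                c(successes = "succ", totals = "tot"),
                                "x", random = "none"))
  log_or <- log((50 / 50) / (20 / 80))
  expect_equal(fit$coef$estimate[fit$coef$term == "x"], log_or,
               tolerance = 1e-6)
})

test_that("beta-binomial at the binomial limit agrees with the binomial fit", {
  set.seed(32)
  n <- 60
  d <- data.frame(day_rel = rep(0:5, 10),
                  nest_id = rep(sprintf("n%d", 1:10), each = 6))
  mu <- plogis(1 - 0.4 * d$day_rel)
  d$tot <- 144L
  d$succ <- rbinom(n, d$tot, mu) # pure binomial data
  sp <- model_spec("beta_binomial", c(successes = "succ", totals = "tot"),
                   "day_rel", random = "none")
  fb <- fit_glmm(d, sp)
  sp$family <- "binomial"
  fg <- fit_glmm(d, sp)
  expect_equal(fb$coef$estimate, fg$coef$estimate,
               tolerance = 2 * max(fg$coef$se))
})

test_that("quadratic terms are dropped only when nonsignificant", {
  set.seed(33)
  d <- data.frame(x = runif(300, -2, 2), nest_id = "n1")
  d$day_rel <- 0
  d$y <- 1 + 0.5 * d$x + rnorm(300, 0, 0.5)
  sel <- select_quadratic(d, model_spec("gaussian", "y", c("x", "I(x^2)"),
                                        random = "none"))
  expect_identical(sel$dropped, "I(x^2)")
  expect_false("I(x^2)" %in% sel$fit$coef$term)
  d$y2 <- 1 + 0.5 * d$x - 0.8 * d$x^2 + rnorm(300, 0, 0.5)
  sel2 <- select_quadratic(d, model_spec("gaussian", "y2", c("x", "I(x^2)"),
                                         random = "none"))
  expect_length(sel2$dropped, 0)
  expect_true("I(x^2)" %in% sel2$fit$coef$term)
  # no quadratic candidates: spec unchanged
  sel3 <- select_quadratic(d, model_spec("gaussian", "y", "x", random = "none"))
  expect_length(sel3$dropped, 0)
})

test_that("diurnal terms lie on the unit circle", {
  # local midnight is 08:00 UTC at UTC-8
  t <- as.POSIXct("2019-06-10 08:00:00", tz = "UTC") + 3600 * c(0, 6, 12, 18)
  d <- diurnal_terms(t)
  expect_equal(d$sin_time, c(0, 1, 0, -1), tolerance = 1e-12)
  expect_equal(d$cos_time, c(1, 0, -1, 0), tolerance = 1e-12)
  expect_equal(d$sin_time^2 + d$cos_time^2, rep(1, 4))
})

test_that("marginal means are the inverse-logit of the linear predictor", {
  d <- data.frame(succ = c(30L, 40L, 50L, 60L), tot = 100L,
                  day_rel = c(0, 1, 2, 3), nest_id = "n1")
  fit <- fit_glmm(d, model_spec("binomial",
                                c(successes = "succ", totals = "tot"),
                                "day_rel", random = "none"))
  mm <- marginal_mean(fit, data.frame(day_rel = c(0, 3)))
  b <- fit$coef$estimate
  expect_equal(mm$estimate, plogis(b[1] + b[2] * c(0, 3)), tolerance = 1e-8)
  expect_true(all(mm$estimate > 0 & mm$estimate < 1))
  expect_true(all(is.finite(mm$se)))
  # delta method: se on response scale = mu(1-mu) * se(eta)
  expect_equal(mm$se, mm$estimate * (1 - mm$estimate) * mm$eta_se)
})

test_that("enriching a model never lowers the maximised likelihood", {
  set.seed(34)
  d <- data.frame(x = runif(120), z = runif(120), nest_id = "n1", day_rel = 0)
  d$y <- 1 + d$x + rnorm(120)
  f1 <- fit_glmm(d, model_spec("gaussian", "y", "x", random = "none"))
  f2 <- fit_glmm(d, model_spec("gaussian", "y", c("x", "z"), random = "none"))
  expect_gte(f2$logLik, f1$logLik - 1e-6)
})

test_that("random-effect fallback ladder reduces deterministically", {
  # nest variance is zero by construction -> slope structure is singular
  set.seed(35)
  d <- data.frame(day_rel = rep(0:4, 8),
                  nest_id = rep(sprintf("n%d", 1:8), each = 5))
  d$y <- 2 + 0.3 * d$day_rel + rnorm(40, 0, 0.1)
  expect_message(
    fit <- fit_glmm(d, model_spec("gaussian", "y", "day_rel", random = "slope")),
    "reduced")
  expect_true(fit$random_used %in% c("diag", "intercept", "none"))
  expect_true(fit$converged)
})
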