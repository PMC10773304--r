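# Mixed models for the daily summaries: binomial (binary together, mover
# sex), beta-binomial (daily proportions) and Gaussian (separation distance)
# GLMMs with logit/identity links, nest-level random intercepts and day_rel
# slopes, fitted by Laplace-approximated maximum likelihood (glmmTMB), with a
# deterministic fallback ladder when the random-effect covariance is singular.

#' Model specification
#'
#' @param family `"beta_binomial"`, `"binomial"` or `"gaussian"`.
#' @param response For proportion models, `c(successes = , totals = )` column
#'   names; otherwise a single column name (binary or continuous).
#' @param fixed_terms Character vector of fixed-effect terms, e.g.
#'   `c("day_rel", "I(day_rel^2)", "std_init_date", "sin_time", "cos_time")`.
#' @param random `"slope"` (random intercept + day_rel slope by `group`,
#'   unstructured 2x2 covariance), `"intercept"`, or `"none"`.
#' @param group Grouping factor column (default `"nest_id"`).
#' @param window Optional integer vector of `day_rel` values to restrict the
#'   data to before fitting.
#' @return List of class `pg_model_spec`.
#' @export
model_spec <- function(family = c("beta_binomial", "binomial", "gaussian"),
                       response, fixed_terms = "day_rel",
                       random = c("slope", "intercept", "none"),
                       group = "nest_id", window = NULL) {
  family <- match.arg(family)
  random <- match.arg(random)
  if (family == "beta_binomial" &&
      !all(c("successes", "totals") %in% names(response)))
    stop("beta_binomial needs response = c(successes=, totals=)", call. = FALSE)
  structure(list(family = family, response = response,
                 fixed_terms = fixed_terms, random = random, group = group,
                 window = window),
            class = "pg_model_spec")
}

spec_formula <- function(spec, random = spec$random) {
  lhs <- if (!is.null(names(spec$response)) &&
             all(c("successes", "totals") %in% names(spec$response)))
    sprintf("cbind(%s, %s - %s)", spec$response[["successes"]],
            spec$response[["totals"]], spec$response[["successes"]])
  else spec$response
  rhs <- paste(c(spec$fixed_terms, "1"), collapse = " + ")
  re <- switch(random,
               slope = sprintf("(1 + day_rel | %s)", spec$group),
               intercept = sprintf("(1 | %s)", spec$group),
               none = NULL)
  stats::as.formula(paste(lhs, "~", paste(c(rhs, re), collapse = " + ")))
}

spec_family <- function(spec) {
  switch(spec$family,
         beta_binomial = glmmTMB::betabinomial(link = "logit"),
         binomial = stats::binomial(link = "logit"),
         gaussian = stats::gaussian())
}

# A fit is usable when the fixed-effect standard errors and a population-level
# prediction SE are finite. (pdHess alone is too strict: a beta-binomial
# dispersion at the binomial boundary flattens the Hessian without affecting
# the fixed-effect inference this package reports.)
fit_ok <- function(m, probe = NULL) {
  if (is.null(m)) return(FALSE)
  co <- tryCatch(summary(m)$coefficients$cond, error = function(e) NULL)
  if (is.null(co) || anyNA(co[, "Std. Error"]) ||
      !all(is.finite(co[, "Std. Error"]))) return(FALSE)
  if (!is.null(probe)) {
    pr <- tryCatch(
      suppressWarnings(stats::predict(m, newdata = probe, type = "link",
                                      se.fit = TRUE, re.form = NA,
                                      allow.new.levels = TRUE)),
      error = function(e) NULL)
    if (is.null(pr) || !all(is.finite(pr$se.fit))) return(FALSE)
  }
  TRUE
}

#' Fit a generalized linear mixed model
#'
#' Laplace-approximated maximum marginal likelihood via glmmTMB. When the
#' requested random-slope covariance cannot be estimated (non-positive-definite
#' Hessian or undefined standard errors) the fit falls back deterministically:
#' unstructured slope -> diagonal slope -> random intercept -> no random
#' effects, with each step recorded.
#'
#' @param data Data frame (or data.table) of model rows.
#' @param spec A [model_spec()] object.
#' @return Object of class `pg_fit`: list with `model` (the glmmTMB fit),
#'   `coef` (fixed-effect table: estimate, SE, Wald z and p), `formula`,
#'   `spec`, `random_used`, `converged`, `logLik`, `nobs`.
#' @export
fit_glmm <- function(data, spec) {
  data <- as.data.frame(data)
  if (!is.null(spec$window)) data <- data[data$day_rel %in% spec$window, ]
  if (!nrow(data)) stop("no data in the model window", call. = FALSE)
  ladder <- switch(spec$random,
                   slope = c("slope", "diag", "intercept", "none"),
                   intercept = c("intercept", "none"),
                   none = "none")
  probe <- data[1, , drop = FALSE]
  fit <- NULL; used <- NULL; ok <- FALSE
  for (lev in ladder) {
    form <- if (lev == "diag")
      stats::as.formula(sub(sprintf("\\(1 \\+ day_rel \\| %s\\)", spec$group),
                            sprintf("diag(1 + day_rel | %s)", spec$group),
                            deparse1(spec_formula(spec, "slope"))))
    else spec_formula(spec, lev)
    m <- tryCatch(
      suppressWarnings(glmmTMB::glmmTMB(form, data = data,
                                        family = spec_family(spec))),
      error = function(e) NULL)
    if (fit_ok(m, probe)) { fit <- m; used <- lev; ok <- TRUE; break }
    if (is.null(fit) && !is.null(m)) { fit <- m; used <- lev } # keep best-effort
  }
  if (is.null(fit)) stop("model could not be fitted", call. = FALSE)
  if (!ok) warning("no random-effect structure gave a well-behaved fit; ",
                   "returning best effort with diagnostics")
  if (used != ladder[1])
    message("random-effect structure reduced to '", used, "'")
  co <- summary(fit)$coefficients$cond
  coef_tab <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                         z = co[, 3], p = co[, 4], row.names = NULL)
  structure(list(model = fit, coef = coef_tab, formula = stats::formula(fit),
                 spec = spec, random_used = used, converged = ok,
                 opt_code = fit$fit$convergence,
                 logLik = as.numeric(stats::logLik(fit)), nobs = nrow(data)),
            class = "pg_fit")
}

#' @export
print.pg_fit <- function(x, ...) {
  cat(sprintf("pairguard %s GLMM (%s random effects%s), logLik %.2f, n = %d\n",
              x$spec$family, x$random_used,
              if (x$converged) "" else "; NOT CONVERGED", x$logLik, x$nobs))
  print(x$coef, digits = 3)
  invisible(x)
}

#' Drop nonsignificant quadratic terms
#'
#' Fits the model with its quadratic candidate terms (`I(term^2)`), removes
#' every quadratic term whose Wald p-value is >= `alpha`, and refits once.
#'
#' @param data Model data.
#' @param spec A [model_spec()] containing quadratic candidates.
#' @param alpha Significance threshold (default 0.05).
#' @return List: `fit` (final [fit_glmm()] result), `spec` (final spec),
#'   `dropped` (character vector of removed terms).
#' @export
select_quadratic <- function(data, spec, alpha = 0.05) {
  quad <- grep("^I\\(.+\\^2\\)$", spec$fixed_terms, value = TRUE)
  if (!length(quad)) return(list(fit = fit_glmm(data, spec), spec = spec,
                                 dropped = character(0)))
  fit0 <- fit_glmm(data, spec)
  pvals <- fit0$coef$p[match(quad, fit0$coef$term)]
  drop <- quad[is.na(pvals) | pvals >= alpha]
  if (!length(drop)) return(list(fit = fit0, spec = spec, dropped = character(0)))
  spec2 <- spec
  spec2$fixed_terms <- setdiff(spec$fixed_terms, drop)
  list(fit = fit_glmm(data, spec2), spec = spec2, dropped = drop)
}

#' Diurnal sine/cosine covariates
#'
#' @param times POSIXct vector (UTC).
#' @param tz_offset_hours Local civil time offset (default -8).
#' @return data.frame with `sin_time`, `cos_time` computed from the local hour
#'   of day h as `sin(2*pi*h/24)`, `cos(2*pi*h/24)`.
#' @export
diurnal_terms <- function(times, tz_offset_hours = -8) {
  loc <- times + tz_offset_hours * 3600
  h <- (as.numeric(loc) %% 86400) / 3600
  data.frame(sin_time = sin(2 * pi * h / 24), cos_time = cos(2 * pi * h / 24))
}

#' Back-transformed marginal means
#'
#' Population-level (random effects at zero) predictions at given covariate
#' values, back-transformed through the link, with delta-method standard
#' errors.
#'
#' @param fit A [fit_glmm()] result.
#' @param newdata Data frame of covariate values (grouping column may be
#'   absent; a placeholder level is used).
#' @return data.frame: `newdata` columns plus `eta, eta_se, estimate, se`.
#' @export
marginal_mean <- function(fit, newdata) {
  newdata <- as.data.frame(newdata)
  g <- fit$spec$group
  if (!g %in% names(newdata)) newdata[[g]] <- NA
  # response placeholders so model.frame can be rebuilt
  rv <- fit$spec$response
  for (v in rv) if (!v %in% names(newdata))
    newdata[[v]] <- if (fit$spec$family == "gaussian") 0 else 1
  pr <- stats::predict(fit$model, newdata = newdata, type = "link",
                       se.fit = TRUE, re.form = NA, allow.new.levels = TRUE)
  eta <- as.numeric(pr$fit); se_eta <- as.numeric(pr$se.fit)
  if (fit$spec$family == "gaussian") {
    est <- eta; se <- se_eta
  } else {
    est <- stats::plogis(eta)
    se <- est * (1 - est) * se_eta
  }
  cbind(newdata, data.frame(eta = eta, eta_se = se_eta,
                            estimate = est, se = se))
}
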