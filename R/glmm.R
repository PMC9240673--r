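#' Fit a binomial logit model with an optional random intercept
#'
#' Fits `Pr(y = 1) = logit^-1(X beta + alpha_group)` with
#' `alpha ~ N(0, sigma^2)` by maximising the marginal likelihood with
#' adaptive Gauss-Hermite quadrature (`quadrature_points` nodes; 1 node is
#' the Laplace approximation used as the fast mode for genome-wide scans).
#' With no grouping column, fewer than two group levels, or
#' `sigma2_zero = TRUE`, the model degenerates to ordinary logistic
#' regression by maximum likelihood. Inference is Wald: `z = beta / se`,
#' `p = 2 * pnorm(-|z|)`.
#'
#' @param data Data frame holding the response, fixed-effect covariates and
#'   the grouping column.
#' @param formula Fixed-effects formula, e.g. `raced ~ f_roh + region + sex`.
#'   The response must be 0/1.
#' @param group Optional name of the column giving the random-intercept
#'   grouping factor (e.g. `"birth_year"`).
#' @param quadrature_points Number of adaptive Gauss-Hermite nodes
#'   (default 15; 1 = Laplace).
#' @param sigma2_zero Force the random-intercept variance to zero (plain
#'   logistic fit).
#' @return An object of class `roh_glmm` with elements `beta`, `se`, `z`,
#'   `p`, `sigma2_group`, `loglik`, `converged`, `n_quadrature` and the
#'   underlying `fit`. Use [tidy()] / [glance()] to extract tables.
#' @export
fit_binomial_glmm <- function(data, formula, group = NULL,
                              quadrature_points = 15, sigma2_zero = FALSE) {
  data <- as.data.frame(data)
  response_name <- all.vars(formula)[1]
  y <- data[[response_name]]
  if (!all(y %in% c(0, 1))) abort("response must be binary 0/1")

  mm <- model.matrix(formula, data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    abort(paste0("design is rank deficient; aliased column(s): ",
                 paste(aliased, collapse = ", ")))
  }

  use_ranef <- !sigma2_zero && !is.null(group) &&
    length(unique(data[[group]])) >= 2

  converged <- TRUE
  if (use_ranef) {
    data$.group <- factor(data[[group]])
    full <- as.formula(paste(deparse(formula, width.cutoff = 500),
                             "+ (1 | .group)"))
    fit <- withCallingHandlers(
      lme4::glmer(full, data = data, family = binomial("logit"),
                  nAGQ = quadrature_points),
      warning = function(w) {
        if (grepl("converge|Hessian|gradient", conditionMessage(w),
                  ignore.case = TRUE)) {
          converged <<- FALSE
        }
        invokeRestart("muffleWarning")
      })
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    sigma2 <- as.numeric(lme4::VarCorr(fit)$.group[1, 1])
    ll <- as.numeric(logLik(fit))
    nq <- quadrature_points
  } else {
    fit <- withCallingHandlers(
      glm(formula, data = data, family = binomial("logit")),
      warning = function(w) {
        if (grepl("fitted probabilities|converge", conditionMessage(w))) {
          converged <<- FALSE
        }
        invokeRestart("muffleWarning")
      })
    if (!fit$converged) converged <- FALSE
    beta <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    sigma2 <- 0
    ll <- as.numeric(logLik(fit))
    nq <- 0L
  }

  big <- abs(beta) > 15
  if (any(big) && !converged) {
    abort(paste0("apparent complete separation; runaway coefficient(s): ",
                 paste(names(beta)[big], collapse = ", ")))
  }

  z <- beta / se
  structure(
    list(beta = beta, se = se, z = z, p = 2 * pnorm(-abs(z)),
         sigma2_group = sigma2, loglik = ll, converged = converged,
         n_quadrature = nq, fit = fit, formula = formula,
         nobs = nrow(data),
         xlevels = stats::.getXlevels(stats::terms(formula, data = data),
                                      data)),
    class = "roh_glmm")
}

#' @export
print.roh_glmm <- function(x, ...) {
  cat(sprintf(
    "<roh_glmm> %d obs, random-intercept variance %.4g, logLik %.2f%s\n",
    x$nobs, x$sigma2_group, x$loglik,
    if (x$converged) "" else " [NOT CONVERGED]"))
  print(tidy(x))
  invisible(x)
}

#' Tidy a fitted binomial (mixed) model
#'
#' @param x An `roh_glmm` fit.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`
#'   (Wald z) and `p.value`.
#' @method tidy roh_glmm
#' @export
tidy.roh_glmm <- function(x, ...) {
  tibble(term = names(x$beta), estimate = unname(x$beta),
         std.error = unname(x$se), statistic = unname(x$z),
         p.value = unname(x$p))
}

#' One-row model summary
#'
#' @param x An `roh_glmm` fit.
#' @param ... Unused.
#' @return Tibble with `nobs`, `sigma2_group`, `logLik`, `converged`,
#'   `n_quadrature`.
#' @method glance roh_glmm
#' @export
glance.roh_glmm <- function(x, ...) {
  tibble(nobs = x$nobs, sigma2_group = x$sigma2_group, logLik = x$loglik,
         converged = x$converged, n_quadrature = x$n_quadrature)
}

#' Predicted probabilities with Wald confidence intervals
#'
#' Probabilities are computed at the fixed effects with the random intercept
#' at zero: `p = logit^-1(x' beta)` with a 95% Wald interval on the linear
#' predictor back-transformed through the inverse logit.
#'
#' @param fit A converged `roh_glmm`.
#' @param new_data Data frame of covariate profiles (same columns as the
#'   fixed effects).
#' @param level Confidence level (default 0.95).
#' @return `new_data` with columns `p_hat`, `lwr`, `upr` appended.
#' @export
predict_probability <- function(fit, new_data, level = 0.95) {
  stopifnot(inherits(fit, "roh_glmm"))
  if (!fit$converged) abort("refusing to predict from an unconverged fit")
  new_data <- as.data.frame(new_data)
  tt <- stats::delete.response(stats::terms(fit$formula))
  X <- model.matrix(tt, new_data, xlev = fit$xlevels)
  if (!identical(colnames(X), names(fit$beta))) {
    abort("new_data columns do not match the fitted design")
  }
  V <- as.matrix(vcov(fit$fit))
  eta <- drop(X %*% fit$beta)
  se_eta <- sqrt(rowSums((X %*% V) * X))
  zq <- qnorm(1 - (1 - level) / 2)
  out <- as_tibble(new_data)
  out$p_hat <- unname(plogis(eta))
  out$lwr <- unname(plogis(eta - zq * se_eta))
  out$upr <- unname(plogis(eta + zq * se_eta))
  out
}

#' Percent change in odds for a covariate shift
#'
#' Converts a log odds ratio to the percent change in odds implied by a
#' shift `delta` in the covariate: `100 * (exp(log_or * delta) - 1)`. A log
#' odds ratio of -5.75 per unit F_ROH with `delta = 0.10` gives a 44%
#' decrease in the odds.
#'
#' @param log_or Log odds ratio per unit covariate.
#' @param delta Covariate shift.
#' @param digits Rounding applied to the percentage (default 0, integer
#'   percent; use `NULL` to skip rounding).
#' @return Percent change in odds.
#' @export
odds_change <- function(log_or, delta, digits = 0) {
  pct <- 100 * (exp(log_or * delta) - 1)
  if (is.null(digits)) pct else round(pct, digits)
}
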