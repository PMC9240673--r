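#' Assign raced/unraced status from race records
#'
#' A sample is `raced` if it has at least one recorded race start before
#' `cutoff_age` years old, and `unraced` otherwise (including samples with
#' no records at all). Race counts are taken from an `n_races` column when
#' present, otherwise counted as the number of qualifying starts.
#'
#' @param race_records Tibble with `id` and `age_at_first_start` (one row
#'   per start, or one row per sample), optionally `n_races`.
#' @param sample_ids All sample ids in the cohort; ids without records are
#'   returned as unraced.
#' @param cutoff_age Age cutoff in years (default 5; starts strictly before
#'   this age count).
#' @return Tibble: `sample_id`, `raced` (0/1), `n_races` (`NA` when
#'   unraced), `age_at_first_start` (earliest start age, `NA` if none).
#' @export
assign_race_status <- function(race_records, sample_ids, cutoff_age = 5) {
  race_records <- as_tibble(race_records)
  if (!"age_at_first_start" %in% names(race_records) &&
      all(c("start_date", "birth_year") %in% names(race_records))) {
    # derive age in years from the start date and the Jan 1 of birth year
    race_records$age_at_first_start <- as.numeric(
      as.Date(race_records$start_date) -
        as.Date(paste0(race_records$birth_year, "-01-01"))) / 365.25
  }
  if (nrow(race_records) > 0) {
    if (any(race_records$age_at_first_start < 0, na.rm = TRUE)) {
      abort("negative ages in race records")
    }
    per_id <- race_records |>
      dplyr::group_by(sample_id = as.character(.data$id)) |>
      dplyr::summarise(
        raced = as.integer(any(.data$age_at_first_start < cutoff_age,
                               na.rm = TRUE)),
        n_races = if ("n_races" %in% names(race_records)) {
          max(.data$n_races, na.rm = TRUE)
        } else {
          sum(.data$age_at_first_start < cutoff_age, na.rm = TRUE)
        },
        age_at_first_start = suppressWarnings(
          min(.data$age_at_first_start, na.rm = TRUE)),
        .groups = "drop")
  } else {
    per_id <- tibble(sample_id = character(), raced = integer(),
                     n_races = integer(), age_at_first_start = numeric())
  }
  tibble(sample_id = as.character(sample_ids)) |>
    dplyr::left_join(per_id, by = "sample_id") |>
    tidyr::replace_na(list(raced = 0L)) |>
    dplyr::mutate(
      n_races = ifelse(.data$raced == 1L, .data$n_races, NA_integer_),
      age_at_first_start = ifelse(is.finite(.data$age_at_first_start),
                                  .data$age_at_first_start, NA_real_))
}

# Join phenotypes + inbreeding + covariates into one analysis frame with
# treatment-coded factors (reference levels: sex F, region ANZ).
.assemble_frame <- function(phenotypes, inbreeding, covariates) {
  covariates <- as_tibble(covariates)
  if ("id" %in% names(covariates) && !"sample_id" %in% names(covariates)) {
    covariates <- dplyr::rename(covariates, sample_id = "id")
  }
  covariates$sample_id <- as.character(covariates$sample_id)
  df <- phenotypes |>
    dplyr::inner_join(inbreeding, by = "sample_id") |>
    dplyr::inner_join(covariates, by = "sample_id")
  if ("region" %in% names(df)) {
    df$region <- factor(df$region,
                        levels = union("ANZ", sort(unique(df$region))))
  }
  if ("sex" %in% names(df)) {
    df$sex <- factor(df$sex, levels = union("F", sort(unique(df$sex))))
  }
  df
}

.fit_depression <- function(df, formula, group, quadrature_points, n_min) {
  used <- unique(c(all.vars(formula), group))
  df <- df[stats::complete.cases(df[, used, drop = FALSE]), , drop = FALSE]
  if (nrow(df) < n_min) {
    warn(sprintf("only %d complete cases; fit may be unstable", nrow(df)))
  }
  fit <- fit_binomial_glmm(df, formula, group = group,
                           quadrature_points = quadrature_points)
  fit$data <- df
  fit
}

#' Genome-wide inbreeding depression model for the probability of racing
#'
#' Fits `raced ~ f_roh + region + sex` with a birth-year random intercept.
#' The returned fit carries an `odds_change_10` attribute: the percent
#' change in the odds of racing for a 0.10 increase in F_ROH.
#'
#' @param phenotypes Tibble from [assign_race_status()].
#' @param inbreeding Tibble from [compute_inbreeding()].
#' @param covariates Tibble with `id` (or `sample_id`), `sex`, `region`,
#'   `birth_year`.
#' @param quadrature_points Gauss-Hermite nodes for the random intercept.
#' @return An `roh_glmm` fit.
#' @export
fit_froh_model <- function(phenotypes, inbreeding, covariates,
                           quadrature_points = 15) {
  df <- .assemble_frame(phenotypes, inbreeding, covariates)
  fit <- .fit_depression(df, raced ~ f_roh + region + sex, "birth_year",
                         quadrature_points, n_min = 100)
  attr(fit, "odds_change_10") <- odds_change(fit$beta[["f_roh"]], 0.10)
  fit
}

#' Short- versus long-ROH inbreeding depression model
#'
#' Replaces F_ROH with its two length-partition components, separating the
#' effects of older (short-ROH) and more recent (long-ROH) inbreeding.
#'
#' @inheritParams fit_froh_model
#' @return An `roh_glmm` fit with terms `f_roh_short` and `f_roh_long`.
#' @export
fit_short_long_model <- function(phenotypes, inbreeding, covariates,
                                 quadrature_points = 15) {
  df <- .assemble_frame(phenotypes, inbreeding, covariates)
  r <- suppressWarnings(stats::cor(df$f_roh_short, df$f_roh_long))
  if (!is.na(r) && abs(r) > 0.99) {
    warn(sprintf("f_roh_short and f_roh_long are nearly collinear (r = %.3f)",
                 r))
  }
  .fit_depression(df, raced ~ f_roh_short + f_roh_long + region + sex,
                  "birth_year", quadrature_points, n_min = 100)
}

#' Inbreeding-by-region interaction model
#'
#' Tests whether the F_ROH slope differs between regions via an
#' `f_roh:region` interaction term.
#'
#' @inheritParams fit_froh_model
#' @return An `roh_glmm` fit including the interaction term.
#' @export
fit_interaction_model <- function(phenotypes, inbreeding, covariates,
                                  quadrature_points = 15) {
  df <- .assemble_frame(phenotypes, inbreeding, covariates)
  if (length(unique(df$region[!is.na(df$region)])) < 2) {
    abort("interaction inestimable: only one region present")
  }
  .fit_depression(df, raced ~ f_roh * region + sex, "birth_year",
                  quadrature_points, n_min = 100)
}

#' Race-count model among raced samples
#'
#' Negative binomial regression (log link) of the number of races on F_ROH,
#' region and sex among samples that raced, with birth year as a fixed
#' factor.
#'
#' @inheritParams fit_froh_model
#' @return An object of class `roh_nb` with [tidy()]/[glance()] methods.
#' @export
fit_race_count_model <- function(phenotypes, inbreeding, covariates) {
  df <- .assemble_frame(phenotypes, inbreeding, covariates)
  df <- df[df$raced == 1L & !is.na(df$n_races), , drop = FALSE]
  if (nrow(df) == 0) abort("no raced samples: race-count model undefined")
  df$birth_year <- factor(df$birth_year)
  form <- n_races ~ f_roh + region + sex + birth_year
  degenerate <- FALSE
  fit <- tryCatch(
    withCallingHandlers(
      MASS::glm.nb(form, data = df),
      warning = function(w) {
        if (grepl("theta|iteration limit|alternation", conditionMessage(w),
                  ignore.case = TRUE)) {
          degenerate <<- TRUE
        }
        invokeRestart("muffleWarning")
      }),
    error = function(e) {
      # underdispersed counts: theta estimation diverges; report the
      # Poisson limit and flag the dispersion fit as degenerate
      degenerate <<- TRUE
      f <- glm(form, data = df, family = stats::poisson())
      f$theta <- Inf
      f
    })
  sm <- summary(fit)$coefficients
  structure(
    list(beta = sm[, 1], se = sm[, 2], z = sm[, 3], p = sm[, 4],
         theta = fit$theta, loglik = as.numeric(logLik(fit)),
         converged = fit$converged && !degenerate,
         dispersion_degenerate = degenerate,
         nobs = nrow(df), fit = fit),
    class = "roh_nb")
}

#' @method tidy roh_nb
#' @export
tidy.roh_nb <- function(x, ...) {
  tibble(term = names(x$beta), estimate = unname(x$beta),
         std.error = unname(x$se), statistic = unname(x$z),
         p.value = unname(x$p))
}

#' @method glance roh_nb
#' @export
glance.roh_nb <- function(x, ...) {
  tibble(nobs = x$nobs, theta = x$theta, logLik = x$loglik,
         converged = x$converged,
         dispersion_degenerate = x$dispersion_degenerate)
}

#' @export
print.roh_nb <- function(x, ...) {
  cat(sprintf("<roh_nb> %d raced samples, theta %.3g%s\n", x$nobs, x$theta,
              if (x$dispersion_degenerate) " [dispersion degenerate]" else ""))
  print(tidy(x))
  invisible(x)
}

#' Predicted racing probabilities over an inbreeding grid
#'
#' Evaluates a fitted depression model over a grid of F_ROH values at a
#' reference covariate profile (sex F, region ANZ, random effect at zero
#' unless overridden).
#'
#' @param fit An `roh_glmm` from [fit_froh_model()] (or any fit whose
#'   formula contains `froh_var`).
#' @param froh_values Numeric grid of inbreeding coefficients.
#' @param froh_var Name of the inbreeding column in the model formula.
#' @param reference Named list of covariate values for the remaining terms;
#'   defaults to `region = "ANZ"`, `sex = "F"` where those terms appear.
#' @return Tibble with the grid and `p_hat`, `lwr`, `upr`.
#' @export
prediction_table <- function(fit, froh_values, froh_var = "f_roh",
                             reference = NULL) {
  stopifnot(inherits(fit, "roh_glmm"))
  vars <- setdiff(all.vars(fit$formula)[-1], froh_var)
  defaults <- list(region = "ANZ", sex = "F")
  reference <- modifyList(defaults[intersect(names(defaults), vars)],
                          reference %||% list())
  missing_ref <- setdiff(vars, names(reference))
  if (length(missing_ref) > 0) {
    abort(paste0("no reference value for covariate(s): ",
                 paste(missing_ref, collapse = ", ")))
  }
  nd <- tibble(.froh = froh_values)
  names(nd) <- froh_var
  for (v in vars) nd[[v]] <- reference[[v]]
  for (v in names(fit$xlevels)) {
    if (v %in% names(nd)) nd[[v]] <- factor(nd[[v]], levels = fit$xlevels[[v]])
  }
  predict_probability(fit, nd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
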