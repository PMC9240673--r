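# Shared small synthetic analysis frame for the model wrappers.
make_analysis_data <- function(n = 600, beta_froh = -4, seed = 1,
                               beta_long = NULL) {
  set.seed(seed)
  f_short <- runif(n, 0.1, 0.25)
  f_long <- runif(n, 0, 0.15)
  f_roh <- f_short + f_long
  sex <- sample(c("F", "M"), n, replace = TRUE)
  region <- sample(c("ANZ", "EUR"), n, replace = TRUE)
  birth_year <- sample(2000:2007, n, replace = TRUE)
  eta <- if (is.null(beta_long)) {
    2 + beta_froh * f_roh
  } else {
    2 + beta_long * f_long
  }
  raced <- rbinom(n, 1, plogis(eta - 0.1 * (sex == "M")))
  n_races <- ifelse(raced == 1, pmax(1, rnbinom(n, size = 3, mu = 12)), NA)
  list(
    phenotypes = tibble::tibble(sample_id = as.character(1:n), raced = raced,
                                n_races = n_races),
    inbreeding = tibble::tibble(sample_id = as.character(1:n), f_roh = f_roh,
                                f_roh_short = f_short, f_roh_long = f_long),
    covariates = tibble::tibble(id = as.character(1:n), sex = sex,
                                region = region, birth_year = birth_year))
}

test_that("race status follows the before-age-five rule", {
  records <- tibble::tibble(
    id = c("a", "b", "b", "d"),
    age_at_first_start = c(4, 6, 3.5, 6))
  ph <- assign_race_status(records, sample_ids = c("a", "b", "c", "d"))
  expect_equal(ph$raced, c(1L, 1L, 0L, 0L))     # d started at 6: unraced
  expect_true(is.na(ph$n_races[ph$sample_id == "c"]))
  expect_equal(ph$age_at_first_start[ph$sample_id == "b"], 3.5)

  # permutation invariance of record order
  ph2 <- assign_race_status(records[c(3, 1, 4, 2), ],
                            sample_ids = c("a", "b", "c", "d"))
  expect_identical(ph, ph2)

  expect_error(assign_race_status(
    tibble::tibble(id = "x", age_at_first_start = -1), "x"), "negative")
})

test_that("the genome-wide inbreeding model recovers a negative F_ROH effect", {
  d <- make_analysis_data(n = 1500, beta_froh = -5, seed = 2)
  fit <- fit_froh_model(d$phenotypes, d$inbreeding, d$covariates,
                        quadrature_points = 1)
  expect_true(fit$converged)
  est <- tidy(fit)
  b1 <- est$estimate[est$term == "f_roh"]
  se1 <- est$std.error[est$term == "f_roh"]
  expect_lt(b1, 0)
  expect_true(abs(b1 - (-5)) < 3 * se1)
  expect_lt(attr(fit, "odds_change_10"), 0)
})

test_that("degenerate inbreeding designs fail loudly", {
  d <- make_analysis_data(n = 300, seed = 3)
  d$inbreeding$f_roh <- 0.25
  expect_error(
    fit_froh_model(d$phenotypes, d$inbreeding, d$covariates,
                   quadrature_points = 1),
    "aliased")

  d2 <- make_analysis_data(n = 300, seed = 4)
  d2$inbreeding$f_roh_short <- d2$inbreeding$f_roh_long
  expect_warning(
    try(fit_short_long_model(d2$phenotypes, d2$inbreeding, d2$covariates,
                             quadrature_points = 1), silent = TRUE),
    "collinear")

  d3 <- make_analysis_data(n = 300, seed = 5)
  d3$inbreeding$f_roh_long <- 0
  expect_error(
    fit_short_long_model(d3$phenotypes, d3$inbreeding, d3$covariates,
                         quadrature_points = 1),
    "aliased")
})

test_that("the short/long model attributes effects to the right component", {
  d <- make_analysis_data(n = 4000, seed = 6, beta_long = -8)
  fit <- fit_short_long_model(d$phenotypes, d$inbreeding, d$covariates,
                              quadrature_points = 1)
  est <- tidy(fit)
  p_long <- est$p.value[est$term == "f_roh_long"]
  b_long <- est$estimate[est$term == "f_roh_long"]
  expect_lt(p_long, 0.01)
  expect_lt(b_long, 0)
})

test_that("the interaction model needs two regions and detects unequal slopes", {
  d <- make_analysis_data(n = 300, seed = 7)
  d$covariates$region <- "EUR"
  expect_error(
    fit_interaction_model(d$phenotypes, d$inbreeding, d$covariates),
    "one region")

  set.seed(8)
  n <- 4000
  f <- runif(n, 0.1, 0.4)
  region <- sample(c("ANZ", "EUR"), n, replace = TRUE)
  slope <- ifelse(region == "EUR", -9, -3)
  raced <- rbinom(n, 1, plogis(2.5 + slope * f))
  d2 <- list(
    phenotypes = tibble::tibble(sample_id = as.character(1:n),
                                raced = raced),
    inbreeding = tibble::tibble(sample_id = as.character(1:n), f_roh = f),
    covariates = tibble::tibble(id = as.character(1:n),
                                sex = sample(c("F", "M"), n, TRUE),
                                region = region,
                                birth_year = sample(2000:2005, n, TRUE)))
  fit <- fit_interaction_model(d2$phenotypes, d2$inbreeding, d2$covariates,
                               quadrature_points = 1)
  est <- tidy(fit)
  p_int <- est$p.value[grepl(":", est$term)]
  expect_lt(p_int, 0.05)
})

test_that("race-count model runs, flags degeneracy, matches Poisson limit", {
  d <- make_analysis_data(n = 800, seed = 9)
  nb <- fit_race_count_model(d$phenotypes, d$inbreeding, d$covariates)
  expect_s3_class(tidy(nb), "tbl_df")
  expect_true("f_roh" %in% tidy(nb)$term)

  # equal counts: dispersion degenerates and is flagged
  d$phenotypes$n_races[d$phenotypes$raced == 1] <- 7L
  flagged <- fit_race_count_model(d$phenotypes, d$inbreeding, d$covariates)
  expect_true(flagged$dispersion_degenerate || flagged$theta > 1e4)

  # Poisson-generated counts: NB estimates match an independent Poisson fit
  d2 <- make_analysis_data(n = 1200, seed = 10)
  raced_idx <- d2$phenotypes$raced == 1
  set.seed(11)
  df <- dplyr::inner_join(
    dplyr::inner_join(d2$phenotypes[raced_idx, ], d2$inbreeding,
                      by = "sample_id"),
    dplyr::rename(d2$covariates, sample_id = id), by = "sample_id")
  df$n_races <- rpois(nrow(df), exp(2 + 0.5 * df$f_roh))
  df <- df[df$n_races > 0, ]
  d2$phenotypes <- dplyr::select(df, sample_id, raced, n_races)
  d2$inbreeding <- dplyr::select(df, sample_id, f_roh, f_roh_short,
                                 f_roh_long)
  d2$covariates <- dplyr::select(df, id = sample_id, sex, region, birth_year)
  nb2 <- fit_race_count_model(d2$phenotypes, d2$inbreeding, d2$covariates)
  pois <- glm(n_races ~ f_roh + region + sex + factor(birth_year),
              data = df, family = poisson())
  expect_equal(nb2$beta[["f_roh"]], coef(pois)[["f_roh"]], tolerance = 0.05)

  expect_error(fit_race_count_model(
    dplyr::mutate(d2$phenotypes, raced = 0L), d2$inbreeding, d2$covariates),
    "no raced samples")
})

test_that("prediction tables are monotone and recover the observed rate", {
  d <- make_analysis_data(n = 2000, beta_froh = -5, seed = 12)
  fit <- fit_froh_model(d$phenotypes, d$inbreeding, d$covariates,
                        quadrature_points = 1)
  tab <- prediction_table(fit, seq(0.15, 0.40, by = 0.05))
  expect_true(all(diff(tab$p_hat) < 0))   # negative slope -> decreasing
  expect_true(all(tab$lwr <= tab$p_hat & tab$p_hat <= tab$upr))

  # intercept-only model mean-matches the observed raced fraction
  df <- data.frame(raced = d$phenotypes$raced)
  f0 <- fit_binomial_glmm(df, raced ~ 1)
  pr <- predict_probability(f0, data.frame(x = 0))
  expect_equal(pr$p_hat, mean(df$raced), tolerance = 1e-8)
})
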