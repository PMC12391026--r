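# Association models between photoperiod sensitivity and species-level
# predictors: inverse-variance-weighted Gamma GLMs for the continuous metric,
# and a binomial GLM for literature-derived flowering photoperiodism.

gamma_predictors <- c("seed_mass", "growth_form", "latitude", "lai", "alpine")
flowering_predictors <- c("latitude", "lai", "seed_mass")
flowering_categories <- c("long_day", "short_day", "day_neutral", "other")

# transformed single-predictor column for modelling; seed mass is log10,
# latitude absolute (stored signed, southern negative)
predictor_column <- function(data, predictor) {
  switch(predictor,
    seed_mass = {
      if (any(data$seed_mass_mg <= 0, na.rm = TRUE)) {
        abort("seed_mass_mg must be strictly positive")
      }
      log10(data$seed_mass_mg)
    },
    latitude = abs(data$latitude_deg),
    lai = data$lai,
    alpine = factor(as.integer(data$alpine), levels = c(0, 1),
                    labels = c("non_alpine", "alpine")),
    growth_form = factor(data$growth_form),
    abort(sprintf("unknown predictor %s", sQuote(predictor)))
  )
}

new_association <- function(predictor, family, fit, data, weights_used) {
  dev <- fit$deviance
  null_dev <- fit$null.deviance
  df <- fit$df.null - fit$df.residual
  dispersion <- if (family == "binomial_logit") 1 else summary(fit)$dispersion
  lr <- max(0, (null_dev - dev) / dispersion)
  structure(
    list(
      predictor = predictor,
      family = family,
      fit = fit,
      data = data,
      coefficients = coef(fit),
      pseudo_r2 = min(1, max(0, 1 - dev / null_dev)),
      lr_statistic = lr,
      df = df,
      p_value = pchisq(lr, df = df, lower.tail = FALSE),
      n_used = nrow(data),
      weights_used = weights_used
    ),
    class = "psm_association"
  )
}

#' Inverse-variance-weighted Gamma GLM of sensitivity on one predictor
#'
#' Fits a Gamma GLM with log link of the (non-negative) photoperiod
#' sensitivity metric on a single species-level predictor, weighting each
#' species by the inverse squared bootstrap standard error of its metric
#' (`weight = 1/se^2`). Seed mass enters log10-transformed, latitude as
#' absolute degrees, and the climber growth form is dropped before fitting
#' (too few species carry it to estimate a contrast). Significance is a
#' likelihood-ratio chi-square against the intercept-only weighted model, so
#' categorical predictors get a single model-level p-value; fit quality is the
#' deviance pseudo-R-squared `1 - residual deviance / null deviance`.
#'
#' A Gamma response must be strictly positive. Species with a metric of
#' exactly zero are an error by default, naming them; passing a small
#' `zero_offset` (e.g. `1e-6`) instead adds it to every response.
#'
#' @param psm_results Sensitivity table from [compute_psm_table()] (needs
#'   `species`, `psm`, `weight`; rows with `retained = FALSE` or missing
#'   weight are dropped).
#' @param traits Species trait table with columns `species`, `seed_mass_mg`,
#'   `growth_form`, `latitude_deg`, `lai`, `alpine`.
#' @param predictor One of `"seed_mass"`, `"growth_form"`, `"latitude"`,
#'   `"lai"`, `"alpine"`.
#' @param zero_offset Optional positive constant added to all responses to
#'   accommodate exact-zero metrics; default `NULL` (error on zeros).
#' @return A `psm_association` object; see [glance.psm_association()] for the
#'   one-row summary and [tidy.psm_association()] for coefficients.
#' @export
fit_weighted_gamma_glm <- function(psm_results, traits, predictor,
                                   zero_offset = NULL) {
  predictor <- match.arg(predictor, gamma_predictors)
  data <- psm_results
  if ("retained" %in% names(data)) data <- filter(data, .data$retained)
  if (!"weight" %in% names(data)) data$weight <- 1
  traits <- as_tibble(traits)
  traits <- traits[, setdiff(names(traits), c("psm", "weight"))]
  data <- data |>
    select("species", "psm", "weight") |>
    left_join(traits, by = "species")
  data$x <- predictor_column(data, predictor)
  if (predictor == "growth_form") {
    data <- filter(data, .data$growth_form != "climber")
    data$x <- droplevels(factor(data$growth_form))
  }
  data <- filter(data, is.finite(.data$psm), !is.na(.data$x),
                 is.finite(.data$weight), .data$weight > 0)
  if (!is.null(zero_offset)) {
    stopifnot(is.numeric(zero_offset), zero_offset > 0)
    data$psm <- data$psm + zero_offset
  }
  zeros <- data$species[data$psm <= 0]
  if (length(zeros) > 0) {
    abort(sprintf(
      "Gamma response must be strictly positive; species with zero metric: %s (use zero_offset to include them)",
      paste(zeros, collapse = ", ")
    ))
  }
  if (nrow(data) < 3) abort("fewer than 3 usable species")
  if (is.factor(data$x) && nlevels(droplevels(data$x)) < 2) {
    abort("predictor has a single level after filtering")
  }
  fit <- glm(psm ~ x, family = Gamma(link = "log"), data = data,
             weights = weight)
  new_association(predictor, "gamma_log", fit, data, weights_used = TRUE)
}

#' Binomial GLM of flowering photoperiodism on one predictor
#'
#' Binarizes literature flowering-photoperiodism categories (day-neutral
#' species are insensitive; long-day, short-day and other-photoperiod species
#' are sensitive) and fits a logit-link binomial GLM on a single predictor
#' (seed mass log10-transformed, latitude absolute). Reports the
#' likelihood-ratio p-value against the intercept-only model and the deviance
#' pseudo-R-squared.
#'
#' @param records Flowering table with columns `species`, `category` (one of
#'   `"long_day"`, `"short_day"`, `"day_neutral"`, `"other"`), and the
#'   predictor columns `latitude_deg`, `lai`, `seed_mass_mg`.
#' @param predictor One of `"latitude"`, `"lai"`, `"seed_mass"`.
#' @return A `psm_association` object.
#' @export
fit_flowering_binomial_glm <- function(records, predictor) {
  predictor <- match.arg(predictor, flowering_predictors)
  data <- as_tibble(records)
  bad <- setdiff(unique(data$category), flowering_categories)
  if (length(bad) > 0) {
    abort(sprintf("unknown flowering category: %s",
                  paste(sQuote(bad), collapse = ", ")))
  }
  data$sensitive <- as.integer(data$category != "day_neutral")
  data$x <- predictor_column(data, predictor)
  data <- filter(data, !is.na(.data$x), !is.na(.data$sensitive))
  if (length(unique(data$sensitive)) < 2) {
    abort("a single response class is present; the model is unidentifiable")
  }
  fit <- glm(sensitive ~ x, family = binomial(link = "logit"), data = data)
  new_association(predictor, "binomial_logit", fit, data, weights_used = FALSE)
}

#' @export
print.psm_association <- function(x, ...) {
  cat(sprintf(
    "<psm_association> %s model, predictor %s (n = %d%s)\n  pseudo-R2 = %.3f, LR chi2(%d) = %.3f, p = %.3g\n",
    x$family, x$predictor, x$n_used,
    if (x$weights_used) ", inverse-variance weighted" else "",
    x$pseudo_r2, x$df, x$lr_statistic, x$p_value
  ))
  invisible(x)
}

#' Tidy an association model
#'
#' @param x A `psm_association`.
#' @param ... Unused.
#' @return Tibble of coefficients with standard errors, Wald z and p-values.
#' @export
tidy.psm_association <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, 1],
    std.error = s[, 2],
    statistic = s[, 3],
    p.value = s[, 4]
  )
}

#' Glance at an association model
#'
#' @param x A `psm_association`.
#' @param ... Unused.
#' @return One-row tibble: predictor, family, pseudo-R-squared,
#'   likelihood-ratio statistic and df, p-value, species count and whether
#'   inverse-variance weights were used.
#' @export
glance.psm_association <- function(x, ...) {
  tibble(
    predictor = x$predictor,
    family = x$family,
    pseudo_r2 = x$pseudo_r2,
    lr_statistic = x$lr_statistic,
    df = x$df,
    p_value = x$p_value,
    n_used = x$n_used,
    weights_used = x$weights_used
  )
}
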