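# The photoperiod sensitivity metric: point value, parametric-bootstrap
# standard error, direction/significance classification, and the per-species
# table assembly.

#' Photoperiod sensitivity metric from treatment contrasts
#'
#' The continuous sensitivity statistic computed from the two logit-scale
#' treatment contrasts of a species' germination model:
#' `sqrt((beta1^2 + beta2^2 + (beta1 - beta2)^2) / 3)`. The radicand equals
#' the sum of squared deviations of the three linear-predictor treatment means
#' `{0, beta1, beta2}` about their mean, so the metric is zero exactly when
#' germination is identical across the three day lengths and grows with any
#' inequality among them.
#'
#' @param beta1 Long-day minus equal-day contrast (log-odds). Vectorized.
#' @param beta2 Short-day minus equal-day contrast (log-odds). Vectorized.
#' @return Non-negative numeric, the metric in logit units.
#' @examples
#' compute_psm(1, 0)   # sqrt(2/3)
#' compute_psm(2, 2)   # sqrt(8/3)
#' @export
compute_psm <- function(beta1, beta2) {
  if (any(!is.finite(beta1)) || any(!is.finite(beta2))) {
    abort("treatment contrasts must be finite")
  }
  sqrt((beta1^2 + beta2^2 + (beta1 - beta2)^2) / 3)
}

#' Parametric-bootstrap standard error of the sensitivity metric
#'
#' Draws coefficient vectors from a multivariate normal centred at the fitted
#' `(mu0, beta1, beta2)` with the fit's full 3x3 posterior covariance,
#' evaluates [compute_psm()] on each draw's contrasts, and returns the sample
#' standard deviation (n - 1 denominator) of the draws. The intercept
#' dimension is included in the draws so intercept-slope correlation
#' propagates through the marginal contrast covariance. Covariances that are
#' PSD up to rounding (eigenvalues in `[-1e-10, 0]`) are repaired by clipping;
#' more negative eigenvalues are an error.
#'
#' @param fit A `species_fit`.
#' @param n_draws Number of bootstrap draws (default 10000).
#' @param seed Integer seed; required, so the SE is reproducible.
#' @return A list: `se` (the bootstrap SE), `n_draws`, and `draws_summary`
#'   (one-row tibble with mean, median and 5/95% quantiles of the drawn
#'   metric values).
#' @export
bootstrap_psm_se <- function(fit, n_draws = 10000L, seed) {
  stopifnot(inherits(fit, "species_fit"))
  if (missing(seed)) abort("a seed is required for the parametric bootstrap")
  draws <- withr::with_seed(
    as.integer(seed),
    draw_mvnorm(n_draws, fit$coefficients, fit$vcov)
  )
  psm_draws <- compute_psm(draws[, 2], draws[, 3])
  q <- quantile(psm_draws, c(0.05, 0.5, 0.95), names = FALSE)
  list(
    se = sd(psm_draws),
    n_draws = as.integer(n_draws),
    draws_summary = tibble(
      mean = mean(psm_draws), q05 = q[1], median = q[2], q95 = q[3]
    )
  )
}

#' Classify the direction and significance of a species' response
#'
#' Runs two-sided Wald z-tests at level `alpha` on the three logit-scale
#' contrasts: long vs equal (`beta1`), short vs equal (`beta2`) and long vs
#' short (`beta1 - beta2`). A species is `significant` when any test rejects.
#' Classification: `long_day` when significant and the fitted long-day
#' germination probability is the strict maximum; `short_day` symmetrically;
#' `intermediate` when the equal-day probability strictly exceeds both others
#' and at least one of `beta1`, `beta2` is significantly negative;
#' `insensitive` otherwise. The sign is +1 when the fitted long-day
#' probability is at least the short-day probability and -1 otherwise, so
#' intermediate responders are signed by whichever of long/short germinated
#' better.
#'
#' @param fit A `species_fit`.
#' @param alpha Two-sided test level (default 0.05).
#' @return One-row tibble: `classification`, `significant`, `sign`.
#' @export
classify_direction <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "species_fit"))
  v <- fit$vcov
  b <- fit$coefficients
  est <- c(b["beta1"], b["beta2"], b["beta1"] - b["beta2"])
  se <- sqrt(c(v[2, 2], v[3, 3], v[2, 2] + v[3, 3] - 2 * v[2, 3]))
  z <- ifelse(se > 0, est / se, 0)
  crit <- qnorm(1 - alpha / 2)
  rejects <- abs(z) > crit
  significant <- any(rejects)
  p <- fit$fitted_probabilities
  classification <- if (!significant) {
    "insensitive"
  } else if (p["equal"] > p["long"] && p["equal"] > p["short"] &&
             ((z[1] < -crit) || (z[2] < -crit))) {
    "intermediate"
  } else if (p["long"] > p["equal"] && p["long"] > p["short"]) {
    "long_day"
  } else if (p["short"] > p["equal"] && p["short"] > p["long"]) {
    "short_day"
  } else {
    "insensitive"
  }
  tibble(
    classification = classification,
    significant = significant,
    sign = if (p["long"] >= p["short"]) 1 else -1
  )
}

#' Per-species photoperiod sensitivity table
#'
#' The full pipeline over a multi-species germination table: inclusion filter,
#' prior-regularized binomial fit, sensitivity metric, parametric-bootstrap
#' standard error, inverse-variance weight and direction classification.
#' Excluded species keep their filter reason and carry `NA` results. Each
#' species' bootstrap stream is derived deterministically from `seed` and the
#' species name, so the table is reproducible and unchanged by row order or by
#' adding further species.
#'
#' @param records Germination records tibble for one or more species.
#' @param prior A [prior_spec()].
#' @param n_draws Bootstrap draws per species (default 10000).
#' @param seed Integer seed for the bootstrap streams; required.
#' @param alpha Level of the Wald classification tests (default 0.05).
#' @return A tibble with one row per species: `species`, `retained`,
#'   `exclusion_reason`, `beta1`, `beta2`, `psm`, `signed_psm`, `se`,
#'   `weight` (`1/se^2`, `NA` when `se` is 0), `classification`,
#'   `significant`, `n_bootstrap`.
#' @examples
#' scen <- tibble::tibble(
#'   species = c("spA", "spB"), p_long = c(0.8, 0.5), p_equal = 0.5,
#'   p_short = c(0.2, 0.5), n_per_treatment = 30)
#' rec <- simulate_germination(scen, seed = 42)
#' compute_psm_table(rec, n_draws = 1000, seed = 42)
#' @export
compute_psm_table <- function(records, prior = prior_spec(),
                              n_draws = 10000L, seed, alpha = 0.05) {
  if (missing(seed)) abort("a seed is required for the bootstrap standard errors")
  records <- aggregate_records(validate_germination(records))
  decisions <- apply_inclusion_filter(records)
  rows <- map(decisions$species, function(sp) {
    dec <- decisions[decisions$species == sp, ]
    base <- tibble(
      species = sp, retained = dec$retained, exclusion_reason = dec$reason,
      beta1 = NA_real_, beta2 = NA_real_, psm = NA_real_,
      signed_psm = NA_real_, se = NA_real_, weight = NA_real_,
      classification = NA_character_, significant = NA,
      n_bootstrap = NA_integer_
    )
    if (!dec$retained) return(base)
    fit <- tryCatch(
      fit_regularized_binomial_glm(records[records$species == sp, ], prior),
      error = function(e) abort(sprintf("species %s: %s", sp, conditionMessage(e)))
    )
    boot <- bootstrap_psm_se(fit, n_draws = n_draws,
                             seed = derive_seed(seed, sp))
    cls <- classify_direction(fit, alpha = alpha)
    psm_val <- unname(compute_psm(fit$coefficients["beta1"],
                                  fit$coefficients["beta2"]))
    base |>
      mutate(
        beta1 = unname(fit$coefficients["beta1"]),
        beta2 = unname(fit$coefficients["beta2"]),
        psm = psm_val,
        signed_psm = cls$sign * psm_val,
        se = boot$se,
        weight = ifelse(boot$se > 0, 1 / boot$se^2, NA_real_),
        classification = cls$classification,
        significant = cls$significant,
        n_bootstrap = boot$n_draws
      )
  })
  bind_rows(rows)
}
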