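test_that("symmetric counts give exactly zero contrasts", {
  fit <- fit_regularized_binomial_glm(records_one(15, 15, 15))
  expect_equal(unname(coef(fit)), c(0, 0, 0))
  expect_true(fit$converged)
  expect_equal(unname(fit$fitted_probabilities), rep(0.5, 3))
})

test_that("weak priors recover the unpenalized logistic MLE", {
  weak <- prior_spec(slope_scale = 1e6, intercept_scale = 1e6)
  cases <- list(c(24, 15, 6), c(20, 18, 12), c(5, 25, 14), c(29, 3, 10))
  for (counts in cases) {
    rec <- records_one(counts[1], counts[2], counts[3])
    fit <- fit_regularized_binomial_glm(rec, weak)
    # independent oracle: Fisher-scoring MLE from stats::glm
    glm_fit <- stats::glm(
      cbind(n_germinated, n_sown - n_germinated) ~ treatment,
      family = stats::binomial(), data = rec
    )
    expect_equal(unname(coef(fit)), unname(coef(glm_fit)), tolerance = 1e-5)
    # and its curvature-based covariance
    expect_equal(unname(vcov(fit)), unname(vcov(glm_fit)), tolerance = 1e-3)
  }
  # saturated logits for the worked three-treatment case
  fit <- fit_regularized_binomial_glm(records_one(24, 15, 6), weak)
  expect_equal(unname(coef(fit)), c(0, qlogis(0.8), qlogis(0.2)),
               tolerance = 1e-3)
})

test_that("log-posterior matches a hand evaluation and is maximised at the fit", {
  rec <- records_one(15, 15, 15)
  prior <- prior_spec()
  prior_at_zero <- sum(
    dt(0, df = c(1, 1, 1), log = TRUE) -
      log(c(10, 2.5, 2.5))
  )
  expect_equal(log_posterior(c(0, 0, 0), rec, prior),
               90 * log(0.5) + prior_at_zero, tolerance = 1e-12)

  # unimodality probe: any perturbation from the MAP decreases the objective
  rec2 <- records_one(24, 15, 6)
  fit <- fit_regularized_binomial_glm(rec2)
  at_map <- log_posterior(coef(fit), rec2)
  for (eps in c(0.05, 0.5, 2)) {
    for (j in 1:3) {
      for (s in c(-1, 1)) {
        probe <- coef(fit)
        probe[j] <- probe[j] + s * eps
        expect_lt(log_posterior(probe, rec2), at_map)
      }
    }
  }

  # weak-prior limit: the objective is the log-likelihood plus a constant
  weak <- prior_spec(slope_scale = 1e8, intercept_scale = 1e8)
  p1 <- c(0.3, 1.2, -0.4)
  p2 <- c(-0.5, 0.1, 0.9)
  # difference of objectives equals difference of binomial log-likelihoods
  binom_ll <- function(p) {
    eta <- c(p[1], p[1] + p[2], p[1] + p[3])  # equal, long, short
    y <- c(15, 24, 6); n <- c(30, 30, 30)
    sum(y * eta - n * log1p(exp(eta)))
  }
  expect_equal(
    log_posterior(p1, rec2, weak) - log_posterior(p2, rec2, weak),
    binom_ll(p1) - binom_ll(p2),
    tolerance = 1e-8
  )
})

test_that("separation stays finite and bounded under the default prior", {
  # one boundary cell against an interior reference: contrasts stay below 5
  single <- list(c(15, 15, 0), c(0, 15, 15), c(30, 15, 6), c(30, 15, 15))
  for (counts in single) {
    fit <- fit_regularized_binomial_glm(
      records_one(counts[1], counts[2], counts[3], n = 30))
    expect_true(all(is.finite(coef(fit))))
    expect_true(all(abs(coef(fit)) <= 5))
    expect_true(all(is.finite(vcov(fit))))
  }
  # stacked separations (boundary cells in opposite directions) are larger
  # but still finite with finite curvature
  double <- list(c(30, 0, 30), c(0, 0, 30), c(30, 30, 0))
  for (counts in double) {
    fit <- fit_regularized_binomial_glm(
      records_one(counts[1], counts[2], counts[3], n = 30))
    expect_true(all(is.finite(coef(fit))))
    expect_true(all(is.finite(vcov(fit))))
  }
})

test_that("swapping long and short counts swaps the contrasts exactly", {
  a <- fit_regularized_binomial_glm(records_one(24, 15, 3))
  b <- fit_regularized_binomial_glm(records_one(3, 15, 24))
  expect_equal(unname(coef(a)["beta1"]), unname(coef(b)["beta2"]),
               tolerance = 1e-12)
  expect_equal(unname(coef(a)["beta2"]), unname(coef(b)["beta1"]),
               tolerance = 1e-12)
  expect_equal(unname(coef(a)["mu0"]), unname(coef(b)["mu0"]),
               tolerance = 1e-12)
})

test_that("the reported covariance is the inverse posterior curvature", {
  rec <- records_one(22, 14, 4)
  fit <- fit_regularized_binomial_glm(rec)
  h <- pracma::hessian(function(p) log_posterior(p, rec), coef(fit))
  expect_equal(unname(vcov(fit)), solve(-(h + t(h)) / 2), tolerance = 1e-5)
})

test_that("reported standard errors track the sampling spread of the MAP", {
  probs <- c(equal = 0.5, long = 0.7, short = 0.3)
  n <- 100L
  rec <- records_one(round(probs["long"] * n), round(probs["equal"] * n),
                     round(probs["short"] * n), n = n)
  fit <- fit_regularized_binomial_glm(rec)
  reported_se <- sqrt(diag(vcov(fit)))[c("beta1", "beta2")]
  est <- withr::with_seed(2024, {
    t(replicate(200, {
      y <- rbinom(3, n, probs[c("long", "equal", "short")])
      coef(fit_regularized_binomial_glm(records_one(y[1], y[2], y[3], n = n)))[2:3]
    }))
  })
  ratio <- apply(est, 2, sd) / reported_se
  expect_true(all(ratio > 0.8 & ratio < 1.2))
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(fit_regularized_binomial_glm(records_one(1, 1, 1)[-2, ]),
               "missing treatment")
  expect_error(prior_spec(slope_scale = -1), "positive")
  two_species <- dplyr::bind_rows(records_one(1, 1, 1),
                                  records_one(1, 1, 1, species = "sp2"))
  expect_error(fit_regularized_binomial_glm(two_species), "one species")
})
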