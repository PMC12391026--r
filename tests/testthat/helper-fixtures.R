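# Fixtures built in code for the test suite.

# one-species germination records with given counts (long, equal, short)
records_one <- function(long, equal, short, n = 30L, species = "sp1") {
  tibble::tibble(
    species = species,
    treatment = parse_treatment(c("18L/6D", "12L/12D", "6L/18D")),
    n_sown = as.integer(n),
    n_germinated = as.integer(c(long, equal, short))
  )
}

# a species_fit-shaped object with chosen coefficients and covariance, for
# probing the bootstrap and classifier in isolation
fake_fit <- function(mu0 = 0, beta1 = 0, beta2 = 0, vcov = diag(0.01, 3),
                     species = "fake") {
  coefs <- c(mu0 = mu0, beta1 = beta1, beta2 = beta2)
  dimnames(vcov) <- list(names(coefs), names(coefs))
  fitted <- stats::plogis(c(mu0, mu0 + beta1, mu0 + beta2))
  names(fitted) <- treatment_levels()
  structure(
    list(species = species, coefficients = coefs, vcov = vcov,
         fitted_probabilities = fitted,
         counts = tibble::tibble(
           treatment = factor(treatment_levels(), levels = treatment_levels()),
           n_sown = 30L, n_germinated = 15L),
         converged = TRUE, n_iterations = 0L, log_posterior = NA_real_,
         prior = prior_spec()),
    class = "species_fit"
  )
}
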