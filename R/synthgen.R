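# Synthetic-data generators: germination trials with known true sensitivity,
# trait tables with configurable effects, flowering tables, and pure-birth
# trees with Brownian-motion tip traits. Every generator is a pure function of
# its parameters and seed; per-species streams are derived from the species
# name so adding a species never perturbs the draws of the others.

#' True sensitivity metric from treatment germination probabilities
#'
#' Evaluates the sensitivity metric on the logit-scale contrasts implied by a
#' scenario's true germination probabilities:
#' `compute_psm(logit(p_long) - logit(p_equal), logit(p_short) - logit(p_equal))`.
#' Boundary probabilities (0 or 1) have infinite logits and are an error.
#'
#' @param p_long,p_equal,p_short Germination probabilities strictly inside
#'   (0, 1). Vectorized.
#' @return Non-negative numeric, the true metric in logit units.
#' @examples
#' true_psm_from_probabilities(0.8, 0.5, 0.2)
#' @export
true_psm_from_probabilities <- function(p_long, p_equal, p_short) {
  p <- c(p_long, p_equal, p_short)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("probabilities must lie strictly inside (0, 1)")
  }
  compute_psm(qlogis(p_long) - qlogis(p_equal),
              qlogis(p_short) - qlogis(p_equal))
}

#' Random species scenarios on the scale of a germination trial study
#'
#' Draws per-species true germination probabilities from a logit-normal model
#' (equal-day log-odds N(0, 1); long- and short-day contrasts N(0, 1)) and
#' per-treatment seed numbers uniform over `n_seeds`. Defaults mirror a
#' realistic trial campaign: 67 species with 6 to 50 seeds per treatment.
#'
#' @param n_species Number of species (default 67).
#' @param n_seeds Integer range of seeds per treatment, inclusive (default
#'   `c(6, 50)`).
#' @param seed Integer seed; required.
#' @return A scenario tibble: `species`, `p_long`, `p_equal`, `p_short`,
#'   `n_per_treatment`, `true_psm`.
#' @export
simulate_scenarios <- function(n_species = 67L, n_seeds = c(6L, 50L), seed) {
  if (missing(seed)) abort("a seed is required")
  withr::with_seed(as.integer(seed), {
    mu0 <- rnorm(n_species, 0, 1)
    b1 <- rnorm(n_species, 0, 1)
    b2 <- rnorm(n_species, 0, 1)
    tibble(
      species = sprintf("sp%03d", seq_len(n_species)),
      p_long = plogis(mu0 + b1),
      p_equal = plogis(mu0),
      p_short = plogis(mu0 + b2),
      n_per_treatment = sample(seq(n_seeds[1], n_seeds[2]), n_species,
                               replace = TRUE),
      true_psm = compute_psm(b1, b2)
    )
  })
}

#' Simulate a germination trial from species scenarios
#'
#' Draws binomial germination counts per species and treatment with each
#' scenario's true probabilities and seed number. The random stream for each
#' species is derived from `seed` and the species name, so tables are
#' reproducible and a species' counts do not change when others are added or
#' reordered.
#'
#' @param scenarios Tibble with columns `species`, `p_long`, `p_equal`,
#'   `p_short`, `n_per_treatment` (e.g. from [simulate_scenarios()]).
#' @param seed Integer seed; required.
#' @return Germination records tibble (`species`, `treatment`, `n_sown`,
#'   `n_germinated`) ready for [compute_psm_table()].
#' @export
simulate_germination <- function(scenarios, seed) {
  if (missing(seed)) abort("a seed is required")
  scenarios <- as_tibble(scenarios)
  req <- c("species", "p_long", "p_equal", "p_short", "n_per_treatment")
  missing_cols <- setdiff(req, names(scenarios))
  if (length(missing_cols) > 0) {
    abort(sprintf("scenarios is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  rows <- map(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    probs <- c(equal = sc$p_equal, long = sc$p_long, short = sc$p_short)
    counts <- withr::with_seed(
      derive_seed(seed, sc$species),
      rbinom(3, size = sc$n_per_treatment, prob = probs)
    )
    tibble(
      species = sc$species,
      treatment = factor(treatment_levels(), levels = treatment_levels()),
      n_sown = as.integer(sc$n_per_treatment),
      n_germinated = as.integer(counts)
    )
  })
  bind_rows(rows)
}

#' Simulate a species trait table, optionally with a sensitivity effect
#'
#' Draws species-level predictors from fixed distributions on the scale of an
#' eastern-Australian trial campaign: log10 seed mass (mg) normal(0.5, 1);
#' latitude uniform on 16-36 degrees south (stored as negative degrees);
#' leaf area index uniform on 0-6; alpine Bernoulli(0.3); growth form
#' categorical over herb/shrub/tree/climber with frequencies
#' 0.35/0.40/0.20/0.05. With `slope = 0` the supplied metric values (if any)
#' pass through untouched, giving a null scenario. With a nonzero `slope` the
#' metric is regenerated with a log-linear dependence on the (transformed)
#' predictor plus Gamma noise:
#' `psm ~ Gamma(shape, rate = shape / exp(intercept + slope * x))`.
#'
#' @param psm Optional tibble with `species` and `psm` columns; its species
#'   define the table. Either `psm` or `n_species` must be given.
#' @param n_species Number of species when `psm` is not supplied.
#' @param predictor Predictor carrying the effect when `slope != 0`: one of
#'   `"seed_mass"` (log10 scale), `"latitude"` (absolute degrees), `"lai"`,
#'   `"alpine"` (0/1 indicator).
#' @param slope Log-linear effect size (default 0: null scenario).
#' @param intercept Log-scale intercept of the generative model (default 0.5).
#' @param shape Gamma shape of the metric noise (default 5).
#' @param seed Integer seed; required.
#' @return Trait tibble: `species`, `seed_mass_mg`, `growth_form`,
#'   `latitude_deg`, `lai`, `alpine`, `psm`.
#' @export
simulate_trait_table <- function(psm = NULL, n_species = NULL,
                                 predictor = "seed_mass", slope = 0,
                                 intercept = 0.5, shape = 5, seed) {
  if (missing(seed)) abort("a seed is required")
  stopifnot(is.finite(slope), shape > 0)
  if (is.null(psm) && is.null(n_species)) {
    abort("supply either psm (species + values) or n_species")
  }
  species <- if (!is.null(psm)) as_tibble(psm)$species else
    sprintf("sp%03d", seq_len(n_species))
  n <- length(species)
  withr::with_seed(as.integer(seed), {
    traits <- tibble(
      species = species,
      seed_mass_mg = 10^rnorm(n, 0.5, 1),
      growth_form = sample(c("herb", "shrub", "tree", "climber"), n,
                           replace = TRUE, prob = c(0.35, 0.40, 0.20, 0.05)),
      latitude_deg = -runif(n, 16, 36),
      lai = runif(n, 0, 6),
      alpine = runif(n) < 0.3
    )
    if (slope != 0) {
      predictor <- match.arg(predictor,
                             c("seed_mass", "latitude", "lai", "alpine"))
      x <- switch(predictor,
        seed_mass = log10(traits$seed_mass_mg),
        latitude = abs(traits$latitude_deg),
        lai = traits$lai,
        alpine = as.numeric(traits$alpine)
      )
      mu <- exp(intercept + slope * x)
      traits$psm <- rgamma(n, shape = shape, rate = shape / mu)
    } else {
      traits$psm <- if (!is.null(psm)) as_tibble(psm)$psm else
        rgamma(n, shape = shape, rate = shape / exp(intercept))
    }
    traits
  })
}

#' Simulate a flowering-photoperiodism table
#'
#' Draws literature-style flowering categories with the supplied class
#' frequencies and attaches predictors from the same distributions as
#' [simulate_trait_table()]. With `slope != 0` the log-odds of being
#' photoperiod sensitive (any category except day-neutral) depend linearly on
#' the transformed predictor.
#'
#' @param n_species Number of records.
#' @param prob Category probabilities for long_day, short_day, day_neutral,
#'   other (default `c(0.33, 0.37, 0.24, 0.06)`, roughly literature-like).
#' @param predictor,slope Optional sensitivity effect as in
#'   [simulate_trait_table()]; predictors `"latitude"`, `"lai"`,
#'   `"seed_mass"`.
#' @param seed Integer seed; required.
#' @return Flowering tibble: `species`, `category`, `latitude_deg`, `lai`,
#'   `seed_mass_mg`.
#' @export
simulate_flowering_table <- function(n_species = 135L,
                                     prob = c(0.33, 0.37, 0.24, 0.06),
                                     predictor = "latitude", slope = 0, seed) {
  if (missing(seed)) abort("a seed is required")
  withr::with_seed(as.integer(seed), {
    out <- tibble(
      species = sprintf("fl%03d", seq_len(n_species)),
      latitude_deg = -runif(n_species, 16, 36),
      lai = runif(n_species, 0, 6),
      seed_mass_mg = 10^rnorm(n_species, 0.5, 1)
    )
    if (slope == 0) {
      out$category <- sample(flowering_categories, n_species, replace = TRUE,
                             prob = prob)
    } else {
      predictor <- match.arg(predictor, c("latitude", "lai", "seed_mass"))
      x <- switch(predictor,
        latitude = abs(out$latitude_deg),
        lai = out$lai,
        seed_mass = log10(out$seed_mass_mg)
      )
      p_sens <- plogis(qlogis(1 - prob[3]) + slope * (x - mean(x)))
      sensitive <- runif(n_species) < p_sens
      sens_prob <- prob[c(1, 2, 4)] / sum(prob[c(1, 2, 4)])
      out$category <- ifelse(
        sensitive,
        sample(flowering_categories[c(1, 2, 4)], n_species, replace = TRUE,
               prob = sens_prob),
        "day_neutral"
      )
    }
    out
  })
}

#' Simulate a pure-birth tree with lambda-transformed Brownian tip traits
#'
#' Generates a pure-birth (Yule) tree, builds its phylogenetic covariance,
#' scales the off-diagonals by `lambda_true` (diagonal kept fixed) and draws
#' tip values from the corresponding multivariate normal with variance scale
#' `sigma2`. `lambda_true = 1` gives plain Brownian motion; `lambda_true = 0`
#' gives independent tips.
#'
#' @param n_tips Number of tips (at least 4).
#' @param birth_rate Speciation rate of the pure-birth process (default 1).
#' @param sigma2 Brownian rate (variance per unit branch length, default 1).
#' @param lambda_true Signal strength in `[0, 1]` (default 1).
#' @param seed Integer seed; required.
#' @return A list: `tree` (an `ape::phylo`), `values` (named numeric tip
#'   values).
#' @export
simulate_tree_bm <- function(n_tips, birth_rate = 1, sigma2 = 1,
                             lambda_true = 1, seed) {
  if (missing(seed)) abort("a seed is required")
  stopifnot(n_tips >= 4, sigma2 > 0, lambda_true >= 0, lambda_true <= 1)
  withr::with_seed(as.integer(seed), {
    tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
    c_mat <- phylo_covariance(tree)
    v <- lambda_cov(c_mat, lambda_true) * sigma2
    values <- as.vector(draw_mvnorm(1, rep(0, n_tips), v))
    names(values) <- colnames(c_mat)
    list(tree = tree, values = values)
  })
}
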