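# photosens

Some plants cue their phenology on day length rather than temperature or
rainfall, which may leave them unable to track a changing climate.
`photosens` quantifies that **photoperiod sensitivity of seed germination**
from a standard three-treatment incubator design — short-day (6L/18D),
equal (12L/12D) and long-day (18L/6D) photoperiods with per-treatment
germination counts — and relates the resulting per-species sensitivity to
phylogeny, traits and habitat. It is aimed at seed biologists and
germination ecologists running day-length manipulation trials.

## The model and metric

For each species, germinant counts are binomial with logit-linear
treatment effects and the equal-day treatment as reference:

    logit p_t = mu0 + beta1·[t = long] + beta2·[t = short]

The fit is the posterior mode under independent zero-centred Student-t
priors (Cauchy, scale 2.5 on the contrasts; scale 10 on the intercept) so
that treatments with zero or complete germination — where the ordinary MLE
diverges — still yield finite contrasts, while well-identified fits stay at
the MLE. Sensitivity is summarised by the continuous metric

    PSM = sqrt( (beta1² + beta2² + (beta1 − beta2)²) / 3 )

which is zero exactly when germination odds are equal across day lengths.
Its standard error comes from a parametric bootstrap (10,000 multivariate
normal draws from the fit's posterior covariance), and species are
classified long-day / short-day / intermediate / insensitive by Wald tests
on the three contrasts, with signed values positive when long-day
germination exceeds short-day. Downstream, inverse-variance-weighted Gamma
GLMs (log link) test single-predictor associations with seed mass, growth
form, latitude, leaf area index and alpine habitat; Pagel's λ and
Blomberg's K test for phylogenetic signal on a user-supplied tree. A
synthetic-data generator produces trials with known true sensitivity so the
whole pipeline is testable without field data. See the vignette in
`vignettes/photoperiod-sensitivity.Rmd` for the full methods account.

## Worked example

```r
library(photosens)

scen <- simulate_scenarios(n_species = 8, seed = 2026)   # known true PSMs
rec  <- simulate_germination(scen, seed = 2027)          # binomial counts
psm  <- compute_psm_table(rec, n_draws = 10000, seed = 2028)
dplyr::select(psm, species, retained, psm, signed_psm, se,
              classification, significant)
#> # A tibble: 8 × 7
#>   species retained   psm signed_psm    se classification significant
#>   <chr>   <lgl>    <dbl>      <dbl> <dbl> <chr>          <lgl>
#> 1 sp001   TRUE     0.240     -0.240 0.231 insensitive    FALSE
#> 2 sp002   TRUE     0.943     -0.943 0.552 insensitive    FALSE
#> 3 sp003   TRUE     0.686      0.686 0.429 insensitive    FALSE
#> 4 sp004   TRUE     1.08      -1.08  0.298 short_day      TRUE
#> 5 sp005   TRUE     0.163      0.163 0.318 insensitive    FALSE
#> 6 sp006   TRUE     0.295      0.295 0.403 insensitive    FALSE
#> 7 sp007   TRUE     2.23      -2.23  1.08  insensitive    FALSE
#> 8 sp008   TRUE     1.12      -1.12  0.370 short_day      TRUE
```

Each row is one species: `psm` is the metric in logit units (0 = equal
germination in all three treatments; here sp004's germination differs by
about one logit across day lengths), `signed_psm` carries the direction
(negative = higher germination under short days), `se` is the bootstrap
standard error, and `significant` marks species whose day-length response
survives a Wald test — sp004 and sp008 are short-day germinators; sp007 has
a large metric but too much uncertainty to call.

```r
traits <- simulate_trait_table(psm = scen[, c("species", "true_psm")] |>
                                 setNames(c("species", "psm")), seed = 2029)
m <- fit_weighted_gamma_glm(psm, traits, "latitude")
glance(m)
#> # A tibble: 1 × 8
#>   predictor family    pseudo_r2 lr_statistic    df p_value n_used weights_used
#> 1 latitude  gamma_log    0.0634        0.441     1   0.507      8 TRUE
```

As expected for traits simulated independently of sensitivity, the weighted
Gamma model finds no latitude association (pseudo-R² = 0.06, p = 0.51).
`plot_psm(psm)` draws the diverging per-species bar chart and
`autoplot(m)` the fitted association; `phylo_signal()` adds Pagel's λ and
Blomberg's K for a supplied newick tree. A thin command-line wrapper over
the same functions ships in `inst/cli/photosens.R`
(`Rscript inst/cli/photosens.R compute germination.csv --out psm.csv --seed 1`).

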