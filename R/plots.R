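# ggplot2 displays for the result types.

#' Diverging bar chart of signed photoperiod sensitivity
#'
#' One bar per retained species, signed by direction (positive: higher
#' germination under long days; negative: under short days), coloured by
#' whether the species' day-length response is significant, with intermediate
#' responders marked.
#'
#' @param psm_table Output of [compute_psm_table()].
#' @return A ggplot object.
#' @export
plot_psm <- function(psm_table) {
  data <- psm_table |>
    filter(.data$retained, is.finite(.data$signed_psm)) |>
    arrange(.data$signed_psm) |>
    mutate(species = factor(.data$species, levels = .data$species))
  ggplot2::ggplot(data, ggplot2::aes(x = .data$signed_psm, y = .data$species,
                                     fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(
      data = filter(data, .data$classification == "intermediate"),
      ggplot2::aes(x = .data$signed_psm, y = .data$species),
      inherit.aes = FALSE, shape = 8, colour = "orange"
    ) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "steelblue")) +
    ggplot2::labs(x = "signed photoperiod sensitivity (logit units)",
                  y = NULL, fill = "significant") +
    ggplot2::theme_minimal()
}

#' Plot fitted germination probabilities for one species
#'
#' Fitted per-treatment germination probabilities from the regularized fit
#' with approximate 95% intervals (Wald on the logit scale), alongside the
#' observed proportions.
#'
#' @param object A `species_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.species_fit <- function(object, ...) {
  x <- design_matrix()
  eta <- as.vector(x %*% object$coefficients)
  se_eta <- sqrt(diag(x %*% object$vcov %*% t(x)))
  data <- tibble(
    treatment = factor(treatment_levels(), levels = treatment_levels()),
    fitted = plogis(eta),
    lower = plogis(eta - 1.96 * se_eta),
    upper = plogis(eta + 1.96 * se_eta),
    observed = object$counts$n_germinated / pmax(object$counts$n_sown, 1)
  )
  ggplot2::ggplot(data, ggplot2::aes(x = .data$treatment)) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$fitted,
                                          ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), shape = 4,
                        size = 3, colour = "firebrick") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(title = object$species, y = "germination probability",
                  x = "day-length treatment") +
    ggplot2::theme_minimal()
}

#' Plot an association model
#'
#' Scatter (numeric predictor) or jittered strip (categorical predictor) of
#' the response against the model predictor, with the fitted mean curve for
#' numeric predictors. Point size reflects the model weight where weights are
#' used.
#'
#' @param object A `psm_association`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psm_association <- function(object, ...) {
  data <- object$data
  resp <- if (object$family == "binomial_logit") "sensitive" else "psm"
  data$.y <- data[[resp]]
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$x, y = .data$.y))
  if (is.numeric(data$x)) {
    grid <- tibble(x = seq(min(data$x), max(data$x), length.out = 100))
    grid$.fit <- predict(object$fit, newdata = grid, type = "response")
    if (object$weights_used) {
      p <- p + ggplot2::geom_point(ggplot2::aes(size = .data$weight),
                                   alpha = 0.6, show.legend = FALSE)
    } else {
      p <- p + ggplot2::geom_point(alpha = 0.6)
    }
    p <- p + ggplot2::geom_line(data = grid,
                                ggplot2::aes(x = .data$x, y = .data$.fit),
                                colour = "steelblue", linewidth = 1)
  } else {
    p <- p + ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6)
  }
  p + ggplot2::labs(x = object$predictor, y = resp) + ggplot2::theme_minimal()
}
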