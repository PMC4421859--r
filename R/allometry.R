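#' Fit the allometric power law between mass and mass-specific rate
#'
#' Estimates the scaling exponent of `q = c * M^(-beta)` (mass-specific
#' metabolic rate versus body mass) by ordinary least squares of
#' `log10(q)` on `log10(M)`; `beta` is minus the fitted slope and its
#' standard error is the OLS slope standard error. Base-10 logarithms are
#' used to match the conventional axes of allometric plots; the exponent
#' and its SE are identical under any log base. For whole-organism rate
#' `B = q * M`, the corresponding exponent is `alpha = 1 - beta`.
#'
#' @param mass Body masses in grams (positive, finite, non-constant).
#' @param q Mass-specific metabolic rates in W/g (positive, finite).
#' @return An object of class `allometry_fit` with elements `beta`,
#'   `standard_error`, `intercept` (log10 scale), `n`, `r_squared` and the
#'   underlying `lm` fit. Has [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
#' @examples
#' m <- 10^seq(0, 6, length.out = 20)
#' fit <- fit_power_law(m, 0.01 * m^-0.25)
#' fit$beta # 0.25
fit_power_law <- function(mass, q) {
  assert_numeric_finite(mass, "mass")
  assert_numeric_finite(q, "q")
  if (length(mass) != length(q)) {
    abort("`mass` and `q` must have equal length.")
  }
  if (length(mass) < 3L) {
    abort("Need n >= 3 to fit a power law.")
  }
  if (any(mass <= 0) || any(q <= 0)) {
    abort("`mass` and `q` must be strictly positive.")
  }
  lm_dat <- tibble(log_mass = log10(mass), log_q = log10(q))
  if (stats::var(lm_dat$log_mass) == 0) {
    abort("Zero variance in mass: slope is unidentifiable.")
  }
  fit <- stats::lm(log_q ~ log_mass, data = lm_dat)
  # summary.lm warns on exactly log-linear data ("essentially perfect
  # fit"); that case is legitimate here (noiseless inputs)
  sm <- suppressWarnings(summary(fit))
  structure(
    list(
      beta = -unname(coef(fit)[2]),
      standard_error = unname(sm$coefficients["log_mass", "Std. Error"]),
      intercept = unname(coef(fit)[1]),
      n = length(mass),
      r_squared = sm$r.squared,
      fit = fit,
      summary = sm,
      data = tibble(mass = mass, q = q)
    ),
    class = "allometry_fit"
  )
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf(
    "Allometric fit q ~ M^(-beta): beta = %.4f +/- %.4f (n = %d, R^2 = %.3f)\n",
    x$beta, x$standard_error, x$n, x$r_squared
  ))
  invisible(x)
}

#' @rdname fit_power_law
#' @param x An `allometry_fit` object.
#' @param ... Unused.
#' @export
tidy.allometry_fit <- function(x, ...) {
  tibble(
    term = c("intercept_log10", "beta"),
    estimate = c(x$intercept, x$beta),
    std.error = c(x$summary$coefficients[1, "Std. Error"],
                  x$standard_error)
  )
}

#' @rdname fit_power_law
#' @export
glance.allometry_fit <- function(x, ...) {
  tibble(beta = x$beta, std.error = x$standard_error,
         intercept = x$intercept, r.squared = x$r_squared, n = x$n)
}

#' @rdname fit_power_law
#' @param object An `allometry_fit` object.
#' @export
autoplot.allometry_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mass, y = .data$q)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Body mass (g)", y = "Mass-specific metabolic rate (W/g)",
      title = sprintf("q ~ M^(-%.3f ± %.3f), n = %d",
                      object$beta, object$standard_error, object$n)
    ) +
    ggplot2::theme_minimal()
}
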