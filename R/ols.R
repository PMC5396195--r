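#' Simple linear regression with F-test, R-squared and Gaussian AIC
#'
#' Ordinary least squares of one response on one predictor, computed
#' from the normal equations so that every reported quantity — slope,
#' intercept, \eqn{R^2}, the F(1, n-2) test, and the Gaussian AIC — has
#' a fixed, documented convention. The AIC is
#' \eqn{n \log(RSS/n) + 2k} with \eqn{k = 3} (slope, intercept, error
#' variance); the additive constant is omitted consistently, so only
#' AIC differences are meaningful, which is all model selection uses.
#'
#' @param data A data frame.
#' @param response,predictor Column names (strings).
#' @return An object of class `pr_ols` with components `coefficients`
#'   (intercept, slope), `std_errors`, `r_squared`, `f_stat`, `df`,
#'   `p_value`, `aic`, `n`, `residuals`, `fitted` and the model frame.
#'   Supports [tidy()], [glance()], [autoplot()] and `print()`.
#' @export
#' @examples
#' d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + rnorm(10))
#' fit <- ols_fit(d, "y", "x")
#' glance(fit)
ols_fit <- function(data, response, predictor) {
  stopifnot(is.character(response), is.character(predictor))
  x <- data[[predictor]]
  y <- data[[response]]
  if (is.null(x) || is.null(y)) {
    abort("`response` and `predictor` must name columns of `data`.")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) abort("At least 3 complete observations are required.")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) abort("Predictor is constant; slope is not identifiable.")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  res <- y - fitted
  rss <- sum(res^2)
  r2 <- if (syy == 0) 0 else 1 - rss / syy
  df2 <- n - 2L
  f <- if (rss == 0) Inf else (syy - rss) / (rss / df2)
  p <- if (is.infinite(f)) 0 else pf(f, 1, df2, lower.tail = FALSE)
  sigma2 <- rss / df2
  se_slope <- sqrt(sigma2 / sxx)
  se_int <- sqrt(sigma2 * (1 / n + mean(x)^2 / sxx))
  aic <- n * log(rss / n) + 2 * 3
  structure(
    list(coefficients = c(intercept = intercept, slope = slope),
         std_errors = c(intercept = se_int, slope = se_slope),
         r_squared = r2, f_stat = f, df = c(1L, df2), p_value = p,
         aic = aic, n = n, residuals = res, fitted = fitted,
         model = tibble(x = x, y = y),
         response = response, predictor = predictor),
    class = "pr_ols")
}

#' @export
print.pr_ols <- function(x, ...) {
  cat(sprintf("OLS: %s ~ %s  (n = %d)\n", x$response, x$predictor, x$n))
  cat(sprintf("  slope %.4g (SE %.3g), intercept %.4g\n",
              x$coefficients[["slope"]], x$std_errors[["slope"]],
              x$coefficients[["intercept"]]))
  cat(sprintf("  F(%d, %d) = %.3g, p = %.3g, R^2 = %.3f, AIC = %.2f\n",
              x$df[1], x$df[2], x$f_stat, x$p_value, x$r_squared, x$aic))
  invisible(x)
}

#' @rdname ols_fit
#' @param x A `pr_ols` object.
#' @param ... Unused.
#' @method tidy pr_ols
#' @export
tidy.pr_ols <- function(x, ...) {
  est <- unname(x$coefficients)
  se <- unname(x$std_errors)
  stat <- est / se
  tibble(
    term = c("(Intercept)", x$predictor),
    estimate = est,
    std.error = se,
    statistic = stat,
    p.value = 2 * pf(stat^2, 1, x$df[2], lower.tail = FALSE)
  )
}

#' @rdname ols_fit
#' @method glance pr_ols
#' @export
glance.pr_ols <- function(x, ...) {
  tibble(
    r.squared = x$r_squared,
    statistic = x$f_stat,
    p.value = x$p_value,
    df = x$df[1], df.residual = x$df[2],
    AIC = x$aic, nobs = x$n
  )
}

#' @rdname ols_fit
#' @param object A `pr_ols` object.
#' @method autoplot pr_ols
#' @export
autoplot.pr_ols <- function(object, ...) {
  ggplot2::ggplot(object$model, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$coefficients[["intercept"]],
                         slope = object$coefficients[["slope"]],
                         colour = "steelblue") +
    ggplot2::labs(
      x = object$predictor, y = object$response,
      subtitle = sprintf("F(%d, %d) = %.1f, p = %.3g, R² = %.2f",
                         object$df[1], object$df[2], object$f_stat,
                         object$p_value, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Fit a batch of simple regressions
#'
#' Convenience wrapper producing the flat regression table the pipeline
#' writes: one [ols_fit()] per (response, predictor) pair.
#'
#' @param data A data frame holding all columns referenced.
#' @param pairs A data frame with character columns `response` and
#'   `predictor`.
#' @return A tibble with one row per pair: `response`, `predictor`,
#'   `slope`, `intercept`, `r_squared`, `f_stat`, `df1`, `df2`,
#'   `p_value`, `aic`, `n`.
#' @export
fit_regressions <- function(data, pairs) {
  pmap(list(pairs$response, pairs$predictor), function(resp, pred) {
    fit <- ols_fit(data, resp, pred)
    tibble(response = resp, predictor = pred,
           slope = fit$coefficients[["slope"]],
           intercept = fit$coefficients[["intercept"]],
           r_squared = fit$r_squared, f_stat = fit$f_stat,
           df1 = fit$df[1], df2 = fit$df[2], p_value = fit$p_value,
           aic = fit$aic, n = fit$n)
  }) |>
    list_rbind()
}
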