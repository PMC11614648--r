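#' Fit a four-parameter logistic dose-response curve
#'
#' Fits the 4PL model
#' \deqn{y(x) = d + \frac{a - d}{1 + (x/c)^b}}
#' by nonlinear least squares, where `a` is the response as dose tends to
#' zero, `d` the response as dose tends to infinity, `c` the inflection
#' dose (at which the response is exactly `(a+d)/2`) and `b` the Hill
#' slope. Internally the model is parameterized on `log(c)` and `log(x)`
#' for conditioning; the reported parameters are on the natural dose
#' scale, and the coefficient of determination is computed on the response
#' scale against the raw points: `r2 = 1 - SSres/SStot`.
#'
#' Starting values: `a = min(response)`, `d = max(response)`, `c` at the
#' geometric mean dose, `b = 1`.
#'
#' @param data A data frame of doses and responses.
#' @param dose,response Column names (unquoted) holding dose (must be > 0;
#'   e.g. viral genomes per cell) and response (e.g. percent GFP-positive
#'   cells). Defaults `dose`, `response`.
#' @return A `fit_4pl` object: list with `coefficients` (a, d, c, b),
#'   `r2`, `data`, `n` and the underlying `nls` fit. Supports `predict()`,
#'   [inverse_4pl()], `tidy()`, `glance()` and `autoplot()`.
#' @examples
#' dr <- sim_dose_response(seed = 1)
#' fit <- fit_4pl(dr)
#' glance(fit)
#' @export
fit_4pl <- function(data, dose = dose, response = response) {
  stopifnot(is.data.frame(data))
  x <- eval_tidy(enquo(dose), data)
  y <- eval_tidy(enquo(response), data)
  if (length(x) < 4) abort("4PL fitting needs at least 4 dose-response points")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("non-finite dose or response")
  if (any(x <= 0)) abort("doses must be strictly positive")
  if (sd(y) == 0) abort("responses are constant; 4PL model is degenerate")
  df <- tibble(dose = as.numeric(x), response = as.numeric(y))
  start <- list(a = min(df$response), d = max(df$response),
                log_c = mean(log(df$dose)), b = 1)
  fit <- minpack.lm::nlsLM(
    response ~ d + (a - d) / (1 + exp(b * (log(dose) - log_c))),
    data = df, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- coef(fit)
  coefs <- c(a = unname(est["a"]), d = unname(est["d"]),
             c = exp(unname(est["log_c"])), b = unname(est["b"]))
  fitted_y <- predict(fit)
  r2 <- 1 - sum((df$response - fitted_y)^2) / sum((df$response - mean(df$response))^2)
  out <- list(coefficients = coefs, r2 = r2, data = df, n = nrow(df), fit = fit)
  class(out) <- "fit_4pl"
  out
}

#' Evaluate a fitted 4PL curve at given doses
#'
#' @param fit A `fit_4pl` object.
#' @param dose Dose(s) at which to predict (> 0).
#' @return Predicted response(s).
#' @export
predict_4pl <- function(fit, dose) {
  stopifnot(inherits(fit, "fit_4pl"))
  if (any(dose <= 0)) abort("doses must be strictly positive")
  p <- fit$coefficients
  p[["d"]] + (p[["a"]] - p[["d"]]) / (1 + (dose / p[["c"]])^p[["b"]])
}

#' @export
predict.fit_4pl <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(predict_4pl(object, object$data$dose))
  if (is.data.frame(newdata)) newdata <- newdata$dose
  predict_4pl(object, newdata)
}

#' Invert a fitted 4PL curve (dose for a target response)
#'
#' Solves `y = d + (a - d)/(1 + (x/c)^b)` for the dose:
#' `x = c * ((a - d)/(y - d) - 1)^(1/b)`. The response must lie strictly
#' between the two asymptotes.
#'
#' @param fit A `fit_4pl` object.
#' @param response Target response(s), strictly inside `(min(a,d), max(a,d))`.
#' @return Dose(s) producing the target response(s).
#' @examples
#' \dontrun{inverse_4pl(fit, 50) # dose for a 50% response}
#' @export
inverse_4pl <- function(fit, response) {
  stopifnot(inherits(fit, "fit_4pl"))
  p <- fit$coefficients
  lo <- min(p[["a"]], p[["d"]])
  hi <- max(p[["a"]], p[["d"]])
  if (any(response <= lo | response >= hi)) {
    abort(sprintf("response must lie strictly between the asymptotes (%.3f, %.3f)",
                  lo, hi))
  }
  p[["c"]] * ((p[["a"]] - p[["d"]]) / (response - p[["d"]]) - 1)^(1 / p[["b"]])
}

#' @export
print.fit_4pl <- function(x, ...) {
  p <- x$coefficients
  cat(sprintf(
    "<fit_4pl> %d points; a = %.3g, d = %.3g, c = %.4g, b = %.3g; R^2 = %.4f\n",
    x$n, p[["a"]], p[["d"]], p[["c"]], p[["b"]], x$r2))
  invisible(x)
}

#' @method tidy fit_4pl
#' @export
tidy.fit_4pl <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  se <- sm[, "Std. Error"]
  # delta method for c = exp(log_c)
  est <- x$coefficients
  tibble(
    term = c("a", "d", "c", "b"),
    estimate = unname(est[c("a", "d", "c", "b")]),
    std.error = unname(c(se["a"], se["d"], est[["c"]] * se["log_c"], se["b"]))
  )
}

#' @method glance fit_4pl
#' @export
glance.fit_4pl <- function(x, ...) {
  tibble(
    r.squared = x$r2,
    sigma = summary(x$fit)$sigma,
    df.residual = x$n - 4L,
    nobs = x$n
  )
}

#' Plot a fitted dose-response curve over its data
#'
#' @param object A `fit_4pl` object.
#' @param n_grid Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot with points and the fitted curve on a log10 dose axis.
#' @method autoplot fit_4pl
#' @export
autoplot.fit_4pl <- function(object, n_grid = 200, ...) {
  rng <- range(object$data$dose)
  grid <- tibble(dose = exp(seq(log(rng[1]), log(rng[2]), length.out = n_grid)))
  grid$response <- predict_4pl(object, grid$dose)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dose, y = .data$response)) +
    ggplot2::geom_line(data = grid, colour = "#2166ac") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose", y = "response") +
    ggplot2::theme_minimal()
}
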