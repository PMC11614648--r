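#' Fit a qPCR standard curve
#'
#' Ordinary least squares of threshold cycle on log10 template copies over
#' a serial-dilution series. Replicate Cts are averaged per dilution level
#' before regression; the per-level Ct standard deviation is kept for the
#' acceptance check. The amplification efficiency follows from the slope:
#' \deqn{E = 10^{-1/\mathrm{slope}} - 1,} so a perfect doubling per cycle
#' (slope -3.3219) gives E = 100%.
#'
#' @param data A data frame of the dilution series.
#' @param copies,ct Column names (unquoted) holding template copies per
#'   reaction (or per mL) and threshold cycle. Defaults `copies`, `ct`.
#'   Replicates are rows sharing a `copies` value.
#' @return A `standard_curve` object: list with `slope` (Ct per log10
#'   copies), `intercept`, `r2`, `efficiency` (fraction), `levels`
#'   (per-level tibble with `ct_mean`, `ct_sd`, `n`), `max_ct_sd` and the
#'   underlying `lm` fit. Supports `tidy()`, `glance()`, `autoplot()`.
#' @examples
#' sc <- fit_standard_curve(sim_standard_curve(seed = 1))
#' glance(sc)
#' @export
fit_standard_curve <- function(data, copies = copies, ct = ct) {
  stopifnot(is.data.frame(data))
  cp <- eval_tidy(enquo(copies), data)
  ctv <- eval_tidy(enquo(ct), data)
  if (any(cp <= 0)) abort("copy numbers must be strictly positive")
  df <- tibble(log10_copies = log10(as.numeric(cp)), ct = as.numeric(ctv))
  levels <- df |>
    dplyr::group_by(.data$log10_copies) |>
    dplyr::summarise(ct_mean = mean(.data$ct),
                     ct_sd = ifelse(dplyr::n() > 1, sd(.data$ct), 0),
                     n = dplyr::n(), .groups = "drop")
  if (nrow(levels) < 3) abort("a standard curve needs at least 3 dilution levels")
  if (sd(levels$ct_mean) == 0) abort("constant Ct across dilutions; no amplification signal")
  fit <- lm(ct_mean ~ log10_copies, data = levels)
  slope <- unname(coef(fit)[["log10_copies"]])
  intercept <- unname(coef(fit)[["(Intercept)"]])
  if (slope >= 0) warn("standard-curve slope is non-negative; check the input orientation")
  r2 <- suppressWarnings(summary(fit)$r.squared) # summary.lm warns on perfect fits
  out <- list(slope = slope, intercept = intercept, r2 = r2,
              efficiency = 10^(-1 / slope) - 1,
              levels = levels, max_ct_sd = max(levels$ct_sd),
              n_levels = nrow(levels), fit = fit)
  class(out) <- "standard_curve"
  out
}

#' Check a standard curve against qPCR acceptance criteria
#'
#' The defaults encode common absolute-quantification acceptance rules:
#' linearity `r2 > 0.9`, amplification efficiency within 85-100%
#' (inclusive), and a per-sample threshold-cycle standard deviation of at
#' most 0.2 cycles.
#'
#' @param curve A `standard_curve`.
#' @param r2_min Minimum r-squared (exclusive bound; default 0.9).
#' @param efficiency_range Inclusive efficiency range as fractions
#'   (default `c(0.85, 1.00)`).
#' @param ct_sd_max Maximum per-level Ct standard deviation (default 0.2).
#' @return A list of class `curve_acceptance` with `pass` (logical),
#'   `reasons` (names of failed criteria among `"linearity"`,
#'   `"efficiency"`, `"ct_sd"`) and a `checks` tibble.
#' @export
check_curve_acceptance <- function(curve, r2_min = 0.9,
                                   efficiency_range = c(0.85, 1.00),
                                   ct_sd_max = 0.2) {
  stopifnot(inherits(curve, "standard_curve"))
  checks <- tibble(
    criterion = c("linearity", "efficiency", "ct_sd"),
    value = c(curve$r2, curve$efficiency, curve$max_ct_sd),
    requirement = c(sprintf("r2 > %g", r2_min),
                    sprintf("%g%% <= E <= %g%%", 100 * efficiency_range[1],
                            100 * efficiency_range[2]),
                    sprintf("max per-level Ct SD <= %g", ct_sd_max)),
    pass = c(curve$r2 > r2_min,
             curve$efficiency >= efficiency_range[1] &
               curve$efficiency <= efficiency_range[2],
             curve$max_ct_sd <= ct_sd_max)
  )
  out <- list(pass = all(checks$pass),
              reasons = checks$criterion[!checks$pass],
              checks = checks)
  class(out) <- "curve_acceptance"
  out
}

#' @export
print.curve_acceptance <- function(x, ...) {
  cat(sprintf("<curve_acceptance> %s\n", if (x$pass) "PASS" else
    paste("FAIL:", paste(x$reasons, collapse = ", "))))
  print(x$checks)
  invisible(x)
}

#' Absolute quantification from a standard curve
#'
#' Converts observed threshold cycles to template copies via the fitted
#' curve, `copies = 10^((ct - intercept)/slope)`, then applies the dilution
#' factor and volume scaling to express the result as a titer (e.g. copies
#' per mL of the original preparation). A warning is attached when the
#' curve fails its acceptance criteria.
#'
#' @param ct Observed threshold cycle(s).
#' @param curve A `standard_curve`.
#' @param dilution_factor Fold dilution applied before qPCR (default 1).
#' @param volume_scale Factor converting per-reaction copies to the
#'   reporting volume (default 1).
#' @param acceptance Optional precomputed [check_curve_acceptance()]
#'   result.
#' @return Numeric vector of copy numbers on the reporting scale.
#' @export
quantify_titer <- function(ct, curve, dilution_factor = 1, volume_scale = 1,
                           acceptance = NULL) {
  stopifnot(inherits(curve, "standard_curve"))
  acceptance <- acceptance %||% check_curve_acceptance(curve)
  if (!acceptance$pass) {
    warn(sprintf("standard curve fails acceptance (%s); titers are unreliable",
                 paste(acceptance$reasons, collapse = ", ")))
  }
  10^((ct - curve$intercept) / curve$slope) * dilution_factor * volume_scale
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> %d levels; slope %.4f Ct/log10, intercept %.2f, r2 = %.4f, efficiency = %.1f%%, max Ct SD = %.3f\n",
    x$n_levels, x$slope, x$intercept, x$r2, 100 * x$efficiency, x$max_ct_sd))
  invisible(x)
}

#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = unname(sm[, "Std. Error"]))
}

#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(r.squared = x$r2, slope = x$slope, intercept = x$intercept,
         efficiency = x$efficiency, max_ct_sd = x$max_ct_sd,
         n_levels = x$n_levels)
}

#' Plot a standard curve
#'
#' @param object A `standard_curve`.
#' @param ... Unused.
#' @return A ggplot of mean Ct against log10 copies with the fitted line.
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$levels,
                  ggplot2::aes(x = .data$log10_copies, y = .data$ct_mean)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#2166ac") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ct_mean - .data$ct_sd,
                                          ymax = .data$ct_mean + .data$ct_sd)) +
    ggplot2::labs(x = "log10 template copies", y = "threshold cycle (Ct)") +
    ggplot2::theme_minimal()
}
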