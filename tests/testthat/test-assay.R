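test_that("noise-free 4PL data is recovered essentially exactly", {
  dat <- sim_dose_response(a = 2, d = 90, c = 4e4, b = 1.5)
  fit <- fit_4pl(dat)
  p <- fit$coefficients
  expect_equal(unname(p["a"]), 2, tolerance = 1e-6)
  expect_equal(unname(p["d"]), 90, tolerance = 1e-6)
  expect_equal(unname(p["c"]), 4e4, tolerance = 1e-6)
  expect_equal(unname(p["b"]), 1.5, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("parameter recovery holds across seeded noise-free draws", {
  withr::local_seed(88)
  for (i in 1:25) {
    a <- runif(1, 0, 10); d <- runif(1, 60, 100)
    cc <- 10^runif(1, 3.8, 4.8); b <- runif(1, 0.7, 2.5)
    dat <- sim_dose_response(a = a, d = d, c = cc, b = b,
                             doses = 10^seq(3, 5.7, length.out = 9))
    fit <- fit_4pl(dat)
    expect_equal(unname(fit$coefficients["c"]), cc, tolerance = 1e-4)
    expect_equal(unname(fit$coefficients["b"]), b, tolerance = 1e-4)
  }
})

test_that("the inflection dose returns the mid-response and inversion round-trips", {
  dat <- sim_dose_response(a = 5, d = 85, c = 3e4, b = 1.2)
  fit <- fit_4pl(dat)
  p <- fit$coefficients
  expect_equal(predict_4pl(fit, p[["c"]]), (p[["a"]] + p[["d"]]) / 2,
               tolerance = 1e-9)
  expect_equal(inverse_4pl(fit, (p[["a"]] + p[["d"]]) / 2), p[["c"]],
               tolerance = 1e-9)
  withr::local_seed(19)
  doses <- 10^runif(10, 3.2, 5.5)
  expect_equal(inverse_4pl(fit, predict_4pl(fit, doses)), doses,
               tolerance = 1e-9)
  expect_error(inverse_4pl(fit, p[["d"]]), "strictly between")
  expect_error(inverse_4pl(fit, p[["a"]] - 1), "strictly between")
  expect_error(predict_4pl(fit, -5), "positive")
})

test_that("predictions are monotone when b > 0 and d > a", {
  dat <- sim_dose_response(a = 2, d = 90, c = 4e4, b = 1.5)
  fit <- fit_4pl(dat)
  grid <- 10^seq(2, 6, length.out = 200)
  expect_true(all(diff(predict_4pl(fit, grid)) >= 0))
})

test_that("noisy replicates recover the inflection dose within 10% median error", {
  rel_err <- vapply(1:200, function(i) {
    dat <- sim_dose_response(a = 2, d = 90, c = 4e4, b = 1.5,
                             noise_sd = 2, seed = 5000 + i)
    fit <- fit_4pl(dat)
    abs(fit$coefficients[["c"]] - 4e4) / 4e4
  }, numeric(1))
  expect_lt(median(rel_err), 0.10)
})

test_that("degenerate dose-response inputs are rejected", {
  expect_error(fit_4pl(tibble::tibble(dose = c(1, 2, 3), response = c(1, 2, 3))),
               "at least 4")
  expect_error(fit_4pl(tibble::tibble(dose = c(1, 2, 3, 4),
                                      response = rep(5, 4))), "constant")
  expect_error(fit_4pl(tibble::tibble(dose = c(-1, 2, 3, 4),
                                      response = c(1, 2, 3, 4))), "positive")
})

test_that("a perfect doubling dilution series gives 100% efficiency", {
  # slope exactly -1/log10(2): Ct rises one cycle per halving
  copies <- 10^(9:4)
  ct <- 10 - (-1 / log10(2)) * (9 - log10(copies))
  curve <- fit_standard_curve(tibble::tibble(copies = copies, ct = ct))
  expect_equal(curve$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(100 * curve$efficiency, 100, tolerance = 0.1)
  expect_equal(curve$r2, 1, tolerance = 1e-12)
})

test_that("generated standard curves recover their efficiency", {
  noisefree <- fit_standard_curve(sim_standard_curve(efficiency = 0.92))
  expect_equal(noisefree$efficiency, 0.92, tolerance = 1e-6)
  noisy <- fit_standard_curve(sim_standard_curve(efficiency = 0.92,
                                                 noise_sd = 0.05, seed = 42))
  expect_equal(100 * noisy$efficiency, 92, tolerance = 2 / 92)
})

test_that("efficiency decreases strictly with |slope|", {
  slopes <- seq(-4.2, -3.0, by = 0.2)
  effs <- 10^(-1 / slopes) - 1
  expect_true(all(diff(effs[order(abs(slopes))]) < 0))
  # and through the fitting path
  e1 <- fit_standard_curve(sim_standard_curve(efficiency = 0.85))$efficiency
  e2 <- fit_standard_curve(sim_standard_curve(efficiency = 1.00))$efficiency
  expect_lt(e1, e2)
})

test_that("degenerate dilution series are rejected", {
  expect_error(fit_standard_curve(tibble::tibble(copies = c(1e4, 1e5),
                                                 ct = c(30, 27))), "3 dilution")
  expect_error(fit_standard_curve(tibble::tibble(copies = 10^(4:9),
                                                 ct = rep(20, 6))), "constant Ct")
})

test_that("curve acceptance applies the documented truth table", {
  mk_curve <- function(r2, eff, ct_sd) {
    structure(list(slope = -1 / log10(1 + eff), intercept = 38, r2 = r2,
                   efficiency = eff, max_ct_sd = ct_sd,
                   levels = tibble::tibble(), n_levels = 6, fit = NULL),
              class = "standard_curve")
  }
  good <- check_curve_acceptance(mk_curve(0.95, 0.92, 0.1))
  expect_true(good$pass)
  expect_length(good$reasons, 0)

  bad_eff <- check_curve_acceptance(mk_curve(0.95, 1.04, 0.1))
  expect_false(bad_eff$pass)
  expect_equal(bad_eff$reasons, "efficiency")

  bad_sd <- check_curve_acceptance(mk_curve(0.95, 0.92, 0.25))
  expect_false(bad_sd$pass)
  expect_equal(bad_sd$reasons, "ct_sd")

  bad_r2 <- check_curve_acceptance(mk_curve(0.85, 0.92, 0.1))
  expect_false(bad_r2$pass)
  expect_equal(bad_r2$reasons, "linearity")

  # boundary cases are inclusive for efficiency and ct_sd
  expect_true(check_curve_acceptance(mk_curve(0.95, 0.85, 0.2))$pass)
  expect_true(check_curve_acceptance(mk_curve(0.95, 1.00, 0.2))$pass)
})

test_that("titer quantification inverts the generating curve", {
  curve <- fit_standard_curve(sim_standard_curve(efficiency = 0.95))
  ct_1e6 <- curve$intercept + curve$slope * 6
  expect_equal(quantify_titer(ct_1e6, curve), 1e6, tolerance = 0.01)
  expect_equal(quantify_titer(curve$intercept, curve), 1, tolerance = 1e-6)
  expect_equal(quantify_titer(ct_1e6, curve, dilution_factor = 10),
               1e7, tolerance = 0.01)
  expect_equal(quantify_titer(ct_1e6, curve, volume_scale = 50),
               5e7, tolerance = 0.01)
})

test_that("an unaccepted curve attaches a warning to titers", {
  curve <- fit_standard_curve(sim_standard_curve(efficiency = 1.5))
  expect_warning(quantify_titer(20, curve), "acceptance")
})

test_that("densitometry normalization is a guarded ratio", {
  expect_equal(densitometry_normalize(5, 5), 1)
  expect_equal(densitometry_normalize(c(2, 4), c(2, 2)), c(1, 2))
  expect_equal(densitometry_normalize(3 * 2.5, 4 * 2.5),
               densitometry_normalize(3, 4))
  expect_error(densitometry_normalize(1, 0), "positive")
})

test_that("fold changes round to the reporting convention", {
  expect_equal(fold_change(253, 158), 1.6)
  expect_equal(fold_change(39898, 15484), 2.6)
  expect_equal(fold_change(7, 7, 3), 1)
  expect_error(fold_change(1, 0), "positive")
})

test_that("tidy and glance expose fit summaries", {
  fit <- fit_4pl(sim_dose_response(noise_sd = 1, seed = 3))
  td <- generics::tidy(fit)
  expect_equal(td$term, c("a", "d", "c", "b"))
  expect_true(all(is.finite(td$std.error)))
  gl <- generics::glance(fit)
  expect_equal(gl$nobs, 6)
  curve <- fit_standard_curve(sim_standard_curve(noise_sd = 0.05, seed = 8))
  expect_equal(generics::tidy(curve)$term, c("intercept", "slope"))
  expect_true(generics::glance(curve)$r.squared > 0.99)
})
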