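# Standard-addition estimator, composition regressions, blend prediction.

test_that("standard-addition estimator inverts the inhibition-duration law", {
  est <- estimate_Ri_over_n(0, 4.72e4, pg_molar = 2.36e-3)
  expect_equal(est$Ri_over_n, 5.0e-8, tolerance = 1e-9)
  expect_false(est$censored)
  # PG ineffective: censored result, not an error
  est0 <- estimate_Ri_over_n(5e4, 5e4, pg_molar = 2.36e-3)
  expect_true(est0$censored)
  expect_true(is.na(est0$Ri_over_n))
  # round trip through the duration law: tau_PG - tau = n*[PG]/Ri with
  # Ri = n*x gives back x
  x <- 3.7e-8; n <- 2; pg <- 2.36e-3
  p <- kinetic_params(AH0 = pg, Ri = n * x, n = n)
  expect_equal(estimate_Ri_over_n(0, inhibition_duration(p), pg)$Ri_over_n, x,
               tolerance = 1e-12)
  # scale consistency: doubling the dose doubles the predicted extension,
  # and the estimator inverts it exactly
  ext1 <- n * pg / (n * x); ext2 <- n * (2 * pg) / (n * x)
  expect_equal(ext2, 2 * ext1)
  expect_equal(estimate_Ri_over_n(0, ext2, 2 * pg)$Ri_over_n, x,
               tolerance = 1e-12)
})

test_that("published steady-rate models evaluate correctly", {
  expect_identical(predict_rst("unsaturation",
                               c(MO_pct = 0, DI_pct = 0, TRI_pct = 0)), 20.1)
  expect_identical(predict_rst("unsaturation_acidity",
                               c(MO_pct = 0, DI_pct = 0, TRI_pct = 0,
                                 acidity_mgKOH_g = 0)), 9.82)
  expect_equal(predict_rst("unsaturation", c(MO_pct = 100)), 77.1)
  # positive TRI coefficient: more polyunsaturation, faster oxidation
  lo <- predict_rst("unsaturation", c(MO_pct = 10, DI_pct = 10, TRI_pct = 5))
  hi <- predict_rst("unsaturation", c(MO_pct = 10, DI_pct = 10, TRI_pct = 10))
  expect_gt(hi, lo)
  expect_error(predict_rst("nope", c(MO_pct = 1)), "unknown reference model")
})

test_that("steady-rate regression reproduces a noiseless generating model exactly", {
  panel <- generate_oil_panel(panel_generator_config(n_oils = 12, seed = 31,
                                                     noise_rel = 0))
  fit <- fit_rst_model(panel, include_acidity = TRUE)
  truth <- rst_reference_models()$unsaturation_acidity
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  pred <- predict(fit, panel)
  expect_equal(pred, panel$R_st_nmol_s, tolerance = 1e-6)
})

test_that("steady-rate regression recovers generating coefficients under noise", {
  panel <- generate_oil_panel(panel_generator_config(n_oils = 30, seed = 32))
  fit <- fit_rst_model(panel, include_acidity = TRUE)
  truth <- rst_reference_models()$unsaturation_acidity
  expect_true(all(abs(coef(fit) - truth) <= 3 * fit$se_robust))
  expect_gt(fit$r2, 0.8)
})

test_that("steady-rate regression rejects degenerate panels", {
  panel <- generate_oil_panel(panel_generator_config(n_oils = 12, seed = 33))
  panel$DI_pct <- 2 * panel$MO_pct  # exact collinearity
  expect_error(fit_rst_model(panel), "collinear")
  small <- generate_oil_panel(panel_generator_config(n_oils = 12, seed = 33))
  expect_error(fit_rst_model(small[1:4, ]), "at least")
  holey <- generate_oil_panel(panel_generator_config(n_oils = 12, seed = 33))
  holey$R_st_nmol_s[1:2] <- NA
  expect_message(f <- fit_rst_model(holey), "dropped 2")
  expect_equal(f$n_obs, 10)
})

test_that("hyperbolic PG-effect fit recovers exact and noisy generating values", {
  exact <- generate_pg_effect_panel(20, seed = 41, noise_rel = 0)
  f <- fit_pg_effect_hyperbolic(exact)
  expect_rel(unname(coef(f)["a"]), 3.0e4, 1e-6)
  expect_rel(unname(coef(f)["b"]), 0.080, 1e-6)
  noisy <- generate_pg_effect_panel(20, seed = 42, noise_rel = 0.05)
  fn <- fit_pg_effect_hyperbolic(noisy)
  expect_rel(unname(coef(fn)["a"]), 3.0e4, 0.10)
  # shape: the effect diverges as bis-allylic -> 0 when b -> 0
  small_b <- list(coefficients = c(a = 3e4, b = 1e-6))
  class(small_b) <- c("pg_hyperbolic_fit", "oxkin_fit")
  expect_gt(predict(small_b, 1e-5) / predict(small_b, 1), 1e4)
})

test_that("reciprocal PG-effect fit recovers the line and flags planted outliers", {
  exact <- generate_pg_effect_panel(20, seed = 43, ba_range = c(0.3, 3),
                                    model = "reciprocal", noise_rel = 0)
  f <- fit_pg_effect_linear_reciprocal(exact)
  expect_rel(unname(coef(f)["slope"]), 1.2e-4, 1e-6)
  expect_rel(abs(unname(coef(f)["intercept"])), 2.2e-5, 1e-5)
  expect_length(f$outlier_ids, 0)
  # displace one oil's effect tenfold: it must be flagged and excluded
  tampered <- exact
  tampered$tau_PG_s[7] <- tampered$tau_PG_s[7] / 10
  ft <- fit_pg_effect_linear_reciprocal(tampered)
  expect_identical(ft$outlier_ids, tampered$oil_id[7])
  expect_rel(unname(coef(ft)["slope"]), 1.2e-4, 0.02)
  noisy <- generate_pg_effect_panel(20, seed = 44, ba_range = c(0.3, 3),
                                    model = "reciprocal", noise_rel = 0.05)
  fn <- fit_pg_effect_linear_reciprocal(noisy)
  expect_rel(unname(coef(fn)["slope"]), 1.2e-4, 0.15)
})

test_that("hyperbolic and reciprocal parameterizations agree on shared data", {
  panel <- generate_pg_effect_panel(24, seed = 45, ba_range = c(0.3, 3),
                                    noise_rel = 0.05)
  fh <- fit_pg_effect_hyperbolic(panel)
  fr <- fit_pg_effect_linear_reciprocal(panel)
  xs <- seq(0.5, 2.5, by = 0.25)  # central range
  pred_h <- predict(fh, xs)
  pred_r <- 1 / predict(fr, xs)
  expect_true(all(abs(pred_h - pred_r) / pred_h < 0.25))
})

test_that("PG-effect fits honour exclusions and refuse starved panels", {
  panel <- generate_pg_effect_panel(8, seed = 46)
  panel$excluded_flag[1:4] <- TRUE
  expect_error(fit_pg_effect_hyperbolic(panel), "usable oils")
  expect_error(fit_pg_effect_hyperbolic(panel[0, ]), "usable oils|lacks")
})

test_that("blend prediction follows the pooled-antioxidant mixing rule", {
  comps <- data.frame(tau_s = c(8e4, 0), Ri_over_n = c(5e-8, 5e-8),
                      MO_pct = c(40, 20), DI_pct = c(10, 30),
                      TRI_pct = c(0, 5), acidity_mgKOH_g = c(0.5, 1))
  # degenerate blends return the pure component
  expect_equal(predict_blend(comps, c(1, 0))$tau_s, 8e4)
  expect_equal(predict_blend(comps, c(0, 1))$tau_s, 0)
  # equal initiation rates: tau mixes linearly
  expect_equal(predict_blend(comps, c(0.5, 0.5))$tau_s, 4e4)
  # high-initiation partner drains the antioxidant pool:
  # tau = tau_stable * R_stable / (R_stable + R_high) at 1:1
  drain <- comps; drain$Ri_over_n[2] <- 5e-7
  expect_equal(predict_blend(drain, c(0.5, 0.5))$tau_s,
               8e4 * 5e-8 / (5e-8 + 5e-7))
  expect_match(predict_blend(drain, c(0.5, 0.5))$rationale, "draining")
  expect_match(predict_blend(comps, c(0.5, 0.5))$rationale, "stabilizable")
  # monotone in the stable fraction
  taus <- vapply(seq(0, 1, by = 0.25),
                 function(f) predict_blend(comps, c(f, 1 - f))$tau_s, 1)
  expect_true(all(diff(taus) > 0))
  # R_st from the composition-mixed model
  b <- predict_blend(comps, c(0.5, 0.5))
  expect_equal(b$R_st_nmol_s,
               predict_rst("unsaturation_acidity",
                           c(MO_pct = 30, DI_pct = 20, TRI_pct = 2.5,
                             acidity_mgKOH_g = 0.75)))
  expect_error(predict_blend(comps, c(0.6, 0.6)), "sum to 1")
  nori <- comps; nori$Ri_over_n <- NULL
  expect_warning(q <- predict_blend(nori, c(0.5, 0.5)), "qualitative")
  expect_true(is.na(q$tau_s))
})
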