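test_that("fit recovers log-linear truth within standard errors", {
  tr <- loglinear_truth(a = -7.5, b = 2, c = 0.03, S = 0.12, L = 1)
  coh <- generate_cohort(cohort_config(n_per_sex = 2000, seed = 21), tr)
  fit <- quiet_fit(coh, lms_spec("fev1", "male", df_m = 0))
  expect_true(fit$converged)
  cf <- coef(fit)
  expect_lt(abs(cf$estimate[cf$term == "b"] - 2), 3 * cf$se[cf$term == "b"])
  expect_lt(abs(cf$estimate[cf$term == "c"] - 0.03),
            3 * cf$se[cf$term == "c"])
  # fitted S within 10% relative error, L near 1
  p <- spirolms:::eval_lms_curves(fit$curves, 40, 170)
  expect_lt(abs(p$S - 0.12) / 0.12, 0.10)
  expect_lt(abs(p$L - 1), 0.5)
})

test_that("refitting identical data is deterministic", {
  coh <- generate_cohort(cohort_config(n_per_sex = 200, seed = 3))
  f1 <- quiet_fit(coh, lms_spec("fvc", "female", df_m = 2))
  f2 <- quiet_fit(coh, lms_spec("fvc", "female", df_m = 2))
  expect_equal(f1$aic, f2$aic, tolerance = 1e-6)
  expect_identical(f1$coef, f2$coef)
})

test_that("rescaling the measurand scales M and leaves S, L unchanged", {
  coh <- generate_cohort(cohort_config(n_per_sex = 400, seed = 13))
  k <- 2.5
  coh2 <- coh; coh2$fev1 <- coh2$fev1 * k
  f1 <- quiet_fit(coh, lms_spec("fev1", "male", df_m = 2))
  f2 <- quiet_fit(coh2, lms_spec("fev1", "male", df_m = 2))
  ages <- seq(10, 75, by = 5); hts <- height_mean_grid(ages, "male")
  p1 <- spirolms:::eval_lms_curves(f1$curves, ages, hts)
  p2 <- spirolms:::eval_lms_curves(f2$curves, ages, hts)
  expect_equal(p2$M, k * p1$M, tolerance = 1e-3)
  expect_equal(p2$S, p1$S, tolerance = 1e-2)
  expect_equal(p2$L, p1$L, tolerance = 0.05)
})

test_that("the block optimizer's objective never decreases", {
  coh <- generate_cohort(cohort_config(n_per_sex = 300, seed = 17))
  for (ix in c("fev1", "fev1_fvc")) {
    fit <- quiet_fit(coh, lms_spec(ix, "female", df_m = 3))
    expect_true(all(diff(fit$iter_loglik) >= -1e-8))
  }
})

test_that("adding spline df never lowers the maximized log-likelihood", {
  coh <- generate_cohort(cohort_config(n_per_sex = 300, seed = 19))
  lls <- sapply(c(0, 2, 4), function(df)
    quiet_fit(coh, lms_spec("fev1", "male", df_m = df))$loglik)
  expect_true(all(diff(lls) >= -1e-4))
})

test_that("selection prefers the parsimonious model under flat truth", {
  tr <- loglinear_truth()
  coh <- generate_cohort(cohort_config(n_per_sex = 600, seed = 23), tr)
  sel <- select_lms(coh, lms_spec_grid("fev1", "male",
                                       df_m_grid = c(0, 2, 4)))
  expect_equal(sel$model$spec$df_m, 0)
  expect_equal(nrow(sel$table), 3)
  # the AIC column is definitional
  expect_equal(sel$table$aic, -2 * sel$table$loglik + 2 * sel$table$edf)
  expect_equal(sum(sel$table$selected), 1)
})

test_that("single-spec selection returns that fit unchanged", {
  coh <- generate_cohort(cohort_config(n_per_sex = 200, seed = 29))
  spec <- lms_spec("fvc", "male", df_m = 1)
  sel <- select_lms(coh, list(spec))
  direct <- quiet_fit(coh, spec)
  expect_equal(sel$model$aic, direct$aic, tolerance = 1e-8)
  expect_equal(nrow(sel$table), 1)
})

test_that("residual z-scores of a well-specified fit are standard normal", {
  coh <- generate_cohort(cohort_config(n_per_sex = 5000, seed = 37))
  fit <- quiet_fit(coh, lms_spec("fev1", "female", df_m = 3))
  dg <- diagnose(fit, coh)
  expect_equal(length(dg$residual_z), fit$n_obs)
  expect_lt(abs(mean(dg$residual_z)), 0.05)
  expect_gt(sd(dg$residual_z), 0.95)
  expect_lt(sd(dg$residual_z), 1.05)
  expect_lt(dg$max_abs_residual_z, 5)
  # central Q-Q points sit on the identity line
  cen <- abs(dg$qq_points$theoretical) <= 2.33
  expect_lt(max(abs(dg$qq_points$observed[cen] -
                      dg$qq_points$theoretical[cen])), 0.1)
})

test_that("parametric-bootstrap residuals respect the +/-5 bound", {
  coh <- generate_cohort(cohort_config(n_per_sex = 2500, seed = 41))
  fit <- quiet_fit(coh, lms_spec("fev1", "male", df_m = 3))
  # fresh draws from the fitted model itself at the cohort's covariates
  d <- coh[coh$sex == "M", ]
  p <- spirolms:::eval_lms_curves(fit$curves, d$age, d$height)
  d$fev1 <- rbccg(nrow(d), p$M, p$S, p$L, seed = 99)
  dg <- diagnose(fit, d)
  expect_lt(dg$max_abs_residual_z, 5)
})

test_that("non-convergence is flagged loudly, never silently", {
  coh <- generate_cohort(cohort_config(n_per_sex = 150, seed = 43))
  expect_warning(
    fit <- fit_lms(coh, lms_spec("fev1", "male", df_m = 2),
                   control = lms_control(max_outer = 1, outer_tol = 0)),
    "convergence")
  expect_false(fit$converged)
})

test_that("degenerate inputs are dropped with a message or refused", {
  coh <- generate_cohort(cohort_config(n_per_sex = 150, seed = 47))
  coh$fev1[1:10] <- NA
  coh$fev1[11:12] <- -1
  expect_message(fit <- fit_lms(coh, lms_spec("fev1", "male", df_m = 1)),
                 "dropped 12")
  expect_equal(fit$n_obs, 138)
  expect_error(fit_lms(coh[1:60, ], lms_spec("fev1", "female")),
               "at least 50")
  expect_error(fit_lms(coh, lms_spec("pef", "male")), "not found")
  expect_error(lms_spec("fev1", "male", df_m = -1), "non-negative")
})

test_that("the FEV1/FVC spec drops the height term by default", {
  s <- lms_spec("fev1_fvc", "female")
  expect_false(s$include_height)
  expect_true(lms_spec("fev1", "female")$include_height)
  # override allowed
  expect_true(lms_spec("fev1_fvc", "female", include_height = TRUE)$include_height)
})
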