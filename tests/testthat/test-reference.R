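test_that("lln matches its closed forms", {
  # L = 1 collapses to M*(1 - 1.645*S)
  expect_equal(lln(3, 0.1, 1), 3 * (1 - 0.1645))
  expect_equal(lln(3, 0.1, 1), 2.5065)
  # general form, evaluated directly
  expect_equal(lln(3, 0.12, 0.8),
               exp(log(3) + log(1 - 1.645 * 0.8 * 0.12) / 0.8),
               tolerance = 1e-12)
  # lognormal limit
  expect_equal(lln(3, 0.12, 0), 3 * exp(-1.645 * 0.12))
  expect_error(lln(3, 0.4, 2), "1 - 1.645")
})

test_that("lln agrees with the exact 5th centile over fitted ranges", {
  # spirometry-like (L, S): L*S small, difference only the rounded 1.645
  grid <- expand.grid(M = c(1, 3, 6), S = c(0.05, 0.1, 0.15),
                      L = c(0.6, 0.8, 1, 1.2, 1.4, 2))
  grid <- grid[grid$L * grid$S <= 0.25, ]
  rel <- with(grid, abs(lln(M, S, L) - qbccg(0.05, M, S, L)) /
                      lln(M, S, L))
  expect_lt(max(rel), 1e-4)
})

test_that("a large sample puts five percent of draws below the LLN", {
  x <- rbccg(2e4, 3, 0.12, 0.8, seed = 11)
  frac <- mean(x < lln(3, 0.12, 0.8))
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 2e4))
})

test_that("the linear Z-score hits its three algebraic anchors", {
  M <- 3.2; l <- lln(M, 0.13, 0.9)
  expect_equal(zscore_paper(M, M, l), 0)
  expect_equal(zscore_paper(l, M, l), -1.645, tolerance = 1e-12)
  expect_equal(zscore_paper(2 * M - l, M, l), 1.645, tolerance = 1e-12)
  expect_error(zscore_paper(3, 2, 2.5), "predicted > LLN")
})

test_that("linear and exact Z agree at the anchors and within 0.25 between", {
  # parameter grid of fitted spirometry-like models
  grid <- expand.grid(M = c(1, 3, 6), S = c(0.05, 0.1, 0.15),
                      L = c(0.6, 0.8, 1, 1.2, 1.4))
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    M <- grid$M[i]; S <- grid$S[i]; L <- grid$L[i]
    l <- lln(M, S, L)
    # exact agreement where the formulas are algebraically tied
    expect_equal(zscore_paper(M, M, l), bccg_z(M, M, S, L))
    z_ex <- seq(-2, 2, length.out = 41)
    y <- qbccg(pnorm(z_ex), M, S, L)
    dz <- abs(zscore_paper(y, M, l) - z_ex)
    worst <- max(worst, max(dz))
  }
  expect_lt(worst, 0.25)
})

test_that("per-subject predictions honour the Z and percentile anchors", {
  coh <- generate_cohort(cohort_config(n_per_sex = 300, seed = 51))
  fit <- quiet_fit(coh, lms_spec("fev1", "male", df_m = 2))
  d <- coh[coh$sex == "M", ][1:20, ]
  base <- quiet_predict(fit, d)
  # observed equal to the predicted median
  d_m <- d; d_m$fev1 <- base$M
  pm <- quiet_predict(fit, d_m)
  expect_equal(pm$Z, rep(0, 20))
  expect_equal(pm$percentile, rep(50, 20), tolerance = 1e-8)
  # observed equal to the LLN
  d_l <- d; d_l$fev1 <- base$LLN
  pl <- quiet_predict(fit, d_l)
  expect_equal(pl$Z, rep(-1.645, 20))
  expect_equal(pl$percentile, rep(5, 20), tolerance = 0.05)
  expect_true(all(pl$z_mode == "paper"))
  # exact mode uses the BCCG transform
  pe <- quiet_predict(fit, d_l, z_mode = "exact")
  expect_equal(pe$percentile, rep(5, 20), tolerance = 0.05)
})

test_that("predictions are calibrated under the model's own draws", {
  coh <- generate_cohort(cohort_config(n_per_sex = 1500, seed = 53))
  fit <- quiet_fit(coh, lms_spec("fev1", "female", df_m = 3))
  d <- coh[coh$sex == "F", ]
  d <- d[rep(seq_len(nrow(d)), length.out = 3e4), ]
  p <- spirolms:::eval_lms_curves(fit$curves, d$age, d$height)
  d$fev1 <- rbccg(nrow(d), p$M, p$S, p$L, seed = 55)
  pr <- quiet_predict(fit, d, z_mode = "paper")
  expect_lt(abs(mean(pr$Z)), 0.02)
  expect_lt(abs(mean(pr$percentile) - 50), 0.5)
})

test_that("subjects outside the fitted hull are flagged, not refused", {
  coh <- generate_cohort(cohort_config(n_per_sex = 200, seed = 57))
  fit <- quiet_fit(coh, lms_spec("fev1", "male", df_m = 2))
  nd <- data.frame(age = c(30, 99), height = c(175, 175))
  expect_warning(pr <- predict(fit, nd), "extrapolation")
  expect_equal(pr$extrapolated, c(FALSE, TRUE))
  expect_error(predict(fit, data.frame(age = -1, height = 170)), "positive")
})

test_that("lookup tables are consistent with per-subject prediction", {
  coh <- generate_cohort(cohort_config(n_per_sex = 300, seed = 59))
  fit <- quiet_fit(coh, lms_spec("fev1", "male", df_m = 2))
  tab1 <- suppressWarnings(lookup_table(fit, ages = 40, heights = 170))
  pr <- quiet_predict(fit, data.frame(age = 40, height = 170))
  expect_equal(tab1$M, pr$M)
  expect_equal(tab1$LLN, pr$LLN)
  expect_equal(tab1$S, pr$S)
  # full default grid: LLN < M everywhere, M monotone in height (b > 0)
  tab <- suppressWarnings(lookup_table(fit))
  expect_true(all(tab$LLN < tab$M))
  one_age <- tab[tab$age == tab$age[1], ]
  expect_true(all(diff(one_age$M[order(one_age$height)]) > 0))
  # refining the grid leaves shared points untouched
  dense <- suppressWarnings(
    lookup_table(fit, ages = seq(20, 40, by = 0.5), heights = 170))
  coarse <- suppressWarnings(
    lookup_table(fit, ages = seq(20, 40, by = 1), heights = 170))
  expect_equal(dense[dense$age %in% coarse$age, "M"], coarse$M)
  expect_error(lookup_table(fit, ages = numeric(0)), "empty")
})
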