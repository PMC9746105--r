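# Shared fixtures: small custom truths and study-scale cohort builders.

# a truth with constant (M, S, L) for every index, identical in both sexes
constant_truth <- function(M = 3, S = 0.1, L = 1,
                           indices = c("fev1", "fvc", "fev1_fvc", "fef2575")) {
  cs <- lapply(indices, function(ix)
    lms_curves(a = log(M), s_intercept = log(S), l_intercept = L))
  names(cs) <- indices
  make_truth(male = cs, female = cs)
}

# a truth with log-linear M in height and age, no spline curvature
loglinear_truth <- function(a = -7.5, b = 2, c = 0.03, S = 0.12, L = 1) {
  cs <- list(fev1 = lms_curves(a = a, b = b, c = c,
                               s_intercept = log(S), l_intercept = L))
  make_truth(male = cs, female = cs)
}

# emulate the unequal study sex sizes (418 females, 204 males)
study_cohort <- function(seed, n_f = 418, n_m = 204) {
  a <- generate_cohort(cohort_config(n_per_sex = n_f, seed = seed))
  b <- generate_cohort(cohort_config(n_per_sex = n_m, seed = seed + 10000))
  rbind(a[a$sex == "F", ], b[b$sex == "M", ])
}

height_mean_grid <- function(ages, sex) spirolms:::height_mean(ages, sex)

# quietly fit (drops the hull-extrapolation warnings irrelevant in tests)
quiet_fit <- function(...) suppressMessages(fit_lms(...))
quiet_predict <- function(...) suppressWarnings(predict(...))
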