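#' @importFrom splines ns
NULL

# ---- LMS curve sets -------------------------------------------------------
# A "curve set" holds the three LMS curves for one (index, sex):
#   mu:    M = exp(a + b*log(height) + c*log(age) + spline(age))
#   sigma: S = exp(intercept + ln_age*log(age) + spline(age))
#   nu:    L = intercept + spline(age)
# Splines are natural cubic bases stored as (knots, boundary, coef) so a
# curve set is a plain, serialisable parameter list.

spline_spec <- function(knots, boundary, coef) {
  stopifnot(length(boundary) == 2, length(coef) == length(knots) + 1L)
  list(knots = as.numeric(knots), boundary = as.numeric(boundary),
       coef = as.numeric(coef))
}

eval_spline <- function(sp, age) {
  if (is.null(sp)) return(rep(0, length(age)))
  B <- splines::ns(age, knots = sp$knots, Boundary.knots = sp$boundary)
  drop(B %*% sp$coef)
}

#' Assemble an LMS curve set
#'
#' Builds the parameter block describing one reference model's L, M and S
#' curves.  Used both by [default_truth()] and to construct custom "true"
#' models for simulation studies.
#'
#' @param a,b,c intercept, log-height and log-age coefficients of the median
#'   predictor `M = exp(a + b log(height) + c log(age) + spline(age))`.
#' @param m_spline,s_spline,l_spline optional [spline_spec()]-style lists
#'   `(knots, boundary, coef)` giving the age-spline contribution of each
#'   curve, or `NULL` for none.
#' @param s_intercept,s_ln_age parameters of
#'   `S = exp(s_intercept + s_ln_age * log(age) + s_spline(age))`.
#' @param l_intercept intercept of `L = l_intercept + l_spline(age)`.
#' @return a list of class `lms_curves`.
#' @export
lms_curves <- function(a, b = 0, c = 0, m_spline = NULL,
                       s_intercept = log(0.12), s_ln_age = 0, s_spline = NULL,
                       l_intercept = 1, l_spline = NULL) {
  structure(list(
    mu = list(a = a, b = b, c = c, spline = m_spline),
    sigma = list(intercept = s_intercept, ln_age = s_ln_age,
                 spline = s_spline),
    nu = list(intercept = l_intercept, spline = l_spline)),
    class = "lms_curves")
}

# Evaluate (M, S, L) at given covariates.  height may be NULL when b = 0.
eval_lms_curves <- function(cs, age, height = NULL) {
  if (any(!is.finite(age)) || any(age <= 0))
    stop("age must be positive", call. = FALSE)
  eta_mu <- cs$mu$a + cs$mu$c * log(age) + eval_spline(cs$mu$spline, age)
  if (cs$mu$b != 0) {
    if (is.null(height)) stop("height required by this model", call. = FALSE)
    if (any(!is.finite(height)) || any(height <= 0))
      stop("height must be positive", call. = FALSE)
    eta_mu <- eta_mu + cs$mu$b * log(height)
  }
  S <- exp(cs$sigma$intercept + cs$sigma$ln_age * log(age) +
             eval_spline(cs$sigma$spline, age))
  L <- cs$nu$intercept + eval_spline(cs$nu$spline, age)
  data.frame(M = exp(eta_mu), S = S, L = L)
}

# ---- demographic model ----------------------------------------------------

# mean height (cm) by age: saturating growth to the adult mean by age 18,
# anchored on the adult means of the emulated population (172 cm men /
# 158 cm women over 21 y)
height_mean <- function(age, sex) {
  sex <- match.arg(sex, SPIRO_SEXES)
  h4 <- if (sex == "male") 104 else 103
  adult <- if (sex == "male") 172 else 158
  u <- pmin(1, pmax(0, (age - 4) / 14))
  h4 + (adult - h4) * u^0.75
}

# residual SD of height around the age mean; ~7 cm in adults (the printed
# adult SD is 8 cm which still includes some age structure), smaller in
# young children
height_sd <- function(age) {
  pmin(7, 5 + (pmax(age, 4) - 4) * 2 / 14)
}

bmi_mean <- function(age, sex) {
  sex <- match.arg(sex, SPIRO_SEXES)
  adult <- if (sex == "male") 25.8 else 27.8
  16 + (adult - 16) * pmin(1, pmax(0, (age - 4) / 17))
}

# ---- the default true model ----------------------------------------------

# Median-curve coefficients of the built-in truth.  The age splines encode a
# childhood rise, a plateau in the mid-20s and a roughly linear adult
# decline, calibrated so that adult medians sit at the emulated population's
# reported means (FEV1 3.65/2.63 L, FVC 4.42/3.20 L, ratio 0.83/0.82 for
# men/women).
.TRUTH_KNOTS <- c(8, 12, 16, 21, 30, 45, 60)
.TRUTH_BOUNDARY <- c(4, 82)

.TRUTH_MU <- list(
  male = list(
    fev1 = list(a = -7.858138, b = 2, c = -1.004371,
                sp = c(1.24789, 1.751544, 2.158141, 2.458591, 2.672945,
                       2.578203, 3.520603, 2.451246)),
    fvc = list(a = -7.772133, b = 2, c = -0.974731,
               sp = c(1.231934, 1.741401, 2.150194, 2.454245, 2.688902,
                      2.612856, 3.564857, 2.531825)),
    fev1_fvc = list(a = -0.083321, b = 0, c = -0.031449,
                    sp = c(0.017555, 0.012354, 0.009985, 0.010149, -0.013868,
                           -0.028734, -0.0376, -0.077812)),
    fef2575 = list(a = -5.430309, b = 1.5, c = -0.867907,
                   sp = c(1.109862, 1.580889, 2.010372, 2.232473, 2.397313,
                          2.203843, 2.856253, 1.989513))),
  female = list(
    fev1 = list(a = -9.673102, b = 2, c = 0.278833,
                sp = c(-0.0151, -0.085535, -0.192404, -0.322272, -0.534556,
                       -0.784733, -1.136801, -1.041934)),
    fvc = list(a = -9.5979, b = 2, c = 0.30812,
               sp = c(-0.030858, -0.095542, -0.200241, -0.326546, -0.518776,
                      -0.750489, -1.093096, -0.962362)),
    fev1_fvc = list(a = -0.072571, b = 0, c = -0.031061,
                    sp = c(0.017322, 0.012171, 0.009824, 0.009977, -0.013751,
                           -0.028434, -0.037181, -0.076876)),
    fef2575 = list(a = -5.810306, b = 1.5, c = -0.637777,
                   sp = c(0.906104, 1.250434, 1.547343, 1.712562, 1.824946,
                          1.622009, 2.134033, 1.406196))))

# constant S (coefficient of variation) and L (skewness) per index
.TRUTH_S <- c(fev1 = 0.13, fvc = 0.13, fev1_fvc = 0.08, fef2575 = 0.20)
.TRUTH_L <- c(fev1 = 0.9, fvc = 0.9, fev1_fvc = 2.0, fef2575 = 0.6)

#' Build a custom true model for simulation
#'
#' Wraps per-sex lists of [lms_curves()] into the true-model container used
#' by [generate_cohort()].
#'
#' @param male,female named lists of `lms_curves`, one entry per spirometric
#'   index (any subset of `fev1`, `fvc`, `fev1_fvc`, `fef2575`).
#' @param age_range ages (years) over which the model is defined.
#' @return an object of class `spiro_truth`.
#' @export
make_truth <- function(male, female, age_range = c(4, 82)) {
  stopifnot(is.list(male), is.list(female), length(age_range) == 2)
  structure(list(params = list(male = male, female = female),
                 age_range = as.numeric(age_range)),
            class = "spiro_truth")
}

#' The built-in true reference model
#'
#' A fixed, documented BCCG-LMS model per sex for FEV1, FVC, FEV1/FVC and
#' FEF25-75%, used as ground truth by the synthetic-cohort generator.  Median
#' curves are log-linear in height and age plus a natural age spline; S and L
#' are constant per index.  Adult medians match the demographic profile of a
#' healthy reference population aged 4-82 (e.g. male FEV1 median ~3.8 L at
#' age 38, height 172 cm).  All curves keep `1 - 1.645*L*S > 0`, so the
#' lower limit of normal is defined everywhere.
#'
#' @return an object of class `spiro_truth`; see [make_truth()].
#' @examples
#' tr <- default_truth()
#' eval_truth(tr, index = "fev1", sex = "male", age = 38, height = 172)
#' @export
default_truth <- function() {
  build <- function(sex) {
    out <- list()
    for (ix in SPIRO_INDICES) {
      p <- .TRUTH_MU[[sex]][[ix]]
      out[[ix]] <- lms_curves(
        a = p$a, b = p$b, c = p$c,
        m_spline = spline_spec(.TRUTH_KNOTS, .TRUTH_BOUNDARY, p$sp),
        s_intercept = log(.TRUTH_S[[ix]]),
        l_intercept = .TRUTH_L[[ix]])
    }
    out
  }
  make_truth(male = build("male"), female = build("female"))
}

#' Evaluate a true model at given covariates
#'
#' @param truth a `spiro_truth` from [default_truth()] or [make_truth()].
#' @param index spirometric index name.
#' @param sex `"male"` or `"female"`.
#' @param age,height covariate vectors (years, cm).
#' @return data.frame with columns `M`, `S`, `L`.
#' @export
eval_truth <- function(truth, index, sex, age, height = NULL) {
  stopifnot(inherits(truth, "spiro_truth"))
  sex <- match.arg(sex, SPIRO_SEXES)
  cs <- truth$params[[sex]][[index]]
  if (is.null(cs))
    stop(sprintf("true model has no index '%s' for sex '%s'", index, sex),
         call. = FALSE)
  if (any(age < truth$age_range[1] - 1e-9) ||
      any(age > truth$age_range[2] + 1e-9))
    stop(sprintf("true model undefined at age outside [%g, %g]",
                 truth$age_range[1], truth$age_range[2]), call. = FALSE)
  eval_lms_curves(cs, age, height)
}

#' @export
print.spiro_truth <- function(x, ...) {
  cat("True BCCG-LMS reference model\n")
  cat("  ages:", paste(x$age_range, collapse = "-"), "y\n")
  for (sex in names(x$params))
    cat(sprintf("  %s: %s\n", sex, paste(names(x$params[[sex]]),
                                         collapse = ", ")))
  invisible(x)
}
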