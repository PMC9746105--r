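#' Lower limit of normal (5th centile) of a BCCG reference point
#'
#' Evaluates the LMS lower-limit-of-normal formula
#' `LLN = exp(ln(M) + ln(1 - 1.645*L*S)/L)` (for L = 0 the lognormal limit
#' `M*exp(-1.645*S)`).  The literal constant 1.645 is used, matching the
#' convention of printed reference equations; the exact 5th centile
#' `qbccg(0.05, ...)` differs only through the rounding of the normal
#' quantile (relative difference below 1e-4 for spirometric L, S ranges).
#'
#' @param mu,sigma,nu the LMS point: median M > 0, coefficient of variation
#'   S > 0, skewness power L.
#' @return the LLN in the units of M.
#' @examples
#' lln(3, 0.1, 1)          # 3 * (1 - 0.1645) = 2.5065
#' lln(3, 0.12, 0.8)
#' @export
lln <- function(mu, sigma, nu) {
  .check_musigma(mu, sigma)
  k <- pmax(length(mu), length(sigma), length(nu))
  mu <- rep_len(mu, k); sigma <- rep_len(sigma, k); nu <- rep_len(nu, k)
  arg <- 1 - 1.645 * nu * sigma
  bad <- abs(nu) >= .L0_TOL & arg <= 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "LLN undefined: 1 - 1.645*L*S = %.4g <= 0 for (L = %.4g, S = %.4g)",
      arg[i], nu[i], sigma[i]), call. = FALSE)
  }
  ifelse(abs(nu) < .L0_TOL,
         mu * exp(-1.645 * sigma),
         exp(log(mu) + log(arg) / nu))
}

#' Linear reference Z-score
#'
#' The Z-score convention of printed spirometry reference equations:
#' `SD = (predicted - LLN) / 1.645` and `Z = (observed - predicted) / SD`.
#' This is linear in the observed value, so `observed = predicted` gives 0
#' and `observed = LLN` gives exactly -1.645; away from those anchors it is
#' an approximation to the exact BCCG z-transform ([bccg_z()]).
#'
#' @param observed measured value.
#' @param predicted predicted median M.
#' @param lln_value lower limit of normal at the same covariates.
#' @return the Z-score (dimensionless).
#' @export
zscore_paper <- function(observed, predicted, lln_value) {
  k <- pmax(length(observed), length(predicted), length(lln_value))
  observed <- rep_len(observed, k)
  predicted <- rep_len(predicted, k); lln_value <- rep_len(lln_value, k)
  if (any(!(predicted > lln_value)))
    stop("zscore_paper requires predicted > LLN", call. = FALSE)
  sd <- (predicted - lln_value) / 1.645
  (observed - predicted) / sd
}

#' Per-subject reference predictions
#'
#' Evaluates a fitted (or user-supplied) LMS model at each subject's
#' covariates: predicted median M, S, L, the LLN, the reference SD, the
#' Z-score of the observed value and its percentile.  Two Z conventions are
#' available: `"paper"` (the linear formula of [zscore_paper()], with the
#' literal 1.645) and `"exact"` (the BCCG z-transform; LLN then uses the
#' full-precision 95th normal quantile).  The output labels which was used.
#' Subjects outside the fitted age/height hull are flagged `extrapolated`
#' (predicted, not refused).
#'
#' @param object an `lms_model` (from [fit_lms()] or [read_lms_model()]).
#' @param newdata data.frame with `age`, `height` (if the model uses height)
#'   and optionally the observed index column.
#' @param z_mode `"paper"` or `"exact"`.
#' @param ... unused.
#' @return data.frame with columns `age`, `height`, `M`, `S`, `L`, `LLN`,
#'   `SD`, `observed`, `Z`, `percentile`, `z_mode`, `extrapolated`, plus
#'   `subject_id` and `sex` when present in `newdata`.
#' @export
predict.lms_model <- function(object, newdata, z_mode = c("paper", "exact"),
                              ...) {
  z_mode <- match.arg(z_mode)
  if (!"age" %in% names(newdata))
    stop("newdata must contain an 'age' column", call. = FALSE)
  age <- newdata$age
  if (any(!is.finite(age)) || any(age <= 0))
    stop("age must be positive", call. = FALSE)
  height <- newdata$height
  if (object$spec$include_height) {
    if (is.null(height))
      stop("this model needs a 'height' column", call. = FALSE)
    if (any(!is.finite(height)) || any(height <= 0))
      stop("height must be positive", call. = FALSE)
  }
  p <- eval_lms_curves(object$curves, age, height)
  z95 <- stats::qnorm(0.95)
  lln_v <- if (z_mode == "paper") lln(p$M, p$S, p$L)
           else qbccg(0.05, p$M, p$S, p$L)
  sd_v <- (p$M - lln_v) / if (z_mode == "paper") 1.645 else z95

  obs <- newdata[[object$spec$index]]
  if (is.null(obs)) obs <- rep(NA_real_, length(age))
  has <- is.finite(obs) & obs > 0
  Z <- pct <- rep(NA_real_, length(age))
  if (any(has)) {
    Z[has] <- if (z_mode == "paper")
      zscore_paper(obs[has], p$M[has], lln_v[has])
    else bccg_z(obs[has], p$M[has], p$S[has], p$L[has])
    pct[has] <- 100 * pbccg(obs[has], p$M[has], p$S[has], p$L[has])
  }

  extra <- age < object$hull$age[1] | age > object$hull$age[2]
  if (object$spec$include_height && !is.null(object$hull$height))
    extra <- extra | height < object$hull$height[1] |
      height > object$hull$height[2]
  if (any(extra))
    warning(sprintf("%d subject(s) outside the fitted covariate hull; predictions are extrapolations",
                    sum(extra)), call. = FALSE)

  out <- data.frame(age = age,
                    height = if (is.null(height)) NA_real_ else height,
                    M = p$M, S = p$S, L = p$L, LLN = lln_v, SD = sd_v,
                    observed = obs, Z = Z, percentile = pct,
                    z_mode = z_mode, extrapolated = extra)
  for (col in c("subject_id", "sex"))
    if (col %in% names(newdata)) out[[col]] <- newdata[[col]]
  out
}

#' Reference lookup table
#'
#' Tabulates M, S, L and the LLN over an age (x height) grid, the form in
#' which reference equations are published for bedside use.  For models
#' without a height term the height column is `NA` and a single row per age
#' is produced.
#'
#' @param model an `lms_model`.
#' @param ages numeric vector of ages (years); default 1-year steps over the
#'   fitted hull.
#' @param heights numeric vector of heights (cm); default 5-cm steps over
#'   the fitted hull (ignored for height-free models).
#' @param z_mode passed to the LLN convention, see [predict.lms_model()].
#' @return data.frame `index, sex, age, height, M, S, L, LLN`.
#' @export
lookup_table <- function(model, ages = NULL, heights = NULL,
                         z_mode = c("paper", "exact")) {
  z_mode <- match.arg(z_mode)
  stopifnot(inherits(model, "lms_model"))
  if (is.null(ages))
    ages <- seq(ceiling(model$hull$age[1]), floor(model$hull$age[2]), by = 1)
  if (length(ages) == 0) stop("empty age grid", call. = FALSE)
  if (model$spec$include_height) {
    if (is.null(heights)) {
      h <- model$hull$height
      heights <- seq(5 * ceiling(h[1] / 5), 5 * floor(h[2] / 5), by = 5)
    }
    if (length(heights) == 0) stop("empty height grid", call. = FALSE)
    g <- expand.grid(age = ages, height = heights)
  } else {
    g <- data.frame(age = ages, height = NA_real_)
  }
  p <- eval_lms_curves(model$curves, g$age,
                       if (model$spec$include_height) g$height)
  lln_v <- if (z_mode == "paper") lln(p$M, p$S, p$L)
           else qbccg(0.05, p$M, p$S, p$L)
  data.frame(index = model$spec$index, sex = model$spec$sex,
             age = g$age, height = g$height,
             M = p$M, S = p$S, L = p$L, LLN = lln_v)
}
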