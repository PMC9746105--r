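#' Specify an LMS reference model
#'
#' Describes the structure of one sex-stratified BCCG-LMS model for one
#' spirometric index.  The median predictor is
#' `M = exp(a + b*log(height) + c*log(age) + spline(age, df_m))`; the
#' coefficient of variation is modelled on the log scale
#' (`S = exp(intercept + [log(age)] + spline(age, df_s))`, guaranteeing
#' S > 0) and the skewness power L on the identity scale
#' (`L = intercept + spline(age, df_l)`), each with an optional natural age
#' spline.  `df = 0` reduces a curve to its parametric part.
#'
#' For the FEV1/FVC ratio the height term is dropped by default (age, not
#' height, predicts the ratio); override with `include_height`.
#'
#' @param index one of `"fev1"`, `"fvc"`, `"fev1_fvc"`, `"fef2575"` (any
#'   positive measurand column works).
#' @param sex `"male"` or `"female"`.
#' @param df_m,df_s,df_l natural-spline degrees of freedom (basis dimension)
#'   for the M, S and L age curves; non-negative integers.
#' @param include_height include the `b*log(height)` term in M; default
#'   `TRUE` except for `fev1_fvc`.
#' @param sigma_ln_age include a `log(age)` term in the S predictor.
#' @param criterion selection criterion used by [select_lms()].
#' @return a list of class `lms_spec`.
#' @export
lms_spec <- function(index, sex, df_m = 3, df_s = 0, df_l = 0,
                     include_height = NULL, sigma_ln_age = FALSE,
                     criterion = c("SBC", "AIC")) {
  sex <- match.arg(sex, SPIRO_SEXES)
  criterion <- match.arg(criterion)
  if (is.null(include_height)) include_height <- !identical(index, "fev1_fvc")
  for (d in c(df_m, df_s, df_l))
    if (length(d) != 1 || !is.finite(d) || d < 0 || d != round(d))
      stop("spline df must be non-negative integers", call. = FALSE)
  structure(list(index = index, sex = sex,
                 df_m = as.integer(df_m), df_s = as.integer(df_s),
                 df_l = as.integer(df_l),
                 include_height = isTRUE(include_height),
                 sigma_ln_age = isTRUE(sigma_ln_age),
                 criterion = criterion),
            class = "lms_spec")
}

#' @rdname lms_spec
#' @param df_m_grid,df_s_grid,df_l_grid candidate df values; the grid is
#'   their Cartesian product.
#' @param ... passed on to [lms_spec()].
#' @return `lms_spec_grid`: a list of `lms_spec`, one per df combination.
#' @export
lms_spec_grid <- function(index, sex, df_m_grid = 0:5, df_s_grid = 0,
                          df_l_grid = 0, ...) {
  g <- expand.grid(df_m = df_m_grid, df_s = df_s_grid, df_l = df_l_grid)
  lapply(seq_len(nrow(g)), function(i)
    lms_spec(index, sex, df_m = g$df_m[i], df_s = g$df_s[i],
             df_l = g$df_l[i], ...))
}

#' Fitting control parameters
#'
#' @param outer_tol relative log-likelihood change below which the cyclic
#'   block updates stop.
#' @param max_outer maximum outer cycles.
#' @param block_maxit BFGS iteration cap per block update.
#' @param final_maxit iteration cap of the final joint polish.
#' @export
lms_control <- function(outer_tol = 1e-8, max_outer = 50, block_maxit = 200,
                        final_maxit = 500) {
  list(outer_tol = outer_tol, max_outer = max_outer,
       block_maxit = block_maxit, final_maxit = final_maxit)
}

sex_code <- function(x) {
  key <- c(m = "male", male = "male", f = "female", female = "female",
           `1` = "male", `2` = "female")
  out <- unname(key[tolower(trimws(as.character(x)))])
  if (any(is.na(out)))
    stop("unrecognised sex codes: ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

# natural-spline design block with knots at age quantiles; returns the
# matrix plus the (knots, boundary) needed to re-evaluate it at new ages
ns_block <- function(age, df) {
  if (df == 0) return(NULL)
  B <- splines::ns(age, df = df)
  list(X = unclass(B),
       knots = as.numeric(attr(B, "knots")),
       boundary = as.numeric(attr(B, "Boundary.knots")))
}

build_designs <- function(age, height, spec) {
  mu_cols <- list(`(Intercept)` = rep(1, length(age)))
  if (spec$include_height) mu_cols$log_height <- log(height)
  mu_cols$log_age <- log(age)
  mu_sp <- ns_block(age, spec$df_m)
  X_mu <- do.call(cbind, mu_cols)
  if (!is.null(mu_sp)) X_mu <- cbind(X_mu, mu_sp$X)

  sg_cols <- list(`(Intercept)` = rep(1, length(age)))
  if (spec$sigma_ln_age) sg_cols$log_age <- log(age)
  sg_sp <- ns_block(age, spec$df_s)
  X_sg <- do.call(cbind, sg_cols)
  if (!is.null(sg_sp)) X_sg <- cbind(X_sg, sg_sp$X)

  nu_sp <- ns_block(age, spec$df_l)
  X_nu <- matrix(1, length(age), 1)
  if (!is.null(nu_sp)) X_nu <- cbind(X_nu, nu_sp$X)

  list(X_mu = X_mu, X_sigma = X_sg, X_nu = X_nu,
       sp = list(mu = mu_sp, sigma = sg_sp, nu = nu_sp))
}

# BCCG log-likelihood for stacked coefficients (mu | sigma | nu blocks)
bccg_loglik <- function(par, y, D, idx) {
  eta_mu <- drop(D$X_mu %*% par[idx$mu])
  eta_sg <- drop(D$X_sigma %*% par[idx$sigma])
  L <- drop(D$X_nu %*% par[idx$nu])
  if (any(!is.finite(eta_mu)) || any(!is.finite(eta_sg)) ||
      any(!is.finite(L)) || any(eta_sg > 5) || any(eta_sg < -20))
    return(-Inf)
  S <- exp(eta_sg)
  r <- log(y) - eta_mu
  z <- ifelse(abs(L) < .L0_TOL, r / S, (exp(L * r) - 1) / (L * S))
  ll <- sum((L - 1) * log(y) - L * eta_mu - eta_sg +
              stats::dnorm(z, log = TRUE))
  if (!is.finite(ll)) -Inf else ll
}

#' Fit a BCCG-LMS reference model by maximum likelihood
#'
#' Maximises the BCCG log-likelihood over the coefficients of the M, S and L
#' age/height curves described by `spec`.  Optimisation cycles block updates
#' of the three curves (BFGS within each block, with a monotone-acceptance
#' guard so the objective never decreases) until the relative log-likelihood
#' change falls below `control$outer_tol`, then polishes all coefficients
#' jointly and extracts standard errors from the observed information.  The
#' fit is deterministic given `data` and `spec`.
#'
#' Subjects of the other sex, and rows with missing or non-positive index
#' values, are dropped with a message.  Non-convergence is flagged via
#' `converged = FALSE` and a warning, never silently.
#'
#' @param data cohort data.frame (see [generate_cohort()] / [read_cohort()]).
#' @param spec an [lms_spec()].
#' @param control an [lms_control()].
#' @return an object of class `lms_model` with elements `curves` (fitted
#'   [lms_curves()]), `coef`, `vcov`, `loglik`, `edf`, `aic`, `sbc`,
#'   `iter_loglik`, `converged`, `n_obs`, `hull` and `valid_lln`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_per_sex = 200, seed = 1))
#' fit <- fit_lms(coh, lms_spec("fev1", "male", df_m = 2))
#' fit
#' @export
fit_lms <- function(data, spec, control = lms_control()) {
  stopifnot(inherits(spec, "lms_spec"))
  if (!spec$index %in% names(data))
    stop(sprintf("column '%s' not found in data", spec$index), call. = FALSE)

  keep <- sex_code(data$sex) == spec$sex
  d <- data[keep, , drop = FALSE]
  y <- d[[spec$index]]
  ok <- is.finite(y) & y > 0 & is.finite(d$age) & d$age > 0
  if (spec$include_height) ok <- ok & is.finite(d$height) & d$height > 0
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message(sprintf("fit_lms: dropped %d of %d %s subjects with missing or non-positive values",
                    n_drop, nrow(d), spec$sex))
  d <- d[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  if (n < 50)
    stop(sprintf("need at least 50 usable %s subjects, got %d", spec$sex, n),
         call. = FALSE)
  if (length(unique(round(d$age, 6))) < max(3, spec$df_m + 1))
    stop("too few distinct ages to support the requested spline",
         call. = FALSE)

  D <- build_designs(d$age, d$height, spec)
  idx <- list(mu = seq_len(ncol(D$X_mu)),
              sigma = ncol(D$X_mu) + seq_len(ncol(D$X_sigma)),
              nu = ncol(D$X_mu) + ncol(D$X_sigma) + seq_len(ncol(D$X_nu)))
  p_tot <- ncol(D$X_mu) + ncol(D$X_sigma) + ncol(D$X_nu)

  # starting values: lognormal fit (L = 1 start for the power)
  b_mu <- stats::lm.fit(D$X_mu, log(y))$coefficients
  b_mu[!is.finite(b_mu)] <- 0
  resid <- log(y) - drop(D$X_mu %*% b_mu)
  par <- numeric(p_tot)
  par[idx$mu] <- b_mu
  par[idx$sigma][1] <- log(max(stats::sd(resid), 1e-3))
  par[idx$nu][1] <- 1

  negll <- function(p) -bccg_loglik(p, y, D, idx)
  ll <- -negll(par)
  iter_ll <- ll
  converged_outer <- FALSE
  for (it in seq_len(control$max_outer)) {
    for (block in c("mu", "sigma", "nu")) {
      j <- idx[[block]]
      opt <- stats::optim(par[j], function(b) {
        p <- par; p[j] <- b; negll(p)
      }, method = "BFGS",
      control = list(maxit = control$block_maxit, reltol = 1e-10))
      if (-opt$value >= ll) {          # monotone acceptance guard
        par[j] <- opt$par
        ll <- -opt$value
      }
    }
    iter_ll <- c(iter_ll, ll)
    rel <- abs(ll - iter_ll[length(iter_ll) - 1]) / (abs(ll) + 1e-10)
    if (rel < control$outer_tol) { converged_outer <- TRUE; break }
  }

  joint <- stats::optim(par, negll, method = "BFGS", hessian = TRUE,
                        control = list(maxit = control$final_maxit,
                                       reltol = 1e-12))
  if (-joint$value >= ll) { par <- joint$par; ll <- -joint$value }
  iter_ll <- c(iter_ll, ll)
  converged <- converged_outer && joint$convergence == 0
  if (!converged)
    warning(sprintf("fit_lms: %s/%s fit did not meet the convergence tolerance",
                    spec$index, spec$sex), call. = FALSE)

  vc <- tryCatch(solve(joint$hessian), error = function(e) {
    matrix(NA_real_, p_tot, p_tot)
  })

  curves <- coef_to_curves(par, spec, D, idx)
  hull <- list(age = range(d$age),
               height = if (spec$include_height) range(d$height) else NULL)
  model <- structure(list(
    spec = spec, curves = curves, coef = par, vcov = vc,
    n_obs = n, n_dropped = n_drop,
    loglik = ll, edf = p_tot,
    aic = -2 * ll + 2 * p_tot, sbc = -2 * ll + log(n) * p_tot,
    iter_loglik = iter_ll, converged = converged, hull = hull),
    class = "lms_model")
  model$valid_lln <- check_lln_valid(model)
  model
}

# map the stacked coefficient vector back into an lms_curves block
coef_to_curves <- function(par, spec, D, idx) {
  b_mu <- par[idx$mu]; b_sg <- par[idx$sigma]; b_nu <- par[idx$nu]
  i <- 1
  a <- b_mu[i]; i <- i + 1
  b <- 0
  if (spec$include_height) { b <- b_mu[i]; i <- i + 1 }
  cc <- b_mu[i]; i <- i + 1
  m_sp <- if (!is.null(D$sp$mu))
    spline_spec(D$sp$mu$knots, D$sp$mu$boundary, b_mu[i:length(b_mu)])
  j <- 1
  s_int <- b_sg[j]; j <- j + 1
  s_lna <- 0
  if (spec$sigma_ln_age) { s_lna <- b_sg[j]; j <- j + 1 }
  s_sp <- if (!is.null(D$sp$sigma))
    spline_spec(D$sp$sigma$knots, D$sp$sigma$boundary, b_sg[j:length(b_sg)])
  l_sp <- if (!is.null(D$sp$nu))
    spline_spec(D$sp$nu$knots, D$sp$nu$boundary, b_nu[2:length(b_nu)])
  lms_curves(a = a, b = b, c = cc, m_spline = m_sp,
             s_intercept = s_int, s_ln_age = s_lna, s_spline = s_sp,
             l_intercept = b_nu[1], l_spline = l_sp)
}

# LLN is defined only where 1 - 1.645*L*S > 0; check over the fitted hull
check_lln_valid <- function(model) {
  ages <- seq(model$hull$age[1], model$hull$age[2], length.out = 101)
  hts <- if (is.null(model$hull$height)) NULL
         else rep(mean(model$hull$height), length(ages))
  p <- eval_lms_curves(model$curves, ages, hts)
  all(p$S > 0) && all(1 - 1.645 * p$L * p$S > 0) &&
    max(bccg_truncation_mass(p$S, p$L)) < 1e-6
}

#' Fitted (a, b, c) coefficients with standard errors
#'
#' @param object an `lms_model`.
#' @param ... unused.
#' @return data.frame with the median-curve coefficients, their standard
#'   errors from the observed information, and the full coefficient vector
#'   is available via `object$coef`.
#' @export
coef.lms_model <- function(object, ...) {
  nms <- c("a", if (object$spec$include_height) "b", "c")
  k <- seq_along(nms)
  se <- sqrt(diag(object$vcov))[k]
  data.frame(term = nms, estimate = object$coef[k], se = se)
}

#' @export
print.lms_model <- function(x, ...) {
  cat(sprintf("BCCG-LMS reference model: %s, %s (n = %d)\n",
              x$spec$index, x$spec$sex, x$n_obs))
  cat(sprintf("  df (M/S/L): %d/%d/%d   height term: %s\n",
              x$spec$df_m, x$spec$df_s, x$spec$df_l,
              if (x$spec$include_height) "yes" else "no"))
  cat(sprintf("  logLik %.3f  edf %d  AIC %.2f  SBC %.2f  converged: %s\n",
              x$loglik, x$edf, x$aic, x$sbc, x$converged))
  if (!x$valid_lln)
    cat("  WARNING: 1 - 1.645*L*S <= 0 somewhere on the hull; LLN invalid\n")
  invisible(x)
}

#' Fit candidate models and select by information criterion
#'
#' Fits every spec (typically an [lms_spec_grid()] over spline df values),
#' tabulates log-likelihood, AIC and SBC, and returns the model minimising
#' the first spec's `criterion` (SBC by default).  Ties are broken toward
#' the smaller effective df.
#'
#' @param data cohort data.frame.
#' @param specs list of [lms_spec()] objects.
#' @param control an [lms_control()].
#' @return list with elements `model` (the selected `lms_model`) and `table`
#'   (one row per candidate: df values, edf, loglik, aic, sbc, converged,
#'   selected flag).
#' @export
select_lms <- function(data, specs, control = lms_control()) {
  if (inherits(specs, "lms_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1)
  fits <- vector("list", length(specs))
  errs <- character(length(specs))
  for (i in seq_along(specs)) {
    fits[[i]] <- tryCatch(fit_lms(data, specs[[i]], control),
                          error = function(e) {
                            errs[i] <<- conditionMessage(e); NULL
                          })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("all candidate specs failed to fit:\n  ",
         paste(sprintf("df_m=%d: %s",
                       vapply(specs, `[[`, integer(1), "df_m"),
                       errs), collapse = "\n  "), call. = FALSE)
  tab <- do.call(rbind, lapply(which(ok), function(i) {
    f <- fits[[i]]
    data.frame(index = f$spec$index, sex = f$spec$sex,
               df_m = f$spec$df_m, df_s = f$spec$df_s, df_l = f$spec$df_l,
               edf = f$edf, loglik = f$loglik, aic = f$aic, sbc = f$sbc,
               converged = f$converged)
  }))
  crit <- if (specs[[1]]$criterion == "AIC") tab$aic else tab$sbc
  use <- which(ok)[order(crit, tab$edf)][1]
  tab$selected <- seq_len(nrow(tab)) == which(which(ok) == use)
  list(model = fits[[use]], table = tab)
}

#' Residual diagnostics of a fitted LMS model
#'
#' Computes exact BCCG residual z-scores on the fitting sample, normal Q-Q
#' points and a normality p-value (Shapiro-Wilk up to n = 5000, otherwise
#' Kolmogorov-Smirnov against N(0, 1)).  Residuals of a well-specified model
#' are standard normal; values beyond +/-5 indicate a fitting problem.
#'
#' @param model a converged `lms_model`.
#' @param data the data it was fitted to (or fresh data for out-of-sample
#'   checks).
#' @return object of class `lms_diagnostics` with `residual_z`,
#'   `max_abs_residual_z`, `qq_points` and `normality_p`.
#' @export
diagnose <- function(model, data) {
  stopifnot(inherits(model, "lms_model"))
  if (!model$converged)
    stop("diagnose() needs a converged model", call. = FALSE)
  data <- data[sex_code(data$sex) == model$spec$sex, , drop = FALSE]
  pr <- predict(model, data, z_mode = "exact")
  z <- pr$Z[!is.na(pr$Z)]
  n <- length(z)
  qq <- data.frame(theoretical = stats::qnorm(stats::ppoints(n)),
                   observed = sort(z))
  p <- if (n >= 3 && n <= 5000) stats::shapiro.test(z)$p.value
       else stats::ks.test(z, "pnorm")$p.value
  structure(list(residual_z = z, max_abs_residual_z = max(abs(z)),
                 qq_points = qq, normality_p = p, n = n,
                 index = model$spec$index, sex = model$spec$sex),
            class = "lms_diagnostics")
}

#' @export
print.lms_diagnostics <- function(x, ...) {
  cat(sprintf("LMS fit diagnostics (%s, %s, n = %d)\n", x$index, x$sex, x$n))
  cat(sprintf("  max |residual z| = %.3f   normality p = %.3g\n",
              x$max_abs_residual_z, x$normality_p))
  invisible(x)
}

#' @export
plot.lms_diagnostics <- function(x, ...) {
  graphics::plot(x$qq_points$theoretical, x$qq_points$observed,
                 xlab = "Theoretical quantiles", ylab = "Residual z",
                 main = sprintf("Normal Q-Q: %s (%s)", x$index, x$sex), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
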