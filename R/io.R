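COHORT_COLUMNS <- c("subject_id", "sex", "age", "height", "weight",
                    SPIRO_INDICES)

#' Read and write cohort CSV files
#'
#' The cohort format is one row per subject with header
#' `subject_id,sex,age,height,weight,fev1,fvc,fev1_fvc,fef2575` (UTF-8,
#' decimal point, `\n` newlines).  `sex` is canonically `M`/`F`;
#' `male`/`female` (any case) are accepted.  `age` is in years, `height` in
#' cm (values read in metres, i.e. all below 3, are converted with a
#' warning), volumes in litres.  Rows with missing or non-positive age or
#' height are rejected with a logged reason; per-index missing values are
#' kept as `NA`.
#'
#' @param path file path.
#' @return `read_cohort`: the cohort data.frame; rejected rows are reported
#'   via a message and recorded in `attr(, "rejections")`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("sex", "age", "height")
  miss <- setdiff(mandatory, names(d))
  if (length(miss))
    stop("cohort file is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(d), COHORT_COLUMNS)
  if (length(unknown))
    warning("ignoring unknown cohort column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  d$sex <- ifelse(sex_code(d$sex) == "male", "M", "F")
  if (all(is.finite(d$height) & d$height < 3)) {
    warning("heights look like metres; converting to cm", call. = FALSE)
    d$height <- d$height * 100
  }
  bad_age <- !is.finite(d$age) | d$age <= 0
  bad_ht <- !is.finite(d$height) | d$height <= 0
  rej <- data.frame(row = which(bad_age | bad_ht),
                    reason = ifelse(bad_age[bad_age | bad_ht],
                                    "non-positive or missing age",
                                    "non-positive or missing height"))
  if (nrow(rej) > 0)
    message(sprintf("read_cohort: rejected %d row(s) (%s)", nrow(rej),
                    paste(unique(rej$reason), collapse = "; ")))
  d <- d[!(bad_age | bad_ht), , drop = FALSE]
  rownames(d) <- NULL
  if (!"subject_id" %in% names(d)) d$subject_id <- sprintf("S%05d", seq_len(nrow(d)))
  attr(d, "rejections") <- rej
  d
}

#' @rdname read_cohort
#' @param cohort a cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  cols <- intersect(COHORT_COLUMNS, names(cohort))
  utils::write.csv(cohort[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# ---- YAML model serialization --------------------------------------------

spline_to_list <- function(sp) {
  if (is.null(sp)) return(NULL)
  list(knots = as.numeric(sp$knots), boundary = as.numeric(sp$boundary),
       coef = as.numeric(sp$coef))
}

curves_to_list <- function(cs) {
  list(mu = list(a = cs$mu$a, b = cs$mu$b, c = cs$mu$c,
                 spline = spline_to_list(cs$mu$spline)),
       sigma = list(intercept = cs$sigma$intercept,
                    ln_age = cs$sigma$ln_age,
                    spline = spline_to_list(cs$sigma$spline)),
       nu = list(intercept = cs$nu$intercept,
                 spline = spline_to_list(cs$nu$spline)))
}

list_to_spline <- function(x) {
  if (is.null(x)) return(NULL)
  spline_spec(x$knots, x$boundary, x$coef)
}

list_to_curves <- function(x) {
  lms_curves(a = x$mu$a, b = x$mu$b %||% 0, c = x$mu$c %||% 0,
             m_spline = list_to_spline(x$mu$spline),
             s_intercept = x$sigma$intercept,
             s_ln_age = x$sigma$ln_age %||% 0,
             s_spline = list_to_spline(x$sigma$spline),
             l_intercept = x$nu$intercept,
             l_spline = list_to_spline(x$nu$spline))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize reference models to YAML
#'
#' A fitted `lms_model` round-trips losslessly (curve coefficients, spline
#' knots, fit metadata, hull).  The same format, with `external: true`,
#' ingests user-supplied coefficient tables for an external standard (e.g. a
#' Caucasian GLI-style model): such files need `index`, `sex`, `curves` and
#' a `hull` block, and are evaluated through the identical prediction path.
#'
#' @param model an `lms_model`.
#' @param path output/input file path.
#' @export
write_lms_model <- function(model, path) {
  stopifnot(inherits(model, "lms_model"))
  x <- list(kind = "lms_model",
            external = isTRUE(model$external),
            index = model$spec$index, sex = model$spec$sex,
            curves = curves_to_list(model$curves),
            hull = list(age = as.numeric(model$hull$age),
                        height = if (!is.null(model$hull$height))
                          as.numeric(model$hull$height)),
            fit = list(n_obs = model$n_obs, edf = model$edf,
                       loglik = model$loglik, aic = model$aic,
                       sbc = model$sbc, converged = model$converged,
                       df_m = model$spec$df_m, df_s = model$spec$df_s,
                       df_l = model$spec$df_l,
                       include_height = model$spec$include_height,
                       sigma_ln_age = model$spec$sigma_ln_age,
                       criterion = model$spec$criterion))
  writeLines(yaml::as.yaml(x, precision = 15), path)
  invisible(path)
}

#' @rdname write_lms_model
#' @return `read_lms_model`: an `lms_model` usable by
#'   [predict.lms_model()] and [lookup_table()]; refitting metadata
#'   (`coef`, `vcov`, `iter_loglik`) is not serialized.
#' @export
read_lms_model <- function(path) {
  x <- yaml::read_yaml(path)
  if (!identical(x$kind, "lms_model"))
    stop("not an lms_model YAML file: ", path, call. = FALSE)
  curves <- list_to_curves(x$curves)
  fit <- x$fit %||% list()
  spec <- lms_spec(index = x$index, sex = x$sex,
                   df_m = fit$df_m %||% 0, df_s = fit$df_s %||% 0,
                   df_l = fit$df_l %||% 0,
                   include_height = fit$include_height %||% (curves$mu$b != 0),
                   sigma_ln_age = fit$sigma_ln_age %||% FALSE,
                   criterion = fit$criterion %||% "SBC")
  model <- structure(list(
    spec = spec, curves = curves, coef = NULL, vcov = NULL,
    n_obs = fit$n_obs %||% NA_integer_, n_dropped = NA_integer_,
    loglik = fit$loglik %||% NA_real_, edf = fit$edf %||% NA_integer_,
    aic = fit$aic %||% NA_real_, sbc = fit$sbc %||% NA_real_,
    iter_loglik = NULL, converged = fit$converged %||% TRUE,
    hull = list(age = as.numeric(x$hull$age),
                height = if (!is.null(x$hull$height))
                  as.numeric(x$hull$height)),
    external = isTRUE(x$external)), class = "lms_model")
  model$valid_lln <- check_lln_valid(model)
  model
}

#' @rdname write_lms_model
#' @param truth a `spiro_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "spiro_truth"))
  x <- list(kind = "spiro_truth",
            age_range = as.numeric(truth$age_range),
            models = lapply(truth$params, function(sx)
              lapply(sx, curves_to_list)))
  writeLines(yaml::as.yaml(x, precision = 15), path)
  invisible(path)
}

#' @rdname write_lms_model
#' @export
read_truth <- function(path) {
  x <- yaml::read_yaml(path)
  if (!identical(x$kind, "spiro_truth"))
    stop("not a spiro_truth YAML file: ", path, call. = FALSE)
  make_truth(male = lapply(x$models$male, list_to_curves),
             female = lapply(x$models$female, list_to_curves),
             age_range = x$age_range)
}
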