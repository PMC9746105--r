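#' Configure a synthetic cohort
#'
#' @param n_per_sex subjects per sex.  Reference-equation validation needs at
#'   least 150 per sex; smaller values are allowed (handy for quick runs) but
#'   flagged with a warning when `validation = TRUE`.
#' @param age_range inclusion ages in years; must lie within \[3, 95\].
#' @param seed integer seed; all randomness in [generate_cohort()] flows from
#'   it.
#' @param validation logical; warn when `n_per_sex` is below the 150-per-sex
#'   validation minimum.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_sex = 300, age_range = c(4, 82), seed = 1,
                          validation = FALSE) {
  if (length(n_per_sex) != 1 || !is.finite(n_per_sex) || n_per_sex < 1)
    stop("n_per_sex must be a positive integer", call. = FALSE)
  if (length(age_range) != 2 || any(!is.finite(age_range)) ||
      age_range[1] >= age_range[2])
    stop("age_range must be an increasing (min, max) pair", call. = FALSE)
  if (age_range[1] < 3 || age_range[2] > 95)
    stop("age_range must lie within [3, 95]", call. = FALSE)
  if (validation && n_per_sex < 150)
    warning("validation cohorts need at least 150 subjects per sex",
            call. = FALSE)
  structure(list(n_per_sex = as.integer(n_per_sex),
                 age_range = as.numeric(age_range),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic spirometry cohort
#'
#' Draws `n_per_sex` subjects per sex with ages uniform over the configured
#' range, heights from a saturating growth curve plus Gaussian noise, weights
#' from an age-dependent BMI model, and each spirometric index independently
#' from the BCCG distribution of the matching true model at the subject's
#' covariates.  Fully reproducible from `config$seed`.
#'
#' Indices are simulated independently per subject (reference models treat
#' each index separately), so the physiological constraint FEV1 <= FVC is
#' not imposed unless `enforce_fev1_le_fvc = TRUE`, which redraws violating
#' pairs.
#'
#' @param config a [cohort_config()].
#' @param truth a `spiro_truth`; defaults to [default_truth()].
#' @param enforce_fev1_le_fvc redraw subjects whose simulated FEV1 exceeds
#'   their FVC (off by default; see Details).
#' @return data.frame with columns `subject_id`, `sex` (`M`/`F`), `age`,
#'   `height`, `weight` and one column per index present in `truth`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_per_sex = 50, seed = 7))
#' table(coh$sex)
#' @export
generate_cohort <- function(config, truth = default_truth(),
                            enforce_fev1_le_fvc = FALSE) {
  stopifnot(inherits(config, "cohort_config"), inherits(truth, "spiro_truth"))
  if (config$age_range[1] < truth$age_range[1] ||
      config$age_range[2] > truth$age_range[2])
    stop("true model undefined over the requested age range", call. = FALSE)
  withr_seed(config$seed, {
    pieces <- lapply(SPIRO_SEXES, function(sex)
      simulate_sex(config, truth, sex, enforce_fev1_le_fvc))
    out <- do.call(rbind, pieces)
    out$subject_id <- sprintf("S%05d", seq_len(nrow(out)))
    rownames(out) <- NULL
    out <- out[, c("subject_id", setdiff(names(out), "subject_id"))]
    attr(out, "config") <- config
    out
  })
}

simulate_sex <- function(config, truth, sex, enforce) {
  n <- config$n_per_sex
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  height <- height_mean(age, sex) + stats::rnorm(n, 0, height_sd(age))
  height <- pmax(height, 60)   # guard against extreme negative noise draws
  bmi <- bmi_mean(age, sex) * exp(stats::rnorm(n, 0, 0.15))
  weight <- round(bmi * (height / 100)^2, 1)
  df <- data.frame(sex = if (sex == "male") "M" else "F",
                   age = age, height = round(height, 1), weight = weight)
  for (ix in names(truth$params[[sex]])) {
    par <- eval_truth(truth, ix, sex, df$age, df$height)
    df[[ix]] <- rbccg(n, par$M, par$S, par$L)
  }
  if (enforce && all(c("fev1", "fvc") %in% names(df))) {
    for (it in 1:100) {
      bad <- which(df$fev1 > df$fvc)
      if (!length(bad)) break
      for (ix in c("fev1", "fvc")) {
        par <- eval_truth(truth, ix, sex, df$age[bad], df$height[bad])
        df[[ix]][bad] <- rbccg(length(bad), par$M, par$S, par$L)
      }
    }
  }
  df
}
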