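#' Age grouping schemes
#'
#' An age-group scheme is an ordered set of half-open bins `[min, max)`.
#' `default_age_groups()` returns the grouping conventionally used for
#' spirometry reference cohorts: `<10, 10-21, 22-29, 30-39, 40-49, 50-59,
#' 60-69, >70`, implemented as `[0,10), [10,22), [22,30), [30,40), [40,50),
#' [50,60), [60,70), [70,Inf)` (the printed labels are gappy; contiguous
#' half-open bins are a documented interpretation).
#'
#' @param labels,min_age,max_age parallel vectors defining the bins.
#' @return data.frame of class `age_group_scheme`.
#' @export
age_group_scheme <- function(labels, min_age, max_age) {
  stopifnot(length(labels) == length(min_age),
            length(labels) == length(max_age))
  o <- order(min_age)
  labels <- labels[o]; min_age <- min_age[o]; max_age <- max_age[o]
  if (any(min_age >= max_age))
    stop("each bin needs min_age < max_age", call. = FALSE)
  if (any(utils::head(max_age, -1) > utils::tail(min_age, -1) + 1e-9))
    stop("age bins must not overlap", call. = FALSE)
  structure(data.frame(label = labels, min_age = min_age, max_age = max_age,
                       stringsAsFactors = FALSE),
            class = c("age_group_scheme", "data.frame"))
}

#' @rdname age_group_scheme
#' @export
default_age_groups <- function() {
  age_group_scheme(
    labels = c("<10", "10-21", "22-29", "30-39", "40-49", "50-59",
               "60-69", ">70"),
    min_age = c(0, 10, 22, 30, 40, 50, 60, 70),
    max_age = c(10, 22, 30, 40, 50, 60, 70, Inf))
}

#' @rdname age_group_scheme
#' @param age numeric ages.
#' @param scheme an `age_group_scheme`.
#' @return `assign_age_group`: factor of group labels (NA outside all bins).
#' @export
assign_age_group <- function(age, scheme) {
  stopifnot(inherits(scheme, "age_group_scheme"))
  lab <- rep(NA_character_, length(age))
  for (i in seq_len(nrow(scheme))) {
    hit <- age >= scheme$min_age[i] & age < scheme$max_age[i]
    lab[hit] <- scheme$label[i]
  }
  factor(lab, levels = scheme$label)
}

# one-sample t-test against zero with documented degenerate conventions:
# n < 2 -> NA; zero variance at the null (all values 0) -> p = 1;
# zero variance off the null -> p = 0
t_vs_zero <- function(z) {
  n <- length(z)
  if (n < 2) return(list(p = NA_real_, ci = c(NA_real_, NA_real_)))
  m <- mean(z); s <- stats::sd(z)
  if (s == 0)
    return(list(p = if (m == 0) 1 else 0, ci = c(m, m)))
  tt <- stats::t.test(z, mu = 0)
  list(p = unname(tt$p.value), ci = unname(tt$conf.int))
}

#' Age-group Z-score summary
#'
#' Summarises reference Z-scores per (age group, sex): n, mean, SD, exact
#' t-based 95% CI, two-sided one-sample t-test against zero, and the
#' clinical-significance flag `|mean Z| > 0.5` (the conventional agreement
#' threshold for reference-equation transfer).  Empty groups are emitted
#' with `n = 0` and `NA` statistics, never dropped.  When the predictions
#' carry `observed` and `LLN`, below-LLN counts are included.  No
#' multiple-testing correction is applied across groups.
#'
#' @param predictions data.frame from [predict.lms_model()] (must contain
#'   `age`, `sex` and `Z`).
#' @param scheme an [age_group_scheme()]; default [default_age_groups()].
#' @param ci one of `"t"` (exact t CI) or `"normal"`.
#' @return data.frame, one row per (group, sex): `label`, `sex`, `n`,
#'   `mean_z`, `sd_z`, `ci_lo`, `ci_hi`, `t_p`, `clinically_significant`,
#'   and `n_below_lln`/`pct_below_lln` when computable.
#' @export
z_summary <- function(predictions, scheme = default_age_groups(),
                      ci = c("t", "normal")) {
  ci <- match.arg(ci)
  need <- c("age", "sex", "Z")
  if (!all(need %in% names(predictions)))
    stop("predictions must contain columns: ",
         paste(setdiff(need, names(predictions)), collapse = ", "),
         call. = FALSE)
  grp <- assign_age_group(predictions$age, scheme)
  sexes <- sort(unique(sex_code(predictions$sex)))
  has_lln <- all(c("observed", "LLN") %in% names(predictions))
  rows <- list()
  for (lab in scheme$label) for (sx in sexes) {
    sel <- !is.na(grp) & grp == lab & sex_code(predictions$sex) == sx
    z <- predictions$Z[sel]
    z <- z[!is.na(z)]
    n <- length(z)
    if (n == 0) {
      row <- data.frame(label = lab, sex = sx, n = 0L, mean_z = NA_real_,
                        sd_z = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        t_p = NA_real_, clinically_significant = NA)
    } else {
      m <- mean(z); s <- if (n > 1) stats::sd(z) else NA_real_
      tt <- t_vs_zero(z)
      if (ci == "normal" && n > 1 && !is.na(s)) {
        half <- 1.96 * s / sqrt(n)
        tt$ci <- c(m - half, m + half)
      }
      row <- data.frame(label = lab, sex = sx, n = n, mean_z = m, sd_z = s,
                        ci_lo = tt$ci[1], ci_hi = tt$ci[2], t_p = tt$p,
                        clinically_significant = abs(m) > 0.5)
    }
    if (has_lln) {
      obs <- predictions$observed[sel]; ll <- predictions$LLN[sel]
      k <- is.finite(obs) & is.finite(ll)
      row$n_below_lln <- sum(obs[k] < ll[k])
      row$pct_below_lln <- if (any(k)) 100 * row$n_below_lln / sum(k)
                           else NA_real_
    }
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "multiple_testing") <- "none"
  out
}

#' Below-LLN frequency table
#'
#' Counts observed values below the lower limit of normal per age group and
#' sex, with a total column, in the layout of published reference-cohort
#' tables: numeric counts/percentages plus formatted `"n (pct)"` cells.
#'
#' @param predictions data.frame with `age`, `sex`, `observed`, `LLN`.
#' @param scheme an [age_group_scheme()].
#' @return data.frame with one row per age group plus a `Total` row;
#'   columns `label`, per-scope `n`, `n_below`, `pct_below` and formatted
#'   `cell` strings for total/male/female.
#' @export
below_lln_table <- function(predictions, scheme = default_age_groups()) {
  need <- c("age", "sex", "observed", "LLN")
  if (!all(need %in% names(predictions)))
    stop("predictions must contain columns: ",
         paste(setdiff(need, names(predictions)), collapse = ", "),
         call. = FALSE)
  ok <- is.finite(predictions$observed) & is.finite(predictions$LLN)
  d <- predictions[ok, , drop = FALSE]
  grp <- assign_age_group(d$age, scheme)
  sx <- sex_code(d$sex)
  below <- d$observed < d$LLN
  one <- function(sel) {
    n <- sum(sel); nb <- sum(below[sel])
    pct <- if (n > 0) 100 * nb / n else NA_real_
    list(n = n, nb = nb, pct = pct,
         cell = if (n > 0) sprintf("%d (%.1f%%)", nb, pct) else "-")
  }
  mk_row <- function(lab, sel) {
    t_ <- one(sel); m_ <- one(sel & sx == "male"); f_ <- one(sel & sx == "female")
    data.frame(label = lab,
               n = t_$n, n_below = t_$nb, pct_below = t_$pct, cell = t_$cell,
               n_male = m_$n, n_below_male = m_$nb, pct_below_male = m_$pct,
               cell_male = m_$cell,
               n_female = f_$n, n_below_female = f_$nb,
               pct_below_female = f_$pct, cell_female = f_$cell,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(scheme$label, function(lab) mk_row(lab, !is.na(grp) & grp == lab))
  rows[[length(rows) + 1]] <- mk_row("Total", !is.na(grp))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bland-Altman agreement between two sets of predictions
#'
#' Computes the mean difference, SD of differences and 95% limits of
#' agreement (`mean +/- 1.96 SD`) between paired predicted values from two
#' reference models.  Differences are taken `a - b`; by convention `a` is
#' the external reference and `b` the newly fitted model, so a negative mean
#' difference means the external model predicts lower values.
#'
#' @param a,b numeric vectors of paired predictions (same subjects, same
#'   order).
#' @param names optional length-2 character vector naming the two models.
#' @return object of class `bland_altman`: `mean_diff`, `sd_diff`, `loa`,
#'   `n`, plus the per-subject `diffs` and pairwise `means` for plotting.
#' @examples
#' ba <- bland_altman(rnorm(100, 3), rnorm(100, 3.2))
#' ba
#' @export
bland_altman <- function(a, b, names = c("a", "b")) {
  if (length(a) != length(b))
    stop("bland_altman: prediction vectors differ in length (",
         length(a), " vs ", length(b), ")", call. = FALSE)
  ok <- is.finite(a) & is.finite(b)
  if (sum(!ok) > 0)
    message(sprintf("bland_altman: dropping %d incomplete pair(s)", sum(!ok)))
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2)
    stop("bland_altman needs at least 2 complete pairs", call. = FALSE)
  d <- a - b
  md <- mean(d); sdd <- stats::sd(d)
  structure(list(mean_diff = md, sd_diff = sdd,
                 loa = c(md - 1.96 * sdd, md + 1.96 * sdd),
                 n = length(d), diffs = d, means = (a + b) / 2,
                 names = names),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (%s - %s), n = %d\n",
              x$names[1], x$names[2], x$n))
  cat(sprintf("  mean difference %.4f (SD %.4f)\n", x$mean_diff, x$sd_diff))
  cat(sprintf("  95%% limits of agreement: [%.4f, %.4f]\n",
              x$loa[1], x$loa[2]))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, xlab = "Mean of paired predictions",
                 ylab = sprintf("Difference (%s - %s)", x$names[1],
                                x$names[2]),
                 main = "Bland-Altman", ...)
  graphics::abline(h = c(x$mean_diff, x$loa), lty = c(1, 2, 2))
  invisible(x)
}
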