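#' The Box-Cox Cole-Green (BCCG) distribution
#'
#' Density, distribution function, quantile function, random generation and
#' the Cole-Green z-transform for the three-parameter BCCG distribution used
#' by the LMS centile method.  A positive measurand `y` follows BCCG(M, S, L)
#' when
#' \deqn{z = \frac{(y/M)^L - 1}{L\,S}}
#' is standard normal (for \eqn{L = 0} the limit \eqn{z = \log(y/M)/S}, i.e.
#' the lognormal).  `M` is the median, `S` the coefficient of variation and
#' `L` the Box-Cox skewness power.
#'
#' The distribution is formally truncated to \eqn{y > 0}, which bounds `z` at
#' \eqn{-1/(LS)} when \eqn{L > 0}.  Following the usual Cole-Green convention
#' the truncation mass is ignored: it equals \eqn{\Phi(-1/(|L|S))} and is
#' negligible (far below 1e-6) for the small \eqn{S|L|} seen in spirometry;
#' [bccg_truncation_mass()] reports it so fitted models can assert the bound.
#'
#' @param x,q vector of positive quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param mu median M, positive.
#' @param sigma coefficient of variation S, positive.
#' @param nu Box-Cox power L (any real; `|nu| < 1e-6` uses the lognormal
#'   limit).
#' @param log logical; return log-density.
#'
#' @return `dbccg` the density, `pbccg` the CDF, `qbccg` quantiles, `rbccg`
#'   random draws, `bccg_z` standard-normal deviates, `bccg_truncation_mass`
#'   the probability mass lost to the `y > 0` truncation.
#'
#' @examples
#' qbccg(0.5, mu = 3, sigma = 0.12, nu = 0.8)   # the median, 3
#' pbccg(qbccg(0.05, 3, 0.12, 0.8), 3, 0.12, 0.8)
#' bccg_z(3, mu = 3, sigma = 0.2, nu = 1.5)     # y = M maps to z = 0
#' @name bccg
NULL

# switch tolerance for the lognormal (L = 0) branch
.L0_TOL <- 1e-6

SPIRO_INDICES <- c("fev1", "fvc", "fev1_fvc", "fef2575")
SPIRO_SEXES <- c("male", "female")

.check_musigma <- function(mu, sigma) {
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("BCCG requires mu > 0", call. = FALSE)
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("BCCG requires sigma > 0", call. = FALSE)
}

#' @rdname bccg
#' @param y vector of positive measurand values.
#' @export
bccg_z <- function(y, mu, sigma, nu) {
  .check_musigma(mu, sigma)
  if (any(!is.finite(y)) || any(y <= 0))
    stop("bccg_z requires y > 0", call. = FALSE)
  k <- pmax(length(y), length(mu), length(sigma), length(nu))
  y <- rep_len(y, k); mu <- rep_len(mu, k)
  sigma <- rep_len(sigma, k); nu <- rep_len(nu, k)
  r <- log(y / mu)
  ifelse(abs(nu) < .L0_TOL,
         r / sigma,
         (exp(nu * r) - 1) / (nu * sigma))
}

#' @rdname bccg
#' @export
dbccg <- function(x, mu, sigma, nu, log = FALSE) {
  z <- bccg_z(x, mu, sigma, nu)
  k <- length(z)
  x <- rep_len(x, k); mu <- rep_len(mu, k)
  sigma <- rep_len(sigma, k); nu <- rep_len(nu, k)
  ld <- (nu - 1) * base::log(x) - nu * base::log(mu) -
    base::log(sigma) + stats::dnorm(z, log = TRUE)
  if (log) ld else exp(ld)
}

#' @rdname bccg
#' @export
pbccg <- function(q, mu, sigma, nu) {
  stats::pnorm(bccg_z(q, mu, sigma, nu))
}

#' @rdname bccg
#' @export
qbccg <- function(p, mu, sigma, nu) {
  .check_musigma(mu, sigma)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("qbccg requires probabilities strictly inside (0, 1)", call. = FALSE)
  k <- pmax(length(p), length(mu), length(sigma), length(nu))
  p <- rep_len(p, k); mu <- rep_len(mu, k)
  sigma <- rep_len(sigma, k); nu <- rep_len(nu, k)
  zp <- stats::qnorm(p)
  arg <- 1 + nu * sigma * zp
  bad <- abs(nu) >= .L0_TOL & arg <= 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(paste0(
      "qbccg: probability %.3g lies beyond the BCCG truncation bound ",
      "z = -1/(L*S) = %.4g for (L = %.4g, S = %.4g)"),
      p[i], -1 / (nu[i] * sigma[i]), nu[i], sigma[i]), call. = FALSE)
  }
  ifelse(abs(nu) < .L0_TOL,
         mu * exp(sigma * zp),
         mu * arg^(1 / nu))
}

#' @rdname bccg
#' @param seed optional integer seed; when supplied, draws are reproducible
#'   and the caller's RNG state is left untouched.
#' @export
rbccg <- function(n, mu, sigma, nu, seed = NULL) {
  .check_musigma(mu, sigma)
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("rbccg requires a positive n", call. = FALSE)
  draw <- function() {
    mu_ <- rep_len(mu, n); sigma_ <- rep_len(sigma, n); nu_ <- rep_len(nu, n)
    z <- stats::rnorm(n)
    # resample the (sub-1e-6 mass) tail beyond the y > 0 truncation bound
    for (it in 1:100) {
      bad <- abs(nu_) >= .L0_TOL & (1 + nu_ * sigma_ * z) <= 0
      if (!any(bad)) break
      z[bad] <- stats::rnorm(sum(bad))
    }
    ifelse(abs(nu_) < .L0_TOL,
           mu_ * exp(sigma_ * z),
           mu_ * (1 + nu_ * sigma_ * z)^(1 / nu_))
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

#' @rdname bccg
#' @export
bccg_truncation_mass <- function(sigma, nu) {
  .check_musigma(1, sigma)
  k <- pmax(length(sigma), length(nu))
  sigma <- rep_len(sigma, k); nu <- rep_len(nu, k)
  ifelse(abs(nu) < .L0_TOL, 0, stats::pnorm(-1 / (abs(nu) * sigma)))
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
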