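#' Poisson-Tweedie count sampling via its named special cases
#'
#' Draws overdispersed counts from the Poisson-Tweedie (PT) family
#' parameterized by mean \code{mu}, dispersion \code{phi} = variance/mean,
#' and shape index \code{a}.  The three shapes supported are the family's
#' named special cases: \code{a = 1} is Poisson, \code{a = 0} is the
#' negative binomial (gamma-Poisson mixture) and \code{a = 0.5} is the
#' Poisson-inverse-Gaussian (inverse-Gaussian-Poisson mixture).
#'
#' For \code{a = 0}, \code{X | L ~ Poisson(L)} with
#' \code{L ~ Gamma(shape = mu/(phi-1), scale = phi-1)}, so
#' \code{E[X] = mu} and \code{Var[X] = phi * mu}.  For \code{a = 0.5},
#' \code{L ~ InvGauss(mean = mu, shape = mu^2/(phi-1))}, giving the same
#' first two moments.  \code{phi = 1} degenerates to Poisson for every
#' shape.
#'
#' @param mu positive mean spectral count.
#' @param phi dispersion (variance/mean), must be >= 1.
#' @param a shape index, one of 1 (Poisson), 0 (negative binomial),
#'   0.5 (Poisson-inverse-Gaussian).
#' @param n number of draws.
#' @param seed optional integer seed; when supplied the draw is
#'   reproducible and the caller's RNG state is left untouched.
#' @return integer vector of \code{n} nonnegative counts.
#' @examples
#' x <- sample_pt_counts(mu = 10, phi = 4, a = 0, n = 1000, seed = 1)
#' mean(x); var(x) / mean(x)   # ~10 and ~4
#' @export
sample_pt_counts <- function(mu, phi, a, n, seed = NULL) {
  stopifnot(length(mu) == 1L, length(phi) == 1L, length(a) == 1L)
  if (!is.finite(mu) || mu <= 0) stop("'mu' must be a positive real")
  if (!is.finite(phi) || phi < 1)
    stop("'phi' must be >= 1 (underdispersion is not supported)")
  if (!a %in% c(1, 0, 0.5))
    stop("'a' must be one of 1 (Poisson), 0 (NB), 0.5 (PIG)")
  if (a == 1 && phi > 1)
    stop("a = 1 (Poisson) is inconsistent with phi > 1")
  if (n == 0) return(integer(0))

  draw <- function() {
    if (phi == 1 || a == 1) {
      stats::rpois(n, mu)
    } else if (a == 0) {
      lambda <- stats::rgamma(n, shape = mu / (phi - 1), scale = phi - 1)
      stats::rpois(n, lambda)
    } else {
      lambda <- rinvgauss(n, mean = mu, shape = mu^2 / (phi - 1))
      stats::rpois(n, lambda)
    }
  }
  as.integer(with_seed(seed, draw()))
}

#' Inverse-Gaussian random deviates
#'
#' Michael-Schucany-Haas transformation sampler for the inverse-Gaussian
#' (Wald) distribution, used as the PT mixing density at shape a = 0.5.
#'
#' @param n number of draws.
#' @param mean distribution mean (> 0).
#' @param shape shape parameter lambda (> 0); variance is mean^3/shape.
#' @return positive numeric vector.
#' @keywords internal
rinvgauss <- function(n, mean, shape) {
  stopifnot(mean > 0, shape > 0)
  y <- stats::rchisq(n, df = 1)
  x1 <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + x1), x1, mean^2 / x1)
}

#' Poisson-inverse-Gaussian log point mass
#'
#' Closed-form log pmf of the PIG distribution (mean mu, dispersion phi)
#' via modified Bessel functions of the second kind at half-integer
#' order, computed by an upward recurrence held entirely in log space so
#' that large counts neither overflow nor underflow.
#'
#' @param x nonnegative integer counts.
#' @param mu mean (> 0).
#' @param phi dispersion (> 1; use the Poisson pmf at phi = 1).
#' @return log probabilities, same length as \code{x}.
#' @keywords internal
dpig_log <- function(x, mu, phi) {
  stopifnot(mu > 0, phi > 1, all(x >= 0), all(x == round(x)))
  lambda <- mu^2 / (phi - 1)           # inverse-Gaussian shape
  A <- 1 + lambda / (2 * mu^2)
  B <- lambda / 2
  z <- 2 * sqrt(A * B)
  # log K_{m + 1/2}(z) for m = 0 .. max(x) - 1 (K_{-1/2} = K_{1/2})
  mmax <- max(max(x) - 1L, 0L)
  logK <- numeric(mmax + 1L)
  logK[1L] <- 0.5 * log(pi / (2 * z)) - z            # K_{1/2}
  if (mmax >= 1L)
    logK[2L] <- logK[1L] + log1p(1 / z)              # K_{3/2}
  if (mmax >= 2L) {
    for (m in 2:mmax) {                               # K_{m+1/2}
      a1 <- logK[m - 1L]
      a2 <- log(2 * (m - 0.5) / z) + logK[m]
      hi <- pmax(a1, a2)
      logK[m + 1L] <- hi + log1p(exp(min(a1, a2) - hi))
    }
  }
  nu <- x - 0.5
  logKx <- logK[pmax(x, 1L)]           # order |x - 1/2|
  0.5 * log(lambda / (2 * pi)) + lambda / mu - lfactorial(x) +
    log(2) + (nu / 2) * (log(B) - log(A)) + logKx
}

#' Negative binomial log point mass in (mu, phi) parameterization
#' @keywords internal
dnb_log <- function(x, mu, phi) {
  stopifnot(mu > 0, phi > 1)
  stats::dnbinom(x, mu = mu, size = mu / (phi - 1), log = TRUE)
}

# Run an expression under a temporary seed, restoring the caller's RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
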