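#' Uncertain scalar quantity
#'
#' Container for a scalar random variable described by its first four moments.
#' The reliability pipeline treats every input (trabecular BMD, hip contact
#' load, yield strain) as one of these; the normal defaults (skewness 0,
#' kurtosis 3) match the distributional assumptions of the FOSM method.
#'
#' @param mean Mean, in the units of the quantity.
#' @param sd Standard deviation, same units; must be >= 0.
#' @param skewness Standardised third moment; 0 for a normal variable.
#' @param kurtosis Standardised fourth moment (not excess); 3 for a normal
#'   variable. Must satisfy the Pearson inequality
#'   `kurtosis >= 1 + skewness^2`.
#' @param label Optional name used in sample-matrix headers and reports.
#'
#' @return An object of class `random_variable`: a list with elements
#'   `mean`, `sd`, `skewness`, `kurtosis`, `label`.
#'
#' @examples
#' bmd <- random_variable(0.5, 0.175, label = "BMD")
#' cov_of(bmd)
#' @seealso [from_mean_cov()], [product_moments()], [square_moments()]
#' @export
random_variable <- function(mean, sd, skewness = 0, kurtosis = 3,
                            label = "") {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(sd), length(sd) == 1L, is.finite(sd))
  if (sd < 0) {
    stop("'sd' must be non-negative, got ", sd)
  }
  if (kurtosis < 1 + skewness^2) {
    stop("kurtosis must satisfy the Pearson inequality ",
         "kurtosis >= 1 + skewness^2 (got kurtosis = ", kurtosis,
         ", skewness = ", skewness, ")")
  }
  structure(
    list(mean = as.numeric(mean), sd = as.numeric(sd),
         skewness = as.numeric(skewness), kurtosis = as.numeric(kurtosis),
         label = as.character(label)),
    class = "random_variable"
  )
}

#' Build a random variable from a mean and coefficient of variation
#'
#' The scenario tables specify uncertainty as a coefficient of variation
#' (COV = sd/mean), so the standard deviation is `|mean| * cov`. The variable
#' is taken as normal (skewness 0, kurtosis 3).
#'
#' @param mean Mean; must be non-zero (COV is undefined at mean 0).
#' @param cov Coefficient of variation, >= 0.
#' @param label Optional name.
#'
#' @return A [random_variable()].
#' @examples
#' from_mean_cov(0.3375, 0.1, "BMD 50-64") # sd 0.03375
#' @export
from_mean_cov <- function(mean, cov, label = "") {
  stopifnot(is.numeric(mean), length(mean) == 1L,
            is.numeric(cov), length(cov) == 1L)
  if (cov < 0) stop("'cov' must be non-negative")
  if (mean == 0 && cov > 0) {
    stop("coefficient of variation is undefined for a zero mean")
  }
  random_variable(mean, abs(mean) * cov, label = label)
}

#' Coefficient of variation of a random variable
#'
#' @param x A [random_variable()].
#' @return `sd/mean`; errors when the mean is zero.
#' @export
cov_of <- function(x) {
  stopifnot(inherits(x, "random_variable"))
  if (x$mean == 0) stop("coefficient of variation is undefined at mean 0")
  x$sd / x$mean
}

#' @export
print.random_variable <- function(x, ...) {
  lbl <- if (nzchar(x$label)) paste0(" '", x$label, "'") else ""
  cat(sprintf("random_variable%s: mean %g, sd %g (skewness %g, kurtosis %g)\n",
              lbl, x$mean, x$sd, x$skewness, x$kurtosis))
  invisible(x)
}

new_term_moments <- function(mean, var) {
  if (var < 0) {
    stop("moment propagation produced a negative variance (", var,
         "); check skewness/kurtosis inputs")
  }
  structure(list(mean = mean, sd = sqrt(var)), class = "term_moments")
}

#' Moments of a product of two independent random variables
#'
#' For independent X and Y, `E[XY] = mu_x mu_y` and
#' `Var(XY) = (sigma_x^2 + mu_x^2)(sigma_y^2 + mu_y^2) - mu_x^2 mu_y^2`.
#' These are exact (no normality needed) and are the building block the
#' term-wise FOSM mode uses for the BMD x BW cross term.
#'
#' @param x,y [random_variable()] objects, assumed independent.
#' @return A `term_moments` object with elements `mean` and `sd`.
#' @examples
#' product_moments(random_variable(0.3375, 0.03375),
#'                 random_variable(2.38, 0.238))
#' @export
product_moments <- function(x, y) {
  stopifnot(inherits(x, "random_variable"), inherits(y, "random_variable"))
  m <- x$mean * y$mean
  v <- (x$sd^2 + x$mean^2) * (y$sd^2 + y$mean^2) - x$mean^2 * y$mean^2
  new_term_moments(m, v)
}

#' Moments of the square of a random variable
#'
#' `E[X^2] = mu^2 + sigma^2` always. The variance uses the general
#' fourth-moment expression
#' `Var(X^2) = 4 mu^2 sigma^2 + 4 mu gamma sigma^3 + (kappa - 1) sigma^4`,
#' where `gamma` is the skewness and `kappa` the kurtosis; for a normal
#' variable this reduces to `4 mu^2 sigma^2 + 2 sigma^4`.
#'
#' @param x A [random_variable()].
#' @return A `term_moments` object with elements `mean` and `sd`.
#' @examples
#' square_moments(random_variable(0, 1)) # chi-square(1): mean 1, var 2
#' @export
square_moments <- function(x) {
  stopifnot(inherits(x, "random_variable"))
  m <- x$mean^2 + x$sd^2
  v <- 4 * x$mean^2 * x$sd^2 +
    4 * x$mean * x$skewness * x$sd^3 +
    (x$kurtosis - 1) * x$sd^4
  new_term_moments(m, v)
}

#' @export
print.term_moments <- function(x, ...) {
  cat(sprintf("term_moments: mean %g, sd %g\n", x$mean, x$sd))
  invisible(x)
}

# Raw moments E[X^k], k = 0..4, of a normal variable; used by the
# exact-moment propagation mode.
normal_raw_moments <- function(mu, sigma) {
  c(1,
    mu,
    mu^2 + sigma^2,
    mu^3 + 3 * mu * sigma^2,
    mu^4 + 6 * mu^2 * sigma^2 + 3 * sigma^4)
}
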