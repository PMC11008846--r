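#' Compressive yield criterion for trabecular bone
#'
#' The capacity side of the performance function: trabecular bone is taken to
#' yield at a compressive strain of 0.85% with a standard deviation of 0.10%
#' (normal). Stored as a fraction: mean 0.0085, sd 0.0010.
#'
#' @param mean Yield strain mean (fraction).
#' @param sd Yield strain standard deviation (fraction).
#' @return A `yield_criterion` wrapping a [random_variable()] named `yield`.
#' @export
yield_criterion <- function(mean = 0.0085, sd = 0.0010) {
  structure(list(yield = random_variable(mean, sd, label = "yield_strain")),
            class = "yield_criterion")
}

check_normal_inputs <- function(bmd, bw) {
  stopifnot(inherits(bmd, "random_variable"), inherits(bw, "random_variable"))
  if (bmd$skewness != 0 || bmd$kurtosis != 3 ||
      bw$skewness != 0 || bw$kurtosis != 3) {
    warning("moment propagation assumes normal inputs; ",
            "non-normal skewness/kurtosis are used only where the formulas ",
            "support them")
  }
  invisible(NULL)
}

#' Strain moments by term-wise FOSM propagation
#'
#' The replication mode of the pipeline. Each regressor of the quadratic
#' surrogate (BMD, BW, BMD*BW, BMD^2, BW^2) is reduced to a mean and standard
#' deviation with the closed-form product/square moment formulas
#' ([product_moments()], [square_moments()]), and the five terms are then
#' combined *as if independent*:
#' `mu_S = scale * (a0 + sum_i a_i * mu_i)` and
#' `sigma_S = scale * sqrt(sum_i a_i^2 * sigma_i^2)`.
#' Ignoring the covariances among the derived terms (e.g. between BMD and
#' BMD^2) systematically overstates or understates `sigma_S` depending on the
#' coefficient signs; [strain_moments_exact()] carries the full covariance
#' structure and is the recommended mode for new analyses.
#'
#' @param model A [quadratic_response_model()].
#' @param bmd,bw [random_variable()] inputs, independent normals.
#' @return List with `mu_S` and `sigma_S` (strain fractions).
#' @export
strain_moments_termwise <- function(model, bmd, bw) {
  stopifnot(inherits(model, "quadratic_response_model"))
  check_normal_inputs(bmd, bw)
  a <- model$coefficients
  terms <- list(
    list(mean = bmd$mean, sd = bmd$sd),
    list(mean = bw$mean, sd = bw$sd),
    product_moments(bmd, bw),
    square_moments(bmd),
    square_moments(bw))
  w <- a[c("a1", "a2", "a3", "a4", "a5")]
  mu <- model$scale *
    (a[["a0"]] + sum(w * vapply(terms, `[[`, numeric(1), "mean")))
  sigma <- model$scale *
    sqrt(sum(w^2 * vapply(terms, `[[`, numeric(1), "sd")^2))
  list(mu_S = mu, sigma_S = sigma)
}

#' Strain moments by first-order Taylor expansion
#'
#' Mean-value first-order second-moment approximation: `mu_S` is the
#' surrogate evaluated at the input means and
#' `sigma_S^2 = (dS/dBMD)^2 sigma_BMD^2 + (dS/dBW)^2 sigma_BW^2` with the
#' gradient taken at the means (inputs independent, so no cross term). Exact
#' for a linear surrogate; for the quadratic surrogate it drops the
#' second-order variance contributions.
#'
#' @inheritParams strain_moments_termwise
#' @return List with `mu_S` and `sigma_S`.
#' @export
strain_moments_taylor <- function(model, bmd, bw) {
  stopifnot(inherits(model, "quadratic_response_model"))
  check_normal_inputs(bmd, bw)
  a <- model$coefficients
  mu <- evaluate_strain(model, bmd$mean, bw$mean, warn_envelope = FALSE)
  d_bmd <- model$scale *
    (a[["a1"]] + a[["a3"]] * bw$mean + 2 * a[["a4"]] * bmd$mean)
  d_bw <- model$scale *
    (a[["a2"]] + a[["a3"]] * bmd$mean + 2 * a[["a5"]] * bw$mean)
  list(mu_S = mu, sigma_S = sqrt(d_bmd^2 * bmd$sd^2 + d_bw^2 * bw$sd^2))
}

#' Exact strain moments for normal inputs
#'
#' Closed-form mean and variance of the quadratic surrogate in two
#' independent normal variables, including every covariance among the five
#' regressor terms. Writing the surrogate as
#' `S = scale * sum_k c_k X^{p_k} W^{q_k}`, independence gives
#' `E[X^i W^j] = E[X^i] E[W^j]`, and the normal raw moments up to order four
#' (`E[X^2] = mu^2 + sigma^2`, `E[X^3] = mu^3 + 3 mu sigma^2`,
#' `E[X^4] = mu^4 + 6 mu^2 sigma^2 + 3 sigma^4`) close both `E[S]` and
#' `E[S^2]`. Serves as the analytic oracle for the two approximate modes.
#'
#' @inheritParams strain_moments_termwise
#' @return List with `mu_S` and `sigma_S`.
#' @export
strain_moments_exact <- function(model, bmd, bw) {
  stopifnot(inherits(model, "quadratic_response_model"))
  check_normal_inputs(bmd, bw)
  a <- model$coefficients
  p <- c(0, 1, 0, 1, 2, 0) # BMD powers of the six terms
  q <- c(0, 0, 1, 1, 0, 2) # BW powers
  mx <- normal_raw_moments(bmd$mean, bmd$sd)
  mw <- normal_raw_moments(bw$mean, bw$sd)
  es <- sum(a * mx[p + 1] * mw[q + 1])
  es2 <- 0
  for (k in 1:6) {
    es2 <- es2 + sum(a[k] * a * mx[p[k] + p + 1] * mw[q[k] + q + 1])
  }
  v <- max(es2 - es^2, 0) # guard tiny negative round-off
  list(mu_S = model$scale * es, sigma_S = model$scale * sqrt(v))
}

#' Strain moments in a named mode
#'
#' Dispatcher over the three analytic propagation modes.
#'
#' @inheritParams strain_moments_termwise
#' @param mode One of `"paper_termwise"`, `"taylor_first_order"`,
#'   `"exact_moments"`.
#' @return List with `mu_S` and `sigma_S`.
#' @export
strain_moments <- function(model, bmd, bw,
                           mode = c("paper_termwise", "taylor_first_order",
                                    "exact_moments")) {
  mode <- match.arg(mode)
  switch(mode,
         paper_termwise = strain_moments_termwise(model, bmd, bw),
         taylor_first_order = strain_moments_taylor(model, bmd, bw),
         exact_moments = strain_moments_exact(model, bmd, bw))
}

new_performance_summary <- function(mode, mu_S, sigma_S, mu_Z, sigma_Z,
                                    beta, pof, n_mc = NA_integer_,
                                    seed = NA_integer_) {
  structure(list(mode = mode, mu_S = mu_S, sigma_S = sigma_S,
                 mu_Z = mu_Z, sigma_Z = sigma_Z, beta = beta, pof = pof,
                 n_mc = n_mc, seed = seed),
            class = "performance_summary")
}

#' Probability of failure from strain moments
#'
#' FOSM reliability step. The performance function is `Z = Y - S` (capacity
#' minus demand): `mu_Z = mu_Y - mu_S`,
#' `sigma_Z = sqrt(sigma_S^2 + sigma_Y^2)`, the reliability index is
#' `beta = mu_Z / sigma_Z`, and `PoF = 1 - pnorm(beta)`. When both standard
#' deviations vanish the step-function limit is used (PoF 0 or 1, with a
#' warning).
#'
#' @param moments List with `mu_S`, `sigma_S` (from one of the
#'   `strain_moments_*` functions).
#' @param criterion A [yield_criterion()].
#' @param mode Mode label recorded in the summary.
#' @return A `performance_summary` with fields `mode`, `mu_S`, `sigma_S`,
#'   `mu_Z`, `sigma_Z`, `beta`, `pof`.
#' @examples
#' m <- strain_moments_termwise(published_model(),
#'                              from_mean_cov(0.3375, 0.1, "BMD"),
#'                              from_mean_cov(2.38, 0.1, "BW"))
#' pof_analytic(m, yield_criterion())
#' @export
pof_analytic <- function(moments, criterion = yield_criterion(),
                         mode = "paper_termwise") {
  stopifnot(is.list(moments), all(c("mu_S", "sigma_S") %in% names(moments)),
            inherits(criterion, "yield_criterion"))
  y <- criterion$yield
  mu_Z <- y$mean - moments$mu_S
  sigma_Z <- sqrt(moments$sigma_S^2 + y$sd^2)
  if (sigma_Z == 0) {
    warning("sigma_Z = 0: degenerate performance function, ",
            "PoF is a step function of the means")
    beta <- if (mu_Z > 0) Inf else -Inf
    pof <- if (moments$mu_S >= y$mean) 1 else 0
  } else {
    beta <- mu_Z / sigma_Z
    pof <- stats::pnorm(beta, lower.tail = FALSE)
  }
  new_performance_summary(mode, moments$mu_S, moments$sigma_S,
                          mu_Z, sigma_Z, beta, pof)
}

#' Probability of failure by Monte Carlo
#'
#' Verification oracle: draws `(bmd, bw, yield)` i.i.d. normal (untruncated
#' by default, matching the analytic modes' assumptions) and reports the
#' fraction of draws with predicted strain exceeding the sampled yield
#' strain, its binomial standard error, and the empirical moments of Z.
#' Unlike the FOSM modes it does not assume Z is normal, so in the far tail
#' it can differ from the analytic values by more than its standard error;
#' that gap measures the normality approximation, not sampling noise.
#'
#' @param model A [quadratic_response_model()].
#' @param bmd,bw [random_variable()] inputs.
#' @param criterion A [yield_criterion()].
#' @param n Number of draws (>= 1e4).
#' @param seed Integer seed.
#' @param truncate_at Optional lower bound applied to the BMD draws
#'   (sensitivity analyses only).
#' @return A `performance_summary` with `mode = "monte_carlo"`, empirical
#'   `mu_S`/`sigma_S`/`mu_Z`/`sigma_Z`, `pof`, plus `n_mc`, `seed` and
#'   attribute `se` (binomial standard error of `pof`).
#' @export
pof_monte_carlo <- function(model, bmd, bw, criterion = yield_criterion(),
                            n = 1e6, seed = 1L, truncate_at = NULL) {
  stopifnot(inherits(model, "quadratic_response_model"))
  if (n < 1e4) stop("'n' must be at least 1e4 for a usable tail estimate")
  vars <- list(bmd, bw, criterion$yield)
  sm <- if (is.null(truncate_at)) {
    monte_carlo(vars, n, seed)
  } else {
    # truncate only the BMD column
    set.seed(as.integer(seed))
    b <- stats::rnorm(n, bmd$mean, bmd$sd)
    bad <- which(b < truncate_at)
    while (length(bad)) {
      b[bad] <- stats::rnorm(length(bad), bmd$mean, bmd$sd)
      bad <- bad[b[bad] < truncate_at]
    }
    cbind(b, stats::rnorm(n, bw$mean, bw$sd),
          stats::rnorm(n, criterion$yield$mean, criterion$yield$sd))
  }
  # raw (possibly negative) draws on purpose: the oracle must match the
  # untruncated-normal assumptions of the analytic modes
  s <- eval_poly(model, sm[, 1], sm[, 2])
  z <- sm[, 3] - s
  pof <- mean(s > sm[, 3])
  out <- new_performance_summary(
    "monte_carlo", mean(s), stats::sd(s), mean(z), stats::sd(z),
    beta = mean(z) / stats::sd(z), pof = pof,
    n_mc = as.integer(n), seed = as.integer(seed))
  attr(out, "se") <- sqrt(pof * (1 - pof) / n)
  out
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf(
    "performance summary [%s]\n  mu_S = %.4g, sigma_S = %.4g\n  mu_Z = %.4g, sigma_Z = %.4g\n  beta = %.4g, PoF = %.4g (%.3g%%)\n",
    x$mode, x$mu_S, x$sigma_S, x$mu_Z, x$sigma_Z, x$beta, x$pof,
    100 * x$pof))
  if (!is.na(x$n_mc)) {
    cat(sprintf("  n = %d, seed = %d\n", x$n_mc, x$seed))
  }
  invisible(x)
}

#' @export
as.data.frame.performance_summary <- function(x, ...) {
  data.frame(mode = x$mode, mu_S = x$mu_S, sigma_S = x$sigma_S,
             mu_Z = x$mu_Z, sigma_Z = x$sigma_Z, beta = x$beta,
             pof = x$pof, n_mc = x$n_mc, seed = x$seed)
}

#' Serialize a performance summary to JSON
#'
#' @param x A `performance_summary`.
#' @param path Optional path; when given the JSON is written there.
#' @return JSON string, invisibly when `path` is given.
#' @export
performance_summary_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "performance_summary"))
  j <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                        na = "null")
  if (!is.null(path)) {
    writeLines(j, path)
    return(invisible(j))
  }
  j
}
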