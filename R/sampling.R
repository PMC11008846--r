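#' Latin hypercube sample of independent normal variables
#'
#' Draws `n` stratified samples for each variable: the unit interval is cut
#' into `n` equiprobable strata, each stratum receives exactly one draw
#' (uniform within the stratum by default, the stratum midpoint with
#' `rule = "midpoint"`), columns are independently permuted, and the uniforms
#' are mapped through the normal quantile function. LHS converges on the input
#' means and variances considerably faster than plain Monte Carlo at equal
#' `n`, which is why it is used to place the virtual-experiment design points.
#'
#' @param variables List of [random_variable()] objects (all treated as
#'   independent normals).
#' @param n Number of samples, >= 1.
#' @param seed Integer seed; the whole matrix is reproducible from it.
#' @param rule Within-stratum placement, `"random"` (default) or
#'   `"midpoint"`.
#'
#' @return A `sample_matrix`: an `n` x `length(variables)` numeric matrix with
#'   variable labels as column names and attributes `seed` and `method`.
#' @examples
#' sm <- latin_hypercube(list(random_variable(0.5, 0.175, label = "bmd"),
#'                            random_variable(2, 0.4, label = "bw")),
#'                       n = 100, seed = 42)
#' colMeans(sm)
#' @export
latin_hypercube <- function(variables, n, seed,
                            rule = c("random", "midpoint")) {
  rule <- match.arg(rule)
  check_variables(variables)
  if (n < 1) stop("'n' must be at least 1")
  k <- length(variables)
  set.seed(as.integer(seed))
  u <- if (rule == "random") {
    lhs::randomLHS(as.integer(n), k)
  } else {
    # one midpoint per stratum, independently permuted per column
    vapply(seq_len(k),
           function(j) (sample.int(n) - 0.5) / n,
           numeric(n))
  }
  u <- matrix(u, nrow = n, ncol = k)
  x <- vapply(seq_len(k), function(j) {
    v <- variables[[j]]
    if (v$sd == 0) rep(v$mean, n) else stats::qnorm(u[, j], v$mean, v$sd)
  }, numeric(n))
  new_sample_matrix(matrix(x, nrow = n, ncol = k), variables, seed, "lhs")
}

#' Plain Monte Carlo sample of independent normal variables
#'
#' I.i.d. normal draws, optionally resampling values below a floor (for
#' physically non-negative quantities such as BMD at high coefficients of
#' variation). Truncation is off by default so that Monte Carlo estimates
#' match the untruncated-normal assumptions of the analytic reliability
#' modes; when any raw draw falls below `truncate_at` a warning reports how
#' many were resampled.
#'
#' @inheritParams latin_hypercube
#' @param truncate_at Optional lower bound; draws below it are redrawn.
#' @return A `sample_matrix` (see [latin_hypercube()]) with method `"mc"`.
#' @export
monte_carlo <- function(variables, n, seed, truncate_at = NULL) {
  check_variables(variables)
  if (n < 1) stop("'n' must be at least 1")
  k <- length(variables)
  set.seed(as.integer(seed))
  x <- vapply(seq_len(k), function(j) {
    v <- variables[[j]]
    draws <- stats::rnorm(n, v$mean, v$sd)
    if (!is.null(truncate_at)) {
      bad <- which(draws < truncate_at)
      if (length(bad)) {
        warning(length(bad), " draw(s) of '", v$label,
                "' fell below ", truncate_at, " and were resampled")
        while (length(bad)) {
          draws[bad] <- stats::rnorm(length(bad), v$mean, v$sd)
          bad <- bad[draws[bad] < truncate_at]
        }
      }
    }
    draws
  }, numeric(n))
  new_sample_matrix(matrix(x, nrow = n, ncol = k), variables, seed, "mc")
}

new_sample_matrix <- function(x, variables, seed, method) {
  labels <- vapply(variables, function(v) v$label, character(1))
  labels[!nzchar(labels)] <- paste0("x", which(!nzchar(labels)))
  colnames(x) <- labels
  structure(x, seed = as.integer(seed), method = method,
            class = c("sample_matrix", class(x)))
}

check_variables <- function(variables) {
  if (!is.list(variables) || !length(variables) ||
      !all(vapply(variables, inherits, logical(1), "random_variable"))) {
    stop("'variables' must be a non-empty list of random_variable objects")
  }
  invisible(variables)
}

#' Write a sample matrix to CSV
#'
#' One column per variable, labelled header row; a comment line records the
#' sampling method and seed so the file is self-describing.
#'
#' @param x A `sample_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(x, path) {
  stopifnot(inherits(x, "sample_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# method=%s seed=%d", attr(x, "method"),
                     attr(x, "seed")), con)
  utils::write.csv(as.data.frame(unclass(x)), con, row.names = FALSE)
  invisible(path)
}
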