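#' Quadratic strain response surface
#'
#' The surrogate for the peak compressive strain `S` in the proximal
#' trabecular bone as a function of apparent BMD (g/cm^3) and hip contact
#' load BW (body-weight multiples):
#'
#' `S = scale * (a0 + a1*BMD + a2*BW + a3*BMD*BW + a4*BMD^2 + a5*BW^2)`
#'
#' Coefficients are stored on the "printed" scale with a separate global
#' multiplier (default `1e-3`) so the published model is represented exactly
#' as reported. Strain is a dimensionless fraction throughout (0.85% is
#' 0.0085); percent appears only in formatted output.
#'
#' @param a0,a1,a2,a3,a4,a5 Polynomial coefficients on the printed scale.
#' @param scale Global multiplier applied to the polynomial.
#' @return An object of class `quadratic_response_model`.
#' @examples
#' m <- published_model()
#' evaluate_strain(m, bmd = 0.3375, bw = 2.38)
#' @export
quadratic_response_model <- function(a0, a1, a2, a3, a4, a5, scale = 1e-3) {
  coef <- c(a0 = a0, a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5)
  stopifnot(all(is.finite(coef)), is.finite(scale))
  structure(list(coefficients = coef, scale = scale),
            class = "quadratic_response_model")
}

#' @rdname quadratic_response_model
#' @details `published_model()` returns the reported fit to 100 finite-element
#'   simulations: `a0 = 4.09`, `a1 = -17.66`, `a2 = 2.80`, `a3 = -2.35`,
#'   `a4 = 15.67`, `a5 = -0.05`, scale `1e-3`.
#' @export
published_model <- function() {
  quadratic_response_model(4.09, -17.66, 2.80, -2.35, 15.67, -0.05,
                           scale = 1e-3)
}

# Training envelope (mean +/- 3 sd of the virtual-experiment sampling
# distributions); evaluations outside it are extrapolations.
training_envelope <- function() {
  list(bmd = c(0.5 - 3 * 0.175, 0.5 + 3 * 0.175),
       bw = c(2 - 3 * 0.4, 2 + 3 * 0.4))
}

#' Evaluate the strain surrogate
#'
#' @param model A [quadratic_response_model()].
#' @param bmd Apparent BMD in g/cm^3 (vectorised); must be >= 0.
#' @param bw Load in body-weight multiples (vectorised); must be >= 0.
#' @param warn_envelope Warn when evaluating outside the training envelope
#'   (BMD or BW beyond mean +/- 3 sd of the design distributions).
#' @return Strain as a dimensionless fraction.
#' @export
evaluate_strain <- function(model, bmd, bw, warn_envelope = TRUE) {
  stopifnot(inherits(model, "quadratic_response_model"))
  if (any(bmd < 0)) stop("'bmd' must be non-negative")
  if (any(bw < 0)) stop("'bw' must be non-negative")
  if (warn_envelope) {
    env <- training_envelope()
    if (any(bmd < env$bmd[1] | bmd > env$bmd[2]) ||
        any(bw < env$bw[1] | bw > env$bw[2])) {
      warning("evaluating outside the training envelope (BMD in [",
              signif(env$bmd[1], 3), ", ", signif(env$bmd[2], 3),
              "], BW in [", signif(env$bw[1], 3), ", ",
              signif(env$bw[2], 3), "]); treat as extrapolation")
    }
  }
  eval_poly(model, bmd, bw)
}

# Polynomial evaluation without domain checks; the Monte Carlo oracle uses
# it on raw normal draws, which may be negative.
eval_poly <- function(model, bmd, bw) {
  a <- model$coefficients
  model$scale * (a[["a0"]] + a[["a1"]] * bmd + a[["a2"]] * bw +
                   a[["a3"]] * bmd * bw + a[["a4"]] * bmd^2 +
                   a[["a5"]] * bw^2)
}

#' @export
predict.quadratic_response_model <- function(object, newdata, ...) {
  evaluate_strain(object, newdata$bmd, newdata$bw, warn_envelope = FALSE)
}

#' @export
print.quadratic_response_model <- function(x, ...) {
  a <- x$coefficients
  cat(sprintf(
    "quadratic strain surrogate: S = %g * (%g %+g*BMD %+g*BW %+g*BMD*BW %+g*BMD^2 %+g*BW^2)\n",
    x$scale, a[["a0"]], a[["a1"]], a[["a2"]], a[["a3"]], a[["a4"]], a[["a5"]]))
  invisible(x)
}

#' Fit the quadratic surrogate by ordinary least squares
#'
#' Regresses strain on `{1, bmd, bw, bmd*bw, bmd^2, bw^2}` with
#' [stats::lm()]. Fitted coefficients are re-expressed on the printed scale
#' of `scale` (default `1e-3`) so fits are directly comparable with the
#' published model.
#'
#' @param data Data frame with columns `bmd`, `bw`, `strain` (>= 6 rows,
#'   non-collinear design).
#' @param scale Printed scale for the returned model.
#' @return List with elements `model` (a [quadratic_response_model()]),
#'   `stats` (class `fit_stats`: `sse`, `r_squared`, `adjusted_r_squared`,
#'   `rmse`, `n`, `p`), and `fit` (the underlying `lm` object).
#' @details With a constant response SST is zero; R-squared is then defined
#'   as 0 (with a warning) rather than NaN. `rmse` is the residual standard
#'   error, `sqrt(sse / (n - p))`.
#' @export
fit_response_surface <- function(data, scale = 1e-3) {
  req <- c("bmd", "bw", "strain")
  if (!all(req %in% names(data))) {
    stop("'data' must have columns ", paste(req, collapse = ", "))
  }
  n <- nrow(data)
  p <- 6L
  if (n < p) stop("need at least ", p, " samples to fit ", p, " coefficients")
  fit <- stats::lm(strain ~ bmd + bw + I(bmd * bw) + I(bmd^2) + I(bw^2),
                   data = data)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; collinear regressors: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  res <- stats::residuals(fit)
  sse <- sum(res^2)
  sst <- sum((data$strain - mean(data$strain))^2)
  if (sst == 0) {
    warning("constant response (SST = 0); defining R-squared = 0")
    r2 <- 0
    adj <- 0
  } else {
    r2 <- 1 - sse / sst
    adj <- 1 - (1 - r2) * (n - 1) / (n - p)
  }
  stats <- structure(
    list(sse = sse, r_squared = r2, adjusted_r_squared = adj,
         rmse = sqrt(sse / (n - p)), n = n, p = p),
    class = "fit_stats")
  model <- quadratic_response_model(
    cf[[1]] / scale, cf[[2]] / scale, cf[[3]] / scale,
    cf[[4]] / scale, cf[[5]] / scale, cf[[6]] / scale, scale = scale)
  list(model = model, stats = stats, fit = fit)
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf(
    "fit: n = %d, SSE = %.4g, R^2 = %.4f, adj. R^2 = %.4f, RMSE = %.4g\n",
    x$n, x$sse, x$r_squared, x$adjusted_r_squared, x$rmse))
  invisible(x)
}

#' BMD values on the failure boundary at a given load
#'
#' Solves `S(bmd, bw) = yield_strain` for BMD at fixed BW: the roots of
#' `a4*bmd^2 + (a1 + a3*bw)*bmd + (a0 + a2*bw + a5*bw^2 - yield/scale) = 0`,
#' filtered to `bmd >= 0`. An empty result means the whole BMD axis is on one
#' side of the boundary; evaluate the surrogate at `bmd = 0` to tell which.
#' A vanishing quadratic coefficient degrades gracefully to the linear solve.
#'
#' @param model A [quadratic_response_model()].
#' @param yield_strain Yield strain as a fraction, > 0.
#' @param bw Load in body-weight multiples.
#' @return Sorted numeric vector of non-negative BMD roots (possibly empty).
#' @examples
#' failure_boundary_bmd(published_model(), 0.0085, bw = 2.5)
#' @export
failure_boundary_bmd <- function(model, yield_strain, bw) {
  stopifnot(inherits(model, "quadratic_response_model"),
            length(bw) == 1L)
  if (yield_strain <= 0) stop("'yield_strain' must be positive")
  a <- model$coefficients
  A <- a[["a4"]]
  B <- a[["a1"]] + a[["a3"]] * bw
  C <- a[["a0"]] + a[["a2"]] * bw + a[["a5"]] * bw^2 -
    yield_strain / model$scale
  if (A == 0) {
    if (B == 0) return(numeric(0))
    roots <- -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) return(numeric(0))
    roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  sort(roots[roots >= 0])
}

#' Classify a (BMD, BW) grid into safe and failure regions
#'
#' @param model A [quadratic_response_model()].
#' @param yield_strain Yield strain (fraction).
#' @param bmd_grid,bw_grid Ascending grids of BMD and BW values.
#' @return Logical matrix (`length(bmd_grid)` x `length(bw_grid)`); `TRUE`
#'   where the predicted strain meets or exceeds the yield strain.
#' @export
classify_region <- function(model, yield_strain, bmd_grid, bw_grid) {
  stopifnot(!is.unsorted(bmd_grid), !is.unsorted(bw_grid))
  s <- outer(bmd_grid, bw_grid,
             function(b, w) evaluate_strain(model, b, w,
                                            warn_envelope = FALSE))
  s >= yield_strain
}

#' Export a classified region as a long-format data frame
#'
#' @inheritParams classify_region
#' @param path Optional CSV path; when given the table is also written there.
#' @return Data frame with columns `bmd`, `bw`, `strain`, `failure`.
#' @export
region_table <- function(model, yield_strain, bmd_grid, bw_grid,
                         path = NULL) {
  g <- expand.grid(bmd = bmd_grid, bw = bw_grid)
  g$strain <- evaluate_strain(model, g$bmd, g$bw, warn_envelope = FALSE)
  g$failure <- g$strain >= yield_strain
  if (!is.null(path)) utils::write.csv(g, path, row.names = FALSE)
  g
}

#' Round-trip a surrogate model through a YAML config file
#'
#' @param model A [quadratic_response_model()].
#' @param path File path.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns the model.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "quadratic_response_model"))
  yaml::write_yaml(c(as.list(model$coefficients),
                     list(scale = model$scale)), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c(paste0("a", 0:5), "scale")
  if (!all(need %in% names(cfg))) {
    stop("model config must contain keys ", paste(need, collapse = ", "))
  }
  quadratic_response_model(cfg$a0, cfg$a1, cfg$a2, cfg$a3, cfg$a4, cfg$a5,
                           scale = cfg$scale)
}
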