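#' Virtual-experiment configuration
#'
#' The pipeline's stand-in for a batch of finite-element simulations: design
#' points `(bmd, bw)` are placed by Latin hypercube from the stated design
#' distributions (BMD ~ N(0.5, 0.175) g/cm^3, load ~ N(2, 0.4) BW), and
#' strain responses come from a truth surrogate plus homoscedastic Gaussian
#' noise. The default noise sd, 6.57e-4, is the root of the reported residual
#' sum of squares over 100 runs (sqrt(4.316e-5 / 100)).
#'
#' @param n Number of virtual simulations (default 100).
#' @param bmd,bw Design distributions as [random_variable()] objects.
#' @param noise_sd Strain noise standard deviation (fraction), >= 0.
#' @param truth_model The generating [quadratic_response_model()]; defaults
#'   to [published_model()].
#' @param seed Integer seed.
#' @return A `virtual_experiment_config` list.
#' @export
virtual_experiment_config <- function(n = 100,
                                      bmd = random_variable(0.5, 0.175,
                                                            label = "bmd"),
                                      bw = random_variable(2, 0.4,
                                                           label = "bw"),
                                      noise_sd = 6.57e-4,
                                      truth_model = published_model(),
                                      seed = 1L) {
  stopifnot(n >= 1, noise_sd >= 0,
            inherits(bmd, "random_variable"), inherits(bw, "random_variable"),
            inherits(truth_model, "quadratic_response_model"))
  structure(list(n = as.integer(n), bmd = bmd, bw = bw,
                 noise_sd = noise_sd, truth_model = truth_model,
                 seed = as.integer(seed)),
            class = "virtual_experiment_config")
}

#' Generate a virtual-experiment dataset
#'
#' Draws the design by [latin_hypercube()] with the config seed, evaluates
#' the truth surrogate and adds i.i.d. Gaussian noise. Sampled BMD values
#' below 0.01 g/cm^3 are clipped to 0.01 (a finite-element input must be
#' physical) with a message reporting the count; the clipping applies only
#' here, never in the reliability oracles.
#'
#' @param config A [virtual_experiment_config()].
#' @return Data frame with columns `bmd`, `bw`, `strain`; attribute `config`
#'   carries the generating configuration.
#' @examples
#' d <- generate_virtual_experiment(virtual_experiment_config(seed = 7))
#' fit_response_surface(d)$stats
#' @export
generate_virtual_experiment <- function(config = virtual_experiment_config()) {
  stopifnot(inherits(config, "virtual_experiment_config"))
  sm <- latin_hypercube(list(config$bmd, config$bw), config$n, config$seed)
  bmd <- sm[, 1]
  n_clip <- sum(bmd < 0.01)
  if (n_clip > 0) {
    message(n_clip, " BMD draw(s) below 0.01 g/cm^3 clipped to 0.01")
    bmd <- pmax(bmd, 0.01)
  }
  bw <- pmax(sm[, 2], 0)
  truth <- evaluate_strain(config$truth_model, bmd, bw,
                           warn_envelope = FALSE)
  # latin_hypercube() already seeded the stream; the noise continues it, so
  # the full dataset is reproducible from the single config seed
  strain <- truth + stats::rnorm(config$n, 0, config$noise_sd)
  out <- data.frame(bmd = bmd, bw = bw, strain = strain)
  attr(out, "config") <- config
  out
}

#' Write/read a virtual-experiment dataset as CSV
#'
#' Columns `bmd_g_cm3`, `bw_multiples`, `strain_fraction`.
#'
#' @param data Data frame from [generate_virtual_experiment()] (or any frame
#'   with columns `bmd`, `bw`, `strain`).
#' @param path File path.
#' @return `write_dataset_csv()` returns `path` invisibly;
#'   `read_dataset_csv()` returns a data frame with columns `bmd`, `bw`,
#'   `strain`.
#' @export
write_dataset_csv <- function(data, path) {
  stopifnot(all(c("bmd", "bw", "strain") %in% names(data)))
  out <- data.frame(bmd_g_cm3 = data$bmd, bw_multiples = data$bw,
                    strain_fraction = data$strain)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  need <- c("bmd_g_cm3", "bw_multiples", "strain_fraction")
  if (!all(need %in% names(d))) {
    bad <- setdiff(need, names(d))
    stop("dataset is missing column(s): ", paste(bad, collapse = ", "))
  }
  data.frame(bmd = d$bmd_g_cm3, bw = d$bw_multiples,
             strain = d$strain_fraction)
}

#' Parameter-recovery experiment
#'
#' Repeated generate-then-fit cycles under one configuration: reports the
#' per-coefficient bias and root-mean-square error of the least-squares fits
#' against the truth model, and the distribution of the downstream
#' probability of failure when each fitted surrogate is pushed through the
#' reliability step for a reference scenario.
#'
#' @param reps Number of replicates (>= 10).
#' @param config A [virtual_experiment_config()]; replicate `r` uses seed
#'   `config$seed + r - 1`.
#' @param scenario Reference scenario for the downstream PoF (default
#'   50-64 / normal walking / COV 0.1, 0.9).
#' @param mode Propagation mode for the downstream PoF.
#' @return List with `coefficients` (data frame: `coefficient`, `truth`,
#'   `mean_estimate`, `bias`, `rmse`, `se_mean`), `pof` (numeric vector of
#'   downstream PoF per replicate), `pof_truth` (PoF under the truth model),
#'   and `estimates` (reps x 6 matrix of fitted coefficients on the printed
#'   scale).
#' @export
parameter_recovery_experiment <- function(reps = 100,
                                          config = virtual_experiment_config(),
                                          scenario = build_scenario(
                                            "50-64", "normal walking",
                                            0.1, 0.9),
                                          mode = "paper_termwise") {
  if (reps < 10) stop("'reps' must be at least 10")
  truth <- config$truth_model$coefficients
  est <- matrix(NA_real_, reps, 6,
                dimnames = list(NULL, names(truth)))
  pofs <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    d <- generate_virtual_experiment(cfg)
    f <- fit_response_surface(d, scale = config$truth_model$scale)
    est[r, ] <- f$model$coefficients
    pofs[r] <- scenario_pof(scenario, f$model, mode)$pof
  }
  bias <- colMeans(est) - truth
  rmse <- sqrt(colMeans(sweep(est, 2, truth)^2))
  se <- apply(est, 2, stats::sd) / sqrt(reps)
  list(
    coefficients = data.frame(
      coefficient = names(truth), truth = as.numeric(truth),
      mean_estimate = as.numeric(colMeans(est)), bias = as.numeric(bias),
      rmse = as.numeric(rmse), se_mean = as.numeric(se),
      row.names = NULL),
    pof = pofs,
    pof_truth = scenario_pof(scenario, config$truth_model, mode)$pof,
    estimates = est)
}
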