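# Shared fixtures for the test suite.

# Reference inputs: age 50-64 BMD and normal-walking load at COV 0.1.
ref_bmd <- function(cov = 0.1) from_mean_cov(0.3375, cov, "BMD")
ref_bw <- function(cov = 0.1) from_mean_cov(2.38, cov, "BW")

# A linear surrogate (a3 = a4 = a5 = 0): all analytic propagation modes
# must coincide exactly on it.
linear_model <- function(a0 = 4.09, a1 = -17.66, a2 = 2.80, scale = 1e-3) {
  quadratic_response_model(a0, a1, a2, 0, 0, 0, scale = scale)
}

# Noise-free draws from a model on a non-degenerate design.
noise_free_data <- function(model = published_model(), n = 100, seed = 11) {
  sm <- latin_hypercube(list(random_variable(0.5, 0.175, label = "bmd"),
                             random_variable(2, 0.4, label = "bw")),
                        n, seed)
  data.frame(bmd = pmax(sm[, 1], 0.01), bw = pmax(sm[, 2], 0),
             strain = evaluate_strain(model, pmax(sm[, 1], 0.01),
                                      pmax(sm[, 2], 0),
                                      warn_envelope = FALSE))
}

# Monte Carlo standard errors for a sample mean and a sample variance.
se_mean <- function(x) stats::sd(x) / sqrt(length(x))
se_var <- function(x) stats::sd((x - mean(x))^2) / sqrt(length(x))
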