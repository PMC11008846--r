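# pfnarel

Probabilistic assessment of mechanical failure for intertrochanteric hip
fractures stabilized with a proximal femoral nail antirotation (PFNA).

After PFNA fixation, the dominant mechanical failure mode is *cut-out*:
the helical blade migrates through the femoral head as the surrounding
trabecular bone yields in compression. Whether that happens depends on two
quantities that vary widely between patients and are uncertain for any one
of them — the apparent bone mineral density (BMD, g/cm³) of the proximal
trabecular bone and the hip contact load during daily activity (in
body-weight multiples, BW). `pfnarel` turns that uncertainty into a
probability of failure (PoF) for clinically interpretable scenarios
(age group × activity × uncertainty level), for use by biomechanics
researchers and implant engineers studying post-operative loading guidance.

## The model

Peak compressive strain in the proximal trabecular bone is approximated by
a quadratic response surface fitted to finite-element simulations:

    S(BMD, BW) = 1e-3 (4.09 − 17.66 BMD + 2.80 BW − 2.35 BMD·BW
                       + 15.67 BMD² − 0.05 BW²)

Failure is strain yielding, with yield strain Y ~ N(0.85%, 0.10%). With the
performance function Z = Y − S, a first-order second-moment (FOSM) analysis
gives

    β = μ_Z / σ_Z,   PoF = 1 − Φ(β),
    μ_Z = μ_Y − μ_S,  σ_Z = √(σ_S² + σ_Y²)

where the moments of S under BMD ~ N(μ_b, σ_b), BW ~ N(μ_w, σ_w) are
computed in three modes: `paper_termwise` (each quadratic regressor reduced
to its moments via the closed-form product/square formulas and combined as
if independent — the replication default), `taylor_first_order` (gradient at
the means), and `exact_moments` (full covariance structure of the quadratic
form; recommended). Latin hypercube and Monte Carlo samplers provide
simulation oracles, and a virtual-experiment generator emulates the
finite-element campaign so the surrogate-fitting stage is testable
end to end.

## Worked example

Probability of failure for a 65–79-year-old climbing stairs, with a BMD
coefficient of variation of 0.25 (a typical literature value) and a load
COV of 0.3:

```r
library(pfnarel)
run_pof("65-79", "up stairs", cov_bmd = 0.25, cov_bw = 0.3)
#> performance summary [paper_termwise]
#>   mu_S = 0.005378, sigma_S = 0.002642
#>   mu_Z = 0.003122, sigma_Z = 0.002825
#>   beta = 1.105, PoF = 0.1345 (13.5%)
```

The expected strain (0.54%) is below the 0.85% yield mean, but the
uncertainty leaves only 1.1 standard deviations of margin, so the failure
probability is 13.5% — far above a 5% acceptable-risk threshold, which is
why stair climbing is flagged for this group.

Where does the safe/failure boundary sit while descending stairs
(BW = 2.6)?

```r
failure_boundary_bmd(published_model(), yield_strain = 0.0085, bw = 2.6)
#> [1] 0.115282 1.401629
```

Below a BMD of about 0.115 g/cm³ the predicted strain exceeds yield (the
second root is an extrapolation artifact outside the physical BMD range).

Fitting the surrogate to a simulated finite-element campaign:

```r
d <- generate_virtual_experiment(virtual_experiment_config(seed = 7))
fit_response_surface(d)$stats
#> fit: n = 100, SSE = 4.864e-05, R^2 = 0.8043, adj. R^2 = 0.7938, RMSE = 0.0007193
```

A full scenario sweep (3 age groups × 5 activities × 9 × 9 COV grid) and
the headline comparison table come from `sweep_pof()` and
`headline_numbers()`; `run_reproduce("out/")` writes both to disk. A thin
command-line front end is installed under `exec/pfnarel`
(`pfnarel pof --age-group 65-79 --activity "up stairs" --cov-bmd 0.25
--cov-bw 0.3`).

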