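# nanorelease

Kinetic modeling of drug release from nanocarriers with reversible
drug–carrier interaction.

Nanocarriers — liposomes, lipid and polymeric nanocapsules, nanoparticles,
micelles, micro- and nanofibers — have large specific surface areas, which
makes sustained release hard: much of the load can leave in an initial
burst.  A useful minimal description keeps the encapsulated drug in two
states, *free* (molecularly dispersed, ready for first-order transport out
of the carrier at rate `k_S` under perfect-sink conditions) and *bound*
(aggregated, complexed or adsorbed, exchanging with the free state at rates
`k_on`/`k_off`):

    dc_F/dt = -(k_S + k_on) c_F + k_off c_A
    dc_A/dt =  k_on c_F - k_off c_A

with the binding reaction at equilibrium at t = 0.  The normalized
cumulative release M_t/M_0 then has a closed-form biexponential solution:
the initially free fraction `k_off/(k_on + k_off)` leaves quickly (the
burst) and the bound pool follows (sustained release).  The association
equilibrium is parameterized by the free-energy difference between the
states, `delta_G = -kB*T*ln(k_on/k_off)`, reported in units of 1e-21 J
(kB*T ≈ 4.14e-21 J at 300 K), so the model triple is `(delta_G, k_S,
k_off)`.

The package provides:

* the closed-form solution, its eigen-decomposition, the confluent
  (repeated-root) limit, and the two limiting cases (pure transport;
  fast-transport/slow-exchange), plus an independent ODE-integration oracle
  used by the tests (`cumulative_release()`, `state_fractions()`,
  `release_eigenvalues()`, `cumulative_release_case1/2()`,
  `ode_reference_solution()`);
* parameter estimation from cumulative-release tables: a physically
  motivated initializer (burst magnitude → `delta_G`, initial rate → `k_S`,
  tail slope → `k_off`) refined by bounded Levenberg–Marquardt least
  squares with deterministic multi-start, nested-model selection by F-test,
  and classification of the profile into the four burst/sustained
  categories I–IV (`estimate_initial_parameters()`, `fit_release_model()`,
  `select_model_variant()`, `classify_release_profile()`);
* bootstrap uncertainty summaries (case or residual resampling; means, SDs,
  p-values for `k_S`, `k_off`, `k_on`, `delta_G`), an F-test against a
  simple linear model, and a Durbin–Watson residual check
  (`bootstrap_parameters()`, `f_test_vs_linear()`,
  `autocorrelation_check()`);
* a model-faithful synthetic-curve generator and a library of 60 published
  parameter sets spanning liposomes, nanocapsules, nanoparticles and fibers
  (`generate_release_curve()`, `fixture_parameter_sets()`,
  `fixture_curves()`, `category_exemplars()`);
* delimited-text I/O for release tables and a CLI
  (`read_release_table()`, `write_release_table()`, `cli_main()`,
  installed script `exec/nanorelease`).

## Worked example

Simulate a low-burst, steady-release system (category IV: `delta_G` =
-5e-21 J, `k_S` = 0.36/day, `k_off` = 0.013/day), fit it blind, classify
it, and bootstrap the fit:

```r
library(nanorelease)

params <- thermo_parameters(-5, 0.36, 0.013, time_unit = "day")
curve  <- generate_release_curve(params, n_points = 25, horizon = 100,
                                 spacing = "log", noise_sd = 0.02, seed = 42)
fit <- fit_release_model(curve)
fit
#> Release model fit (full variant, per day):
#>   k_S = 0.6379, k_off = 0.01346, delta_G = -6.14 x 1e-21 J
#>   n = 25, SSE = 0.01252, R^2 = 0.9885, converged: TRUE

classify_release_profile(fit, horizon = 100)
#> [1] "IV"

bootstrap_parameters(curve, fit, n_replicates = 1000, seed = 7)
#> Bootstrap summary (case resampling, 1000 replicates, 0 failed, seed 7)
#>  parameter estimate     mean        sd p_value
#>        k_S  0.63787  0.63632 0.1166557 < 0.002
#>      k_off  0.01346  0.01340 0.0007828 < 0.002
#>       k_on  0.05928  0.05889 0.0087545 < 0.002
#>    delta_G -6.13959 -6.09343 0.4564549 < 0.002
#> Residual lag-1 Durbin-Watson: 2.132 (consistent with independence)

f_test_vs_linear(curve, fit)
#> F-test vs linear model: F(1, 22) = 147.8, p = 3.1e-11
#>   SSE linear = 0.09659, SSE model = 0.01252
```

Reading the output: `k_off` (the disassociation rate that governs sustained
release) and `delta_G` (negative: binding is favored, so the burst is small)
are recovered close to truth, with `k_S` the least certain — the burst
amplitude here is only ~23% of the load, so the transport rate is the
hardest parameter to pin down from noisy data.  The bootstrap SDs quantify
exactly that, the Durbin–Watson value near 2 supports independent
residuals, and the F-test rejects a straight-line description outright.

The same workflow is available from the shell:

```sh
nanorelease simulate --delta-G -5 --k-S 0.36 --k-off 0.013 \
    --horizon 100 --time-unit day --seed 42 --out curve.tsv
nanorelease fit --in curve.tsv
nanorelease bootstrap --in curve.tsv --replicates 1000 --seed 7
nanorelease classify --delta-G -5 --k-S 0.36 --k-off 0.013 \
    --horizon 100 --time-unit day
```

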