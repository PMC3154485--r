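# Shared fixtures for the test suite: the four canonical category triples
# and a couple of convenience generators.

fig_triples <- list(I = c(4, 0.18, 0.002), II = c(-4, 0.18, 0.001),
                    III = c(1, 0.24, 0.015), IV = c(-5, 0.36, 0.013))

triple_params <- function(name) {
  v <- fig_triples[[name]]
  thermo_parameters(v[1], v[2], v[3], time_unit = "day")
}

noiseless_curve <- function(params, n = 20, horizon = 100) {
  generate_release_curve(params, n_points = n, horizon = horizon,
                         spacing = "log", noise_model = "none", noise_sd = 0)
}

# Random but reproducible rate triples spanning several decades, including
# occasional near-degenerate discriminants (k_on ~ 0 with k_S ~ k_off).
random_rate_draws <- function(n, seed = 20260925) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code()
  }
  withr_seed(function() {
    lapply(seq_len(n), function(i) {
      if (i %% 10 == 0) {      # push toward a repeated root
        k_S <- 10^stats::runif(1, -2, 0)
        rate_parameters(k_S, k_on = 10^stats::runif(1, -8, -6),
                        k_off = k_S * (1 + stats::runif(1, -1e-4, 1e-4)))
      } else {
        rate_parameters(10^stats::runif(1, -2, 1),
                        k_on = 10^stats::runif(1, -4, 0),
                        k_off = 10^stats::runif(1, -4, 0))
      }
    })
  })
}
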