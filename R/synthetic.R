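# Synthetic release curves and the library of literature parameter sets.
#
# The generator evaluates the closed-form model on a sampling schedule and
# adds seeded noise; the true generating parameters travel with the curve so
# recovery studies can score themselves.  The fixture library ships as a
# reviewable delimited text file under extdata, one row per fitted
# drug/carrier system (time units per row; single-exponential rows carry NA
# for k_off and delta_G, the analogue of a dash in a results table).

#' Generate a noisy cumulative-release curve from the model
#'
#' @param params [thermo_parameters()] or [rate_parameters()]; their time
#'   unit becomes the curve's.
#' @param times Explicit sampling times; overrides the schedule arguments.
#' @param n_points Number of sampling times (default 20) when `times` is not
#'   given.
#' @param horizon Last sampling time.
#' @param spacing `"log"` (default; dense early sampling, the usual design
#'   for release assays whose burst and sustained phases live on different
#'   timescales, spanning `horizon/500` to `horizon`) or `"uniform"`.
#' @param noise_sd Standard deviation of the noise, in released-fraction
#'   units (default 0.02, a typical assay scatter).
#' @param noise_model `"additive_gaussian"` (homoscedastic, default),
#'   `"fractional_gaussian"` (sd proportional to the signal) or `"none"`.
#' @param seed Optional integer; a given seed reproduces the curve exactly
#'   and leaves the session RNG untouched.
#' @param label Curve label.
#' @return A [release_curve()]; the generating parameters are attached as
#'   `attr(curve, "truth")`.  Noisy values are clipped below at 0 but may
#'   exceed 1 slightly, as real normalized data do.
#' @export
generate_release_curve <- function(params, times = NULL, n_points = 20,
                                   horizon = NULL,
                                   spacing = c("log", "uniform"),
                                   noise_sd = 0.02,
                                   noise_model = c("additive_gaussian",
                                                   "fractional_gaussian",
                                                   "none"),
                                   seed = NULL, label = "") {
  spacing <- match.arg(spacing)
  noise_model <- match.arg(noise_model)
  rp <- as_rate_parameters(params)
  if (is.null(times)) {
    stopifnot(is.numeric(n_points), n_points >= 4, !is.null(horizon),
              horizon > 0)
    times <- switch(spacing,
      log = exp(seq(log(horizon / 500), log(horizon), length.out = n_points)),
      uniform = seq(horizon / n_points, horizon, length.out = n_points))
  }
  stopifnot(all(times > 0), !is.unsorted(times, strictly = TRUE))
  truth <- cumulative_release(rp, times)
  y <- if (noise_model == "none" || noise_sd == 0) truth else {
    draw <- function() switch(noise_model,
      additive_gaussian = truth + stats::rnorm(length(times), 0, noise_sd),
      fractional_gaussian = truth * (1 + stats::rnorm(length(times), 0, noise_sd)))
    if (is.null(seed)) draw() else .with_seed(seed, draw)
  }
  curve <- release_curve(times, pmax(y, 0), time_unit = rp$time_unit,
                         label = label)
  attr(curve, "truth") <- params
  attr(curve, "noise_sd") <- noise_sd
  curve
}

#' Literature parameter sets for 60 drug/carrier release systems
#'
#' Returns the shipped library of fitted model parameters covering release of
#' drugs, proteins and growth factors from liposomes, nanocapsules,
#' nanoparticles, micelles, and micro/nanofibers.
#'
#' @param table Optional filter on the source table (`"T1"`, `"T2"`, `"T3"`).
#' @param filter Optional string matched (fixed, case-insensitive) against
#'   the concatenated drug/carrier/condition description.
#' @return Data frame with columns `drug`, `carrier`, `condition`, `k_S`,
#'   `k_off`, `delta_G` (1e-21 J; `NA` for single-exponential rows),
#'   `time_unit`, `variant`, `source_table`.
#' @export
fixture_parameter_sets <- function(table = NULL, filter = NULL) {
  path <- system.file("extdata", "release_parameter_sets.tsv",
                      package = "nanorelease", mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(table)) d <- d[d$source_table %in% table, , drop = FALSE]
  if (!is.null(filter)) {
    hay <- tolower(paste(d$drug, d$carrier, d$condition))
    d <- d[grepl(tolower(filter), hay, fixed = TRUE), , drop = FALSE]
  }
  rownames(d) <- NULL
  d
}

# Default evaluation grid for a fixture: 30 log-spaced times resolving both
# the fast mode (from 1/20 of its timescale) and the slow mode (to 5 of its
# e-foldings), so noiseless refits see both phases.
.fixture_grid <- function(rp) {
  eig <- release_eigenvalues(rp)
  t_min <- 0.05 / eig$lambda1
  t_max <- if (eig$lambda2 > 0) 5 / eig$lambda2 else 7 / eig$lambda1
  exp(seq(log(t_min), log(t_max), length.out = 30))
}

#' Noiseless release curves for the fixture library
#'
#' Renders each (optionally filtered) fixture row through the closed-form
#' model.  Single-exponential rows use the Case 1 solution.
#'
#' @inheritParams fixture_parameter_sets
#' @param times Optional shared time grid; by default each record gets a
#'   30-point log grid spanning its own fast and slow timescales.
#' @return List of `list(record = <1-row data.frame>, params, curve)`.
#' @export
fixture_curves <- function(table = NULL, filter = NULL, times = NULL) {
  d <- fixture_parameter_sets(table = table, filter = filter)
  lapply(seq_len(nrow(d)), function(i) {
    rec <- d[i, , drop = FALSE]
    label <- paste(rec$drug, rec$carrier, rec$condition, sep = " / ")
    if (rec$variant == "single_exponential") {
      params <- rate_parameters(rec$k_S, 0, 0, time_unit = rec$time_unit)
    } else {
      params <- thermo_parameters(rec$delta_G, rec$k_S, rec$k_off,
                                  time_unit = rec$time_unit)
    }
    grid <- if (is.null(times)) .fixture_grid(as_rate_parameters(params)) else times
    curve <- generate_release_curve(params, times = grid, noise_model = "none",
                                    noise_sd = 0, label = label)
    list(record = rec, params = params, curve = curve)
  })
}

#' The four canonical release-category exemplars
#'
#' Parameter triples (`delta_G` 1e-21 J, `k_S`, `k_off` per day) whose
#' release profiles realize the four burst/sustained categories:
#' I (4, 0.18, 0.002), II (-4, 0.18, 0.001), III (1, 0.24, 0.015),
#' IV (-5, 0.36, 0.013), rendered over a 100-day horizon.
#'
#' @param horizon Observation window in days (default 100).
#' @param n_points Points per curve (default 50).
#' @return Named list (`I`..`IV`) of `list(params, curve)`.
#' @export
category_exemplars <- function(horizon = 100, n_points = 50) {
  triples <- list(I = c(4, 0.18, 0.002), II = c(-4, 0.18, 0.001),
                  III = c(1, 0.24, 0.015), IV = c(-5, 0.36, 0.013))
  lapply(triples, function(v) {
    params <- thermo_parameters(v[1], v[2], v[3], time_unit = "day")
    curve <- generate_release_curve(params, n_points = n_points,
                                    horizon = horizon, spacing = "log",
                                    noise_model = "none", noise_sd = 0)
    list(params = params, curve = curve)
  })
}
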