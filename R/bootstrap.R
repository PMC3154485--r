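# Bootstrap inference for the fitted release model and the F-test against a
# simple linear model.
#
# Case resampling (whole (t, y) pairs drawn with replacement) is the default:
# observations in a release assay are treated as independent, which is
# exactly the pairs-bootstrap assumption.  Residual resampling is available
# as an option.

# Run fn with a private, seeded RNG stream; the caller's RNG state is
# untouched, so summaries are reproducible without side effects.
.with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Bootstrap distribution of the fitted parameters
#'
#' Resamples the curve `n_replicates` times, refits the model from the
#' original fit as starting point, and summarizes each parameter (`k_S`,
#' `k_off`, `k_on`, `delta_G`; `k_on` is derived from the other two but
#' summarized alongside them) by its bootstrap mean, standard deviation and
#' a two-sided proportion-based p-value for the null that the parameter is
#' zero, with a +1 continuity correction so p is never exactly 0 (zero
#' exceedances report as `< 1/(B+1)`).
#'
#' @param curve A [release_curve()] with at least 6 points; smaller samples
#'   are rejected, matching the usual exclusion of release series too short
#'   to resample meaningfully.
#' @param fit A converged [fit_release_model()] result for `curve`.
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the same seed gives a bitwise-identical summary.
#' @param method `"case"` (pairs, default) or `"residual"` (resampled
#'   residuals added to the fitted curve).
#' @return Object of class `bootstrap_summary`: a `summary` data frame with
#'   one row per parameter (estimate, mean, sd, p_value), plus
#'   `n_replicates`, `n_failed`, `seed`, `valid` (FALSE when more than half
#'   the replicates failed to converge) and the lag-1 autocorrelation check
#'   of the original fit residuals.
#' @export
bootstrap_parameters <- function(curve, fit, n_replicates = 1000, seed = 1,
                                 method = c("case", "residual")) {
  stopifnot(inherits(curve, "release_curve"), inherits(fit, "release_fit"))
  method <- match.arg(method)
  if (!isTRUE(fit$converged)) {
    stop("bootstrap requires a converged fit", call. = FALSE)
  }
  n <- length(curve$times)
  if (n < 6L) {
    stop("sample size too small for the bootstrap (", n,
         " points < 6); such cases are excluded from resampling analysis",
         call. = FALSE)
  }
  full <- fit$variant == "full"
  init <- if (full) {
    thermo_parameters(fit$delta_G, fit$k_S, fit$k_off,
                      temperature = fit$temperature, time_unit = fit$time_unit)
  } else {
    thermo_parameters(0, fit$k_S, 0, temperature = fit$temperature,
                      time_unit = fit$time_unit)
  }

  draws <- .with_seed(seed, function() {
    out <- matrix(NA_real_, nrow = n_replicates, ncol = 3,
                  dimnames = list(NULL, c("k_S", "k_off", "delta_G")))
    for (b in seq_len(n_replicates)) {
      if (method == "case") {
        idx <- sort(sample.int(n, n, replace = TRUE))
        tb <- curve$times[idx]
        yb <- curve$released[idx]
      } else {
        tb <- curve$times
        yb <- fit$fitted + sample(fit$residuals, n, replace = TRUE)
      }
      rfit <- tryCatch(
        .refit_once(tb, yb, init, fit$variant, fit$temperature),
        error = function(e) NULL)
      if (!is.null(rfit) && rfit$converged) {
        out[b, ] <- c(rfit$k_S,
                      if (full) rfit$k_off else NA_real_,
                      if (full) rfit$delta_G else NA_real_)
      }
    }
    out
  })

  ok <- is.finite(draws[, "k_S"])
  n_failed <- sum(!ok)
  kT <- thermal_energy(fit$temperature)
  k_on <- if (full) draws[ok, "k_off"] * exp(-draws[ok, "delta_G"] / kT) else
    rep(NA_real_, sum(ok))

  cols <- list(k_S = draws[ok, "k_S"], k_off = draws[ok, "k_off"],
               k_on = k_on, delta_G = draws[ok, "delta_G"])
  boot_p <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) return(NA_real_)
    min(1, 2 * (min(sum(x <= 0), sum(x >= 0)) + 1) / (length(x) + 1))
  }
  summary <- data.frame(
    parameter = names(cols),
    estimate = c(fit$k_S, fit$k_off,
                 if (full) rates_from_delta_g(fit$delta_G, fit$k_off,
                                              fit$temperature) else NA_real_,
                 fit$delta_G),
    mean = vapply(cols, function(x) mean(x), numeric(1)),
    sd = vapply(cols, function(x) stats::sd(x), numeric(1)),
    p_value = vapply(cols, boot_p, numeric(1)),
    row.names = NULL)

  structure(list(summary = summary,
                 n_replicates = n_replicates,
                 n_failed = n_failed,
                 seed = seed,
                 method = method,
                 valid = n_failed < n_replicates / 2,
                 autocorrelation = autocorrelation_check(fit$residuals),
                 time_unit = fit$time_unit),
            class = "bootstrap_summary")
}

# One bootstrap refit: single Levenberg-Marquardt start from the original
# estimates (resampled times need not be distinct, so the release_curve
# constructor is bypassed).
.refit_once <- function(tb, yb, init, variant, temperature) {
  resid_fn <- function(par) .model_eval(par, tb, variant, temperature) - yb
  if (variant == "full") {
    par0 <- c(init$k_S, init$k_off, init$delta_G)
    lower <- c(1e-10, 0, -.DG_BOUND)
    upper <- c(Inf, Inf, .DG_BOUND)
  } else {
    par0 <- init$k_S
    lower <- 1e-10
    upper <- Inf
  }
  f <- .lm_polished(par0, lower, upper, resid_fn, restarts = 1L,
                    ftol = 1e-12, ptol = 1e-12, maxiter = 300)
  if (is.null(f)) stop("replicate fit failed")
  list(k_S = f$par[[1]],
       k_off = if (variant == "full") f$par[[2]] else NA_real_,
       delta_G = if (variant == "full") f$par[[3]] else NA_real_,
       converged = f$info %in% 1:4)
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("Bootstrap summary (%s resampling, %d replicates, %d failed, seed %d)%s\n",
              x$method, x$n_replicates, x$n_failed, x$seed,
              if (x$valid) "" else " [INVALID: too many failures]"))
  s <- x$summary
  s$p_value <- ifelse(s$p_value <= 2 / (x$n_replicates + 1),
                      sprintf("< %.2g", 2 / (x$n_replicates + 1)),
                      sprintf("%.4g", s$p_value))
  print(format(s, digits = 4), row.names = FALSE)
  if (!is.na(x$autocorrelation$statistic)) {
    cat(sprintf("Residual lag-1 Durbin-Watson: %.3f (%s)\n",
                x$autocorrelation$statistic,
                if (x$autocorrelation$independent) "consistent with independence"
                else "autocorrelation suspected"))
  }
  invisible(x)
}

#' F-test of the release model against a simple linear model
#'
#' Fits an ordinary least-squares line `y = a + b t` to the curve and
#' compares it with the nonlinear fit:
#' `F = (SSE_linear - SSE_nonlinear) / (SSE_nonlinear / (n - 3))`,
#' referred to the F distribution with (1, n-3) degrees of freedom.  A small
#' p-value says the release kinetics are significantly better described by
#' the model than by a straight line.  A perfect nonlinear fit reports
#' `F = Inf` and a zero p-value (below any machine-representable bound).
#'
#' @param curve A [release_curve()] with at least 5 points.
#' @param fit A converged [fit_release_model()] result for `curve`.
#' @return List of class `model_comparison`: `f_statistic`, `p_value`,
#'   `df_num`, `df_den`, `sse_linear`, `sse_nonlinear`.
#' @export
f_test_vs_linear <- function(curve, fit) {
  stopifnot(inherits(curve, "release_curve"), inherits(fit, "release_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  n <- length(curve$times)
  if (n < 5L) stop("need at least 5 points for the F-test", call. = FALSE)
  lin <- stats::lm(released ~ time, data = as.data.frame(curve))
  sse_lin <- sum(stats::residuals(lin)^2)
  sse_nl <- fit$sse
  df_den <- n - 3L
  if (sse_nl <= 0) {
    message("perfect nonlinear fit: F is infinite")
    f_stat <- Inf
    p <- 0
  } else {
    f_stat <- max(0, (sse_lin - sse_nl) / (sse_nl / df_den))
    p <- stats::pf(f_stat, 1, df_den, lower.tail = FALSE)
  }
  structure(list(f_statistic = f_stat, p_value = p, df_num = 1L,
                 df_den = df_den, sse_linear = sse_lin, sse_nonlinear = sse_nl),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("F-test vs linear model: F(%d, %d) = %.4g, p = %.3g\n",
              x$df_num, x$df_den, x$f_statistic, x$p_value))
  cat(sprintf("  SSE linear = %.4g, SSE model = %.4g\n",
              x$sse_linear, x$sse_nonlinear))
  invisible(x)
}

#' Lag-1 autocorrelation check of fit residuals
#'
#' Durbin-Watson statistic `sum(diff(r)^2) / sum(r^2)`; values near 2
#' indicate uncorrelated residuals.  The advisory independence verdict uses
#' the conservative band [1, 3].  Degenerate (all-equal) residuals have no
#' defined statistic and report `independent = FALSE` with a warning.
#'
#' @param residuals Numeric vector of at least 6 residuals.
#' @return List with `statistic` and logical `independent`.
#' @export
autocorrelation_check <- function(residuals) {
  stopifnot(is.numeric(residuals))
  if (length(residuals) < 6L) {
    stop("need at least 6 residuals for the autocorrelation check", call. = FALSE)
  }
  denom <- sum(residuals^2)
  if (denom < 1e-300 || stats::var(residuals) < 1e-300) {
    warning("residuals have (near) zero variance; independence check is undefined")
    return(list(statistic = NA_real_, independent = FALSE))
  }
  dw <- sum(diff(residuals)^2) / denom
  list(statistic = dw, independent = dw >= 1 && dw <= 3)
}
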