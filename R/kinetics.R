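# Closed-form kinetics of the two-state release model.
#
# The free (c_F) and bound (c_A) drug concentrations obey
#   dc_F/dt = -(k_S + k_on) c_F + k_off c_A
#   dc_A/dt =  k_on c_F - k_off c_A
# from the equilibrium initial condition, and -lambda1, -lambda2 are the
# eigenvalues of the system matrix.  Cumulative release is
# M_t/M_0 = 1 - c_F/c_0 - c_A/c_0, a weighted sum of two exponential modes.

#' Decay rates of the two release modes
#'
#' Returns the eigenvalue pair (negated, so both are decay rates) of the
#' two-state linear system: the roots of
#' `lambda^2 - (k_S + k_on + k_off) lambda + k_S k_off = 0`.
#'
#' The larger root is computed from the additive branch of the quadratic
#' formula and the smaller from the product identity
#' `lambda1 * lambda2 = k_S * k_off`, which avoids cancellation when the
#' roots are widely separated.
#'
#' @param params A [rate_parameters()] or [thermo_parameters()] object.
#' @return List of class `eigenpair` with `lambda1 >= lambda2 >= 0` and a
#'   `repeated` flag set when the discriminant is below `1e-12` times the
#'   squared rate sum (confluent double root).
#' @examples
#' release_eigenvalues(rate_parameters(2, 0, 0.5))   # 2 and 0.5
#' @export
release_eigenvalues <- function(params) {
  p <- as_rate_parameters(params)
  s <- p$k_S + p$k_on + p$k_off
  prod <- p$k_S * p$k_off
  disc <- s^2 - 4 * prod
  disc <- max(disc, 0)            # guard tiny negative round-off
  repeated <- disc < 1e-12 * s^2
  lambda1 <- (s + sqrt(disc)) / 2
  lambda2 <- if (lambda1 > 0) prod / lambda1 else 0
  structure(list(lambda1 = lambda1, lambda2 = lambda2, repeated = repeated,
                 time_unit = p$time_unit),
            class = "eigenpair")
}

# Free and bound fractions at the requested times; shared by the exported
# trajectory and cumulative-release evaluators.  Handles the pure-transport
# boundary (k_on + k_off = 0) and the confluent double root, where the modal
# decomposition degenerates to exp(-lambda t) * (a + b t).
.free_bound <- function(p, times) {
  eig <- release_eigenvalues(p)
  l1 <- eig$lambda1
  l2 <- eig$lambda2
  denom <- p$k_on + p$k_off
  if (denom == 0) {
    free <- exp(-p$k_S * times)
    return(list(free = free, bound = rep(0, length(times)), eig = eig))
  }
  w_free <- p$k_off / denom
  w_bound <- p$k_on / denom
  if (!eig$repeated) {
    e1 <- exp(-l1 * times)
    e2 <- exp(-l2 * times)
    free <- w_free * ((p$k_S - l2) * e1 + (l1 - p$k_S) * e2) / (l1 - l2)
    bound <- w_bound * (-l2 * e1 + l1 * e2) / (l1 - l2)
  } else {
    # confluent limit lambda1 -> lambda2 = lambda:
    #   free  -> w_free  * exp(-lambda t) * (1 + (lambda - k_S) t)
    #   bound -> w_bound * exp(-lambda t) * (1 + lambda t)
    lam <- (l1 + l2) / 2
    e <- exp(-lam * times)
    free <- w_free * e * (1 + (lam - p$k_S) * times)
    bound <- w_bound * e * (1 + lam * times)
  }
  list(free = free, bound = bound, eig = eig)
}

#' Free, bound and released fractions over time
#'
#' Evaluates the closed-form solution for `c_F(t)/c_0` and `c_A(t)/c_0` and
#' the released fraction `M_t/M_0 = 1 - c_F/c_0 - c_A/c_0`.  At a confluent
#' (repeated) eigenvalue the analytic `t * exp(-lambda t)` limit is used, so
#' the solution is continuous across parameter space.
#'
#' @param params [rate_parameters()] or [thermo_parameters()].
#' @param times Nonnegative, nondecreasing evaluation times in the
#'   parameters' time unit.
#' @return A `data.frame` of class `state_trajectory` with columns `time`,
#'   `free`, `bound`, `released`; the three fractions sum to 1 at every row.
#' @export
state_fractions <- function(params, times) {
  p <- as_rate_parameters(params)
  stopifnot(is.numeric(times), all(is.finite(times)), all(times >= 0),
            !is.unsorted(times))
  fb <- .free_bound(p, times)
  out <- data.frame(time = times, free = fb$free, bound = fb$bound,
                    released = 1 - fb$free - fb$bound)
  attr(out, "time_unit") <- p$time_unit
  class(out) <- c("state_trajectory", "data.frame")
  out
}

# Mode weights of the cumulative-release biexponential; they sum to 1
# algebraically.  Only defined away from the degenerate branches.
.release_prefactors <- function(p) {
  eig <- release_eigenvalues(p)
  l1 <- eig$lambda1
  l2 <- eig$lambda2
  denom <- (p$k_on + p$k_off) * (l1 - l2)
  c(a1 = l2 * (p$k_S - l2) / denom, a2 = l1 * (l1 - p$k_S) / denom)
}

#' Cumulative release fraction of the full model
#'
#' The normalized cumulative release is a weighted sum of two saturating
#' exponentials,
#' `M_t/M_0 = a1 (1 - exp(-lambda1 t)) + a2 (1 - exp(-lambda2 t))`,
#' with `a1 + a2 = 1`.  Values start at 0, increase monotonically and tend
#' to 1.  Small-time evaluation uses `expm1` for full precision.
#'
#' @inheritParams state_fractions
#' @param times Nonnegative times.
#' @return Numeric vector of released fractions in `[0, 1)`.
#' @export
cumulative_release <- function(params, times) {
  p <- as_rate_parameters(params)
  stopifnot(is.numeric(times), all(is.finite(times)), all(times >= 0))
  if (p$k_on + p$k_off == 0) {
    return(-expm1(-p$k_S * times))
  }
  eig <- release_eigenvalues(p)
  if (!eig$repeated) {
    a <- .release_prefactors(p)
    -(a[["a1"]] * expm1(-eig$lambda1 * times) +
        a[["a2"]] * expm1(-eig$lambda2 * times))
  } else {
    lam <- (eig$lambda1 + eig$lambda2) / 2
    w_free <- p$k_off / (p$k_on + p$k_off)
    # 1 - exp(-lam t) (1 + (lam - w_free k_S) t)
    -expm1(-lam * times) - exp(-lam * times) * (lam - w_free * p$k_S) * times
  }
}

#' Case 1 limit: pure first-order transport
#'
#' When association is negligible relative to disassociation
#' (`k_on/k_off -> 0`) essentially all drug is free at t = 0 and release
#' reduces to the single exponential `1 - exp(-k_S t)`.
#'
#' @param k_S Positive transport rate constant.
#' @param times Nonnegative times.
#' @return Released fractions.
#' @export
cumulative_release_case1 <- function(k_S, times) {
  stopifnot(is.numeric(k_S), length(k_S) == 1L, k_S > 0,
            is.numeric(times), all(times >= 0))
  -expm1(-k_S * times)
}

#' Case 2 limit: fast transport, slow exchange
#'
#' When `k_S >> k_on` and `k_S >> k_off` transport decouples from the binding
#' kinetics: the initially free pool leaves at rate `k_S` and the bound pool
#' at rate `k_off`, with the equilibrium weights
#' `k_off/(k_on+k_off)` and `k_on/(k_on+k_off)`.  Outside its regime this
#' approximation over-predicts release, because it ignores the transport
#' bottleneck during the sustained phase.
#'
#' @inheritParams state_fractions
#' @param times Nonnegative times.
#' @return Released fractions.
#' @export
cumulative_release_case2 <- function(params, times) {
  p <- as_rate_parameters(params)
  stopifnot(is.numeric(times), all(times >= 0))
  if (p$k_on + p$k_off == 0) {
    return(-expm1(-p$k_S * times))
  }
  w_free <- p$k_off / (p$k_on + p$k_off)
  -(w_free * expm1(-p$k_S * times) + (1 - w_free) * expm1(-p$k_off * times))
}

#' Numerical reference solution of the two-state ODE system
#'
#' Integrates the free/bound rate equations directly with an adaptive
#' stiff-capable solver (deSolve::lsoda, relative tolerance 1e-11) from the
#' equilibrium initial condition.  This is a test oracle for the closed-form
#' evaluators, deliberately independent of them.
#'
#' @inheritParams state_fractions
#' @return A `state_trajectory` data frame, as [state_fractions()].
#' @export
ode_reference_solution <- function(params, times) {
  p <- as_rate_parameters(params)
  stopifnot(is.numeric(times), all(is.finite(times)), all(times >= 0),
            !is.unsorted(times))
  eq <- if (p$k_on + p$k_off == 0) c(free = 1, bound = 0) else
    suppressMessages(equilibrium_fractions(p$k_on, p$k_off))
  deriv <- function(t, y, parms) {
    list(c(-(parms$k_S + parms$k_on) * y[1] + parms$k_off * y[2],
           parms$k_on * y[1] - parms$k_off * y[2]))
  }
  grid <- times
  prepend <- length(grid) == 0L || grid[1] > 0
  if (prepend) grid <- c(0, grid)
  sol <- deSolve::lsoda(y = c(eq[["free"]], eq[["bound"]]), times = grid,
                        func = deriv, parms = p, rtol = 1e-11, atol = 1e-13)
  istate <- attr(sol, "istate")[1]
  if (is.null(istate) || istate < 0) {
    stop("ODE integration failed (istate = ", istate, ")", call. = FALSE)
  }
  if (prepend) sol <- sol[-1, , drop = FALSE]
  out <- data.frame(time = times, free = sol[, 2], bound = sol[, 3],
                    released = 1 - sol[, 2] - sol[, 3])
  attr(out, "time_unit") <- p$time_unit
  class(out) <- c("state_trajectory", "data.frame")
  out
}

#' @export
print.eigenpair <- function(x, ...) {
  cat(sprintf("Release mode decay rates (per %s): lambda1 = %g, lambda2 = %g%s\n",
              x$time_unit, x$lambda1, x$lambda2,
              if (x$repeated) " (repeated root)" else ""))
  invisible(x)
}
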