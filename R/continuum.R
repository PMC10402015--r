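#' Right-hand side of the continuum colony-growth model
#'
#' The whole colony is modelled as a single elastic medium of area `A` and
#' preferred area `A0`:
#' \deqn{\frac{dA}{dt} = -\lambda (A - A_0),}
#' \deqn{\frac{dA_0}{dt} = \frac{G}{a_0} e^{-k (A - A_0)^2}
#'       A_0 \left(1 - \frac{A_0}{A_{max}}\right),}
#' i.e. stress relaxation of the realised area towards the preferred one,
#' and logistic growth of the preferred area under a confinement of area
#' `Amax`, suppressed by crowding exactly as in the cell-scale growth rule.
#' The homeostatic fixed point is `A = A0 = Amax`.
#'
#' @param A,A0 Current colony area and preferred area (> 0).
#' @param params A [continuum_params()] object.
#' @return Numeric vector `c(dA, dA0)`.
#' @export
continuum_rhs <- function(A, A0, params) {
  dA <- -params$lambda * (A - A0)
  dA0 <- (params$G / params$a0) * exp(-params$k * (A - A0)^2) *
    A0 * (1 - A0 / params$Amax)
  c(dA, dA0)
}

#' Integrate the continuum model
#'
#' Integrates from the newborn initial condition `A(0) = A0(0) = a0` with a
#' fixed-step 4th-order Runge-Kutta scheme (the default step `dt = 1e-3` in
#' units of `1/lambda` passes a step-halving refinement check at relative
#' tolerance 1e-6).
#'
#' @param params A [continuum_params()] object.
#' @param t_end End time (in `1/lambda` units when `lambda = 1`).
#' @param dt Integration step.
#' @param sample_every Keep every `sample_every`-th step in the returned
#'   trajectory (all intermediate steps are still integrated).
#' @return A data frame of class `continuum_trajectory` with columns `t`,
#'   `A`, `A0` and `pressure` (`lambda * (A0 - A)`, positive while the
#'   preferred area runs ahead of the realised one); the parameters are
#'   attached as an attribute.
#' @examples
#' tr <- integrate_continuum(continuum_params(), t_end = 40)
#' continuum_tgrowth(tr)
#' @export
integrate_continuum <- function(params, t_end, dt = 1e-3, sample_every = 10L) {
  stopifnot(inherits(params, "continuum_params"), t_end > 0, dt > 0)
  times <- seq(0, t_end, by = dt)
  rhs <- function(t, y, parms) {
    list(continuum_rhs(y[1], y[2], params))
  }
  sol <- deSolve::ode(y = c(A = params$a0, A0 = params$a0), times = times,
                      func = rhs, parms = NULL, method = "rk4")
  if (any(!is.finite(sol[, -1])) || any(sol[, -1] <= 0) ||
      any(sol[, "A0"] > params$Amax * (1 + 1e-9))) {
    stop("continuum integration unstable: decrease dt")
  }
  keep <- unique(c(seq(1, nrow(sol), by = sample_every), nrow(sol)))
  out <- data.frame(t = sol[keep, "time"], A = sol[keep, "A"],
                    A0 = sol[keep, "A0"])
  out$pressure <- params$lambda * (out$A0 - out$A)
  attr(out, "params") <- params
  class(out) <- c("continuum_trajectory", "data.frame")
  out
}

#' Integrate the continuum model to its steady state
#'
#' Repeatedly extends the integration until both derivatives fall below
#' `tol` in absolute value, and returns the final state.
#'
#' @param params A [continuum_params()] object.
#' @param tol Derivative tolerance (default 1e-10).
#' @param chunk Time extent integrated per iteration.
#' @param max_time Abort threshold.
#' @return A list with elements `A`, `A0`, `t`.
#' @export
continuum_steady_state <- function(params, tol = 1e-10, chunk = 50,
                                   max_time = 1e5) {
  y <- c(params$a0, params$a0)
  t <- 0
  rhs <- function(t, y, parms) list(continuum_rhs(y[1], y[2], params))
  repeat {
    d <- continuum_rhs(y[1], y[2], params)
    if (all(abs(d) < tol)) break
    if (t >= max_time) stop("no steady state reached by t = ", max_time)
    sol <- deSolve::ode(y = y, times = c(0, chunk), func = rhs, parms = NULL,
                        method = "lsoda", rtol = 1e-12, atol = 1e-12)
    y <- as.numeric(sol[nrow(sol), -1])
    t <- t + chunk
  }
  list(A = y[1], A0 = y[2], t = t)
}

#' Growth time of the continuum colony
#'
#' Time at which the colony area first reaches `0.95 * Amax`, linearly
#' interpolated between trajectory samples.
#'
#' @param traj A `continuum_trajectory`.
#' @param Amax Confinement area; taken from the trajectory's parameters by
#'   default.
#' @return Crossing time, or `NA` with a `"reason"` attribute if the
#'   trajectory never reaches the threshold.
#' @export
continuum_tgrowth <- function(traj, Amax = attr(traj, "params")$Amax) {
  thr <- 0.95 * Amax
  above <- which(traj$A >= thr)
  if (length(above) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "trajectory never reaches 0.95 Amax"
    return(out)
  }
  i <- above[1]
  if (i == 1) return(traj$t[1])
  t0 <- traj$t[i - 1]; t1 <- traj$t[i]
  a0 <- traj$A[i - 1]; a1 <- traj$A[i]
  t0 + (thr - a0) / (a1 - a0) * (t1 - t0)
}

#' Maximum tissue pressure along a continuum trajectory
#'
#' Pressure is `lambda * (A0 - A)` (compression-positive, matching the sign
#' convention of the cell-scale pressure; the single-`lambda` prefactor
#' follows the relaxation term of the area equation).
#'
#' @param traj A `continuum_trajectory`.
#' @param lambda Stress relaxation rate; taken from the trajectory's
#'   parameters by default.
#' @return Maximum pressure over the trajectory.
#' @export
continuum_max_pressure <- function(traj, lambda = attr(traj, "params")$lambda) {
  max(lambda * (traj$A0 - traj$A))
}
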