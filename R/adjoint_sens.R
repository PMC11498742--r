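# Adjoint sensitivity analysis (ASA): the adjoint state p obeys
#   p' = -(df/dx)^T p
# backward in time, with jumps  sum_i (dh_i/dx)^T (ybar_ij - y_i)/sigma_ij^2
# at each measurement time, and the gradient uses the quadrature
# integral p^T df/dtheta dt, carried as extra backward ODE components.
# At a stable steady state the equilibration-window quadrature collapses to
# a linear solve against the transposed Jacobian ("tailored" ASA).

#' Cubic Hermite interpolant of a stored trajectory
#'
#' Builds a dense interpolant of a forward solution from stored states and
#' their exact derivatives \eqn{\dot x = f(x)} at the stored times, the
#' scheme used by the backward (adjoint) passes in place of re-simulation.
#'
#' @param times increasing time points.
#' @param states `n_t` x `n_x` matrix.
#' @param derivs `n_t` x `n_x` matrix of exact time derivatives.
#' @return function `x_at(t)` returning the interpolated state vector;
#'   constant extrapolation outside the stored range.
#' @export
hermite_interp <- function(times, states, derivs) {
  states <- as.matrix(states); derivs <- as.matrix(derivs)
  n <- length(times)
  force(times)
  function(t) {
    if (n == 1 || t <= times[1]) return(states[1, ])
    if (t >= times[n]) return(states[n, ])
    i <- findInterval(t, times)
    h <- times[i + 1] - times[i]
    if (h <= 0) return(states[i, ])
    s <- (t - times[i]) / h
    h00 <- (1 + 2 * s) * (1 - s)^2
    h10 <- s * (1 - s)^2
    h01 <- s^2 * (3 - 2 * s)
    h11 <- s^2 * (s - 1)
    h00 * states[i, ] + h10 * h * derivs[i, ] +
      h01 * states[i + 1, ] + h11 * h * derivs[i + 1, ]
  }
}

# backward RHS in s = t_hi - t: p gains d/ds p = J^T p, and the quadrature
# components accumulate p^T df/dtheta
rhs_adjoint <- function(s, y, parms) {
  p <- y[seq_len(parms$nx)]
  x <- parms$x_at(parms$t_hi - s)
  J <- eval_jac(parms$deriv, parms$model, x, parms$theta, parms$u)
  dfdp <- eval_dfdp(parms$deriv, parms$model, x, parms$theta, parms$u)
  list(c(as.vector(t(J) %*% p), as.vector(p %*% dfdp)))
}

# instantaneous adjoint jump at a measurement time (event in backward time)
adjoint_jump_event <- function(t, y, parms) {
  i <- which.min(abs(parms$ev_s - t))
  y[seq_len(parms$nx)] <- y[seq_len(parms$nx)] + parms$ev_jumps[[i]]
  y
}

# analytic Jacobian of the backward system in s: d(pdot)/dp = J^T,
# d(qdot)/dp = dfdp^T, quadrature columns are zero
jac_adjoint <- function(s, y, parms) {
  nx <- parms$nx
  x <- parms$x_at(parms$t_hi - s)
  J <- eval_jac(parms$deriv, parms$model, x, parms$theta, parms$u)
  dfdp <- eval_dfdp(parms$deriv, parms$model, x, parms$theta, parms$u)
  n <- length(y)
  M <- matrix(0, n, n)
  M[seq_len(nx), seq_len(nx)] <- t(J)
  M[nx + seq_len(n - nx), seq_len(nx)] <- t(dfdp)
  M
}

# integrate p' = -J^T p and the quadrature q = integral p^T df/dtheta dt
# backward over [t_lo, t_hi] from p(t_hi) = p_hi, with x(t) supplied by
# an interpolant.  Returns p(t_lo) and the window quadrature (length n_theta).
adjoint_window <- function(model, deriv, theta, u, x_at, t_lo, t_hi, p_hi,
                           config, phase = "adjoint", jumps_s = numeric(0),
                           jump_vecs = list()) {
  nx <- length(model$state_names)
  np <- length(model$parameter_names)
  if (t_hi <= t_lo) return(list(p_lo = p_hi, quad = numeric(np)))
  span <- t_hi - t_lo
  parms <- list(model = model, deriv = deriv, theta = theta, u = u,
                nx = nx, x_at = x_at, t_hi = t_hi,
                ev_s = jumps_s, ev_jumps = jump_vecs)
  events <- if (length(jumps_s))
    list(func = adjoint_jump_event, time = sort(jumps_s))
  res <- safe_ode(c(p_hi, numeric(np)), c(0, span), rhs_adjoint,
                  jacfunc = jac_adjoint, config = config,
                  maxsteps = config$max_steps, parms = parms,
                  events = events, method = "vode",
                  atol = c(rep(config$sim_atol, nx),
                           rep(config$sim_atol_sens, np)))
  if (!res$ok)
    signal_failure("numerical_error",
                   paste0("backward adjoint integration failed: ", res$msg),
                   phase = phase)
  fin <- unname(res$out[nrow(res$out), -1])
  list(p_lo = fin[seq_len(nx)], quad = fin[nx + seq_len(np)])
}

#' Backward adjoint pass over the dynamic window
#'
#' Integrates \eqn{\dot p = -(\partial f/\partial x)^T p} backward from the
#' last measurement time (where \eqn{p = 0} beyond it), applying the
#' weighted-residual jump at each measurement time, while accumulating the
#' quadrature \eqn{q_k = \int_{t_0}^{t_{n_t}} p^T \partial f/\partial\theta_k\,dt}
#' as augmented backward components.  Forward states are supplied by dense
#' Hermite interpolation of the stored forward solution.
#'
#' @param model,deriv model and derivatives.
#' @param theta,u parameters (linear scale) and inputs.
#' @param forward_trajectory list with `times`, `states`, `derivs` covering
#'   the dynamic window (as stored by the forward simulation).
#' @param residual_jumps list of `list(time = , jump = )` with jump vectors
#'   \eqn{\sum_i (\partial h_i/\partial x)^T (\bar y_{ij} - y_i(t_j)) /
#'   \sigma_{ij}^2} evaluated on the forward solution.
#' @param config an [eqsens_config()].
#' @param p_end adjoint handed over at the window end from a
#'   post-equilibration backward pass (zero in the tailored route, where the
#'   steady-state adjoint has decayed over the infinite horizon).
#' @return list with `p_t0` (adjoint at the initial time, after any jump at
#'   t0), `quadrature` (length `n_theta`) and `status`.
#' @export
backward_adjoint <- function(model, deriv, theta, u, forward_trajectory,
                             residual_jumps, config = eqsens_config(),
                             p_end = NULL) {
  nx <- length(model$state_names)
  np <- length(model$parameter_names)
  x_at <- hermite_interp(forward_trajectory$times, forward_trajectory$states,
                         forward_trajectory$derivs)
  jt <- vapply(residual_jumps, function(j) j$time, numeric(1))
  p <- if (is.null(p_end)) numeric(nx) else as.numeric(p_end)
  quad <- numeric(np)
  t_hi <- if (any(p != 0))
    forward_trajectory$times[length(forward_trajectory$times)]
  else max(c(jt, 0))
  # jumps at the top of the window apply before integration starts
  for (j in which(jt >= t_hi)) p <- p + residual_jumps[[j]]$jump
  if (t_hi > 0) {
    inner <- which(jt > 0 & jt < t_hi)
    ev_s <- t_hi - jt[inner]
    w <- adjoint_window(model, deriv, theta, u, x_at, 0, t_hi, p, config,
                        jumps_s = ev_s,
                        jump_vecs = lapply(residual_jumps[inner], `[[`,
                                           "jump"))
    p <- w$p_lo; quad <- quad + w$quad
  }
  # measurements exactly at the initial time jump after the pass
  for (j in which(jt == 0)) p <- p + residual_jumps[[j]]$jump
  list(p_t0 = p, quadrature = quad, status = "ok")
}

# shared tailored linear solve: (df/dx)^T p_integral = -p_boundary
steady_state_adjoint_solve <- function(deriv, model, theta, u, x_star,
                                       p_boundary, cond_max = 1e12) {
  J <- eval_jac(deriv, model, x_star, theta, u)
  kap <- tryCatch(kappa(J, exact = FALSE), error = function(e) Inf)
  if (!is.finite(kap) || kap > cond_max)
    signal_tailored_inapplicable(paste0(
      "transposed Jacobian is singular or ill-conditioned (condition ",
      "estimate ", format(kap), "); tailored adjoint solve not applicable"))
  p_integral <- tryCatch(solve(t(J), -as.numeric(p_boundary)),
                         error = function(e)
                           signal_tailored_inapplicable(conditionMessage(e)))
  dfdp <- eval_dfdp(deriv, model, x_star, theta, u)
  list(p_integral = p_integral, p_boundary = as.numeric(p_boundary),
       increment = -as.numeric(p_integral %*% dfdp))
}

#' Tailored pre-equilibration adjoint contribution
#'
#' Replaces the adjoint quadrature over the pre-equilibration interval by a
#' single linear solve \eqn{(\partial f/\partial x)^T p_{\mathrm{integral}}
#' = -p(t_0)} at the pre-equilibration steady state, returning the gradient
#' increment \eqn{-p_{\mathrm{integral}}^T\,\partial f/\partial\theta}.
#' The initial-condition term of the extended adjoint gradient vanishes
#' because the adjoint has decayed to zero at the far end of the
#' pre-equilibration interval.
#'
#' @param deriv,model derivatives and model.
#' @param theta parameters (linear scale).
#' @param u_e pre-equilibration inputs.
#' @param x_star_pre pre-equilibration steady state.
#' @param p_t0 adjoint at the initial time of the dynamic window.
#' @param cond_max condition-number threshold.
#' @return list with `increment` (length `n_theta`), `p_integral`,
#'   `p_boundary`.
#' @export
preeq_adjoint_contribution <- function(deriv, model, theta, u_e, x_star_pre,
                                       p_t0, cond_max = 1e12) {
  steady_state_adjoint_solve(deriv, model, theta, u_e, x_star_pre, p_t0,
                             cond_max)
}

#' Tailored post-equilibration adjoint contribution
#'
#' For steady-state measurements the equilibration-window adjoint
#' quadrature reduces to the linear solve
#' \eqn{(\partial f/\partial x)^T p_{\mathrm{integral}} = -p_{ss}} at the
#' (stable) steady state, with
#' \eqn{p_{ss} = \sum_i (\partial h_i/\partial x)^T(\bar y_i^* - y_i^*)/\sigma_i^{*2}},
#' followed by the matrix-vector product
#' \eqn{-p_{\mathrm{integral}}^T \partial f/\partial\theta}.  The adjoint
#' handed back to the dynamic window is zero (infinite-horizon decay).
#'
#' @inheritParams preeq_adjoint_contribution
#' @param x_star post-equilibration steady state.
#' @param p_ss steady-state residual adjoint (length `n_x`).
#' @export
posteq_adjoint_contribution <- function(deriv, model, theta, u, x_star, p_ss,
                                        cond_max = 1e12) {
  steady_state_adjoint_solve(deriv, model, theta, u, x_star, p_ss, cond_max)
}

#' Post-equilibration adjoint contribution by backward integration
#'
#' The fully integration-based alternative to
#' [posteq_adjoint_contribution()]: integrates the adjoint plus quadrature
#' backward over the stored equilibration window, starting from the
#' steady-state residual adjoint at the window end, and returns the
#' negated quadrature as the gradient increment together with the (tiny)
#' adjoint reaching the window start.
#'
#' @inheritParams posteq_adjoint_contribution
#' @param equilibration_trajectory dense trajectory retained by
#'   [equilibrate_by_integration()] with `keep_trajectory = TRUE`
#'   (times relative to the window start).
#' @param config an [eqsens_config()].
#' @return list with `increment` (length `n_theta`) and `p_start` (adjoint
#'   at the window start, handed to the dynamic backward pass).
#' @export
posteq_adjoint_by_integration <- function(model, deriv, theta, u,
                                          equilibration_trajectory, p_ss,
                                          config = eqsens_config()) {
  tr <- equilibration_trajectory
  x_at <- hermite_interp(tr$times, tr$states, tr$derivs)
  t_hi <- tr$times[length(tr$times)]
  w <- adjoint_window(model, deriv, theta, u, x_at, 0, t_hi, as.numeric(p_ss),
                      config, phase = "posteq")
  list(increment = -w$quad, p_start = w$p_lo)
}
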