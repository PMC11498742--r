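# Steady-state computation: x*(theta, u) with f(x*) = 0, found either by
# stiff numerical integration until the weighted root-mean-square (WRMS) of
# the time derivatives drops below 1, or by damped Newton iteration on f.

#' Equilibration and simulation settings
#'
#' @param rtol,atol relative/absolute tolerance of the WRMS steady-state
#'   criterion (dimensionless / state units).
#' @param sim_rtol,sim_atol integrator tolerances for all dynamic phases.
#' @param sim_atol_sens absolute integrator tolerance for sensitivity and
#'   adjoint-quadrature components, which can span many orders of magnitude
#'   more than the states (a component pinned at zero with a scalar `atol`
#'   as tight as the states' would reject every step on roundoff forcing).
#' @param max_time integration horizon cap for equilibration (time units).
#' @param max_steps integrator step cap per equilibration.
#' @param t_first first WRMS checkpoint time; checkpoints grow by
#'   `chunk_factor` until `max_time`.
#' @param chunk_factor geometric growth factor of the checkpoint schedule.
#' @param newton_max_iters damped-Newton iteration cap.
#' @param gamma_init,gamma_min initial / minimal damping factor
#'   (`0 < gamma_min <= gamma_init <= 1`).
#' @param gamma_up,gamma_down multiplicative damping adaptation factors
#'   applied after an accepted / rejected step (both > 1).
#' @param neg_tol tolerance below zero before a state counts as negative
#'   (defaults to `atol`: tiny integrator undershoots are not failures,
#'   Newton's far-negative solutions are).
#' @param cond_max condition-number threshold above which linear solves
#'   against the Jacobian are refused.
#' @param sens_wrms if `TRUE`, forward-sensitivity equilibration additionally
#'   requires the sensitivity time-derivative WRMS to drop below 1.
#' @param fd_step central finite-difference step (optimization scale), used
#'   by the finite-difference gradient oracle.
#' @return a list of settings of class `eqsens_config`.
#' @export
eqsens_config <- function(rtol = 1e-8, atol = 1e-10,
                          sim_rtol = 1e-10, sim_atol = 1e-12,
                          sim_atol_sens = 1e-8,
                          max_time = 1e7, max_steps = 1e6,
                          t_first = 1e-3, chunk_factor = 10,
                          newton_max_iters = 100L,
                          gamma_init = 1, gamma_min = 1e-10,
                          gamma_up = 2, gamma_down = 4,
                          neg_tol = atol, cond_max = 1e12,
                          sens_wrms = FALSE, fd_step = 1e-6) {
  stopifnot(rtol > 0, atol > 0, sim_rtol > 0, sim_atol > 0,
            gamma_min <= gamma_init, gamma_init <= 1,
            gamma_up > 1, gamma_down > 1, max_time > 0, t_first > 0,
            chunk_factor > 1)
  structure(list(rtol = rtol, atol = atol, sim_rtol = sim_rtol,
                 sim_atol = sim_atol, sim_atol_sens = sim_atol_sens,
                 max_time = max_time,
                 max_steps = max_steps, t_first = t_first,
                 chunk_factor = chunk_factor,
                 newton_max_iters = as.integer(newton_max_iters),
                 gamma_init = gamma_init, gamma_min = gamma_min,
                 gamma_up = gamma_up, gamma_down = gamma_down,
                 neg_tol = neg_tol, cond_max = cond_max,
                 sens_wrms = sens_wrms, fd_step = fd_step),
            class = "eqsens_config")
}

#' Weighted root-mean-square convergence measure
#'
#' Computes \eqn{\sqrt{\frac{1}{n_x}\sum_i (\dot x_i w_i)^2}} with weights
#' \eqn{w_i = 1/(\mathrm{rtol}\,|x_i| + \mathrm{atol})}.  A value below 1
#' declares the state a steady state.  The absolute value in the weight
#' keeps it positive for transiently negative states.
#'
#' @param xdot state time-derivative vector.
#' @param x state vector (same length).
#' @param rtol,atol relative and absolute tolerance.
#' @return nonnegative scalar; `Inf` when any entry is non-finite.
#' @export
wrms <- function(xdot, x, rtol, atol) {
  stopifnot(length(xdot) == length(x), length(x) > 0)
  if (any(!is.finite(xdot)) || any(!is.finite(x))) return(Inf)
  w <- 1 / (rtol * abs(x) + atol)
  sqrt(mean((xdot * w)^2))
}

# structured steady-state result
ss_result <- function(x_star, status, wrms_final, iterations_or_steps, method,
                      elapsed, trajectory = NULL, reason = NA_character_) {
  structure(list(x_star = x_star, status = status, wrms_final = wrms_final,
                 iterations_or_steps = iterations_or_steps, method = method,
                 equilibration_time_elapsed = elapsed,
                 trajectory = trajectory, reason = reason),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat("steady_state_result [", x$method, "]: ", x$status,
      " (wrms ", format(x$wrms_final), ", ",
      x$iterations_or_steps, " steps)\n", sep = "")
  if (x$status == "converged") cat("  x* =", format(x$x_star), "\n")
  invisible(x)
}

# package-level integrator callbacks (byte-compiled once, not per call)
rhs_state <- function(t, y, parms) {
  list(eval_f(parms$model, y, parms$theta, parms$u))
}


jac_state <- function(t, y, parms) {
  eval_jac(parms$deriv, parms$model, y, parms$theta, parms$u)
}

# deSolve call with structured error capture; returns list(out=, ok=, msg=)
# With a rootfunc, stopping at the root counts as success (root = TRUE).
safe_ode <- function(y, times, func, jacfunc, config, maxsteps, parms = NULL,
                     events = NULL, atol = NULL, method = "lsoda") {
  warn <- NULL
  if (is.null(atol)) atol <- config$sim_atol
  out <- withCallingHandlers(
    tryCatch(deSolve::ode(
      y = y, times = times, func = func, parms = parms,
      jacfunc = jacfunc, jactype = if (is.null(jacfunc)) "fullint" else "fullusr",
      method = method, events = events,
      rtol = config$sim_rtol, atol = atol,
      maxsteps = maxsteps),
      error = function(e) e),
    warning = function(w) { warn <<- conditionMessage(w); invokeRestart("muffleWarning") })
  if (inherits(out, "error"))
    return(list(out = NULL, ok = FALSE, msg = conditionMessage(out)))
  got <- out[nrow(out), 1]
  want <- times[length(times)]
  if (anyNA(out[nrow(out), -1]) || !is.finite(got) ||
      abs(got - want) > 1e-8 * max(1, abs(want)))
    return(list(out = out, ok = FALSE,
                msg = if (is.null(warn)) "integration stopped early" else warn))
  list(out = out, ok = TRUE, msg = warn)
}

# geometric checkpoint schedule for equilibration
chunk_times <- function(config) {
  ts <- config$t_first * config$chunk_factor^
    (0:ceiling(log(config$max_time / config$t_first, config$chunk_factor)))
  ts[ts <= config$max_time * (1 + 1e-12)]
}

#' Steady state by numerical integration
#'
#' Integrates \eqn{\dot x = f(x,\theta,u)} with a stiff solver until the
#' WRMS criterion drops below 1, checking at geometrically growing
#' checkpoint times up to `max_time`.  States more negative than
#' `-neg_tol` at any stored point fail with `negative_state`; hitting
#' `max_time`/`max_steps` first yields `no_steady_state`; integrator
#' breakdown yields `numerical_error`.  Convergence is checked once at
#' `x_init` before any work, so starting at a steady state is a no-op.
#'
#' @param model an [ode_model()].
#' @param deriv its [derive()] result.
#' @param theta parameters (linear scale).
#' @param u inputs.
#' @param x_init initial state.
#' @param config an [eqsens_config()].
#' @param keep_trajectory retain the dense forward solution (times, states,
#'   derivatives), needed when an adjoint pass over the equilibration
#'   window will follow.
#' @return a `steady_state_result`.
#' @export
equilibrate_by_integration <- function(model, deriv, theta, u, x_init,
                                       config = eqsens_config(),
                                       keep_trajectory = FALSE) {
  t_start <- Sys.time()
  elapsed <- function() as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  x <- as.numeric(x_init)
  f0 <- tryCatch(eval_f(model, x, theta, u), error = function(e) NaN)
  w <- wrms(f0, x, config$rtol, config$atol)
  if (!is.finite(w))
    return(ss_result(x, "numerical_error", w, 0L, "integration", elapsed()))
  traj <- list(times = 0, states = matrix(x, 1), derivs = matrix(f0, 1))
  if (w < 1)
    return(ss_result(x, "converged", w, 0L, "integration", elapsed(),
                     if (keep_trajectory) traj))

  parms <- list(model = model, deriv = deriv, theta = theta, u = u)
  steps <- 0L
  maxsteps_chunk <- max(1000, ceiling(config$max_steps / 20))
  checkpoints <- chunk_times(config)
  t_prev <- 0
  # one chunk of the stiff (BDF) integration; returns NULL on early exit
  run_chunk <- function(t_lo, t_hi) {
    grid <- unique(c(t_lo, t_lo + (t_hi - t_lo) * c(1 / 3, 2 / 3), t_hi))
    res <- safe_ode(x, grid, rhs_state, jac_state, config,
                    maxsteps = maxsteps_chunk, parms = parms,
                    method = "vode")
    steps <<- steps + attr_steps(res$out)
    if (!res$ok) return("numerical_error")
    states <- unname(as.matrix(res$out[-1, -1, drop = FALSE]))
    times <- res$out[-1, 1]
    dmat <- t(apply(states, 1, function(s) eval_f(model, s, theta, u)))
    if (length(model$state_names) == 1) dmat <- matrix(dmat, ncol = 1)
    if (keep_trajectory) {
      traj$times <<- c(traj$times, times)
      traj$states <<- rbind(traj$states, states)
      traj$derivs <<- rbind(traj$derivs, dmat)
    }
    neg_rows <- which(apply(states, 1, min) < -config$neg_tol)
    if (length(neg_rows)) {
      x <<- states[neg_rows[1], ]
      return("negative_state")
    }
    x <<- states[nrow(states), ]
    w <<- wrms(dmat[nrow(dmat), ], x, config$rtol, config$atol)
    if (!is.finite(w)) return("numerical_error")
    NULL
  }
  for (t_next in checkpoints) {
    if (t_next <= t_prev) next
    bad <- run_chunk(t_prev, t_next)
    if (!is.null(bad))
      return(ss_result(x, bad, w, steps, "integration", elapsed()))
    t_prev <- t_next
    if (w < 1) {
      # the criterion passed somewhere inside this chunk; consolidate to
      # twice the chunk end so the returned state sits strictly inside
      # the converged region, not on its boundary
      bad <- run_chunk(t_prev, 2 * t_prev)
      if (!is.null(bad))
        return(ss_result(x, bad, w, steps, "integration", elapsed()))
      t_prev <- 2 * t_prev
      if (w < 1)
        return(ss_result(x, "converged", w, steps, "integration", elapsed(),
                         if (keep_trajectory) traj))
    }
  }
  ss_result(x, "no_steady_state", w, steps, "integration", elapsed(),
            if (keep_trajectory) traj)
}

attr_steps <- function(out) {
  st <- attr(out, "istate")
  if (is.null(st) || length(st) < 3 || !is.finite(st[3])) 0L else as.integer(st[3])
}

#' Steady state by damped Newton iteration
#'
#' Iterates \eqn{x^{l+1} = x^l - \gamma (\partial f/\partial x)^{-1} f(x^l)}.
#' After each trial step the WRMS error is compared with the previous one:
#' if reduced the step is accepted and \eqn{\gamma} grows (up to 1) by
#' `gamma_up`, otherwise the step is rejected, \eqn{\gamma} shrinks by
#' `gamma_down` and the step is retried.  Convergence is declared at
#' WRMS < 1; \eqn{\gamma} falling below `gamma_min` or exhausting
#' `newton_max_iters` yields `newton_nonconverged`.  A singular or
#' ill-conditioned Jacobian, or a non-finite iterate, yields
#' `numerical_error`; a converged solution with a state below `-neg_tol`
#' yields `negative_state`.
#'
#' @inheritParams equilibrate_by_integration
#' @return a `steady_state_result`.
#' @export
equilibrate_by_newton <- function(model, deriv, theta, u, x_init,
                                  config = eqsens_config()) {
  t_start <- Sys.time()
  elapsed <- function() as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  x <- as.numeric(x_init)
  fx <- tryCatch(eval_f(model, x, theta, u), error = function(e) NaN)
  e_cur <- wrms(fx, x, config$rtol, config$atol)
  if (!is.finite(e_cur))
    return(ss_result(x, "numerical_error", e_cur, 0L, "newton", elapsed()))
  if (e_cur < 1)
    return(finish_newton(x, e_cur, 0L, config, elapsed()))

  gamma <- config$gamma_init
  iters <- 0L
  while (iters < config$newton_max_iters) {
    iters <- iters + 1L
    J <- eval_jac(deriv, model, x, theta, u)
    if (any(!is.finite(J)))
      return(ss_result(x, "numerical_error", e_cur, iters, "newton", elapsed()))
    d <- tryCatch({
      kap <- kappa(J, exact = FALSE)
      if (!is.finite(kap) || kap > config$cond_max)
        stop("ill-conditioned Jacobian")
      solve(J, fx)
    }, error = function(e) e)
    if (inherits(d, "error"))
      return(ss_result(x, "numerical_error", e_cur, iters, "newton",
                       elapsed(), reason = "singular_jacobian"))
    repeat {
      trial <- x - gamma * d
      f_tr <- eval_f(model, trial, theta, u)
      e_new <- wrms(f_tr, trial, config$rtol, config$atol)
      if (any(!is.finite(trial)))
        return(ss_result(x, "numerical_error", e_cur, iters, "newton", elapsed()))
      if (is.finite(e_new) && e_new < e_cur) {    # accept
        x <- trial; fx <- f_tr; e_cur <- e_new
        gamma <- min(1, gamma * config$gamma_up)
        break
      }
      gamma <- gamma / config$gamma_down          # reject, retry from x
      if (gamma < config$gamma_min)
        return(ss_result(x, "newton_nonconverged", e_cur, iters, "newton",
                         elapsed()))
    }
    if (e_cur < 1) return(finish_newton(x, e_cur, iters, config, elapsed()))
  }
  ss_result(x, "newton_nonconverged", e_cur, iters, "newton", elapsed())
}

finish_newton <- function(x, e, iters, config, elapsed) {
  status <- if (any(x < -config$neg_tol)) "negative_state" else "converged"
  ss_result(x, status, e, iters, "newton", elapsed)
}
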