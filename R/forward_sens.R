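# Forward sensitivity analysis (FSA): the state sensitivities s_k = dx/dtheta_k
# obey  s_k' = (df/dx) s_k + df/dtheta_k,  integrated coupled with the states.
# At a steady state with full-rank Jacobian the ODE system collapses to the
# linear system  (df/dx) S = -df/dtheta, one factorization for all columns.

# augmented RHS for states + sensitivities (S stored column-major)
rhs_fsa <- function(t, y, parms) {
  nx <- parms$nx
  x <- y[seq_len(nx)]
  S <- matrix(y[-seq_len(nx)], nx, parms$np)
  fx <- eval_f(parms$model, x, parms$theta, parms$u)
  J <- eval_jac(parms$deriv, parms$model, x, parms$theta, parms$u)
  dfdp <- eval_dfdp(parms$deriv, parms$model, x, parms$theta, parms$u)
  list(c(fx, as.vector(J %*% S + dfdp)))
}

# analytic Jacobian of the augmented system: block structure with J on the
# diagonal and the second-derivative couplings of the sensitivity blocks to
# the states in the first block column
jac_fsa <- function(t, y, parms) {
  nx <- parms$nx; np <- parms$np
  x <- y[seq_len(nx)]
  J <- eval_jac(parms$deriv, parms$model, x, parms$theta, parms$u)
  n <- nx * (1 + np)
  M <- matrix(0, n, n)
  M[seq_len(nx), seq_len(nx)] <- J
  H <- eval_d2fdxdx(parms$deriv, parms$model, x, parms$theta, parms$u)
  G <- eval_d2fdpdx(parms$deriv, parms$model, x, parms$theta, parms$u)
  S <- matrix(y[-seq_len(nx)], nx, np)
  for (k in seq_len(np)) {
    rows <- nx * k + seq_len(nx)
    M[rows, rows] <- J
    # d(sdot_k)/dx_l = sum_j d2f/(dx_j dx_l) s_jk + d2f/(dtheta_k dx_l)
    for (l in seq_len(nx)) {
      Hl <- matrix(H[, l], nx, nx)
      M[rows, l] <- Hl %*% S[, k] + G[(k - 1) * nx + seq_len(nx), l]
    }
  }
  M
}

# component-wise absolute tolerances: states tight, sensitivities looser
fsa_atol <- function(model, config) {
  nx <- length(model$state_names)
  np <- length(model$parameter_names)
  c(rep(config$sim_atol, nx), rep(config$sim_atol_sens, nx * np))
}

fsa_parms <- function(model, deriv, theta, u, config = NULL) {
  list(model = model, deriv = deriv, theta = theta, u = u,
       nx = length(model$state_names), np = length(model$parameter_names),
       rtol = config$rtol, atol = config$atol,
       sens_wrms = isTRUE(config$sens_wrms))
}

# FSA equilibration convergence: state WRMS (optionally also the
# sensitivity-derivative WRMS) below 1
fsa_converged <- function(y, parms) {
  nx <- parms$nx
  d <- rhs_fsa(0, y, parms)[[1]]
  w <- wrms(d[seq_len(nx)], y[seq_len(nx)], parms$rtol, parms$atol)
  if (parms$sens_wrms) {
    ws <- wrms(d[-seq_len(nx)], y[-seq_len(nx)], parms$rtol, parms$atol)
    w <- max(w, ws)
  }
  w < 1
}

#' Steady-state sensitivities by a tailored linear solve
#'
#' At a steady state the forward sensitivity ODEs reduce to the linear
#' system \eqn{(\partial f/\partial x)\,S = -\partial f/\partial\theta},
#' solved column-wise from a single LU factorization.  Applicable only when
#' the Jacobian has full rank: a rank-deficient or ill-conditioned Jacobian
#' (condition number above `cond_max`) signals
#' `tailored_method_inapplicable`, upon which callers fall back to
#' integration-based equilibration.
#'
#' @param deriv a [derive()] result.
#' @param model the model.
#' @param theta parameters (linear scale).
#' @param u inputs.
#' @param x_star steady state.
#' @param cond_max condition-number threshold for refusing the solve.
#' @return `n_x` x `n_theta` matrix \eqn{\partial x^*/\partial\theta}.
#' @export
steady_state_sensitivities <- function(deriv, model, theta, u, x_star,
                                       cond_max = 1e12) {
  J <- eval_jac(deriv, model, x_star, theta, u)
  kap <- tryCatch(kappa(J, exact = FALSE), error = function(e) Inf)
  if (!is.finite(kap) || kap > cond_max)
    signal_tailored_inapplicable(paste0(
      "Jacobian at the steady state is singular or ill-conditioned ",
      "(condition estimate ", format(kap), "); the tailored steady-state ",
      "sensitivity solve is not applicable"))
  dfdp <- eval_dfdp(deriv, model, x_star, theta, u)
  S <- tryCatch(solve(J, -dfdp), error = function(e)
    signal_tailored_inapplicable(conditionMessage(e)))
  S
}

#' Integrate states and forward sensitivities over a time grid
#'
#' Solves the augmented state + sensitivity system with one stiff
#' integrator call and evaluates observables and output sensitivities
#' \eqn{\partial y_i/\partial\theta_k =
#' (\partial h_i/\partial x)\,s_k + \partial h_i/\partial\theta_k}
#' at each grid time.
#'
#' @param model,deriv model and derivatives.
#' @param theta,u parameters (linear scale) and inputs.
#' @param x0 initial state.
#' @param s0 initial sensitivity matrix (`n_x` x `n_theta`): the
#'   equilibrated steady-state sensitivity for pre-equilibrated starts,
#'   otherwise \eqn{\partial x_0/\partial\theta}.
#' @param t_grid output times (t = 0 is the initial time and is prepended
#'   if absent).
#' @param config an [eqsens_config()].
#' @return list with `times`, `states` (`n_t` x `n_x`), `sens`
#'   (`n_t` x `n_x` x `n_theta`), `outputs` (`n_t` x `n_y`), `output_sens`
#'   (`n_t` x `n_y` x `n_theta`).
#' @export
integrate_with_fsa <- function(model, deriv, theta, u, x0, s0, t_grid,
                               config = eqsens_config()) {
  nx <- length(model$state_names)
  np <- length(model$parameter_names)
  ny <- length(model$observables)
  times <- sort(unique(c(0, t_grid)))
  y0 <- c(as.numeric(x0), as.vector(s0))
  res <- safe_ode(y0, times, rhs_fsa, jacfunc = jac_fsa, config = config,
                  maxsteps = config$max_steps,
                  parms = fsa_parms(model, deriv, theta, u),
                  atol = fsa_atol(model, config))
  if (!res$ok)
    signal_failure("numerical_error",
                   paste0("forward sensitivity integration failed: ", res$msg),
                   phase = "dynamic")
  out <- res$out
  nt <- nrow(out)
  states <- matrix(out[, 1 + seq_len(nx)], nt, nx)
  sens <- array(out[, 1 + nx + seq_len(nx * np)], dim = c(nt, nx, np))
  outputs <- matrix(NA_real_, nt, ny,
                    dimnames = list(NULL, names(model$observables)))
  osens <- array(NA_real_, dim = c(nt, ny, np))
  for (r in seq_len(nt)) {
    xr <- states[r, ]
    outputs[r, ] <- eval_h(model, xr, theta, u)
    dhdx <- eval_dhdx(deriv, model, xr, theta, u)
    dhdp <- eval_dhdp(deriv, model, xr, theta, u)
    osens[r, , ] <- dhdx %*% matrix(sens[r, , ], nx, np) + dhdp
  }
  list(times = times, states = states, sens = sens,
       outputs = outputs, output_sens = osens)
}

#' Equilibrate states and sensitivities jointly by integration
#'
#' Integrates the augmented state + forward-sensitivity system until the
#' state WRMS criterion is met (optionally also requiring the sensitivity
#' derivative WRMS below 1 when `config$sens_wrms` is set), returning both
#' the steady state and the sensitivities at the stopping time.  This is the
#' fully integration-based route to steady-state sensitivities; the
#' stopping rule is evaluated on the states, as in plain equilibration.
#'
#' @inheritParams integrate_with_fsa
#' @param x_init,s_init initial state and sensitivity matrix.
#' @return list with `result` (a `steady_state_result`) and `sens`
#'   (`n_x` x `n_theta` matrix, `NULL` unless converged).
#' @export
equilibrate_with_fsa_by_integration <- function(model, deriv, theta, u,
                                                x_init, s_init,
                                                config = eqsens_config()) {
  t_start <- Sys.time()
  elapsed <- function() as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  nx <- length(model$state_names)
  np <- length(model$parameter_names)
  parms <- fsa_parms(model, deriv, theta, u, config)

  y <- c(as.numeric(x_init), as.vector(s_init))
  f0 <- tryCatch(eval_f(model, y[seq_len(nx)], theta, u),
                 error = function(e) NaN)
  w <- wrms(f0, y[seq_len(nx)], config$rtol, config$atol)
  if (!is.finite(w))
    return(list(result = ss_result(y[seq_len(nx)], "numerical_error", w, 0L,
                                   "integration", elapsed()), sens = NULL))
  if (fsa_converged(y, parms))
    return(list(result = ss_result(y[seq_len(nx)], "converged", w, 0L,
                                   "integration", elapsed()),
                sens = matrix(y[-seq_len(nx)], nx, np)))

  steps <- 0L
  maxsteps_chunk <- max(1000, ceiling(config$max_steps / 20))
  checkpoints <- chunk_times(config)
  t_prev <- 0
  run_chunk <- function(t_lo, t_hi) {
    grid <- unique(c(t_lo, t_lo + (t_hi - t_lo) * 0.5, t_hi))
    res <- safe_ode(y, grid, rhs_fsa, jacfunc = jac_fsa, config = config,
                    maxsteps = maxsteps_chunk, parms = parms,
                    atol = fsa_atol(model, config), method = "vode")
    steps <<- steps + attr_steps(res$out)
    if (!res$ok) return("numerical_error")
    rows <- as.matrix(res$out[-1, -1, drop = FALSE])
    neg <- which(apply(rows[, seq_len(nx), drop = FALSE], 1, min) <
                   -config$neg_tol)
    if (length(neg)) {
      y <<- rows[neg[1], ]
      return("negative_state")
    }
    y <<- rows[nrow(rows), ]
    w <<- wrms(eval_f(model, y[seq_len(nx)], theta, u), y[seq_len(nx)],
               config$rtol, config$atol)
    if (!is.finite(w)) return("numerical_error")
    NULL
  }
  for (t_next in checkpoints) {
    if (t_next <= t_prev) next
    bad <- run_chunk(t_prev, t_next)
    if (!is.null(bad))
      return(list(result = ss_result(y[seq_len(nx)], bad, w, steps,
                                     "integration", elapsed()), sens = NULL))
    t_prev <- t_next
    if (w < 1) {
      bad <- run_chunk(t_prev, 2 * t_prev)   # consolidate past the boundary
      if (!is.null(bad))
        return(list(result = ss_result(y[seq_len(nx)], bad, w, steps,
                                       "integration", elapsed()),
                    sens = NULL))
      t_prev <- 2 * t_prev
      if (w < 1 && fsa_converged(y, parms))
        return(list(result = ss_result(y[seq_len(nx)], "converged", w, steps,
                                       "integration", elapsed()),
                    sens = matrix(y[-seq_len(nx)], nx, np)))
    }
  }
  list(result = ss_result(y[seq_len(nx)], "no_steady_state", w, steps,
                          "integration", elapsed()), sens = NULL)
}
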