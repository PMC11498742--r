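# Per-condition simulation (pre-equilibration -> dynamic phase ->
# post-equilibration), the negative log-likelihood with dynamic and
# steady-state measurements, and gradient dispatch to the selected
# method pair.

#' Method pairs for steady-state and sensitivity computation
#'
#' A method pair combines one steady-state method (`integration` or
#' `newton`) with one sensitivity-at-steady-state method
#' (`fsa_integration`, `fsa_tailored`, `asa_integration`, `asa_tailored`).
#' Six of the eight combinations are admissible.  Newton's method produces
#' no trajectory, so it cannot be combined with integration-based
#' sensitivity equilibration: with FSA the sensitivity ODEs are integrated
#' coupled with the states, and with ASA the tailored solve is always
#' applicable whenever Newton converged, making the integrated variant
#' pointless.  Both Newton + integration combinations are therefore
#' rejected at construction.
#'
#' @param name short pair name: one of `int_int_fsa`, `int_int_asa`,
#'   `int_lin_fsa`, `int_lin_asa`, `newton_lin_fsa`, `newton_lin_asa`.
#'   Alternatively give `steady_state_method` and `sensitivity_method`.
#' @param steady_state_method `"integration"` or `"newton"`.
#' @param sensitivity_method one of the four sensitivity methods above.
#' @return an object of class `method_pair`.
#' @export
method_pair <- function(name = NULL, steady_state_method = NULL,
                        sensitivity_method = NULL) {
  by_name <- list(
    int_int_fsa    = c("integration", "fsa_integration"),
    int_int_asa    = c("integration", "asa_integration"),
    int_lin_fsa    = c("integration", "fsa_tailored"),
    int_lin_asa    = c("integration", "asa_tailored"),
    newton_lin_fsa = c("newton", "fsa_tailored"),
    newton_lin_asa = c("newton", "asa_tailored"))
  if (!is.null(name)) {
    if (!name %in% names(by_name))
      stop("unknown method pair '", name, "'; available: ",
           paste(names(by_name), collapse = ", "))
    ss <- by_name[[name]][1]; sm <- by_name[[name]][2]
  } else {
    ss <- match.arg(steady_state_method, c("integration", "newton"))
    sm <- match.arg(sensitivity_method,
                    c("fsa_integration", "fsa_tailored",
                      "asa_integration", "asa_tailored"))
    if (ss == "newton" && sm %in% c("fsa_integration", "asa_integration"))
      stop("method pair (newton, ", sm, ") is not admissible: Newton's ",
           "method yields no trajectory to integrate sensitivities along; ",
           "use a tailored sensitivity method or integration-based ",
           "steady states")
    name <- names(by_name)[vapply(by_name, function(v)
      v[1] == ss && v[2] == sm, logical(1))]
  }
  structure(list(name = name, steady_state_method = ss,
                 sensitivity_method = sm), class = "method_pair")
}

#' @export
print.method_pair <- function(x, ...) {
  cat("method_pair", x$name, "(", x$steady_state_method, "+",
      x$sensitivity_method, ")\n")
  invisible(x)
}

#' All six admissible method pairs
#' @return named list of [method_pair()] objects.
#' @export
all_method_pairs <- function() {
  nms <- c("int_int_fsa", "int_int_asa", "int_lin_fsa", "int_lin_asa",
           "newton_lin_fsa", "newton_lin_asa")
  stats::setNames(lapply(nms, method_pair), nms)
}

# ---- conditions & datasets --------------------------------------------------

#' Define an experimental condition
#'
#' @param condition_id identifier.
#' @param input_values named numeric vector assigning every model input.
#' @param preeq_condition_id optional id of the condition supplying the
#'   pre-equilibration inputs.
#' @return a list of class `eqsens_condition`.
#' @export
condition <- function(condition_id, input_values = numeric(0),
                      preeq_condition_id = NA_character_) {
  structure(list(condition_id = condition_id,
                 input_values = input_values,
                 preeq_condition_id = preeq_condition_id),
            class = "eqsens_condition")
}

#' Bundle conditions and measurements into a dataset
#'
#' Validates that every measurement row references a known condition and
#' observable, that pre-equilibration references resolve without cycles,
#' and that all declared inputs are assigned in every condition.
#'
#' @param model an [ode_model()].
#' @param conditions list of [condition()] objects.
#' @param measurements data.frame with columns `observableId`,
#'   `simulationConditionId`, `time` (finite or `Inf` for steady-state
#'   rows) and `measurement`.
#' @return a list of class `eqsens_dataset`.
#' @export
dataset <- function(model, conditions, measurements) {
  names(conditions) <- vapply(conditions, function(cn) cn$condition_id,
                              character(1))
  for (cn in conditions) {
    missing_u <- setdiff(model$input_names, names(cn$input_values))
    if (length(missing_u))
      stop("condition '", cn$condition_id, "' does not assign input(s): ",
           paste(missing_u, collapse = ", "))
    seen <- cn$condition_id; ref <- cn$preeq_condition_id
    while (!is.na(ref)) {
      if (!ref %in% names(conditions))
        stop("condition '", cn$condition_id,
             "' references unknown pre-equilibration condition '", ref, "'")
      if (ref %in% seen)
        stop("cyclic pre-equilibration reference at condition '", ref, "'")
      seen <- c(seen, ref); ref <- conditions[[ref]]$preeq_condition_id
    }
  }
  m <- as.data.frame(measurements)
  need <- c("observableId", "simulationConditionId", "time", "measurement")
  if (!all(need %in% names(m)))
    stop("measurements need columns: ", paste(need, collapse = ", "))
  bad_obs <- setdiff(unique(m$observableId), names(model$observables))
  if (length(bad_obs))
    stop("unknown observable id(s): ", paste(bad_obs, collapse = ", "))
  bad_cond <- setdiff(unique(m$simulationConditionId), names(conditions))
  if (length(bad_cond))
    stop("unknown condition id(s): ", paste(bad_cond, collapse = ", "))
  if (any(is.finite(m$time) & m$time < 0))
    stop("negative measurement times are not allowed")
  structure(list(conditions = conditions, measurements = m),
            class = "eqsens_dataset")
}

cond_inputs <- function(model, cn) {
  if (!length(model$input_names)) return(numeric(0))
  as.numeric(cn$input_values[model$input_names])
}

# ---- forward simulation -----------------------------------------------------

# dense forward solve over the dynamic window [0, max(mtimes)] with
# geometric refinement after each knot, retaining exact derivatives for
# Hermite interpolation in the adjoint pass
forward_dynamic <- function(model, deriv, theta, u, x0, mtimes, config) {
  knots <- sort(unique(c(0, mtimes)))
  grid <- 0
  for (i in seq_len(length(knots) - 1)) {
    a <- knots[i]; b <- knots[i + 1]
    grid <- c(grid, a + (b - a) * 10^seq(-8, 0, by = 0.0625))
  }
  grid <- sort(unique(grid))
  res <- safe_ode(as.numeric(x0), grid, rhs_state, jac_state, config,
                  maxsteps = config$max_steps,
                  parms = list(model = model, deriv = deriv, theta = theta,
                               u = u))
  if (!res$ok)
    signal_failure("numerical_error",
                   paste0("dynamic simulation failed: ", res$msg),
                   phase = "dynamic")
  states <- unname(as.matrix(res$out[, -1, drop = FALSE]))
  derivs <- t(apply(states, 1, function(s) eval_f(model, s, theta, u)))
  if (length(model$state_names) == 1) derivs <- matrix(derivs, ncol = 1)
  idx <- match(mtimes, grid)
  ny <- length(model$observables)
  outputs <- matrix(NA_real_, length(mtimes), ny,
                    dimnames = list(NULL, names(model$observables)))
  for (r in seq_along(mtimes))
    outputs[r, ] <- eval_h(model, states[idx[r], ], theta, u)
  list(times = grid, states = states, derivs = derivs,
       mtimes = mtimes, outputs = outputs,
       end_state = states[nrow(states), ], m_index = idx)
}

run_equilibration <- function(method, model, deriv, theta, u, x_init, config,
                              keep_trajectory = FALSE) {
  if (method == "newton")
    equilibrate_by_newton(model, deriv, theta, u, x_init, config)
  else
    equilibrate_by_integration(model, deriv, theta, u, x_init, config,
                               keep_trajectory = keep_trajectory)
}

#' Simulate one experimental condition
#'
#' Runs the phases a condition requires: pre-equilibration under the
#' referenced condition's inputs (the resulting steady state becomes the
#' dynamic initial condition), the dynamic phase over the finite
#' measurement times, and post-equilibration when steady-state
#' (`time = Inf`) rows are present, continuing from the last dynamic state.
#' Steady states are computed by the pair's steady-state method.  Failures
#' are returned as structured categories with the failing phase, never
#' raised.
#'
#' @param model,deriv model and derivatives.
#' @param theta parameters (linear scale).
#' @param cond a [condition()].
#' @param data an `eqsens_dataset` (only this condition's rows are used).
#' @param pair a [method_pair()].
#' @param config an [eqsens_config()].
#' @param keep_trajectories retain dense trajectories for adjoint passes.
#' @return a list of class `simulation_result` with fields `condition_id`,
#'   `status` (`"ok"` or a failure category), `phase`, `x_preeq_star`,
#'   `dyn` (dense dynamic solution incl. outputs at measurement times),
#'   `x_star`, `y_steady`, `sigma`, `posteq_result`, `preeq_result`,
#'   `timings`.
#' @export
simulate_condition <- function(model, deriv, theta, cond, data, pair,
                               config = eqsens_config(),
                               keep_trajectories = FALSE) {
  rows <- data$measurements[data$measurements$simulationConditionId ==
                              cond$condition_id, , drop = FALSE]
  u <- cond_inputs(model, cond)
  ft <- sort(unique(rows$time[is.finite(rows$time)]))
  has_post <- any(is.infinite(rows$time))
  out <- list(condition_id = cond$condition_id, status = "ok",
              phase = NA_character_, x_preeq_star = NULL, preeq_result = NULL,
              dyn = NULL, x_star = NULL, y_steady = NULL,
              posteq_result = NULL,
              sigma = eval_sigma(model, theta),
              timings = c(equilibration = 0, dynamic = 0, overhead = 0))
  t_all0 <- Sys.time()
  fail <- function(category, phase) {
    out$status <- category; out$phase <- phase
    out$timings[["overhead"]] <- max(0,
      as.numeric(difftime(Sys.time(), t_all0, units = "secs")) -
        out$timings[["equilibration"]] - out$timings[["dynamic"]])
    class(out) <- "simulation_result"
    out
  }

  # pre-equilibration
  if (!is.na(cond$preeq_condition_id)) {
    pre_cond <- data$conditions[[cond$preeq_condition_id]]
    u_e <- cond_inputs(model, pre_cond)
    x_init <- eval_x0(model, theta, u_e)
    res <- run_equilibration(pair$steady_state_method, model, deriv, theta,
                             u_e, x_init, config,
                             keep_trajectory = keep_trajectories)
    out$timings[["equilibration"]] <- out$timings[["equilibration"]] +
      res$equilibration_time_elapsed
    out$preeq_result <- res
    if (res$status != "converged")
      return(fail(classify_ss_failure(model, deriv, res), "preeq"))
    out$x_preeq_star <- res$x_star
    x0_dyn <- res$x_star
  } else {
    x0_dyn <- eval_x0(model, theta, u)
  }

  # dynamic phase
  if (length(ft)) {
    t_dyn <- Sys.time()
    dyn <- tryCatch(forward_dynamic(model, deriv, theta, u, x0_dyn, ft, config),
                    eqsens_failure = function(e) e)
    out$timings[["dynamic"]] <- as.numeric(difftime(Sys.time(), t_dyn,
                                                    units = "secs"))
    if (inherits(dyn, "eqsens_failure"))
      return(fail(failure_category(dyn), "dynamic"))
    if (min(dyn$states) < -config$neg_tol)
      return(fail("negative_state", "dynamic"))
    out$dyn <- dyn
    x_post_init <- dyn$end_state
  } else {
    x_post_init <- x0_dyn
  }

  # post-equilibration
  if (has_post) {
    res <- run_equilibration(pair$steady_state_method, model, deriv, theta,
                             u, x_post_init, config,
                             keep_trajectory = keep_trajectories)
    out$timings[["equilibration"]] <- out$timings[["equilibration"]] +
      res$equilibration_time_elapsed
    out$posteq_result <- res
    if (res$status != "converged")
      return(fail(classify_ss_failure(model, deriv, res), "posteq"))
    out$x_star <- res$x_star
    out$y_steady <- eval_h(model, res$x_star, theta, u)
  }
  out$timings[["overhead"]] <- max(0,
    as.numeric(difftime(Sys.time(), t_all0, units = "secs")) -
      out$timings[["equilibration"]] - out$timings[["dynamic"]])
  class(out) <- "simulation_result"
  out
}

# ---- likelihood -------------------------------------------------------------

#' Negative log-likelihood of simulated conditions
#'
#' Gaussian measurement model: for finite-time rows
#' \eqn{\frac12[\log(2\pi\sigma_{ij}^2) + ((\bar y_{ij} - y_i(t_j))/\sigma_{ij})^2]},
#' plus the analogous terms over `time = Inf` rows evaluated at the
#' post-equilibration steady state.
#'
#' @param results named list of `simulation_result` objects (one per
#'   condition, all with status `"ok"`).
#' @param measurements measurement data.frame.
#' @return scalar negative log-likelihood (nats).
#' @export
negative_log_likelihood <- function(results, measurements) {
  nll <- 0
  for (r in seq_len(nrow(measurements))) {
    row <- measurements[r, ]
    res <- results[[row$simulationConditionId]]
    if (is.null(res) || res$status != "ok")
      signal_failure(if (is.null(res)) "numerical_error" else res$status,
                     paste0("condition '", row$simulationConditionId,
                            "' did not simulate successfully"),
                     phase = if (is.null(res)) NA_character_ else res$phase)
    sig <- res$sigma[[row$observableId]]
    if (!is.finite(sig) || sig <= 0)
      stop("noise standard deviation must be positive for observable '",
           row$observableId, "'")
    y <- if (is.infinite(row$time)) {
      res$y_steady[[row$observableId]]
    } else {
      res$dyn$outputs[match(row$time, res$dyn$mtimes), row$observableId]
    }
    nll <- nll + 0.5 * (log(2 * pi * sig^2) + ((row$measurement - y) / sig)^2)
  }
  as.numeric(nll)
}

#' Objective value for a parameter vector
#'
#' Simulates every condition referenced by the measurements with the given
#' method pair and evaluates [negative_log_likelihood()].
#'
#' @inheritParams objective_gradient
#' @return scalar, or a structured failure (class `eqsens_failure`) if any
#'   condition fails.
#' @export
evaluate_objective <- function(model, deriv, theta, data,
                               pair = method_pair("int_lin_fsa"),
                               config = eqsens_config()) {
  ids <- unique(data$measurements$simulationConditionId)
  results <- list()
  for (id in ids) {
    res <- simulate_condition(model, deriv, theta, data$conditions[[id]],
                              data, pair, config)
    if (res$status != "ok")
      signal_failure(res$status,
                     paste0("condition '", id, "' failed in phase ",
                            res$phase), phase = res$phase)
    results[[id]] <- res
  }
  negative_log_likelihood(results, data$measurements)
}

# convert a linear-scale gradient to the declared optimization scale
grad_to_scale <- function(model, theta, grad) {
  islog <- model$scale == "log10"
  grad[islog] <- grad[islog] * theta[islog] * log(10)
  stats::setNames(grad, model$parameter_names)
}

gradient_result <- function(objective_value, gradient, pair, status = "ok",
                            phase = NA_character_, timings = NULL) {
  structure(list(objective_value = objective_value, gradient = gradient,
                 method_pair = pair$name, status = status, phase = phase,
                 timings = timings),
            class = "gradient_result")
}

#' @export
print.gradient_result <- function(x, ...) {
  cat("gradient_result [", x$method_pair, "]: ", x$status, "\n", sep = "")
  if (x$status == "ok") {
    cat("  objective:", format(x$objective_value), "\n  gradient:",
        format(x$gradient), "\n")
  }
  invisible(x)
}

# ---- gradient computation ---------------------------------------------------

#' Objective-function gradient by a chosen method pair
#'
#' Computes the negative log-likelihood and its gradient with respect to
#' the parameters on their declared optimization scale (for `log10`-scaled
#' parameters the linear-scale gradient is multiplied by
#' \eqn{\theta_k \ln 10}).  The FSA routes propagate state sensitivities
#' (initialized from the tailored linear solve or from equilibrated
#' forward sensitivities, according to the pair) and assemble the gradient
#' from output sensitivities; the ASA routes run a backward adjoint pass
#' over the dynamic window plus tailored or integrated equilibration
#' contributions.  All failures are returned as structured categories.
#'
#' @param model,deriv model and derivatives.
#' @param theta named parameter vector (linear scale).
#' @param data an [dataset()].
#' @param pair a [method_pair()].
#' @param config an [eqsens_config()].
#' @return a `gradient_result` with `objective_value`, `gradient`,
#'   `method_pair`, `status`.
#' @export
objective_gradient <- function(model, deriv, theta, data,
                               pair = method_pair("int_lin_fsa"),
                               config = eqsens_config()) {
  t0 <- Sys.time()
  res <- tryCatch(
    objective_gradient_impl(model, deriv, theta, data, pair, config),
    eqsens_failure = function(e)
      gradient_result(NA_real_, NULL, pair, status = failure_category(e),
                      phase = if (is.null(e$phase)) NA_character_ else e$phase))
  res$timings <- c(total = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  res
}

objective_gradient_impl <- function(model, deriv, theta, data, pair, config) {
  np <- length(model$parameter_names)
  ids <- unique(data$measurements$simulationConditionId)
  nll <- 0
  grad <- numeric(np)
  is_fsa <- pair$sensitivity_method %in% c("fsa_integration", "fsa_tailored")
  for (id in ids) {
    contrib <- if (is_fsa) {
      condition_gradient_fsa(model, deriv, theta, data, id, pair, config)
    } else {
      condition_gradient_asa(model, deriv, theta, data, id, pair, config)
    }
    nll <- nll + contrib$nll
    grad <- grad + contrib$grad
  }
  gradient_result(as.numeric(nll), grad_to_scale(model, theta, grad), pair)
}

# shared per-row likelihood/σ-term machinery
row_terms <- function(measurement, y, sigma, dsig_row) {
  y <- as.numeric(y); sigma <- as.numeric(sigma)
  r <- measurement - y
  list(nll = 0.5 * (log(2 * pi * sigma^2) + (r / sigma)^2),
       sigma_term = (1 / sigma) * (1 - r^2 / sigma^2) * dsig_row,
       wres = r / sigma^2)
}

condition_gradient_fsa <- function(model, deriv, theta, data, id, pair,
                                   config) {
  cond <- data$conditions[[id]]
  rows <- data$measurements[data$measurements$simulationConditionId == id, ,
                            drop = FALSE]
  u <- cond_inputs(model, cond)
  ft <- sort(unique(rows$time[is.finite(rows$time)]))
  has_post <- any(is.infinite(rows$time))
  np <- length(model$parameter_names)
  tailored <- pair$sensitivity_method == "fsa_tailored"

  equilibrate_with_sens <- function(u_eq, x_init, s_init, phase) {
    if (pair$steady_state_method == "newton") {
      res <- equilibrate_by_newton(model, deriv, theta, u_eq, x_init, config)
      if (res$status != "converged")
        signal_failure(classify_ss_failure(model, deriv, res),
                       "Newton equilibration failed", phase)
      S <- steady_state_sensitivities(deriv, model, theta, u_eq, res$x_star,
                                      config$cond_max)
    } else if (tailored) {
      res <- equilibrate_by_integration(model, deriv, theta, u_eq, x_init,
                                        config)
      if (res$status != "converged")
        signal_failure(res$status, "equilibration failed", phase)
      S <- steady_state_sensitivities(deriv, model, theta, u_eq, res$x_star,
                                      config$cond_max)
    } else {
      eq <- equilibrate_with_fsa_by_integration(model, deriv, theta, u_eq,
                                                x_init, s_init, config)
      res <- eq$result
      if (res$status != "converged")
        signal_failure(res$status, "sensitivity equilibration failed", phase)
      S <- eq$sens
    }
    list(result = res, S = S)
  }

  # initial state and sensitivity of the dynamic phase
  if (!is.na(cond$preeq_condition_id)) {
    u_e <- cond_inputs(model, data$conditions[[cond$preeq_condition_id]])
    x_init <- eval_x0(model, theta, u_e)
    pre <- equilibrate_with_sens(u_e, x_init,
                                 eval_dx0dp(deriv, model, theta, u_e),
                                 phase = "preeq")
    x0_dyn <- pre$result$x_star
    s0_dyn <- pre$S
  } else {
    x0_dyn <- eval_x0(model, theta, u)
    s0_dyn <- eval_dx0dp(deriv, model, theta, u)
  }

  # dynamic phase with coupled sensitivities
  if (length(ft)) {
    tr <- integrate_with_fsa(model, deriv, theta, u, x0_dyn, s0_dyn, ft,
                             config)
    if (min(tr$states) < -config$neg_tol)
      signal_failure("negative_state", "negative state in dynamic phase",
                     "dynamic")
    mt_idx <- match(ft, tr$times)
    x_post_init <- tr$states[nrow(tr$states), ]
    s_post_init <- matrix(tr$sens[nrow(tr$states), , ],
                          length(model$state_names), np)
  } else {
    tr <- NULL
    x_post_init <- x0_dyn
    s_post_init <- s0_dyn
  }

  # post-equilibration steady state and its sensitivities
  if (has_post) {
    post <- tryCatch(
      equilibrate_with_sens(u, x_post_init, s_post_init, phase = "posteq"),
      eqsens_failure = function(e) {
        e$phase <- if (is.null(e$phase) || is.na(e$phase)) "posteq" else e$phase
        stop(e)
      })
    x_star <- post$result$x_star
    S_star <- post$S
    y_star <- eval_h(model, x_star, theta, u)
    osens_ss <- eval_dhdx(deriv, model, x_star, theta, u) %*% S_star +
      eval_dhdp(deriv, model, x_star, theta, u)
  }

  sigma <- eval_sigma(model, theta)
  dsig <- eval_dsigmadp(deriv, model, theta)
  obs_idx <- stats::setNames(seq_along(model$observables),
                             names(model$observables))
  nll <- 0; grad <- numeric(np)
  for (r in seq_len(nrow(rows))) {
    row <- rows[r, ]
    i <- obs_idx[[row$observableId]]
    if (is.infinite(row$time)) {
      tm <- row_terms(row$measurement, y_star[i], sigma[i], dsig[i, ])
      grad <- grad + tm$sigma_term - tm$wres * osens_ss[i, ]
    } else {
      j <- mt_idx[match(row$time, ft)]
      tm <- row_terms(row$measurement, tr$outputs[j, i], sigma[i], dsig[i, ])
      grad <- grad + tm$sigma_term - tm$wres * tr$output_sens[j, i, ]
    }
    nll <- nll + tm$nll
  }
  list(nll = nll, grad = grad)
}

condition_gradient_asa <- function(model, deriv, theta, data, id, pair,
                                   config) {
  cond <- data$conditions[[id]]
  rows <- data$measurements[data$measurements$simulationConditionId == id, ,
                            drop = FALSE]
  u <- cond_inputs(model, cond)
  np <- length(model$parameter_names)
  nx <- length(model$state_names)
  tailored <- pair$sensitivity_method == "asa_tailored"
  ft <- sort(unique(rows$time[is.finite(rows$time)]))
  has_post <- any(is.infinite(rows$time))

  sim <- simulate_condition(model, deriv, theta, cond, data, pair, config,
                            keep_trajectories = !tailored)
  if (sim$status != "ok")
    signal_failure(sim$status, paste0("condition '", id, "' failed"),
                   sim$phase)

  sigma <- sim$sigma
  dsig <- eval_dsigmadp(deriv, model, theta)
  obs_idx <- stats::setNames(seq_along(model$observables),
                             names(model$observables))
  nll <- 0; grad <- numeric(np)

  # steady-state (time = Inf) rows: direct sigma/h terms + residual adjoint
  p_ss <- numeric(nx)
  if (has_post) {
    dhdx_ss <- eval_dhdx(deriv, model, sim$x_star, theta, u)
    dhdp_ss <- eval_dhdp(deriv, model, sim$x_star, theta, u)
  }
  for (r in which(is.infinite(rows$time))) {
    row <- rows[r, ]
    i <- obs_idx[[row$observableId]]
    tm <- row_terms(row$measurement, sim$y_steady[[row$observableId]],
                    sigma[i], dsig[i, ])
    nll <- nll + tm$nll
    grad <- grad + tm$sigma_term - tm$wres * dhdp_ss[i, ]
    p_ss <- p_ss + tm$wres * dhdx_ss[i, ]
  }

  # post-equilibration adjoint contribution
  p_end_dyn <- numeric(nx)
  if (has_post && any(p_ss != 0)) {
    if (tailored) {
      contrib <- posteq_adjoint_contribution(deriv, model, theta, u,
                                             sim$x_star, p_ss,
                                             config$cond_max)
      grad <- grad + contrib$increment
    } else {
      contrib <- posteq_adjoint_by_integration(model, deriv, theta, u,
                                               sim$posteq_result$trajectory,
                                               p_ss, config)
      grad <- grad + contrib$increment
      p_end_dyn <- contrib$p_start
    }
  }

  # dynamic-window rows: sigma/h terms and residual jumps
  jumps <- list()
  if (length(ft)) {
    for (tj in ft) {
      jump <- numeric(nx)
      sel <- which(rows$time == tj)
      xj <- sim$dyn$states[sim$dyn$m_index[match(tj, sim$dyn$mtimes)], ]
      dhdx_j <- eval_dhdx(deriv, model, xj, theta, u)
      dhdp_j <- eval_dhdp(deriv, model, xj, theta, u)
      for (r in sel) {
        row <- rows[r, ]
        i <- obs_idx[[row$observableId]]
        tm <- row_terms(row$measurement,
                        sim$dyn$outputs[match(tj, sim$dyn$mtimes), i],
                        sigma[i], dsig[i, ])
        nll <- nll + tm$nll
        grad <- grad + tm$sigma_term - tm$wres * dhdp_j[i, ]
        jump <- jump + tm$wres * dhdx_j[i, ]
      }
      jumps[[length(jumps) + 1]] <- list(time = tj, jump = jump)
    }
    adj <- backward_adjoint(model, deriv, theta, u, sim$dyn, jumps, config,
                            p_end = p_end_dyn)
    p_t0 <- adj$p_t0
    grad <- grad - adj$quadrature
  } else {
    p_t0 <- p_end_dyn
  }

  # initial-condition term: pre-equilibration contribution or -p(t0)' dx0/dp
  if (!is.na(cond$preeq_condition_id)) {
    u_e <- cond_inputs(model, data$conditions[[cond$preeq_condition_id]])
    if (any(p_t0 != 0)) {
      if (tailored) {
        contrib <- preeq_adjoint_contribution(deriv, model, theta, u_e,
                                              sim$x_preeq_star, p_t0,
                                              config$cond_max)
        grad <- grad + contrib$increment
      } else {
        tr_pre <- sim$preeq_result$trajectory
        x_at <- hermite_interp(tr_pre$times, tr_pre$states, tr_pre$derivs)
        w <- adjoint_window(model, deriv, theta, u_e, x_at, 0,
                            tr_pre$times[length(tr_pre$times)], p_t0, config,
                            phase = "preeq")
        grad <- grad - w$quad -
          as.numeric(w$p_lo %*% eval_dx0dp(deriv, model, theta, u_e))
      }
    }
  } else if (any(p_t0 != 0)) {
    grad <- grad - as.numeric(p_t0 %*% eval_dx0dp(deriv, model, theta, u))
  }

  list(nll = nll, grad = grad)
}

#' Central finite-difference gradient (reference oracle)
#'
#' Central differences of the negative log-likelihood on the parameters'
#' optimization scale, simulating with integration-based steady states.
#' Intended as an independent reference for testing gradient
#' implementations; finite differences are less stable and far more
#' expensive than FSA/ASA for production use.
#'
#' @inheritParams objective_gradient
#' @param step central difference step on the optimization scale.
#' @return named gradient vector on the optimization scale.
#' @export
finite_difference_gradient <- function(model, deriv, theta, data,
                                       config = eqsens_config(),
                                       step = config$fd_step) {
  pair <- method_pair("int_lin_fsa")  # steady states by integration
  np <- length(model$parameter_names)
  to_opt <- function(th) ifelse(model$scale == "log10", log10(th), th)
  to_lin <- function(v) ifelse(model$scale == "log10", 10^v, v)
  v0 <- to_opt(as.numeric(theta[model$parameter_names]))
  g <- numeric(np)
  for (k in seq_len(np)) {
    vp <- v0; vp[k] <- vp[k] + step
    vm <- v0; vm[k] <- vm[k] - step
    fp <- evaluate_objective(model, deriv,
                             stats::setNames(to_lin(vp), model$parameter_names),
                             data, pair, config)
    fm <- evaluate_objective(model, deriv,
                             stats::setNames(to_lin(vm), model$parameter_names),
                             data, pair, config)
    g[k] <- (fp - fm) / (2 * step)
  }
  stats::setNames(g, model$parameter_names)
}
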