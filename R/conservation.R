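# Conserved quantities: linear combinations c'x with c'f == 0 everywhere.
# They make the Jacobian rank-deficient, which rules out Newton's method and
# the tailored (linear-solve) sensitivity methods, so they must be removed
# before those are applicable.

#' Detect conserved quantities numerically
#'
#' Finds a basis of vectors `c` such that \eqn{c^T f(x,\theta,u) = 0} at all
#' probe points, via the common left null space of Jacobian evaluations at
#' random probes (random positive states, parameters sampled within their
#' bounds on the declared scale).  Detection is numeric rather than
#' stoichiometry-based because the model dialect stores general rate
#' expressions, not a stoichiometric matrix.
#'
#' @param model an [ode_model()].
#' @param deriv optional [derive()] result (computed if missing).
#' @param n_probes number of probe points (at least `n_x`).
#' @param seed RNG seed for the probes.
#' @param tol relative SVD threshold below which a singular value is treated
#'   as zero.
#' @return list of conservation laws, each a list with `coefficients`
#'   (length `n_x`, largest entry normalized to 1), `total_name` (identifier
#'   for the conserved total), and `eliminated_state` (index of the state
#'   chosen for elimination: largest absolute coefficient, ties broken by
#'   lowest index).  Empty list when the Jacobian has full rank.
#' @export
detect_conservation <- function(model, deriv = NULL, n_probes = NULL,
                                seed = 1L, tol = 1e-10) {
  nx <- length(model$state_names)
  if (is.null(n_probes)) n_probes <- max(nx + 2L, 5L)
  if (n_probes < nx) stop("n_probes must be at least the number of states")
  if (is.null(deriv)) deriv <- derive(model)
  probes <- with_preserved_rng({
    set.seed(seed)
    replicate(n_probes, list(
      x = stats::runif(nx, 0.1, 2),
      theta = sample_theta_once(model),
      u = stats::runif(length(model$input_names), 0.5, 2)), simplify = FALSE)
  })
  stacked <- do.call(rbind, lapply(probes, function(p)
    t(eval_jac(deriv, model, p$x, p$theta, p$u))))
  sv <- svd(stacked, nu = 0, nv = nx)
  dmax <- max(sv$d, 0)
  null_idx <- if (dmax == 0) seq_len(nx) else which(sv$d < tol * dmax)
  # all-zero Jacobian: every direction is conserved
  if (dmax == 0) {
    basis <- diag(nx)
  } else if (length(null_idx) == 0) {
    return(list())
  } else {
    basis <- sv$v[, null_idx, drop = FALSE]
  }
  laws <- list()
  # lowest index among coefficients tied (to roundoff) for the largest
  # magnitude, so elimination choices are deterministic
  lead_index <- function(v) which(abs(v) >= max(abs(v)) * (1 - 1e-9))[1]
  for (j in seq_len(ncol(basis))) {
    co <- basis[, j]
    co[abs(co) < 1e-12] <- 0
    lead <- lead_index(co)
    co <- co / co[lead]              # leading entry -> +1
    co[abs(co) < 1e-10] <- 0
    co[abs(co - round(co)) < 1e-9] <- round(co[abs(co - round(co)) < 1e-9])
    # validate c'f ~ 0 at the probes
    resid <- max(vapply(probes, function(p)
      abs(sum(co * eval_f(model, p$x, p$theta, p$u))), numeric(1)))
    fscale <- max(vapply(probes, function(p)
      max(abs(eval_f(model, p$x, p$theta, p$u)), 1e-300), numeric(1)))
    if (resid > 1e-8 * max(fscale, 1)) next
    elim <- lead_index(co)           # ties -> lowest index
    total <- make.unique(c(model$parameter_names,
                           paste0("total_", model$state_names[elim])))[
                             length(model$parameter_names) + 1L]
    laws[[length(laws) + 1L]] <- list(coefficients = co,
                                      total_name = total,
                                      eliminated_state = elim)
  }
  laws
}

#' Remove conserved quantities from a model
#'
#' Eliminates one state per conservation law: the eliminated state is
#' replaced in every rate and observable expression by
#' `(total - sum of the other weighted states) / its coefficient`, and the
#' conserved total becomes a new parameter whose defining expression
#' \eqn{c^T x_0(\theta, u)} is recorded in `model$total_exprs`.  Bounds for
#' the new parameter are obtained by evaluating that expression at the lower
#' and upper parameter bound vectors.  After reduction with a complete law
#' basis the Jacobian has full rank, so Newton's method and the tailored
#' sensitivity methods become applicable.
#'
#' @param model an [ode_model()].
#' @param laws laws from [detect_conservation()] (the `eliminated_state`
#'   field may be overridden by the caller).
#' @param reference_state optional state vector used, together with `theta`
#'   at mid-bounds, to sanity-check that the substituted dynamics evaluate
#'   finitely.
#' @return a reduced [ode_model()] with `n_x - length(laws)` states.
#' @export
reduce_model <- function(model, laws, reference_state = NULL) {
  if (length(laws) == 0) return(model)
  elim_idx <- vapply(laws, function(l) as.integer(l$eliminated_state), 1L)
  if (anyDuplicated(elim_idx)) stop("eliminated states must be distinct")

  states <- model$state_names
  rhs <- model$rhs
  init <- model$init
  obs <- model$observables
  par_names <- model$parameter_names
  lower <- model$lower; upper <- model$upper; scale <- model$scale
  total_exprs <- model$total_exprs

  for (law in laws) {
    e <- law$eliminated_state
    co <- law$coefficients
    if (co[e] == 0) stop("eliminated state has zero coefficient in the law")
    total <- law$total_name
    # replacement: (total - sum_{i != e} c_i x_i) / c_e
    repl <- as.name(total)
    for (i in seq_along(states)) {
      if (i == e || co[i] == 0) next
      repl <- call("-", repl, call("*", co[i], as.name(states[i])))
    }
    if (co[e] != 1) repl <- call("/", repl, co[e])
    subs <- stats::setNames(list(repl), states[e])

    # total's defining expression c' x0 in the original parameters/inputs
    tot_expr <- NULL
    for (i in seq_along(states)) {
      if (co[i] == 0) next
      term <- if (co[i] == 1) init[[i]] else call("*", co[i], init[[i]])
      tot_expr <- if (is.null(tot_expr)) term else call("+", tot_expr, term)
    }

    # bounds for the total from the bound corners of c' x0
    env_lo <- c(as.list(lower), as.list(stats::setNames(
      rep(1, length(model$input_names)), model$input_names)))
    env_hi <- c(as.list(upper), as.list(stats::setNames(
      rep(1, length(model$input_names)), model$input_names)))
    b <- sort(c(eval_expr(tot_expr, env_lo), eval_expr(tot_expr, env_hi)))
    if (!all(is.finite(b))) stop("cannot derive bounds for total '", total, "'")

    keep <- setdiff(seq_along(states), e)
    rhs <- lapply(rhs[keep], subst_lang, subs = subs)
    init <- init[keep]
    states <- states[keep]
    obs <- lapply(obs, function(o)
      list(formula = subst_lang(o$formula, subs), noise = o$noise))
    par_names <- c(par_names, total)
    tot_scale <- if (b[1] > 0) "log10" else "lin"
    lower <- c(lower, stats::setNames(b[1], total))
    upper <- c(upper, stats::setNames(b[2], total))
    scale <- c(scale, stats::setNames(tot_scale, total))
    total_exprs[[total]] <- tot_expr

    # remaining laws refer to the original state indexing; re-map
    laws <- lapply(laws, function(l) {
      if (identical(l$total_name, total)) return(l)
      l$coefficients <- l$coefficients[-e]
      l$eliminated_state <- l$eliminated_state - (l$eliminated_state > e)
      l
    })
  }

  out <- ode_model(
    states = stats::setNames(init, states),
    parameters = data.frame(name = par_names, lower = as.numeric(lower),
                            upper = as.numeric(upper),
                            scale = as.character(scale),
                            stringsAsFactors = FALSE),
    rates = stats::setNames(rhs, states),
    observables = stats::setNames(
      lapply(obs, function(o)
        list(formula = o$formula, noise_formula = o$noise)),
      names(obs)),
    inputs = model$input_names,
    validate_sigma = 0L)
  out$total_exprs <- total_exprs

  if (!is.null(reference_state)) {
    th <- stats::setNames(sqrt(out$lower * pmax(out$upper, out$lower)),
                          out$parameter_names)
    fx <- eval_f(out, reference_state[seq_along(out$state_names)], th,
                 rep(1, length(out$input_names)))
    if (any(!is.finite(fx)))
      stop("reduced dynamics do not evaluate finitely at the reference state")
  }
  out
}

#' Value of the conserved totals for a reduced model
#'
#' Evaluates each recorded total expression \eqn{c^T x_0} of a reduced model
#' at the given original-model parameters, producing the total-parameter
#' values that make the reduced model's trajectories match the full model's.
#'
#' @param model a reduced [ode_model()] with non-empty `total_exprs`.
#' @param theta named parameters of the *original* model (linear scale).
#' @param u inputs.
#' @return named numeric vector of totals.
#' @export
eval_totals <- function(model, theta, u = numeric(0)) {
  env <- c(as.list(theta), as.list(stats::setNames(as.numeric(u),
                                                   model$input_names)))
  vapply(model$total_exprs, eval_expr, numeric(1), env = env)
}
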