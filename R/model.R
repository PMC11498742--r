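# ---- expression helpers -----------------------------------------------------

parse_expr <- function(x, what = "expression") {
  if (is.language(x) || is.numeric(x)) {
    if (is.numeric(x)) return(as.numeric(x))
    return(x)
  }
  out <- tryCatch(str2lang(as.character(x)),
                  error = function(e) stop("cannot parse ", what, ": '", x, "'",
                                           call. = FALSE))
  out
}

expr_vars <- function(e) if (is.language(e)) all.vars(e) else character(0)

#' @keywords internal
expr_matrix <- function(nrow, ncol) {
  matrix(rep(list(0), nrow * ncol), nrow = nrow, ncol = ncol)
}

eval_expr <- function(e, env) {
  if (is.numeric(e)) return(as.numeric(e))
  eval(e, envir = env)
}

eval_expr_list <- function(exprs, env) {
  vapply(exprs, eval_expr, numeric(1), env = env)
}

eval_expr_matrix <- function(m, env) {
  out <- vapply(m, eval_expr, numeric(1), env = env)
  dim(out) <- dim(m)
  out
}

# substitute a named list of language replacements into an expression
subst_lang <- function(e, subs) {
  if (is.numeric(e)) return(e)
  do.call(substitute, list(e, subs))
}

deriv_expr <- function(e, var) {
  if (is.numeric(e)) return(0)
  tryCatch(stats::D(e, var),
           error = function(err) stop(
             "expression '", deparse1(e), "' is not differentiable with ",
             "respect to '", var, "': ", conditionMessage(err),
             " (discontinuous rate laws need piecewise handling, ",
             "which is not supported)", call. = FALSE))
}

# ---- compiled evaluators ----------------------------------------------------
# Expressions are compiled once per model into plain closures that unpack
# (x, theta, u) positionally; ~10x faster than per-expression eval() in a
# constructed environment, which matters inside integrator callbacks.

compile_fun <- function(model, exprs, nrow = NULL, ncol = NULL) {
  dep <- vapply(as.list(exprs), deparse1, character(1))
  asg <- c(
    sprintf("%s <- .x[[%d]]", model$state_names,
            seq_along(model$state_names)),
    sprintf("%s <- .theta[[%d]]", model$parameter_names,
            seq_along(model$parameter_names)),
    if (length(model$input_names))
      sprintf("%s <- .u[[%d]]", model$input_names,
              seq_along(model$input_names)))
  core <- paste0("c(", paste(dep, collapse = ", "), ")")
  if (!is.null(nrow))
    core <- sprintf("matrix(%s, %dL, %dL)", core, nrow, ncol)
  txt <- paste0("function(.x, .theta, .u) {\n",
                paste(asg, collapse = "\n"), "\n", core, "\n}")
  eval(str2lang(txt), envir = baseenv())
}

get_compiled <- function(cache, key, builder) {
  if (is.null(cache[[key]])) cache[[key]] <- builder()
  cache[[key]]
}

pad_u <- function(model, u) {
  if (length(u) == length(model$input_names)) as.numeric(u)
  else rep(NA_real_, length(model$input_names))
}

model_env <- function(model, x, theta, u) {
  env <- c(as.list(stats::setNames(as.numeric(x), model$state_names)),
           as.list(stats::setNames(as.numeric(theta), model$parameter_names)))
  if (length(model$input_names)) {
    uu <- as.numeric(u)
    if (length(uu) != length(model$input_names))
      uu <- rep(NA_real_, length(model$input_names))  # e.g. sigma(theta) only
    env <- c(env, as.list(stats::setNames(uu, model$input_names)))
  }
  env
}

# ---- OdeModel ---------------------------------------------------------------

#' Construct an ODE model
#'
#' An `ode_model` holds a system of ordinary differential equations
#' \eqn{\dot x = f(x, \theta, u)} with initial condition \eqn{x_0(\theta, u)},
#' an observation map \eqn{y = h(x, \theta, u)} and a Gaussian noise model
#' with standard deviations \eqn{\sigma(\theta)}.  States represent, e.g.,
#' species abundances, `theta` are unknown kinetic parameters with box bounds
#' and a sampling/optimization scale (`lin` or `log10`), and `u` are known
#' experimental inputs.
#'
#' All expressions are stored symbolically (as R language objects) so that
#' exact derivatives can be produced by [derive()].
#'
#' @param states named list mapping state name to its initial-value
#'   expression (a string, number, or language object in parameters/inputs).
#' @param parameters data.frame with columns `name`, `lower`, `upper`,
#'   `scale` (`"lin"` or `"log10"`).
#' @param rates named list mapping each state name to its rate expression
#'   \eqn{f_i} (string or language object).
#' @param observables named list mapping observable name to
#'   `list(formula = , noise_formula = )`.
#' @param inputs character vector of input names (may be empty).
#' @param validate_sigma number of parameter samples used to check noise
#'   expressions evaluate to positive values within bounds.
#' @return an object of class `ode_model`.
#' @export
ode_model <- function(states, parameters, rates, observables,
                      inputs = character(0), validate_sigma = 10L) {
  if (length(states) < 1) stop("model must declare at least one state")
  if (NROW(parameters) < 1) stop("model must declare at least one parameter")
  if (length(observables) < 1) stop("model must declare at least one observable")

  state_names <- names(states)
  if (is.null(state_names) || any(state_names == ""))
    stop("states must be a named list")
  par_names <- as.character(parameters$name)
  scale <- as.character(parameters$scale)
  if (!all(scale %in% c("lin", "log10")))
    stop("parameter scale must be 'lin' or 'log10'")
  lower <- as.numeric(parameters$lower)
  upper <- as.numeric(parameters$upper)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower > upper))
    stop("parameter bounds must be finite with lower <= upper")
  bad <- scale == "log10" & lower <= 0
  if (any(bad))
    stop("log10-scaled parameter(s) need positive bounds: ",
         paste(par_names[bad], collapse = ", "))

  all_names <- c(state_names, par_names, inputs)
  if (anyDuplicated(all_names))
    stop("duplicated identifier(s): ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "))

  if (!setequal(names(rates), state_names))
    stop("rates must be given for exactly the declared states")

  init <- lapply(states, parse_expr, what = "initial value")
  rhs <- lapply(rates[state_names], parse_expr, what = "rate")
  obs <- lapply(observables, function(o)
    list(formula = parse_expr(o$formula, "observable formula"),
         noise = parse_expr(o$noise_formula, "noise formula")))

  check_closed <- function(exprs, allowed, where) {
    for (nm in names(exprs)) {
      e <- exprs[[nm]]
      vars <- if (is.list(e)) unlist(lapply(e, expr_vars)) else expr_vars(e)
      extra <- setdiff(vars, allowed)
      if (length(extra))
        stop("undeclared symbol(s) in ", where, " '", nm, "': ",
             paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  check_closed(rhs, all_names, "rate for")
  check_closed(init, c(par_names, inputs), "initial value of")
  check_closed(obs, all_names, "observable")

  model <- structure(list(
    state_names = state_names,
    parameter_names = par_names,
    lower = stats::setNames(lower, par_names),
    upper = stats::setNames(upper, par_names),
    scale = stats::setNames(scale, par_names),
    input_names = inputs,
    rhs = rhs,
    init = init,
    observables = obs,
    total_exprs = list(),
    cache = new.env(parent = emptyenv())
  ), class = "ode_model")

  # noise expressions must be positive anywhere inside the bounds
  if (validate_sigma > 0) {
    with_preserved_rng({
      set.seed(20241023L)
      for (i in seq_len(validate_sigma)) {
        th <- sample_theta_once(model)
        env <- model_env(model, rep(1, length(state_names)), th,
                         rep(1, length(inputs)))
        sig <- vapply(obs, function(o) eval_expr(o$noise, env), numeric(1))
        if (any(!is.finite(sig)) || any(sig <= 0))
          stop("noise formula(s) not positive within parameter bounds: ",
               paste(names(obs)[!is.finite(sig) | sig <= 0], collapse = ", "))
      }
    })
  }
  model
}

# one draw of theta on the declared scale, linear values returned
sample_theta_once <- function(model) {
  lo <- model$lower; hi <- model$upper; sc <- model$scale
  th <- numeric(length(lo))
  for (k in seq_along(lo)) {
    if (sc[k] == "log10") {
      th[k] <- 10^stats::runif(1, log10(lo[k]), log10(hi[k]))
    } else {
      th[k] <- stats::runif(1, lo[k], hi[k])
    }
  }
  stats::setNames(th, model$parameter_names)
}

#' @export
print.ode_model <- function(x, ...) {
  cat("ode_model:", length(x$state_names), "state(s),",
      length(x$parameter_names), "parameter(s),",
      length(x$input_names), "input(s),",
      length(x$observables), "observable(s)\n")
  cat("  states:", paste(x$state_names, collapse = ", "), "\n")
  cat("  parameters:", paste(x$parameter_names, collapse = ", "), "\n")
  invisible(x)
}

#' Parse a model definition from YAML
#'
#' Reads the model dialect with top-level keys `states` (list of
#' `name`/`init`), `parameters` (list of `name`/`lower`/`upper`/`scale`),
#' `inputs` (list of names), `rates` (map state -> expression) and
#' `observables` (list of `name`/`formula`/`noise_formula`).
#'
#' @param path path to a YAML file, or a YAML string.
#' @return an [ode_model()].
#' @export
parse_model <- function(path) {
  doc <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  if (is.null(doc$states) || length(doc$states) == 0)
    stop("model document must declare a non-empty 'states' list")
  if (is.null(doc$parameters) || length(doc$parameters) == 0)
    stop("model document must declare a non-empty 'parameters' list")
  states <- stats::setNames(
    lapply(doc$states, function(s) s$init),
    vapply(doc$states, function(s) s$name, character(1)))
  parameters <- data.frame(
    name = vapply(doc$parameters, function(p) p$name, character(1)),
    lower = vapply(doc$parameters, function(p) as.numeric(p$lower), numeric(1)),
    upper = vapply(doc$parameters, function(p) as.numeric(p$upper), numeric(1)),
    scale = vapply(doc$parameters, function(p)
      if (is.null(p$scale)) "lin" else p$scale, character(1)),
    stringsAsFactors = FALSE)
  observables <- stats::setNames(
    lapply(doc$observables, function(o)
      list(formula = o$formula, noise_formula = o$noise_formula)),
    vapply(doc$observables, function(o) o$name, character(1)))
  ode_model(states = states, parameters = parameters, rates = doc$rates,
            observables = observables,
            inputs = as.character(unlist(doc$inputs)))
}

#' Serialize a model to the YAML dialect
#'
#' @param model an [ode_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_yaml <- function(model, path) {
  dep <- function(e) if (is.numeric(e)) e else deparse1(e)
  doc <- list(
    states = lapply(model$state_names, function(s)
      list(name = s, init = dep(model$init[[s]]))),
    parameters = lapply(model$parameter_names, function(p)
      list(name = p, lower = model$lower[[p]], upper = model$upper[[p]],
           scale = model$scale[[p]])),
    inputs = as.list(model$input_names),
    rates = lapply(model$rhs, dep),
    observables = lapply(names(model$observables), function(o)
      list(name = o, formula = dep(model$observables[[o]]$formula),
           noise_formula = dep(model$observables[[o]]$noise))))
  yaml::write_yaml(doc, path)
  invisible(path)
}

# ---- numeric evaluation -----------------------------------------------------

#' Evaluate the right-hand side f(x, theta, u)
#'
#' @param model an [ode_model()].
#' @param x state vector.
#' @param theta parameter vector (linear scale).
#' @param u input vector.
#' @return numeric vector of length `n_x`.
#' @export
eval_f <- function(model, x, theta, u = numeric(0)) {
  fn <- get_compiled(model$cache, "f", function() compile_fun(model, model$rhs))
  fn(x, theta, pad_u(model, u))
}

#' Evaluate the initial condition x0(theta, u)
#' @inheritParams eval_f
#' @return numeric vector of length `n_x`.
#' @export
eval_x0 <- function(model, theta, u = numeric(0)) {
  fn <- get_compiled(model$cache, "x0",
                     function() compile_fun(model, model$init))
  fn(rep(NA_real_, length(model$state_names)), theta, pad_u(model, u))
}

#' Evaluate observables h(x, theta, u)
#' @inheritParams eval_f
#' @return numeric vector of length `n_y`.
#' @export
eval_h <- function(model, x, theta, u = numeric(0)) {
  fn <- get_compiled(model$cache, "h", function()
    compile_fun(model, lapply(model$observables, `[[`, "formula")))
  stats::setNames(fn(x, theta, pad_u(model, u)), names(model$observables))
}

#' Evaluate noise standard deviations sigma(theta)
#' @inheritParams eval_f
#' @return numeric vector of length `n_y`.
#' @export
eval_sigma <- function(model, theta, x = rep(NA_real_, length(model$state_names)),
                       u = numeric(0)) {
  fn <- get_compiled(model$cache, "sigma", function()
    compile_fun(model, lapply(model$observables, `[[`, "noise")))
  stats::setNames(fn(x, theta, pad_u(model, u)), names(model$observables))
}

# ---- DerivativeSet ----------------------------------------------------------

#' Symbolic derivatives of a model
#'
#' Produces, by exact symbolic differentiation, the six derivative matrices
#' used throughout steady-state and sensitivity computation: the Jacobian
#' \eqn{\partial f/\partial x}, \eqn{\partial f/\partial\theta},
#' \eqn{\partial x_0/\partial\theta}, \eqn{\partial h/\partial x},
#' \eqn{\partial h/\partial\theta} and \eqn{\partial\sigma/\partial\theta}.
#'
#' @param model an [ode_model()].
#' @return an object of class `deriv_set` with expression matrices `jac`
#'   (`n_x` x `n_x`), `dfdp` (`n_x` x `n_theta`), `dx0dp`, `dhdx`, `dhdp`,
#'   `dsigmadp`, and evaluation helpers [eval_jac()] etc.
#' @export
derive <- function(model) {
  nx <- length(model$state_names)
  np <- length(model$parameter_names)
  ny <- length(model$observables)
  jac <- expr_matrix(nx, nx); dfdp <- expr_matrix(nx, np)
  dx0dp <- expr_matrix(nx, np)
  dhdx <- expr_matrix(ny, nx); dhdp <- expr_matrix(ny, np)
  dsig <- expr_matrix(ny, np)
  for (i in seq_len(nx)) {
    for (j in seq_len(nx))
      jac[[i, j]] <- deriv_expr(model$rhs[[i]], model$state_names[j])
    for (k in seq_len(np)) {
      dfdp[[i, k]] <- deriv_expr(model$rhs[[i]], model$parameter_names[k])
      dx0dp[[i, k]] <- deriv_expr(model$init[[i]], model$parameter_names[k])
    }
  }
  for (i in seq_len(ny)) {
    o <- model$observables[[i]]
    for (j in seq_len(nx))
      dhdx[[i, j]] <- deriv_expr(o$formula, model$state_names[j])
    for (k in seq_len(np)) {
      dhdp[[i, k]] <- deriv_expr(o$formula, model$parameter_names[k])
      dsig[[i, k]] <- deriv_expr(o$noise, model$parameter_names[k])
    }
  }
  # second derivatives wrt states, needed for the analytic Jacobian of the
  # augmented forward-sensitivity system: d2f/dx2 and d2f/(dx dtheta)
  d2fdxdx <- expr_matrix(nx * nx, nx)
  d2fdpdx <- expr_matrix(nx * np, nx)
  for (l in seq_len(nx)) {
    for (i in seq_len(nx)) {
      for (j in seq_len(nx))
        d2fdxdx[[(j - 1) * nx + i, l]] <-
          deriv_expr(jac[[i, j]], model$state_names[l])
      for (k in seq_len(np))
        d2fdpdx[[(k - 1) * nx + i, l]] <-
          deriv_expr(dfdp[[i, k]], model$state_names[l])
    }
  }
  structure(list(jac = jac, dfdp = dfdp, dx0dp = dx0dp,
                 dhdx = dhdx, dhdp = dhdp, dsigmadp = dsig,
                 d2fdxdx = d2fdxdx, d2fdpdx = d2fdpdx,
                 cache = new.env(parent = emptyenv())),
            class = "deriv_set")
}

#' Evaluate derivative matrices at a point
#'
#' @param deriv a [derive()] result.
#' @param model the model it was derived from.
#' @param x,theta,u evaluation point (`theta` on linear scale).
#' @return numeric matrix.
#' @export
eval_jac <- function(deriv, model, x, theta, u = numeric(0)) {
  fn <- get_compiled(deriv$cache, "jac", function()
    compile_fun(model, deriv$jac, nrow(deriv$jac), ncol(deriv$jac)))
  fn(x, theta, pad_u(model, u))
}

#' @rdname eval_jac
#' @export
eval_dfdp <- function(deriv, model, x, theta, u = numeric(0)) {
  fn <- get_compiled(deriv$cache, "dfdp", function()
    compile_fun(model, deriv$dfdp, nrow(deriv$dfdp), ncol(deriv$dfdp)))
  fn(x, theta, pad_u(model, u))
}

#' @rdname eval_jac
#' @export
eval_dx0dp <- function(deriv, model, theta, u = numeric(0)) {
  fn <- get_compiled(deriv$cache, "dx0dp", function()
    compile_fun(model, deriv$dx0dp, nrow(deriv$dx0dp), ncol(deriv$dx0dp)))
  fn(rep(NA_real_, length(model$state_names)), theta, pad_u(model, u))
}

# second-derivative tensors, as (nx*nx) x nx and (nx*np) x nx matrices
eval_d2fdxdx <- function(deriv, model, x, theta, u = numeric(0)) {
  fn <- get_compiled(deriv$cache, "d2fdxdx", function()
    compile_fun(model, deriv$d2fdxdx, nrow(deriv$d2fdxdx),
                ncol(deriv$d2fdxdx)))
  fn(x, theta, pad_u(model, u))
}

eval_d2fdpdx <- function(deriv, model, x, theta, u = numeric(0)) {
  fn <- get_compiled(deriv$cache, "d2fdpdx", function()
    compile_fun(model, deriv$d2fdpdx, nrow(deriv$d2fdpdx),
                ncol(deriv$d2fdpdx)))
  fn(x, theta, pad_u(model, u))
}

#' @rdname eval_jac
#' @export
eval_dhdx <- function(deriv, model, x, theta, u = numeric(0)) {
  fn <- get_compiled(deriv$cache, "dhdx", function()
    compile_fun(model, deriv$dhdx, nrow(deriv$dhdx), ncol(deriv$dhdx)))
  fn(x, theta, pad_u(model, u))
}

#' @rdname eval_jac
#' @export
eval_dhdp <- function(deriv, model, x, theta, u = numeric(0)) {
  fn <- get_compiled(deriv$cache, "dhdp", function()
    compile_fun(model, deriv$dhdp, nrow(deriv$dhdp), ncol(deriv$dhdp)))
  fn(x, theta, pad_u(model, u))
}

#' @rdname eval_jac
#' @export
eval_dsigmadp <- function(deriv, model, theta,
                          x = rep(NA_real_, length(model$state_names)),
                          u = numeric(0)) {
  fn <- get_compiled(deriv$cache, "dsigmadp", function()
    compile_fun(model, deriv$dsigmadp, nrow(deriv$dsigmadp),
                ncol(deriv$dsigmadp)))
  fn(x, theta, pad_u(model, u))
}
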