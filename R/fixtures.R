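# Built-in fixture models with closed-form steady states, so every method
# pair is testable without external model downloads.  Fixtures are small
# (n_x <= 3) on purpose: what desk-scale problems can check is the
# correctness of the methods, not wall-clock performance at scale.

#' Built-in fixture problems
#'
#' Returns a named fixture with its model, generating parameters,
#' experimental conditions and closed-form steady state (and steady-state
#' sensitivities where available):
#'
#' * `decay2` — two-state linear chain `x1' = k1*u - k2*x1`,
#'   `x2' = k2*x1 - k3*x2`, post-equilibration; steady state
#'   `(k1 u/k2, k1 u/k3)`.
#' * `scalar_relax` — scalar relaxation `x' = a - k*x` with a
#'   parameter-valued noise standard deviation (exercises the
#'   noise-derivative terms of the gradient); steady state `a/k`.
#' * `reversible_pair` — reversible isomerization with a conserved total
#'   (singular Jacobian until reduced by [reduce_model()]).
#' * `cascade_preeq` — three-state linear cascade whose condition
#'   pre-equilibrates under a different input than the dynamic phase, so
#'   the initial state depends on the parameters through the
#'   pre-equilibration steady state.
#' * `no_steady_state` — constant growth `x' = k`, which never
#'   equilibrates (exercises the failure taxonomy).
#'
#' @param name fixture name.
#' @return a list of class `fixture` with `name`, `model`, `true_theta`,
#'   `conditions`, `times` (default measurement grid),
#'   `closed_form_steady_state(theta, u)`,
#'   `closed_form_sensitivities(theta, u)` (or `NULL`),
#'   `has_steady_state_data`.
#' @export
build_fixture <- function(name) {
  fixtures <- c("decay2", "scalar_relax", "reversible_pair",
                "cascade_preeq", "no_steady_state")
  if (!name %in% fixtures)
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtures, collapse = ", "))
  fx <- switch(name,
    decay2 = {
      model <- ode_model(
        states = list(x1 = 0, x2 = 0),
        parameters = data.frame(
          name = c("k1", "k2", "k3"),
          lower = 1e-3, upper = 1e3, scale = "log10"),
        rates = list(x1 = "k1 * u - k2 * x1", x2 = "k2 * x1 - k3 * x2"),
        observables = list(
          obs_x1 = list(formula = "x1", noise_formula = "0.1"),
          obs_x2 = list(formula = "x2", noise_formula = "0.1")),
        inputs = "u")
      list(model = model,
           true_theta = c(k1 = 1, k2 = 2, k3 = 4),
           conditions = list(condition("c1", c(u = 1))),
           times = c(0.1, 0.25, 0.5, 1, 2, 4),
           has_steady_state_data = TRUE,
           closed_form_steady_state = function(theta, u)
             c(theta[["k1"]] * u / theta[["k2"]],
               theta[["k1"]] * u / theta[["k3"]]),
           closed_form_sensitivities = function(theta, u)
             rbind(c(u / theta[["k2"]],
                     -theta[["k1"]] * u / theta[["k2"]]^2, 0),
                   c(u / theta[["k3"]], 0,
                     -theta[["k1"]] * u / theta[["k3"]]^2)))
    },
    scalar_relax = {
      model <- ode_model(
        states = list(x = 0),
        parameters = data.frame(
          name = c("a", "k", "s0"),
          lower = c(1e-2, 1e-2, 0.05), upper = c(1e2, 1e2, 5),
          scale = "log10"),
        rates = list(x = "a - k * x"),
        observables = list(
          obs_x = list(formula = "x", noise_formula = "s0")))
      list(model = model,
           true_theta = c(a = 1, k = 2, s0 = 0.5),
           conditions = list(condition("c1")),
           times = c(0.2, 0.5, 1, 2),
           has_steady_state_data = TRUE,
           closed_form_steady_state = function(theta, u)
             theta[["a"]] / theta[["k"]],
           closed_form_sensitivities = function(theta, u)
             matrix(c(1 / theta[["k"]],
                      -theta[["a"]] / theta[["k"]]^2, 0), 1, 3))
    },
    reversible_pair = {
      model <- ode_model(
        states = list(x1 = "a0", x2 = 0),
        parameters = data.frame(
          name = c("k1", "k2", "a0"),
          lower = c(1e-2, 1e-2, 0.1), upper = c(1e2, 1e2, 10),
          scale = "log10"),
        rates = list(x1 = "-k1 * x1 + k2 * x2", x2 = "k1 * x1 - k2 * x2"),
        observables = list(
          obs_x2 = list(formula = "x2", noise_formula = "0.1")))
      list(model = model,
           true_theta = c(k1 = 1, k2 = 2, a0 = 1),
           conditions = list(condition("c1")),
           times = c(0.25, 0.5, 1, 2),
           has_steady_state_data = TRUE,
           closed_form_steady_state = function(theta, u) {
             tot <- theta[["a0"]]
             c(theta[["k2"]] * tot, theta[["k1"]] * tot) /
               (theta[["k1"]] + theta[["k2"]])
           },
           closed_form_sensitivities = NULL)
    },
    cascade_preeq = {
      model <- ode_model(
        states = list(x1 = 0, x2 = 0, x3 = 0),
        parameters = data.frame(
          name = c("k1", "k2", "k3", "k4"),
          lower = 1e-2, upper = 1e2, scale = "log10"),
        rates = list(x1 = "k1 * u - k2 * x1",
                     x2 = "k2 * x1 - k3 * x2",
                     x3 = "k3 * x2 - k4 * x3"),
        observables = list(
          obs_x1 = list(formula = "x1", noise_formula = "0.1"),
          obs_x3 = list(formula = "x3", noise_formula = "0.1")),
        inputs = "u")
      list(model = model,
           true_theta = c(k1 = 1, k2 = 2, k3 = 1, k4 = 4),
           conditions = list(
             condition("c_pre", c(u = 1)),
             condition("c_main", c(u = 4), preeq_condition_id = "c_pre")),
           times = c(0.1, 0.5, 1, 2, 5),
           has_steady_state_data = TRUE,
           closed_form_steady_state = function(theta, u)
             theta[["k1"]] * u / c(theta[["k2"]], theta[["k3"]],
                                   theta[["k4"]]),
           closed_form_sensitivities = function(theta, u) {
             k1 <- theta[["k1"]]
             rates <- c(theta[["k2"]], theta[["k3"]], theta[["k4"]])
             S <- matrix(0, 3, 4)
             S[, 1] <- u / rates
             for (i in 1:3) S[i, i + 1] <- -k1 * u / rates[i]^2
             S
           })
    },
    no_steady_state = {
      model <- ode_model(
        states = list(x = 0),
        parameters = data.frame(name = "k", lower = 0.1, upper = 10,
                                scale = "log10"),
        rates = list(x = "k"),
        observables = list(
          obs_x = list(formula = "x", noise_formula = "0.1")))
      list(model = model,
           true_theta = c(k = 1),
           conditions = list(condition("c1")),
           times = c(0.5, 1, 2),
           has_steady_state_data = TRUE,
           closed_form_steady_state = NULL,
           closed_form_sensitivities = NULL)
    })
  fx$name <- name
  fx$deriv <- derive(fx$model)
  class(fx) <- "fixture"
  fx
}

#' Generate synthetic measurements from a fixture
#'
#' Simulates the fixture at the given parameters (integration-based steady
#' states) and emits a measurement table with i.i.d. additive Gaussian
#' noise; with `noise_sd = 0` the values are exact model outputs.
#' Steady-state rows use `time = Inf`.
#'
#' @param fixture a [build_fixture()] result.
#' @param theta named parameters (linear scale, defaults to the fixture's
#'   generating values).
#' @param times finite measurement times (defaults to the fixture's grid).
#' @param noise_sd standard deviation of the added noise (>= 0).
#' @param seed RNG seed.
#' @param include_steady_state_rows add `time = Inf` rows for every
#'   observable.
#' @param config an [eqsens_config()].
#' @return an [dataset()] whose measurements carry attributes `noise_sd`
#'   and `seed`.
#' @export
generate_synthetic_data <- function(fixture, theta = fixture$true_theta,
                                    times = fixture$times, noise_sd = 0.01,
                                    seed = 1L,
                                    include_steady_state_rows =
                                      fixture$has_steady_state_data,
                                    config = eqsens_config()) {
  stopifnot(noise_sd >= 0, !is.unsorted(times), all(is.finite(times)))
  model <- fixture$model
  deriv <- fixture$deriv
  pair <- method_pair("int_lin_fsa")
  obs <- names(model$observables)
  rows <- list()
  # conditions that only serve as pre-equilibration references get no rows
  target_ids <- vapply(fixture$conditions, function(cn) cn$condition_id,
                       character(1))
  preeq_only <- vapply(fixture$conditions, function(cn)
    cn$condition_id %in% vapply(fixture$conditions, function(o)
      o$preeq_condition_id, character(1)) &&
      is.na(cn$preeq_condition_id) && length(fixture$conditions) > 1,
    logical(1))
  skeleton <- do.call(rbind, lapply(target_ids[!preeq_only], function(id) {
    tt <- c(times, if (include_steady_state_rows) Inf)
    expand.grid(observableId = obs, simulationConditionId = id, time = tt,
                stringsAsFactors = FALSE)
  }))
  skeleton$measurement <- 0
  data0 <- dataset(model, fixture$conditions, skeleton)
  for (id in unique(skeleton$simulationConditionId)) {
    sim <- simulate_condition(model, deriv, theta, data0$conditions[[id]],
                              data0, pair, config)
    if (sim$status != "ok")
      signal_failure(sim$status,
                     paste0("synthetic-data simulation failed for ",
                            "condition '", id, "' in phase ", sim$phase),
                     sim$phase)
    sel <- skeleton$simulationConditionId == id
    for (r in which(sel)) {
      row <- skeleton[r, ]
      skeleton$measurement[r] <- if (is.infinite(row$time))
        sim$y_steady[[row$observableId]]
      else
        sim$dyn$outputs[match(row$time, sim$dyn$mtimes), row$observableId]
    }
  }
  set.seed(seed)
  skeleton$measurement <- skeleton$measurement +
    stats::rnorm(nrow(skeleton), 0, noise_sd)
  attr(skeleton, "noise_sd") <- noise_sd
  attr(skeleton, "seed") <- seed
  dataset(model, fixture$conditions, skeleton)
}

#' Export a fixture as model YAML + condition and measurement TSV
#'
#' @param fixture a [build_fixture()] result.
#' @param dir output directory (created if needed).
#' @param data optional [dataset()] (defaults to noise-free synthetic
#'   data).
#' @return named character vector of the written paths.
#' @export
export_fixture <- function(fixture, dir, data = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(data))
    data <- generate_synthetic_data(fixture, noise_sd = 0)
  paths <- c(model = file.path(dir, "model.yaml"),
             conditions = file.path(dir, "conditions.tsv"),
             measurements = file.path(dir, "measurements.tsv"))
  write_model_yaml(fixture$model, paths[["model"]])
  write_conditions(data$conditions, fixture$model, paths[["conditions"]])
  write_measurements(data$measurements, paths[["measurements"]])
  paths
}
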