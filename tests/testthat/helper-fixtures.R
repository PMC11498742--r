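# shared fixture/data builders, memoized so expensive simulations run once
.cache <- new.env(parent = emptyenv())

fx_get <- function(name) {
  key <- paste0("fx_", name)
  if (is.null(.cache[[key]])) .cache[[key]] <- build_fixture(name)
  .cache[[key]]
}

data_get <- function(name, noise_sd = 0.05, seed = 3L, ...) {
  key <- paste0("data_", name, "_", noise_sd, "_", seed)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- generate_synthetic_data(fx_get(name), noise_sd = noise_sd,
                                             seed = seed, ...)
  .cache[[key]]
}

# relative deviation with a magnitude floor
rel_dev <- function(a, b, floor = 1e-12) {
  abs(a - b) / pmax(abs(a), abs(b), floor)
}

# norm-wise relative deviation: sane for vectors with exact-zero entries
norm_dev <- function(a, b) {
  max(abs(a - b)) / max(abs(a), abs(b), 1e-300)
}

# reversible_pair after conserved-total removal, with the closed form of
# its surviving state and the parameters extended by the total
fx_reduced_reversible <- function() {
  if (is.null(.cache$red_rev)) {
    fx <- fx_get("reversible_pair")
    laws <- detect_conservation(fx$model, fx$deriv, seed = 2)
    red <- reduce_model(fx$model, laws)
    .cache$red_rev <- list(
      model = red, deriv = derive(red),
      true_theta = c(fx$true_theta, eval_totals(red, fx$true_theta)),
      closed_form_steady_state = function(theta, u)
        theta[["k1"]] * theta[["total_x1"]] /
          (theta[["k1"]] + theta[["k2"]]))
  }
  .cache$red_rev
}

# finite differences at their most accurate: tightened tolerances and a
# step balancing truncation against simulation noise
fd_oracle <- function(model, deriv, theta, data) {
  cfg <- eqsens_config(rtol = 1e-10, atol = 1e-12,
                       sim_rtol = 1e-12, sim_atol = 1e-14)
  finite_difference_gradient(model, deriv, theta, data, config = cfg,
                             step = 1e-4)
}

# a scalar relaxation problem with one steady-state measurement, used for
# the closed-form adjoint checks: x' = a - k*x, y = x, sigma = 1
scalar_posteq_problem <- function(ybar = 2, a = 1, k = 1) {
  model <- ode_model(
    states = list(x = 0),
    parameters = data.frame(name = c("a", "k"), lower = 1e-3, upper = 1e3,
                            scale = "lin"),
    rates = list(x = "a - k * x"),
    observables = list(obs_x = list(formula = "x", noise_formula = "1")))
  data <- dataset(model, list(condition("c1")),
                  data.frame(observableId = "obs_x",
                             simulationConditionId = "c1",
                             time = Inf, measurement = ybar))
  list(model = model, deriv = derive(model),
       theta = c(a = a, k = k), data = data)
}
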