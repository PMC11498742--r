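test_that("exactly six method pairs are admissible", {
  pairs <- all_method_pairs()
  expect_length(pairs, 6)
  expect_setequal(names(pairs),
                  c("int_int_fsa", "int_int_asa", "int_lin_fsa",
                    "int_lin_asa", "newton_lin_fsa", "newton_lin_asa"))
  expect_error(method_pair(steady_state_method = "newton",
                           sensitivity_method = "fsa_integration"),
               "not admissible")
  expect_error(method_pair(steady_state_method = "newton",
                           sensitivity_method = "asa_integration"),
               "not admissible")
  expect_error(method_pair("int_int_fda"), "unknown method pair")
})

test_that("simulate_condition runs the phases a condition requires", {
  fx <- fx_get("decay2")
  data <- data_get("decay2", noise_sd = 0)
  sim <- simulate_condition(fx$model, fx$deriv, fx$true_theta,
                            data$conditions[["c1"]], data,
                            method_pair("int_lin_fsa"))
  expect_identical(sim$status, "ok")
  expect_equal(sim$y_steady, c(obs_x1 = 0.5, obs_x2 = 0.25),
               tolerance = 1e-6)

  # pre-equilibration with u_e = u gives the same steady state as posteq
  cs <- fx_get("cascade_preeq")
  conds <- list(condition("c_pre", c(u = 1)),
                condition("c_same", c(u = 1), preeq_condition_id = "c_pre"))
  meas <- data.frame(observableId = "obs_x3", simulationConditionId = "c_same",
                     time = Inf, measurement = 0.25)
  dat <- dataset(cs$model, conds, meas)
  sim2 <- simulate_condition(cs$model, cs$deriv, cs$true_theta,
                             dat$conditions[["c_same"]], dat,
                             method_pair("int_lin_fsa"))
  expect_identical(sim2$status, "ok")
  expect_equal(sim2$x_preeq_star, sim2$x_star, tolerance = 1e-6)

  # drift fixture fails in the post-equilibration phase
  nss <- fx_get("no_steady_state")
  datn <- dataset(nss$model, nss$conditions,
                  data.frame(observableId = "obs_x",
                             simulationConditionId = "c1",
                             time = Inf, measurement = 1))
  sim3 <- simulate_condition(nss$model, nss$deriv, c(k = 1),
                             datn$conditions[["c1"]], datn,
                             method_pair("int_lin_fsa"))
  expect_identical(sim3$status, "no_steady_state")
  expect_identical(sim3$phase, "posteq")
})

test_that("negative log-likelihood matches hand arithmetic", {
  pb <- scalar_posteq_problem(ybar = 2, a = 1, k = 1)  # residual 1, sigma 1
  pair <- method_pair("int_lin_fsa")
  sim <- simulate_condition(pb$model, pb$deriv, pb$theta,
                            pb$data$conditions[["c1"]], pb$data, pair)
  nll <- negative_log_likelihood(list(c1 = sim), pb$data$measurements)
  expect_equal(nll, 0.5 * log(2 * pi) + 0.5, tolerance = 1e-8)

  # m zero-residual rows with sigma = 1 give (m/2) log(2 pi); doubling
  # sigma with zero residual adds log 2 per row
  m <- ode_model(
    list(x = 0),
    data.frame(name = c("a", "k", "s"), lower = c(0.01, 0.01, 0.01),
               upper = c(100, 100, 100), scale = "lin"),
    rates = list(x = "a - k * x"),
    observables = list(obs_x = list(formula = "x", noise_formula = "s")))
  d <- derive(m)
  rows <- data.frame(observableId = "obs_x", simulationConditionId = "c1",
                     time = c(0.5, 1, Inf), measurement = NA)
  dat <- dataset(m, list(condition("c1")), rows)
  th1 <- c(a = 1, k = 1, s = 1)
  sim1 <- simulate_condition(m, d, th1, dat$conditions[["c1"]], dat, pair)
  y <- c(sim1$dyn$outputs[, 1], sim1$y_steady[[1]])
  dat$measurements$measurement <- y                 # zero residuals
  expect_equal(negative_log_likelihood(list(c1 = sim1), dat$measurements),
               1.5 * log(2 * pi), tolerance = 1e-8)
  th2 <- c(a = 1, k = 1, s = 2)
  sim2 <- simulate_condition(m, d, th2, dat$conditions[["c1"]], dat, pair)
  expect_equal(negative_log_likelihood(list(c1 = sim2), dat$measurements),
               1.5 * log(2 * pi) + 3 * log(2), tolerance = 1e-8)
})

test_that("all six pairs give the closed-form gradient on the scalar problem", {
  pb <- scalar_posteq_problem(ybar = 2, a = 1, k = 1)
  # J = 1/2 (log 2 pi + (2 - a/k)^2), dJ/da = -(2 - a/k)/k = -1 at (1, 1)
  for (pair in all_method_pairs()) {
    g <- objective_gradient(pb$model, pb$deriv, pb$theta, pb$data, pair)
    expect_identical(g$status, "ok")
    expect_equal(g$gradient[["a"]], -1, tolerance = 1e-6)
    expect_equal(g$gradient[["k"]], 1, tolerance = 1e-6)  # dJ/dk = +1
    expect_equal(g$objective_value, 0.5 * log(2 * pi) + 0.5,
                 tolerance = 1e-8)
  }
  fd <- finite_difference_gradient(pb$model, pb$deriv, pb$theta, pb$data)
  expect_equal(unname(fd), c(-1, 1), tolerance = 1e-5)
})

test_that("zero-residual data give a zero gradient for every pair", {
  fx <- fx_get("decay2")
  data <- data_get("decay2", noise_sd = 0)
  for (pair in all_method_pairs()) {
    g <- objective_gradient(fx$model, fx$deriv, fx$true_theta, data, pair)
    expect_identical(g$status, "ok")
    expect_lt(max(abs(g$gradient)), 1e-5)
  }
  fd <- finite_difference_gradient(fx$model, fx$deriv, fx$true_theta, data)
  expect_lt(max(abs(fd)), 1e-5)
})

test_that("objective value is invariant across the six pairs", {
  fx <- fx_get("cascade_preeq")
  data <- data_get("cascade_preeq")
  th <- sample_parameters(fx$model, 1, seed = 71)[[1]]
  vals <- vapply(all_method_pairs(), function(p)
    objective_gradient(fx$model, fx$deriv, th, data, p)$objective_value,
    numeric(1))
  expect_lt(max(abs(vals - vals[1])) / max(abs(vals[1]), 1), 1e-8)
})

test_that("gradients are reported on the declared optimization scale", {
  fx <- fx_get("decay2")
  data <- data_get("decay2")
  th <- fx$true_theta * c(1.2, 0.9, 1.1)
  # same model but with linear parameter scales
  m_lin <- ode_model(
    states = list(x1 = 0, x2 = 0),
    parameters = data.frame(name = c("k1", "k2", "k3"), lower = 1e-3,
                            upper = 1e3, scale = "lin"),
    rates = list(x1 = "k1 * u - k2 * x1", x2 = "k2 * x1 - k3 * x2"),
    observables = list(
      obs_x1 = list(formula = "x1", noise_formula = "0.1"),
      obs_x2 = list(formula = "x2", noise_formula = "0.1")),
    inputs = "u")
  d_lin <- derive(m_lin)
  data_lin <- dataset(m_lin, data$conditions, data$measurements)
  pair <- method_pair("int_lin_asa")
  g_log <- objective_gradient(fx$model, fx$deriv, th, data, pair)$gradient
  g_lin <- objective_gradient(m_lin, d_lin, th, data_lin, pair)$gradient
  expect_equal(g_log, g_lin * th * log(10), tolerance = 1e-8)
})

test_that("failures propagate as structured categories, not exceptions", {
  nss <- fx_get("no_steady_state")
  dat <- dataset(nss$model, nss$conditions,
                 data.frame(observableId = "obs_x",
                            simulationConditionId = "c1",
                            time = Inf, measurement = 1))
  g <- objective_gradient(nss$model, nss$deriv, c(k = 1), dat,
                          method_pair("int_int_fsa"))
  expect_identical(g$status, "no_steady_state")
  expect_null(g$gradient)
  rv <- fx_get("reversible_pair")
  drv <- data_get("reversible_pair")
  g2 <- objective_gradient(rv$model, rv$deriv, rv$true_theta, drv,
                           method_pair("int_lin_fsa"))
  expect_identical(g2$status, "tailored_method_inapplicable")
})
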