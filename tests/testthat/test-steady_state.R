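test_that("wrms matches hand-computed values and flags non-finite input", {
  expect_equal(wrms(c(0, 0), c(3, -1), 1e-3, 1e-6), 0)
  expect_equal(wrms(c(0.2, 0.2), c(1, 1), 0.1, 0.1), 1.0)
  expect_equal(wrms(c(0.1, 0.3), c(1, 1), 0.1, 0.1), sqrt(1.25))
  expect_identical(wrms(c(NaN, 0), c(1, 1), 0.1, 0.1), Inf)
})

test_that("wrms is invariant under x -> cx, xdot -> c xdot, atol -> c atol", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(1:4, 1)
    x <- rnorm(n); xd <- rnorm(n); cc <- runif(1, 0.01, 100)
    expect_equal(wrms(cc * xd, cc * x, 1e-3, cc * 1e-5),
                 wrms(xd, x, 1e-3, 1e-5))
  }
})

test_that("integration equilibration reaches the analytic steady state", {
  fx <- fx_get("decay2")
  th <- fx$true_theta
  r <- equilibrate_by_integration(fx$model, fx$deriv, th, 1, c(0, 0))
  expect_identical(r$status, "converged")
  expect_lt(r$wrms_final, 1)
  expect_equal(r$x_star, c(0.5, 0.25), tolerance = 1e-6)

  # starting at the fixed point is a no-op
  r0 <- equilibrate_by_integration(fx$model, fx$deriv, th, 1, c(0.5, 0.25))
  expect_identical(r0$status, "converged")
  expect_identical(r0$iterations_or_steps, 0L)

  # pure drift never equilibrates
  nss <- fx_get("no_steady_state")
  rn <- equilibrate_by_integration(nss$model, nss$deriv, c(k = 1), numeric(0), 0)
  expect_identical(rn$status, "no_steady_state")
})

test_that("damped Newton solves the linear fixture in one exact step", {
  fx <- fx_get("decay2")
  th <- fx$true_theta
  r <- equilibrate_by_newton(fx$model, fx$deriv, th, 1, c(0, 0))
  expect_identical(r$status, "converged")
  expect_identical(r$iterations_or_steps, 1L)
  expect_equal(r$x_star, c(0.5, 0.25), tolerance = 1e-12)

  r0 <- equilibrate_by_newton(fx$model, fx$deriv, th, 1, c(0.5, 0.25))
  expect_identical(r0$iterations_or_steps, 0L)

  nss <- fx_get("no_steady_state")
  rn <- equilibrate_by_newton(nss$model, nss$deriv, c(k = 1), numeric(0), 0)
  expect_identical(rn$status, "numerical_error")   # zero Jacobian
})

test_that("both steady-state methods agree with closed forms and each other", {
  for (name in c("decay2", "scalar_relax", "cascade_preeq")) {
    fx <- fx_get(name)
    cfg <- eqsens_config()
    tol <- 100 * (cfg$rtol + cfg$atol)
    u <- rep(1, length(fx$model$input_names))
    for (th in sample_parameters(fx$model, 5, seed = 17)) {
      xs <- fx$closed_form_steady_state(th, 1)
      x0 <- eval_x0(fx$model, th, u)
      ri <- equilibrate_by_integration(fx$model, fx$deriv, th, u, x0, cfg)
      rn <- equilibrate_by_newton(fx$model, fx$deriv, th, u, x0, cfg)
      expect_identical(ri$status, "converged")
      expect_identical(rn$status, "converged")
      expect_lt(max(rel_dev(ri$x_star, xs)), tol)
      expect_lt(max(rel_dev(rn$x_star, xs)), tol)
      expect_lt(max(rel_dev(ri$x_star, rn$x_star)), tol)
    }
  }
})

test_that("convergence is monotone in the tolerances", {
  fx <- fx_get("decay2")
  for (th in sample_parameters(fx$model, 5, seed = 23)) {
    tight <- eqsens_config(rtol = 1e-8, atol = 1e-10)
    loose <- eqsens_config(rtol = 1e-6, atol = 1e-8)
    ri <- equilibrate_by_integration(fx$model, fx$deriv, th, 1, c(0, 0), tight)
    if (ri$status == "converged") {
      rl <- equilibrate_by_integration(fx$model, fx$deriv, th, 1, c(0, 0),
                                       loose)
      expect_identical(rl$status, "converged")
    }
  }
})

test_that("integration flags far-negative states as negative_state", {
  # x' = -k with x(0) = 1 runs through zero and keeps falling
  m <- ode_model(
    list(x = 1),
    data.frame(name = "k", lower = 0.1, upper = 10, scale = "log10"),
    list(x = "-k"),
    list(obs = list(formula = "x", noise_formula = "0.1")))
  r <- equilibrate_by_integration(m, derive(m), c(k = 1), numeric(0), 1)
  expect_identical(r$status, "negative_state")
  expect_true(any(r$x_star < -eqsens_config()$neg_tol))
})

test_that("Newton's gamma backoff gives up with newton_nonconverged", {
  # f(x) = k (1 - x^3): Newton from a point where full and damped steps
  # cannot reduce the residual within the damping budget
  m <- ode_model(
    list(x = 0),
    data.frame(name = "k", lower = 0.1, upper = 10, scale = "log10"),
    list(x = "k * (1 - x^3)"),
    list(obs = list(formula = "x", noise_formula = "0.1")))
  d <- derive(m)
  cfg <- eqsens_config(newton_max_iters = 3L, gamma_min = 0.5, gamma_init = 1)
  r <- equilibrate_by_newton(m, d, c(k = 1), numeric(0), -50, cfg)
  expect_true(r$status %in% c("newton_nonconverged", "numerical_error"))
  # with the full damping budget the same start converges
  r2 <- equilibrate_by_newton(m, d, c(k = 1), numeric(0), -50, eqsens_config())
  expect_identical(r2$status, "converged")
  expect_equal(r2$x_star, 1, tolerance = 1e-6)
})
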