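test_that("backward adjoint pass reproduces the closed-form decay example", {
  # x' = -x, x0 = th; one measurement (h = x, sigma = 1, residual 1) at
  # t1 = ln 2: the jump of 1 at t1 decays to p(t0) = 1/2, and the gradient
  # initial-condition term is -p(t0) dx0/dth = -1/2
  m <- ode_model(
    list(x = "th"),
    data.frame(name = "th", lower = 0.01, upper = 100, scale = "log10"),
    list(x = "-x"),
    list(obs = list(formula = "x", noise_formula = "1")))
  d <- derive(m)
  t1 <- log(2)
  tr <- integrate_with_fsa(m, d, c(th = 1), numeric(0), 1, matrix(0, 1, 1),
                           seq(0, t1, length.out = 50))
  traj <- list(times = tr$times, states = tr$states,
               derivs = matrix(-tr$states[, 1], ncol = 1))
  adj <- backward_adjoint(m, d, c(th = 1), numeric(0), traj,
                          list(list(time = t1, jump = 1)))
  expect_equal(adj$p_t0, 0.5, tolerance = 1e-7)
  # th enters only through x0, so the quadrature vanishes identically
  expect_equal(adj$quadrature, 0, tolerance = 1e-12)

  # zero residuals: homogeneous backward system with zero boundary
  adj0 <- backward_adjoint(m, d, c(th = 1), numeric(0), traj,
                           list(list(time = t1, jump = 0)))
  expect_equal(adj0$p_t0, 0)
  expect_equal(adj0$quadrature, 0)
})

test_that("tailored pre-equilibration solve matches the chain rule", {
  # x' = th - k x under u_e, k = 2: x* = th/2, (df/dx)^T p_int = -p_t0
  m <- ode_model(
    list(x = 0),
    data.frame(name = c("th", "k"), lower = 0.01, upper = 100,
               scale = "log10"),
    list(x = "th - k * x"),
    list(obs = list(formula = "x", noise_formula = "1")))
  d <- derive(m)
  th <- c(th = 1, k = 2)
  x_star <- 0.5
  ctb <- preeq_adjoint_contribution(d, m, th, numeric(0), x_star, p_t0 = 4)
  expect_equal(ctb$p_integral, 2)
  expect_equal(ctb$increment[1], -2)            # matches -p_t0 * dx*/dth
  expect_equal(ctb$increment[2], 2 * x_star)    # df/dk = -x*
  # linear-system invariant (df/dx)^T p_integral + p_boundary = 0
  J <- eval_jac(d, m, x_star, th)
  expect_lt(abs(t(J) %*% ctb$p_integral + ctb$p_boundary), 1e-10)

  expect_equal(preeq_adjoint_contribution(d, m, th, numeric(0), x_star,
                                          p_t0 = 0)$increment, c(0, 0))
})

test_that("tailored post-equilibration solve matches the quadratic objective", {
  pb <- scalar_posteq_problem(ybar = 2, a = 1, k = 1)
  # steady state x* = 1, residual 1, p_ss = 1 -> p_int = 1, dJ/da = -1
  ctb <- posteq_adjoint_contribution(pb$deriv, pb$model, pb$theta, numeric(0),
                                     x_star = 1, p_ss = 1)
  expect_equal(ctb$p_integral, 1)
  expect_equal(ctb$increment[1], -1)
  expect_equal(posteq_adjoint_contribution(pb$deriv, pb$model, pb$theta,
                                           numeric(0), 1, 0)$increment,
               c(0, 0))

  # rank-deficient Jacobian is refused
  rv <- fx_get("reversible_pair")
  expect_error(
    posteq_adjoint_contribution(rv$deriv, rv$model, rv$true_theta, numeric(0),
                                c(2 / 3, 1 / 3), c(1, 0)),
    class = "eqsens_tailored_inapplicable")
})

test_that("tailored posteq increment equals -residual * dx*/dtheta on decay2", {
  fx <- fx_get("decay2")
  for (th in sample_parameters(fx$model, 4, seed = 53)) {
    xs <- fx$closed_form_steady_state(th, 1)
    r <- 0.37                                    # arbitrary residual, sigma 1
    dhdx <- c(0, 1)                              # observable x2
    ctb <- posteq_adjoint_contribution(fx$deriv, fx$model, th, 1, xs,
                                       r * dhdx)
    S <- fx$closed_form_sensitivities(th, 1)
    expect_lt(norm_dev(ctb$increment, -r * S[2, ]), 1e-8)
  }
})

test_that("integrated posteq adjoint converges to the tailored solve", {
  pb <- scalar_posteq_problem(ybar = 2, a = 1, k = 1)
  cfg <- eqsens_config()
  eq <- equilibrate_by_integration(pb$model, pb$deriv, pb$theta, numeric(0),
                                   0, cfg, keep_trajectory = TRUE)
  ctb <- posteq_adjoint_by_integration(pb$model, pb$deriv, pb$theta,
                                       numeric(0), eq$trajectory, p_ss = 1,
                                       cfg)
  # closed form: -(1 - exp(-T)) -> -1 for a long window
  expect_equal(ctb$increment[1], -1, tolerance = 1e-4)
  expect_lt(max(abs(ctb$p_start)), 1e-6)         # adjoint has decayed
  ctb0 <- posteq_adjoint_by_integration(pb$model, pb$deriv, pb$theta,
                                        numeric(0), eq$trajectory, 0, cfg)
  expect_equal(ctb0$increment, c(0, 0))

  # decay2: tailored vs integrated over the WRMS-stopped window
  fx <- fx_get("decay2")
  for (th in sample_parameters(fx$model, 3, seed = 61)) {
    eqd <- equilibrate_by_integration(fx$model, fx$deriv, th, 1, c(0, 0),
                                      cfg, keep_trajectory = TRUE)
    p_ss <- c(0, 0.8)
    tai <- posteq_adjoint_contribution(fx$deriv, fx$model, th, 1,
                                       eqd$x_star, p_ss)
    int <- posteq_adjoint_by_integration(fx$model, fx$deriv, th, 1,
                                         eqd$trajectory, p_ss, cfg)
    expect_lt(norm_dev(tai$increment, int$increment), 1e-3)
  }
})

test_that("short equilibration windows follow the analytic partial integral", {
  # truncating the backward window at T gives -(1 - exp(-T)) for x' = a - x
  pb <- scalar_posteq_problem(ybar = 2, a = 1, k = 1)
  cfg <- eqsens_config()
  for (T in c(0.5, 1, 2)) {
    ts <- seq(0, T, length.out = 200)
    xs <- 1 - exp(-ts)
    traj <- list(times = ts, states = matrix(xs, ncol = 1),
                 derivs = matrix(1 - xs, ncol = 1))
    ctb <- posteq_adjoint_by_integration(pb$model, pb$deriv, pb$theta,
                                         numeric(0), traj, 1, cfg)
    expect_equal(ctb$increment[1], -(1 - exp(-T)), tolerance = 1e-6)
  }
})
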