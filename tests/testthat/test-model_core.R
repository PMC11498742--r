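test_that("parse_model reads the YAML dialect and closes the symbol table", {
  fx <- fx_get("decay2")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_yaml(fx$model, path)
  m <- parse_model(path)
  expect_s3_class(m, "ode_model")
  expect_length(m$state_names, 2)
  expect_length(m$parameter_names, 3)
  expect_identical(m$input_names, "u")
  expect_equal(eval_f(m, c(0, 0), fx$true_theta, 1),
               eval_f(fx$model, c(0, 0), fx$true_theta, 1))

  bad <- "
states:
  - {name: x1, init: 0}
parameters:
  - {name: k1, lower: 0.1, upper: 10, scale: log10}
rates:
  x1: k9 * x1
observables:
  - {name: obs, formula: x1, noise_formula: '0.1'}
"
  expect_error(parse_model(bad), "k9")

  empty_states <- "
states: []
parameters:
  - {name: k1, lower: 0.1, upper: 10, scale: log10}
rates: {}
observables:
  - {name: obs, formula: k1, noise_formula: '0.1'}
"
  expect_error(parse_model(empty_states), "states")
})

test_that("model validation rejects bad bounds, duplicates and bad noise", {
  pars <- data.frame(name = "k", lower = -1, upper = 1, scale = "log10")
  expect_error(
    ode_model(list(x = 0), pars, list(x = "-k * x"),
              list(obs = list(formula = "x", noise_formula = "0.1"))),
    "positive bounds")
  pars2 <- data.frame(name = "x", lower = 0.1, upper = 1, scale = "lin")
  expect_error(
    ode_model(list(x = 0), pars2, list(x = "-x * x"),
              list(obs = list(formula = "x", noise_formula = "0.1"))),
    "duplicated")
  pars3 <- data.frame(name = "s", lower = -2, upper = 2, scale = "lin")
  expect_error(
    ode_model(list(x = 0), pars3, list(x = "-x"),
              list(obs = list(formula = "x", noise_formula = "s"))),
    "noise")
})

test_that("derive produces the exact symbolic derivative matrices", {
  fx <- fx_get("decay2")
  th <- fx$true_theta   # (k1, k2, k3) = (1, 2, 4)
  J <- eval_jac(fx$deriv, fx$model, c(0.3, 0.1), th, 1)
  expect_equal(J, rbind(c(-2, 0), c(2, -4)))
  dfdp <- eval_dfdp(fx$deriv, fx$model, c(0.3, 0.1), th, 1)
  expect_equal(dfdp[, 1], c(1, 0))          # df/dk1 = (u, 0)

  # sigma given by a bare parameter: dsigma/dp is a unit vector on it
  sr <- fx_get("scalar_relax")
  ds <- eval_dsigmadp(sr$deriv, sr$model, sr$true_theta)
  expect_equal(as.numeric(ds), c(0, 0, 1))
})

test_that("derivative matrices match central finite differences", {
  for (name in c("decay2", "scalar_relax", "cascade_preeq",
                 "reversible_pair")) {
    fx <- fx_get(name)
    m <- fx$model; d <- fx$deriv
    set.seed(42)
    for (rep in 1:3) {
      x <- runif(length(m$state_names), 0.2, 2)
      th <- sample_parameters(m, 1, seed = rep * 11L)[[1]]
      u <- rep(1.3, length(m$input_names))
      h <- 1e-6
      for (j in seq_along(m$state_names)) {
        xp <- x; xp[j] <- xp[j] + h
        xm <- x; xm[j] <- xm[j] - h
        fd <- (eval_f(m, xp, th, u) - eval_f(m, xm, th, u)) / (2 * h)
        expect_equal(eval_jac(d, m, x, th, u)[, j], fd, tolerance = 1e-6)
      }
      for (k in seq_along(m$parameter_names)) {
        tp <- th; tp[k] <- tp[k] + h
        tm <- th; tm[k] <- tm[k] - h
        fd <- (eval_f(m, x, tp, u) - eval_f(m, x, tm, u)) / (2 * h)
        expect_equal(eval_dfdp(d, m, x, th, u)[, k], fd, tolerance = 1e-6)
        fd0 <- (eval_x0(m, tp, u) - eval_x0(m, tm, u)) / (2 * h)
        expect_equal(eval_dx0dp(d, m, th, u)[, k], fd0, tolerance = 1e-6)
      }
    }
  }
})

test_that("non-differentiable rate expressions give an advisory error", {
  pars <- data.frame(name = "k", lower = 0.1, upper = 10, scale = "log10")
  m <- ode_model(list(x = 1), pars, list(x = "-k * sign(x)"),
                 list(obs = list(formula = "x", noise_formula = "0.1")))
  expect_error(derive(m), "differentiable")
})

test_that("conservation detection finds the reversible pair's law", {
  fx <- fx_get("reversible_pair")
  laws <- detect_conservation(fx$model, fx$deriv, seed = 2)
  expect_length(laws, 1)
  expect_equal(laws[[1]]$coefficients, c(1, 1), tolerance = 1e-8)
  expect_equal(laws[[1]]$eliminated_state, 1L)  # tie -> lowest index

  expect_length(detect_conservation(fx_get("decay2")$model,
                                    fx_get("decay2")$deriv, seed = 2), 0)

  frozen <- ode_model(
    list(x = 1),
    data.frame(name = "k", lower = 0.1, upper = 10, scale = "log10"),
    list(x = "0 * k"),
    list(obs = list(formula = "x", noise_formula = "0.1")))
  laws0 <- detect_conservation(frozen, seed = 2)
  expect_length(laws0, 1)
  expect_equal(laws0[[1]]$coefficients, 1)

  # drift (x' = k) has a singular Jacobian but no conserved quantity
  nss <- fx_get("no_steady_state")
  expect_length(detect_conservation(nss$model, nss$deriv, seed = 2), 0)
})

test_that("reduce_model eliminates the law and yields the closed form", {
  fx <- fx_get("reversible_pair")
  th <- c(k1 = 1, k2 = 2, a0 = 1)
  laws <- list(list(coefficients = c(1, 1), total_name = "total",
                    eliminated_state = 2L))  # eliminate x2 explicitly
  red <- reduce_model(fx$model, laws)
  expect_identical(red$state_names, "x1")
  expect_true("total" %in% red$parameter_names)
  # x1' = -k1 x1 + k2 (T - x1); steady state x1* = k2 T / (k1 + k2)
  th_red <- c(th, total = unname(eval_totals(red, th)))
  dred <- derive(red)
  r <- equilibrate_by_newton(red, dred, th_red, numeric(0), 0.8)
  expect_equal(r$x_star, 2 * 1 / (1 + 2), tolerance = 1e-8)
  th_sym <- c(k1 = 2, k2 = 2, a0 = 1, total = 1)
  r2 <- equilibrate_by_newton(red, dred, th_sym, numeric(0), 0.8)
  expect_equal(r2$x_star, 0.5, tolerance = 1e-8)  # k1 = k2 -> T/2

  expect_identical(reduce_model(fx$model, list()), fx$model)
  bad <- list(list(coefficients = c(1, 0), total_name = "t2",
                   eliminated_state = 2L))
  expect_error(reduce_model(fx$model, bad), "zero coefficient")
})

test_that("reduction preserves dynamics and restores a full-rank Jacobian", {
  fx <- fx_get("reversible_pair")
  laws <- detect_conservation(fx$model, fx$deriv, seed = 2)
  red <- reduce_model(fx$model, laws)
  dred <- derive(red)
  th <- c(k1 = 0.7, k2 = 1.9, a0 = 2.5)
  th_red <- c(th, eval_totals(red, th))

  # retained state trajectory matches the full model
  times <- c(0.3, 0.8, 1.5, 3)
  cfg <- eqsens_config()
  full <- integrate_with_fsa(fx$model, fx$deriv, th, numeric(0),
                             eval_x0(fx$model, th),
                             eval_dx0dp(fx$deriv, fx$model, th), times, cfg)
  redu <- integrate_with_fsa(red, dred, th_red, numeric(0),
                             eval_x0(red, th_red),
                             eval_dx0dp(dred, red, th_red), times, cfg)
  expect_equal(redu$states[, 1], full$states[, 2], tolerance = 1e-7)

  # smallest singular value of the reduced Jacobian is bounded away from 0
  set.seed(99)
  for (i in 1:10) {
    x <- runif(1, 0.1, 2)
    thp <- sample_parameters(red, 1, seed = i)[[1]]
    sv <- svd(matrix(eval_jac(dred, red, x, thp), 1, 1))$d
    expect_gt(min(sv), 1e-8 * max(sv))
  }
})
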