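test_that("parameter sampling is log-uniform within bounds and seeded", {
  fx <- fx_get("decay2")                 # bounds [1e-3, 1e3], log10 scale
  ths <- sample_parameters(fx$model, 1000, seed = 4)
  vals <- vapply(ths, `[[`, numeric(1), "k1")
  expect_true(all(vals >= 1e-3 & vals <= 1e3))
  expect_equal(mean(vals < 1), 0.5, tolerance = 0.06)  # log-symmetry
  expect_identical(sample_parameters(fx$model, 10, seed = 4),
                   sample_parameters(fx$model, 10, seed = 4))
  expect_identical(sample_parameters(fx$model, 0, seed = 4), list())

  m_bad <- fx$model
  m_bad$lower[1] <- 0
  expect_error(sample_parameters(m_bad, 3, seed = 1), "positive")
})

test_that("classify_outcome aggregates condition-level failures", {
  ok <- structure(list(status = "ok"), class = "simulation_result")
  bad <- structure(list(status = "numerical_error"),
                   class = "simulation_result")
  expect_identical(classify_outcome(ok), "ok")
  expect_identical(classify_outcome(list(ok, ok)), "ok")
  expect_identical(classify_outcome(list(ok, bad, ok)), "numerical_error")
  neg <- structure(list(status = "negative_state"),
                   class = "simulation_result")
  expect_identical(classify_outcome(neg), "negative_state")
})

test_that("compare_gradients computes the agreement statistics", {
  g1 <- list(c(1, 2, 3), c(4, 5, 6))
  same <- compare_gradients(list(a = g1, b = g1))
  expect_equal(same$pearson_log10, 1)
  expect_equal(same$max_rel_dev, 0)
  expect_identical(same$sign_mismatches, 0L)

  g2 <- lapply(g1, function(v) 2 * v)
  doubled <- compare_gradients(list(a = g1, b = g2))
  expect_equal(doubled$pearson_log10, 1)       # log shift preserves corr
  expect_equal(doubled$max_rel_dev, 0.5)
  expect_equal(doubled$median_rel_dev, 0.5)

  single <- compare_gradients(list(a = list(c(1, 2), NULL),
                                   b = list(c(1, 2), NULL)))
  expect_false(single$defined)
  expect_true(is.na(single$max_rel_dev))

  flipped <- compare_gradients(list(a = list(c(1, -2), c(3, 4)),
                                    b = list(c(1, 2), c(3, 4))))
  expect_identical(flipped$sign_mismatches, 1L)
})

test_that("run_benchmark tabulates failures, agreement and timings", {
  fx <- fx_get("decay2")
  data <- data_get("decay2")
  rep <- run_benchmark(fx$model, fx$deriv, data,
                       pairs = all_method_pairs()[c("int_lin_fsa",
                                                    "int_lin_asa",
                                                    "newton_lin_asa")],
                       n = 3, seed = 9)
  expect_s3_class(rep, "benchmark_report")
  expect_equal(unname(rep$failure_rates), c(0, 0, 0))
  expect_true(all(rep$failures[, "ok"] == 3))
  expect_true(all(rep$agreement$pearson_log10 > 0.999))
  expect_true(all(rep$agreement$median_rel_dev < 1e-4))
  for (tt in rep$timings) {
    ok_rows <- !is.na(tt$total)
    expect_true(all(tt$total[ok_rows] >=
                      tt$equilibration[ok_rows] + tt$dynamic[ok_rows] - 1e-9))
  }

  # drift fixture: every integration pair fails with no_steady_state
  nss <- fx_get("no_steady_state")
  datn <- dataset(nss$model, nss$conditions,
                  data.frame(observableId = "obs_x",
                             simulationConditionId = "c1",
                             time = Inf, measurement = 1))
  repn <- run_benchmark(nss$model, nss$deriv, datn,
                        pairs = all_method_pairs()[c("int_int_fsa",
                                                     "int_lin_asa")],
                        n = 3, seed = 9)
  expect_equal(unname(repn$failure_rates), c(100, 100))
  expect_true(all(repn$failures[, "no_steady_state"] == 3))
})

test_that("tightening tolerances does not worsen pairwise agreement", {
  fx <- fx_get("decay2")
  data <- data_get("decay2")
  pairs <- all_method_pairs()[c("int_int_fsa", "int_lin_asa")]
  loose <- run_benchmark(fx$model, fx$deriv, data, pairs, n = 3, seed = 13,
                         config = eqsens_config(rtol = 1e-6, atol = 1e-8,
                                                sim_rtol = 1e-8))
  tight <- run_benchmark(fx$model, fx$deriv, data, pairs, n = 3, seed = 13,
                         config = eqsens_config(rtol = 1e-7, atol = 1e-9,
                                                sim_rtol = 1e-9))
  expect_lte(tight$agreement$median_rel_dev,
             loose$agreement$median_rel_dev * (1 + 1e-6))
})
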