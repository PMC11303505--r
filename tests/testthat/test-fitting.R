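test_that("the weighted objective evaluates the printed formula", {
  p <- c(X0 = 0.02, mu = 0.8, glc_0 = 20, q_glc = -8)
  tt <- c(0, 1, 2)
  sim <- simulate_model("exponential", p, tt)

  # perfect fit: objective exactly zero
  ds0 <- timecourse_dataset(sim, c(X = 0.02, glc = 0.2))
  expect_identical(weighted_sse(p, "exponential", ds0), 0)

  # a single off point: ((x - y)/sigma)^2 = ((2-1)/0.5)^2 = 4
  d1 <- sim
  d1$glc[2] <- sim$glc[2] + 1
  ds1 <- timecourse_dataset(d1, c(X = 1, glc = 0.5))
  expect_equal(weighted_sse(p, "exponential", ds1), 4)

  # doubling every sigma divides the objective by 4
  ds2 <- timecourse_dataset(d1, c(X = 2, glc = 1))
  expect_equal(weighted_sse(p, "exponential", ds2),
               weighted_sse(p, "exponential", ds1) / 4)

  # missing observations contribute nothing
  d2 <- d1
  d2$X[1] <- NA
  d2 <- rbind(d2, data.frame(time = 3, X = NA, glc = NA))
  ds3 <- timecourse_dataset(d2, c(X = 1, glc = 0.5))
  expect_equal(weighted_sse(p, "exponential", ds3), 4)
})

test_that("noiseless exponential data recovers the generating parameters within 1%", {
  truth <- builtin_truth("exponential")
  d <- simulate_model("exponential", truth, ref_times())
  fit <- quiet_fit(d, "exponential", sds = noise_sds_for("exponential"),
                   mc_iterations = 0, seed = 42)
  expect_lt(max_rel_err(fit$params, truth), 0.01)
  refit_traj <- fitted_trajectory(fit, ref_times())
  expect_equal(refit_traj$X, d$X, tolerance = 0.01)
  expect_equal(refit_traj$glc, d$glc, tolerance = 0.01)
  expect_equal(fit$objective_value, 0, tolerance = 1e-6)
})

test_that("fixing a flux at zero yields a flat metabolite fit at the fitted initial value", {
  set.seed(8)
  truth <- c(X0 = 0.02, mu = 0.6, glc_0 = 12, q_glc = 0)
  g <- generate_dataset(synthetic_spec("exponential", truth,
                                       noise_sds = c(X = 0.01, glc = 0.1), seed = 8))
  fit <- quiet_fit(g$data, "exponential", sds = c(X = 0.01, glc = 0.1),
                   parameters = list(q_glc = list(initial = 0, fixed = TRUE)),
                   mc_iterations = 0, seed = 8)
  traj <- fitted_trajectory(fit, ref_times())
  expect_equal(traj$glc, rep(fit$params[["glc_0"]], length(ref_times())))
  expect_false("q_glc" %in% colnames(fit$mc$samples))
  expect_identical(fit$n_params, 3L)
})

test_that("refinement dominates the global stage and is idempotent at convergence", {
  truth <- builtin_truth("exponential")
  sds <- noise_sds_for("exponential")
  g <- generate_dataset(synthetic_spec("exponential", truth, noise_sds = sds, seed = 31))
  fit <- quiet_fit(g$data, "exponential", sds = sds, mc_iterations = 0, seed = 31)
  expect_lte(fit$objective_value, fit$diagnostics$de$value)

  # restarting the whole two-stage fit from the returned optimum leaves the
  # objective essentially unchanged
  inits <- lapply(fit$params, function(v) list(initial = v))
  fit2 <- quiet_fit(g$data, "exponential", sds = sds, parameters = inits,
                    mc_iterations = 0, seed = 31)
  expect_lt(abs(fit2$objective_value - fit$objective_value),
            1e-9 * fit$objective_value)
})

test_that("identical data, configuration and seed give identical fits end to end", {
  truth <- builtin_truth("exponential")
  sds <- noise_sds_for("exponential")
  g <- generate_dataset(synthetic_spec("exponential", truth, noise_sds = sds, seed = 12))
  f1 <- quiet_fit(g$data, "exponential", sds = sds, mc_iterations = 25, seed = 99)
  f2 <- quiet_fit(g$data, "exponential", sds = sds, mc_iterations = 25, seed = 99)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$objective_value, f2$objective_value)
  expect_identical(f1$mc$ci, f2$mc$ci)
  expect_identical(f1$mc$samples, f2$mc$samples)
})

test_that("the noiseless bootstrap collapses onto the point estimate", {
  truth <- builtin_truth("exponential")
  d <- simulate_model("exponential", truth, ref_times())
  fit <- quiet_fit(d, "exponential", sds = c(X = 1e-12, glc = 1e-12),
                   mc_iterations = 0, seed = 3)
  fit <- mc_uncertainty(fit, n_iter = 10, seed = 3)
  width <- fit$mc$ci$ci_upper - fit$mc$ci$ci_lower
  expect_true(all(width <= 1e-6 * pmax(abs(fit$mc$ci$mean), 1)))
  expect_true(all(fit$mc$ci$ci_lower <= fit$mc$ci$mean + 1e-12))
  expect_true(all(fit$mc$ci$mean <= fit$mc$ci$ci_upper + 1e-12))
})

test_that("bootstrap summaries have coherent shape and respect missingness", {
  truth <- builtin_truth("exponential")
  sds <- noise_sds_for("exponential")
  g <- generate_dataset(synthetic_spec("exponential", truth, noise_sds = sds, seed = 21))
  d <- g$data
  d$glc[4] <- NA   # one missing metabolite observation
  fit <- quiet_fit(d, "exponential", sds = sds, mc_iterations = 30, seed = 21)
  expect_identical(fit$n_data, 23L)
  expect_identical(nrow(fit$mc$samples) + fit$mc$n_failed, 30L)
  expect_true(all(fit$mc$ci$ci_lower <= fit$mc$ci$ci_upper))
  td <- tidy(fit)
  expect_identical(td$parameter, c("X0", "mu", "glc_0", "q_glc"))
  expect_false(anyNA(td$mc_mean))
})

test_that("datasets and fits reject invalid configurations", {
  truth <- builtin_truth("exponential")
  d <- simulate_model("exponential", truth, ref_times())
  expect_error(timecourse_dataset(d, c(X = 0, glc = 0.1)), class = "exflux_input_error")
  expect_error(timecourse_dataset(d[, c("time", "glc")], c(glc = 0.1)),
               class = "exflux_schema_error")
  short <- d
  short$glc[-1] <- NA
  expect_error(timecourse_dataset(short, c(X = 0.1, glc = 0.1)),
               class = "exflux_validation_error")
  expect_error(
    quiet_fit(d, "exponential", sds = c(X = 0.1, glc = 0.1),
              parameters = list(nope = list(initial = 1)), mc_iterations = 0),
    class = "exflux_input_error")
  all_fixed <- lapply(truth, function(v) list(initial = v, fixed = TRUE))
  expect_error(
    quiet_fit(d, "exponential", sds = c(X = 0.1, glc = 0.1),
              parameters = all_fixed, mc_iterations = 0),
    class = "exflux_fit_error")
})
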