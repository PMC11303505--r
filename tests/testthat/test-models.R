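test_that("registry exposes the five built-in models and round-trips user models", {
  expect_setequal(list_models(),
                  c("exponential", "exponential_lag", "exponential_degradation",
                    "exponential_lag_degradation", "monod"))
  toy <- growth_model(
    name = "toy_constant", solution_kind = "analytical",
    biomass_params = data.frame(parameter = "X0", default = 1, lower = 0, upper = 10),
    simulate = function(params, times, metabolites)
      cbind(X = rep(params[["X0"]], length(times))),
    rhs = function(t, state, params, metabolites) 0,
    init_state = function(params, metabolites) c(X = params[["X0"]])
  )
  register_model(toy)
  expect_identical(get_model("toy_constant"), toy)
  expect_error(register_model(toy), class = "exflux_registry_error")
  err <- tryCatch(get_model("no_such_model"), error = identity)
  expect_s3_class(err, "exflux_registry_error")
  expect_match(conditionMessage(err), "exponential")  # lists available names
  rm("toy_constant", envir = exflux:::the_registry)
})

test_that("exponential closed form matches hand-computed values and identities", {
  p <- c(X0 = 0.02, mu = 0.8, glc_0 = 20, q_glc = -8)
  tr <- simulate_model("exponential", p, c(0, 2))
  expect_equal(tr$X[1], 0.02)           # initial condition, exactly
  expect_equal(tr$glc[1], 20)
  expect_equal(tr$X[2], 0.0990606484879023)      # X0 e^{mu t}
  expect_equal(tr$glc[2], 19.209393515120976)    # M0 + (q/mu) X0 (e^{mu t} - 1)

  # zero growth rate: biomass constant at X0
  flat <- simulate_model("exponential", c(X0 = 0.02, mu = 0, glc_0 = 5, q_glc = 0),
                         seq(0, 6, by = 1))
  expect_equal(flat$X, rep(0.02, 7))
  # zero flux: metabolite constant at M0
  expect_equal(flat$glc, rep(5, 7))
})

test_that("degradation closed form matches its printed value and independent ODE integration", {
  p <- c(X0 = 0.02, mu = 0.8, glc_0 = 20, q_glc = -8, k_glc = 0.05)
  tt <- c(0, 0.5, 1, 2)
  tr <- simulate_model("exponential_degradation", p, tt)
  expect_equal(tr$glc[4], 17.334735183051585)    # frozen closed-form value
  ode <- integrate_ode("exponential_degradation", p, tt)
  expect_equal(tr$glc, unname(ode[, "glc"]), tolerance = 1e-7)
  expect_equal(tr$X, unname(ode[, "X"]), tolerance = 1e-7)

  # pure abiotic decay when the flux is zero
  p0 <- c(X0 = 0.02, mu = 0.8, glc_0 = 20, q_glc = 0, k_glc = 0.3)
  tr0 <- simulate_model("exponential_degradation", p0, tt)
  expect_equal(tr0$glc, 20 * exp(-0.3 * tt))
})

test_that("lag and degradation variants collapse to their simpler counterparts in the limits", {
  tt <- seq(0, 8, length.out = 9)
  base <- c(X0 = 0.02, mu = 0.6, glc_0 = 20, q_glc = -4)
  ref <- simulate_model("exponential", base, tt)

  lag0 <- simulate_model("exponential_lag", c(base, t_lag = 0), tt)
  expect_equal(lag0$X, ref$X, tolerance = 1e-12)
  expect_equal(lag0$glc, ref$glc, tolerance = 1e-12)

  deg0 <- simulate_model("exponential_degradation", c(base, k_glc = 0), tt)
  expect_equal(deg0$X, ref$X, tolerance = 1e-12)
  expect_equal(deg0$glc, ref$glc, tolerance = 1e-12)

  ld00 <- simulate_model("exponential_lag_degradation", c(base, t_lag = 0, k_glc = 0), tt)
  expect_equal(ld00$glc, ref$glc, tolerance = 1e-12)

  # lag shift identity: X(t) with t_lag = 1 equals the plain model at t - 1
  lag <- simulate_model("exponential_lag", c(base, t_lag = 1), c(0.5, 3))
  expect_equal(lag$X[1], 0.02)    # pre-growth plateau
  expect_equal(lag$glc[1], 20)
  expect_equal(lag$X[2], unname(simulate_model("exponential", base, 2)$X))
})

test_that("lag+degradation trajectory is continuous at the lag time", {
  p <- c(X0 = 0.05, mu = 0.7, t_lag = 2.3, glc_0 = 15, q_glc = -3, k_glc = 0.2)
  eps <- 1e-9
  tr <- simulate_model("exponential_lag_degradation", p,
                       c(p[["t_lag"]] - eps, p[["t_lag"]], p[["t_lag"]] + eps))
  expect_lt(abs(tr$glc[2] - tr$glc[1]), 1e-8)
  expect_lt(abs(tr$glc[3] - tr$glc[2]), 1e-8)
  # during the lag only first-order decay acts on the metabolite
  expect_equal(tr$glc[2], 15 * exp(-0.2 * 2.3), tolerance = 1e-12)
})

test_that("analytical solutions agree with numerical integration of their own rate equations", {
  set.seed(412)
  for (m in setdiff(list_models(), "monod")) {
    mod <- get_model(m)
    pt <- model_parameters(mod, "glc")
    for (r in 1:5) {
      pars <- stats::setNames(runif(nrow(pt), pt$lower, pt$upper), pt$parameter)
      tt <- seq(0, 10, length.out = 10)
      cf <- simulate_model(mod, pars, tt)
      ode <- integrate_ode(mod, pars, tt)
      scale <- pmax(apply(abs(ode), 2, max), 1e-6)
      dev <- max(abs(as.matrix(cf[-1]) - ode) / rep(scale, each = nrow(ode)))
      expect_lt(dev, 1e-6)
    }
  }
})

test_that("Monod kinetics: exhaustion, saturation, and mass conservation", {
  expect_equal(monod_rates(1, 0, 0.8, 2, 0.5), c(dX = 0, dS = 0))
  # saturation: S >> Km approaches exponential growth at mu_max
  r <- monod_rates(1, 1e6, 0.8, 2, 0.5)
  expect_equal(unname(r["dX"]), 0.8, tolerance = 1e-5)

  p <- builtin_truth("monod")
  tt <- seq(0, 8, length.out = 25)
  tr <- simulate_model("monod", p, tt)
  conserved <- tr$X / p[["yield"]] + tr$glc
  expect_lt(diff(range(conserved)) / conserved[1], 1e-6)
  expect_true(all(diff(tr$X) >= 0))
  expect_true(all(tr$glc >= -1e-9))

  # Km -> 0 approaches the exponential closed form while substrate remains
  p0 <- p; p0[["Km"]] <- 1e-4
  tr0 <- simulate_model("monod", p0, seq(0, 3, length.out = 7))
  ref <- simulate_model("exponential",
                        c(X0 = p[["X0"]], mu = p[["mu_max"]], glc_0 = 0, q_glc = 0),
                        seq(0, 3, length.out = 7))
  expect_equal(tr0$X, ref$X, tolerance = 1e-3)
})

test_that("built-in biomass trajectories are non-negative and non-decreasing for mu >= 0", {
  set.seed(71)
  for (m in list_models()) {
    mod <- get_model(m)
    pt <- model_parameters(mod, "glc")
    for (r in 1:5) {
      pars <- stats::setNames(runif(nrow(pt), pt$lower, pt$upper), pt$parameter)
      tr <- simulate_model(mod, pars, seq(0, 10, length.out = 15))
      expect_true(all(tr$X >= 0))
      expect_true(all(diff(tr$X) >= -1e-9 * max(tr$X)))
    }
  }
})

test_that("simulation rejects malformed inputs", {
  p <- c(X0 = 0.02, mu = 0.8, glc_0 = 20, q_glc = -8)
  expect_error(simulate_model("exponential", p, c(2, 1)), class = "exflux_input_error")
  expect_error(simulate_model("exponential", p, numeric(0)), class = "exflux_input_error")
  expect_error(simulate_model("nope", p, 1), class = "exflux_registry_error")
  expect_error(simulate_model("exponential", c(X0 = 0.02), 1), class = "exflux_input_error")
  expect_error(simulate_model("exponential", c(p, mu = NA), 1), class = "exflux_input_error")
  # monod requires exactly one substrate column
  expect_error(model_parameters("monod", c("a", "b")), class = "exflux_input_error")
})

test_that("a template-conforming user model loads and fits end to end", {
  tmpl <- system.file("extdata", "model_template.R", package = "exflux")
  expect_true(nzchar(tmpl))
  mod <- load_model_file(tmpl, overwrite = TRUE)
  expect_s3_class(mod, "growth_model")
  expect_true("linear_growth" %in% list_models())

  truth <- c(X0 = 0.2, r = 0.5, glc_0 = 12, q_glc = -2)
  d <- simulate_model("linear_growth", truth, ref_times())
  fit <- quiet_fit(d, "linear_growth", sds = c(X = 0.05, glc = 0.1),
                   mc_iterations = 0, seed = 5)
  expect_lt(max_rel_err(fit$params, truth), 0.01)
  rm("linear_growth", envir = exflux:::the_registry)
})
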