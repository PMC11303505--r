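#' Construct a growth model
#'
#' A growth model bundles everything needed to simulate biomass and
#' extracellular metabolite concentrations over time and to fit the model to
#' data: the parameter set (names, defaults, bounds), a simulation rule
#' (a closed-form trajectory where one is known, otherwise numerical ODE
#' integration), and the model's rate equations \eqn{dX/dt = f(p, X, M)},
#' \eqn{dM_j/dt = g_j(p, X, M_j)}.
#'
#' Parameters split into two groups: *biomass parameters* shared by the whole
#' model (e.g. `X0`, `mu`, `t_lag`) and *metabolite parameters* instantiated
#' once per metabolite column in the dataset (e.g. `glc_0`, `q_glc`,
#' `k_glc` for a metabolite named `glc`). The `metabolite_params` argument is
#' a function that, given one metabolite name, returns that metabolite's
#' parameter rows.
#'
#' Even analytical models must supply `rhs` and `init_state`: the closed form
#' is required to agree with numerical integration of its own rate equations,
#' and the package's test-suite and model contract enforce this equivalence.
#'
#' @param name Unique model identifier.
#' @param solution_kind `"analytical"` (closed-form `simulate` used) or
#'   `"ode"` (trajectories obtained by numerical integration of `rhs`).
#' @param biomass_params Data frame with columns `parameter`, `default`,
#'   `lower`, `upper` describing metabolite-independent parameters.
#' @param metabolite_params `NULL`, or `function(metabolite)` returning a data
#'   frame in the same shape for one metabolite.
#' @param simulate For analytical models: `function(params, times,
#'   metabolites)` returning a numeric matrix with columns `X` and one per
#'   metabolite. Ignored for ODE models.
#' @param rhs Rate equations: `function(t, state, params, metabolites)`
#'   returning the state derivative (same order as `init_state`).
#' @param init_state `function(params, metabolites)` returning the named
#'   initial state at time 0, first element the biomass `X`.
#' @param n_metabolites Length-2 integer vector, the allowed range of
#'   metabolite counts (the Monod model requires exactly one substrate).
#' @param description One-line human-readable summary.
#' @return An object of class `growth_model`.
#' @seealso [register_model()], [simulate_model()], [model_parameters()]
#' @export
growth_model <- function(name, solution_kind = c("analytical", "ode"),
                         biomass_params, metabolite_params = NULL,
                         simulate = NULL, rhs = NULL, init_state = NULL,
                         n_metabolites = c(0, Inf), description = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  solution_kind <- match.arg(solution_kind)
  biomass_params <- check_param_table(biomass_params, name)
  if (!is.null(metabolite_params)) {
    stopifnot(is.function(metabolite_params))
    check_param_table(metabolite_params("m"), name)
  }
  if (solution_kind == "analytical" && !is.function(simulate)) {
    rlang::abort("analytical models must supply a `simulate` closed form",
                 class = "exflux_input_error")
  }
  if (!is.function(rhs) || !is.function(init_state)) {
    rlang::abort("every model must supply `rhs` and `init_state` so its rate equations can be integrated",
                 class = "exflux_input_error")
  }
  structure(
    list(name = name, solution_kind = solution_kind,
         biomass_params = biomass_params, metabolite_params = metabolite_params,
         simulate = simulate, rhs = rhs, init_state = init_state,
         n_metabolites = as.numeric(n_metabolites), description = description),
    class = "growth_model"
  )
}

check_param_table <- function(tab, model_name) {
  tab <- tibble::as_tibble(tab)
  needed <- c("parameter", "default", "lower", "upper")
  if (!all(needed %in% names(tab))) {
    rlang::abort(sprintf("parameter table for model '%s' needs columns %s",
                         model_name, paste(needed, collapse = ", ")),
                 class = "exflux_input_error")
  }
  if (anyDuplicated(tab$parameter)) {
    rlang::abort(sprintf("duplicate parameter names in model '%s'", model_name),
                 class = "exflux_input_error")
  }
  bad <- tab$lower > tab$default | tab$default > tab$upper
  if (any(bad)) {
    rlang::abort(sprintf("model '%s': defaults must satisfy lower <= default <= upper (violated for %s)",
                         model_name, paste(tab$parameter[bad], collapse = ", ")),
                 class = "exflux_input_error")
  }
  tab[needed]
}

#' @export
print.growth_model <- function(x, ...) {
  cat("<growth_model> ", x$name, " (", x$solution_kind, ")\n", sep = "")
  if (nzchar(x$description)) cat("  ", x$description, "\n", sep = "")
  cat("  biomass parameters: ", paste(x$biomass_params$parameter, collapse = ", "), "\n", sep = "")
  if (!is.null(x$metabolite_params)) {
    cat("  per-metabolite parameters: ",
        paste(x$metabolite_params("<met>")$parameter, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Parameter table of a model bound to a set of metabolites
#'
#' Expands a model's parameter specification for a concrete dataset: the
#' biomass parameters followed by each metabolite's parameters, in dataset
#' column order. The `default`, `lower` and `upper` columns seed the
#' optimizer unless overridden in the run configuration.
#'
#' @param model A `growth_model` or a registered model name.
#' @param metabolites Character vector of metabolite names (dataset columns).
#' @return A tibble with columns `parameter`, `default`, `lower`, `upper`.
#' @export
model_parameters <- function(model, metabolites = character()) {
  model <- as_growth_model(model)
  check_metabolite_count(model, metabolites)
  tabs <- list(model$biomass_params)
  if (!is.null(model$metabolite_params)) {
    tabs <- c(tabs, lapply(metabolites, model$metabolite_params))
  }
  dplyr::bind_rows(tabs)
}

check_metabolite_count <- function(model, metabolites) {
  n <- length(metabolites)
  if (n < model$n_metabolites[1] || n > model$n_metabolites[2]) {
    rlang::abort(sprintf("model '%s' supports between %s and %s metabolites, got %d",
                         model$name, model$n_metabolites[1], model$n_metabolites[2], n),
                 class = "exflux_input_error")
  }
  invisible(TRUE)
}

as_growth_model <- function(model) {
  if (inherits(model, "growth_model")) return(model)
  if (is.character(model) && length(model) == 1L) return(get_model(model))
  rlang::abort("`model` must be a growth_model or a registered model name",
               class = "exflux_input_error")
}

# ---- closed-form trajectory kernels ------------------------------------
# X0 anchored at t = 0 of the time axis, not at the first observation.
# mu = 0 and mu + k = 0 are removable singularities handled by their limits
# so direct simulation works; fitting keeps mu's lower bound strictly
# positive so the optimizer never sits on the singular manifold.

x_exponential <- function(times, X0, mu) X0 * exp(mu * times)

m_exponential <- function(times, X0, mu, M0, q) {
  if (mu == 0) return(M0 + q * X0 * times)
  M0 + (q / mu) * X0 * (exp(mu * times) - 1)
}

x_exponential_lag <- function(times, X0, mu, t_lag) {
  X0 * exp(mu * pmax(times - t_lag, 0))
}

# exchange frozen during the lag: M stays at M0 (degradation-free case)
m_exponential_lag <- function(times, X0, mu, t_lag, M0, q) {
  m_exponential(pmax(times - t_lag, 0), X0, mu, M0, q)
}

m_exponential_degradation <- function(times, X0, mu, M0, q, k) {
  if (mu + k == 0) return(M0 + q * X0 * times)  # only reachable at mu = k = 0
  M0 * exp(-k * times) + (q * X0 / (mu + k)) * (exp(mu * times) - exp(-k * times))
}

# during the lag only first-order decay acts on M; after t_lag the
# degradation solution restarts from M(t_lag) = M0 * exp(-k * t_lag),
# which collapses to a single expression continuous at t_lag
m_exponential_lag_degradation <- function(times, X0, mu, t_lag, M0, q, k) {
  s <- pmax(times - t_lag, 0)
  if (mu + k == 0) return(M0 + q * X0 * s)
  M0 * exp(-k * times) + (q * X0 / (mu + k)) * (exp(mu * s) - exp(-k * s))
}

#' Monod growth rates
#'
#' Right-hand side of the single-substrate Monod model:
#' \eqn{dX/dt = \mu_{max} S/(K_m + S) X} and
#' \eqn{dS/dt = -(1/\text{yield}) \, dX/dt}. When the substrate is exhausted
#' (`S <= 0`) both derivatives are zero. This is the conventional
#' single-substrate parameterization; the fitted parameters are
#' `mu_max` (1/h), `Km` (concentration) and the biomass yield
#' (biomass formed per unit substrate consumed).
#'
#' @param X Biomass concentration.
#' @param S Substrate concentration.
#' @param mu_max Maximum specific growth rate (1/h).
#' @param Km Half-saturation constant (same units as `S`).
#' @param yield Biomass yield on substrate (X units per S unit).
#' @return Named numeric vector `c(dX, dS)`.
#' @export
monod_rates <- function(X, S, mu_max, Km, yield) {
  S <- max(S, 0)
  growth <- mu_max * S / (Km + S) * X
  c(dX = growth, dS = -growth / yield)
}

# ---- built-in model definitions ----------------------------------------

bp <- function(...) {
  rows <- list(...)
  tibble::tibble(
    parameter = vapply(rows, `[[`, "", 1L),
    default = vapply(rows, function(r) as.numeric(r[[2]]), 0),
    lower = vapply(rows, function(r) as.numeric(r[[3]]), 0),
    upper = vapply(rows, function(r) as.numeric(r[[4]]), 0)
  )
}

met_par <- function(m, what) paste0(switch(what, init = "", flux = "q_", deg = "k_"),
                                    if (what == "init") paste0(m, "_0") else m)

mp_exchange <- function(with_degradation = FALSE) {
  function(m) {
    out <- bp(list(paste0(m, "_0"), 10, 0, 100),
              list(paste0("q_", m), -1, -50, 50))
    if (with_degradation) {
      out <- dplyr::bind_rows(out, bp(list(paste0("k_", m), 0.05, 0, 2)))
    }
    out
  }
}

sim_matrix <- function(times, X, metabolites, m_fun) {
  M <- matrix(0, length(times), length(metabolites),
              dimnames = list(NULL, metabolites))
  for (m in metabolites) M[, m] <- m_fun(m)
  cbind(X = X, M)
}

make_exponential_model <- function() {
  growth_model(
    name = "exponential", solution_kind = "analytical",
    biomass_params = bp(list("X0", 0.1, 1e-4, 10), list("mu", 0.5, 1e-6, 3)),
    metabolite_params = mp_exchange(FALSE),
    simulate = function(params, times, metabolites) {
      X0 <- params[["X0"]]; mu <- params[["mu"]]
      sim_matrix(times, x_exponential(times, X0, mu), metabolites, function(m) {
        m_exponential(times, X0, mu, params[[paste0(m, "_0")]], params[[paste0("q_", m)]])
      })
    },
    rhs = function(t, state, params, metabolites) {
      mu <- params[["mu"]]
      dX <- mu * state[["X"]]
      dM <- vapply(metabolites, function(m) params[[paste0("q_", m)]] * state[["X"]], 0)
      c(dX, dM)
    },
    init_state = function(params, metabolites) {
      c(X = params[["X0"]],
        stats::setNames(vapply(metabolites, function(m) params[[paste0(m, "_0")]], 0), metabolites))
    },
    description = "Steady-state exponential growth, constant per-biomass exchange fluxes"
  )
}

make_exponential_lag_model <- function() {
  growth_model(
    name = "exponential_lag", solution_kind = "analytical",
    biomass_params = bp(list("X0", 0.1, 1e-4, 10), list("mu", 0.5, 1e-6, 3),
                        list("t_lag", 1, 0, 10)),
    metabolite_params = mp_exchange(FALSE),
    simulate = function(params, times, metabolites) {
      X0 <- params[["X0"]]; mu <- params[["mu"]]; t_lag <- params[["t_lag"]]
      sim_matrix(times, x_exponential_lag(times, X0, mu, t_lag), metabolites, function(m) {
        m_exponential_lag(times, X0, mu, t_lag, params[[paste0(m, "_0")]], params[[paste0("q_", m)]])
      })
    },
    rhs = function(t, state, params, metabolites) {
      if (t < params[["t_lag"]]) return(rep(0, 1L + length(metabolites)))
      mu <- params[["mu"]]
      c(mu * state[["X"]],
        vapply(metabolites, function(m) params[[paste0("q_", m)]] * state[["X"]], 0))
    },
    init_state = function(params, metabolites) {
      c(X = params[["X0"]],
        stats::setNames(vapply(metabolites, function(m) params[[paste0(m, "_0")]], 0), metabolites))
    },
    description = "Exponential growth after a lag phase; exchange frozen during the lag"
  )
}

make_exponential_degradation_model <- function() {
  growth_model(
    name = "exponential_degradation", solution_kind = "analytical",
    biomass_params = bp(list("X0", 0.1, 1e-4, 10), list("mu", 0.5, 1e-6, 3)),
    metabolite_params = mp_exchange(TRUE),
    simulate = function(params, times, metabolites) {
      X0 <- params[["X0"]]; mu <- params[["mu"]]
      sim_matrix(times, x_exponential(times, X0, mu), metabolites, function(m) {
        m_exponential_degradation(times, X0, mu, params[[paste0(m, "_0")]],
                                  params[[paste0("q_", m)]], params[[paste0("k_", m)]])
      })
    },
    rhs = function(t, state, params, metabolites) {
      mu <- params[["mu"]]
      c(mu * state[["X"]],
        vapply(metabolites, function(m) {
          -params[[paste0("k_", m)]] * state[[m]] + params[[paste0("q_", m)]] * state[["X"]]
        }, 0))
    },
    init_state = function(params, metabolites) {
      c(X = params[["X0"]],
        stats::setNames(vapply(metabolites, function(m) params[[paste0(m, "_0")]], 0), metabolites))
    },
    description = "Exponential growth with first-order abiotic metabolite degradation"
  )
}

make_exponential_lag_degradation_model <- function() {
  growth_model(
    name = "exponential_lag_degradation", solution_kind = "analytical",
    biomass_params = bp(list("X0", 0.1, 1e-4, 10), list("mu", 0.5, 1e-6, 3),
                        list("t_lag", 1, 0, 10)),
    metabolite_params = mp_exchange(TRUE),
    simulate = function(params, times, metabolites) {
      X0 <- params[["X0"]]; mu <- params[["mu"]]; t_lag <- params[["t_lag"]]
      sim_matrix(times, x_exponential_lag(times, X0, mu, t_lag), metabolites, function(m) {
        m_exponential_lag_degradation(times, X0, mu, t_lag, params[[paste0(m, "_0")]],
                                      params[[paste0("q_", m)]], params[[paste0("k_", m)]])
      })
    },
    rhs = function(t, state, params, metabolites) {
      lag <- t < params[["t_lag"]]
      mu <- params[["mu"]]
      dX <- if (lag) 0 else mu * state[["X"]]
      dM <- vapply(metabolites, function(m) {
        d <- -params[[paste0("k_", m)]] * state[[m]]
        if (!lag) d <- d + params[[paste0("q_", m)]] * state[["X"]]
        d
      }, 0)
      c(dX, dM)
    },
    init_state = function(params, metabolites) {
      c(X = params[["X0"]],
        stats::setNames(vapply(metabolites, function(m) params[[paste0(m, "_0")]], 0), metabolites))
    },
    description = "Lag phase plus exponential growth with first-order metabolite degradation"
  )
}

make_monod_model <- function() {
  growth_model(
    name = "monod", solution_kind = "ode",
    biomass_params = bp(list("X0", 0.1, 1e-4, 10), list("mu_max", 0.5, 1e-6, 3),
                        list("Km", 1, 1e-4, 50), list("yield", 0.5, 1e-4, 10)),
    metabolite_params = function(m) bp(list(paste0(m, "_0"), 10, 0, 100)),
    rhs = function(t, state, params, metabolites) {
      r <- monod_rates(state[["X"]], state[[metabolites]],
                       params[["mu_max"]], params[["Km"]], params[["yield"]])
      unname(r)
    },
    init_state = function(params, metabolites) {
      c(X = params[["X0"]],
        stats::setNames(params[[paste0(metabolites, "_0")]], metabolites))
    },
    n_metabolites = c(1, 1),
    description = "Dynamic single-substrate Monod growth (substrate-limited kinetics)"
  )
}

# ---- registry -----------------------------------------------------------

the_registry <- new.env(parent = emptyenv())

#' Model registry
#'
#' `register_model()` adds a model under its name, `get_model()` retrieves
#' one, `list_models()` names all registered models. The five built-in
#' models (`exponential`, `exponential_lag`, `exponential_degradation`,
#' `exponential_lag_degradation`, `monod`) are registered when the package
#' is loaded; user models constructed with [growth_model()] or loaded from
#' a template file with [load_model_file()] join the same registry and are
#' fittable exactly like the built-ins.
#'
#' @param model A `growth_model`.
#' @param overwrite Allow replacing an existing entry of the same name.
#' @return `register_model()` returns the model invisibly; `get_model()` a
#'   `growth_model`; `list_models()` a sorted character vector.
#' @export
register_model <- function(model, overwrite = FALSE) {
  stopifnot(inherits(model, "growth_model"))
  if (!overwrite && exists(model$name, envir = the_registry, inherits = FALSE)) {
    rlang::abort(sprintf("a model named '%s' is already registered", model$name),
                 class = "exflux_registry_error")
  }
  assign(model$name, model, envir = the_registry)
  invisible(model)
}

#' @rdname register_model
#' @param name Registered model name.
#' @export
get_model <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !exists(name, envir = the_registry, inherits = FALSE)) {
    rlang::abort(sprintf("unknown model '%s'; available models: %s",
                         paste(name, collapse = ","),
                         paste(list_models(), collapse = ", ")),
                 class = "exflux_registry_error")
  }
  get(name, envir = the_registry, inherits = FALSE)
}

#' @rdname register_model
#' @export
list_models <- function() sort(ls(the_registry))

register_builtin_models <- function() {
  for (maker in list(make_exponential_model, make_exponential_lag_model,
                     make_exponential_degradation_model,
                     make_exponential_lag_degradation_model, make_monod_model)) {
    register_model(maker(), overwrite = TRUE)
  }
}

.onLoad <- function(libname, pkgname) {
  register_builtin_models()
}

#' Load a user model from a template file
#'
#' A user model is a single R source file defining a function
#' `create_model()` that returns a [growth_model()]. A commented template is
#' shipped at `system.file("extdata", "model_template.R", package =
#' "exflux")`. `load_model_file()` sources one file and registers the model;
#' `load_model_dir()` loads every `*.R` file in a directory.
#'
#' @param path Path to the model source file (or directory).
#' @param register Register the model after construction.
#' @param overwrite Passed to [register_model()].
#' @return The loaded `growth_model` (invisibly a list of them for
#'   `load_model_dir()`).
#' @export
load_model_file <- function(path, register = TRUE, overwrite = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("model file '%s' does not exist", path),
                 class = "exflux_input_error")
  }
  env <- new.env(parent = asNamespace("exflux"))
  sys.source(path, envir = env)
  if (!is.function(env$create_model)) {
    rlang::abort(sprintf("model file '%s' must define a function `create_model()` returning a growth_model",
                         path),
                 class = "exflux_input_error")
  }
  model <- env$create_model()
  if (!inherits(model, "growth_model")) {
    rlang::abort(sprintf("`create_model()` in '%s' did not return a growth_model", path),
                 class = "exflux_input_error")
  }
  if (register) register_model(model, overwrite = overwrite)
  invisible(model)
}

#' @rdname load_model_file
#' @export
load_model_dir <- function(path, overwrite = FALSE) {
  files <- list.files(path, pattern = "\\.[Rr]$", full.names = TRUE)
  invisible(lapply(files, load_model_file, register = TRUE, overwrite = overwrite))
}
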