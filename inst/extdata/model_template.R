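# Template for a user-defined growth model.
#
# A model file is a single R script defining `create_model()`, which must
# return an exflux::growth_model(). Load it with
#   exflux::load_model_file("my_model.R")
# or pass it to the CLI with --model-file; the model then behaves exactly
# like a built-in (simulation, fitting, Monte-Carlo, statistics).
#
# The example below implements linear (constant-rate) biomass growth with
# constant volumetric exchange rates: dX/dt = r, dMj/dt = qj * X. It has a
# closed form, so solution_kind = "analytical"; drop the `simulate` function
# and use solution_kind = "ode" if your model has no closed form — the rate
# equations in `rhs` are then integrated numerically.

create_model <- function() {
  exflux::growth_model(
    name = "linear_growth",
    solution_kind = "analytical",

    # metabolite-independent parameters: name, default, lower, upper
    biomass_params = data.frame(
      parameter = c("X0", "r"),
      default = c(0.1, 0.1),
      lower = c(1e-4, 0),
      upper = c(10, 5)
    ),

    # parameters instantiated once per metabolite column in the dataset
    metabolite_params = function(m) data.frame(
      parameter = c(paste0(m, "_0"), paste0("q_", m)),
      default = c(10, -1),
      lower = c(0, -50),
      upper = c(100, 50)
    ),

    # closed form: X(t) = X0 + r t; Mj(t) = Mj0 + qj (X0 t + r t^2 / 2)
    simulate = function(params, times, metabolites) {
      X <- params[["X0"]] + params[["r"]] * times
      M <- matrix(0, length(times), length(metabolites),
                  dimnames = list(NULL, metabolites))
      for (m in metabolites) {
        M[, m] <- params[[paste0(m, "_0")]] +
          params[[paste0("q_", m)]] *
            (params[["X0"]] * times + params[["r"]] * times^2 / 2)
      }
      cbind(X = X, M)
    },

    # rate equations; required even for analytical models (the closed form
    # must agree with their numerical integration)
    rhs = function(t, state, params, metabolites) {
      c(params[["r"]],
        vapply(metabolites,
               function(m) params[[paste0("q_", m)]] * state[["X"]], 0))
    },

    init_state = function(params, metabolites) {
      c(X = params[["X0"]],
        stats::setNames(
          vapply(metabolites, function(m) params[[paste0(m, "_0")]], 0),
          metabolites))
    },

    description = "Linear biomass growth with constant exchange fluxes (template example)"
  )
}
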