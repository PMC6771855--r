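#' Default run configuration
#'
#' Run-level knobs of the full pipeline, shipped as a YAML file
#' (`system.file("extdata", "default_config.yaml", package = "plgfcea")`).
#' Generator parameters that the configuration does not override come from
#' [default_generator_params()].
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(seed = 20160101,
       n_clusters = 11,
       n_steps = 12,
       n_iterations = 5000,
       test_cost = 70,
       test_cost_sweep = c(50, 100, 150, 200),
       wtp_max = 50000,
       wtp_step = 1000,
       weights_mode = "pooled",
       standardise = "conditional",
       sigma_c = 0.3,
       beta_t = 0.005,
       nAGQ = 7,
       adverse = list(events_usual = 24, n_usual = 447,
                      events_plgf = 22, n_plgf = 573))
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file path, or `NULL` for the packaged default.
#' @return named list as [default_config()].
#' @export
read_config <- function(path = NULL) {
  base <- default_config()
  if (is.null(path)) return(base)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  modifyList(base, user)
}

#' Run the full within-trial cost-effectiveness pipeline
#'
#' Chains the stages on synthetic data: stepped-wedge design, trial
#' simulation, per-category model selection and adjusted means, unit
#' costing, the probabilistic Monte Carlo model, and the delivery-cost
#' model.  Deterministic given `config$seed` (or the `seed` override).
#'
#' @param config list from [read_config()].
#' @param seed optional integer overriding `config$seed`.
#' @param unit_costs optional `unit_cost_table` (default
#'   [default_unit_costs()] at `config$test_cost`).
#' @param params optional `generator_params` overriding the defaults (e.g.
#'   smaller enrolment for quick runs).
#' @return list with `trial`, `fits`, `selected`, `adjusted_means`,
#'   `weights`, `psa` (a `psa_result`) and `delivery` (a
#'   `delivery_cost_fit`).
#' @export
run_pipeline <- function(config = default_config(), seed = NULL,
                         unit_costs = NULL, params = NULL) {
  seed <- seed %||% config$seed
  unit_costs <- unit_costs %||% default_unit_costs(config$test_cost)
  design <- build_design(config$n_clusters, config$n_steps, seed = seed)
  params <- params %||% default_generator_params(sigma_c = config$sigma_c,
                                                 beta_t = config$beta_t)
  params$adverse <- config$adverse
  trial <- simulate_trial(design, params, seed = seed)
  fitted <- fit_all_resources(trial, nAGQ = config$nAGQ,
                              standardise = config$standardise)
  weights <- cell_weights(trial, mode = config$weights_mode)
  psa <- run_psa(fitted$adjusted_means, unit_costs,
                 adverse = config$adverse,
                 weights = weights,
                 n_iterations = config$n_iterations,
                 seed = seed + 1L,
                 test_cost = config$test_cost,
                 test_cost_sweep = config$test_cost_sweep,
                 wtp_grid = seq(0, config$wtp_max, by = config$wtp_step))
  delivery <- fit_delivery_cost(trial, unit_costs)
  list(trial = trial, fits = fitted$fits, selected = fitted$selected,
       adjusted_means = fitted$adjusted_means, weights = weights,
       psa = psa, delivery = delivery, config = config, seed = seed)
}
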