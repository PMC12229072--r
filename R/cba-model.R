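#' Fit the cost-benefit / cost-effectiveness model
#'
#' Evaluates the five-year economic model of the AI surgical-safety
#' system over the configured scenario grid of near-miss-to-error
#' progression probabilities (conservative 0%, intermediate 50%,
#' high-risk 100% by default). The returned object supports the usual
#' model verbs: `print`, `summary` (the scenario grid), `coef` (the model
#' inputs), `predict` (evaluate at new `pi` values), `simulate` (the
#' Monte Carlo probabilistic sensitivity analysis) and `plot` (tornado
#' diagram of the one-way sensitivity analysis).
#'
#' @param config an [econ_config()]; defaults to the study's published
#'   cost inputs.
#' @return an object of class `cba_model`: the config, a list of
#'   `econ_result` per scenario, and the [one_way_sensitivity()] table at
#'   the intermediate scenario.
#' @examples
#' m <- cba_model(econ_config())
#' summary(m)
#' predict(m, pi = 0.25)
#' @export
cba_model <- function(config = econ_config()) {
  stopifnot(inherits(config, "econ_config"))
  scenarios <- lapply(config$scenario_pis, function(p) eval_scenario(config, p))
  names(scenarios) <- paste0("pi_", config$scenario_pis)
  structure(list(config = config,
                 scenarios = scenarios,
                 tornado = one_way_sensitivity(config, pi = 0.5)),
            class = "cba_model")
}

scenario_frame <- function(m) {
  do.call(rbind, lapply(m$scenarios, function(s) data.frame(
    pi = s$scenario_pi,
    errors_prevented_ai = s$errors_prevented_ai,
    errors_prevented_trad = s$errors_prevented_trad,
    incremental_effect = s$errors_prevented_ai - s$errors_prevented_trad,
    benefit = s$total_benefit,
    npv = s$npv,
    npv_absolute = s$npv_absolute,
    icer = s$icer,
    row.names = NULL)))
}

#' @export
print.cba_model <- function(x, ...) {
  cat(sprintf("Cost-benefit model: %d-year horizon, %.0f%% discount rate\n",
              x$config$horizon_years, 100 * x$config$discount_rate))
  cat(sprintf("PV costs: AI $%.2f vs traditional $%.2f\n",
              total_cost(x$config$cost_ai, x$config),
              total_cost(x$config$cost_traditional, x$config)))
  cat("\nScenario grid (near-miss progression probability pi):\n")
  sf <- scenario_frame(x)
  sf$benefit <- sprintf("%.2f", sf$benefit)
  sf$npv <- sprintf("%.2f", sf$npv)
  sf$npv_absolute <- sprintf("%.2f", sf$npv_absolute)
  sf$icer <- sprintf("%.2f", sf$icer)
  print(sf, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cba_model <- function(object, ...) {
  out <- list(scenarios = scenario_frame(object), tornado = object$tornado,
              config = object$config)
  class(out) <- "summary.cba_model"
  out
}

#' @export
print.summary.cba_model <- function(x, ...) {
  cat("Scenario grid:\n")
  print(x$scenarios, row.names = FALSE)
  cat("\n")
  print(x$tornado)
  invisible(x)
}

#' @export
coef.cba_model <- function(object, ...) {
  cf <- object$config
  c(cost_ai = total_cost(cf$cost_ai, cf),
    cost_traditional = total_cost(cf$cost_traditional, cf),
    cf$benefit_per_error,
    near_misses = cf$near_misses,
    direct_errors_preventable = cf$direct_errors_preventable,
    comparator_errors_prevented = cf$comparator_errors_prevented,
    discount_rate = cf$discount_rate,
    horizon_years = cf$horizon_years)
}

#' Evaluate the economic model at new progression probabilities
#'
#' @param object a [cba_model()].
#' @param pi vector of near-miss-to-error progression probabilities.
#' @param ... unused.
#' @return a data.frame with one row per `pi` (effects, benefit, NPVs,
#'   ICER).
#' @export
predict.cba_model <- function(object, pi = object$config$scenario_pis, ...) {
  check_prob(pi, "pi", len = length(pi))
  res <- lapply(pi, function(p) eval_scenario(object$config, p))
  names(res) <- paste0("pi_", pi)
  scenario_frame(list(scenarios = res))
}

#' Simulate the model: Monte Carlo probabilistic sensitivity analysis
#'
#' @param object a [cba_model()].
#' @param nsim number of Monte Carlo iterations.
#' @param seed RNG seed.
#' @param pi scenario at which to simulate (default 0.5).
#' @param ... unused.
#' @return a [monte_carlo_psa()] result.
#' @export
simulate.cba_model <- function(object, nsim = object$config$mc_iterations,
                               seed = object$config$mc_seed, pi = 0.5, ...) {
  monte_carlo_psa(object$config, pi = pi, iterations = nsim, seed = seed)
}

#' Tornado diagram of the one-way sensitivity analysis
#'
#' @param x a [cba_model()].
#' @param ... passed to [graphics::barplot()].
#' @return the tornado table, invisibly.
#' @export
plot.cba_model <- function(x, ...) {
  tn <- x$tornado
  tn <- tn[order(tn$range), ]  # widest on top
  lo <- pmin(tn$npv_low, tn$npv_high) - tn$npv_base
  hi <- pmax(tn$npv_low, tn$npv_high) - tn$npv_base
  old <- graphics::par(mar = c(5, 12, 4, 2))
  on.exit(graphics::par(old))
  graphics::barplot(rbind(lo, hi), beside = TRUE, horiz = TRUE,
                    names.arg = tn$parameter,
                    las = 1, col = c("grey40", "grey75"),
                    xlab = "Change in incremental NPV (USD)",
                    main = sprintf("One-way sensitivity (+/-%.0f%%)",
                                   100 * x$config$sensitivity_fraction), ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x$tornado)
}
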