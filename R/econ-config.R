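#' Configuration for the cost-benefit / cost-effectiveness model
#'
#' Holds every input of the five-year economic evaluation comparing the AI
#' authentication system against traditional safety measures. Cost inputs
#' may be given either as a single present-value total over the horizon
#' (the study's convention: US$461 426.49 for the AI system vs
#' US$125 872.46 for traditional measures, used as-is in the ICER) or as a
#' per-year schedule of length `horizon_years`, in which case years
#' 1..horizon are discounted at `discount_rate` with the end-of-year
#' convention (a schedule's first element is year 1).
#'
#' Effectiveness counts errors prevented over the study horizon:
#' the AI arm prevents `direct_errors_preventable` observed errors plus a
#' fraction `pi` of the `near_misses` it intercepted (the scenario grid
#' `scenario_pis` spans the conservative 0%, intermediate 50% and
#' high-risk 100% progression assumptions); the traditional arm prevents
#' `comparator_errors_prevented` (assumed 1).
#'
#' Per-error benefit components (additional treatment cost, legal
#' compensation, reputation-driven revenue loss) default to round
#' US-cost-scale placeholders; use [calibrate_benefit()] to pin them to an
#' external NPV figure.
#'
#' @param horizon_years evaluation horizon in years.
#' @param discount_rate annual discount rate (0.03 = 3%).
#' @param cost_ai,cost_traditional present-value total (length 1) or
#'   per-year schedule (length `horizon_years`), USD.
#' @param benefit_per_error named numeric: `treatment_cost`,
#'   `legal_compensation`, `reputation_revenue_loss` (USD per error).
#' @param near_misses near misses intercepted by the AI system.
#' @param direct_errors_preventable observed errors judged preventable by
#'   full authentication coverage (the non-authenticated errors).
#' @param comparator_errors_prevented errors prevented by traditional
#'   safety measures alone.
#' @param scenario_pis near-miss-to-error progression probabilities for
#'   the scenario grid.
#' @param sensitivity_fraction relative perturbation of the one-way
#'   sensitivity analysis (0.2 = +/-20%).
#' @param mc_iterations Monte Carlo iterations for the probabilistic
#'   sensitivity analysis.
#' @param mc_seed RNG seed for the PSA.
#' @param mc_cost_fraction half-width of the uniform cost distributions in
#'   the PSA, as a fraction of the point value.
#' @param mc_benefit_cv coefficient of variation of the gamma benefit
#'   distributions in the PSA (0 = degenerate).
#' @return an object of class `econ_config`.
#' @seealso [cba_model()], [npv()], [icer()], [monte_carlo_psa()]
#' @export
econ_config <- function(horizon_years = 5L,
                        discount_rate = 0.03,
                        cost_ai = 461426.49,
                        cost_traditional = 125872.46,
                        benefit_per_error = c(treatment_cost = 15000,
                                              legal_compensation = 80000,
                                              reputation_revenue_loss = 25000),
                        near_misses = 30L,
                        direct_errors_preventable = 4L,
                        comparator_errors_prevented = 1L,
                        scenario_pis = c(0, 0.5, 1),
                        sensitivity_fraction = 0.20,
                        mc_iterations = 10000L,
                        mc_seed = 1L,
                        mc_cost_fraction = 0.20,
                        mc_benefit_cv = 0.20) {
  horizon_years <- check_count(horizon_years, "horizon_years", positive = TRUE)
  check_nonneg(discount_rate, "discount_rate")
  for (nm in c("cost_ai", "cost_traditional")) {
    v <- get(nm)
    if (!is.numeric(v) || anyNA(v) || any(v < 0) ||
        !length(v) %in% c(1L, horizon_years))
      stop_arg(nm, sprintf(
        "must be a non-negative total or schedule of length %d", horizon_years))
  }
  comp <- c("treatment_cost", "legal_compensation", "reputation_revenue_loss")
  benefit_per_error <- benefit_per_error[comp]
  if (anyNA(benefit_per_error) || any(benefit_per_error < 0))
    stop_arg("benefit_per_error",
             paste("must be non-negative and named:",
                   paste(comp, collapse = ", ")))
  near_misses <- check_count(near_misses, "near_misses")
  direct_errors_preventable <- check_count(direct_errors_preventable,
                                           "direct_errors_preventable")
  comparator_errors_prevented <- check_count(comparator_errors_prevented,
                                             "comparator_errors_prevented")
  check_prob(scenario_pis, "scenario_pis", len = length(scenario_pis))
  if (!is.numeric(sensitivity_fraction) || sensitivity_fraction <= 0 ||
      sensitivity_fraction >= 1)
    stop_arg("sensitivity_fraction", "must be in (0, 1)")
  mc_iterations <- check_count(mc_iterations, "mc_iterations", positive = TRUE)
  mc_seed <- check_count(mc_seed, "mc_seed")
  check_nonneg(mc_cost_fraction, "mc_cost_fraction")
  check_nonneg(mc_benefit_cv, "mc_benefit_cv")

  structure(list(
    horizon_years = horizon_years, discount_rate = discount_rate,
    cost_ai = as.numeric(cost_ai),
    cost_traditional = as.numeric(cost_traditional),
    benefit_per_error = benefit_per_error,
    near_misses = near_misses,
    direct_errors_preventable = direct_errors_preventable,
    comparator_errors_prevented = comparator_errors_prevented,
    scenario_pis = as.numeric(scenario_pis),
    sensitivity_fraction = sensitivity_fraction,
    mc_iterations = mc_iterations, mc_seed = mc_seed,
    mc_cost_fraction = mc_cost_fraction, mc_benefit_cv = mc_benefit_cv
  ), class = "econ_config")
}

#' @export
print.econ_config <- function(x, ...) {
  cat("Economic evaluation configuration\n")
  cat(sprintf("  horizon: %d years, discount rate %.1f%%\n",
              x$horizon_years, 100 * x$discount_rate))
  cat(sprintf("  PV costs: AI $%s vs traditional $%s\n",
              format(total_cost(x$cost_ai, x), big.mark = " "),
              format(total_cost(x$cost_traditional, x), big.mark = " ")))
  cat(sprintf("  per-error benefit: $%s (treatment %s + legal %s + reputation %s)\n",
              format(sum(x$benefit_per_error), big.mark = " "),
              x$benefit_per_error[[1]], x$benefit_per_error[[2]],
              x$benefit_per_error[[3]]))
  cat(sprintf("  effects: %d direct + pi x %d near misses vs %d (traditional); scenarios pi = %s\n",
              x$direct_errors_preventable, x$near_misses,
              x$comparator_errors_prevented,
              paste(x$scenario_pis, collapse = ", ")))
  invisible(x)
}

#' Read an economic configuration from YAML or JSON
#'
#' Field names mirror [econ_config()] exactly; unknown fields are an
#' error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an `econ_config`.
#' @export
read_econ_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(vals), names(formals(econ_config)))
  if (length(unknown) > 0L)
    stop(sprintf("unknown field(s) in %s: %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (!is.null(vals$benefit_per_error))
    vals$benefit_per_error <- unlist(vals$benefit_per_error)
  do.call(econ_config, vals)
}
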