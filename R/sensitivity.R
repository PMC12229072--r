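#' One-way (tornado) sensitivity analysis of the NPV
#'
#' Recomputes the incremental NPV with each perturbable parameter set to
#' `(1 - fraction)` and `(1 + fraction)` times its point value, holding
#' every other parameter fixed. Perturbable parameters: the two cost
#' totals, the three per-error benefit components, the near-miss count
#' (the error-rate lever) and the directly preventable error count.
#' Results are ordered by range width (tornado order, widest bar first).
#'
#' @inheritParams effectiveness
#' @param fraction relative perturbation; defaults to the config's
#'   `sensitivity_fraction` (0.20 = +/-20%).
#' @return a data.frame of class `tornado`: columns `parameter`, `low`,
#'   `high` (parameter values), `npv_low`, `npv_high`, `npv_base`,
#'   `range`.
#' @export
one_way_sensitivity <- function(config, pi = 0.5,
                                fraction = config$sensitivity_fraction) {
  stopifnot(inherits(config, "econ_config"))
  check_prob(pi, "pi")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop_arg("fraction", "must be in (0, 1)")
  base <- eval_scenario(config, pi)$npv

  params <- c("cost_ai", "cost_traditional", "treatment_cost",
              "legal_compensation", "reputation_revenue_loss",
              "near_misses", "direct_errors_preventable")
  perturb <- function(cfg, name, mult) {
    if (name %in% names(cfg$benefit_per_error))
      cfg$benefit_per_error[name] <- cfg$benefit_per_error[name] * mult
    else cfg[[name]] <- cfg[[name]] * mult
    cfg
  }
  value_of <- function(cfg, name) {
    if (name %in% names(cfg$benefit_per_error))
      cfg$benefit_per_error[[name]] else sum(cfg[[name]])
  }
  rows <- lapply(params, function(p) {
    lo_cfg <- perturb(config, p, 1 - fraction)
    hi_cfg <- perturb(config, p, 1 + fraction)
    npv_lo <- eval_scenario(lo_cfg, pi)$npv
    npv_hi <- eval_scenario(hi_cfg, pi)$npv
    data.frame(parameter = p,
               low = value_of(config, p) * (1 - fraction),
               high = value_of(config, p) * (1 + fraction),
               npv_low = npv_lo, npv_high = npv_hi, npv_base = base,
               range = abs(npv_hi - npv_lo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$range), ]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' @export
print.tornado <- function(x, ...) {
  cat(sprintf("One-way sensitivity of incremental NPV (base $%.2f):\n",
              x$npv_base[1]))
  print.data.frame(
    data.frame(parameter = x$parameter,
               npv_low = sprintf("%.2f", pmin(x$npv_low, x$npv_high)),
               npv_high = sprintf("%.2f", pmax(x$npv_low, x$npv_high)),
               range = sprintf("%.2f", x$range)),
    row.names = FALSE)
  invisible(x)
}
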