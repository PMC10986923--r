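#' Accrue costs over a cohort trace
#'
#' Applies the pinned accrual rules to the expected event counts of a
#' cohort trace:
#' \itemize{
#'   \item trim cost: expected cow-trimmings x price per trim;
#'   \item block cost: expected ulcer-trims x expected block cost per
#'     ulcer trim (block price x block probability, folded into the
#'     single per-event price);
#'   \item labor: one sorting-labor charge per session — every cycle for
#'     the partial-herd strategy, session cycles only for whole-herd;
#'   \item reproduction: each cow-cycle accrues 1/6 of the annual AI cost
#'     conditional on its ulcer state at cycle start;
#'   \item production loss from sole ulcers: per ulcer cow-cycle, either
#'     the fractional additional-cow cost (supply-managed quota systems,
#'     the reference) or the direct milk-loss cost (`milk_loss` mode).
#' }
#' Components are reported undiscounted; the discounted total groups the
#' per-cycle outlays into model years (6 cycles) and applies
#' beginning-of-year discount weights `1/(1+r)^y`.
#'
#' @param trace A `cohort_trace` produced under `config`/`strategy`.
#' @param config The `su_config` used to produce the trace.
#' @param strategy `"partial"` or `"whole"` (drives the labor schedule).
#' @param production_cost_mode `"additional_cow"` (default) or
#'   `"milk_loss"`.
#' @param cost_overrides Optional named list of USD unit-cost overrides
#'   (names as in `config$costs`); used by the probabilistic analysis.
#' @return An object of class `cost_breakdown`: list with `trim_cost`,
#'   `block_cost`, `reproduction_cost`, `labor_cost`,
#'   `su_production_cost`, `total_undiscounted`, `total_discounted`, and
#'   `per_cycle` (matrix of per-cycle component outlays).
#' @export
accrue_costs <- function(trace, config, strategy,
                         production_cost_mode = c("additional_cow", "milk_loss"),
                         cost_overrides = NULL) {
  stopifnot(inherits(trace, "cohort_trace"))
  strategy <- match.arg(strategy, c("partial", "whole"))
  production_cost_mode <- match.arg(production_cost_mode)
  if (trace$n_cycles != config$n_cycles)
    stop("trace and config disagree on n_cycles", call. = FALSE)
  unit <- unit_costs(config, cost_overrides)
  occ <- trace$occupancies
  hs <- trace$herd_size
  cycles_per_year <- 12 / config$cycle_months

  trimmed <- occ$frac_trimmed_ulcer + occ$frac_trimmed_healthy
  trim_pc <- hs * trimmed * unit[["trim_cost"]]
  block_pc <- hs * occ$frac_trimmed_ulcer * unit[["block_cost"]]
  if (strategy == "partial") {
    labor_pc <- rep(unit[["labor_partial"]], trace$n_cycles)
  } else {
    session <- occ$cycle %% as.integer(config$whole_interval) == 0L
    labor_pc <- ifelse(session, unit[["labor_whole"]], 0)
  }
  repro_pc <- hs * (occ$s_start * unit[["ai_cost_ulcer"]] +
                      (1 - occ$s_start) * unit[["ai_cost_healthy"]]) /
    cycles_per_year
  su_unit <- if (production_cost_mode == "additional_cow")
    unit[["additional_cow"]] else unit[["milk_loss"]]
  su_pc <- hs * occ$s_start * su_unit

  per_cycle <- cbind(trim = trim_pc, block = block_pc,
                     reproduction = repro_pc, labor = labor_pc,
                     su_production = su_pc)
  totals <- colSums(per_cycle)
  total_pc <- rowSums(per_cycle)
  year <- floor(occ$cycle / cycles_per_year)
  year_sums <- tapply(total_pc, year, sum)
  total_disc <- discount_yearly(as.numeric(year_sums), config$discount_rate)

  out <- list(trim_cost = totals[["trim"]],
              block_cost = totals[["block"]],
              reproduction_cost = totals[["reproduction"]],
              labor_cost = totals[["labor"]],
              su_production_cost = totals[["su_production"]],
              total_undiscounted = sum(totals),
              total_discounted = total_disc,
              production_cost_mode = production_cost_mode,
              per_cycle = per_cycle)
  class(out) <- "cost_breakdown"
  out
}

# deterministic USD unit costs, with optional per-draw overrides
unit_costs <- function(config, cost_overrides = NULL) {
  unit <- vapply(config$costs, `[[`, 0, "usd")
  if (!is.null(cost_overrides)) {
    bad <- setdiff(names(cost_overrides), names(unit))
    if (length(bad)) stop("unknown cost override: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    unit[names(cost_overrides)] <- unlist(cost_overrides)
  }
  unit
}

#' Annual herd-level benefits
#'
#' Milk sales plus net cattle sales per cow-year, scaled by herd size.
#' Benefits are identical in both strategy arms (the herd produces and
#' sells regardless of the trimming schedule), so they cancel in the
#' net-benefit difference but anchor the net-benefit level.
#'
#' @param config An `su_config`.
#' @param cost_overrides Optional named USD overrides (as in
#'   [accrue_costs()]).
#' @return USD per year for the whole herd.
#' @export
annual_benefits <- function(config, cost_overrides = NULL) {
  unit <- unit_costs(config, cost_overrides)
  config$herd_size * (unit[["milk_sales"]] + unit[["cattle_sales"]])
}

#' Discount a yearly cash-flow sequence
#'
#' Beginning-of-year convention: year `y` (0-based) is weighted
#' `1/(1+rate)^y`.
#'
#' @param values_per_year Numeric vector of yearly amounts.
#' @param rate Annual discount rate, non-negative.
#' @return Present value (sum of discounted amounts).
#' @export
#' @examples
#' discount_yearly(rep(660510, 3), 0.015)
discount_yearly <- function(values_per_year, rate) {
  if (!is.finite(rate) || rate < 0)
    stop("discount rate must be non-negative", call. = FALSE)
  y <- seq_along(values_per_year) - 1
  sum(values_per_year / (1 + rate)^y)
}

#' Compare the two trimming strategies
#'
#' Runs the cohort model for both arms, accrues costs, computes
#' discounted benefits (identical across arms) and returns net benefits
#' and their difference (partial minus whole). A positive difference
#' means the targeted partial-herd strategy is the cost-effective one.
#'
#' @param config An `su_config`.
#' @param production_cost_mode `"additional_cow"` or `"milk_loss"`.
#' @param policy_partial Optional policy override for the partial arm
#'   (scenario analyses).
#' @param onset Optional per-cycle onset probability override.
#' @param cost_overrides Optional named USD unit-cost overrides.
#' @return An object of class `net_benefit`: list with
#'   `benefits_discounted`, `cost_partial`, `cost_whole`
#'   (`cost_breakdown`s), `net_benefit_partial`, `net_benefit_whole` and
#'   `difference`.
#' @export
#' @examples
#' nb <- compare_strategies(reference_parameters())
#' nb$difference > 0
compare_strategies <- function(config,
                               production_cost_mode = c("additional_cow", "milk_loss"),
                               policy_partial = NULL, onset = NULL,
                               cost_overrides = NULL) {
  production_cost_mode <- match.arg(production_cost_mode)
  tr_p <- run_cohort(config, "partial", policy = policy_partial, onset = onset)
  tr_w <- run_cohort(config, "whole", onset = onset)
  cost_p <- accrue_costs(tr_p, config, "partial", production_cost_mode,
                         cost_overrides)
  cost_w <- accrue_costs(tr_w, config, "whole", production_cost_mode,
                         cost_overrides)
  cycles_per_year <- 12 / config$cycle_months
  n_years <- config$n_cycles / cycles_per_year
  years <- unique(floor((seq_len(config$n_cycles) - 1) / cycles_per_year))
  annual <- annual_benefits(config, cost_overrides)
  # last (possibly partial) model year earns a prorated benefit
  per_year <- vapply(years, function(y) {
    cycles_in_y <- sum(floor((seq_len(config$n_cycles) - 1) /
                               cycles_per_year) == y)
    annual * cycles_in_y / cycles_per_year
  }, 0)
  benefits <- discount_yearly(per_year, config$discount_rate)
  nb_p <- benefits - cost_p$total_discounted
  nb_w <- benefits - cost_w$total_discounted
  out <- list(benefits_discounted = benefits,
              cost_partial = cost_p, cost_whole = cost_w,
              trace_partial = tr_p, trace_whole = tr_w,
              net_benefit_partial = nb_p, net_benefit_whole = nb_w,
              difference = nb_p - nb_w,
              production_cost_mode = production_cost_mode,
              n_years = n_years)
  class(out) <- "net_benefit"
  out
}

#' @export
print.net_benefit <- function(x, ...) {
  cat("Net-benefit comparison, partial-herd vs whole-herd hoof trimming\n")
  cat(sprintf("  discounted benefits (both arms): $%s\n",
              format(round(x$benefits_discounted), big.mark = ",")))
  cat(sprintf("  discounted costs: partial $%s, whole $%s\n",
              format(round(x$cost_partial$total_discounted), big.mark = ","),
              format(round(x$cost_whole$total_discounted), big.mark = ",")))
  cat(sprintf("  difference in net benefits (partial - whole): $%s\n",
              format(round(x$difference), big.mark = ",")))
  cat(sprintf("  preferred strategy: %s herd trimming\n",
              if (x$difference > 0) "partial" else "whole"))
  invisible(x)
}

#' @export
summary.net_benefit <- function(object, ...) {
  comp <- c("trim_cost", "block_cost", "reproduction_cost", "labor_cost",
            "su_production_cost", "total_undiscounted", "total_discounted")
  tab <- data.frame(
    component = comp,
    partial = vapply(comp, function(k) object$cost_partial[[k]], 0),
    whole = vapply(comp, function(k) object$cost_whole[[k]], 0),
    row.names = NULL)
  structure(list(costs = tab,
                 benefits_discounted = object$benefits_discounted,
                 difference = object$difference),
            class = "summary.net_benefit")
}

#' @export
print.summary.net_benefit <- function(x, ...) {
  tab <- x$costs
  tab$partial <- round(tab$partial)
  tab$whole <- round(tab$whole)
  print(tab, row.names = FALSE)
  cat(sprintf("benefits (discounted, both arms): %s\n",
              format(round(x$benefits_discounted), big.mark = ",")))
  cat(sprintf("difference in net benefits: %s\n",
              format(round(x$difference), big.mark = ",")))
  invisible(x)
}

#' Export a net-benefit result as JSON
#'
#' @param result A `net_benefit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_net_benefit_json <- function(result, path) {
  stopifnot(inherits(result, "net_benefit"))
  keep <- function(cb) cb[c("trim_cost", "block_cost", "reproduction_cost",
                            "labor_cost", "su_production_cost",
                            "total_undiscounted", "total_discounted")]
  obj <- list(benefits_discounted = result$benefits_discounted,
              cost_partial = keep(result$cost_partial),
              cost_whole = keep(result$cost_whole),
              net_benefit_partial = result$net_benefit_partial,
              net_benefit_whole = result$net_benefit_whole,
              difference = result$difference)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
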