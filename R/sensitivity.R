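#' One-way sensitivity bounds
#'
#' The published lower/upper limits used in the deterministic one-way
#' (tornado) analysis. Derived entries are recomputed from the varied
#' component: the expected block cost is block price x block
#' probability, so varying either recomputes the product; the AI bound
#' (+/- $38.50) shifts the with-ulcer and without-ulcer annual AI costs
#' together; the overall partial-herd trim probability rescales both
#' conditional selection probabilities proportionally. Labor for the two
#' strategies is listed on one published row but varied as two separate
#' (near-degenerate) parameters here.
#'
#' @return A data frame with columns `param_name`, `low`, `high`.
#' @export
sensitivity_bounds <- function() {
  data.frame(
    param_name = c("herd_size", "prevalence", "p_trim_overall",
                   "cure_trim", "cure_notrim", "incidence_risk",
                   "trim_cost", "block_price", "block_prob",
                   "labor_partial", "labor_whole",
                   "additional_cow", "ai_cost",
                   "milk_sales", "cattle_sales"),
    low  = c(50, 0.014, 0.10, 0.68, 0.10, 0.009,
             13.48, 26.95, 0.50, 13.29, 2.96, 75.37,
             132.48 - 38.50, 5802.82, 248.49),
    high = c(500, 0.28, 0.30, 0.97, 0.40, 0.315,
             16.56, 30.80, 0.95, 13.39, 2.97, 135.40,
             132.48 + 38.50, 6698.71, 333.54))
}

# set one sensitivity parameter in a config, recomputing derived inputs
apply_bound <- function(config, param_name, value) {
  cfg <- config
  set_cost <- function(cfg, nm, usd) {
    cfg$costs[[nm]]$usd <- usd
    cfg$costs[[nm]]$cad_mean <- usd / cfg$fx_rate
    cfg
  }
  if (param_name == "herd_size") {
    cfg$herd_size <- value
  } else if (param_name == "p_trim_overall") {
    scale <- value / config$probabilities$p_trim_overall$value
    cfg$probabilities$p_trim_overall$value <- value
    cfg$probabilities$p_trim_ulcer$value <-
      min(1, config$probabilities$p_trim_ulcer$value * scale)
    cfg$probabilities$p_trim_healthy$value <-
      min(1, config$probabilities$p_trim_healthy$value * scale)
  } else if (param_name == "block_price") {
    cfg$block_price_usd <- value
    cfg <- set_cost(cfg, "block_cost",
                    value * cfg$probabilities$block_prob$value)
  } else if (param_name == "block_prob") {
    cfg$probabilities$block_prob$value <- value
    cfg <- set_cost(cfg, "block_cost", cfg$block_price_usd * value)
  } else if (param_name == "ai_cost") {
    delta <- value - config$costs$ai_cost_healthy$usd
    cfg <- set_cost(cfg, "ai_cost_healthy", value)
    cfg <- set_cost(cfg, "ai_cost_ulcer",
                    config$costs$ai_cost_ulcer$usd + delta)
  } else if (param_name %in% names(cfg$probabilities)) {
    cfg$probabilities[[param_name]]$value <- value
  } else if (param_name %in% names(cfg$costs)) {
    cfg <- set_cost(cfg, param_name, value)
  } else {
    stop("unknown sensitivity parameter: ", param_name, call. = FALSE)
  }
  cfg
}

#' Deterministic one-way (tornado) sensitivity analysis
#'
#' Reruns the deterministic strategy comparison with each input set to
#' its lower and then its upper bound, all other inputs at their
#' reference values, and ranks inputs by the induced swing in the
#' difference in net benefits.
#'
#' @param config An `su_config`.
#' @param bounds Data frame as returned by [sensitivity_bounds()].
#' @return An object of class `su_tornado`: a data frame sorted by
#'   descending `range_width`, with columns `param_name`, `low_value`,
#'   `high_value`, `difference_at_low`, `difference_at_high`,
#'   `range_width`, plus attribute `base_difference` (the reference
#'   deterministic difference).
#' @export
one_way_sensitivity <- function(config, bounds = sensitivity_bounds()) {
  stopifnot(all(c("param_name", "low", "high") %in% names(bounds)))
  if (any(bounds$low > bounds$high))
    stop("each bound must satisfy low <= high", call. = FALSE)
  diff_at <- function(nm, v)
    compare_strategies(apply_bound(config, nm, v))$difference
  lo <- mapply(diff_at, bounds$param_name, bounds$low)
  hi <- mapply(diff_at, bounds$param_name, bounds$high)
  out <- data.frame(param_name = bounds$param_name,
                    low_value = bounds$low, high_value = bounds$high,
                    difference_at_low = lo, difference_at_high = hi,
                    range_width = abs(hi - lo), row.names = NULL)
  out <- out[order(-out$range_width), ]
  rownames(out) <- NULL
  attr(out, "base_difference") <- compare_strategies(config)$difference
  class(out) <- c("su_tornado", "data.frame")
  out
}

#' @export
print.su_tornado <- function(x, ...) {
  cat(sprintf("One-way sensitivity analysis (deterministic base difference $%s)\n",
              format(round(attr(x, "base_difference")), big.mark = ",")))
  df <- as.data.frame(x)
  df$difference_at_low <- round(df$difference_at_low)
  df$difference_at_high <- round(df$difference_at_high)
  df$range_width <- round(df$range_width)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tornado plot of a one-way sensitivity analysis
#'
#' Horizontal bars spanning the net-benefit difference at each input's
#' bounds, widest on top, centred around the deterministic base case.
#'
#' @param x An `su_tornado`.
#' @param n_bars Number of widest bars to show.
#' @param ... Passed to [graphics::barplot()] (unused).
#' @return `x`, invisibly.
#' @export
plot.su_tornado <- function(x, n_bars = 10, ...) {
  df <- utils::head(as.data.frame(x), n_bars)
  df <- df[nrow(df):1, ]
  lo <- pmin(df$difference_at_low, df$difference_at_high)
  hi <- pmax(df$difference_at_low, df$difference_at_high)
  base <- attr(x, "base_difference")
  graphics::plot(NULL, xlim = range(c(lo, hi, base)),
                 ylim = c(0.5, nrow(df) + 0.5), yaxt = "n",
                 xlab = "difference in net benefits (USD, partial - whole)",
                 ylab = "")
  graphics::rect(lo, seq_len(nrow(df)) - 0.35, hi,
                 seq_len(nrow(df)) + 0.35, col = "steelblue")
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(df)), labels = df$param_name,
                 las = 1, cex.axis = 0.7)
  invisible(x)
}

#' Solve the healthy-cow selection probability for a trim budget
#'
#' Given a targeting level (the probability that an ulcer cow is
#' selected at a partial-herd session), finds the selection probability
#' for healthy cows such that the deterministic cohort's expected total
#' cow-trimmings equals the budget. The prevalence trajectory is
#' recomputed at each trial value, since selection feeds back on
#' prevalence through cure.
#'
#' @param p_trim_ulcer Targeting probability in \[0, 1\].
#' @param trim_budget Total expected cow-trimmings over the horizon
#'   (reference design: 324).
#' @param config An `su_config`.
#' @return The healthy-cow selection probability; the implied expected
#'   trims match the budget to within 0.01 trims.
#' @export
solve_nonulcer_trim_probability <- function(p_trim_ulcer, trim_budget,
                                            config) {
  if (p_trim_ulcer < 0 || p_trim_ulcer > 1)
    stop("p_trim_ulcer must be in [0, 1]", call. = FALSE)
  trims_at <- function(ph) {
    cfg <- config
    cfg$probabilities$p_trim_ulcer$value <- p_trim_ulcer
    cfg$probabilities$p_trim_healthy$value <- ph
    run_cohort(cfg, "partial")$expected_trims_total
  }
  lo <- trims_at(0); hi <- trims_at(1)
  if (trim_budget < lo - 0.01 || trim_budget > hi + 0.01)
    stop(sprintf("trim budget %.1f infeasible (achievable range %.1f-%.1f)",
                 trim_budget, lo, hi), call. = FALSE)
  root <- stats::uniroot(function(ph) trims_at(ph) - trim_budget,
                         c(0, 1), tol = 1e-12)
  root$root
}

# wrap a scenario output
new_scenario <- function(id, description, outputs, seed = NA_integer_) {
  structure(list(scenario_id = id, description = description,
                 outputs = outputs, seed = seed), class = "su_scenario")
}

#' @export
print.su_scenario <- function(x, ...) {
  cat(sprintf("Scenario %s: %s\n", x$scenario_id, x$description))
  if (inherits(x$outputs, "su_psa")) print(x$outputs)
  else if (is.data.frame(x$outputs)) print(x$outputs, row.names = FALSE)
  else utils::str(x$outputs, max.level = 1)
  invisible(x)
}

#' Scenario: random selection for partial-herd trimming
#'
#' Sets both partial-herd selection probabilities (with and without an
#' ulcer) to the overall 18% trim probability — cows are picked at
#' random rather than by lameness — and reruns the probabilistic
#' analysis. The headline is reported from the whole-herd perspective
#' (whole minus partial), matching the direction in which the preference
#' flips.
#'
#' @param config An `su_config`.
#' @param n_iter PSA iterations.
#' @param seed Master seed.
#' @return An `su_scenario`; `outputs` holds the `su_psa` plus
#'   `mean_difference_whole_minus_partial`, its percentile CI, and
#'   `fraction_whole_preferred`.
#' @export
scenario_random_selection <- function(config, n_iter = config$psa_iterations,
                                      seed = config$seed) {
  psa <- run_psa(config, n_iter = n_iter, seed = seed,
                 selection = "random")
  wm <- -psa$differences
  out <- list(psa = psa,
              mean_difference_whole_minus_partial = mean(wm),
              ci_low = unname(stats::quantile(wm, 0.025)),
              ci_high = unname(stats::quantile(wm, 0.975)),
              fraction_whole_preferred = mean(wm > 0))
  new_scenario("random_selection",
               "partial-herd trim selection random at the overall 18%",
               out, seed)
}

#' Scenario: targeting sweep at a fixed trimming budget
#'
#' Compares partial-herd targeting levels (probability that an ulcer cow
#' is selected) while holding the total number of cow-trimmings fixed,
#' so strategies differ only in who gets trimmed, not how much trimming
#' is bought. For each level the healthy-cow probability is solved for
#' the budget, then the deterministic strategy comparison is run.
#'
#' @param config An `su_config`.
#' @param ulcer_trim_probs Targeting levels (default 0.18, 0.54, 1.00).
#' @param trim_budget Fixed expected cow-trimmings (default 324).
#' @return An `su_scenario`; `outputs` is a data frame with one row per
#'   level: `p_trim_ulcer`, `p_trim_healthy` (solved), `expected_trims`
#'   (achieved), `difference` (partial minus whole, USD).
#' @export
scenario_targeting_sweep <- function(config,
                                     ulcer_trim_probs = c(0.18, 0.54, 1.00),
                                     trim_budget = 324) {
  rows <- lapply(ulcer_trim_probs, function(pu) {
    ph <- solve_nonulcer_trim_probability(pu, trim_budget, config)
    cfg <- config
    cfg$probabilities$p_trim_ulcer$value <- pu
    cfg$probabilities$p_trim_healthy$value <- ph
    trims <- run_cohort(cfg, "partial")$expected_trims_total
    nb <- compare_strategies(cfg)
    data.frame(p_trim_ulcer = pu, p_trim_healthy = ph,
               expected_trims = trims, difference = nb$difference)
  })
  new_scenario("targeting_sweep",
               sprintf("targeting levels at a fixed budget of %g cow-trimmings",
                       trim_budget),
               do.call(rbind, rows))
}

#' Scenario: herd-size sweep
#'
#' Deterministic difference in net benefits across herd sizes, with the
#' least-squares line describing the (near-exact) linear relationship;
#' only the per-session labor charge does not scale with herd size.
#'
#' @param config An `su_config`.
#' @param sizes Herd sizes (default 50 to 500 by 50).
#' @return An `su_scenario`; `outputs` is a list with `table` (data
#'   frame `herd_size`, `difference`), `slope`, `intercept`,
#'   `r_squared`.
#' @export
scenario_herd_size_sweep <- function(config, sizes = seq(50, 500, by = 50)) {
  if (any(sizes < 1)) stop("herd sizes must be >= 1", call. = FALSE)
  diffs <- vapply(sizes, function(n) {
    cfg <- config
    cfg$herd_size <- n
    compare_strategies(cfg)$difference
  }, 0)
  tab <- data.frame(herd_size = sizes, difference = diffs)
  fit <- stats::lm(difference ~ herd_size, data = tab)
  out <- list(table = tab,
              slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r_squared = summary(fit)$r.squared)
  new_scenario("herd_size_sweep",
               "difference in net benefits across herd sizes", out)
}

#' Scenario: no supply management (milk-loss costing)
#'
#' Replaces the fractional additional-cow cost (quota systems) by the
#' direct milk-loss cost per ulcer cow-cycle and reruns the
#' probabilistic analysis, for comparison with dairy systems without
#' supply management.
#'
#' @param config An `su_config`.
#' @param n_iter PSA iterations.
#' @param seed Master seed.
#' @return An `su_scenario`; `outputs` holds the `su_psa` (milk-loss
#'   mode).
#' @export
scenario_no_quota <- function(config, n_iter = config$psa_iterations,
                              seed = config$seed) {
  psa <- run_psa(config, n_iter = n_iter, seed = seed,
                 production_cost_mode = "milk_loss")
  new_scenario("no_quota",
               "production loss costed as direct milk loss (no quota)",
               list(psa = psa,
                    mean_difference = psa$mean_difference,
                    ci_low = psa$ci_low, ci_high = psa$ci_high,
                    fraction_partial_preferred =
                      psa$fraction_partial_preferred),
               seed)
}
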