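#' Individual-based herd simulation (one replicate)
#'
#' Simulates every cow of the herd through the trimming horizon with the
#' identical event structure and order as the cohort model, but with
#' Bernoulli realisations instead of expectations: initial ulcer status
#' from the prevalence, then per two-month cycle trim selection by ulcer
#' status and policy, cure by trim status, and onset among healthy cows
#' (including those cured this cycle). Costs are tallied with the same
#' accrual rules as [accrue_costs()]. The cohort model computes exactly
#' the expectation of these tallies, which is what
#' [validate_against_cohort()] checks.
#'
#' @param config An `su_config`.
#' @param strategy `"partial"` or `"whole"`.
#' @param seed Integer seed; the same seed reproduces bit-identical
#'   tallies.
#' @param production_cost_mode `"additional_cow"` or `"milk_loss"`.
#' @return An object of class `su_microsim`: list with realised `trims`,
#'   `ulcer_trims`, `ulcer_cow_cycles` (counts), the five cost
#'   components, `total_undiscounted` and `total_discounted` (USD).
#' @export
simulate_herd <- function(config, strategy, seed,
                          production_cost_mode = c("additional_cow", "milk_loss")) {
  strategy <- match.arg(strategy, c("partial", "whole"))
  production_cost_mode <- match.arg(production_cost_mode)
  set.seed(as.integer(seed))
  h <- as.integer(config$herd_size)
  n <- as.integer(config$n_cycles)
  policy <- build_policy(strategy, config)
  onset <- onset_probability(config)
  cure_t <- config$probabilities$cure_trim$value
  cure_n <- config$probabilities$cure_notrim$value
  unit <- unit_costs(config)
  su_unit <- if (production_cost_mode == "additional_cow")
    unit[["additional_cow"]] else unit[["milk_loss"]]
  cycles_per_year <- 12 / config$cycle_months

  ulcer <- stats::runif(h) < config$probabilities$prevalence$value
  trims <- 0L; ulcer_trims <- 0L; ulcer_cycles <- 0L
  per_cycle <- matrix(0, n, 5,
                      dimnames = list(NULL, c("trim", "block", "reproduction",
                                              "labor", "su_production")))
  for (k in seq_len(n)) {
    n_ulcer <- sum(ulcer)
    ulcer_cycles <- ulcer_cycles + n_ulcer
    p_sel <- ifelse(ulcer, policy$p_trim_ulcer[k], policy$p_trim_healthy[k])
    trimmed <- stats::runif(h) < p_sel
    trims <- trims + sum(trimmed)
    ulcer_trims <- ulcer_trims + sum(trimmed & ulcer)

    per_cycle[k, "trim"] <- sum(trimmed) * unit[["trim_cost"]]
    per_cycle[k, "block"] <- sum(trimmed & ulcer) * unit[["block_cost"]]
    per_cycle[k, "reproduction"] <-
      (n_ulcer * unit[["ai_cost_ulcer"]] +
         (h - n_ulcer) * unit[["ai_cost_healthy"]]) / cycles_per_year
    per_cycle[k, "labor"] <- if (strategy == "partial")
      unit[["labor_partial"]]
    else if (policy$cycle[k] %% as.integer(config$whole_interval) == 0L)
      unit[["labor_whole"]] else 0
    per_cycle[k, "su_production"] <- n_ulcer * su_unit

    p_cure <- ifelse(trimmed, cure_t, cure_n)
    cured <- ulcer & (stats::runif(h) < p_cure)
    ulcer <- ulcer & !cured
    new_ulcer <- !ulcer & (stats::runif(h) < onset)
    ulcer <- ulcer | new_ulcer
  }
  totals <- colSums(per_cycle)
  year <- floor((seq_len(n) - 1) / cycles_per_year)
  year_sums <- tapply(rowSums(per_cycle), year, sum)
  out <- list(strategy = strategy, seed = as.integer(seed),
              trims = as.integer(trims),
              ulcer_trims = as.integer(ulcer_trims),
              ulcer_cow_cycles = as.integer(ulcer_cycles),
              trim_cost = totals[["trim"]], block_cost = totals[["block"]],
              reproduction_cost = totals[["reproduction"]],
              labor_cost = totals[["labor"]],
              su_production_cost = totals[["su_production"]],
              total_undiscounted = sum(totals),
              total_discounted = discount_yearly(as.numeric(year_sums),
                                                 config$discount_rate))
  class(out) <- "su_microsim"
  out
}

microsim_quantities <- c("trims", "ulcer_trims", "ulcer_cow_cycles",
                         "trim_cost", "block_cost", "reproduction_cost",
                         "labor_cost", "su_production_cost",
                         "total_discounted")

#' Replicate the herd microsimulation
#'
#' Runs [simulate_herd()] over independent replicates whose seeds are
#' derived deterministically from the master seed, and reports the mean
#' and Monte-Carlo standard error of every tallied quantity.
#'
#' @param config An `su_config`.
#' @param strategy `"partial"` or `"whole"`.
#' @param n_reps Number of replicates (>= 2).
#' @param seed Master seed.
#' @param production_cost_mode Passed to [simulate_herd()].
#' @return A list with `n_replicates`, `means`, `se` (named numeric
#'   vectors over the tallied quantities) and `replicates` (matrix,
#'   one row per replicate).
#' @export
replicate_mean <- function(config, strategy, n_reps, seed,
                           production_cost_mode = "additional_cow") {
  n_reps <- as.integer(n_reps)
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  reps <- matrix(NA_real_, n_reps, length(microsim_quantities),
                 dimnames = list(NULL, microsim_quantities))
  for (j in seq_len(n_reps)) {
    sim <- simulate_herd(config, strategy, rep_seeds[j],
                         production_cost_mode)
    reps[j, ] <- vapply(microsim_quantities, function(q) sim[[q]], 0)
  }
  list(n_replicates = n_reps,
       means = colMeans(reps),
       se = apply(reps, 2, stats::sd) / sqrt(n_reps),
       replicates = reps)
}

#' Validate the cohort model against the microsimulation
#'
#' The structural correctness check of the package: for each strategy
#' arm and each tallied quantity (trims, ulcer-trims, ulcer cow-cycles,
#' every cost component, the discounted total, and the between-arm
#' discounted cost difference), asserts that the microsimulation
#' replicate mean lies within `tolerance_se` Monte-Carlo standard errors
#' of the cohort model's expectation. Quantities with zero sampling
#' variance (e.g. whole-herd trims, labor) must match exactly.
#'
#' @param config An `su_config`.
#' @param n_reps Number of replicates (>= 100 recommended).
#' @param seed Master seed.
#' @param tolerance_se Allowed deviation in standard-error units
#'   (default 3).
#' @param production_cost_mode Passed through to the accrual.
#' @return An object of class `microsim_validation`: a data frame with
#'   columns `arm`, `quantity`, `cohort`, `microsim_mean`, `se`, `z`,
#'   `pass`, plus attribute `all_pass`.
#' @export
validate_against_cohort <- function(config, n_reps, seed, tolerance_se = 3,
                                    production_cost_mode = "additional_cow") {
  rows <- list()
  disc <- list()
  for (arm in c("partial", "whole")) {
    trace <- run_cohort(config, arm)
    costs <- accrue_costs(trace, config, arm, production_cost_mode)
    expected <- c(trims = trace$expected_trims_total,
                  ulcer_trims = trace$expected_ulcer_trims_total,
                  ulcer_cow_cycles = trace$expected_ulcer_cow_cycles,
                  trim_cost = costs$trim_cost, block_cost = costs$block_cost,
                  reproduction_cost = costs$reproduction_cost,
                  labor_cost = costs$labor_cost,
                  su_production_cost = costs$su_production_cost,
                  total_discounted = costs$total_discounted)
    ms <- replicate_mean(config, arm, n_reps, seed, production_cost_mode)
    disc[[arm]] <- list(mean = ms$means[["total_discounted"]],
                        se = ms$se[["total_discounted"]],
                        cohort = costs$total_discounted)
    for (q in microsim_quantities) {
      dev <- ms$means[[q]] - expected[[q]]
      se <- ms$se[[q]]
      z <- if (se > 0) dev / se else 0
      pass <- if (se > 0) abs(z) <= tolerance_se else abs(dev) < 1e-6
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, quantity = q, cohort = expected[[q]],
        microsim_mean = ms$means[[q]], se = se, z = z, pass = pass)
    }
  }
  # between-arm discounted cost difference (whole minus partial, the
  # quantity whose sign decides the preferred strategy)
  dev <- (disc$whole$mean - disc$partial$mean) -
    (disc$whole$cohort - disc$partial$cohort)
  se <- sqrt(disc$whole$se^2 + disc$partial$se^2)
  rows[[length(rows) + 1L]] <- data.frame(
    arm = "both", quantity = "discounted_cost_difference",
    cohort = disc$whole$cohort - disc$partial$cohort,
    microsim_mean = disc$whole$mean - disc$partial$mean,
    se = se, z = dev / se, pass = abs(dev / se) <= tolerance_se)
  report <- do.call(rbind, rows)
  attr(report, "all_pass") <- all(report$pass)
  class(report) <- c("microsim_validation", "data.frame")
  report
}

#' @export
print.microsim_validation <- function(x, ...) {
  cat("Microsimulation vs cohort-expectation validation\n")
  df <- as.data.frame(x)
  df$cohort <- signif(df$cohort, 6)
  df$microsim_mean <- signif(df$microsim_mean, 6)
  df$se <- signif(df$se, 3)
  df$z <- round(df$z, 2)
  print(df, row.names = FALSE)
  cat(if (attr(x, "all_pass")) "All quantities within tolerance.\n"
      else "SOME QUANTITIES OUT OF TOLERANCE.\n")
  invisible(x)
}
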