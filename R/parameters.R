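#' Reference model configuration
#'
#' Builds the complete input set of the reference case: the structural
#' constants (100-cow herd, 18 two-month cycles, 1.5% annual discounting,
#' CAD->USD conversion at 0.77), every probability with its Beta
#' uncertainty distribution, and every price/benefit with its Normal
#' (CAD mean, sd 0.1) uncertainty distribution.
#'
#' Probabilities are parameterised as Beta(alpha, beta) with alpha the
#' number of events and beta the number of non-events. Money is held
#' internally in 2019 USD; the CAD sampling means are converted at the
#' fixed exchange rate when drawn. Two CAD means are corrected for
#' typographical errors (block 26.30, AI-with-ulcer 286.75) so that
#' usd = cad * 0.77 holds for every row; see the package vignette.
#'
#' The annual sole-ulcer incidence risk is carried with the deterministic
#' value 7.8% and the uncertainty distribution Beta(465, 1624.7) exactly
#' as published, although the distribution's mean (0.2225) differs from
#' the deterministic value; deterministic analyses use 7.8% and the
#' probabilistic analysis samples the Beta. The two-month onset
#' probability is always recomputed from the (deterministic or sampled)
#' incidence risk via [rate_from_risk()] and
#' [cycle_probability_from_rate()].
#'
#' @return An object of class `su_config`: a list with elements
#'   `herd_size`, `n_cycles`, `cycle_months`, `discount_rate`, `fx_rate`,
#'   `whole_interval` (whole-herd session interval in cycles),
#'   `psa_iterations`, `seed`, `probabilities` (named list; each element
#'   has `value`, and `alpha`/`beta` when a Beta distribution is defined)
#'   and `costs` (named list; each element has `usd`, `cad_mean`,
#'   `cad_sd`).
#' @seealso [load_config()], [compare_strategies()], [run_psa()]
#' @export
#' @examples
#' cfg <- reference_parameters()
#' cfg$probabilities$prevalence$value   # 0.064
#' cfg$costs$trim_cost$usd              # 15.02
reference_parameters <- function() {
  prob <- function(value, alpha = NA_real_, beta = NA_real_) {
    list(value = value, alpha = alpha, beta = beta)
  }
  money <- function(usd, cad_mean, cad_sd = 0.1) {
    list(usd = usd, cad_mean = cad_mean, cad_sd = cad_sd)
  }
  cfg <- list(
    herd_size      = 100,
    n_cycles       = 18L,
    cycle_months   = 2,
    discount_rate  = 0.015,
    fx_rate        = 0.77,
    whole_interval = 3L,
    psa_iterations = 2000L,
    seed           = 1L,
    probabilities = list(
      # starting prevalence of sole ulcer among cows presented to a trimmer
      prevalence     = prob(0.064, 1830, 26777),
      # overall fraction of the herd trimmed at a partial-herd session
      p_trim_overall = prob(0.18, 43.74, 199.26),
      # trim selection conditional on ulcer status (lameness-targeted)
      p_trim_ulcer   = prob(0.54, 853.7, 727.3),
      p_trim_healthy = prob(0.1699, 16.99, 83.01),
      cure_trim      = prob(0.85, 2927.4, 516.6),
      cure_notrim    = prob(0.20, 20, 80),
      # annual incidence risk; deterministic value and Beta differ by design
      incidence_risk = prob(0.078, 465, 1624.7),
      # probability of applying an orthopedic block at an ulcer trim;
      # already folded into the expected block cost, kept for sensitivity
      block_prob     = prob(0.70)
    ),
    costs = list(
      milk_sales     = money(6320.50, 8208.44),  # per cow per year
      cattle_sales   = money(284.60, 369.60),    # net, per cow per year
      trim_cost      = money(15.02, 19.50),      # one trim
      block_cost     = money(20.25, 26.30),      # expected, per ulcer trim
      ai_cost_healthy = money(132.48, 172.05),   # 3 AIs per cow-year
      ai_cost_ulcer  = money(220.80, 286.75),    # 5 AIs per cow-year
      labor_partial  = money(13.34, 17.33),      # sorting labor per session
      labor_whole    = money(2.96, 3.85),        # per whole-herd session
      additional_cow = money(101.63, 131.99),    # per ulcer cow-cycle (quota)
      milk_loss      = money(73.50, 95.46)       # per ulcer cow-cycle
    ),
    # full block price; expected block cost = price * block probability
    block_price_usd = 28.88
  )
  class(cfg) <- "su_config"
  validate_config(cfg)
}

#' Validate a model configuration
#'
#' Checks structural invariants (positive herd size and cycle count,
#' discount rate in \[0, 1)), that every probability lies in \[0, 1\] with
#' positive Beta shapes where a distribution is defined, that no price is
#' negative, and that each USD value agrees with its CAD mean times the
#' exchange rate to within 0.5%.
#'
#' @param config An `su_config` list.
#' @return The validated configuration, invisibly classed `su_config`.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  if (!is.numeric(config$herd_size) || config$herd_size < 1)
    stop("herd_size must be >= 1", call. = FALSE)
  if (!is.numeric(config$n_cycles) || config$n_cycles < 1)
    stop("n_cycles must be >= 1", call. = FALSE)
  if (config$discount_rate < 0 || config$discount_rate >= 1)
    stop("discount_rate must be in [0, 1)", call. = FALSE)
  if (config$fx_rate <= 0) stop("fx_rate must be positive", call. = FALSE)
  for (nm in names(config$probabilities)) {
    p <- config$probabilities[[nm]]
    if (!is.finite(p$value) || p$value < 0 || p$value > 1)
      stop(sprintf("probability '%s' must be in [0, 1], got %s", nm,
                   format(p$value)), call. = FALSE)
    if (!is.na(p$alpha) && (p$alpha <= 0 || p$beta <= 0))
      stop(sprintf("probability '%s' has non-positive Beta shapes", nm),
           call. = FALSE)
  }
  for (nm in names(config$costs)) {
    cst <- config$costs[[nm]]
    if (!is.finite(cst$usd) || cst$usd < 0)
      stop(sprintf("cost '%s' must be non-negative", nm), call. = FALSE)
    if (cst$cad_sd < 0)
      stop(sprintf("cost '%s' has negative sd", nm), call. = FALSE)
    if (!is.na(cst$cad_mean)) {
      implied <- cst$cad_mean * config$fx_rate
      if (abs(implied - cst$usd) > 0.005 * max(cst$usd, 1e-9))
        stop(sprintf(
          "cost '%s': USD %.2f does not match CAD %.2f x %.2f = %.2f",
          nm, cst$usd, cst$cad_mean, config$fx_rate, implied), call. = FALSE)
    }
  }
  class(config) <- "su_config"
  invisible(config)
}

#' Load a model configuration from a YAML file
#'
#' Reads a flat key/value YAML file and overlays it on
#' [reference_parameters()]; keys not present keep their reference values,
#' so an empty file reproduces the reference configuration. Recognised
#' keys are the structural constants (`herd_size`, `n_cycles`,
#' `discount_rate`, `fx_rate`, `psa_iterations`, `seed`), one key per
#' probability (e.g. `prevalence`, `p_trim_ulcer`, `incidence_risk`,
#' overriding the deterministic value and leaving the distribution's
#' shapes untouched) and one key per cost (e.g. `trim_cost`,
#' `additional_cow`, overriding the USD value; the CAD sampling mean is
#' rescaled to keep usd = cad * fx consistent).
#'
#' @param path Path to a YAML file.
#' @return A validated `su_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must be a key/value mapping",
                          call. = FALSE)
  cfg <- reference_parameters()
  structural <- c("herd_size", "n_cycles", "cycle_months", "discount_rate",
                  "fx_rate", "whole_interval", "psa_iterations", "seed")
  for (key in names(raw)) {
    val <- raw[[key]]
    if (key %in% structural) {
      cfg[[key]] <- val
    } else if (key %in% names(cfg$probabilities)) {
      if (!is.numeric(val) || val < 0 || val > 1)
        stop(sprintf("validation error: '%s' must be a probability in [0, 1]",
                     key), call. = FALSE)
      cfg$probabilities[[key]]$value <- val
    } else if (key %in% names(cfg$costs)) {
      if (!is.numeric(val) || val < 0)
        stop(sprintf("validation error: '%s' must be a non-negative cost",
                     key), call. = FALSE)
      cfg$costs[[key]]$usd <- val
      cfg$costs[[key]]$cad_mean <- val / cfg$fx_rate
    } else {
      stop("unknown configuration key: ", key, call. = FALSE)
    }
  }
  validate_config(cfg)
  cfg
}

#' Convert an incidence risk to an incidence rate
#'
#' For a cumulative risk over one time unit, the constant event rate over
#' the same unit is `-log(1 - risk)` (exponential waiting-time
#' assumption). The 7.8% annual sole-ulcer risk maps to a rate of 0.081
#' per year.
#'
#' @param risk Probability of at least one event per period, in \[0, 1).
#' @return Events per period (same period as the risk).
#' @export
#' @examples
#' rate_from_risk(0.078)  # 0.0812
rate_from_risk <- function(risk) {
  if (any(!is.finite(risk)) || any(risk < 0) || any(risk >= 1))
    stop("risk must be in [0, 1)", call. = FALSE)
  -log(1 - risk)
}

#' Convert a rate to a per-cycle transition probability
#'
#' `1 - exp(-rate * cycle_fraction)`: the probability of at least one
#' event in a cycle spanning `cycle_fraction` of the rate's time unit.
#' With the annual rate 0.081 and a two-month cycle (1/6 year) this gives
#' the 0.013 per-cycle probability of developing a sole ulcer.
#'
#' @param rate Events per time unit, non-negative.
#' @param cycle_fraction Cycle length as a fraction of the rate's unit,
#'   in (0, 1].
#' @return Transition probability per cycle.
#' @export
#' @examples
#' cycle_probability_from_rate(0.081, 1 / 6)  # 0.0134
cycle_probability_from_rate <- function(rate, cycle_fraction) {
  if (any(!is.finite(rate)) || any(rate < 0))
    stop("rate must be non-negative", call. = FALSE)
  if (any(cycle_fraction <= 0) || any(cycle_fraction > 1))
    stop("cycle_fraction must be in (0, 1]", call. = FALSE)
  1 - exp(-rate * cycle_fraction)
}

#' Mean of a Beta distribution
#'
#' @param alpha,beta_ Positive shape parameters (events / non-events).
#' @return `alpha / (alpha + beta_)`.
#' @export
beta_mean <- function(alpha, beta_) {
  if (any(alpha <= 0) || any(beta_ <= 0))
    stop("Beta shapes must be positive", call. = FALSE)
  alpha / (alpha + beta_)
}

#' Convert 2019 CAD to 2019 USD
#'
#' @param amount Amount in Canadian dollars.
#' @param fx_rate US dollars per Canadian dollar (default 0.77).
#' @return Amount in US dollars.
#' @export
usd_from_cad <- function(amount, fx_rate = 0.77) {
  amount * fx_rate
}

#' Two-month ulcer onset probability implied by a configuration
#'
#' Chains [rate_from_risk()] and [cycle_probability_from_rate()] from the
#' configuration's annual incidence risk and cycle length.
#'
#' @param config An `su_config`.
#' @param risk Optional override of the annual incidence risk (used by
#'   the probabilistic analysis with sampled risks).
#' @return Per-cycle onset probability.
#' @export
onset_probability <- function(config, risk = NULL) {
  if (is.null(risk)) risk <- config$probabilities$incidence_risk$value
  cycle_probability_from_rate(rate_from_risk(risk), config$cycle_months / 12)
}

#' @export
print.su_config <- function(x, ...) {
  cat("Hoof-trimming model configuration\n")
  cat(sprintf("  herd size %d, %d cycles of %g months, discount %.1f%%/yr\n",
              as.integer(x$herd_size), as.integer(x$n_cycles),
              x$cycle_months, 100 * x$discount_rate))
  cat(sprintf("  %d probability inputs, %d price inputs, fx CAD->USD %.2f\n",
              length(x$probabilities), length(x$costs), x$fx_rate))
  invisible(x)
}
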