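#' Draw one set of probabilistic inputs
#'
#' Samples every probability that carries a Beta distribution from
#' Beta(alpha, beta) and every price from Normal(CAD mean, CAD sd)
#' converted to USD at the fixed exchange rate; negative price draws are
#' resampled (with the published sd of 0.1 CAD this is effectively never
#' triggered). The per-cycle onset probability is recomputed from the
#' drawn annual incidence risk. Parameters without a distribution keep
#' their deterministic values. Uses the current RNG state; seed upstream.
#'
#' @param config An `su_config`.
#' @return A list with named numeric vectors `probabilities` and `costs`
#'   (USD), and the derived `incidence_rate` and `onset` probability.
#' @export
sample_parameters <- function(config) {
  probs <- vapply(config$probabilities, `[[`, 0, "value")
  for (nm in names(config$probabilities)) {
    p <- config$probabilities[[nm]]
    if (!is.na(p$alpha)) probs[[nm]] <- stats::rbeta(1, p$alpha, p$beta)
  }
  costs <- vapply(config$costs, `[[`, 0, "usd")
  for (nm in names(config$costs)) {
    cst <- config$costs[[nm]]
    if (!is.na(cst$cad_mean) && cst$cad_sd > 0) {
      repeat {
        draw <- stats::rnorm(1, cst$cad_mean, cst$cad_sd)
        if (draw >= 0) break
      }
      costs[[nm]] <- usd_from_cad(draw, config$fx_rate)
    }
  }
  rate <- rate_from_risk(probs[["incidence_risk"]])
  onset <- cycle_probability_from_rate(rate, config$cycle_months / 12)
  list(probabilities = probs, costs = costs,
       incidence_rate = rate, onset = onset)
}

#' Probabilistic sensitivity analysis
#'
#' Repeats the strategy comparison `n_iter` times, each time with all
#' uncertain inputs drawn from their distributions, and summarises the
#' distribution of the difference in net benefits by its mean, empirical
#' 2.5/97.5 percentile interval and the fraction of draws in which each
#' strategy wins. Each iteration runs on its own RNG substream derived
#' deterministically from the master seed, so results do not depend on
#' execution order.
#'
#' @param config An `su_config`.
#' @param n_iter Number of iterations (reference analysis: 2000).
#' @param seed Master seed (integer).
#' @param production_cost_mode `"additional_cow"` or `"milk_loss"`.
#' @param selection `"targeted"` (reference: drawn conditional trim
#'   probabilities) or `"random"` (both conditional probabilities set to
#'   the drawn overall trim probability — the random-selection scenario).
#' @return An object of class `su_psa`: list with `n_iterations`,
#'   `differences` (one per draw), `components` (per-draw component
#'   matrices for both arms), `benefits` (per-draw discounted benefits),
#'   `mean_difference`, `ci_low`, `ci_high`,
#'   `fraction_partial_preferred`, `seed`, `production_cost_mode`,
#'   `selection`, and `draws` (data frame of sampled inputs).
#' @export
#' @examples
#' \donttest{
#' psa <- run_psa(reference_parameters(), n_iter = 200, seed = 42)
#' psa$fraction_partial_preferred
#' }
run_psa <- function(config, n_iter = config$psa_iterations,
                    seed = config$seed,
                    production_cost_mode = c("additional_cow", "milk_loss"),
                    selection = c("targeted", "random")) {
  production_cost_mode <- match.arg(production_cost_mode)
  selection <- match.arg(selection)
  n_iter <- as.integer(n_iter)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)

  comp_names <- c("trim_cost", "block_cost", "reproduction_cost",
                  "labor_cost", "su_production_cost", "total_undiscounted",
                  "total_discounted")
  comp_p <- matrix(NA_real_, n_iter, length(comp_names),
                   dimnames = list(NULL, comp_names))
  comp_w <- comp_p
  differences <- numeric(n_iter)
  benefits <- numeric(n_iter)
  draw_rows <- vector("list", n_iter)

  for (i in seq_len(n_iter)) {
    set.seed(iter_seeds[i])
    dr <- sample_parameters(config)
    cfg_i <- config
    for (nm in names(dr$probabilities))
      cfg_i$probabilities[[nm]]$value <- dr$probabilities[[nm]]
    if (selection == "random") {
      cfg_i$probabilities$p_trim_ulcer$value <-
        dr$probabilities[["p_trim_overall"]]
      cfg_i$probabilities$p_trim_healthy$value <-
        dr$probabilities[["p_trim_overall"]]
    }
    nb <- compare_strategies(cfg_i, production_cost_mode,
                             onset = dr$onset,
                             cost_overrides = as.list(dr$costs))
    differences[i] <- nb$difference
    benefits[i] <- nb$benefits_discounted
    comp_p[i, ] <- vapply(comp_names, function(k) nb$cost_partial[[k]], 0)
    comp_w[i, ] <- vapply(comp_names, function(k) nb$cost_whole[[k]], 0)
    draw_rows[[i]] <- c(dr$probabilities, dr$costs, onset = dr$onset)
  }
  draws <- as.data.frame(do.call(rbind, draw_rows))
  draws$difference <- differences

  out <- list(
    n_iterations = n_iter,
    differences = differences,
    components = list(partial = comp_p, whole = comp_w),
    benefits = benefits,
    mean_difference = mean(differences),
    ci_low = unname(stats::quantile(differences, 0.025)),
    ci_high = unname(stats::quantile(differences, 0.975)),
    fraction_partial_preferred = mean(differences > 0),
    seed = as.integer(seed),
    production_cost_mode = production_cost_mode,
    selection = selection,
    draws = draws)
  class(out) <- "su_psa"
  out
}

#' Summarise a probabilistic analysis as a component table
#'
#' Per cost component and strategy arm: the mean and empirical 95%
#' interval of the undiscounted component across draws, plus discounted
#' totals, discounted benefits, the difference in net benefits and the
#' fraction of draws preferring the partial-herd strategy.
#'
#' @param result An `su_psa`.
#' @return An object of class `su_psa_summary`: list with `table` (data
#'   frame, one row per component x arm with `mean`, `ci_low`,
#'   `ci_high`), `mean_difference`, `ci_low`, `ci_high`,
#'   `fraction_partial_preferred`.
#' @export
summarize_psa <- function(result) {
  stopifnot(inherits(result, "su_psa"))
  if (result$n_iterations < 1) stop("empty PSA result", call. = FALSE)
  q <- function(x, p) unname(stats::quantile(x, p))
  rows <- list()
  labels <- c(trim_cost = "trim", block_cost = "block",
              reproduction_cost = "reproduction", labor_cost = "labor",
              su_production_cost =
                if (result$production_cost_mode == "additional_cow")
                  "additional_cow" else "milk_loss",
              total_discounted = "total")
  for (arm in c("partial", "whole")) {
    m <- result$components[[arm]]
    for (comp in names(labels)) {
      x <- m[, comp]
      rows[[length(rows) + 1L]] <- data.frame(
        component = labels[[comp]], arm = arm, mean = mean(x),
        ci_low = q(x, 0.025), ci_high = q(x, 0.975))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      component = "benefits", arm = arm, mean = mean(result$benefits),
      ci_low = q(result$benefits, 0.025),
      ci_high = q(result$benefits, 0.975))
  }
  out <- list(table = do.call(rbind, rows),
              mean_difference = result$mean_difference,
              ci_low = result$ci_low, ci_high = result$ci_high,
              fraction_partial_preferred = result$fraction_partial_preferred,
              n_iterations = result$n_iterations)
  class(out) <- "su_psa_summary"
  out
}

#' @export
print.su_psa <- function(x, ...) {
  cat(sprintf("Probabilistic analysis: %d iterations (seed %d, %s mode, %s selection)\n",
              x$n_iterations, x$seed, x$production_cost_mode, x$selection))
  cat(sprintf("  difference in net benefits (partial - whole): mean $%s, 95%% CI $%s-$%s\n",
              format(round(x$mean_difference), big.mark = ","),
              format(round(x$ci_low), big.mark = ","),
              format(round(x$ci_high), big.mark = ",")))
  cat(sprintf("  partial-herd strategy preferred in %.1f%% of draws\n",
              100 * x$fraction_partial_preferred))
  invisible(x)
}

#' @export
print.su_psa_summary <- function(x, ...) {
  tab <- x$table
  tab$mean <- round(tab$mean)
  tab$ci_low <- round(tab$ci_low)
  tab$ci_high <- round(tab$ci_high)
  print(tab, row.names = FALSE)
  cat(sprintf("difference in net benefits: $%s (95%% CI $%s-$%s); partial preferred %.1f%% of draws\n",
              format(round(x$mean_difference), big.mark = ","),
              format(round(x$ci_low), big.mark = ","),
              format(round(x$ci_high), big.mark = ","),
              100 * x$fraction_partial_preferred))
  invisible(x)
}

#' Export per-draw PSA inputs and outcomes as CSV
#'
#' One row per iteration: every sampled input plus the resulting
#' difference in net benefits.
#'
#' @param result An `su_psa`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psa_draws_csv <- function(result, path) {
  stopifnot(inherits(result, "su_psa"))
  utils::write.csv(result$draws, path, row.names = FALSE)
  invisible(path)
}
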