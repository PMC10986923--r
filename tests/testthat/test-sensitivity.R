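test_that("tornado analysis ranks inputs and honours degenerate bounds", {
  tor <- one_way_sensitivity(ref_config)
  expect_true(all(diff(tor$range_width) <= 1e-9))
  expect_equal(tor$range_width,
               abs(tor$difference_at_high - tor$difference_at_low))
  # the three widest bars are herd size, trim probability and prevalence
  expect_setequal(tor$param_name[1:3],
                  c("herd_size", "p_trim_overall", "prevalence"))

  # all-degenerate bounds collapse every bar to zero width
  b <- sensitivity_bounds()
  ref_vals <- c(herd_size = 100, prevalence = 0.064, p_trim_overall = 0.18,
                cure_trim = 0.85, cure_notrim = 0.20, incidence_risk = 0.078,
                trim_cost = 15.02, block_price = 28.88, block_prob = 0.70,
                labor_partial = 13.34, labor_whole = 2.96,
                additional_cow = 101.63, ai_cost = 132.48,
                milk_sales = 6320.50, cattle_sales = 284.60)
  b$low <- b$high <- unname(ref_vals[b$param_name])
  tor0 <- one_way_sensitivity(ref_config, b)
  expect_true(all(tor0$range_width < 1e-6))

  # one degenerate bar leaves the others unchanged
  b1 <- sensitivity_bounds()
  b1[b1$param_name == "prevalence", c("low", "high")] <- 0.064
  tor1 <- one_way_sensitivity(ref_config, b1)
  expect_lt(tor1$range_width[tor1$param_name == "prevalence"], 1e-9)
  expect_equal(tor1$range_width[tor1$param_name == "herd_size"],
               tor$range_width[tor$param_name == "herd_size"])

  expect_error(one_way_sensitivity(
    ref_config, data.frame(param_name = "nope", low = 1, high = 2)),
    "unknown")
})

test_that("the herd-size bound scales the difference near-proportionally", {
  tor <- one_way_sensitivity(
    ref_config, data.frame(param_name = "herd_size", low = 50, high = 500))
  ratio <- tor$difference_at_high / tor$difference_at_low
  expect_equal(ratio, 10, tolerance = 0.15)
})

test_that("varying the block price or probability recomputes the expected block cost", {
  tor <- one_way_sensitivity(
    ref_config,
    data.frame(param_name = c("block_prob", "block_price"),
               low = c(0.50, 26.95), high = c(0.95, 30.80)))
  # halving/raising the probability swings more than the narrow price range
  expect_gt(tor$range_width[tor$param_name == "block_prob"],
            tor$range_width[tor$param_name == "block_price"])
})

test_that("the healthy-cow selection probability solves the trim budget", {
  ph <- solve_nonulcer_trim_probability(0.54, 324, ref_config)
  expect_equal(ph, 0.1699, tolerance = 0.005)
  cfg <- ref_config
  cfg$probabilities$p_trim_ulcer$value <- 0.54
  cfg$probabilities$p_trim_healthy$value <- ph
  expect_equal(run_cohort(cfg, "partial")$expected_trims_total, 324,
               tolerance = 0.01 / 324)

  # with no ulcers, an 18-trims-per-cycle budget forces 0.18 exactly
  ph0 <- solve_nonulcer_trim_probability(0.18, 324, disease_free_config())
  expect_equal(ph0, 0.18, tolerance = 1e-8)

  # full targeting frees budget from healthy cows
  ph1 <- solve_nonulcer_trim_probability(1.0, 324, ref_config)
  expect_lt(ph1, 0.1699)
  cfg$probabilities$p_trim_ulcer$value <- 1.0
  cfg$probabilities$p_trim_healthy$value <- ph1
  expect_equal(run_cohort(cfg, "partial")$expected_trims_total, 324,
               tolerance = 0.01 / 324)

  expect_error(solve_nonulcer_trim_probability(0.54, 5000, ref_config),
               "infeasible")
})

test_that("targeting sweep increases the difference at a conserved budget", {
  sc <- scenario_targeting_sweep(ref_config)
  out <- sc$outputs
  expect_equal(out$p_trim_ulcer, c(0.18, 0.54, 1.00))
  expect_true(all(abs(out$expected_trims - 324) <= 0.01))
  expect_true(all(diff(out$difference) > 0))
  # the reference targeting level reproduces the reference comparison
  expect_equal(out$difference[2], compare_strategies(ref_config)$difference,
               tolerance = 0.005)
  # random targeting (0.18) agrees in sign with the random-selection flip
  expect_lt(out$difference[1], out$difference[2])
})

test_that("random selection flips the preferred strategy", {
  sc <- scenario_random_selection(ref_config, n_iter = 300, seed = 17)
  out <- sc$outputs
  expect_gt(out$fraction_whole_preferred, 0.5)
  expect_equal(out$mean_difference_whole_minus_partial,
               -out$psa$mean_difference)
  # restoring targeted selection reduces to the reference analysis
  ref_psa <- run_psa(ref_config, n_iter = 50, seed = 31)
  tgt_psa <- run_psa(ref_config, n_iter = 50, seed = 31,
                     selection = "targeted")
  expect_identical(ref_psa$differences, tgt_psa$differences)
})

test_that("the difference grows linearly in herd size", {
  sc <- scenario_herd_size_sweep(ref_config)
  out <- sc$outputs
  expect_equal(out$table$herd_size, seq(50, 500, by = 50))
  expect_gt(out$r_squared, 0.999)
  expect_gt(out$slope, 0)
  expect_gt(out$table$difference[10], out$table$difference[1])

  # with labor zeroed everything scales in herd size: intercept vanishes
  cfg <- set_cost_usd(set_cost_usd(reference_parameters(),
                                   "labor_partial", 0), "labor_whole", 0)
  sc0 <- scenario_herd_size_sweep(cfg)
  expect_lt(abs(sc0$outputs$intercept), 1e-6)
  expect_gt(sc0$outputs$r_squared, 1 - 1e-12)
})

test_that("milk-loss costing lowers the difference but keeps the preference", {
  nb_cow <- compare_strategies(ref_config, "additional_cow")
  nb_milk <- compare_strategies(ref_config, "milk_loss")
  expect_lt(nb_milk$difference, nb_cow$difference)  # 73.50 < 101.63
  expect_gt(nb_milk$difference, 0)

  sc <- scenario_no_quota(ref_config, n_iter = 200, seed = 13)
  expect_gt(sc$outputs$fraction_partial_preferred, 0.95)

  # with equal unit costs the two modes coincide draw for draw
  cfg_eq <- reference_parameters()
  cfg_eq$costs$milk_loss <- cfg_eq$costs$additional_cow
  cfg_eq$costs$milk_loss$cad_sd <- 0       # degenerate prices so the
  cfg_eq$costs$additional_cow$cad_sd <- 0  # two modes share unit costs
  a <- run_psa(cfg_eq, n_iter = 50, seed = 8,
               production_cost_mode = "additional_cow")
  b <- run_psa(cfg_eq, n_iter = 50, seed = 8,
               production_cost_mode = "milk_loss")
  expect_equal(a$differences, b$differences, tolerance = 1e-12)
})
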