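test_that("one cycle follows the pinned select -> cure -> onset order", {
  # hand-enumerated: survivors 0.064 x (1 - (0.54*0.85 + 0.46*0.20))
  #                = 0.064 x 0.449 = 0.028736
  # healthy after cure = 0.971264; new = 0.971264 x 0.0134 = 0.01301494
  st <- step_cycle(0.064, c(0.54, 0.1699), 0.85, 0.20, 0.0134)
  expect_equal(st$frac_trimmed_ulcer, 0.064 * 0.54)
  expect_equal(st$frac_untrimmed_ulcer, 0.064 * 0.46)
  expect_equal(st$s_end, 0.028736 + 0.971264 * 0.0134, tolerance = 1e-10)
  expect_equal(st$s_end, 0.0417509, tolerance = 1e-6)

  # disease-free herd stays disease-free; partial policy still trims
  st0 <- step_cycle(0, c(0.54, 0.1699), 0.85, 0.20, 0)
  expect_equal(st0$frac_trimmed_healthy, 0.1699)
  expect_equal(st0$frac_untrimmed_healthy, 0.8301)
  expect_equal(st0$s_end, 0)

  # perfect cure of a fully ulcerated, fully trimmed herd
  st1 <- step_cycle(1, c(1, 1), 1, 0.2, 0)
  expect_equal(st1$s_end, 0)

  expect_error(step_cycle(1.2, c(0.5, 0.5), 0.8, 0.2, 0.01), "\\[0, 1\\]")
  expect_error(step_cycle(0.5, c(0.5, 0.5), -0.1, 0.2, 0.01), "\\[0, 1\\]")
})

test_that("occupancy is conserved and partitions the prevalence every cycle", {
  set.seed(101)
  for (i in 1:25) {
    st <- step_cycle(runif(1), runif(2), runif(1), runif(1), runif(1))
    total <- st$frac_trimmed_ulcer + st$frac_trimmed_healthy +
      st$frac_untrimmed_ulcer + st$frac_untrimmed_healthy
    expect_equal(total, 1, tolerance = 1e-12)
    expect_equal(st$frac_trimmed_ulcer + st$frac_untrimmed_ulcer,
                 st$s_start, tolerance = 1e-12)
    expect_true(st$s_end >= 0 && st$s_end <= 1)
  }
  # and over a full trace
  tr <- run_cohort(ref_config, "partial")
  occ <- tr$occupancies
  expect_equal(rowSums(occ[, 2:5]), rep(1, 18), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("whole-herd strategy trims every cow at each of 6 sessions", {
  pol <- build_policy("whole", ref_config)
  sessions <- pol$p_trim_ulcer == 1 & pol$p_trim_healthy == 1
  expect_equal(sum(sessions), 6)
  expect_equal(pol$cycle[sessions], c(0, 3, 6, 9, 12, 15))
  expect_true(all(pol$p_trim_ulcer[!sessions] == 0))

  tr <- run_cohort(ref_config, "whole")
  expect_identical(tr$expected_trims_total, 600)
  expect_equal(expected_trims(tr), 600)
})

test_that("partial policy repeats the conditional selection probabilities", {
  pol <- build_policy("partial", ref_config)
  expect_equal(pol$p_trim_ulcer, rep(0.54, 18))
  expect_equal(pol$p_trim_healthy, rep(0.1699, 18))
  expect_error(build_policy("weekly", ref_config))

  cfg <- ref_config
  cfg$probabilities$p_trim_ulcer$value <- 0.18
  cfg$probabilities$p_trim_healthy$value <- 0.18
  pol18 <- build_policy("partial", cfg)
  expect_equal(unlist(pol18[, 2:3], use.names = FALSE), rep(0.18, 36))
})

test_that("partial-herd trims total about 325 and match trace re-summation", {
  tr <- run_cohort(ref_config, "partial")
  # independent re-summation of the occupancy sequence
  occ <- tr$occupancies
  resum <- 100 * sum(occ$frac_trimmed_ulcer + occ$frac_trimmed_healthy)
  expect_equal(tr$expected_trims_total, resum, tolerance = 1e-12)
  expect_equal(tr$expected_trims_total, 324.5, tolerance = 2e-3)
  expect_equal(expected_trims(tr), tr$expected_trims_total)

  # zero policy -> zero trims
  pol0 <- build_policy("partial", ref_config)
  pol0$p_trim_ulcer <- 0
  pol0$p_trim_healthy <- 0
  expect_equal(run_cohort(ref_config, "partial",
                          policy = pol0)$expected_trims_total, 0)
})

test_that("a disease-free cohort accrues no ulcer cow-cycles", {
  cfg <- disease_free_config()
  for (arm in c("partial", "whole")) {
    tr <- run_cohort(cfg, arm)
    expect_equal(tr$expected_ulcer_cow_cycles, 0)
    expect_equal(tr$expected_ulcer_trims_total, 0)
    expect_true(all(tr$occupancies$frac_trimmed_ulcer == 0))
    expect_true(all(tr$occupancies$frac_untrimmed_ulcer == 0))
  }
})

test_that("better cure never increases, faster onset never decreases, ulcer burden", {
  burden <- function(cure_trim = 0.85, risk = 0.078) {
    cfg <- reference_parameters()
    cfg$probabilities$cure_trim$value <- cure_trim
    cfg$probabilities$incidence_risk$value <- risk
    run_cohort(cfg, "partial")$expected_ulcer_cow_cycles
  }
  cures <- seq(0, 1, by = 0.2)
  b_cure <- vapply(cures, function(ct) burden(cure_trim = ct), 0)
  expect_true(all(diff(b_cure) <= 1e-12))
  risks <- seq(0, 0.9, by = 0.15)
  b_risk <- vapply(risks, function(r) burden(risk = r), 0)
  expect_true(all(diff(b_risk) >= -1e-12))
})

test_that("constant-policy prevalence converges to the closed-form fixed point", {
  # s* = i / (c + i - c*i) for per-cycle cure fraction
  # c = 0.54*cure_trim + 0.46*cure_notrim and onset i
  cases <- list(c(i = 0.0411, ct = 0.85, cn = 0.20),
                c(i = 0.0134, ct = 0.85, cn = 0.20),
                c(i = 0.10, ct = 0.50, cn = 0.05))
  for (cs in cases) {
    c_eff <- 0.54 * cs[["ct"]] + 0.46 * cs[["cn"]]
    s_star <- cs[["i"]] / (c_eff + cs[["i"]] - c_eff * cs[["i"]])
    s <- 0.064
    for (k in 1:500)
      s <- step_cycle(s, c(0.54, 0.1699), cs[["ct"]], cs[["cn"]],
                      cs[["i"]])$s_end
    expect_equal(s, s_star, tolerance = 1e-12)
  }
})

test_that("trace CSV export round-trips the occupancy table", {
  tr <- run_cohort(ref_config, "whole")
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  back <- read.csv(f)
  expect_equal(names(back), names(tr$occupancies))
  expect_equal(back$s_start, tr$occupancies$s_start, tolerance = 1e-12)
})
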