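test_that("parameter validation rejects impossible settings", {
  arms <- tibble::tibble(arm = c("c", "t"), deterrence = c(0, 0.5),
                         p_death = c(0.05, 0.5), p_feed = c(0.3, 0.1),
                         p_exit = c(0.8, 0.9))
  expect_s3_class(trial_params(arms, mu = 10), "trial_params")
  bad <- arms; bad$p_death[2] <- 1.2
  expect_error(trial_params(bad, mu = 10), "p_death")
  bad2 <- arms; bad2$deterrence[2] <- 1.0
  expect_error(trial_params(bad2, mu = 10), "deterrence")
  expect_error(trial_params(arms, mu = 0), "mu")
  expect_error(trial_params(arms, mu = 10, k = 0), "k must")
  bad3 <- arms; bad3$deterrence[1] <- 0.1
  expect_error(trial_params(bad3, mu = 10, control_arm = "c"), "control arm")
})

test_that("simulation is byte-identical under a fixed seed", {
  prm <- two_arm_params(seed = 42, sigma_hut = 0.3, sigma_sleeper = 0.3)
  a <- simulate_trial(prm)
  b <- simulate_trial(prm)
  expect_identical(a, b)
  prm2 <- two_arm_params(seed = 43, sigma_hut = 0.3, sigma_sleeper = 0.3)
  expect_false(identical(a, simulate_trial(prm2)))
})

test_that("simulated records conserve their cross-classified counts", {
  prm <- two_arm_params(seed = 7, d = 0.4, m = c(0.05, 0.5),
                        f = c(0.3, 0.1), e = c(0.7, 0.9),
                        sigma_hut = 0.2, sigma_sleeper = 0.2)
  sim <- simulate_trial(prm)
  cells <- hut_count_cells()
  caught <- rowSums(sim[, cells])
  dead <- rowSums(sim[, grep("_dead_", cells, value = TRUE)])
  alive <- rowSums(sim[, grep("_alive_", cells, value = TRUE)])
  fed <- rowSums(sim[, grep("^fed_", cells, value = TRUE)])
  unfed <- rowSums(sim[, grep("^unfed_", cells, value = TRUE)])
  room <- rowSums(sim[, grep("_room$", cells, value = TRUE)])
  trapped <- rowSums(sim[, grep("_(verandah|window)$", cells, value = TRUE)])
  expect_equal(dead + alive, caught)
  expect_equal(fed + unfed, caught)
  expect_equal(room + trapped, caught)
  expect_true(validate_hut_records(sim)$pass)
})

test_that("null deterrence estimates concentrate near zero at large n", {
  # ~10^6 mosquitoes over 48 near-Poisson hut-nights: catch-ratio noise
  # well below one percentage point
  prm <- two_arm_params(seed = 10, mu = 10000, d = 0, k = 5000,
                        n_periods = 12)
  et <- summarize_trial(aggregate_arms(simulate_trial(prm)), "ctrl")
  expect_lt(abs(et$deterrence_raw[et$arm == "trt"]), 1)
})

test_that("the treated/control catch ratio recovers 1 - d within Monte Carlo error", {
  d <- 0.35
  ratios <- vapply(1:100, function(s) {
    sim <- simulate_trial(two_arm_params(seed = 4000 + s, mu = 30, d = d))
    agg <- aggregate_arms(sim)
    agg$total_caught[agg$arm == "trt"] / agg$total_caught[agg$arm == "ctrl"]
  }, numeric(1))
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - (1 - d)), 2 * se + 1e-9)
})

test_that("the copula correlation induces dependence between death and feeding", {
  base <- list(seed = 5, mu = 2000, m = c(0.5, 0.5), f = c(0.5, 0.5))
  sim0 <- simulate_trial(do.call(two_arm_params, base))
  prm_r <- do.call(two_arm_params, base)
  prm_r$rho <- 0.8
  sim_r <- simulate_trial(prm_r)
  joint <- function(sim) {
    cells <- hut_count_cells()
    sum(sim[, grep("^fed_dead_", cells, value = TRUE)]) / sum(sim[, cells])
  }
  # independent: P(fed & dead) ~ 0.25; rho = 0.8 pushes it well above
  expect_lt(abs(joint(sim0) - 0.25), 0.03)
  expect_gt(joint(sim_r), 0.30)
})

test_that("endpoint tables invert to parameters that reproduce their endpoints", {
  rec <- reconstruct_trial_records("moshi")
  et <- summarize_trial(aggregate_arms(rec), "untreated")
  prm <- params_from_endpoint_table(et, nights_per_period = 4, n_periods = 6,
                                    seed = 8)
  ee <- expected_endpoints(prm)
  expect_equal(round_half_up(ee$bfi_pct[ee$arm == "icon_washed20"]), 69.6)
  expect_equal(round_half_up(ee$corrected_mortality_pct[ee$arm == "icon_unwashed"]),
               47.4)
  # simulate large and recompute: endpoints match within Monte Carlo error
  prm_big <- params_from_endpoint_table(et, nights_per_period = 4,
                                        n_periods = 6, mu = 2000, seed = 9)
  et2 <- summarize_trial(aggregate_arms(simulate_trial(prm_big)), "untreated")
  m <- merge(et2[, c("arm", "bfi_raw", "corrected_mortality_raw")],
             ee, by = "arm")
  expect_true(all(abs(m$bfi_raw - m$bfi_pct) < 5))
  expect_true(all(abs(m$corrected_mortality_raw - m$corrected_mortality_pct) < 3))
})

test_that("inverting an all-control table returns the control parameters", {
  rec <- reconstruct_trial_records("moshi")
  et <- summarize_trial(aggregate_arms(rec[rec$arm == "untreated", ]),
                        "untreated")
  # a single-arm "trial": control parameters only, no treated arms
  expect_error(
    prm <- params_from_endpoint_table(et, nights_per_period = 4,
                                      n_periods = 2, seed = 1),
    NA
  )
  expect_equal(prm$arms$deterrence, 0)
  expect_equal(prm$arms$p_feed, 131 / 483)
})

test_that("truncated-only endpoint tables refuse inversion at the boundary", {
  rec <- reconstruct_trial_records("moshi")
  et <- summarize_trial(aggregate_arms(rec), "untreated")
  et$deterrence_raw <- NULL # lose the signed values; icon_washed20 prints 0
  expect_error(params_from_endpoint_table(et, seed = 1), "ambiguity")
})
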