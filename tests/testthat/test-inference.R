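test_that("a large mortality contrast is detected in the right direction", {
  # mortality 70% (28/40) vs 33% (19/57), spread over nights
  totals <- tibble::tibble(
    arm = c("hi", "lo"), caught = c(40L, 57L), dead = c(28L, 19L),
    fed = c(10L, 15L), exited = c(30L, 45L)
  )
  rec <- records_from_totals(totals, n_nights = 12)
  pm <- compare_proportions(rec, "mortality")
  expect_lt(pm$p["hi", "lo"], 0.05)
  fit_props <- tapply(
    rowSums(rec[, grep("_dead_", hut_count_cells(), value = TRUE)]),
    rec$arm, sum) / tapply(rowSums(rec[, hut_count_cells()]), rec$arm, sum)
  expect_gt(fit_props[["hi"]], fit_props[["lo"]])
})

test_that("duplicated arms with a zero outcome fall back to the exact test with p = 1", {
  totals <- tibble::tibble(
    arm = c("a", "b"), caught = c(20L, 20L), dead = c(0L, 0L),
    fed = c(5L, 5L), exited = c(10L, 10L)
  )
  rec <- records_from_totals(totals, n_nights = 4)
  pm <- compare_proportions(rec, "mortality")
  expect_equal(pm$method["a", "b"], "exact")
  expect_equal(pm$p["a", "b"], 1)
})

test_that("arms with zero total caught are excluded with a warning", {
  totals <- tibble::tibble(
    arm = c("a", "b", "empty"), caught = c(30L, 30L, 0L),
    dead = c(10L, 12L, 0L), fed = c(5L, 6L, 0L), exited = c(20L, 21L, 0L)
  )
  rec <- records_from_totals(totals, n_nights = 4)
  expect_warning(pm <- compare_proportions(rec, "mortality"), "excluded")
  expect_equal(pm$arms, c("a", "b"))
})

test_that("model-based and exact two-proportion tests agree on balanced unadjusted data", {
  # no hut/sleeper effects, two arms: the adjusted Wald test and Fisher's
  # exact test on the pooled table should reach the same rejection decision
  # in nearly all cases
  agree <- 0
  n_cases <- 40
  for (s in seq_len(n_cases)) {
    m2 <- 0.15 + 0.2 * (s %% 2) # alternate null and modest effect
    sim <- simulate_trial(two_arm_params(seed = 1000 + s, m = c(0.15, m2)))
    pm <- compare_proportions(sim, "mortality", adjust = character())
    cells <- hut_count_cells()
    k <- tapply(rowSums(sim[, grep("_dead_", cells, value = TRUE)]), sim$arm, sum)
    n <- tapply(rowSums(sim[, cells]), sim$arm, sum)
    exact_p <- fisher.test(matrix(c(k[1], n[1] - k[1], k[2], n[2] - k[2]), 2,
                                  byrow = TRUE))$p.value
    agree <- agree + ((pm$p["ctrl", "trt"] < 0.05) == (exact_p < 0.05))
  }
  expect_gte(agree / n_cases, 0.95)
})

test_that("count comparisons detect a 3x entry-rate ratio", {
  hits <- 0
  n_rep <- 30
  for (s in seq_len(n_rep)) {
    prm <- two_arm_params(seed = 2000 + s, mu = 20, d = 2 / 3)
    sim <- simulate_trial(prm) # treated entry rate mu/3
    pc <- compare_counts(sim, "entries")
    hits <- hits + (pc$p["ctrl", "trt"] < 0.05)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("zero-variance counts trigger the Poisson fallback with a warning", {
  totals <- tibble::tibble(
    arm = c("a", "b"), caught = c(40L, 36L), dead = c(10L, 12L),
    fed = c(8L, 6L), exited = c(20L, 18L)
  )
  rec <- records_from_totals(totals, n_nights = 4) # even spread: 10 and 9 per night
  expect_warning(pc <- compare_counts(rec, "entries"), "Poisson")
  expect_equal(pc$model_family, "poisson")
  expect_true(all(pc$p[upper.tri(pc$p)] >= 0 & pc$p[upper.tri(pc$p)] <= 1))
})

test_that("an all-zero outcome is a degenerate model error", {
  totals <- tibble::tibble(
    arm = c("a", "b"), caught = c(20L, 20L), dead = c(0L, 0L),
    fed = c(5L, 5L), exited = c(10L, 10L)
  )
  rec <- records_from_totals(totals, n_nights = 4)
  expect_error(compare_counts(rec, "dead"), "degenerate")
})

test_that("Holm adjustment never lowers a p-value", {
  rec <- reconstruct_trial_records("moshi")
  raw <- compare_proportions(rec, "mortality")
  adj <- compare_proportions(rec, "mortality", p_adjust = "holm")
  ut <- upper.tri(raw$p)
  expect_true(all(adj$p[ut] >= raw$p[ut] - 1e-12))
})

test_that("letter grouping reproduces canonical patterns", {
  mk <- function(v, arms) {
    p <- matrix(NA_real_, length(arms), length(arms),
                dimnames = list(arms, arms))
    p[upper.tri(p)] <- v
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
    p
  }
  # pairs (1,2) and (1,3) significant, (2,3) not -> a / b / b
  p <- mk(c(0.01, 0.01, 0.60), c("A", "B", "C"))
  lg <- letter_grouping(p, alpha = 0.05)
  expect_equal(unname(lg[["A"]]), "a")
  expect_equal(unname(lg[["B"]]), "b")
  expect_equal(unname(lg[["C"]]), "b")
  # nothing significant -> everyone shares one letter
  lg2 <- letter_grouping(mk(rep(0.9, 3), c("A", "B", "C")), alpha = 0.05)
  expect_true(all(lg2 == "a"))
  # everything significant -> distinct single letters
  lg3 <- letter_grouping(mk(rep(0.001, 3), c("A", "B", "C")), alpha = 0.05)
  expect_equal(sort(unname(as.character(lg3))), c("a", "b", "c"))
})

test_that("letter assignments satisfy the sharing iff-invariant on random matrices", {
  set.seed(31)
  for (i in 1:60) {
    k <- sample(3:6, 1)
    arms <- paste0("arm", seq_len(k))
    p <- matrix(NA_real_, k, k, dimnames = list(arms, arms))
    v <- runif(k * (k - 1) / 2)^2 # skew towards small p so splits happen
    p[upper.tri(p)] <- v
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
    lg <- letter_grouping(p, alpha = 0.05)
    expect_true(letters_satisfy_iff(p, lg, 0.05))
  }
})

test_that("letters merge into the endpoint table row-by-species", {
  rec <- reconstruct_trial_records("both")
  et <- summarize_trial(aggregate_arms(rec), "untreated")
  pm <- compare_proportions(rec, "mortality", species = "An. arabiensis")
  et2 <- attach_letters(et, letter_grouping(pm), "mortality",
                        species = "An. arabiensis")
  ar <- et2[et2$species == "An. arabiensis", ]
  expect_true(all(!is.na(ar$mortality_letters)))
  expect_true(all(is.na(et2$mortality_letters[et2$species != "An. arabiensis"])))
})
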