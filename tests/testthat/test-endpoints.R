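test_that("endpoint formulas reproduce published single-cell values", {
  # deterrence
  expect_equal(round_half_up(deterrence(76, 222)), 65.8)
  expect_equal(deterrence(533, 483), 0) # negative entry reduction truncates
  expect_equal(deterrence(100, 100), 0)
  # exiting
  expect_equal(round_half_up(exiting_proportion(200, 222)), 90.1)
  expect_equal(round_half_up(exiting_proportion(392, 483)), 81.2)
  expect_equal(exiting_proportion(0, 10), 0)
  # Abbott-corrected mortality
  expect_equal(round_half_up(corrected_mortality(26, 38, 6, 97)), 66.3)
  expect_equal(round_half_up(corrected_mortality(183, 573, 15, 483)), 29.8)
  expect_equal(corrected_mortality(10, 100, 5, 50), 0) # p_t == p_u
  # overall killing effect
  expect_equal(round_half_up(killing_effect(233, 15, 483)), 45.1)
  expect_equal(round_half_up(killing_effect(92, 8, 222)), 37.8)
  expect_equal(killing_effect(12, 12, 100), 0)
  # blood-feeding inhibition
  expect_equal(round_half_up(blood_feeding_inhibition(44, 533, 131, 483)), 69.6)
  expect_equal(blood_feeding_inhibition(88, 218, 81, 222), 0) # negative truncates
  expect_equal(blood_feeding_inhibition(10, 100, 5, 50), 0)
  # personal protection
  expect_equal(round_half_up(personal_protection(3, 48)), 93.8)
  expect_equal(round_half_up(personal_protection(40, 131)), 69.5)
  expect_equal(personal_protection(7, 7), 0)
})

test_that("undefined endpoints raise errors rather than NaN", {
  expect_error(deterrence(10, 0), "undefined")
  expect_error(exiting_proportion(0, 0), "undefined")
  expect_error(corrected_mortality(5, 10, 50, 50), "undefined")
  expect_error(killing_effect(5, 2, 0), "undefined")
  expect_error(blood_feeding_inhibition(1, 10, 0, 50), "undefined")
  expect_error(personal_protection(3, 0), "undefined")
})

test_that("truncation reports zero but the raw signed value survives", {
  expect_equal(deterrence(533, 483), 0)
  expect_lt(deterrence(533, 483, truncate = FALSE), 0)
  rec <- reconstruct_trial_records("moshi")
  et <- summarize_trial(aggregate_arms(rec), "untreated")
  icon20 <- et[et$arm == "icon_washed20", ]
  expect_equal(icon20$deterrence_pct, 0)
  expect_lt(icon20$deterrence_raw, 0)
})

test_that("monotonicity: more treated deaths raise corrected mortality, more entries lower deterrence", {
  cm <- vapply(10:60, function(k) corrected_mortality(k, 80, 5, 100), numeric(1))
  expect_true(all(diff(cm) > 0))
  det <- vapply(seq(10, 300, by = 10), function(t) {
    deterrence(t, 200, truncate = FALSE)
  }, numeric(1))
  expect_true(all(diff(det) < 0))
})

test_that("an arm identical to the control scores zero on every comparative endpoint", {
  rec <- reconstruct_trial_records("moshi")
  clone <- rec[rec$arm == "untreated", ]
  clone$arm <- "clone"
  clone$hut <- paste0(clone$hut, "b")
  et <- summarize_trial(aggregate_arms(dplyr::bind_rows(rec, clone)), "untreated")
  cl <- et[et$arm == "clone", ]
  expect_equal(cl$deterrence_pct, 0)
  expect_equal(cl$corrected_mortality_pct, 0)
  expect_equal(cl$killing_effect_pct, 0)
  expect_equal(cl$bfi_pct, 0)
  expect_equal(cl$personal_protection_pct, 0)
})

test_that("trial summary reports the published average catch per night", {
  rec <- reconstruct_trial_records("both")
  et <- summarize_trial(aggregate_arms(rec), "untreated")
  ar <- et[et$species == "An. arabiensis" & et$arm == "untreated", ]
  expect_equal(round_half_up(ar$avg_catch_per_night), 20.1)
  fu <- et[et$species == "An. funestus" & et$arm == "untreated", ]
  expect_equal(round_half_up(fu$avg_catch_per_night), 6.2)
  # control rows score zero by construction
  ctl <- et[et$is_control, ]
  expect_true(all(ctl$deterrence_pct == 0))
  expect_true(all(ctl$corrected_mortality_pct == 0))
  expect_true(all(ctl$bfi_pct == 0))
  expect_true(all(ctl$personal_protection_pct == 0))
  expect_true(all(ctl$killing_effect_pct == 0))
})

test_that("a control-only dataset yields a populated row with zero comparative endpoints", {
  rec <- reconstruct_trial_records("moshi")
  et <- summarize_trial(aggregate_arms(rec[rec$arm == "untreated", ]), "untreated")
  expect_equal(nrow(et), 1)
  expect_equal(et$total_caught, 483)
  expect_equal(et$deterrence_pct, 0)
  expect_equal(et$personal_protection_pct, 0)
  expect_error(summarize_trial(aggregate_arms(rec), "no_such_arm"),
               "configuration error")
})

test_that("half-up rounding matches report conventions where base round() differs", {
  expect_equal(round_half_up(93.75, 1), 93.8)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(65.77, 0), 66)
  expect_equal(round_half_up(-1.25, 1), -1.3)
})

test_that("rendered endpoint table carries rounded values and letters", {
  rec <- reconstruct_trial_records("moshi")
  et <- summarize_trial(aggregate_arms(rec), "untreated")
  et <- attach_letters(
    et, structure(setNames(rep("a", nrow(et)), et$arm),
                  class = "letter_assignment"),
    "corrected_mortality", species = "An. arabiensis")
  md <- format_endpoint_table(et)
  expect_true(any(grepl("% mortality corrected for control", md)))
  expect_true(any(grepl("20.1", md, fixed = TRUE)))
  expect_true(any(grepl("\\^a\\^", md)))
})
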