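# Published endpoint values of the 2008 Tanzania hut trials, to the printed
# precision (digits = decimal places as printed). Cells flagged `excluded`
# are inconsistent with the defining formulas applied to the published
# counts (documented in the methods vignette) and are not reproduction
# targets.
printed_endpoint_values <- function() {
  arms4 <- c("icon_unwashed", "icon_washed20", "ctn_cutoff", "ctn_washed20")
  arms5 <- c("untreated", arms4)
  long <- function(species, endpoint, arms, printed, digits, excluded = FALSE) {
    tibble::tibble(species = species, endpoint = endpoint, arm = arms,
                   printed = printed, digits = digits,
                   excluded = rep_len(excluded, length(arms)))
  }
  dplyr::bind_rows(
    long("An. funestus", "avg_catch_per_night", arms5,
         c(6.2, 3.4, 2.1, 4.6, 6.1), 1),
    long("An. gambiae", "avg_catch_per_night", arms5,
         c(2.7, 1.1, 1.1, 1.6, 2.4), 1),
    long("An. arabiensis", "avg_catch_per_night", arms5,
         c(20.1, 15.4, 22.2, 23.9, 17.7), 1),
    long("An. funestus", "deterrence_pct", arms4,
         c(45, 65.8, 24.8, 1.8), c(0, 1, 1, 1)),
    long("An. gambiae", "deterrence_pct", arms4,
         c(57.7, 60.8, 41.2, 12.4), 1),
    long("An. arabiensis", "deterrence_pct", arms4,
         c(23.6, 0, 0, 12.2), c(1, 0, 0, 1)),
    long("An. funestus", "exiting_pct", arms5,
         c(90.1, 86.9, 93.4, 98.2, 91.7), 1),
    long("An. gambiae", "exiting_pct", arms5,
         c(81.4, 82.9, 86.8, 98.3, 88.2), 1,
         excluded = c(FALSE, FALSE, FALSE, TRUE, FALSE)),
    long("An. arabiensis", "exiting_pct", arms5,
         c(81.2, 86.4, 88.0, 78.5, 83.0), 1),
    long("An. funestus", "corrected_mortality_pct", arms4,
         c(74.6, 57.7, 51.6, 39.6), 1,
         excluded = c(TRUE, FALSE, TRUE, FALSE)),
    long("An. gambiae", "corrected_mortality_pct", arms4,
         c(71.4, 66.3, 32.7, 39.8), 1),
    long("An. arabiensis", "corrected_mortality_pct", arms4,
         c(47.4, 41.9, 29.8, 35.7), 1),
    long("An. funestus", "killing_effect_pct", arms4,
         c(37.8, 16.7, 34.5, 37.4), 1,
         excluded = c(FALSE, FALSE, TRUE, FALSE)),
    long("An. gambiae", "killing_effect_pct", arms4,
         c(30.4, 25.3, 19, 39.2), c(1, 1, 0, 1), excluded = TRUE),
    long("An. arabiensis", "killing_effect_pct", arms4,
         c(34.4, 45.1, 34.8, 30), c(1, 1, 1, 0)),
    long("An. funestus", "bfi_pct", arms4,
         c(48.3, 27.9, 32.7, 0), c(1, 1, 1, 0)),
    long("An. gambiae", "bfi_pct", arms4,
         c(85.2, 46.8, 11.3, 19.2), 1,
         excluded = c(FALSE, FALSE, TRUE, FALSE)),
    long("An. arabiensis", "bfi_pct", arms4,
         c(60, 69.6, 66.5, 53), c(0, 1, 1, 0)),
    long("An. funestus", "personal_protection_pct", arms4,
         c(71.6, 75.3, 49.2, 0), c(1, 1, 1, 0),
         excluded = c(FALSE, FALSE, TRUE, FALSE)),
    long("An. gambiae", "personal_protection_pct", arms4,
         c(93.8, 79.2, 47.9, 29.2), 1),
    long("An. arabiensis", "personal_protection_pct", arms4,
         c(69.5, 66.4, 60.3, 58.8), 1)
  )
}
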