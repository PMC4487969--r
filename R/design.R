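#' Generate a Latin-square rotation plan for a hut trial
#'
#' Treatment arms are rotated once through each hut: the core plan is a
#' row-randomised cyclic Latin square of arms over huts (one row per
#' rotation period), so each arm occupies each hut for exactly
#' `nights_per_period` nights over the core rotation. Sleepers rotate
#' cyclically through the huts every night. Net replicates within an arm are
#' cycled every two nights (`net_index` in the schedule). Huts are cleaned
#' and aired between periods; those washout nights are calendar gaps, not
#' analysis nights, and are recorded only as `washout_nights` metadata.
#'
#' When `n_periods` exceeds the number of arms, the plan appends extra
#' periods that re-use the square's rows cyclically (a trial may run longer
#' than one full rotation); the strict Latin-square invariants then apply to
#' the core square only.
#'
#' @param n_arms Number of treatment arms (>= 2).
#' @param nights_per_period Nights each arm stays in a hut before rotating.
#' @param n_huts Number of huts; must equal `n_arms` (incomplete designs are
#'   unsupported).
#' @param n_periods Number of rotation periods (default `n_arms`, the exact
#'   Latin square; must be >= `n_arms`).
#' @param seed Optional seed for the row randomisation; a fixed seed gives
#'   an identical plan on every call.
#' @param arms,huts,sleepers Optional label vectors.
#' @param washout_nights Cleaning nights between periods (metadata; default 1).
#' @return An object of class `rotation_plan`: list with the label vectors,
#'   the `square` (periods x huts arm matrix) and a `schedule` tibble
#'   (night, period, night_in_period, hut, arm, sleeper, net_index).
#' @export
generate_rotation <- function(n_arms, nights_per_period, n_huts = n_arms,
                              n_periods = n_arms, seed = NULL,
                              arms = paste0("arm", seq_len(n_arms)),
                              huts = paste0("H", seq_len(n_huts)),
                              sleepers = paste0("S", seq_len(n_huts)),
                              washout_nights = 1) {
  if (n_arms < 2) abort("a rotation needs at least two arms")
  if (n_huts != n_arms) {
    abort("unsupported design: the rotation requires as many huts as arms")
  }
  if (n_periods < n_arms) {
    abort("unsupported design: n_periods below n_arms leaves the rotation incomplete")
  }
  if (nights_per_period < 1) abort("nights_per_period must be >= 1")
  row_order <- with_seed(seed, sample.int(n_arms))
  square <- matrix(NA_character_, n_periods, n_huts,
                   dimnames = list(paste0("P", seq_len(n_periods)), huts))
  for (p in seq_len(n_periods)) {
    off <- row_order[(p - 1) %% n_arms + 1]
    for (h in seq_len(n_huts)) {
      square[p, h] <- arms[(off + h - 2) %% n_arms + 1]
    }
  }
  n_nights <- n_periods * nights_per_period
  sched <- expand.grid(hut_i = seq_len(n_huts), night = seq_len(n_nights))
  sched$period <- (sched$night - 1) %/% nights_per_period + 1
  sched$night_in_period <- (sched$night - 1) %% nights_per_period + 1
  sched$hut <- huts[sched$hut_i]
  sched$arm <- square[cbind(sched$period, sched$hut_i)]
  sched$sleeper <- sleepers[(sched$hut_i + sched$night - 2) %% length(sleepers) + 1]
  sched$net_index <- (sched$night_in_period - 1) %/% 2 + 1
  structure(
    list(
      n_arms = n_arms, n_huts = n_huts, n_periods = n_periods,
      nights_per_period = nights_per_period, washout_nights = washout_nights,
      arms = arms, huts = huts, sleepers = sleepers, square = square,
      schedule = tibble::as_tibble(
        sched[, c("night", "period", "night_in_period", "hut", "arm",
                  "sleeper", "net_index")]
      )
    ),
    class = "rotation_plan"
  )
}

#' @export
print.rotation_plan <- function(x, ...) {
  cat(sprintf(
    "<rotation_plan> %d arms x %d huts, %d period(s) of %d night(s) (%d analysis nights)\n",
    x$n_arms, x$n_huts, x$n_periods, x$nights_per_period,
    nrow(x$schedule) / x$n_huts
  ))
  print(x$square)
  invisible(x)
}

#' Validate a rotation plan
#'
#' Checks the Latin-square invariants on the core square (each arm exactly
#' once per period and exactly once per hut over the first `n_arms`
#' periods), night accounting in the schedule, per-(arm, hut) balance, and
#' sleeper coverage (each sleeper should occupy each hut at least once over
#' the plan; a shortfall is a warning since short plans cannot achieve it).
#'
#' @param plan A `rotation_plan`.
#' @return A [validation_report()].
#' @export
validate_rotation <- function(plan) {
  entries <- list()
  add <- function(locator, rule, message, severity = "error") {
    entries[[length(entries) + 1]] <<- tibble::tibble(
      locator = locator, rule = rule, message = message, severity = severity
    )
  }
  core <- plan$square[seq_len(plan$n_arms), , drop = FALSE]
  for (p in seq_len(nrow(core))) {
    if (!setequal(core[p, ], plan$arms) || anyDuplicated(core[p, ])) {
      add(sprintf("period %d", p), "latin_rows",
          "each arm must appear exactly once per period")
    }
  }
  for (h in seq_len(ncol(core))) {
    if (!setequal(core[, h], plan$arms) || anyDuplicated(core[, h])) {
      add(sprintf("hut %s", plan$huts[h]), "latin_columns",
          "each arm must appear exactly once per hut over the core rotation")
    }
  }
  expected_nights <- plan$n_periods * plan$nights_per_period
  sched_nights <- length(unique(plan$schedule$night))
  if (sched_nights != expected_nights) {
    add("schedule", "night_accounting",
        sprintf("schedule has %d nights; expected %d", sched_nights, expected_nights))
  }
  core_sched <- plan$schedule[plan$schedule$period <= plan$n_arms, ]
  bal <- table(core_sched$arm, core_sched$hut)
  if (nrow(bal) > 0 && any(bal != plan$nights_per_period)) {
    add("schedule", "arm_hut_balance",
        "each (arm, hut) pair must contribute exactly nights_per_period nights in the core rotation")
  }
  cover <- table(plan$schedule$sleeper, plan$schedule$hut)
  if (any(cover == 0)) {
    add("schedule", "sleeper_coverage",
        "some sleeper never occupies some hut under this plan",
        severity = "warning")
  }
  validation_report(if (length(entries) > 0) dplyr::bind_rows(entries) else NULL)
}
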