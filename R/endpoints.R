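#' Entomological endpoints of an experimental hut trial
#'
#' The six standard WHOPES Phase-II endpoints, each expressed as a
#' percentage. Symbols follow field convention: `Tt`/`Tu` total caught in
#' treated/untreated (control) huts, `Kt`/`Ku` total dead, `Bt`/`Bu` total
#' blood-fed, `E` total exiting into verandah or window traps.
#'
#' * **Deterrence**: `100 (Tu - Tt) / Tu`, the reduction in hut entry caused
#'   by the treatment.
#' * **Exiting**: `100 E / T`, the proportion of the catch found in exit
#'   traps (induced exophily is judged by comparing arms).
#' * **Corrected mortality**: Abbott's control correction
#'   `100 (pt - pu) / (1 - pu)` with `pt = Kt/Tt`, `pu = Ku/Tu`.
#' * **Overall killing effect**: `100 (Kt - Ku) / Tu`, treated-arm excess
#'   deaths as a fraction of the control catch. May legitimately exceed raw
#'   mortality only when deterrence is negative.
#' * **Blood-feeding inhibition**: `100 (1 - (Bt/Tt) / (Bu/Tu))`, the
#'   proportional reduction of the blood-fed fraction.
#' * **Personal protection**: `100 (Bu - Bt) / Bu`, the reduction in the
#'   absolute number of blood-fed mosquitoes.
#'
#' Comparative endpoints are truncated at 0 for reporting (a published table
#' prints "0" where entry was higher in the treated arm); pass
#' `truncate = FALSE` to obtain the raw signed value.
#'
#' @param t_treated,t_control Total caught in the treated / control arm.
#' @param k_t,k_u Total dead in the treated / control arm.
#' @param b_t,b_u Total blood-fed in the treated / control arm.
#' @param t_t,t_u Total caught in the treated / control arm.
#' @param e,t Total exiting and total caught for one arm.
#' @param truncate Truncate negative values to 0 (default `TRUE`).
#' @return A percentage (numeric, vectorised over its count arguments).
#' @name endpoints
NULL

#' @rdname endpoints
#' @export
deterrence <- function(t_treated, t_control, truncate = TRUE) {
  assert_scalar_count(t_treated, "t_treated")
  assert_scalar_count(t_control, "t_control")
  if (any(t_control == 0)) {
    abort("undefined endpoint: deterrence requires a control catch > 0")
  }
  v <- 100 * (t_control - t_treated) / t_control
  if (truncate) pmax(v, 0) else v
}

#' @rdname endpoints
#' @export
exiting_proportion <- function(e, t) {
  assert_scalar_count(e, "e")
  assert_scalar_count(t, "t")
  if (any(t == 0)) {
    abort("undefined endpoint: exiting requires a total catch > 0")
  }
  100 * e / t
}

#' @rdname endpoints
#' @export
corrected_mortality <- function(k_t, t_t, k_u, t_u, truncate = TRUE) {
  assert_scalar_count(k_t, "k_t"); assert_scalar_count(t_t, "t_t")
  assert_scalar_count(k_u, "k_u"); assert_scalar_count(t_u, "t_u")
  if (any(t_t == 0) || any(t_u == 0)) {
    abort("undefined endpoint: corrected mortality requires catches > 0 in both arms")
  }
  p_t <- k_t / t_t
  p_u <- k_u / t_u
  if (any(p_u >= 1)) {
    abort("undefined endpoint: control mortality of 100% leaves no room for correction")
  }
  v <- 100 * (p_t - p_u) / (1 - p_u)
  if (truncate) pmax(v, 0) else v
}

#' @rdname endpoints
#' @export
killing_effect <- function(k_t, k_u, t_u, truncate = TRUE) {
  assert_scalar_count(k_t, "k_t"); assert_scalar_count(k_u, "k_u")
  assert_scalar_count(t_u, "t_u")
  if (any(t_u == 0)) {
    abort("undefined endpoint: killing effect requires a control catch > 0")
  }
  v <- 100 * (k_t - k_u) / t_u
  if (truncate) pmax(v, 0) else v
}

#' @rdname endpoints
#' @export
blood_feeding_inhibition <- function(b_t, t_t, b_u, t_u, truncate = TRUE) {
  assert_scalar_count(b_t, "b_t"); assert_scalar_count(t_t, "t_t")
  assert_scalar_count(b_u, "b_u"); assert_scalar_count(t_u, "t_u")
  if (any(t_t == 0) || any(t_u == 0)) {
    abort("undefined endpoint: BFI requires catches > 0 in both arms")
  }
  if (any(b_u == 0)) {
    abort("undefined endpoint: BFI requires blood-feeding in the control arm")
  }
  v <- 100 * (1 - (b_t / t_t) / (b_u / t_u))
  if (truncate) pmax(v, 0) else v
}

#' @rdname endpoints
#' @export
personal_protection <- function(b_t, b_u, truncate = TRUE) {
  assert_scalar_count(b_t, "b_t"); assert_scalar_count(b_u, "b_u")
  if (any(b_u == 0)) {
    abort("undefined endpoint: personal protection requires blood-feeding in the control arm")
  }
  v <- 100 * (b_u - b_t) / b_u
  if (truncate) pmax(v, 0) else v
}

#' Assemble the full endpoint table for a trial
#'
#' Applies all six endpoints to arm-level summaries, using the designated
#' control arm of each species as the reference. Comparative endpoints are
#' reported truncated at 0; the raw signed values are kept alongside in
#' `*_raw` columns so that no information is lost to truncation.
#'
#' @param summaries Arm-level summaries from [aggregate_arms()].
#' @param control_arm Identifier of the untreated control arm; must be
#'   present for every species in `summaries`.
#' @return A tibble (one row per arm x species) with the summary totals,
#'   `avg_catch_per_night`, `mortality_pct` (raw, uncorrected),
#'   `exiting_pct`, and the comparative endpoints `deterrence_pct`,
#'   `corrected_mortality_pct`, `killing_effect_pct`, `bfi_pct`,
#'   `personal_protection_pct` plus their `_raw` twins.
#' @export
summarize_trial <- function(summaries, control_arm) {
  out <- vector("list", length(unique(summaries$species)))
  for (i in seq_along(sp_all <- sort(unique(summaries$species)))) {
    sp <- sp_all[i]
    s <- summaries[summaries$species == sp, , drop = FALSE]
    cu <- s[s$arm == control_arm, , drop = FALSE]
    if (nrow(cu) != 1) {
      abort(sprintf("configuration error: control arm `%s` missing for species `%s`",
                    control_arm, sp))
    }
    t_u <- cu$total_caught; k_u <- cu$total_dead; b_u <- cu$total_fed
    s$avg_catch_per_night <- s$total_caught / s$n_nights
    s$mortality_pct <- ifelse(s$total_caught > 0,
                              100 * s$total_dead / s$total_caught, NA_real_)
    s$exiting_pct <- ifelse(s$total_caught > 0,
                            100 * s$total_exited / s$total_caught, NA_real_)
    s$deterrence_raw <- deterrence(s$total_caught, t_u, truncate = FALSE)
    s$corrected_mortality_raw <- corrected_mortality(
      s$total_dead, s$total_caught, k_u, t_u, truncate = FALSE)
    s$killing_effect_raw <- killing_effect(s$total_dead, k_u, t_u, truncate = FALSE)
    s$bfi_raw <- blood_feeding_inhibition(
      s$total_fed, s$total_caught, b_u, t_u, truncate = FALSE)
    s$personal_protection_raw <- personal_protection(s$total_fed, b_u,
                                                     truncate = FALSE)
    for (ep in c("deterrence", "corrected_mortality", "killing_effect",
                 "bfi", "personal_protection")) {
      s[[paste0(ep, "_pct")]] <- pmax(s[[paste0(ep, "_raw")]], 0)
    }
    s$is_control <- s$arm == control_arm
    out[[i]] <- s
  }
  res <- dplyr::bind_rows(out)
  attr(res, "control_arm") <- control_arm
  res
}

#' Render an endpoint table as Markdown
#'
#' Rounds to `digits` decimals half-up (matching how field reports print
#' endpoint tables) and lays arms out as columns per species. Significance
#' letters, when present as `<endpoint>_letters` columns, are appended as
#' superscript-style suffixes.
#'
#' @param et An endpoint table from [summarize_trial()].
#' @param digits Decimal places for the rendered values (default 1).
#' @return A character vector of Markdown lines.
#' @export
format_endpoint_table <- function(et, digits = 1) {
  rows <- c(
    avg_catch_per_night = "Average catch per night",
    total_caught = "Total females caught",
    deterrence_pct = "% deterrence",
    total_exited = "Total females exiting",
    exiting_pct = "% exiting",
    total_dead = "Total dead",
    corrected_mortality_pct = "% mortality corrected for control",
    killing_effect_pct = "% overall killing effect",
    total_fed = "Total blood-fed",
    bfi_pct = "% blood-feeding inhibition",
    personal_protection_pct = "% personal protection"
  )
  lines <- character()
  for (sp in unique(et$species)) {
    s <- et[et$species == sp, , drop = FALSE]
    lines <- c(lines, sprintf("### %s", sp), "",
               paste0("| | ", paste(s$arm, collapse = " | "), " |"),
               paste0("|---", strrep("|---", nrow(s)), "|"))
    for (key in names(rows)) {
      vals <- s[[key]]
      txt <- if (is.integer(vals) || key %in% c("total_caught", "total_exited",
                                                "total_dead", "total_fed")) {
        format(vals)
      } else {
        format(round_half_up(vals, digits))
      }
      lk <- paste0(sub("_pct$", "", key), "_letters")
      if (lk %in% names(s)) txt <- paste0(txt, " ^", s[[lk]], "^")
      lines <- c(lines, paste0("| ", rows[[key]], " | ",
                               paste(txt, collapse = " | "), " |"))
    }
    lines <- c(lines, "")
  }
  lines
}
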