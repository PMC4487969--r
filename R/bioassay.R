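#' Read a serial cone-bioassay table
#'
#' One row per wash x replicate, with columns `net`, `wash`, `replicate`,
#' `n_exposed`, `n_kd60` (knocked down at 60 min; may be `NA` throughout if
#' knockdown was not scored) and `n_dead24` (dead at 24 h). The standard
#' WHOPES series exposes ten replicates of five susceptible mosquitoes for
#' 3 min on five net panels after each wash.
#'
#' @param path CSV file path.
#' @return A tibble of replicate-level bioassay results.
#' @export
read_bioassay_series <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("net", "wash", "replicate", "n_exposed", "n_kd60", "n_dead24")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("bioassay schema error: missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bad <- which(df$n_dead24 > df$n_exposed |
                 (!is.na(df$n_kd60) & df$n_kd60 > df$n_exposed))
  if (length(bad) > 0) {
    abort(sprintf("bioassay validation error: row %d: outcome exceeds n_exposed", bad[1]))
  }
  df
}

#' Pooled knockdown and mortality at one wash point
#'
#' Percentages are pooled across replicates (sum of outcomes over sum of
#' exposed), the convention for 10 x 5 cone series.
#'
#' @param series Replicate-level bioassay tibble (see
#'   [read_bioassay_series()]).
#' @param wash Wash number to summarise.
#' @return A list with elements `knockdown_pct` (`NA` if knockdown was not
#'   scored), `mortality_pct`, `n_exposed`.
#' @export
cone_summary <- function(series, wash) {
  s <- series[series$wash == wash, , drop = FALSE]
  if (nrow(s) == 0) {
    abort(sprintf("wash %s not present in the bioassay series", wash))
  }
  n <- sum(s$n_exposed)
  if (n == 0) abort("total exposed is zero at this wash")
  kd <- if (all(is.na(s$n_kd60))) NA_real_ else 100 * sum(s$n_kd60, na.rm = TRUE) / n
  list(
    knockdown_pct = kd,
    mortality_pct = 100 * sum(s$n_dead24) / n,
    n_exposed = n
  )
}

#' Determine the wash-resistance cut-off (point of insecticide exhaustion)
#'
#' The cut-off is the smallest wash number at which the net no longer meets
#' the cone-bioassay efficacy criterion: pooled mortality below
#' `mortality_threshold` or pooled knockdown below `kd_threshold`. If no
#' wash in the series fails, the series has not reached exhaustion and
#' `NA_integer_` is returned.
#'
#' @param series Replicate-level bioassay tibble; must include wash 0.
#' @param mortality_threshold Mortality criterion in percent (default 80).
#' @param kd_threshold Knockdown criterion in percent (default 95). Applied
#'   only when knockdown was scored; a mortality-only series is allowed with
#'   a warning.
#' @return The cut-off wash number (integer), or `NA_integer_` if the
#'   criterion never fails within the series.
#' @export
determine_cutoff <- function(series, mortality_threshold = 80, kd_threshold = 95) {
  if (nrow(series) == 0) abort("empty bioassay series")
  for (th in c(mortality_threshold, kd_threshold)) {
    if (!is.numeric(th) || th <= 0 || th > 100) {
      abort("thresholds must lie in (0, 100]")
    }
  }
  washes <- sort(unique(series$wash))
  if (washes[1] != 0) abort("bioassay series must include the unwashed (wash 0) point")
  has_kd <- !all(is.na(series$n_kd60))
  if (!has_kd) {
    warn("no knockdown data in series; cut-off determined from mortality alone")
  }
  for (w in washes) {
    cs <- cone_summary(series, w)
    fail <- cs$mortality_pct < mortality_threshold ||
      (has_kd && !is.na(cs$knockdown_pct) && cs$knockdown_pct < kd_threshold)
    if (fail) return(as.integer(w))
  }
  NA_integer_
}

#' Bootstrap confidence interval for the wash cut-off
#'
#' Resamples replicates with replacement within each wash and recomputes the
#' cut-off; percentile interval. A resample in which the criterion never
#' fails is treated as censored above the largest wash number.
#'
#' @inheritParams determine_cutoff
#' @param n_boot Number of bootstrap resamples (default 500).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed (required; the resampling is the only randomness).
#' @return A list with `estimate`, `lower`, `upper`, `n_boot`.
#' @export
cutoff_bootstrap_ci <- function(series, mortality_threshold = 80,
                                kd_threshold = 95, n_boot = 500,
                                level = 0.95, seed = 1) {
  est <- determine_cutoff(series, mortality_threshold, kd_threshold)
  max_w <- max(series$wash)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      res <- dplyr::group_modify(
        dplyr::group_by(series, .data$wash),
        ~ .x[sample(nrow(.x), replace = TRUE), , drop = FALSE]
      )
      w <- suppressWarnings(
        determine_cutoff(dplyr::ungroup(res), mortality_threshold, kd_threshold))
      if (is.na(w)) max_w + 1 else as.numeric(w)
    }, numeric(1))
  })
  qs <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  list(
    estimate = est,
    lower = qs[1],
    upper = qs[2],
    upper_censored = qs[2] > max_w, # criterion never failed in some resamples
    n_boot = n_boot
  )
}

#' Summarise a tunnel test
#'
#' Overnight baited-tunnel assay through holed netting: all three outcome
#' proportions use the number of mosquitoes released as the denominator.
#'
#' @param n_released Females released into the tunnel (> 0).
#' @param n_penetrated Number found beyond the netting (bait side).
#' @param n_fed Number blood-fed.
#' @param n_dead Number dead, immediate plus 24-h delayed.
#' @return A list with `penetration_pct`, `feeding_pct`, `mortality_pct`.
#' @export
tunnel_summary <- function(n_released, n_penetrated, n_fed, n_dead) {
  assert_scalar_count(n_released, "n_released")
  if (any(n_released == 0)) abort("tunnel test requires n_released > 0")
  for (x in list(n_penetrated, n_fed, n_dead)) {
    if (any(x > n_released)) abort("tunnel outcome exceeds the number released")
  }
  list(
    penetration_pct = 100 * n_penetrated / n_released,
    feeding_pct = 100 * n_fed / n_released,
    mortality_pct = 100 * n_dead / n_released
  )
}

#' Insecticide retention after washing
#'
#' Retention index: the percentage of the initial surface concentration
#' (mg AI/m^2) remaining after a washing series; removal is its complement,
#' so `retained + removed == 100` exactly.
#'
#' @param c0 Initial concentration in mg/m^2 (> 0).
#' @param c_after Concentration after washing, mg/m^2 (>= 0).
#' @return A list with `retained_pct` and `removed_pct`.
#' @export
retention_index <- function(c0, c_after) {
  if (!is.numeric(c0) || any(c0 <= 0)) abort("initial concentration must be > 0")
  if (!is.numeric(c_after) || any(c_after < 0)) {
    abort("post-wash concentration must be >= 0")
  }
  retained <- 100 * c_after / c0
  list(retained_pct = retained, removed_pct = 100 - retained)
}
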