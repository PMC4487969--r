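#' Generative parameters for a simulated hut trial
#'
#' The count-level generative model: on each hut-night the number of
#' mosquitoes entering is negative binomial with mean
#' `mu * (1 - deterrence_arm) * hut_effect * sleeper_effect` and dispersion
#' `k`; each entering mosquito then independently dies (probability
#' `p_death`), blood-feeds (`p_feed`) and exits into a trap (`p_exit`).
#' Hut and sleeper effects are multiplicative log-normal with log-scale
#' standard deviations `sigma_hut` and `sigma_sleeper`. An optional Gaussian
#' copula (`rho`) correlates the three per-mosquito Bernoulli draws for
#' sensitivity analyses; the default is independence.
#'
#' Negative `deterrence` (attraction to the treated hut) is admitted: field
#' tables truncate it to zero in print, but the generative scale is signed.
#'
#' @param arms A data frame with columns `arm`, `deterrence` (in (-1, 1)),
#'   `p_death`, `p_feed`, `p_exit` (probabilities). The control arm must
#'   have `deterrence = 0`.
#' @param mu Control-arm entry rate, mosquitoes per hut per night (> 0).
#' @param k Negative-binomial dispersion (size) of nightly entries (> 0);
#'   nightly hut catches are overdispersed, so the default is a moderately
#'   overdispersed `k = 5` rather than Poisson.
#' @param sigma_hut,sigma_sleeper Log-normal scale of hut and sleeper
#'   effects (0 disables them).
#' @param rho Gaussian-copula correlation among the death/feed/exit draws
#'   (default 0 = independent).
#' @param nights_per_period,n_periods Rotation geometry passed to
#'   [generate_rotation()]; defaults give one full Latin square.
#' @param species Species label stamped on the simulated records.
#' @param control_arm Which arm is the untreated control (default: the arm
#'   with zero deterrence, or the first arm).
#' @param seed Mandatory RNG seed; simulation output is byte-identical for
#'   identical parameter sets including the seed.
#' @return An object of class `trial_params`.
#' @export
trial_params <- function(arms, mu, k = 5, sigma_hut = 0.25,
                         sigma_sleeper = 0.25, rho = 0,
                         nights_per_period = 6, n_periods = nrow(arms),
                         species = "An. gambiae (simulated)",
                         control_arm = NULL, seed = 1) {
  arms <- tibble::as_tibble(arms)
  need <- c("arm", "deterrence", "p_death", "p_feed", "p_exit")
  missing <- setdiff(need, names(arms))
  if (length(missing) > 0) {
    abort(sprintf("parameter error: arms table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  for (pc in c("p_death", "p_feed", "p_exit")) {
    if (any(is.na(arms[[pc]])) || any(arms[[pc]] < 0) || any(arms[[pc]] > 1)) {
      abort(sprintf("parameter error: `%s` must lie in [0, 1]", pc))
    }
  }
  if (any(abs(arms$deterrence) >= 1)) {
    abort("parameter error: deterrence must lie in (-1, 1)")
  }
  if (!is.numeric(mu) || mu <= 0) abort("parameter error: mu must be > 0")
  if (!is.numeric(k) || k <= 0) abort("parameter error: k must be > 0")
  if (abs(rho) > 0.99) abort("parameter error: |rho| must be <= 0.99")
  control_arm <- control_arm %||%
    (if (any(arms$deterrence == 0)) arms$arm[arms$deterrence == 0][1] else arms$arm[1])
  if (!control_arm %in% arms$arm) abort("parameter error: control arm not in arms table")
  if (arms$deterrence[arms$arm == control_arm] != 0) {
    abort("parameter error: the control arm must have deterrence = 0")
  }
  if (is.null(seed)) abort("parameter error: a seed is mandatory")
  structure(
    list(arms = arms, mu = mu, k = k, sigma_hut = sigma_hut,
         sigma_sleeper = sigma_sleeper, rho = rho,
         nights_per_period = nights_per_period, n_periods = n_periods,
         species = species, control_arm = control_arm, seed = seed),
    class = "trial_params"
  )
}

#' Simulate a complete hut-trial dataset
#'
#' Draws a rotation plan, hut and sleeper effects and per-hut-night catches
#' under the generative model of [trial_params()], and returns records in
#' the canonical 12-cell format, ready for [aggregate_arms()] and
#' [summarize_trial()]. Conservation holds exactly per record:
#' dead + alive = fed + unfed = room + traps = caught. Exiting mosquitoes
#' split evenly at random between the verandah and window traps.
#'
#' @param params A [trial_params()] object.
#' @return A tibble of hut records.
#' @export
simulate_trial <- function(params) {
  stopifnot(inherits(params, "trial_params"))
  with_seed(params$seed, {
    n_arms <- nrow(params$arms)
    plan <- generate_rotation(
      n_arms, params$nights_per_period, n_periods = params$n_periods,
      arms = params$arms$arm
    )
    sched <- plan$schedule
    hut_eff <- setNames(exp(rnorm(plan$n_huts, 0, params$sigma_hut)), plan$huts)
    slp_eff <- setNames(exp(rnorm(length(plan$sleepers), 0, params$sigma_sleeper)),
                        plan$sleepers)
    ai <- match(sched$arm, params$arms$arm)
    lambda <- params$mu * (1 - params$arms$deterrence[ai]) *
      hut_eff[sched$hut] * slp_eff[sched$sleeper]
    n_i <- rnbinom(nrow(sched), size = params$k, mu = lambda)
    idx <- rep(seq_len(nrow(sched)), n_i)
    N <- length(idx)
    cells <- hut_count_cells()
    counts <- matrix(0L, nrow(sched), length(cells),
                     dimnames = list(NULL, cells))
    if (N > 0) {
      # latent Gaussian copula for the three per-mosquito outcomes
      R <- matrix(params$rho, 3, 3); diag(R) <- 1
      z <- matrix(rnorm(3 * N), N, 3) %*% chol(R)
      pa <- params$arms[match(sched$arm[idx], params$arms$arm), ]
      dead <- z[, 1] < qnorm(pa$p_death)
      fed <- z[, 2] < qnorm(pa$p_feed)
      exited <- z[, 3] < qnorm(pa$p_exit)
      loc <- rep("room", N)
      loc[exited] <- ifelse(runif(sum(exited)) < 0.5, "verandah", "window")
      cell <- paste(ifelse(fed, "fed", "unfed"),
                    ifelse(dead, "dead", "alive"), loc, sep = "_")
      tab <- table(factor(idx, levels = seq_len(nrow(sched))),
                   factor(cell, levels = cells))
      counts <- matrix(as.integer(tab), nrow(sched), length(cells),
                       dimnames = list(NULL, cells))
    }
    out <- tibble::tibble(
      night = sched$night, period = sched$period, hut = sched$hut,
      sleeper = sched$sleeper, arm = sched$arm, species = params$species
    )
    dplyr::bind_cols(out, tibble::as_tibble(counts))
  })
}

#' Expected endpoint values under a set of generative parameters
#'
#' Closed-form expectations of the six endpoints implied by
#' [trial_params()], against which estimates recovered from simulated data
#' can be compared. Over a balanced rotation the hut and sleeper effects
#' cancel from every ratio, so they do not appear.
#'
#' @param params A [trial_params()] object.
#' @return A tibble with one row per arm and the expected (untruncated)
#'   endpoint percentages.
#' @export
expected_endpoints <- function(params) {
  a <- params$arms
  cu <- a[a$arm == params$control_arm, ]
  tibble::tibble(
    arm = a$arm,
    deterrence_pct = 100 * a$deterrence,
    exiting_pct = 100 * a$p_exit,
    mortality_pct = 100 * a$p_death,
    corrected_mortality_pct = 100 * (a$p_death - cu$p_death) / (1 - cu$p_death),
    killing_effect_pct = 100 * (a$p_death * (1 - a$deterrence) - cu$p_death),
    bfi_pct = 100 * (1 - a$p_feed / cu$p_feed),
    personal_protection_pct = 100 * (1 - a$p_feed * (1 - a$deterrence) / cu$p_feed)
  )
}

#' Invert an endpoint table into generative parameters
#'
#' Calibration helper: recovers the generative probabilities whose expected
#' endpoints equal a trial's endpoint table, so that simulations can be run
#' "at" an observed trial. The inversion needs the untruncated (`*_raw`)
#' endpoint columns: a comparative endpoint sitting at the truncation
#' boundary (reported 0, raw value lost) cannot be inverted unambiguously
#' and raises an error.
#'
#' @param et An endpoint table from [summarize_trial()] for a single
#'   species, containing the control arm row.
#' @param nights_per_period,n_periods,k,sigma_hut,sigma_sleeper,rho,seed
#'   Remaining generative settings passed through to [trial_params()];
#'   effect scales default to 0 so that expected endpoints match exactly.
#' @param mu Control entry rate; defaults to the control arm's observed
#'   average catch per night.
#' @return A [trial_params()] object.
#' @export
params_from_endpoint_table <- function(et, nights_per_period = 6,
                                       n_periods = nrow(et), mu = NULL,
                                       k = 5, sigma_hut = 0, sigma_sleeper = 0,
                                       rho = 0, seed = 1) {
  if (length(unique(et$species)) != 1) {
    abort("inversion needs an endpoint table for a single species")
  }
  control_arm <- attr(et, "control_arm")
  cu <- et[et$arm == control_arm, , drop = FALSE]
  if (nrow(cu) != 1) abort("endpoint table lacks its control arm row")
  need_raw <- c("deterrence_raw", "corrected_mortality_raw", "bfi_raw")
  for (nc in need_raw) {
    if (!nc %in% names(et)) {
      boundary <- any(et[[sub("_raw$", "_pct", nc)]] == 0 & et$arm != control_arm)
      if (boundary) {
        abort(paste0(
          "inversion ambiguity: `", nc, "` is absent and the truncated value ",
          "sits at 0; the raw (signed) endpoint is required to invert it"
        ))
      }
      et[[nc]] <- et[[sub("_raw$", "_pct", nc)]]
    }
  }
  m_u <- cu$mortality_pct / 100
  f_u <- cu$total_fed / cu$total_caught
  e_u <- cu$exiting_pct / 100
  arms <- tibble::tibble(
    arm = et$arm,
    deterrence = ifelse(et$arm == control_arm, 0, et$deterrence_raw / 100),
    p_death = ifelse(et$arm == control_arm, m_u,
                     m_u + (et$corrected_mortality_raw / 100) * (1 - m_u)),
    p_feed = ifelse(et$arm == control_arm, f_u,
                    f_u * (1 - et$bfi_raw / 100)),
    p_exit = et$exiting_pct / 100
  )
  trial_params(
    arms, mu = mu %||% cu$avg_catch_per_night, k = k,
    sigma_hut = sigma_hut, sigma_sleeper = sigma_sleeper, rho = rho,
    nights_per_period = nights_per_period, n_periods = n_periods,
    species = unique(et$species), control_arm = control_arm, seed = seed
  )
}
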