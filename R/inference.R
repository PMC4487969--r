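#' Pairwise arm comparison of proportional outcomes
#'
#' Fits one logistic regression to the per-hut-night binomial outcomes
#' (successes out of the nightly catch), with treatment arm as a factor and,
#' following the trial's analysis plan, sleeper and hut position as
#' adjustment covariates. Pairwise arm contrasts are Wald tests on the link
#' scale, unadjusted for multiplicity by default (set `p_adjust = "holm"`
#' to adjust). Night is deliberately not a covariate; add it via `adjust`
#' if desired.
#'
#' For any arm pair whose pooled 2 x 2 table contains a zero cell the Wald
#' test is unreliable, and the comparison falls back to Fisher's exact test
#' on the pooled table; the `method` matrix records which route produced
#' each p-value.
#'
#' @param records Hut-night records tibble.
#' @param endpoint One of `"mortality"`, `"blood_feeding"`, `"exiting"`.
#' @param adjust Covariates to adjust for; any subset of
#'   `c("sleeper", "hut", "night")`. Covariates with a single observed level
#'   are dropped automatically.
#' @param alpha Significance level carried into letter grouping.
#' @param p_adjust `"none"` (default; raw p-values, as trial reports quote)
#'   or `"holm"`.
#' @param species Optional single species filter.
#' @return An object of class `pairwise_matrix`: list with `arms`, symmetric
#'   matrix `p`, character matrix `method` (`"wald"`/`"exact"`), `endpoint`,
#'   `alpha`, and the fitted `model`.
#' @export
compare_proportions <- function(records,
                                endpoint = c("mortality", "blood_feeding", "exiting"),
                                adjust = c("sleeper", "hut"),
                                alpha = 0.05,
                                p_adjust = c("none", "holm"),
                                species = NULL) {
  endpoint <- match.arg(endpoint)
  p_adjust <- match.arg(p_adjust)
  if (!is.null(species)) records <- records[records$species == species, ]
  cells <- hut_count_cells()
  tot <- rowSums(records[, cells])
  y <- switch(endpoint,
    mortality = rowSums(records[, grep("_dead_", cells, value = TRUE)]),
    blood_feeding = rowSums(records[, grep("^fed_", cells, value = TRUE)]),
    exiting = rowSums(records[, grep("_(verandah|window)$", cells, value = TRUE)])
  )
  d <- tibble::tibble(
    arm = records$arm, sleeper = records$sleeper, hut = records$hut,
    night = as.character(records$night), y = y, n = tot
  )
  arm_tot <- tapply(d$n, d$arm, sum)
  empty <- names(arm_tot)[arm_tot == 0]
  if (length(empty) > 0) {
    warn(sprintf("arm(s) with zero total caught excluded: %s",
                 paste(empty, collapse = ", ")))
    d <- d[!d$arm %in% empty, ]
  }
  arms <- sort(unique(d$arm))
  if (length(arms) < 2) abort("need at least two arms with catches to compare")
  d <- d[d$n > 0, ]
  d$arm <- factor(d$arm, levels = arms)
  fit <- glm(build_formula("cbind(y, n - y)", d, adjust),
             family = binomial(), data = d)
  res <- pairwise_from_fit(fit, arms)
  # exact-test fallback for sparse pooled tables
  pooled_y <- tapply(d$y, d$arm, sum)
  pooled_n <- tapply(d$n, d$arm, sum)
  for (i in seq_len(length(arms) - 1)) {
    for (j in (i + 1):length(arms)) {
      tab <- matrix(c(pooled_y[i], pooled_n[i] - pooled_y[i],
                      pooled_y[j], pooled_n[j] - pooled_y[j]),
                    nrow = 2, byrow = TRUE)
      if (any(tab == 0)) {
        res$p[i, j] <- res$p[j, i] <- fisher.test(tab)$p.value
        res$method[i, j] <- res$method[j, i] <- "exact"
      }
    }
  }
  finalize_pairwise(res, arms, endpoint, alpha, p_adjust, fit)
}

#' Pairwise arm comparison of nightly counts
#'
#' Overdispersed count regression of per-hut-night counts (entries,
#' blood-fed or dead) on treatment arm with sleeper and hut adjustment.
#' The mean model is the log-linear model of negative-binomial count
#' regression; the dispersion entering the contrast standard errors is the
#' moment (Pearson) estimate of a quasi-Poisson fit, with a t reference on
#' the residual degrees of freedom. At hut-trial sample sizes (tens of
#' hut-nights) this holds its nominal size, whereas Wald z intervals based
#' on the maximum-likelihood NB dispersion are noticeably anticonservative;
#' the NB dispersion estimate (`theta`) is still reported when estimable.
#' When an arm has zero-variance counts the dispersion moment estimate is
#' degenerate and the model falls back to plain Poisson with a warning.
#'
#' @inheritParams compare_proportions
#' @param outcome One of `"entries"`, `"blood_fed"`, `"dead"`.
#' @return A `pairwise_matrix` (see [compare_proportions()]); its
#'   `model_family` element records `"quasipoisson"` or `"poisson"`, and
#'   `theta` the NB dispersion estimate (`NA` if inestimable).
#' @export
compare_counts <- function(records,
                           outcome = c("entries", "blood_fed", "dead"),
                           adjust = c("sleeper", "hut"),
                           alpha = 0.05,
                           p_adjust = c("none", "holm"),
                           species = NULL) {
  outcome <- match.arg(outcome)
  p_adjust <- match.arg(p_adjust)
  if (!is.null(species)) records <- records[records$species == species, ]
  cells <- hut_count_cells()
  y <- switch(outcome,
    entries = rowSums(records[, cells]),
    blood_fed = rowSums(records[, grep("^fed_", cells, value = TRUE)]),
    dead = rowSums(records[, grep("_dead_", cells, value = TRUE)])
  )
  d <- tibble::tibble(
    arm = records$arm, sleeper = records$sleeper, hut = records$hut,
    night = as.character(records$night), y = y
  )
  if (all(d$y == 0)) abort("degenerate model: outcome is zero for every arm")
  arms <- sort(unique(d$arm))
  if (length(arms) < 2) abort("need at least two arms to compare")
  d$arm <- factor(d$arm, levels = arms)
  form <- build_formula("y", d, adjust)
  zero_var <- any(tapply(d$y, d$arm, function(v) var(v) == 0))
  if (zero_var) {
    warn("an arm has zero-variance counts; dispersion not estimable, falling back to Poisson")
    family_used <- "poisson"
    fit <- glm(form, family = poisson(), data = d)
    theta <- NA_real_
  } else {
    family_used <- "quasipoisson"
    fit <- glm(form, family = stats::quasipoisson(), data = d)
    nb <- tryCatch(suppressWarnings(MASS::glm.nb(form, data = d)),
                   error = function(e) NULL)
    theta <- if (is.null(nb)) NA_real_ else nb$theta
  }
  res <- pairwise_from_fit(fit, arms)
  out <- finalize_pairwise(res, arms, outcome, alpha, p_adjust, fit)
  out$model_family <- family_used
  out$theta <- theta
  out
}

build_formula <- function(lhs, d, adjust) {
  adjust <- intersect(adjust, c("sleeper", "hut", "night"))
  keep <- adjust[vapply(adjust, function(a) length(unique(d[[a]])) > 1, logical(1))]
  as.formula(paste(lhs, "~", paste(c("arm", keep), collapse = " + ")))
}

# Wald p-values for all arm pairs from a single fitted model, via emmeans
pairwise_from_fit <- function(fit, arms) {
  em <- emmeans::emmeans(fit, "arm")
  pr <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "none"))
  k <- length(arms)
  idx <- t(utils::combn(k, 2)) # emmeans emits pairs in combn order over levels
  p <- matrix(NA_real_, k, k, dimnames = list(arms, arms))
  method <- matrix(NA_character_, k, k, dimnames = list(arms, arms))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    p[i, j] <- p[j, i] <- pr$p.value[r]
    method[i, j] <- method[j, i] <- "wald"
  }
  list(p = p, method = method)
}

finalize_pairwise <- function(res, arms, endpoint, alpha, p_adjust, fit) {
  if (p_adjust == "holm") {
    ut <- upper.tri(res$p)
    res$p[ut] <- p.adjust(res$p[ut], method = "holm")
    res$p[lower.tri(res$p)] <- t(res$p)[lower.tri(res$p)]
  }
  structure(
    list(arms = arms, p = res$p, method = res$method, endpoint = endpoint,
         alpha = alpha, model = fit),
    class = "pairwise_matrix"
  )
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix> endpoint: %s, alpha = %g\n", x$endpoint, x$alpha))
  print(round(x$p, 4))
  invisible(x)
}
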