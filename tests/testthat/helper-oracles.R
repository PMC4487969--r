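# Independent oracles and small data builders used across the suite.

# Naive linear scan over washes: first wash whose pooled mortality or
# (when scored) pooled knockdown fails the criterion. Deliberately written
# from the per-wash percentage table, independent of determine_cutoff().
brute_force_cutoff <- function(series, mortality_threshold = 80,
                               kd_threshold = 95) {
  washes <- sort(unique(series$wash))
  has_kd <- !all(is.na(series$n_kd60))
  for (w in washes) {
    s <- series[series$wash == w, ]
    mort <- 100 * sum(s$n_dead24) / sum(s$n_exposed)
    kd <- if (has_kd) 100 * sum(s$n_kd60, na.rm = TRUE) / sum(s$n_exposed) else NA
    if (mort < mortality_threshold || (has_kd && kd < kd_threshold)) {
      return(as.integer(w))
    }
  }
  NA_integer_
}

# Random replicate-level bioassay series of random length for the oracle
# equivalence property.
random_bioassay_series <- function() {
  n_washes <- sample(2:30, 1)
  dplyr::bind_rows(lapply(seq_len(n_washes), function(w1) {
    tibble::tibble(
      net = "x", wash = w1 - 1L, replicate = 1:10, n_exposed = 5L,
      n_kd60 = sample(0:5, 10, replace = TRUE),
      n_dead24 = sample(0:5, 10, replace = TRUE)
    )
  }))
}

# Does a letter assignment satisfy the defining iff-property of table
# superscripts? Brute force over all arm pairs.
letters_satisfy_iff <- function(p, assignment, alpha) {
  arms <- rownames(p)
  for (i in seq_len(length(arms) - 1)) {
    for (j in (i + 1):length(arms)) {
      share <- length(intersect(
        strsplit(assignment[[arms[i]]], "")[[1]],
        strsplit(assignment[[arms[j]]], "")[[1]]
      )) > 0
      if (share != (p[arms[i], arms[j]] >= alpha)) return(FALSE)
    }
  }
  TRUE
}

# Build per-hut-night records carrying exact arm-level totals: each arm's
# catch is spread round-robin over nights and attributes are assigned over
# staggered index windows (same scheme as the shipped reconstruction, but
# for arbitrary totals).
records_from_totals <- function(totals, n_nights, species = "An. testus") {
  cells <- hut_count_cells()
  n_arms <- nrow(totals)
  out <- list()
  for (r in seq_len(n_arms)) {
    T_ <- totals$caught[r]; K <- totals$dead[r]
    B <- totals$fed[r]; E <- totals$exited[r]
    nights <- seq_len(n_nights)
    hut_i <- ((r + nights - 2L) %% n_arms) + 1L
    rec <- tibble::tibble(
      night = nights, period = 1L,
      hut = paste0("H", hut_i),
      sleeper = paste0("S", ((hut_i + nights - 2L) %% n_arms) + 1L),
      arm = totals$arm[r], species = species
    )
    counts <- matrix(0L, n_nights, length(cells), dimnames = list(NULL, cells))
    if (T_ > 0) {
      i <- seq_len(T_) - 1L
      night <- (i %% n_nights) + 1L
      dead <- i < K
      fed <- i >= (T_ - B)
      exited <- ((i + T_ %/% 3L) %% T_) < E
      loc <- rep("room", T_)
      loc[exited] <- c("verandah", "window")[(which(exited) %% 2L) + 1L]
      cell <- paste(ifelse(fed, "fed", "unfed"),
                    ifelse(dead, "dead", "alive"), loc, sep = "_")
      tab <- table(factor(night, levels = nights),
                   factor(cell, levels = cells))
      counts <- matrix(as.integer(tab), n_nights, length(cells),
                       dimnames = list(NULL, cells))
    }
    out[[r]] <- dplyr::bind_cols(rec, tibble::as_tibble(counts))
  }
  dplyr::bind_rows(out)
}

# Two-arm simulated trial under shared or distinct generative settings.
two_arm_params <- function(seed, mu = 20, d = 0, m = c(0.1, 0.1),
                           f = c(0.3, 0.3), e = c(0.8, 0.8), k = 5,
                           sigma_hut = 0, sigma_sleeper = 0,
                           nights_per_period = 4, n_periods = 6) {
  trial_params(
    tibble::tibble(
      arm = c("ctrl", "trt"), deterrence = c(0, d),
      p_death = m, p_feed = f, p_exit = e
    ),
    mu = mu, k = k, sigma_hut = sigma_hut, sigma_sleeper = sigma_sleeper,
    nights_per_period = nights_per_period, n_periods = n_periods,
    control_arm = "ctrl", seed = seed
  )
}
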