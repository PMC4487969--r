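#' Compact-letter display for pairwise comparisons
#'
#' Assigns significance letters to arms using the insert-and-absorb
#' algorithm: start from one letter covering all arms; for each significantly
#' different pair, split every letter set containing both members into two
#' copies (each lacking one member of the pair), then absorb sets contained
#' in others. The result satisfies the defining property of table
#' superscripts: **two arms share at least one letter if and only if their
#' pairwise p-value is >= alpha**. The greedy absorption keeps the number of
#' letters small but does not guarantee the minimum.
#'
#' @param x A `pairwise_matrix` (from [compare_proportions()] or
#'   [compare_counts()]), or a symmetric numeric p-value matrix with arm
#'   names as dimnames.
#' @param alpha Significance level; defaults to the `alpha` carried by a
#'   `pairwise_matrix`, else 0.05.
#' @return A named character vector (class `letter_assignment`) mapping each
#'   arm to its letter string, e.g. `c(control = "a", icon = "b", ctn = "ab")`.
#'   The letter sets are attached as attribute `"sets"`.
#' @export
letter_grouping <- function(x, alpha = NULL) {
  if (inherits(x, "pairwise_matrix")) {
    alpha <- alpha %||% x$alpha
    p <- x$p
  } else {
    alpha <- alpha %||% 0.05
    p <- x
  }
  arms <- rownames(p)
  if (is.null(arms)) abort("p-value matrix must carry arm names as dimnames")
  k <- length(arms)
  sets <- list(arms)
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (is.na(p[i, j]) || p[i, j] >= alpha) next
        a <- arms[i]; b <- arms[j]
        new_sets <- list()
        for (s in sets) {
          if (a %in% s && b %in% s) {
            new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
          } else {
            new_sets <- c(new_sets, list(s))
          }
        }
        sets <- absorb_sets(new_sets)
      }
    }
  }
  # stable ordering: by first member's position in the arm list
  ord <- order(vapply(sets, function(s) min(match(s, arms)), numeric(1)),
               -lengths(sets))
  sets <- sets[ord]
  symbols <- make_letter_symbols(length(sets))
  out <- vapply(arms, function(a) {
    paste(symbols[vapply(sets, function(s) a %in% s, logical(1))], collapse = "")
  }, character(1))
  structure(out, sets = sets, alpha = alpha, class = "letter_assignment")
}

absorb_sets <- function(sets) {
  sets <- sets[lengths(sets) > 0]
  sets <- unique(lapply(sets, sort))
  keep <- vapply(seq_along(sets), function(i) {
    !any(vapply(seq_along(sets), function(j) {
      i != j && all(sets[[i]] %in% sets[[j]])
    }, logical(1)))
  }, logical(1))
  sets[keep]
}

make_letter_symbols <- function(n) {
  pool <- c(letters, as.vector(outer(letters, letters, paste0)))
  pool[seq_len(n)]
}

#' @export
print.letter_assignment <- function(x, ...) {
  cat("<letter_assignment> alpha =", attr(x, "alpha"), "\n")
  print(setNames(as.character(x), names(x)))
  invisible(x)
}

#' Merge significance letters into an endpoint table
#'
#' @param et Endpoint table from [summarize_trial()].
#' @param assignment A [letter_grouping()] result.
#' @param endpoint Name used for the new column `<endpoint>_letters`.
#' @param species Optional species whose rows receive the letters (required
#'   when the table spans several species).
#' @return The endpoint table with the letters column added.
#' @export
attach_letters <- function(et, assignment, endpoint, species = NULL) {
  col <- paste0(endpoint, "_letters")
  if (!col %in% names(et)) et[[col]] <- NA_character_
  rows <- if (is.null(species)) seq_len(nrow(et)) else which(et$species == species)
  m <- match(et$arm[rows], names(assignment))
  et[[col]][rows] <- as.character(assignment)[m]
  et
}
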