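#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used in the rendered endpoint tables.
#' Base R's [round()] rounds half to even, which would print 93.75 as 93.7;
#' field reports round it to 93.8.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(93.75, 1) # 93.8
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  # small eps guards against values like 65.75 stored as 65.74999999999999
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

# evaluate `code` under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0 || any(is.na(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be a non-negative count", name))
  }
}

#' Construct a validation report
#'
#' A validation report collects rule violations found in a dataset or design
#' rather than failing on the first one. A report passes iff it contains no
#' entry of severity `"error"`; `"warning"` entries flag suspicious but
#' admissible structure (e.g. an incomplete rotation).
#'
#' @param entries A data frame with columns `locator`, `rule`, `message`,
#'   `severity` (one of `"error"`, `"warning"`). Zero rows mean a clean pass.
#' @return An object of class `hut_validation_report` with elements
#'   `entries` and logical `pass`.
#' @export
validation_report <- function(entries = NULL) {
  if (is.null(entries)) {
    entries <- tibble::tibble(
      locator = character(), rule = character(),
      message = character(), severity = character()
    )
  }
  entries <- tibble::as_tibble(entries)
  structure(
    list(entries = entries, pass = !any(entries$severity == "error")),
    class = "hut_validation_report"
  )
}

#' @export
print.hut_validation_report <- function(x, ...) {
  cat(sprintf(
    "<hut_validation_report> %s (%d error(s), %d warning(s))\n",
    if (x$pass) "PASS" else "FAIL",
    sum(x$entries$severity == "error"),
    sum(x$entries$severity == "warning")
  ))
  if (nrow(x$entries) > 0) print(x$entries, ...)
  invisible(x)
}
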