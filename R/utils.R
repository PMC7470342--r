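#' @keywords internal
"_PACKAGE"

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

#' Leap-aware day of year
#'
#' @param date a `Date` (or something coercible to one).
#' @return Integer day of year, 1--366 (Feb 29 counts, so March dates in leap
#'   years are one day later than in common years).
#' @examples
#' day_of_year(as.Date("2016-03-25"))  # 85 (2016 is a leap year)
#' day_of_year(as.Date("2017-03-25"))  # 84
#' @export
day_of_year <- function(date) {
  as.POSIXlt(as.Date(date))$yday + 1L
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite scalar", name), call. = FALSE)
  }
  invisible(x)
}
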