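#' Legal EDSS values
#'
#' The Expanded Disability Status Scale takes values on the grid
#' \{0, 1.0, 1.5, 2.0, ..., 10.0\}. Note there is no 0.5 step: the scale
#' jumps from 0 directly to 1.0.
#'
#' @return Numeric vector of the 20 legal EDSS values.
#' @export
edss_levels <- function() {
  c(0, seq(1, 10, by = 0.5))
}

#' Round a latent disability value to the legal EDSS grid
#'
#' Values are rounded to the nearest legal EDSS step, with ties rounded up.
#' Because the scale has no 0.5 level, values below 1.0 go to 0.0 or 1.0,
#' whichever is nearer (0.5 itself rounds up to 1.0). Input is clamped to
#' \[0, 10\] first, so latent values beyond the scale emit the extremes.
#'
#' @param x Numeric vector of latent (continuous) disability values.
#' @return Numeric vector on the legal EDSS grid.
#' @export
#' @examples
#' round_edss(c(-0.2, 0.49, 0.5, 1.74, 1.75, 11.3))
round_edss <- function(x) {
  stopifnot(is.numeric(x))
  x <- pmin(pmax(x, 0), 10)
  # nearest 0.5 step, ties up: floor(2x + 0.5) / 2
  g <- floor(2 * x + 0.5) / 2
  # collapse the non-existent 0.5 level: [0.5, 1) already rounds to 0.5 or 1;
  # re-round the sub-1 region against the {0, 1} pair only
  low <- x < 1
  g[low] <- ifelse(x[low] < 0.5, 0, 1)
  g
}

#' Test whether values lie on the legal EDSS grid
#'
#' @param x Numeric vector.
#' @param tol Numeric tolerance for float comparison.
#' @return Logical vector.
#' @export
is_edss <- function(x, tol = 1e-9) {
  ok <- x >= 0 & x <= 10 & abs(x * 2 - round(x * 2)) < tol
  ok & !(x > 0 & x < 1 - tol)
}

# Evaluate code under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  force(code)
}

# Derive a reproducible 31-bit substream seed from a master seed and an index.
# Patient i's stream is then independent of cohort size.
substream_seed <- function(seed, index, salt = 0L) {
  s <- (as.numeric(seed) * 48271 + as.numeric(index) * 9973 +
          as.numeric(salt) * 7919) %% 2147483629
  as.integer(s)
}

DAYS_PER_YEAR <- 365.25

days2years <- function(d) d / DAYS_PER_YEAR
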