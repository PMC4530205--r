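## Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not
#' perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Geometric mean with zero flooring
#'
#' Zeros are floored to half the smallest positive value present before
#' taking logs (geometric means are undefined at zero; flooring is the
#' standard treatment for log-scale cytometry channels).
#' @noRd
geomean <- function(x, floor_value = NULL) {
  if (length(x) == 0L) stop("geometric mean of an empty vector")
  if (any(x < 0)) stop("negative values have no geometric mean")
  if (any(x == 0)) {
    if (is.null(floor_value)) {
      pos <- x[x > 0]
      if (length(pos) == 0L) stop("all values are zero")
      floor_value <- min(pos) / 2
    }
    x[x == 0] <- floor_value
  }
  exp(mean(log(x)))
}

is_proportion <- function(x) is.numeric(x) && length(x) == 1L &&
  is.finite(x) && x >= 0 && x <= 1

stopifnot_proportion <- function(x, name) {
  if (!is_proportion(x)) stop(sprintf("'%s' must be a proportion in [0, 1]", name))
}

#' Robust mode and one-sided spread of a unimodal cluster
#'
#' The mode is located on a kernel density; the spread is estimated from
#' the left half of the cluster only (median absolute deviation below the
#' mode, scaled for a half-normal), so that a positive tail or a second
#' population to the right does not inflate it.
#' @noRd
mode_and_left_spread <- function(x) {
  d <- stats::density(x, n = 512)
  m <- d$x[which.max(d$y)]
  below <- x[x <= m]
  sigma <- stats::median(m - below) / 0.6745
  list(mode = m, sigma = sigma)
}
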