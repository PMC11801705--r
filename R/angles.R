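#' Angle utilities
#'
#' All torsion angles in lampart are handled in degrees on the half-open
#' domain \eqn{[0, 360)}. `wrap_angle()` maps any angle into that domain;
#' `wrap_deviation()` returns the signed periodic difference between two
#' angles, mapped into \eqn{(-180, 180]}, which keeps Taylor expansions
#' local to their reference point.
#'
#' @param theta numeric vector of angles (degrees).
#' @param theta_ref numeric vector of reference angles (degrees), recycled
#'   against `theta`.
#'
#' @return `wrap_angle()`: angles in `[0, 360)`. `wrap_deviation()`: signed
#'   deviations in `(-180, 180]`, congruent to `theta - theta_ref` mod 360.
#'
#' @examples
#' wrap_deviation(104, 90)   # 14
#' wrap_deviation(350, 10)   # -20
#' wrap_angle(-30)           # 330
#' @export
wrap_angle <- function(theta) {
  stopifnot(is.numeric(theta), all(is.finite(theta)))
  theta %% 360
}

#' @rdname wrap_angle
#' @export
wrap_deviation <- function(theta, theta_ref) {
  stopifnot(is.numeric(theta), is.numeric(theta_ref),
            all(is.finite(theta)), all(is.finite(theta_ref)))
  d <- (theta - theta_ref) %% 360
  ifelse(d > 180, d - 360, d)
}

# degrees -> radians scale, used throughout the analytic derivative code
D2R <- pi / 180

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
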