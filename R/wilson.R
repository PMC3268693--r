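#' Wilson intensity model on a resolution-shell grid
#'
#' Describes the zero-dose scattering power of a crystal as shell-mean
#' intensities following Wilson statistics: in the shell centred at
#' `s2 = (sin(theta)/lambda)^2`, acentric intensities are exponentially
#' distributed with mean `scale0 * exp(-2 * b0 * s2)`. The shell grid is
#' equal-width in `s2` from a low-resolution limit down to `d_min`.
#'
#' @param b0 Zero-dose overall isotropic B-factor, in squared angstroms.
#'   Must be >= 0.
#' @param scale0 Intensity scale of the lowest-resolution limit (arbitrary
#'   units). Must be > 0.
#' @param d_min High-resolution limit in angstroms. Must be > 0.
#' @param d_max Low-resolution limit in angstroms (default 20).
#' @param n_shells Number of equal-width `s2` shells (default 10).
#'
#' @return An object of class `wilson_model`: list with `b0`, `scale0`,
#'   `d_min` and a `shells` tibble (`shell`, `s2_lo`, `s2_hi`, `s2_mid`).
#' @export
#' @examples
#' wm <- wilson_model(b0 = 20, scale0 = 1000, d_min = 2)
#' wm$shells
wilson_model <- function(b0, scale0, d_min, d_max = 20, n_shells = 10) {
  if (b0 < 0) abort("b0 must be >= 0")
  if (scale0 <= 0) abort("scale0 must be > 0")
  if (d_min <= 0 || d_max <= d_min) abort("need d_max > d_min > 0")
  s2_lo <- (1 / (2 * d_max))^2
  s2_hi <- (1 / (2 * d_min))^2
  edges <- seq(s2_lo, s2_hi, length.out = n_shells + 1)
  shells <- tibble::tibble(
    shell = seq_len(n_shells),
    s2_lo = edges[-(n_shells + 1)],
    s2_hi = edges[-1]
  )
  shells$s2_mid <- (shells$s2_lo + shells$s2_hi) / 2
  structure(list(b0 = b0, scale0 = scale0, d_min = d_min, d_max = d_max,
                 shells = shells),
            class = "wilson_model")
}

# shell-mean true intensity of the model at s2
.wilson_mean <- function(model, s2) {
  model$scale0 * exp(-2 * model$b0 * s2)
}

#' Resolution / s-squared conversions
#'
#' `s = sin(theta)/lambda = 1/(2 d)`, so `s2 = 1/(4 d^2)`.
#'
#' @param d Resolution in angstroms.
#' @param s2 Squared reciprocal coordinate, in inverse squared angstroms.
#' @return The converted quantity.
#' @export
d_to_s2 <- function(d) 1 / (4 * d^2)

#' @rdname d_to_s2
#' @export
s2_to_d <- function(s2) 1 / (2 * sqrt(s2))
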