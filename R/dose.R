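#' Describe the X-ray beam
#'
#' @param flux Total photon flux, photons/s. Must be >= 0.
#' @param energy_kev Photon energy, keV. Must be > 0.
#' @param fwhm_h_um,fwhm_v_um Horizontal and vertical beam sizes, full width
#'   at half maximum, in micrometres. Must be > 0.
#' @param profile Beam intensity profile: `"gaussian"` (default; the stated
#'   FWHMs, truncated at plus/minus 3 sigma) or `"uniform"` (top-hat of the
#'   stated sizes).
#'
#' @return An object of class `beam_parameters`.
#' @export
beam_parameters <- function(flux, energy_kev, fwhm_h_um = 45, fwhm_v_um = 35,
                            profile = c("gaussian", "uniform")) {
  profile <- match.arg(profile)
  if (!is.finite(flux) || flux < 0) abort("flux must be >= 0")
  if (!is.finite(energy_kev) || energy_kev <= 0) abort("energy_kev must be > 0")
  if (fwhm_h_um <= 0 || fwhm_v_um <= 0) abort("beam FWHMs must be > 0")
  structure(list(flux = flux, energy_kev = energy_kev,
                 fwhm_h_um = fwhm_h_um, fwhm_v_um = fwhm_v_um,
                 profile = profile),
            class = "beam_parameters")
}

#' Describe the crystal
#'
#' The beam is taken to travel along the third dimension (`size_um[3]` is the
#' absorption path length); the first and second dimensions face the
#' horizontal and vertical beam extents.
#'
#' @param size_um Numeric length-3: crystal dimensions in micrometres, all > 0.
#' @param comp Chemical composition, an [composition()] object. Defaults to
#'   the average protein crystal.
#'
#' @return An object of class `crystal_description`.
#' @export
crystal_description <- function(size_um, comp = default_composition()) {
  size_um <- as.numeric(size_um)
  if (length(size_um) != 3 || any(!is.finite(size_um)) || any(size_um <= 0)) {
    abort("size_um must be three positive dimensions (micrometres)")
  }
  stopifnot(inherits(comp, "xtal_composition"))
  structure(list(size_um = size_um, composition = comp),
            class = "crystal_description")
}

#' Absorbed dose rate in the illuminated crystal volume
#'
#' Computes the mean absorbed dose rate over the illuminated part of the
#' crystal: the power deposited per second (photon flux intercepted by the
#' crystal face, times photon energy, times the absorbed fraction
#' `1 - exp(-mu * t)` along the beam path) divided by the mass of the
#' illuminated volume. For a gaussian beam the illuminated footprint is the
#' crystal face clipped to the plus/minus 3 sigma beam extent; for a uniform
#' beam it is clipped to the stated FWHM sizes. A single scalar dose rate is
#' returned (no depth-resolved dose field).
#'
#' @param beam A [beam_parameters()] object.
#' @param crystal A [crystal_description()] object.
#'
#' @return An object of class `dose_rate`: a list with `value` (MGy/s),
#'   `assumptions` (text record of the composition used) and a `detail` list
#'   (intercepted flux fraction, absorbed fraction, illuminated mass).
#' @export
#' @examples
#' beam <- beam_parameters(flux = 6.2e11, energy_kev = 12.76)
#' dose_rate(beam, crystal_description(c(300, 50, 50)))
dose_rate <- function(beam, crystal) {
  stopifnot(inherits(beam, "beam_parameters"),
            inherits(crystal, "crystal_description"))
  comp <- crystal$composition
  sz <- crystal$size_um

  # footprint clipping and intercepted-flux fraction, per transverse axis
  axis_geom <- function(fwhm_um, size_um) {
    if (beam$profile == "gaussian") {
      sigma <- fwhm_um / (2 * sqrt(2 * log(2)))
      half <- min(3 * sigma, size_um / 2)
      frac <- pnorm(half / sigma) - pnorm(-half / sigma)
      # renormalize for the 3-sigma truncation of the beam itself
      frac <- frac / (pnorm(3) - pnorm(-3))
      list(half_um = half, frac = min(frac, 1))
    } else {
      half <- min(fwhm_um / 2, size_um / 2)
      list(half_um = half, frac = min(1, size_um / fwhm_um))
    }
  }
  gx <- axis_geom(beam$fwhm_h_um, sz[1])
  gy <- axis_geom(beam$fwhm_v_um, sz[2])

  mu_mm <- absorption_coefficient(comp, beam$energy_kev)
  t_mm <- sz[3] * 1e-3
  absorbed_frac <- 1 - exp(-mu_mm * t_mm)

  e_joule <- beam$energy_kev * 1.602176634e-16
  power_w <- beam$flux * gx$frac * gy$frac * e_joule * absorbed_frac

  area_cm2 <- (2 * gx$half_um * 1e-4) * (2 * gy$half_um * 1e-4)
  mass_kg <- comp$density * area_cm2 * (sz[3] * 1e-4) * 1e-3
  value <- if (power_w == 0) 0 else power_w / mass_kg / 1e6  # MGy/s

  structure(list(
    value = value,
    assumptions = comp$label,
    detail = list(intercepted_fraction = gx$frac * gy$frac,
                  absorbed_fraction = absorbed_frac,
                  mu_mm = mu_mm, illuminated_mass_kg = mass_kg,
                  profile = beam$profile)
  ), class = "dose_rate")
}

#' @export
print.dose_rate <- function(x, ...) {
  cat(sprintf("<dose_rate> %.4g MGy/s  (%s)\n", x$value, x$assumptions))
  invisible(x)
}

#' Composition correction factor for the decay rate
#'
#' Nominal doses assume the default average-protein-crystal composition. When
#' the true composition is known, the true dose rate differs from the nominal
#' one by the ratio `r = dose_rate(true) / dose_rate(default)`; a decay rate
#' fitted against nominal dose is converted to the true dose scale as
#' `beta_corrected = beta / r`. A composition that absorbs more than the
#' default (e.g. bound heavy atoms) gives `r > 1` and a smaller corrected
#' sensitivity.
#'
#' @param beam A [beam_parameters()] object.
#' @param crystal A [crystal_description()] whose composition is the *true*
#'   sample composition.
#' @param reference Composition assumed when the nominal doses were computed;
#'   defaults to [default_composition()].
#'
#' @return Dimensionless ratio `r`; exactly 1 when the compositions match.
#' @seealso [summarize_positions()] which applies the correction to a set of
#'   fitted decay rates.
#' @export
beta_correction_factor <- function(beam, crystal,
                                   reference = default_composition()) {
  ref_crystal <- crystal_description(crystal$size_um, comp = reference)
  r_true <- dose_rate(beam, crystal)$value
  r_ref <- dose_rate(beam, ref_crystal)$value
  if (r_ref == 0) abort("reference dose rate is zero; cannot form ratio")
  r_true / r_ref
}
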