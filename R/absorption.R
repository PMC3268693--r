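# Photoelectric mass absorption coefficients (cm^2/g) per element on a
# 5-25 keV grid, shipped as a text table; log-log interpolation between grid
# points. Between absorption edges the cross sections are near power-law in
# energy, so log-log interpolation on a 0.25 keV grid is accurate to <0.1%.
.betaburn_env <- new.env(parent = emptyenv())

.pe_table <- function() {
  if (is.null(.betaburn_env$pe)) {
    path <- system.file("extdata", "photoelectric_mu_rho.csv",
                        package = "betaburn", mustWork = TRUE)
    .betaburn_env$pe <- readr::read_csv(path, show_col_types = FALSE)
  }
  .betaburn_env$pe
}

# photoelectric mu/rho (cm^2/g) for one element at energies E (keV)
.mu_rho_pe <- function(element, energy_kev) {
  tab <- .pe_table()
  if (!element %in% names(tab)) {
    abort(paste0("unsupported element: ", element))
  }
  grid <- tab$energy_kev
  y <- tab[[element]]
  if (all(y == 0)) return(rep(0, length(energy_kev)))  # H: negligible PE
  exp(stats::approx(log(grid), log(y), xout = log(energy_kev),
                    rule = 1)$y)
}

# Klein-Nishina energy-transfer cross section per electron (cm^2), numeric
# integration over scattering angle; free-electron approximation.
.kn_sigma_tr <- function(energy_kev) {
  r_e <- 2.8179403262e-13  # classical electron radius, cm
  vapply(energy_kev, function(E) {
    k <- E / 511.0
    f <- function(theta) {
      ratio <- 1 / (1 + k * (1 - cos(theta)))  # E'/E
      dsdo <- 0.5 * r_e^2 * ratio^2 * (1 / ratio + ratio - sin(theta)^2)
      dsdo * (1 - ratio) * 2 * pi * sin(theta)
    }
    integrate(f, 0, pi, rel.tol = 1e-8)$value
  }, numeric(1))
}

#' Linear X-ray energy-absorption coefficient of a composition
#'
#' Sums, over the elements of the composition, the photoelectric mass
#' absorption cross section (tabulated, log-log interpolated in energy) and
#' the Compton energy-transfer cross section (Klein-Nishina, free-electron),
#' weighted by the elemental number densities. Fluorescence escape and
#' near-edge anomalous structure are not modelled; photon energies are
#' assumed to sit away from the absorption edges of the elements present.
#'
#' @param comp An [composition()] object.
#' @param energy_kev Photon energy in keV; must lie in the tabulated range
#'   `[5, 25]`.
#'
#' @return Linear energy-absorption coefficient in mm^-1.
#' @export
#' @examples
#' absorption_coefficient(water_composition(), 12.4)
absorption_coefficient <- function(comp, energy_kev) {
  stopifnot(inherits(comp, "xtal_composition"))
  if (any(energy_kev < 5 | energy_kev > 25)) {
    abort("energy_kev outside tabulated range [5, 25] keV")
  }
  els <- comp$elements
  if (nrow(els) == 0) return(0 * energy_kev)
  info <- .element_data()
  idx <- match(els$element, info$element)
  if (anyNA(idx)) {
    abort(paste0("unsupported element(s): ",
                 paste(els$element[is.na(idx)], collapse = ", ")))
  }
  sigma_tr <- .kn_sigma_tr(energy_kev)  # per electron, one per energy
  n_cm3 <- els$n_per_nm3 * 1e21
  mu_cm <- vapply(seq_along(energy_kev), function(j) {
    E <- energy_kev[j]
    per_el <- vapply(seq_len(nrow(els)), function(i) {
      sigma_pe <- .mu_rho_pe(els$element[i], E) *
        info$weight[idx[i]] / .AVOGADRO  # cm^2/atom
      n_cm3[i] * (sigma_pe + info$z[idx[i]] * sigma_tr[j])
    }, numeric(1))
    sum(per_el)
  }, numeric(1))
  mu_cm / 10  # mm^-1
}

# mass energy-absorption coefficient (cm^2/g), for cross-checks
.mass_absorption <- function(comp, energy_kev) {
  absorption_coefficient(comp, energy_kev) * 10 / comp$density
}
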