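# Elemental constants for the supported absorber set.
# Weights in g/mol; Z used for the Compton (free-electron) term.
.element_data <- function() {
  tibble::tibble(
    element = c("H", "C", "N", "O", "Na", "Mg", "P", "S", "Cl", "K", "Ca",
                "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Se", "Br", "I"),
    z = c(1, 6, 7, 8, 11, 12, 15, 16, 17, 19, 20,
          25, 26, 27, 28, 29, 30, 34, 35, 53),
    weight = c(1.008, 12.011, 14.007, 15.9994, 22.9898, 24.305, 30.9738,
               32.06, 35.453, 39.0983, 40.078, 54.938, 55.845, 58.9332,
               58.6934, 63.546, 65.38, 78.971, 79.904, 126.904)
  )
}

.AVOGADRO <- 6.02214076e23

# Average amino-acid residue stoichiometry used for the protein fraction.
# Sulfur is added separately (default 0.05 S per residue).
.RESIDUE_FORMULA <- c(C = 4.9, H = 7.8, N = 1.4, O = 1.5)

#' Construct a crystal composition
#'
#' A composition records, per chemical element, the number of atoms per cubic
#' nanometre of crystal, together with the bulk mass density. These are the
#' quantities the absorbed-dose model needs; helper constructors
#' ([protein_crystal_composition()], [default_composition()],
#' [water_composition()]) build them from the usual crystallographic
#' description (solvent fraction, solute concentrations, atoms per residue).
#'
#' @param elements Tibble or data frame with columns `element` (symbol) and
#'   `n_per_nm3` (atoms per nm^3 of crystal). May have zero rows (vacuum-like
#'   composition, useful for testing).
#' @param density Bulk mass density of the crystal in g/cm^3. Must be > 0.
#' @param solvent_fraction Volume fraction of solvent, in `[0, 1]`.
#' @param label Free-text record of the assumptions behind the composition.
#' @param extra Named list of extra recorded fields (e.g. sulfur per residue).
#'
#' @return An object of class `xtal_composition`.
#' @export
composition <- function(elements, density, solvent_fraction = NA_real_,
                        label = "explicit composition", extra = list()) {
  elements <- tibble::as_tibble(elements)
  if (nrow(elements) == 0) {
    elements <- tibble::tibble(element = character(), n_per_nm3 = numeric())
  }
  stopifnot(all(c("element", "n_per_nm3") %in% names(elements)))
  if (any(elements$n_per_nm3 < 0)) {
    abort("element number densities must be >= 0")
  }
  unknown <- setdiff(elements$element, .element_data()$element)
  if (length(unknown) > 0) {
    abort(paste0("unsupported element(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.na(solvent_fraction) &&
      (solvent_fraction < 0 || solvent_fraction > 1)) {
    abort("solvent_fraction must be in [0, 1]")
  }
  if (!is.finite(density) || density <= 0) {
    abort("density must be a positive number (g/cm^3)")
  }
  # collapse duplicate element rows
  elements <- elements |>
    dplyr::group_by(.data$element) |>
    dplyr::summarise(n_per_nm3 = sum(.data$n_per_nm3), .groups = "drop")
  structure(
    c(list(elements = elements, density = density,
           solvent_fraction = solvent_fraction, label = label), extra),
    class = "xtal_composition"
  )
}

#' @export
print.xtal_composition <- function(x, ...) {
  cat("<xtal_composition> ", x$label, "\n", sep = "")
  cat("  density: ", format(x$density, digits = 4), " g/cm^3",
      if (!is.na(x$solvent_fraction))
        paste0("; solvent fraction: ", x$solvent_fraction), "\n", sep = "")
  print(x$elements, n = 5)
  invisible(x)
}

#' Build a protein-crystal composition from solvent content and solutes
#'
#' Models the crystal as a protein region (average-residue stoichiometry
#' C4.9 H7.8 N1.4 O1.5 plus a configurable sulfur content) occupying
#' `1 - solvent_fraction` of the volume, and an aqueous solvent region
#' carrying dissolved species at millimolar concentrations.
#'
#' @param solvent_fraction Solvent volume fraction in `[0, 1]`.
#' @param sulfur_per_residue S atoms per amino-acid residue in the protein.
#' @param solvent_mM Named numeric vector of solute concentrations in the
#'   solvent, in mM per element (e.g. `c(S = 300)`).
#' @param extra_per_residue Named numeric vector of additional atoms per
#'   residue in the protein region (e.g. `c(Se = 0.02)` for Se-Met).
#' @param protein_density,solvent_density Mass densities of the two regions,
#'   g/cm^3.
#' @param label Text record of the assumptions.
#'
#' @return An `xtal_composition`.
#' @export
protein_crystal_composition <- function(solvent_fraction = 0.47,
                                        sulfur_per_residue = 0.05,
                                        solvent_mM = c(S = 300),
                                        extra_per_residue = NULL,
                                        protein_density = 1.35,
                                        solvent_density = 1.0,
                                        label = NULL) {
  fs <- solvent_fraction
  if (fs < 0 || fs > 1) abort("solvent_fraction must be in [0, 1]")

  residue <- .RESIDUE_FORMULA
  if (sulfur_per_residue > 0) {
    residue <- c(residue, S = unname(sulfur_per_residue))
  }
  if (!is.null(extra_per_residue)) {
    residue <- c(residue, extra_per_residue)
  }
  wt <- setNames(.element_data()$weight, .element_data()$element)
  unknown <- setdiff(names(residue), names(wt))
  if (length(unknown) > 0) {
    abort(paste0("unsupported element(s): ", paste(unknown, collapse = ", ")))
  }
  residue_mw <- sum(residue * wt[names(residue)])
  # residues per nm^3 of protein matter
  res_per_nm3 <- protein_density * .AVOGADRO / residue_mw * 1e-21

  protein_atoms <- tibble::tibble(
    element = names(residue),
    n_per_nm3 = (1 - fs) * res_per_nm3 * unname(residue)
  )

  # water: molecules per nm^3 at solvent_density
  water_per_nm3 <- solvent_density * .AVOGADRO / 18.015 * 1e-21
  solvent_atoms <- tibble::tibble(
    element = c("H", "O"),
    n_per_nm3 = fs * water_per_nm3 * c(2, 1)
  )
  if (length(solvent_mM) > 0) {
    # mM -> atoms per nm^3: 1 mM = 6.022e-4 atoms/nm^3
    solvent_atoms <- dplyr::bind_rows(
      solvent_atoms,
      tibble::tibble(element = names(solvent_mM),
                     n_per_nm3 = fs * unname(solvent_mM) * 6.02214076e-4)
    )
  }

  density <- (1 - fs) * protein_density + fs * solvent_density
  composition(
    dplyr::bind_rows(protein_atoms, solvent_atoms),
    density = density,
    solvent_fraction = fs,
    label = label %||% sprintf(
      "protein crystal: %.0f%% solvent, %.2f S/residue, solutes [%s] mM",
      100 * fs, sulfur_per_residue,
      paste(sprintf("%s=%g", names(solvent_mM), solvent_mM), collapse = ", ")),
    extra = list(sulfur_per_residue = sulfur_per_residue,
                 solvent_mM = solvent_mM)
  )
}

#' The default "average protein crystal" composition
#'
#' 47% solvent content, 0.05 sulfur atoms per amino-acid residue and 300 mM
#' sulfur in the buffer solution — the composition assumed when the sample's
#' chemistry has not been characterized. Nominal doses are defined against
#' this composition; [beta_correction_factor()] rescales a fitted decay rate
#' when the true composition is known.
#'
#' @return An `xtal_composition` with `label = "default average protein crystal"`.
#' @export
default_composition <- function() {
  protein_crystal_composition(
    solvent_fraction = 0.47,
    sulfur_per_residue = 0.05,
    solvent_mM = c(S = 300),
    label = "default average protein crystal"
  )
}

#' Pure-water composition
#'
#' Useful as an absorption reference: tabulated mass energy-absorption
#' coefficients for water are widely available.
#'
#' @return An `xtal_composition` for liquid water at 1 g/cm^3.
#' @export
water_composition <- function() {
  protein_crystal_composition(
    solvent_fraction = 1, sulfur_per_residue = 0, solvent_mM = NULL,
    solvent_density = 1.0, label = "pure water"
  )
}
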