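#' Published per-position decay rates for common test crystals
#'
#' Per-position B-factor decay rates (squared angstroms per MGy, measured
#' against nominal dose with the default average-protein-crystal
#' composition) reported for a panel of standard test systems: thermolysin,
#' trypsin, an A-DNA decamer, the FAE feruloyl-esterase module (two
#' crystals), RecR and a beta-1 adrenergic GPCR. Each sample was probed at
#' one to six positions; the last-shell signal-to-noise of the first and
#' last wedge and the mosaicity are included. These serve as reference
#' inputs for the summary statistics ([sensitivity_table()]) and for
#' report-format examples.
#'
#' @return Tibble with columns `crystal`, `position`, `mosaicity_deg`,
#'   `snr_first`, `snr_last`, `beta`.
#' @export
reference_beta_positions <- function() {
  path <- system.file("extdata", "reference_beta_positions.tsv",
                      package = "betaburn", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
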