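#' Bundle the results of initial sample characterization
#'
#' Collects everything the protocol generator needs: the dose rate at full
#' transmission, a Wilson-model estimate of the crystal's scattering power,
#' the detector noise calibration, the mosaicity and the diffractometer
#' limits.
#'
#' @param dose_rate_mgy_s Absorbed dose rate at full transmission, MGy/s.
#' @param model A [wilson_model()] estimate; its `d_min` is treated as the
#'   finest resolution considered, and [choose_resolution()] may return a
#'   coarser limit.
#' @param gain Detector gain (counts per intensity unit) at the standard
#'   0.1 MGy collection dose; defaults to the gain at which a crystal of
#'   this model diffracting to 2.0 angstroms would reach last-shell
#'   signal-to-noise 5.
#' @param background_var Detector background variance (squared counts).
#' @param mosaicity_deg Crystal mosaicity, degrees.
#' @param center_angle_deg Rotation angle (degrees) on which the wedge is
#'   centred, carried over from the characterization images.
#' @param rotation_range_deg Total rotation per cycle, degrees; must lie in
#'   `[3, 5]` (default 4).
#' @param min_exposure_s Minimum exposure per frame allowed by the
#'   diffractometer, seconds.
#' @param max_rotation_speed_deg_s Maximum rotation speed, degrees/second.
#' @param transmission_range Attainable attenuator transmission range.
#'
#' @return An object of class `characterization_input`.
#' @export
characterization_input <- function(dose_rate_mgy_s,
                                   model,
                                   gain = NULL,
                                   background_var = 0,
                                   mosaicity_deg = 0.5,
                                   center_angle_deg = 0,
                                   rotation_range_deg = 4,
                                   min_exposure_s = 0.04,
                                   max_rotation_speed_deg_s = 10,
                                   transmission_range = c(1e-4, 1)) {
  stopifnot(inherits(model, "wilson_model"))
  if (dose_rate_mgy_s <= 0) abort("dose_rate_mgy_s must be > 0")
  if (rotation_range_deg < 3 || rotation_range_deg > 5) {
    abort("rotation_range_deg must lie in [3, 5] degrees")
  }
  if (min_exposure_s <= 0 || max_rotation_speed_deg_s <= 0) {
    abort("diffractometer limits must be positive")
  }
  if (is.null(gain)) {
    ref <- wilson_model(model$b0, model$scale0, d_min = 2,
                        d_max = model$d_max, n_shells = nrow(model$shells))
    gain <- calibrate_gain(ref, 5, background_var)
  }
  structure(list(dose_rate_mgy_s = dose_rate_mgy_s, model = model,
                 gain = gain, background_var = background_var,
                 mosaicity_deg = mosaicity_deg,
                 center_angle_deg = center_angle_deg,
                 rotation_range_deg = rotation_range_deg,
                 min_exposure_s = min_exposure_s,
                 max_rotation_speed_deg_s = max_rotation_speed_deg_s,
                 transmission_range = transmission_range),
            class = "characterization_input")
}

#' Choose the collection resolution limit
#'
#' Returns the finest resolution at which the predicted last-shell
#' `<J>/<sigma>` of a collection cycle reaches the target within the
#' per-cycle dose budget, but never finer than the floor of 2.0 angstroms:
#' strongly diffracting crystals are held at 2.0 angstroms (and simply
#' achieve a higher signal-to-noise), weak ones get a coarser limit.
#'
#' @param char A [characterization_input()].
#' @param snr_target Target last-shell `<J>/<sigma>` (default 5).
#' @param d_floor Finest allowed resolution, angstroms (default 2.0).
#' @param d_max Coarsest resolution considered before declaring the
#'   protocol infeasible (default 8).
#'
#' @return The chosen `d_min` in angstroms.
#' @export
choose_resolution <- function(char, snr_target = 5, d_floor = 2, d_max = 8) {
  stopifnot(inherits(char, "characterization_input"))
  model <- char$model
  # predicted last-shell <J>/<sigma> of a wedge binned to resolution d:
  # evaluate the Wilson mean at the midpoint of the last shell of the grid
  # that would be used at that d (consistent with the simulated statistic)
  snr_at <- function(d) {
    grid <- wilson_model(model$b0, model$scale0, d_min = d,
                         d_max = model$d_max, n_shells = nrow(model$shells))
    m <- .wilson_mean(grid, tail(grid$shells$s2_mid, 1))
    .predicted_snr(m, char$gain, char$background_var)
  }
  target <- snr_target * (1 - 1e-9)  # tolerate rounding at the floor
  if (snr_at(d_floor) >= target) return(d_floor)
  candidates <- seq(d_floor, d_max, by = 0.05)
  ok <- vapply(candidates, snr_at, numeric(1)) >= target
  if (!any(ok)) {
    abort(sprintf(
      "protocol infeasible: predicted last-shell <J>/<sigma> stays below %g even at %g A",
      snr_target, d_max))
  }
  candidates[which(ok)[1]]
}

#' Total burn dose from the factor-3 decay rule
#'
#' The total absorbed dose of the experiment is chosen so that, at the
#' assumed decay rate, the intensity in the last resolution shell falls by
#' approximately a factor of 3:
#' `D_total = ln(3) / (2 * assumed_beta * s_min^2)` with
#' `s_min = 1 / (2 * d_min)`. For `d_min = 2.0` and `assumed_beta = 1` this
#' gives 8.8 MGy, about one third of the Garman limit; coarser resolution
#' limits lead to proportionally higher doses.
#'
#' @param d_min Resolution limit, angstroms.
#' @param assumed_beta Assumed decay rate, squared angstroms per MGy
#'   (default 1).
#'
#' @return Total dose in MGy.
#' @export
#' @examples
#' total_burn_dose(2)   # ~8.8 MGy
#' total_burn_dose(3)   # ~19.8 MGy
total_burn_dose <- function(d_min, assumed_beta = 1) {
  if (d_min <= 0) abort("d_min must be > 0")
  if (assumed_beta <= 0) abort("assumed_beta must be > 0")
  log(3) / (2 * assumed_beta * d_to_s2(d_min))
}

#' Frame width, exposure and transmission for one collection cycle
#'
#' The frame width is the largest divisor of the rotation range not
#' exceeding the overlap bound `min(1, max(0.1, 1.5 - mosaicity))` degrees
#' (wider mosaic spread leaves less angular room before neighbouring
#' reflections overlap within a frame). The
#' transmission is maximal subject to the per-frame minimum exposure and
#' the maximum rotation speed; when even full transmission cannot deliver
#' the cycle dose within those limits, the exposure is stretched instead.
#'
#' @param char A [characterization_input()].
#' @param cycle_dose Planned dose of the collection cycle, MGy.
#'
#' @return List with `frame_width_deg`, `n_frames`, `exposure_per_frame_s`,
#'   `exposure_total_s`, `transmission`.
#' @export
frame_width_and_exposure <- function(char, cycle_dose) {
  stopifnot(inherits(char, "characterization_input"))
  rot <- char$rotation_range_deg
  # reflections spread over ~ the mosaic width as the crystal rotates, so
  # the allowed frame width shrinks as mosaicity grows; never below 0.1 deg
  bound <- min(1, max(0.1, 1.5 - char$mosaicity_deg))
  widths <- c(1, 0.5, 0.25, 0.2, 0.1)
  ok <- widths <= bound + 1e-12 &
    abs(rot / widths - round(rot / widths)) < 1e-9
  if (!any(ok)) abort("no feasible frame width divides the rotation range")
  fw <- widths[which(ok)[1]]
  n_frames <- round(rot / fw)

  # minimum total exposure allowed by the diffractometer
  t_min_total <- max(n_frames * char$min_exposure_s,
                     rot / char$max_rotation_speed_deg_s)
  t_full <- cycle_dose / char$dose_rate_mgy_s  # exposure at transmission 1
  if (t_full >= t_min_total) {
    transmission <- 1
    t_total <- t_full
  } else {
    transmission <- t_full / t_min_total
    t_total <- t_min_total
  }
  if (transmission < char$transmission_range[1]) {
    abort(sprintf(
      "protocol infeasible: required transmission %.2g below attainable minimum %.2g",
      transmission, char$transmission_range[1]))
  }
  list(frame_width_deg = fw, n_frames = n_frames,
       exposure_per_frame_s = t_total / n_frames,
       exposure_total_s = t_total, transmission = transmission)
}

#' Generate the burn/collect protocol
#'
#' Builds the full experimental sequence: 11 collection cycles of at most
#' 0.1 MGy each, interleaved with 10 equal burn cycles, all over the same
#' rotation range centred on the characterization angle, with the total
#' dose set by the factor-3 decay rule of [total_burn_dose()].
#'
#' @param char A [characterization_input()].
#' @param assumed_beta Assumed decay rate used for the dose schedule,
#'   squared angstroms per MGy (default 1).
#' @param d_min Resolution limit; defaults to [choose_resolution()].
#' @param n_collections Number of collection cycles (default 11).
#' @param collection_dose Dose per collection cycle, MGy; capped at 0.1.
#'
#' @return An object of class `burn_protocol`: a tibble with one row per
#'   cycle (`cycle`, `type`, `start_angle_deg`, `rotation_deg`,
#'   `frame_width_deg`, `exposure_s` per frame for collections / total for
#'   burns, `transmission`, `planned_dose`), with attributes `d_min`,
#'   `assumed_beta`, `dose_rate_mgy_s`, `total_dose`, `gain`,
#'   `background_var`.
#' @export
generate_protocol <- function(char, assumed_beta = 1, d_min = NULL,
                              n_collections = 11, collection_dose = 0.1) {
  stopifnot(inherits(char, "characterization_input"))
  if (collection_dose > 0.1 + 1e-12) {
    abort("collection_dose must not exceed 0.1 MGy")
  }
  if (is.null(d_min)) d_min <- choose_resolution(char)
  total <- total_burn_dose(d_min, assumed_beta)
  collect_total <- n_collections * collection_dose
  n_burns <- n_collections - 1
  if (total <= collect_total) {
    abort("total dose target smaller than the collection doses alone")
  }
  burn_dose <- (total - collect_total) / n_burns

  fwe <- frame_width_and_exposure(char, collection_dose)
  start <- char$center_angle_deg - char$rotation_range_deg / 2

  rows <- purrr::map_dfr(seq_len(n_collections + n_burns), function(j) {
    if (j %% 2 == 1) {
      tibble::tibble(type = "collection",
                     frame_width_deg = fwe$frame_width_deg,
                     exposure_s = fwe$exposure_per_frame_s,
                     transmission = fwe$transmission,
                     planned_dose = collection_dose)
    } else {
      tibble::tibble(type = "burn",
                     frame_width_deg = NA_real_,
                     exposure_s = burn_dose / char$dose_rate_mgy_s,
                     transmission = 1,
                     planned_dose = burn_dose)
    }
  })
  rows <- dplyr::mutate(rows,
                        cycle = dplyr::row_number(),
                        start_angle_deg = start,
                        rotation_deg = char$rotation_range_deg,
                        d_min = ifelse(.data$type == "collection", d_min, NA)) |>
    dplyr::relocate("cycle", "type", "start_angle_deg", "rotation_deg")

  structure(rows, class = c("burn_protocol", class(rows)),
            d_min = d_min, assumed_beta = assumed_beta,
            dose_rate_mgy_s = char$dose_rate_mgy_s,
            total_dose = total, gain = char$gain,
            background_var = char$background_var)
}

#' Nominal dose stamps of a protocol
#'
#' Cumulative absorbed dose at the midpoint of each collection cycle
#' (collect and burn doses both accumulate). These are the nominal doses
#' against which per-wedge B-factors are plotted and fitted.
#'
#' @param protocol A [generate_protocol()] object.
#' @return Tibble with `wedge_index` (1-based collection counter) and
#'   `nominal_dose` (MGy), strictly increasing.
#' @export
dose_stamps <- function(protocol) {
  stopifnot(inherits(protocol, "burn_protocol"))
  cum <- 0
  out <- list()
  wi <- 0
  for (j in seq_len(nrow(protocol))) {
    d <- protocol$planned_dose[j]
    if (protocol$type[j] == "collection") {
      wi <- wi + 1
      out[[wi]] <- tibble::tibble(wedge_index = wi,
                                  nominal_dose = cum + d / 2)
    }
    cum <- cum + d
  }
  dplyr::bind_rows(out)
}
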