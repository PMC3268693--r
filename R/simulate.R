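# run code with a private, restorable RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' True damage parameters for simulation
#'
#' @param beta_true B-factor decay rate in squared angstroms per MGy;
#'   must be >= 0.
#' @param scale_drift Fractional change of the overall scale per MGy
#'   (default 0): intensities are additionally multiplied by
#'   `1 + scale_drift * dose`.
#'
#' @return An object of class `damage_truth`.
#' @export
damage_truth <- function(beta_true = 1, scale_drift = 0) {
  if (beta_true < 0) abort("beta_true must be >= 0")
  structure(list(beta_true = beta_true, scale_drift = scale_drift),
            class = "damage_truth")
}

#' Draw a zero-dose synthetic reflection set
#'
#' Per shell of the Wilson model, draws `n_per_shell` acentric intensities
#' from an exponential distribution with mean
#' `scale0 * exp(-2 * b0 * s2_mid)`. Reflections carry a sequential id and
#' the `s2` of their shell midpoint; no space-group machinery is used since
#' downstream scaling operates on shell means only.
#'
#' @param model A [wilson_model()].
#' @param n_per_shell Reflections per shell (default 200, roughly matching a
#'   3-5 degree wedge of 2 angstrom data binned into 10 shells).
#' @param seed Optional integer seed; identical seeds give identical draws.
#'
#' @return Tibble with columns `id`, `shell`, `s2`, `J_true`.
#' @export
simulate_reference <- function(model, n_per_shell = 200, seed = NULL) {
  stopifnot(inherits(model, "wilson_model"))
  if (n_per_shell < 1) abort("n_per_shell must be >= 1")
  .with_seed(seed, {
    refl <- model$shells |>
      dplyr::rowwise() |>
      dplyr::mutate(J_true = list(rexp(n_per_shell,
                                       rate = 1 / .wilson_mean(model, .data$s2_mid)))) |>
      dplyr::ungroup() |>
      tidyr::unnest("J_true") |>
      dplyr::transmute(shell = .data$shell, s2 = .data$s2_mid,
                       J_true = .data$J_true)
    refl$id <- seq_len(nrow(refl))
    dplyr::relocate(refl, "id")
  })
}

#' Apply dose-dependent decay to true intensities
#'
#' Multiplies each true intensity by
#' `(1 + scale_drift * dose) * exp(-2 * beta_true * dose * s2)` — the
#' intensity form of a linear B-factor growth `B(D) = B0 + beta * D`.
#'
#' @param reflections Tibble with columns `s2` and `J_true`.
#' @param dose Accumulated dose in MGy; must be >= 0.
#' @param truth A [damage_truth()].
#'
#' @return The reflections with decayed `J_true`.
#' @export
apply_decay <- function(reflections, dose, truth) {
  stopifnot(inherits(truth, "damage_truth"))
  if (dose < 0) abort("dose must be >= 0")
  dplyr::mutate(
    reflections,
    J_true = .data$J_true * (1 + truth$scale_drift * dose) *
      exp(-2 * truth$beta_true * dose * .data$s2)
  )
}

#' Add counting noise and sigma estimates
#'
#' Models an integrating detector with linear gain: the recorded counts for a
#' reflection of true intensity `J` are Poisson-like with variance
#' `J * gain + background_var`, so the observed intensity has variance
#' `(J * gain + background_var) / gain^2`. A gaussian error of that variance
#' is added and `sigma` is set to the model standard deviation.
#'
#' @param reflections Tibble with column `J_true` (and `s2`).
#' @param gain Detector gain in counts per intensity unit; must be > 0.
#' @param background_var Background variance in squared counts (default 0).
#' @param seed Optional integer seed.
#'
#' @return Tibble with added columns `J` (observed) and `sigma`.
#' @export
add_noise <- function(reflections, gain, background_var = 0, seed = NULL) {
  if (gain <= 0) abort("gain must be > 0")
  if (background_var < 0) abort("background_var must be >= 0")
  .with_seed(seed, {
    sigma <- sqrt(reflections$J_true / gain + background_var / gain^2)
    dplyr::mutate(reflections,
                  sigma = sigma,
                  J = .data$J_true + rnorm(dplyr::n(), 0, sigma))
  })
}

# expected shell-mean sigma for exponential intensities of mean m
.expected_mean_sigma <- function(m, gain, background_var = 0) {
  if (background_var == 0) {
    # E[sqrt(J/g)] for J ~ Exp(m) is sqrt(m/g) * gamma(3/2)
    return(sqrt(m / gain) * sqrt(pi) / 2)
  }
  integrate(function(j) sqrt(j / gain + background_var / gain^2) *
              exp(-j / m) / m,
            0, Inf, rel.tol = 1e-9)$value
}

# predicted last-shell <J>/<sigma> for a shell mean m at given noise
.predicted_snr <- function(m, gain, background_var = 0) {
  m / .expected_mean_sigma(m, gain, background_var)
}

#' Calibrate the detector gain to a target last-shell signal-to-noise
#'
#' Finds the gain at which the first (undamaged) wedge of the model has an
#' expected last-resolution-shell `<J>/<sigma>` equal to `noise_target`
#' (the planning convention is a target of 5). Solved on the expectation,
#' so the realized ratio on a finite simulated wedge fluctuates around the
#' target by roughly `1/sqrt(n_per_shell)`.
#'
#' @param model A [wilson_model()].
#' @param noise_target Target `<J>/<sigma>` in the last shell; must be > 0.
#' @param background_var Background variance in squared counts.
#'
#' @return The calibrated gain (counts per intensity unit).
#' @export
calibrate_gain <- function(model, noise_target = 5, background_var = 0) {
  stopifnot(inherits(model, "wilson_model"))
  if (noise_target <= 0) abort("noise_target must be > 0")
  m <- .wilson_mean(model, tail(model$shells$s2_mid, 1))
  if (background_var == 0) {
    # closed form: snr = sqrt(m * g) / gamma(3/2)
    return((noise_target * sqrt(pi) / 2)^2 / m)
  }
  f <- function(lg) .predicted_snr(m, exp(lg), background_var) - noise_target
  sol <- tryCatch(uniroot(f, lower = log(1e-12), upper = log(1e12),
                          tol = 1e-10),
                  error = function(e) abort(paste0(
                    "gain calibration failed (target unreachable): ",
                    conditionMessage(e))))
  exp(sol$root)
}

#' Simulate a full burn/collect experiment
#'
#' Draws one zero-dose reflection set from the Wilson model, then, for each
#' collection cycle of the protocol, decays it to the cumulative dose at the
#' cycle midpoint (collect and burn doses both accumulate) and adds counting
#' noise. All wedges share the same underlying reflections, as in a real
#' experiment where the same narrow wedge is re-collected.
#'
#' @param protocol A [generate_protocol()] object.
#' @param model A [wilson_model()].
#' @param truth A [damage_truth()].
#' @param gain Detector gain; defaults to [calibrate_gain()] at a last-shell
#'   signal-to-noise of 5 on the first wedge.
#' @param background_var Background variance (squared counts).
#' @param n_per_shell Reflections per shell.
#' @param seed Optional integer seed controlling both the reference draw and
#'   the per-wedge noise.
#' @param noiseless If `TRUE`, skip the noise step; `J = J_true` and `sigma`
#'   is a nominal small constant.
#'
#' @return Tibble with one row per reflection per wedge: `wedge_index`
#'   (1-based), `nominal_dose` (MGy), `id`, `shell`, `s2`, `J`, `sigma`.
#' @export
simulate_experiment <- function(protocol, model, truth,
                                gain = NULL, background_var = 0,
                                n_per_shell = 200, seed = NULL,
                                noiseless = FALSE) {
  stopifnot(inherits(protocol, "burn_protocol"),
            inherits(model, "wilson_model"),
            inherits(truth, "damage_truth"))
  stamps <- dose_stamps(protocol)
  if (is.null(gain)) gain <- calibrate_gain(model, 5, background_var)
  .with_seed(seed, {
    ref <- simulate_reference(model, n_per_shell = n_per_shell, seed = NULL)
    purrr::map_dfr(seq_len(nrow(stamps)), function(i) {
      decayed <- apply_decay(ref, stamps$nominal_dose[i], truth)
      obs <- if (noiseless) {
        dplyr::mutate(decayed, sigma = 1e-12, J = .data$J_true)
      } else {
        add_noise(decayed, gain, background_var, seed = NULL)
      }
      dplyr::mutate(obs,
                    wedge_index = stamps$wedge_index[i],
                    nominal_dose = stamps$nominal_dose[i]) |>
        dplyr::select("wedge_index", "nominal_dose", "id", "shell",
                      "s2", "J", "sigma")
    })
  })
}
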