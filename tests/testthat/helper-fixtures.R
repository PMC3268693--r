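# Shared fixtures: a strong diffractor at the standard beamline-like
# conditions (dose rate 0.15 MGy/s, 2.0 A floor), and small helpers.

strong_model <- function() wilson_model(b0 = 20, scale0 = 1000, d_min = 2)

default_char <- function(dose_rate = 0.15, model = strong_model(), ...) {
  characterization_input(dose_rate_mgy_s = dose_rate, model = model, ...)
}

default_protocol <- function(...) generate_protocol(default_char(), ...)

# one simulated experiment ready for scaling
simulated_series <- function(seed, beta_true = 1, noiseless = FALSE,
                             protocol = default_protocol(),
                             model = strong_model(), n_per_shell = 200) {
  simulate_experiment(protocol, model, damage_truth(beta_true = beta_true),
                      n_per_shell = n_per_shell, seed = seed,
                      noiseless = noiseless)
}

# closed-form 2x2 solve of ln(Jw/Jr) = ln k - 2 dB s2 on two shells
two_shell_solution <- function(jw, jr, s2) {
  slope <- (log(jw[2] / jr[2]) - log(jw[1] / jr[1])) / (s2[2] - s2[1])
  intercept <- log(jw[1] / jr[1]) - slope * s2[1]
  list(k = exp(intercept), b = -slope / 2)
}

# published per-sample experimental setups (beam + crystal) used for the
# factor-of-2 dose-rate sanity check
published_setups <- function() {
  tibble::tibble(
    crystal = c("thermolysin", "trypsin", "A-DNA", "FAE 1", "RecR", "GPCR"),
    flux = c(6.2e11, 9.9e11, 2.0e11, 8.0e11, 7.6e11, 4.3e11),
    energy_kev = c(12.76, 12.76, 7.70, 12.64, 12.75, 12.72),
    size = list(c(300, 50, 50), c(900, 100, 100), c(400, 200, 200),
                c(400, 40, 40), c(20, 20, 20), c(50, 40, 10)),
    dose_rate_published = c(0.15, 0.24, 0.14, 0.20, 0.17, 0.10)
  )
}
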