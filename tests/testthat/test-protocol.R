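test_that("the protocol interleaves 11 collections with 10 equal burns", {
  pr <- default_protocol()
  expect_equal(sum(pr$type == "collection"), 11)
  expect_equal(sum(pr$type == "burn"), 10)
  expect_equal(pr$type, rep(c("collection", "burn"), length.out = 21))
  expect_true(all(pr$rotation_deg == pr$rotation_deg[1]))
  expect_true(all(pr$start_angle_deg == pr$start_angle_deg[1]))
  burns <- pr$planned_dose[pr$type == "burn"]
  expect_equal(max(burns) - min(burns), 0, tolerance = 1e-12)
})

test_that("collection-cycle doses never exceed 0.1 MGy", {
  for (dr in c(0.05, 0.15, 0.25)) {
    for (d in c(2, 3, 4.2)) {
      pr <- generate_protocol(default_char(dose_rate = dr), d_min = d)
      expect_true(all(pr$planned_dose[pr$type == "collection"] <= 0.1 + 1e-12))
    }
  }
  expect_error(generate_protocol(default_char(), collection_dose = 0.2),
               "0.1")
})

test_that("the factor-3 rule sets the total dose", {
  expect_equal(total_burn_dose(2, 1), log(3) / 0.125, tolerance = 1e-12)
  expect_equal(total_burn_dose(2, 1), 8.8, tolerance = 0.01)
  expect_equal(total_burn_dose(3, 1), 19.8, tolerance = 0.01)
  expect_gt(total_burn_dose(3, 1), total_burn_dose(2, 1))
  expect_equal(total_burn_dose(2, 2), total_burn_dose(2, 1) / 2,
               tolerance = 1e-12)
  pr <- default_protocol()
  expect_equal(sum(pr$planned_dose), total_burn_dose(2, 1), tolerance = 1e-9)
})

test_that("resolution choice floors at 2.0 A and degrades for weak crystals", {
  char <- default_char()
  expect_equal(choose_resolution(char), 2.0)

  # weaker diffraction (larger B0) at the same detector calibration
  weak <- characterization_input(0.15, wilson_model(60, 1000, d_min = 2),
                                 gain = char$gain)
  d_weak <- choose_resolution(weak)
  expect_gt(d_weak, 2.0)

  # monotone: increasing B0 never improves the resolution
  ds <- vapply(c(20, 40, 60, 80), function(b0) {
    ch <- characterization_input(0.15, wilson_model(b0, 1000, d_min = 2),
                                 gain = char$gain)
    choose_resolution(ch)
  }, numeric(1))
  expect_true(all(diff(ds) >= 0))

  # hopelessly weak: infeasible rather than silently coarse
  hopeless <- characterization_input(0.15, wilson_model(20, 1, d_min = 2),
                                     gain = char$gain / 1e4)
  expect_error(choose_resolution(hopeless), "infeasible")
})

test_that("the predicted signal-to-noise at the chosen resolution is realized", {
  char <- default_char()
  d <- choose_resolution(char)
  pr <- generate_protocol(char, d_min = d)
  snr <- vapply(1:5, function(s) {
    refl <- simulate_experiment(pr, char$model, damage_truth(0),
                                gain = char$gain, seed = s)
    st <- shell_statistics(dplyr::filter(refl, wedge_index == 1))
    st$mean_J[nrow(st)] / st$mean_sigma[nrow(st)]
  }, numeric(1))
  expect_gt(mean(snr), 5 * 0.9)
})

test_that("frame width respects mosaicity and divides the wedge", {
  char <- default_char(mosaicity_deg = 0.5)
  fwe <- frame_width_and_exposure(char, 0.1)
  expect_lte(fwe$frame_width_deg, 1.0)
  expect_equal(fwe$n_frames * fwe$frame_width_deg, char$rotation_range_deg,
               tolerance = 1e-9)
  expect_lte(fwe$transmission, 1)
  expect_gte(fwe$transmission, char$transmission_range[1])

  # higher mosaicity never widens the frames
  widths <- vapply(c(0.1, 0.4, 0.8, 2), function(m) {
    frame_width_and_exposure(default_char(mosaicity_deg = m),
                             0.1)$frame_width_deg
  }, numeric(1))
  expect_true(all(diff(widths) <= 0))
})

test_that("transmission absorbs dose-rate changes; burn exposures scale inversely", {
  pr1 <- generate_protocol(default_char(dose_rate = 0.1))
  pr2 <- generate_protocol(default_char(dose_rate = 0.2))
  expect_equal(pr1$planned_dose, pr2$planned_dose, tolerance = 1e-12)
  b1 <- pr1$exposure_s[pr1$type == "burn"]
  b2 <- pr2$exposure_s[pr2$type == "burn"]
  expect_equal(b1, 2 * b2, tolerance = 1e-12)

  # very high dose rate: minimum exposure forces attenuation, dose unchanged
  fast <- default_char(dose_rate = 5)
  fwe <- frame_width_and_exposure(fast, 0.1)
  expect_lt(fwe$transmission, 1)
  delivered <- fwe$exposure_total_s * fwe$transmission * 5
  expect_equal(delivered, 0.1, tolerance = 1e-9)
})

test_that("dose stamps increase strictly and account for every cycle", {
  pr <- default_protocol()
  st <- dose_stamps(pr)
  expect_equal(nrow(st), 11)
  expect_true(all(diff(st$nominal_dose) > 0))
  expect_lt(st$nominal_dose[11], sum(pr$planned_dose))

  # without burns, stamps advance by collection doses only
  char <- default_char()
  pr2 <- generate_protocol(char, d_min = 3)
  st2 <- dose_stamps(pr2)
  gaps <- diff(st2$nominal_dose)
  burn_each <- pr2$planned_dose[pr2$type == "burn"][1]
  expect_equal(unique(round(gaps - burn_each, 9)), 0.1)
})

test_that("the schedule tolerates a factor-3 error in the assumed sensitivity", {
  pr <- default_protocol()
  wm <- strong_model()
  for (bt in c(1 / 3, 1, 3)) {
    refl0 <- simulate_experiment(pr, wm, damage_truth(beta_true = bt),
                                 seed = 2, noiseless = TRUE)
    sc <- scale_wedge_series(refl0)
    expect_true(all(diff(sc$b) > 0))
    fit <- fit_beta(sc, weighted = FALSE)
    expect_gt(fit$r_squared, 0.9)
    expect_equal(fit$beta, bt, tolerance = 1e-6)
  }
})
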