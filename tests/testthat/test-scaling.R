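test_that("shell statistics report means, counts and last-shell signal-to-noise", {
  refl <- tibble::tibble(s2 = c(0.01, 0.012), J = c(2, 4), sigma = c(1, 2))
  st <- shell_statistics(refl, n_shells = 1)
  expect_equal(st$mean_J, 3)
  expect_equal(st$mean_sigma, 1.5)
  expect_equal(st$n_obs, 2L)
  expect_equal(st$mean_J / st$mean_sigma, 2)  # snr by definition

  # equal-width binning on raw s2 (no shell column)
  raw <- tibble::tibble(s2 = seq(0.01, 0.06, length.out = 60),
                        J = 1, sigma = 1)
  st2 <- shell_statistics(raw, n_shells = 5)
  expect_equal(nrow(st2), 5)
  expect_false(attr(st2, "merged"))
  # empty interior bin gets merged and flagged
  gap <- tibble::tibble(s2 = c(0.01, 0.011, 0.012, 0.05, 0.051, 0.052),
                        J = 1, sigma = 1)
  expect_warning(st3 <- shell_statistics(gap, n_shells = 4), "merged")
  expect_true(attr(st3, "merged"))
  # a discrete s2 grid is grouped by value, one shell per distinct s2
  grid <- tibble::tibble(s2 = rep(c(0.01, 0.02, 0.03), each = 5),
                         J = 1, sigma = 1)
  st4 <- shell_statistics(grid, n_shells = 10)
  expect_equal(nrow(st4), 3)
  expect_equal(st4$n_obs, rep(5L, 3))
})

test_that("single-wedge scaling recovers exact scale and B against a reference", {
  wm <- strong_model()
  ref <- simulate_reference(wm, 50, seed = 2) |>
    dplyr::mutate(J = J_true, sigma = 1) |>
    shell_statistics()

  expect_equal(fit_wedge_scale(ref, ref)$k, 1, tolerance = 1e-12)
  expect_equal(fit_wedge_scale(ref, ref)$b, 0, tolerance = 1e-12)

  wedge <- dplyr::mutate(ref, mean_J = mean_J * 0.8 * exp(-2 * 2 * s2_mid))
  fit <- fit_wedge_scale(wedge, ref)
  expect_equal(fit$k, 0.8, tolerance = 1e-9)
  expect_equal(fit$b, 2.0, tolerance = 1e-9)
})

test_that("two-shell scaling equals the closed-form 2x2 solution", {
  ref <- tibble::tibble(shell = 1:2, s2_lo = c(0.01, 0.04),
                        s2_hi = c(0.04, 0.07), s2_mid = c(0.025, 0.055),
                        mean_J = c(120, 40), mean_sigma = c(3, 2),
                        n_obs = c(100, 100))
  wedge <- dplyr::mutate(ref, mean_J = mean_J * 0.7 * exp(-2 * 1.6 * s2_mid))
  oracle <- two_shell_solution(wedge$mean_J, ref$mean_J, ref$s2_mid)
  fit <- fit_wedge_scale(wedge, ref)
  expect_equal(fit$k, oracle$k, tolerance = 1e-9)
  expect_equal(fit$b, oracle$b, tolerance = 1e-9)
  expect_equal(oracle$k, 0.7, tolerance = 1e-9)
  expect_equal(oracle$b, 1.6, tolerance = 1e-9)
})

test_that("scaling estimates are unbiased under gaussian noise", {
  wm <- strong_model()
  base <- simulate_reference(wm, 200, seed = 33)
  ref <- shell_statistics(dplyr::mutate(base, J = J_true, sigma = 1))
  true_k <- 0.85
  true_b <- 1.5
  set.seed(99)
  est <- t(replicate(500, {
    noisy <- base |>
      dplyr::mutate(J_true = J_true * true_k * exp(-2 * true_b * s2)) |>
      add_noise(gain = 1, background_var = 0) |>
      shell_statistics()
    unlist(fit_wedge_scale(noisy, ref)[, c("k", "b")])
  }))
  se_b <- sd(est[, "b"]) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, "b"]) - true_b), 2 * se_b + 0.01)
  se_k <- sd(est[, "k"]) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, "k"]) - true_k), 2 * se_k + 0.005)
})

test_that("degenerate scaling inputs are rejected or excluded", {
  ref <- tibble::tibble(shell = 1, s2_lo = 0.01, s2_hi = 0.02,
                        s2_mid = 0.015, mean_J = 10, mean_sigma = 1,
                        n_obs = 10)
  expect_error(fit_wedge_scale(ref, ref), "degenerate")
  ref3 <- tibble::tibble(shell = 1:3, s2_lo = 1:3 / 100, s2_hi = 2:4 / 100,
                         s2_mid = c(0.015, 0.025, 0.035),
                         mean_J = c(10, 8, -1), mean_sigma = 1,
                         n_obs = 10)
  wedge3 <- dplyr::mutate(ref3, mean_J = abs(mean_J))
  expect_warning(fit <- fit_wedge_scale(wedge3, ref3), "excluded")
  expect_equal(fit$n_shells_used, 2L)
})

test_that("joint scaling fixes the gauge and is order-invariant", {
  wm <- strong_model()
  pr <- default_protocol()
  refl <- simulated_series(seed = 17)
  sc <- suppressWarnings(scale_wedge_series(refl))
  expect_equal(sc$b[1], 0, tolerance = 1e-12)
  expect_equal(max(sc$k), 1, tolerance = 1e-12)
  expect_true(attr(sc, "converged"))

  shuffled <- refl[sample.int(nrow(refl)), ]
  sc2 <- suppressWarnings(scale_wedge_series(shuffled))
  expect_equal(sc$k, sc2$k, tolerance = 1e-12)
  expect_equal(sc$b, sc2$b, tolerance = 1e-12)

  # all wedges identical: k = 1, B = 0 throughout
  one <- dplyr::filter(refl, wedge_index == 1)
  same <- purrr::map_dfr(1:3, function(i) {
    dplyr::mutate(one, wedge_index = i, nominal_dose = i * 0.5)
  })
  sc3 <- scale_wedge_series(same)
  expect_equal(sc3$k, rep(1, 3), tolerance = 1e-12)
  expect_equal(sc3$b, rep(0, 3), tolerance = 1e-12)
})

test_that("noiseless decay series is recovered exactly and monotonically", {
  refl0 <- simulated_series(seed = 4, noiseless = TRUE)
  sc0 <- scale_wedge_series(refl0)
  expect_true(all(diff(sc0$b) > 0))
  # B_i = beta_true * (D_i - D_1) to near machine precision
  expected <- sc0$nominal_dose - sc0$nominal_dose[1]
  expect_equal(sc0$b, expected, tolerance = 1e-6)
})

test_that("pairwise scaling is reciprocal in the noiseless case", {
  wm <- strong_model()
  ref <- simulate_reference(wm, 100, seed = 8) |>
    dplyr::mutate(J = J_true, sigma = 1) |>
    shell_statistics()
  wedge <- dplyr::mutate(ref, mean_J = mean_J * 0.6 * exp(-2 * 3 * s2_mid))
  fwd <- fit_wedge_scale(wedge, ref)
  rev <- fit_wedge_scale(ref, wedge)
  expect_equal(fwd$k * rev$k, 1, tolerance = 1e-8)
  expect_equal(fwd$b + rev$b, 0, tolerance = 1e-8)
})

test_that("recovered B series is linear in dose with slope near truth", {
  refl <- simulated_series(seed = 23)
  sc <- suppressWarnings(scale_wedge_series(refl))
  fit <- fit_beta(sc)
  expect_lt(abs(fit$beta - 1), 0.05 * 3)  # single-seed slack; mean tested elsewhere
  expect_gt(fit$r_squared, 0.99)
})
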