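test_that("absorption coefficient is zero for vacuum and increases toward low energy", {
  vac <- composition(tibble::tibble(element = character(),
                                    n_per_nm3 = numeric()),
                     density = 1, label = "vacuum")
  expect_identical(absorption_coefficient(vac, 12.4), 0)

  dc <- default_composition()
  expect_gt(absorption_coefficient(dc, 6.35),
            absorption_coefficient(dc, 12.7))
  # roughly photoelectric E^-3 scaling away from edges
  ratio <- absorption_coefficient(dc, 6.35) / absorption_coefficient(dc, 12.7)
  expect_gt(ratio, 4)
})

test_that("water energy-absorption matches tabulated reference values within 10%", {
  # NIST mass energy-absorption coefficients for liquid water, cm^2/g
  nist <- c("10" = 4.944, "15" = 1.374)
  w <- water_composition()
  for (e in names(nist)) {
    mu_mass <- absorption_coefficient(w, as.numeric(e)) * 10 / w$density
    expect_lt(abs(mu_mass - nist[[e]]) / nist[[e]], 0.10)
  }
})

test_that("absorption coefficient is continuous in energy for edge-free compositions", {
  dc <- default_composition()  # H,C,N,O,S: no edges in [5, 25] keV
  es <- seq(5, 25, by = 0.1)
  mu <- absorption_coefficient(dc, es)
  rel_step <- abs(diff(mu)) / mu[-length(mu)]
  expect_lt(max(rel_step), 0.06)
  expect_true(all(diff(mu) < 0))  # monotone decreasing away from edges
})

test_that("energy range and unknown elements are rejected", {
  dc <- default_composition()
  expect_error(absorption_coefficient(dc, 4.0), "range")
  expect_error(absorption_coefficient(dc, 30), "range")
  expect_error(
    composition(tibble::tibble(element = "Xx", n_per_nm3 = 1), density = 1),
    "unsupported element")
})

test_that("dose rate is linear in flux and zero at zero flux", {
  set.seed(7)
  for (i in 1:10) {
    flux <- runif(1, 1e10, 1e13)
    energy <- runif(1, 6, 20)
    sz <- runif(3, 10, 400)
    profile <- sample(c("gaussian", "uniform"), 1)
    cr <- crystal_description(sz)
    d1 <- dose_rate(beam_parameters(flux, energy, profile = profile), cr)$value
    d2 <- dose_rate(beam_parameters(2 * flux, energy, profile = profile),
                    cr)$value
    expect_equal(d2, 2 * d1, tolerance = 1e-12)
  }
  expect_identical(
    dose_rate(beam_parameters(0, 12.7), crystal_description(c(50, 50, 50)))$value,
    0)
})

test_that("dose rate matches a voxelized numeric integration", {
  beam <- beam_parameters(1e12, 12.7, fwhm_h_um = 45, fwhm_v_um = 35,
                          profile = "gaussian")
  cr <- crystal_description(c(60, 40, 30))
  analytic <- dose_rate(beam, cr)$value

  # brute force: integrate the gaussian flux density over the illuminated
  # footprint and deposit 1 - exp(-mu t) along each voxel column
  comp <- cr$composition
  mu_mm <- absorption_coefficient(comp, beam$energy_kev)
  sig_h <- 45 / (2 * sqrt(2 * log(2)))
  sig_v <- 35 / (2 * sqrt(2 * log(2)))
  hx <- min(3 * sig_h, 30); hy <- min(3 * sig_v, 20)
  nx <- 400; ny <- 400
  xs <- seq(-hx, hx, length.out = nx)
  ys <- seq(-hy, hy, length.out = ny)
  wx <- exp(-xs^2 / (2 * sig_h^2)) / (sqrt(2 * pi) * sig_h)
  wy <- exp(-ys^2 / (2 * sig_v^2)) / (sqrt(2 * pi) * sig_v)
  # truncation renormalization as in the beam model
  trunc_norm <- (pnorm(3) - pnorm(-3))^2
  frac_hit <- sum(wx) * diff(xs)[1] * sum(wy) * diff(ys)[1] / trunc_norm
  absorbed <- 1 - exp(-mu_mm * 30e-3)
  e_j <- beam$energy_kev * 1.602176634e-16
  power <- beam$flux * frac_hit * e_j * absorbed
  mass <- comp$density * (2 * hx * 1e-4) * (2 * hy * 1e-4) * (30e-4) * 1e-3
  brute <- power / mass / 1e6
  expect_equal(analytic, brute, tolerance = 0.01)
})

test_that("thin-crystal limit reduces to flux density * E * mu/rho", {
  beam <- beam_parameters(1e11, 12.7, fwhm_h_um = 50, fwhm_v_um = 50,
                          profile = "uniform")
  cr <- crystal_description(c(200, 200, 1))  # 1 um path: mu*t << 1
  comp <- cr$composition
  mu_mm <- absorption_coefficient(comp, 12.7)
  e_j <- 12.7 * 1.602176634e-16
  flux_density <- beam$flux / (50e-4 * 50e-4)        # photons / s / cm^2
  mu_rho <- mu_mm * 10 / comp$density                # cm^2 / g
  closed <- flux_density * e_j * mu_rho * 1000 / 1e6 # MGy/s
  expect_equal(dose_rate(beam, cr)$value, closed, tolerance = 0.001)
})

test_that("heavier compositions absorb more at equal density", {
  light <- composition(tibble::tibble(element = "C", n_per_nm3 = 50),
                       density = 1)
  heavy <- composition(tibble::tibble(element = "S", n_per_nm3 = 50),
                       density = 1)
  expect_gt(absorption_coefficient(heavy, 12.4),
            absorption_coefficient(light, 12.4))
})

test_that("beta correction factor is 1 for identical compositions and > 1 with heavy atoms", {
  beam <- beam_parameters(6e11, 12.7)
  cr <- crystal_description(c(100, 100, 100))
  expect_equal(beta_correction_factor(beam, cr), 1, tolerance = 1e-12)

  se_comp <- protein_crystal_composition(extra_per_residue = c(Se = 0.05))
  cr_se <- crystal_description(c(100, 100, 100), comp = se_comp)
  r <- beta_correction_factor(beam, cr_se)
  expect_gt(r, 1)
  # the factor is exactly the ratio of the two dose rates
  ref <- crystal_description(c(100, 100, 100))
  expect_equal(r, dose_rate(beam, cr_se)$value / dose_rate(beam, ref)$value,
               tolerance = 1e-12)
})

test_that("dose rates for the published experimental setups agree within a factor of 2", {
  # top-hat beam profile, as assumed by the dose-estimation programs of the
  # era the published rates were computed with
  setups <- published_setups()
  for (i in seq_len(nrow(setups))) {
    beam <- beam_parameters(setups$flux[i], setups$energy_kev[i],
                            profile = "uniform")
    dr <- dose_rate(beam, crystal_description(setups$size[[i]]))$value
    ratio <- dr / setups$dose_rate_published[i]
    expect_gt(ratio, 0.5)
    expect_lt(ratio, 2)
  }
})

test_that("invalid beams and crystals are rejected", {
  expect_error(beam_parameters(-1, 12), "flux")
  expect_error(beam_parameters(1e12, 0), "energy")
  expect_error(crystal_description(c(0, 10, 10)), "positive")
  expect_error(crystal_description(c(10, 10)), "positive|three")
})
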