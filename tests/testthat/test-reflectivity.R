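test_that("band energy fractions are exact on analytic irradiances", {
  const <- flat_spectrum(1.0, 300, 500, by = 10, kind = "irradiance")
  expect_equal(band_energy_fraction(const, band(300, 400), band(300, 500)),
               0.5)
  expect_equal(band_energy_fraction(const, band(300, 500), band(300, 500)),
               1.0)
  # endpoints not on the grid are interpolated in
  expect_equal(band_energy_fraction(const, band(305.5, 402.5),
                                    band(300, 500)), 97 / 200)
  expect_error(band_energy_fraction(const, band(300, 600), band(300, 500)),
               "not contained")
})

test_that("band fractions over a partition of the reference sum to one", {
  sun <- solar_spectrum_synthetic()
  ref <- band(300, 2600)
  cuts <- c(300, 454.3, 700, 950, 1233.7, 1700, 2600)
  fracs <- vapply(seq_len(length(cuts) - 1L), function(i)
    band_energy_fraction(sun, band(cuts[i], cuts[i + 1L]), ref), numeric(1))
  expect_true(all(fracs >= 0 & fracs <= 1))
  expect_equal(sum(fracs), 1, tolerance = 1e-9)
})

test_that("reflectivity reproduces closed-form cases", {
  sun <- solar_spectrum_synthetic(seq(300, 1700))
  ones <- flat_spectrum(1.0, 300, 1700)
  zeros <- flat_spectrum(0, 300, 1700)
  expect_equal(reflectivity(ones, sun, band(300, 1700))$R_percent, 100)
  expect_equal(reflectivity(zeros, sun, band(300, 1700))$R_percent, 0)

  # linearly rising reflectance under constant irradiance: mean 1/2
  rising <- spectrum(c(300, 1700), c(0, 1))
  flat_sun <- flat_spectrum(0.8, 300, 1700, kind = "irradiance")
  expect_equal(reflectivity(rising, flat_sun, band(300, 1700))$R_percent, 50,
               tolerance = 1e-9)
})

test_that("constant reflectance gives 100c percent under any irradiance", {
  irrs <- list(solar_spectrum_synthetic(seq(300, 1700)),
               flat_spectrum(2, 300, 1700, kind = "irradiance"),
               smooth_irradiance())
  for (c_val in c(0.05, 0.31, 0.99)) {
    s <- flat_spectrum(c_val, 300, 1700)
    for (I in irrs)
      expect_equal(reflectivity(s, I, band(320, 1650))$R_percent, 100 * c_val,
                   tolerance = 1e-9)
  }
})

test_that("reflectivity is monotone in pointwise reflectance", {
  sun <- solar_spectrum_synthetic(seq(300, 1700))
  set.seed(11)
  for (i in 1:5) {
    wl <- seq(300, 1700, by = 1)
    lo_vals <- pmin(pmax(0.2 + cumsum(rnorm(length(wl), 0, 1e-3)), 0), 1)
    hi_vals <- pmin(lo_vals + runif(length(wl), 0, 0.3), 1.2)
    s_lo <- spectrum(wl, lo_vals)
    s_hi <- spectrum(wl, hi_vals)
    expect_gte(reflectivity(s_hi, sun, band(300, 1700))$R_percent,
               reflectivity(s_lo, sun, band(300, 1700))$R_percent)
  }
})

test_that("trapezoid reflectivity matches the exact product integral", {
  S <- smooth_reflectance()
  I <- smooth_irradiance()
  res <- reflectivity(S, I, band(300, 1700))$R_percent
  wl <- S$wavelength_nm
  oracle <- 100 * exact_product_integral(wl, S$value, I$value) /
    trapz_ref(wl, I$value)
  expect_equal(res, oracle, tolerance = 1e-6)
})

test_that("reflectivity refuses bands with coverage gaps", {
  sun <- solar_spectrum_synthetic(seq(300, 1700))
  short <- flat_spectrum(0.5, 300, 950)
  err <- tryCatch(reflectivity(short, sun, band(300, 1700)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "missing interval")
  expect_match(err, "1700")
})

test_that("exponential extension matches its closed form and is continuous", {
  # R(950) = 0.10, slope -1e-4 per nm -> k = 1e-3, R(1700) = 0.1 e^-0.75
  wl <- seq(700, 950, by = 1)
  s <- spectrum(wl, 0.10 - 1e-4 * (wl - 950))
  ext <- extend_exponential(s)
  expect_equal(max(ext$wavelength_nm), 1700)
  at <- function(sp, w) sp$value[sp$wavelength_nm == w]
  expect_equal(at(ext, 950), 0.10, tolerance = 1e-9)
  expect_equal(at(ext, 1700), 0.10 * exp(-0.75), tolerance = 1e-6)
  # continuity at the anchor: no jump between 949, 950, 951
  expect_lt(abs(at(ext, 951) - at(ext, 950)), 2e-4)

  # zero trailing slope: constant continuation
  s_flat <- spectrum(wl, rep(0.25, length(wl)))
  ext_flat <- extend_exponential(s_flat)
  expect_equal(at(ext_flat, 1700), 0.25, tolerance = 1e-9)
  # positive trailing slope also falls back to a constant
  s_up <- spectrum(wl, 0.2 + 1e-4 * (wl - 700))
  expect_equal(extend_exponential(s_up)$value[
    extend_exponential(s_up)$wavelength_nm == 1700], at(s_up, 950),
    tolerance = 1e-9)

  expect_error(extend_exponential(spectrum(c(900, 940), c(0.1, 0.1))),
               "slope window")
})

test_that("linear extension continues the fitted slope and clips at zero", {
  wl <- seq(700, 950, by = 1)
  at <- function(sp, w) sp$value[sp$wavelength_nm == w]
  # R(950) = 0.05, slope -1e-4: hits zero at 1450 and stays there
  s <- spectrum(wl, 0.05 - 1e-4 * (wl - 950))
  ext <- extend_linear(s)
  expect_equal(at(ext, 1450), 0, tolerance = 1e-9)
  expect_equal(at(ext, 1700), 0)
  expect_equal(at(ext, 1200), 0.05 - 1e-4 * 250, tolerance = 1e-9)
  expect_true(all(ext$value >= 0))
  # rising slope: no clipping
  s_up <- spectrum(wl, 0.30 + 2e-4 * (wl - 950))
  expect_equal(at(extend_linear(s_up), 1700), 0.45, tolerance = 1e-9)
  # continuity at 950
  expect_equal(at(ext, 950), 0.05, tolerance = 1e-9)

  expect_error(extend_linear(spectrum(c(900, 940), c(0.1, 0.1))),
               "slope window")
})

test_that("group comparison is exact, symmetric, and validates its inputs", {
  expect_equal(group_comparison(c(4.2), c(4.2))$difference_rounded, 0)
  g <- group_comparison(c(10, 20), c(5))
  expect_equal(g$mean_difference, g$mean_hi - g$mean_lo)

  sun <- solar_spectrum_synthetic(seq(300, 1700))
  r1 <- reflectivity(flat_spectrum(0.5, 300, 1700), sun, band(300, 1700))
  r2 <- reflectivity(flat_spectrum(0.2, 300, 1700), sun, band(300, 1700),
                     method = "linear_extension")
  expect_error(group_comparison(rbind(r1, r2), r1), "methods")
  r3 <- reflectivity(flat_spectrum(0.4, 300, 1700), sun, band(300, 950))
  expect_error(group_comparison(rbind(r1, r3), r1), "bands")
  # reflectivity_result inputs work like numeric ones
  expect_equal(group_comparison(r1, r3 <- r1)$difference_rounded, 0)
})
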