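test_that("segmentation assigns samples by elapsed time", {
  sch <- default_schedule()
  expect_equal(sum(sch$duration_s), 8400)
  t <- seq(0, by = 20, length.out = 420)
  tr <- heating_trace(t, internal_C = rep(20, 420))
  seg <- segment(tr, sch)
  expect_equal(sum(seg$phase == "stabilise"), 15)       # t = 0..280
  expect_equal(seg$phase[seg$time_s == 300], factor("full_spectrum",
               levels = sch$label))                     # boundary -> later
  expect_false(anyNA(seg$phase))

  # shifting the schedule start shifts every boundary
  seg2 <- segment(heating_trace(t + 100, internal_C = rep(20, 420)), sch,
                  start_s = 100)
  expect_equal(as.character(seg2$phase), as.character(seg$phase))

  short <- heating_trace(seq(0, by = 20, length.out = 100),
                         internal_C = rep(20, 100))
  expect_error(segment(short, sch), "covers only")
  expect_error(regime_schedule(character(0), character(0), numeric(0),
                               list()), "at least one phase")
})

test_that("heating rate is the exact slope of an affine trace", {
  sch <- mini_schedule()
  tr <- affine_trace(sch, intercept = 20, slope_per_s = 0.0234)
  for (w in c(60, 120, 300, 600))
    expect_equal(heating_rate(tr, sch, "heat", "internal_C", window_s = w),
                 0.0234 * 60, tolerance = 1e-12)
  expect_equal(heating_rate(tr, sch, "heat"), 1.404)

  # constant trace: zero rate; adding a constant leaves the rate unchanged
  t <- tr$time_s
  flat <- heating_trace(t, internal_C = rep(21, length(t)))
  expect_equal(heating_rate(flat, sch, "heat"), 0)
  shifted <- heating_trace(t, internal_C = tr$internal_C + 7)
  expect_equal(heating_rate(shifted, sch, "heat"),
               heating_rate(tr, sch, "heat"))
})

test_that("heating rate from noisy samples stays near the true slope", {
  sch <- mini_schedule()
  t <- seq(0, sum(sch$duration_s) - 20, by = 20)
  set.seed(202)
  noisy <- heating_trace(t, internal_C = 20 + 0.02 * t + rnorm(length(t),
                                                               0, 0.05))
  # 7 samples in the 2 min window; OLS sampling error is well under 0.1
  est <- heating_rate(noisy, sch, "heat")
  expect_lt(abs(est - 1.2), 0.1)

  expect_error(heating_rate(noisy, sch, "heat", window_s = 30), "fewer than 3")
  expect_error(heating_rate(noisy, sch, "pre"), "not a heating phase")
  expect_error(heating_rate(noisy, sch, "heat", channel = "surface_C"),
               "absent")
})

test_that("end temperature distinguishes final-sample and phase-maximum", {
  sch <- mini_schedule()
  t <- seq(0, sum(sch$duration_s) - 20, by = 20)
  rising <- heating_trace(t, internal_C = 20 + 0.002 * t)
  expect_equal(end_temperature(rising, sch, "heat"),
               end_temperature(rising, sch, "heat", mode = "max"))

  # dip after an early peak: final != max
  ph_t <- t - 300
  dip <- 22 + 3 * exp(-pmax(ph_t - 400, 0)^2 / 1e5) * (ph_t > 0)
  dip_tr <- heating_trace(t, internal_C = dip)
  expect_lt(end_temperature(dip_tr, sch, "heat"),
            end_temperature(dip_tr, sch, "heat", mode = "max"))
  expect_equal(end_temperature(dip_tr, sch, "heat", mode = "max"), 25,
               tolerance = 0.01)

  # saturating exponential approach: closed-form end value
  sat <- heating_trace(t, internal_C = ifelse(ph_t < 0, 20,
                                              28 - 8 * exp(-ph_t / 600)))
  last_t <- max(ph_t)
  expect_equal(end_temperature(sat, sch, "heat"),
               28 - 8 * exp(-last_t / 600), tolerance = 1e-9)
  expect_equal(round(end_temperature(sat, sch, "heat"), 1), 27.6)
  # final never exceeds the maximum
  for (tr in list(rising, dip_tr, sat))
    expect_lte(end_temperature(tr, sch, "heat"),
               end_temperature(tr, sch, "heat", mode = "max"))
})

test_that("summarize_heating tabulates constructed slopes exactly", {
  sch <- default_schedule()
  t <- seq(0, 8380, by = 20)
  mk <- function(slopes) {
    # piecewise-affine: given slope per phase (C/s), cooling phases flat
    v <- numeric(length(t)); cur <- 20
    for (i in seq_len(nrow(sch))) {
      idx <- t >= sch$start_s[i] & t < sch$end_s[i]
      ph_t <- t[idx] - sch$start_s[i]
      v[idx] <- cur + slopes[i] * ph_t
      cur <- cur + slopes[i] * sch$duration_s[i]
    }
    v
  }
  slopes1 <- c(0, 0.005, 0, 0.002, 0, 0.001, 0)
  slopes2 <- c(0, 0.004, 0, 0.003, 0, 0.0005, 0)
  tr1 <- heating_trace(t, internal_C = mk(slopes1), label = "m1",
                       treatment = "LNIR")
  tr2 <- heating_trace(t, internal_C = mk(slopes2), label = "m2",
                       treatment = "HNIR")
  tab <- summarize_heating(list(tr1, tr2), sch)
  expect_equal(nrow(tab), 6)    # 2 traces x 3 heating phases x 1 channel
  r1 <- tab[tab$label == "m1", ]
  expect_equal(r1$heating_rate_C_per_min[r1$phase == "full_spectrum"],
               0.005 * 60, tolerance = 1e-9)
  expect_equal(r1$heating_rate_C_per_min[r1$phase == "nir_only"],
               0.002 * 60, tolerance = 1e-9)
  # monotone phases: end_C equals the phase maximum, no flag
  expect_false(any(tab$end_differs))
  expect_equal(tab$end_C, tab$end_C_max)
})

test_that("heating traces validate sampling regularity and bounds", {
  expect_error(heating_trace(c(0, 20, 60), internal_C = c(20, 20, 20)),
               "irregular")
  expect_error(heating_trace(c(0, 20, 40), internal_C = c(20, 95, 20)),
               "plausible")
  expect_error(heating_trace(c(0, 20, 40)), "channel")
  # trace files round-trip through the CSV reader
  t <- seq(0, 200, by = 20)
  tr <- heating_trace(t, internal_C = 20 + 0.01 * t, surface_C = 21 + 0.02 * t)
  p <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = t, internal_C = tr$internal_C,
                       surface_C = tr$surface_C), p, row.names = FALSE)
  tr2 <- read_heating_trace(p, treatment = "LNIR", size = "large")
  expect_equal(tr2$internal_C, tr$internal_C)
  expect_identical(tr2$treatment, "LNIR")
})
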