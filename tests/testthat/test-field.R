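test_that("surface-vs-leaf deltas are simple differences with NA handling", {
  obs <- data.frame(pair_id = c("p1", "p1", "p2"),
                    coating = c("HNIR", "LNIR", "uncoated"),
                    model_surface_C = c(24.0, 26.0, 24.0),
                    leaf_surface_C = c(26.0, 26.0, NA))
  expect_message(d <- surface_leaf_delta(obs), "dropped")
  expect_equal(nrow(d), 2)
  expect_equal(d$delta_C, c(-2.0, 0.0))

  # constructed uncoated group 2 C below the leaf
  set.seed(5)
  n <- 200
  leaf <- 26 + rnorm(n, 0, 0.5)
  obs2 <- data.frame(coating = "uncoated", model_surface_C = leaf - 2 +
                       rnorm(n, 0, 0.3), leaf_surface_C = leaf)
  expect_equal(mean(surface_leaf_delta(obs2)$delta_C), -2, tolerance = 0.1)
})

test_that("daily 95th percentile follows order-statistic interpolation", {
  mk <- function(v) field_series(seq(0, by = 300, length.out = length(v)), v,
                                 "m1", "HNIR", "small", "p1", "s1")
  expect_equal(daily_p95(mk(sample(1:100)))$p95_C, 95.05)
  expect_equal(daily_p95(mk(rep(23.5, 40)))$p95_C, 23.5)

  # equals the brute-force sorted interpolation, lies within [min, max]
  set.seed(31)
  for (i in 1:10) {
    n <- sample(20:120, 1)
    v <- rnorm(n, 25, 2)
    p <- runif(1, 0.5, 0.99)
    got <- daily_p95(mk(v), p = p)$p95_C
    expect_equal(got, brute_quantile(v, p))
    expect_gte(got, min(v)); expect_lte(got, max(v))
  }

  # a single +10 C spike among 96 samples does not reach the 95th percentile
  v <- rep(25, 96); v[40] <- 35
  expect_lt(daily_p95(mk(v))$p95_C, 35)

  expect_warning(out <- daily_p95(list(mk(rep(25, 5)), mk(rep(26, 40)))),
                 "omitted")
  expect_equal(nrow(out), 1)
})

test_that("paired differences are oriented LNIR minus HNIR and antisymmetric", {
  t <- seq(0, by = 300, length.out = 50)
  hn <- field_series(t, rep(25, 50), "mH", "HNIR", "small", "p1", "s1")
  ln <- field_series(t, rep(26, 50), "mL", "LNIR", "small", "p1", "s1")
  d1 <- pair_difference(hn, ln)
  expect_equal(unique(d1$diff_C), 1.0)      # LNIR is 1 C warmer
  d2 <- pair_difference(ln, hn)
  expect_equal(d2$diff_C, d1$diff_C)        # orientation fixed by treatment
  same <- pair_difference(hn, field_series(t, rep(25, 50), "mL", "LNIR",
                                           "small", "p1", "s1"))
  expect_true(all(same$diff_C == 0))

  # uncoated pairs: large minus small
  us <- field_series(t, rep(24, 50), "u1", "uncoated", "small", "p2", "s1")
  ul <- field_series(t, rep(25.5, 50), "u2", "uncoated", "large", "p2", "s1")
  expect_equal(unique(pair_difference(us, ul)$diff_C), 1.5)

  expect_error(pair_difference(hn, us), "different pairs")
  # offset timestamps beyond tolerance: unmatched samples dropped / error
  ln_late <- field_series(t + 200, rep(26, 50), "mL", "LNIR", "small",
                          "p1", "s1")
  expect_error(pair_difference(hn, ln_late, tolerance_s = 50), "matched")
})

test_that("delta LMM detects a constructed uncoated offset", {
  set.seed(77)
  d <- make_null_lmm_data(coating_shift = c(0, 0, -2))
  fit <- fit_delta_lmm(d)
  expect_s3_class(fit, "stat_test_result")
  expect_equal(fit$terms$df[fit$terms$term == "coating"], 2)
  expect_lt(fit$terms$p[fit$terms$term == "coating"], 0.001)
  g <- fit$groups
  unc <- g[g$coating == "uncoated", ]
  coa <- g[g$coating != "uncoated", ]
  expect_true(all(unc$upper < min(coa$lower)))
  expect_equal(mean(unc$estimate) - mean(coa$estimate), -2, tolerance = 0.4)
})

test_that("p95 LMM recovers logger-level bias as a variance component", {
  set.seed(78)
  d <- make_null_lmm_data(n_days = 4)
  # inject a per-logger bias
  loggers <- unique(d$logger_id)
  bias <- setNames(rnorm(length(loggers), 0, 1.5), loggers)
  d$p95_C <- d$p95_C + bias[d$logger_id]
  fit <- fit_p95_lmm(d)
  expect_s3_class(fit, "stat_test_result")
  # with strong logger bias the logger intercept must have survived the fit
  expect_match(fit$structure, "logger_id")
  expect_equal(fit$terms$df, c(2, 1, 2))
})

test_that("paired AR1 model recovers constructed intercepts and phi", {
  set.seed(90)
  # mean +1 C: CI excludes zero and contains the truth
  d1 <- make_diff_data(n_sites = 5, n_pairs = 4, n = 80, mu = 1.0)
  f1 <- fit_paired_ar1(d1, include_size = FALSE)
  expect_false(f1$intercept$crosses_zero)
  expect_gt(f1$intercept$lower, 0)
  expect_lt(abs(f1$intercept$estimate - 1.0), 0.15)
  expect_lt(abs(f1$phi - 0.8), 0.1)

  # independent noise: estimated autocorrelation near zero
  d2 <- make_diff_data(n_sites = 4, n_pairs = 3, n = 100, mu = 0, phi = 0)
  f2 <- fit_paired_ar1(d2, include_size = FALSE)
  expect_lt(abs(f2$phi), 0.15)

  # air and size predictors produce Wald tests with 1 d.f. each
  d3 <- make_diff_data(n_sites = 4, n_pairs = 4, n = 60, with_air = TRUE)
  d3$size <- rep(c("small", "large"), length.out = nrow(d3))
  f3 <- fit_paired_ar1(d3)
  expect_setequal(f3$terms$term, c("air_C", "size"))
  expect_true(all(f3$terms$df == 1))
})

test_that("paired AR1 intercepts are recovered without bias at scale", {
  set.seed(91)
  for (mu in c(0, 0.5, 1.0)) {
    d <- make_diff_data(n_sites = 10, n_pairs = 5, n = 80, mu = mu)
    f <- fit_paired_ar1(d, include_size = FALSE)
    expect_lt(abs(f$intercept$estimate - mu), 0.1)
  }
})

test_that("sunspot detection flags sharp transient spikes only", {
  t <- seq(0, by = 300, length.out = 96)
  mk <- function(v, id = "m1", trt = "HNIR")
    field_series(t, v, id, trt, "small", "p1", "s1")

  expect_equal(nrow(detect_sunspot_events(mk(rep(25, 96)))), 0)

  # 25 min rectangular spike of +3 C
  v <- rep(25, 96)
  spike_idx <- t >= 4 * 3600 & t < 4 * 3600 + 25 * 60
  v[spike_idx] <- 28
  ev <- detect_sunspot_events(mk(v))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_min, 25, tolerance = 5)
  expect_equal(ev$peak_excess_C, 3, tolerance = 0.01)

  # a slow 3 C drift over hours is not a sunspot
  drift <- 25 + 3 * (t / max(t))
  expect_equal(nrow(detect_sunspot_events(mk(drift))), 0)

  # paired detection reports the LNIR-over-HNIR excess at peak
  v_ln <- rep(25, 96); v_ln[spike_idx] <- 28
  v_hn <- rep(25, 96); v_hn[spike_idx] <- 26.8
  ev_p <- detect_sunspot_events_paired(mk(v_ln, "mL", "LNIR"),
                                       mk(v_hn, "mH", "HNIR"))
  expect_equal(nrow(ev_p), 1)
  expect_equal(ev_p$peak_paired_excess_C, 1.2, tolerance = 0.01)
})
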