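# Shared fixture builders: everything is generated in code at test time.

flat_spectrum <- function(value, lo = 300, hi = 1700, by = 50,
                          kind = "reflectance", label = "flat") {
  wl <- seq(lo, hi, by = by)
  spectrum(wl, rep(value, length(wl)), kind = kind, label = label)
}

write_spec_file <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Smooth synthetic spectra for integration oracles: broad Gaussian features,
# 1 nm sampling.
smooth_reflectance <- function(lo = 300, hi = 1700) {
  wl <- seq(lo, hi, by = 1)
  spectrum(wl, 0.2 + 0.3 * exp(-((wl - 550)^2) / (2 * 100^2)),
           kind = "reflectance", label = "smooth")
}
smooth_irradiance <- function(lo = 300, hi = 1700) {
  wl <- seq(lo, hi, by = 1)
  spectrum(wl, 0.2 + exp(-((wl - 900)^2) / (2 * 400^2)),
           kind = "irradiance", label = "smooth sun")
}

trapz_ref <- function(x, y) {
  n <- length(x)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

# Exact integral of the product of two piecewise-linear functions sharing
# the same knots: per cell of width h, h/6 * (2 a0 b0 + a0 b1 + a1 b0 +
# 2 a1 b1). Independent closed-form oracle for the trapezoid pipeline.
exact_product_integral <- function(x, a, b) {
  n <- length(x)
  h <- x[-1L] - x[-n]
  a0 <- a[-n]; a1 <- a[-1L]; b0 <- b[-n]; b1 <- b[-1L]
  sum(h / 6 * (2 * a0 * b0 + a0 * b1 + a1 * b0 + 2 * a1 * b1))
}

# Brute-force order-statistic quantile: sort, then linearly interpolate at
# position (n - 1) * p + 1.
brute_quantile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  hpos <- (n - 1) * p + 1
  lo <- floor(hpos)
  if (lo >= n) return(v[n])
  v[lo] + (hpos - lo) * (v[lo + 1L] - v[lo])
}

# A short two-phase schedule for affine-trace tests (keeps temperatures
# within physical bounds).
mini_schedule <- function() {
  regime_schedule(label = c("pre", "heat"),
                  mode = c("cooling", "heating"),
                  duration_s = c(300, 1800),
                  illumination = list(NULL, band(300, 1700)))
}

affine_trace <- function(schedule, intercept = 20, slope_per_s = 0.0234,
                         dt = 20, ...) {
  t <- seq(0, sum(schedule$duration_s) - dt, by = dt)
  heating_trace(t, internal_C = intercept + slope_per_s * t,
                label = "affine", ...)
}

# AR1 difference-series generator for the paired model simulations.
make_diff_data <- function(n_sites = 3, n_pairs = 2, n = 60, mu = 0,
                           phi = 0.8, sdi = 0.15, pair_sd = 0,
                           with_air = FALSE, days = 1) {
  rows <- list()
  for (s in seq_len(n_sites)) for (p in seq_len(n_pairs)) {
    peff <- if (pair_sd > 0) rnorm(1, 0, pair_sd) else 0
    for (d in seq_len(days)) {
      e <- rnorm(n, 0, sdi)
      x <- numeric(n)
      x[1L] <- e[1L] / sqrt(1 - phi^2)
      for (i in seq_len(n)[-1L]) x[i] <- phi * x[i - 1L] + e[i]
      r <- data.frame(pair_id = sprintf("p%d_%d", s, p),
                      site_id = sprintf("s%d", s), day = d,
                      time_s = seq(0, by = 300, length.out = n),
                      diff_C = mu + peff + x,
                      size = rep(c("small", "large"), length.out = 1),
                      stringsAsFactors = FALSE)
      if (with_air) r$air_C <- 25 + rnorm(n, 0, 1)
      rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, rows)
}

# Balanced null dataset for the factorial LMMs: no coating or size effect.
# Each pair holds two models (each with its own logger), observed on
# `n_days` occasions, mirroring the repeated field deployments.
make_null_lmm_data <- function(n_sites = 8, n_pairs_per_site = 6,
                               n_days = 2, site_sd = 0.5, pair_sd = 0.3,
                               resid_sd = 0.5, coating_shift = c(0, 0, 0)) {
  coatings <- c("HNIR", "LNIR", "uncoated")
  rows <- list()
  for (s in seq_len(n_sites)) {
    seff <- rnorm(1, 0, site_sd)
    for (p in seq_len(n_pairs_per_site)) {
      coating <- coatings[(p - 1L) %% 3L + 1L]
      size <- c("small", "large")[(p - 1L) %/% 3L %% 2L + 1L]
      peff <- rnorm(1, 0, pair_sd)
      shift <- coating_shift[match(coating, coatings)]
      for (m in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          coating = coating, size = size,
          pair_id = sprintf("s%d_p%d", s, p), site_id = sprintf("s%d", s),
          logger_id = sprintf("s%d_p%d_m%d", s, p, m),
          delta_C = shift + seff + peff + rnorm(n_days, 0, resid_sd),
          stringsAsFactors = FALSE)
      }
    }
  }
  d <- do.call(rbind, rows)
  d$p95_C <- d$delta_C + 25
  d
}
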