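#' Fraction of irradiance energy within a wavelength band
#'
#' Trapezoid integral of the irradiance over `band` divided by the integral
#' over `reference`, with both bands' endpoints inserted into the wavelength
#' grid by interpolation so that fractions over a partition of the reference
#' band sum exactly to one.
#'
#' @param I An irradiance [spectrum()] covering `reference`.
#' @param bnd A [band()] contained in `reference`.
#' @param reference Reference [band()] (default 300--2600 nm, the range of
#'   terrestrially relevant solar radiation).
#' @return A fraction in `[0, 1]`.
#' @export
band_energy_fraction <- function(I, bnd, reference = band(300, 2600)) {
  stopifnot(inherits(I, "spectrum"))
  bnd <- as_band(bnd); reference <- as_band(reference)
  if (bnd[["lo"]] < reference[["lo"]] || bnd[["hi"]] > reference[["hi"]])
    stop_nirtherm("band [", bnd[["lo"]], ", ", bnd[["hi"]],
                  "] not contained in reference band [",
                  reference[["lo"]], ", ", reference[["hi"]], "]")
  if (!spectrum_covers(I, reference[["lo"]], reference[["hi"]]))
    stop_nirtherm("irradiance spectrum does not cover the reference band")
  integral_over(I, bnd) / integral_over(I, reference)
}

# Trapezoid integral of a spectrum over a band, endpoints interpolated in.
integral_over <- function(s, bnd) {
  lo <- bnd[["lo"]]; hi <- bnd[["hi"]]
  wl <- s$wavelength_nm
  inside <- wl > lo & wl < hi
  x <- c(lo, wl[inside], hi)
  y <- c(spectrum_at(s, lo), s$value[inside], spectrum_at(s, hi))
  trapz(x, y)
}

#' Solar-weighted reflectivity over a band
#'
#' The irradiance-weighted mean reflectance, expressed in percent:
#' \deqn{R = 100 \frac{\int_{i}^{n} S(\lambda) I(\lambda)\,d\lambda}
#'                    {\int_{i}^{n} I(\lambda)\,d\lambda},}
#' where \eqn{S} is reflectance (fraction of a white standard), \eqn{I} the
#' solar spectral irradiance, and \eqn{[i, n]} the wavelength band. This is
#' the single number governing the radiative heat load on the surface: a
#' perfect reflector has `R = 100`, a black body `R = 0`.
#'
#' Both spectra are resampled onto a merged 1 nm working grid over the band
#' and integrated by the trapezoid rule.
#'
#' @param S A reflectance [spectrum()] covering the band (apply
#'   [extend_exponential()] or [extend_linear()] first if it does not).
#' @param I An irradiance [spectrum()] covering the band.
#' @param bnd A [band()].
#' @param method Extension-method tag carried into the result:
#'   `"measured"`, `"exponential_decline"` or `"linear_extension"`.
#' @return A one-row data frame of class `reflectivity_result` with columns
#'   `label`, `band_lo_nm`, `band_hi_nm`, `method`, `R_percent`.
#' @examples
#' sun <- solar_spectrum_synthetic()
#' grey <- spectrum(c(300, 1700), c(0.3, 0.3))
#' reflectivity(grey, sun, band(300, 1700))  # 30%
#' @export
reflectivity <- function(S, I, bnd,
                         method = c("measured", "exponential_decline",
                                    "linear_extension")) {
  stopifnot(inherits(S, "spectrum"), inherits(I, "spectrum"))
  method <- match.arg(method)
  bnd <- as_band(bnd)
  lo <- bnd[["lo"]]; hi <- bnd[["hi"]]
  for (sp in list(S = S, I = I)) {
    sup <- spectrum_support(sp)
    if (sup[1L] > lo)
      stop_nirtherm("spectrum missing interval [", lo, ", ",
                    min(sup[1L], hi), "] nm within the band")
    if (sup[2L] < hi)
      stop_nirtherm("spectrum missing interval [", max(sup[2L], lo), ", ",
                    hi, "] nm within the band")
  }
  grid <- seq(lo, hi, by = 1)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  s <- spectrum_at(S, grid)
  i <- spectrum_at(I, grid)
  denom <- trapz(grid, i)
  if (denom <= 0) stop_nirtherm("irradiance integrates to zero over the band")
  out <- data.frame(label = S$label, band_lo_nm = lo, band_hi_nm = hi,
                    method = method,
                    R_percent = 100 * trapz(grid, s * i) / denom,
                    stringsAsFactors = FALSE)
  class(out) <- c("reflectivity_result", class(out))
  out
}

#' Extend a reflectance spectrum by exponential decline
#'
#' Appends `R(lambda) = R(anchor) * exp(-k * (lambda - anchor))` on a 1 nm
#' grid from the anchor wavelength to `stop_nm`. The decay rate is chosen so
#' that the extension's initial derivative matches the measured trend:
#' `k = -m / R(anchor)`, with `m` the least-squares slope of the spectrum
#' over the 100 nm leading up to the anchor. A non-negative trailing slope
#' (or zero reflectance at the anchor) gives a constant extension (`k = 0`).
#' The result is continuous at the anchor.
#'
#' @param S Reflectance [spectrum()] covering at least
#'   `[anchor_nm - 100, anchor_nm]`.
#' @param anchor_nm Wavelength at which the measurement ends (default 950).
#' @param stop_nm Wavelength to extend to (default 1700).
#' @return A [spectrum()]: the measurement up to the anchor plus the
#'   exponential tail.
#' @export
extend_exponential <- function(S, anchor_nm = 950, stop_nm = 1700) {
  stopifnot(inherits(S, "spectrum"))
  ext <- extension_setup(S, c(anchor_nm - 100, anchor_nm), anchor_nm, stop_nm)
  k <- if (ext$m >= 0 || ext$R0 <= 0) 0 else -ext$m / ext$R0
  tail_val <- ext$R0 * exp(-k * (ext$tail_wl - anchor_nm))
  assemble_extension(S, anchor_nm, ext, tail_val)
}

#' Extend a reflectance spectrum linearly
#'
#' Continues the least-squares slope fitted over `slope_window` from the
#' window's upper edge to `stop_nm` on a 1 nm grid; values that would go
#' negative are clipped to zero when `clip_at_zero` is set. The result is
#' continuous at the window's upper edge.
#'
#' @param S Reflectance [spectrum()] covering `slope_window`.
#' @param slope_window Wavelength window for the slope fit
#'   (default 850--950 nm).
#' @param stop_nm Wavelength to extend to (default 1700).
#' @param clip_at_zero Replace negative extension values by zero?
#' @return A [spectrum()].
#' @export
extend_linear <- function(S, slope_window = c(850, 950), stop_nm = 1700,
                          clip_at_zero = TRUE) {
  stopifnot(inherits(S, "spectrum"))
  anchor_nm <- max(slope_window)
  ext <- extension_setup(S, slope_window, anchor_nm, stop_nm)
  tail_val <- ext$R0 + ext$m * (ext$tail_wl - anchor_nm)
  if (clip_at_zero) tail_val <- pmax(tail_val, 0)
  assemble_extension(S, anchor_nm, ext, tail_val)
}

# Shared scaffolding for the two extension rules: trailing-slope fit,
# anchor value, and the 1 nm extension grid.
extension_setup <- function(S, window, anchor_nm, stop_nm) {
  sup <- spectrum_support(S)
  if (sup[1L] > min(window) || sup[2L] < anchor_nm)
    stop_nirtherm("spectrum does not cover the slope window [",
                  min(window), ", ", anchor_nm, "] nm")
  if (stop_nm <= anchor_nm) stop_nirtherm("stop_nm must exceed the anchor")
  in_win <- S$wavelength_nm >= min(window) & S$wavelength_nm <= anchor_nm
  wl <- S$wavelength_nm[in_win]; va <- S$value[in_win]
  if (length(wl) < 2L) {                      # sparse spectra: interpolate
    wl <- seq(min(window), anchor_nm, length.out = 11L)
    va <- spectrum_at(S, wl)
  }
  m <- unname(coef(lm(va ~ wl))[2L])
  if (!is.finite(m)) m <- 0
  tail_wl <- seq(floor(anchor_nm) + 1, stop_nm, by = 1)
  if (tail_wl[length(tail_wl)] < stop_nm) tail_wl <- c(tail_wl, stop_nm)
  list(m = m, R0 = spectrum_at(S, anchor_nm), tail_wl = tail_wl)
}

assemble_extension <- function(S, anchor_nm, ext, tail_val) {
  keep <- S$wavelength_nm < anchor_nm
  wl <- c(S$wavelength_nm[keep], anchor_nm, ext$tail_wl)
  va <- c(S$value[keep], ext$R0, tail_val)
  spectrum(wl, pmax(va, 0), kind = S$kind, label = S$label)
}

#' Compare mean reflectivity between high- and low-NIR groups
#'
#' Computes the arithmetic mean reflectivity of each group and their
#' difference (high minus low), reported at `round_dp` decimals with
#' round-half-to-even.
#'
#' @param hi,lo Reflectivity values for the two groups: numeric vectors of
#'   percentages, or `reflectivity_result` data frames (rows are stacked).
#' @param round_dp Decimal places for the reported values (default 1).
#' @return A list of class `group_comparison` with `mean_hi`, `mean_lo`,
#'   `mean_difference` (exact) and their rounded counterparts.
#' @examples
#' group_comparison(c(26.0, 33.3, 29.2), c(10.7, 7.8))$difference_rounded
#' @export
group_comparison <- function(hi, lo, round_dp = 1) {
  hi <- as_R_percent(hi); lo <- as_R_percent(lo)
  if (!length(hi) || !length(lo))
    stop_nirtherm("both groups must be non-empty")
  res <- list(mean_hi = mean(hi), mean_lo = mean(lo),
              mean_difference = mean(hi) - mean(lo),
              round_dp = round_dp)
  res$mean_hi_rounded <- round(res$mean_hi, round_dp)
  res$mean_lo_rounded <- round(res$mean_lo, round_dp)
  res$difference_rounded <- round(res$mean_difference, round_dp)
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group comparison> mean high %.*f%%, mean low %.*f%%, difference (high-low) %.*f%%\n",
              x$round_dp, x$mean_hi_rounded, x$round_dp, x$mean_lo_rounded,
              x$round_dp, x$difference_rounded))
  invisible(x)
}

as_R_percent <- function(x) {
  if (inherits(x, "reflectivity_result") || is.data.frame(x)) {
    if (is.data.frame(x) && "R_percent" %in% names(x)) {
      if (length(unique(x$method)) > 1L)
        stop_nirtherm("mixed extension methods within one group")
      if (nrow(unique(x[c("band_lo_nm", "band_hi_nm")])) > 1L)
        stop_nirtherm("mixed bands within one group")
      return(x$R_percent)
    }
  }
  if (is.list(x) && !is.data.frame(x)) {
    df <- do.call(rbind, x)
    return(as_R_percent(df))
  }
  as.numeric(x)
}

#' Published reflectivity of real leaf-sitting frogs and painted models
#'
#' Reported solar-weighted reflectivity (percent) for five leaf-sitting frog
#' species with measured spectra to 950 nm, and for high- and low-NIR painted
#' model surfaces measured to 1700 nm. Columns give reflectivity over
#' 300--950 nm from the measured data, and over 300--1700 nm after extending
#' the frog spectra by exponential decline or by linear continuation (model
#' values over 300--1700 nm are measured, so both extension columns repeat
#' the measured value).
#'
#' @return A data frame with columns `label`, `group` (`"hi"`/`"lo"`),
#'   `type` (`"frog"`/`"model"`), `R_300_950`, `R_exp_300_1700`,
#'   `R_lin_300_1700`.
#' @export
published_reflectivity <- function() {
  data.frame(
    label = c("high NIR model", "Cruziohyla calcarifer",
              "Cruziohyla craspedopus", "Phyllomedusa sauvagii",
              "low NIR model", "Gastrotheca riobambae", "Hyla cinerea"),
    group = c("hi", "hi", "hi", "hi", "lo", "lo", "lo"),
    type = c("model", "frog", "frog", "frog", "model", "frog", "frog"),
    R_300_950 = c(24.7, 26.0, 33.3, 29.2, 9.5, 10.7, 7.8),
    R_exp_300_1700 = c(39.5, 26.1, 32.6, 28.4, 13.7, 9.4, 6.8),
    R_lin_300_1700 = c(39.5, 27.7, 39.7, 33.3, 13.7, 13.2, 9.7),
    stringsAsFactors = FALSE)
}
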