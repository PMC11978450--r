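#' Synthetic AM1.5G-like solar irradiance spectrum
#'
#' A smooth analytic approximation of the terrestrial global-tilt solar
#' spectrum, built from a 5772 K Planck envelope attenuated by standard
#' atmospheric extinction terms at airmass 1.5: Rayleigh scattering, an
#' Angstrom-law aerosol term, the ozone Hartley/Huggins UV cut-off and
#' Chappuis band, the O2 A/B lines, the major water-vapour bands (around
#' 720, 820, 940, 1130, 1400, 1870 and 2500 nm) and the 2.0 um CO2 bands.
#' Band positions and optical depths are taken from standard atmospheric
#' radiative-transfer practice (rural aerosol, ~1.4 cm precipitable water,
#' 0.34 atm-cm ozone).
#'
#' This is a *synthetic* stand-in for the ASTM G-173-03 reference table: it
#' reproduces the qualitative shape of the AM1.5 global spectrum (visible
#' peak near 500 nm, deep water bands, weak tail beyond 2500 nm) so that
#' irradiance-weighted quantities behave realistically, but it is not the
#' standard itself. Analyses that must cite the standard's band fractions
#' should load the real table with [read_astm_g173()].
#'
#' @param grid Wavelength grid in nm (default 1 nm over 300--2600 nm).
#' @param total_W_m2 Normalisation: integral over the grid (default 975
#'   W m^-2, the approximate AM1.5G power between 300 and 2600 nm).
#' @return An irradiance [spectrum()].
#' @examples
#' sun <- solar_spectrum_synthetic()
#' band_energy_fraction(sun, band(300, 700), band(300, 2600))
#' @export
solar_spectrum_synthetic <- function(grid = seq(300, 2600, by = 1),
                                     total_W_m2 = 975) {
  wl_um <- grid / 1000
  # Planck spectral radiance shape at the solar effective temperature
  h <- 6.62607015e-34; c0 <- 2.99792458e8; kB <- 1.380649e-23; Tsun <- 5772
  lam <- grid * 1e-9
  planck <- (2 * h * c0^2 / lam^5) / (expm1(h * c0 / (lam * kB * Tsun)))

  am <- 1.5
  tau_rayleigh <- 0.008735 * wl_um^(-4.08)
  tau_aerosol <- 0.084 * wl_um^(-1.3)          # Angstrom law, rural aerosol

  gauss <- function(center, width, depth) depth * exp(-((grid - center)^2) /
                                                        (2 * width^2))
  # absorption optical depth: ozone Chappuis + O2 + H2O + CO2 bands
  tau_abs <-
    gauss(600, 60, 0.03) +                      # ozone Chappuis
    gauss(688, 3, 0.15) + gauss(762, 4, 0.45) + # O2 B and A bands
    gauss(719, 12, 0.18) + gauss(823, 12, 0.22) +
    gauss(940, 28, 0.95) + gauss(1135, 32, 1.3) +
    gauss(1400, 55, 6.0) + gauss(1870, 75, 7.0) +
    gauss(2010, 25, 1.1) + gauss(2060, 25, 1.2) +
    gauss(2500, 120, 3.0) +
    gauss(2700, 150, 8.0)                       # 2.7 um H2O/CO2 shoulder
  # ozone Hartley/Huggins: hard UV cut-off below ~320 nm
  tau_uv <- ifelse(grid < 340, 25 * exp(-(grid - 290) / 12), 0)

  transmission <- exp(-(tau_rayleigh + tau_aerosol) * am) *
    exp(-tau_abs) * exp(-tau_uv)
  val <- planck * transmission
  val <- val / trapz(grid, val) * total_W_m2
  spectrum(grid, val, kind = "irradiance", label = "AM1.5G-like (synthetic)")
}

#' Read an ASTM G-173-03 style irradiance table
#'
#' Parses the reference solar spectral irradiance table layout: wavelength
#' (nm) followed by irradiance columns (W m^-2 nm^-1), typically
#' extraterrestrial, global tilt and direct+circumsolar. The requested
#' column is selected by name match or by index.
#'
#' @param path Path to the delimited table (CSV or whitespace separated).
#' @param column Which irradiance column to use: a name fragment matched
#'   case-insensitively against the header (default `"global"`), or a column
#'   index counted after the wavelength column.
#' @return An irradiance [spectrum()] restricted to 250--2600 nm.
#' @export
read_astm_g173 <- function(path, column = "global") {
  if (!file.exists(path))
    stop_nirtherm("reference irradiance table not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(trimws(first),
    if (sep == ",") "," else "[ \t]+")[[1L]][1L])))
  tab <- read.table(path, sep = sep, header = has_header,
                    strip.white = TRUE, check.names = FALSE)
  if (ncol(tab) < 2L) stop_nirtherm("expected at least 2 columns in ", path)
  if (is.character(column)) {
    idx <- grep(column, names(tab), ignore.case = TRUE)
    idx <- if (length(idx)) idx[1L] else 2L
  } else idx <- as.integer(column) + 1L
  wl <- as.numeric(tab[[1L]]); va <- as.numeric(tab[[idx]])
  keep <- is.finite(wl) & is.finite(va) & wl >= 250 & wl <= 2600
  spectrum(wl[keep], pmax(va[keep], 0), kind = "irradiance",
           label = "ASTM G-173 global tilt")
}
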