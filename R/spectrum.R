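#' Construct a wavelength-indexed spectrum
#'
#' A `spectrum` is the package's carrier for any wavelength-resolved curve:
#' reflectance measured against a white standard (stored as a fraction of the
#' standard, 0--1 with small excursions above 1 tolerated) or spectral
#' irradiance in W m^-2 nm^-1.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm, strictly
#'   increasing, all within 250--2600 nm.
#' @param value Numeric vector of the same length; non-negative and finite.
#'   Reflectance values above 2 are rejected (measurements against a 99%
#'   Spectralon standard may slightly exceed 1, but not double it).
#' @param kind `"reflectance"` or `"irradiance"`.
#' @param label Free-text identity (species, model, treatment).
#' @return An object of class `spectrum`: a list with elements
#'   `wavelength_nm`, `value`, `kind`, `label`.
#' @examples
#' s <- spectrum(c(400, 500, 600), c(0.10, 0.35, 0.12))
#' s
#' @export
spectrum <- function(wavelength_nm, value,
                     kind = c("reflectance", "irradiance"), label = "") {
  kind <- match.arg(kind)
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  s <- structure(
    list(wavelength_nm = wavelength_nm, value = value,
         kind = kind, label = as.character(label)[1L]),
    class = "spectrum")
  validate_spectrum(s)
}

validate_spectrum <- function(s) {
  w <- s$wavelength_nm; v <- s$value
  if (length(w) != length(v))
    stop_nirtherm("wavelength and value lengths differ (",
                  length(w), " vs ", length(v), ")")
  if (length(w) < 1L)
    stop_nirtherm("a spectrum needs at least 1 point")
  if (anyNA(w) || any(!is.finite(w)))
    stop_nirtherm("non-finite wavelengths")
  if (is.unsorted(w, strictly = TRUE))
    stop_nirtherm("wavelengths must be strictly increasing")
  if (w[1L] < 250 || w[length(w)] > 2600)
    stop_nirtherm("wavelengths must lie within [250, 2600] nm; got range [",
                  w[1L], ", ", w[length(w)], "]")
  if (anyNA(v) || any(!is.finite(v)))
    stop_nirtherm("non-finite values in spectrum")
  if (any(v < 0))
    stop_nirtherm("negative values in spectrum")
  if (s$kind == "reflectance" && any(v > 2))
    stop_nirtherm("reflectance above 2.0 (is this file already in percent?)")
  s
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum:%s> %s\n  %d points, %.0f-%.0f nm, values %.4g-%.4g\n",
              x$kind, if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$wavelength_nm),
              min(x$wavelength_nm), max(x$wavelength_nm),
              min(x$value), max(x$value)))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength_nm, value = x$value)
}

spectrum_support <- function(s) range(s$wavelength_nm)

spectrum_covers <- function(s, lo, hi) {
  r <- spectrum_support(s)
  r[1L] <= lo && r[2L] >= hi
}

# Linear interpolation of a spectrum at arbitrary wavelengths inside support.
spectrum_at <- function(s, wl) {
  approx(s$wavelength_nm, s$value, xout = wl, method = "linear",
         ties = "ordered")$y
}

#' Wavelength band
#'
#' @param lo_nm,hi_nm Band limits in nm; `250 <= lo_nm < hi_nm <= 2600`.
#' @return A `band` object (named numeric of length 2).
#' @examples
#' band(300, 1700)  # full measured range
#' band(700, 1700)  # NIR only
#' @export
band <- function(lo_nm, hi_nm) {
  lo_nm <- as.numeric(lo_nm); hi_nm <- as.numeric(hi_nm)
  if (!is.finite(lo_nm) || !is.finite(hi_nm) || lo_nm >= hi_nm)
    stop_nirtherm("band limits must satisfy lo < hi; got [", lo_nm, ", ",
                  hi_nm, "]")
  if (lo_nm < 250 || hi_nm > 2600)
    stop_nirtherm("band must lie within [250, 2600] nm")
  structure(c(lo = lo_nm, hi = hi_nm), class = "band")
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("<band> %g-%g nm\n", x[["lo"]], x[["hi"]])); invisible(x)
}

as_band <- function(x) {
  if (inherits(x, "band")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(band(x[1L], x[2L]))
  stop_nirtherm("cannot interpret object as a wavelength band")
}

#' Read a two-column spectral file
#'
#' Parses delimited text with wavelength (nm) in the first column and the
#' measured value in the second. The delimiter is auto-detected among comma,
#' tab, semicolon and whitespace, and a single non-numeric header line is
#' skipped. Rows are sorted by wavelength, duplicate wavelengths are collapsed
#' by their mean, and rows outside 250--2600 nm are dropped (with a message
#' giving the count).
#'
#' @param path File path.
#' @param kind `"reflectance"` or `"irradiance"`.
#' @param label Label for the spectrum; defaults to the file name.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, kind = c("reflectance", "irradiance"),
                          label = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_nirtherm("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_nirtherm("empty spectral file: ", path)

  parse_with <- function(split) {
    lapply(strsplit(trimws(lines), split), function(f) {
      f <- f[nzchar(f)]
      suppressWarnings(as.numeric(f[seq_len(min(2L, length(f)))]))
    })
  }
  delims <- c(comma = ",", semicolon = ";", tab = "\t", whitespace = "[ \t]+")
  best <- NULL; best_ok <- -1L
  for (d in delims) {
    p <- parse_with(d)
    ok <- sum(vapply(p, function(r) length(r) == 2L && !anyNA(r), logical(1)))
    if (ok > best_ok) { best <- p; best_ok <- ok }
  }
  parsed <- best
  row_ok <- vapply(parsed, function(r) length(r) == 2L && !anyNA(r), logical(1))

  # tolerate one header line
  body_idx <- seq_along(parsed)
  if (!row_ok[1L] && length(parsed) > 1L) body_idx <- body_idx[-1L]
  bad <- body_idx[!row_ok[body_idx]]
  if (length(bad) > 0.10 * length(body_idx))
    stop_nirtherm("unparseable rows exceed 10% of file ", path,
                  "; first bad line ", bad[1L], ": '", lines[bad[1L]], "'")
  good <- body_idx[row_ok[body_idx]]
  if (!length(good)) stop_nirtherm("no parseable data rows in ", path)

  wl <- vapply(parsed[good], `[[`, numeric(1), 1L)
  va <- vapply(parsed[good], `[[`, numeric(1), 2L)

  keep <- wl >= 250 & wl <= 2600
  if (any(!keep))
    message(sum(!keep), " row(s) outside 250-2600 nm dropped from ",
            basename(path))
  wl <- wl[keep]; va <- va[keep]
  if (length(wl) < 2L)
    stop_nirtherm("fewer than 2 usable rows within 250-2600 nm in ", path)

  o <- order(wl); wl <- wl[o]; va <- va[o]
  if (anyDuplicated(wl)) {
    va <- as.numeric(tapply(va, wl, mean))
    wl <- sort(unique(wl))
  }
  spectrum(wl, va, kind = kind, label = label %||% basename(path))
}

#' Write a spectrum as two-column delimited text
#'
#' @param s A [spectrum()].
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @param header Write a `wavelength_nm<delim>value` header line?
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, delim = ",", header = TRUE) {
  stopifnot(inherits(s, "spectrum"))
  lines <- paste(sprintf("%.17g", s$wavelength_nm),
                 sprintf("%.17g", s$value), sep = delim)
  if (header) lines <- c(paste("wavelength_nm", "value", sep = delim), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Calibrate a raw spectrum against a white reference
#'
#' Converts raw counts to reflectance relative to a white standard:
#' `standard_reflectance * (raw - dark) / (white - dark)`, evaluated on the
#' raw spectrum's wavelength grid (restricted to the white reference's
#' support) after interpolating the references. Dark counts default to zero
#' when no dark measurement is supplied. Small negative results from dark
#' noise are clipped to zero.
#'
#' @param raw,white,dark Spectra of raw counts; `dark` may be `NULL`.
#' @param standard_reflectance Reflectance of the white standard (default
#'   0.99, a Spectralon 99% standard).
#' @return A reflectance [spectrum()] on the (restricted) raw grid.
#' @export
calibrate <- function(raw, white, dark = NULL, standard_reflectance = 0.99) {
  stopifnot(inherits(raw, "spectrum"), inherits(white, "spectrum"))
  sup <- spectrum_support(white)
  if (!is.null(dark)) {
    stopifnot(inherits(dark, "spectrum"))
    sup <- c(max(sup[1L], spectrum_support(dark)[1L]),
             min(sup[2L], spectrum_support(dark)[2L]))
  }
  wl <- raw$wavelength_nm
  wl <- wl[wl >= sup[1L] & wl <= sup[2L]]
  if (length(wl) < 2L)
    stop_nirtherm("raw and reference spectra share fewer than 2 wavelengths")
  r <- spectrum_at(raw, wl)
  w <- spectrum_at(white, wl)
  d <- if (is.null(dark)) rep(0, length(wl)) else spectrum_at(dark, wl)
  denom <- w - d
  bad <- denom <= 0
  if (mean(bad) > 0.01)
    stop_nirtherm("white reference <= dark at ",
                  round(100 * mean(bad), 1),
                  "% of wavelengths: saturated or invalid reference")
  refl <- standard_reflectance * (r - d) / denom
  refl[bad] <- 0
  refl <- pmax(refl, 0)
  spectrum(wl, refl, kind = "reflectance", label = raw$label)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation between measured points; never extrapolates.
#'
#' @param s A [spectrum()].
#' @param grid Increasing wavelengths, all inside the closed support of `s`.
#' @return A [spectrum()] on `grid`.
#' @export
resample <- function(s, grid) {
  stopifnot(inherits(s, "spectrum"))
  grid <- as.numeric(grid)
  sup <- spectrum_support(s)
  if (any(grid < sup[1L]) || any(grid > sup[2L]))
    stop_nirtherm("grid extends outside the measured support [",
                  sup[1L], ", ", sup[2L], "] nm; use extend_exponential() or ",
                  "extend_linear() to extrapolate beyond the measurement")
  spectrum(grid, spectrum_at(s, grid), kind = s$kind, label = s$label)
}

#' Splice a UV-Vis and a NIR spectrum at a boundary wavelength
#'
#' Joins spectra from two spectrometer ranges (e.g. 300--1000 nm and
#' 1000--1700 nm) into one. Below `boundary_nm - overlap_nm` the UV-Vis
#' points are used as measured, above `boundary_nm + overlap_nm` the NIR
#' points; inside the overlap window the two are resampled to a 1 nm grid
#' and averaged where both are defined.
#'
#' @param vis Spectrum covering the shorter wavelengths.
#' @param nir Spectrum covering the longer wavelengths.
#' @param boundary_nm Junction wavelength (default 1000 nm).
#' @param overlap_nm Half-width of the averaging window (default 5 nm).
#' @return A single [spectrum()] with strictly increasing wavelengths.
#' @export
splice <- function(vis, nir, boundary_nm = 1000, overlap_nm = 5) {
  stopifnot(inherits(vis, "spectrum"), inherits(nir, "spectrum"))
  if (vis$kind != nir$kind) stop_nirtherm("cannot splice different kinds")
  vsup <- spectrum_support(vis); nsup <- spectrum_support(nir)
  gap <- nsup[1L] - vsup[2L]
  if (gap > 10)
    stop_nirtherm("gap of ", gap, " nm between spectrometer ranges (max 10)")
  if (vsup[2L] < boundary_nm - overlap_nm)
    stop_nirtherm("UV-Vis spectrum stops ", boundary_nm - overlap_nm - vsup[2L],
                  " nm short of the overlap window")
  if (nsup[1L] > boundary_nm + overlap_nm)
    stop_nirtherm("NIR spectrum starts ", nsup[1L] - boundary_nm - overlap_nm,
                  " nm beyond the overlap window")

  win_lo <- boundary_nm - overlap_nm
  win_hi <- boundary_nm + overlap_nm
  grid <- seq(win_lo, win_hi, by = 1)
  v_ok <- grid >= vsup[1L] & grid <= vsup[2L]
  n_ok <- grid >= nsup[1L] & grid <= nsup[2L]
  mid_v <- ifelse(v_ok, approx(vis$wavelength_nm, vis$value, grid,
                               ties = "ordered")$y, NA_real_)
  mid_n <- ifelse(n_ok, approx(nir$wavelength_nm, nir$value, grid,
                               ties = "ordered")$y, NA_real_)
  mid <- rowMeans(cbind(mid_v, mid_n), na.rm = TRUE)
  keep <- is.finite(mid)

  lo_part <- vis$wavelength_nm < win_lo
  hi_part <- nir$wavelength_nm > win_hi
  wl <- c(vis$wavelength_nm[lo_part], grid[keep], nir$wavelength_nm[hi_part])
  va <- c(vis$value[lo_part], mid[keep], nir$value[hi_part])
  o <- order(wl)
  wl <- wl[o]; va <- va[o]
  dup <- duplicated(wl)
  spectrum(wl[!dup], va[!dup], kind = vis$kind,
           label = if (nzchar(vis$label)) vis$label else nir$label)
}
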