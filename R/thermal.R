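#' Illumination/cooling regime schedule
#'
#' An ordered sequence of chamber phases, each either a dark cooling phase or
#' a heating phase under a given illumination band.
#'
#' @param label Character vector of phase labels.
#' @param mode `"cooling"` or `"heating"` per phase.
#' @param duration_s Positive phase durations in seconds.
#' @param illumination List of [band()]s (or `NULL` for cooling phases),
#'   one per phase; heating phases must carry a band.
#' @return A data frame of class `regime_schedule` with columns `label`,
#'   `mode`, `duration_s`, `lo_nm`, `hi_nm`, `start_s`, `end_s`.
#' @seealso [default_schedule()] for the standard chamber protocol.
#' @export
regime_schedule <- function(label, mode, duration_s, illumination) {
  n <- length(label)
  if (n == 0L) stop_nirtherm("schedule must contain at least one phase")
  stopifnot(length(mode) == n, length(duration_s) == n,
            length(illumination) == n)
  mode <- match.arg(mode, c("cooling", "heating"), several.ok = TRUE)
  if (any(duration_s <= 0)) stop_nirtherm("phase durations must be positive")
  lo <- hi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    b <- illumination[[i]]
    if (mode[i] == "heating") {
      if (is.null(b)) stop_nirtherm("heating phase '", label[i],
                                    "' lacks an illumination band")
      b <- as_band(b); lo[i] <- b[["lo"]]; hi[i] <- b[["hi"]]
    }
  }
  ends <- cumsum(duration_s)
  out <- data.frame(label = as.character(label), mode = mode,
                    duration_s = as.numeric(duration_s),
                    lo_nm = lo, hi_nm = hi,
                    start_s = c(0, head(ends, -1L)), end_s = ends,
                    stringsAsFactors = FALSE)
  class(out) <- c("regime_schedule", class(out))
  out
}

#' The standard chamber heating/cooling protocol
#'
#' Seven phases totalling 7500 s: 5 min dark cooling to stabilise, then three
#' 30 min heating periods (full spectrum 300--1700 nm, NIR-only 700--1700 nm,
#' UV-Vis-only 300--700 nm) each followed by 15 min of dark cooling so that
#' every heating period starts from a comparable temperature.
#'
#' @return A [regime_schedule()].
#' @export
default_schedule <- function() {
  regime_schedule(
    label = c("stabilise", "full_spectrum", "cool1", "nir_only", "cool2",
              "uvvis_only", "cool3"),
    mode = c("cooling", "heating", "cooling", "heating", "cooling",
             "heating", "cooling"),
    duration_s = c(300, 1800, 900, 1800, 900, 1800, 900),
    illumination = list(NULL, band(300, 1700), NULL, band(700, 1700), NULL,
                        band(300, 700), NULL))
}

#' Construct a laboratory heating trace
#'
#' Temperatures logged at a nominal 20 s interval from thermocouples placed
#' inside the model (`internal_C`), on its surface (`surface_C`) and in the
#' chamber air (`air_C`); any channel may be absent (`NULL`).
#'
#' @param time_s Strictly increasing sample times in seconds; spacing must
#'   stay within 10% of its nominal (median) value.
#' @param internal_C,surface_C,air_C Temperature channels in Celsius, within
#'   -10 to 90; `NULL` when not recorded.
#' @param label Trace identity.
#' @param treatment `"HNIR"`, `"LNIR"` or `"uncoated"`.
#' @param size `"small"` or `"large"`.
#' @return An object of class `heating_trace`.
#' @export
heating_trace <- function(time_s, internal_C = NULL, surface_C = NULL,
                          air_C = NULL, label = "",
                          treatment = c("HNIR", "LNIR", "uncoated"),
                          size = c("small", "large")) {
  treatment <- match.arg(treatment)
  size <- match.arg(size)
  time_s <- as.numeric(time_s)
  if (length(time_s) < 2L) stop_nirtherm("trace needs at least 2 samples")
  if (is.unsorted(time_s, strictly = TRUE))
    stop_nirtherm("sample times must be strictly increasing")
  dt <- diff(time_s)
  nominal <- median(dt)
  if (any(abs(dt - nominal) > 0.10 * nominal))
    stop_nirtherm("irregular sampling: interval deviates more than 10% from ",
                  "the nominal ", nominal, " s")
  chans <- list(internal_C = internal_C, surface_C = surface_C, air_C = air_C)
  chans <- chans[!vapply(chans, is.null, logical(1))]
  if (!length(chans)) stop_nirtherm("at least one temperature channel needed")
  for (nm in names(chans)) {
    v <- as.numeric(chans[[nm]])
    if (length(v) != length(time_s))
      stop_nirtherm("channel ", nm, " length differs from time vector")
    if (anyNA(v) || any(v < -10 | v > 90))
      stop_nirtherm("channel ", nm, " outside plausible range [-10, 90] C")
    chans[[nm]] <- v
  }
  structure(c(list(time_s = time_s), chans,
              list(label = as.character(label), treatment = treatment,
                   size = size)),
            class = "heating_trace")
}

#' @export
print.heating_trace <- function(x, ...) {
  ch <- intersect(c("internal_C", "surface_C", "air_C"), names(x))
  cat(sprintf("<heating trace> %s (%s, %s): %d samples over %.0f s; channels: %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)", x$treatment,
              x$size, length(x$time_s), diff(range(x$time_s)),
              paste(ch, collapse = ", ")))
  invisible(x)
}

trace_channels <- function(trace)
  intersect(c("internal_C", "surface_C", "air_C"), names(trace))

#' Assign trace samples to schedule phases
#'
#' Each sample is assigned to exactly one phase by its elapsed time since
#' `start_s`; a sample falling exactly on a phase boundary belongs to the
#' later phase. Samples after the schedule's end are left unassigned (`NA`).
#'
#' @param trace A [heating_trace()].
#' @param schedule A [regime_schedule()].
#' @param start_s Time at which the schedule begins (default 0).
#' @return A data frame: `time_s`, `phase` (factor in schedule order),
#'   `phase_time_s` (elapsed within phase), plus one column per channel.
#' @export
segment <- function(trace, schedule, start_s = 0) {
  stopifnot(inherits(trace, "heating_trace"),
            inherits(schedule, "regime_schedule"))
  total <- sum(schedule$duration_s)
  t <- trace$time_s
  dt <- median(diff(t))
  covered <- (max(t) - start_s + dt) / total
  if (max(t) - start_s < total - dt - 1e-9)
    stop_nirtherm("trace covers only ", round(100 * min(covered, 1), 1),
                  "% of the ", total, " s schedule")
  elapsed <- t - start_s
  starts <- c(schedule$start_s, total)
  idx <- findInterval(elapsed, starts)        # boundary sample -> later phase
  idx[idx < 1L | idx > nrow(schedule)] <- NA_integer_
  out <- data.frame(
    time_s = t,
    phase = factor(schedule$label[idx], levels = schedule$label),
    phase_time_s = elapsed - schedule$start_s[idx])
  for (ch in trace_channels(trace)) out[[ch]] <- trace[[ch]]
  out
}

phase_slice <- function(trace, schedule, phase, start_s = 0) {
  seg <- segment(trace, schedule, start_s)
  if (!phase %in% schedule$label)
    stop_nirtherm("unknown phase '", phase, "'")
  seg[!is.na(seg$phase) & seg$phase == phase, , drop = FALSE]
}

#' Initial heating rate of a phase
#'
#' Ordinary least-squares slope of temperature against time over the first
#' `window_s` seconds of the phase (the sample at phase start included),
#' converted to degrees Celsius per minute. The fit uses the actual sample
#' timestamps, so mildly irregular spacing is handled exactly.
#'
#' @param trace A [heating_trace()].
#' @param schedule A [regime_schedule()].
#' @param phase Label of a heating phase.
#' @param channel `"internal_C"`, `"surface_C"` or `"air_C"`.
#' @param window_s Fitting window from phase start (default 120 s, i.e. the
#'   first two minutes of heating).
#' @param start_s Schedule start time.
#' @return Heating rate in degrees C per minute.
#' @export
heating_rate <- function(trace, schedule, phase, channel = "internal_C",
                         window_s = 120, start_s = 0) {
  if (!channel %in% trace_channels(trace))
    stop_nirtherm("channel ", channel, " absent from trace")
  ph <- schedule[schedule$label == phase, ]
  if (!nrow(ph)) stop_nirtherm("unknown phase '", phase, "'")
  if (ph$mode != "heating")
    stop_nirtherm("'", phase, "' is not a heating phase")
  sl <- phase_slice(trace, schedule, phase, start_s)
  sl <- sl[sl$phase_time_s <= window_s + 1e-9, , drop = FALSE]
  if (nrow(sl) < 3L)
    stop_nirtherm("fewer than 3 samples in the first ", window_s,
                  " s of phase '", phase, "'")
  slope_per_s <- unname(coef(lm(sl[[channel]] ~ sl$phase_time_s))[2L])
  60 * slope_per_s
}

#' Temperature reached at the end of a heating phase
#'
#' The chamber heating curves approach saturation, so the temperature at the
#' phase's final sample is the operational "maximum temperature reached at
#' the end of the heating period". `mode = "max"` instead returns the phase
#' maximum, which differs only when the trace dips after an early peak.
#'
#' @inheritParams heating_rate
#' @param mode `"final"` (default) or `"max"`.
#' @return Temperature in degrees Celsius.
#' @export
end_temperature <- function(trace, schedule, phase, channel = "internal_C",
                            mode = c("final", "max"), start_s = 0) {
  mode <- match.arg(mode)
  if (!channel %in% trace_channels(trace))
    stop_nirtherm("channel ", channel, " absent from trace")
  sl <- phase_slice(trace, schedule, phase, start_s)
  if (!nrow(sl)) stop_nirtherm("phase '", phase, "' holds no samples")
  v <- sl[[channel]]
  if (mode == "final") v[length(v)] else max(v)
}

#' Summarise heating rates and end temperatures across traces
#'
#' Applies [segment()], [heating_rate()] and [end_temperature()] to every
#' heating phase and available channel of each trace, producing a long-format
#' table (one row per trace x phase x channel). When the final-sample and
#' phase-maximum temperatures differ by more than 0.1 C both are reported;
#' otherwise `end_C_max` repeats `end_C`.
#'
#' @param traces A list of [heating_trace()] objects (or a single trace).
#' @param schedule A [regime_schedule()].
#' @param window_s Heating-rate window (default 120 s).
#' @param start_s Schedule start time.
#' @return A data frame: `label`, `treatment`, `size`, `phase`, `channel`,
#'   `heating_rate_C_per_min`, `end_C`, `end_C_max`, `end_differs`.
#' @export
summarize_heating <- function(traces, schedule, window_s = 120, start_s = 0) {
  if (inherits(traces, "heating_trace")) traces <- list(traces)
  heat <- schedule[schedule$mode == "heating", ]
  rows <- list()
  for (tr in traces) {
    for (ph in heat$label) {
      for (ch in trace_channels(tr)) {
        if (ch == "air_C") next   # air channel monitors the chamber, not the model
        fin <- end_temperature(tr, schedule, ph, ch, "final", start_s)
        mx <- end_temperature(tr, schedule, ph, ch, "max", start_s)
        rows[[length(rows) + 1L]] <- data.frame(
          label = tr$label, treatment = tr$treatment, size = tr$size,
          phase = ph, channel = ch,
          heating_rate_C_per_min =
            heating_rate(tr, schedule, ph, ch, window_s, start_s),
          end_C = fin, end_C_max = mx,
          end_differs = (mx - fin) > 0.1,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Read a heating trace from delimited text
#'
#' Expects a header with a `time_s` column and any of `internal_C`,
#' `surface_C`, `air_C`.
#'
#' @param path CSV path.
#' @param label,treatment,size Trace metadata (see [heating_trace()]).
#' @return A [heating_trace()].
#' @export
read_heating_trace <- function(path, label = basename(path),
                               treatment = "HNIR", size = "small") {
  if (!file.exists(path)) stop_nirtherm("file not found: ", path)
  tab <- read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(tab))
    stop_nirtherm("trace file needs a time_s column: ", path)
  heating_trace(tab$time_s,
                internal_C = tab[["internal_C"]],
                surface_C = tab[["surface_C"]],
                air_C = tab[["air_C"]],
                label = label, treatment = treatment, size = size)
}
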