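#' Construct a field logger series
#'
#' One deployment day of internal-temperature readings for one model frog,
#' logged at a nominal 5 min interval, with the metadata the field design
#' needs: treatment, size, pairing and site.
#'
#' @param time_s Strictly increasing sample times in seconds (from the start
#'   of the deployment window).
#' @param internal_C Internal temperatures in Celsius.
#' @param model_id,pair_id,site_id,logger_id Identifiers; `pair_id` groups
#'   the two co-located models on one leaf.
#' @param treatment `"HNIR"`, `"LNIR"` or `"uncoated"`.
#' @param size `"small"` or `"large"`.
#' @param day Deployment day index (integer or date-like label).
#' @return An object of class `field_series`.
#' @export
field_series <- function(time_s, internal_C, model_id, treatment, size,
                         pair_id, site_id, logger_id = model_id, day = 1L) {
  treatment <- match.arg(treatment, c("HNIR", "LNIR", "uncoated"))
  size <- match.arg(size, c("small", "large"))
  time_s <- as.numeric(time_s)
  internal_C <- as.numeric(internal_C)
  if (length(time_s) != length(internal_C))
    stop_nirtherm("time and temperature lengths differ")
  if (is.unsorted(time_s, strictly = TRUE))
    stop_nirtherm("timestamps must be strictly increasing")
  structure(list(time_s = time_s, internal_C = internal_C,
                 model_id = as.character(model_id), treatment = treatment,
                 size = size, pair_id = as.character(pair_id),
                 site_id = as.character(site_id),
                 logger_id = as.character(logger_id), day = day),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf("<field series> %s (%s, %s) pair %s site %s day %s: %d samples\n",
              x$model_id, x$treatment, x$size, x$pair_id, x$site_id,
              format(x$day), length(x$time_s)))
  invisible(x)
}

series_meta <- function(s)
  data.frame(model_id = s$model_id, treatment = s$treatment, size = s$size,
             pair_id = s$pair_id, site_id = s$site_id,
             logger_id = s$logger_id, day = s$day, stringsAsFactors = FALSE)

#' Surface-minus-leaf temperature differences
#'
#' For each thermal-image observation, the difference between the model's
#' mean surface temperature and the adjacent leaf's mean temperature. A
#' negative delta means the model is cooler than its leaf. Rows with a
#' missing leaf temperature are dropped with a message giving the count.
#'
#' @param obs Data frame with columns `model_surface_C` and `leaf_surface_C`
#'   (plus any metadata, carried through).
#' @return `obs` with rows with missing temperatures removed and a new
#'   `delta_C` column.
#' @export
surface_leaf_delta <- function(obs) {
  stopifnot(is.data.frame(obs), nrow(obs) > 0,
            all(c("model_surface_C", "leaf_surface_C") %in% names(obs)))
  ok <- is.finite(obs$model_surface_C) & is.finite(obs$leaf_surface_C)
  if (any(!ok))
    message(sum(!ok), " observation(s) with missing surface temperature dropped")
  out <- obs[ok, , drop = FALSE]
  if (!nrow(out)) stop_nirtherm("no complete observations left")
  out$delta_C <- out$model_surface_C - out$leaf_surface_C
  out
}

#' Daily 95th-percentile internal temperature
#'
#' Summarises each logger series-day by its 95th percentile, a maximum-like
#' statistic robust to single-sample spikes (e.g. a brief sunspot hitting one
#' model of a pair). The percentile uses linear interpolation of order
#' statistics at position `(n - 1) * p + 1`.
#'
#' @param series A [field_series()] or list of them.
#' @param p Percentile (default 0.95).
#' @param min_samples Series-days with fewer samples are omitted with a
#'   warning (default 20).
#' @return A data frame with the series metadata plus `p95_C` and `n`.
#' @export
daily_p95 <- function(series, p = 0.95, min_samples = 20) {
  if (inherits(series, "field_series")) series <- list(series)
  rows <- list()
  for (s in series) {
    n <- length(s$internal_C)
    if (n < min_samples) {
      warning("series ", s$model_id, " day ", format(s$day), " has ", n,
              " samples (< ", min_samples, "); omitted", call. = FALSE)
      next
    }
    r <- series_meta(s)
    r$p95_C <- unname(quantile(s$internal_C, p, type = 7))
    r$n <- n
    rows[[length(rows) + 1L]] <- r
  }
  if (!length(rows)) stop_nirtherm("no adequately sampled series-days")
  do.call(rbind, rows)
}

#' Paired temperature-difference series
#'
#' Matches the timestamps of two co-located logger series (same `pair_id`
#' and day) and returns their per-timestamp difference, oriented as
#' LNIR minus HNIR for coated pairs and large minus small for uncoated
#' pairs. Unmatched samples are dropped with a message; fewer than 50%
#' matched is an error.
#'
#' @param a,b [field_series()] objects from the same pair.
#' @param air Optional [field_series()] of air temperature near the pair;
#'   matched values are attached as `air_C`.
#' @param tolerance_s Timestamp matching tolerance (default 150 s, half the
#'   5 min logging interval).
#' @return A data frame: `pair_id`, `site_id`, `size`, `day`, `time_s`,
#'   `diff_C` and (if `air` given) `air_C`.
#' @export
pair_difference <- function(a, b, air = NULL, tolerance_s = 150) {
  stopifnot(inherits(a, "field_series"), inherits(b, "field_series"))
  if (a$pair_id != b$pair_id)
    stop_nirtherm("series belong to different pairs (", a$pair_id, " vs ",
                  b$pair_id, ")")
  tr <- c(a$treatment, b$treatment)
  if (setequal(tr, c("LNIR", "HNIR"))) {
    if (a$treatment != "LNIR") { tmp <- a; a <- b; b <- tmp }
    size <- a$size
  } else if (all(tr == "uncoated")) {          # uncoated pairs: large - small
    if (a$size != "large") { tmp <- a; a <- b; b <- tmp }
    size <- NA_character_
  } else {
    stop_nirtherm("pair must be LNIR/HNIR or uncoated/uncoated, got ",
                  paste(tr, collapse = "/"))
  }
  j <- vapply(a$time_s, function(t) {
    d <- abs(b$time_s - t)
    i <- which.min(d)
    if (d[i] <= tolerance_s) i else NA_integer_
  }, integer(1))
  matched <- !is.na(j)
  if (mean(matched) < 0.5)
    stop_nirtherm("only ", round(100 * mean(matched)),
                  "% of samples matched within ", tolerance_s, " s")
  if (any(!matched))
    message(sum(!matched), " unmatched sample(s) dropped")
  out <- data.frame(pair_id = a$pair_id, site_id = a$site_id, size = size,
                    day = a$day, time_s = a$time_s[matched],
                    diff_C = a$internal_C[matched] - b$internal_C[j[matched]],
                    stringsAsFactors = FALSE)
  if (!is.null(air)) {
    ja <- vapply(out$time_s, function(t) {
      d <- abs(air$time_s - t); i <- which.min(d)
      if (d[i] <= tolerance_s) i else NA_integer_
    }, integer(1))
    out$air_C <- air$internal_C[ja]
  }
  out
}

# ---- mixed-model machinery ------------------------------------------------

new_stat_test_result <- function(terms, groups = NULL, intercept = NULL,
                                 phi = NA_real_, structure, flags = character()) {
  structure(list(terms = terms, groups = groups, intercept = intercept,
                 phi = phi, structure = structure, flags = flags),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat("<stat test result> ", x$structure, "\n", sep = "")
  if (length(x$flags)) cat("  flags: ", paste(x$flags, collapse = "; "), "\n")
  if (!is.null(x$terms) && nrow(x$terms)) {
    cat("  Wald chi-square tests (Type II):\n")
    print(x$terms, row.names = FALSE)
  }
  if (!is.null(x$intercept))
    cat(sprintf("  intercept MLE %.3f, 95%% CI [%.3f, %.3f]%s\n",
                x$intercept$estimate, x$intercept$lower, x$intercept$upper,
                if (x$intercept$crosses_zero) " (crosses zero)" else ""))
  if (!is.na(x$phi)) cat(sprintf("  AR1 phi = %.3f\n", x$phi))
  invisible(x)
}

wald_table <- function(fit) {
  a <- suppressMessages(car::Anova(fit, type = "II"))
  keep <- rownames(a) != "(Intercept)"
  chi_col <- intersect(c("Chisq", "LR Chisq"), colnames(a))[1L]
  p_col <- grep("^Pr", colnames(a), value = TRUE)[1L]
  data.frame(term = rownames(a)[keep],
             chisq = a[[chi_col]][keep],
             df = a[["Df"]][keep],
             p = a[[p_col]][keep],
             stringsAsFactors = FALSE)
}

# Fit a Gaussian LMM by REML with random intercepts; on a singular fit,
# drop the zero-variance component(s) and refit, recording what was
# dropped. REML variance estimation keeps the Wald chi-square tests close
# to nominal size; ML's downward variance bias makes them liberal.
fit_lmm_wald <- function(data, fixed_rhs, random_ids, response) {
  data <- droplevels(as.data.frame(data))
  for (id in random_ids) data[[id]] <- factor(data[[id]])
  flags <- character()
  build <- function(ids) {
    rhs <- paste(c(fixed_rhs,
                   sprintf("(1 | %s)", ids)), collapse = " + ")
    as.formula(paste(response, "~", rhs))
  }
  ids <- random_ids
  fit <- NULL
  while (length(ids)) {
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(build(ids), data = data, REML = TRUE)))
    if (!lme4::isSingular(fit, tol = 1e-5)) break
    vc <- as.data.frame(lme4::VarCorr(fit))
    vc <- vc[vc$grp != "Residual" & is.na(vc$var2), ]
    worst <- vc$grp[which.min(vc$vcov)]
    worst <- sub(":.*", "", worst)
    if (!worst %in% ids || length(ids) == 1L) break
    ids <- setdiff(ids, worst)
    flags <- c(flags, paste0("singular fit: random intercept for ", worst,
                             " dropped (variance ~ 0)"))
  }
  if (is.null(fit)) {
    fit <- lm(as.formula(paste(response, "~", fixed_rhs)), data = data)
    flags <- c(flags, "all random components dropped; ordinary linear model")
  }
  list(fit = fit, ids = ids, flags = flags)
}

#' Mixed model for surface-vs-leaf temperature deltas
#'
#' Gaussian linear mixed model for the surface-minus-leaf delta with NIR
#' coating, size and their interaction as fixed effects and random
#' intercepts for pair and site, fitted by REML (the variance estimator
#' that keeps Wald tests close to nominal size). Fixed terms are tested
#' with Type II Wald chi-square tests; group (coating x size) estimates
#' are reported with asymptotic 95% confidence intervals.
#'
#' @param deltas Data frame from [surface_leaf_delta()] with columns
#'   `delta_C`, `coating` (or `treatment`), `size`, `pair_id`, `site_id`.
#' @return A `stat_test_result`.
#' @export
fit_delta_lmm <- function(deltas) {
  deltas <- normalise_factors(deltas)
  check_design(deltas, c("pair_id", "site_id"))
  res <- fit_lmm_wald(deltas, "coating * size", c("pair_id", "site_id"),
                      "delta_C")
  groups <- tryCatch(
    as.data.frame(summary(emmeans::emmeans(res$fit, ~ coating * size,
                                           lmer.df = "asymptotic"))),
    error = function(e) NULL)
  new_stat_test_result(
    terms = wald_table(res$fit), groups = tidy_groups(groups),
    structure = paste0("delta_C ~ coating * size + random intercepts (",
                       paste(res$ids, collapse = ", "), "), Gaussian REML"),
    flags = res$flags)
}

#' Mixed model for daily 95th-percentile internal temperature
#'
#' As [fit_delta_lmm()], with a third random intercept for the logger
#' (instrument-level bias).
#'
#' @param p95 Data frame from [daily_p95()] with columns `p95_C`,
#'   `coating` (or `treatment`), `size`, `pair_id`, `site_id`, `logger_id`.
#' @return A `stat_test_result`.
#' @export
fit_p95_lmm <- function(p95) {
  p95 <- normalise_factors(p95)
  check_design(p95, c("pair_id", "site_id", "logger_id"))
  res <- fit_lmm_wald(p95, "coating * size",
                      c("pair_id", "site_id", "logger_id"), "p95_C")
  groups <- tryCatch(
    as.data.frame(summary(emmeans::emmeans(res$fit, ~ coating * size,
                                           lmer.df = "asymptotic"))),
    error = function(e) NULL)
  new_stat_test_result(
    terms = wald_table(res$fit), groups = tidy_groups(groups),
    structure = paste0("p95_C ~ coating * size + random intercepts (",
                       paste(res$ids, collapse = ", "), "), Gaussian REML"),
    flags = res$flags)
}

normalise_factors <- function(d) {
  d <- as.data.frame(d)
  if (!"coating" %in% names(d) && "treatment" %in% names(d))
    d$coating <- d$treatment
  d$coating <- factor(d$coating, levels = intersect(
    c("HNIR", "LNIR", "uncoated"), unique(as.character(d$coating))))
  if ("size" %in% names(d))
    d$size <- factor(d$size, levels = intersect(c("small", "large"),
                                                unique(as.character(d$size))))
  d
}

check_design <- function(d, random_ids) {
  if (nlevels(d$coating) < 2L)
    stop_nirtherm("need at least 2 coating levels")
  for (id in random_ids)
    if (length(unique(d[[id]])) < 3L)
      stop_nirtherm("need at least 3 groups for random factor ", id)
  invisible(d)
}

tidy_groups <- function(g) {
  if (is.null(g)) return(NULL)
  names(g)[names(g) == "emmean"] <- "estimate"
  names(g)[grep("lower|LCL", names(g))] <- "lower"
  names(g)[grep("upper|UCL", names(g))] <- "upper"
  g[, intersect(c("coating", "size", "estimate", "lower", "upper"), names(g))]
}

#' Paired-difference model with AR1 residual autocorrelation
#'
#' Fits a linear mixed model to LNIR-minus-HNIR (or large-minus-small
#' uncoated) temperature-difference series: air temperature and, for coated
#' pairs, size as fixed effects; random intercepts for site and pair (pair
#' nested within site); and a first-order autoregressive correlation
#' structure on the residuals within each series. The quantity of interest
#' is the intercept's maximum-likelihood estimate: a 95% confidence interval
#' excluding zero indicates that one member of the pairs runs consistently
#' warmer. Air temperature is centred and size coded sum-to-zero before
#' fitting, so the intercept is the mean paired difference rather than an
#' extrapolation to 0 C air.
#'
#' Consecutive deployment days of the same pair are decorrelated by an index
#' gap, so the AR1 process never bridges a day boundary. If the AR1 model
#' fails to converge the model is refitted with independent residuals and
#' flagged loudly.
#'
#' @param diffs Data frame from [pair_difference()] (rows from several pairs
#'   stacked): columns `diff_C`, `pair_id`, `site_id`, `day`, `time_s`, and
#'   optionally `air_C` and `size`.
#' @param include_size Include size as a predictor (default `TRUE`; set
#'   `FALSE` for uncoated pairs, whose difference is large minus small).
#' @return A `stat_test_result` with the intercept MLE, its 95% CI, the
#'   estimated AR1 coefficient `phi`, and Type II Wald chi-square tests for
#'   the predictors.
#' @export
fit_paired_ar1 <- function(diffs, include_size = TRUE) {
  d <- as.data.frame(diffs)
  stopifnot(all(c("diff_C", "pair_id", "site_id") %in% names(d)))
  if (!"day" %in% names(d)) d$day <- 1L
  d$site_id <- factor(d$site_id)
  d$pair_id <- factor(d$pair_id)
  d <- d[order(d$site_id, d$pair_id, d$day, d$time_s), ]
  # integer AR1 index; +1000 between days so runs never bridge a boundary
  d$ar_index <- local({
    g <- interaction(d$site_id, d$pair_id, drop = TRUE)
    idx <- integer(nrow(d))
    for (lv in levels(g)) {
      i <- which(g == lv)
      day_rank <- match(d$day[i], unique(d$day[i]))
      idx[i] <- stats::ave(rep(1L, length(i)), day_rank, FUN = seq_along) +
        1000L * (day_rank - 1L)
    }
    idx
  })
  # centre the covariates so the intercept is the mean paired difference
  # (uncentred, it would be the extrapolated difference at 0 C air)
  if ("air_C" %in% names(d) && !all(is.na(d$air_C)))
    d$air_C <- d$air_C - mean(d$air_C, na.rm = TRUE)
  if ("size" %in% names(d)) {
    d$size <- factor(d$size)
    if (nlevels(d$size) > 1L) contrasts(d$size) <- "contr.sum"
  }
  preds <- c(if ("air_C" %in% names(d) && !all(is.na(d$air_C))) "air_C",
             if (include_size && "size" %in% names(d) &&
                 nlevels(d$size) > 1L) "size")
  fixed <- as.formula(paste("diff_C ~",
                            if (length(preds)) paste(preds, collapse = " + ")
                            else "1"))
  flags <- character(); phi <- NA_real_
  fit <- tryCatch(
    nlme::lme(fixed, random = ~ 1 | site_id / pair_id,
              correlation = nlme::corAR1(form = ~ ar_index | site_id / pair_id),
              data = d, method = "ML",
              control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                         opt = "optim", returnObject = TRUE)),
    error = function(e) e)
  structure_desc <- paste0(deparse(fixed), " + random intercepts ",
                           "(pair within site) + AR1 within series, ML")
  if (inherits(fit, "error")) {
    flags <- c(flags, paste0("AR1 LMM failed (", conditionMessage(fit),
                             "); refitted with AR1 GLS without random effects"))
    fit <- tryCatch(
      nlme::gls(fixed, correlation = nlme::corAR1(form = ~ ar_index | pair_id),
                data = d, method = "ML"),
      error = function(e) e)
    structure_desc <- paste0(deparse(fixed), " + AR1 within series, GLS ML")
  }
  if (inherits(fit, "error")) {
    flags <- c(flags,
               "AR1 estimation non-convergent; independent residuals assumed")
    fit <- lm(fixed, data = d)
    structure_desc <- paste0(deparse(fixed), ", independent residuals (OLS)")
  } else {
    cs <- fit$modelStruct$corStruct
    if (!is.null(cs)) phi <- unname(coef(cs, unconstrained = FALSE)[1L])
  }
  est <- if (inherits(fit, "lm")) coef(summary(fit))["(Intercept)", 1:2] else
    summary(fit)$tTable["(Intercept)", c("Value", "Std.Error")]
  z <- qnorm(0.975)
  intercept <- list(estimate = unname(est[1L]),
                    lower = unname(est[1L] - z * est[2L]),
                    upper = unname(est[1L] + z * est[2L]))
  intercept$crosses_zero <- intercept$lower <= 0 && intercept$upper >= 0
  terms <- if (length(preds)) tryCatch(wald_table(fit),
                                       error = function(e) NULL) else NULL
  new_stat_test_result(terms = terms, intercept = intercept, phi = phi,
                       structure = structure_desc, flags = flags)
}

#' Detect transient sunspot heating events
#'
#' Flags maximal intervals where the internal temperature exceeds a running
#' baseline (the median of the preceding `baseline_min` minutes) by at least
#' `rise_C`, provided the rise is reached within `window_min` minutes of the
#' event's onset — the signature of a moving patch of direct sun rather than
#' a slow warming trend.
#'
#' @param series A [field_series()].
#' @param rise_C Minimum excess over baseline (default 2).
#' @param window_min Maximum onset-to-threshold time in minutes (default 20).
#' @param baseline_min Baseline window in minutes (default 60).
#' @return A data frame of events: `day`, `start_s`, `end_s`,
#'   `duration_min`, `peak_excess_C` (zero rows when none).
#' @export
detect_sunspot_events <- function(series, rise_C = 2.0, window_min = 20,
                                  baseline_min = 60) {
  stopifnot(inherits(series, "field_series"))
  t <- series$time_s; v <- series$internal_C
  n <- length(t)
  dt <- median(diff(t))
  base <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- which(t < t[i] & t >= t[i] - baseline_min * 60)
    if (length(w) >= 3L) base[i] <- median(v[w])
  }
  excess <- v - base
  above <- !is.na(excess) & excess >= rise_C
  soft <- !is.na(excess) & excess >= rise_C / 2   # onset/offset envelope
  events <- list()
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    onset <- i0
    while (onset > 1L && soft[onset - 1L]) onset <- onset - 1L
    if (t[i0] - t[onset] > window_min * 60) next   # slow drift, not a spike
    off <- i1
    while (off < n && soft[off + 1L]) off <- off + 1L
    events[[length(events) + 1L]] <- data.frame(
      day = series$day, start_s = t[onset], end_s = t[off],
      duration_min = (t[off] - t[onset] + dt) / 60,
      peak_excess_C = max(excess[i0:i1]))
  }
  if (!length(events))
    return(data.frame(day = series$day[0], start_s = numeric(0),
                      end_s = numeric(0), duration_min = numeric(0),
                      peak_excess_C = numeric(0)))
  do.call(rbind, events)
}

#' Detect sunspot events in a co-located pair
#'
#' Runs [detect_sunspot_events()] on both members, merges overlapping
#' events, and reports the peak paired excess (first minus second series,
#' timestamps matched) within each merged event window — e.g. how much
#' hotter the low-NIR model ran than its high-NIR partner during the spike.
#'
#' @param a,b [field_series()] objects from the same pair.
#' @inheritParams detect_sunspot_events
#' @return Event data frame with an extra `peak_paired_excess_C` column.
#' @export
detect_sunspot_events_paired <- function(a, b, rise_C = 2.0, window_min = 20,
                                         baseline_min = 60) {
  ev <- rbind(detect_sunspot_events(a, rise_C, window_min, baseline_min),
              detect_sunspot_events(b, rise_C, window_min, baseline_min))
  if (!nrow(ev)) return(cbind(ev, peak_paired_excess_C = numeric(0)))
  ev <- ev[order(ev$start_s), ]
  merged <- ev[1L, , drop = FALSE]
  for (i in seq_len(nrow(ev))[-1L]) {
    last <- nrow(merged)
    if (ev$start_s[i] <= merged$end_s[last]) {
      merged$end_s[last] <- max(merged$end_s[last], ev$end_s[i])
      merged$duration_min[last] <- max(merged$duration_min[last],
                                       (merged$end_s[last] -
                                          merged$start_s[last]) / 60)
      merged$peak_excess_C[last] <- max(merged$peak_excess_C[last],
                                        ev$peak_excess_C[i])
    } else merged <- rbind(merged, ev[i, ])
  }
  merged$peak_paired_excess_C <- vapply(seq_len(nrow(merged)), function(i) {
    w <- a$time_s >= merged$start_s[i] & a$time_s <= merged$end_s[i]
    if (!any(w)) return(NA_real_)
    bi <- vapply(a$time_s[w], function(tt) which.min(abs(b$time_s - tt)),
                 integer(1))
    max(a$internal_C[w] - b$internal_C[bi])
  }, numeric(1))
  merged
}
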