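# Baseline-relative ventricle-volume event analysis: percent-of-baseline
# normalisation, the healthy-variation threshold, detection of above-threshold
# expansion/contraction events, and stratification of a cohort by sustained
# contraction status.

#' Percent change from the baseline scan
#'
#' Entry `t` is `100 * (V_t - V_0) / V_0`; the first entry is 0 by
#' construction. The baseline is always the first scan — series are never
#' re-baselined.
#'
#' @param vv_series Positive volume series, length >= 2; the first value must
#'   be observed and positive.
#' @return Numeric percent trace, same length, first entry 0.
#' @export
percent_change_from_baseline <- function(vv_series) {
  if (length(vv_series) < 2L) stop("series must have at least 2 time points")
  v0 <- vv_series[1L]
  if (is.na(v0) || v0 <= 0) stop("baseline volume must be observed and positive")
  100 * (vv_series - v0) / v0
}

#' Healthy-variation threshold from a control cohort
#'
#' The one-sided magnitude of normal intra-individual VV fluctuation: the
#' maximum over control subjects of the maximum absolute percent change from
#' baseline. With no control data the fixed literature band of 6% is used.
#'
#' @param healthy_cohort A [vv_cohort()] of healthy subjects, or `NULL` to
#'   fall back to the fixed 6% default.
#' @return List of class `threshold_estimate` with `value` (%), `source`
#'   (`"fixed"` or `"estimated"`) and `per_subject_maxima`.
#' @export
estimate_normal_variation_threshold <- function(healthy_cohort = NULL) {
  if (is.null(healthy_cohort)) {
    return(structure(list(value = 6, source = "fixed",
                          per_subject_maxima = numeric(0)),
                     class = "threshold_estimate"))
  }
  stopifnot(inherits(healthy_cohort, "vv_cohort"))
  if (length(healthy_cohort) < 1L) stop("empty healthy cohort")
  maxima <- vapply(healthy_cohort, function(s) {
    vv <- s$variables$ventricle_volume
    if (is.null(vv)) vv <- s$variables$vv
    if (is.null(vv) || sum(!is.na(vv)) < 2L) {
      stop("subject '", s$subject_id, "' lacks a usable VV series")
    }
    max(abs(percent_change_from_baseline(vv)), na.rm = TRUE)
  }, 1)
  value <- max(maxima)
  if (value == 0) {
    warning("all control series constant: zero threshold is degenerate",
            call. = FALSE)
  }
  structure(list(value = value, source = "estimated",
                 per_subject_maxima = unname(maxima)),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("healthy-variation threshold: %.4g%% (%s", x$value, x$source))
  if (length(x$per_subject_maxima)) {
    cat(sprintf(", n = %d controls", length(x$per_subject_maxima)))
  }
  cat(")\n")
  invisible(x)
}

#' Detect above-threshold interval events in a percent trace
#'
#' An event is a maximal run of consecutive same-sign interval changes of the
#' percent-of-baseline trace whose cumulative magnitude strictly exceeds the
#' threshold. Zero-change intervals terminate a run. Interval changes are
#' percentage-point differences of the baseline-relative trace, not
#' month-over-month ratios.
#'
#' @param pct_trace Percent-of-baseline trace (first entry 0).
#' @param threshold Positive threshold in percentage points.
#' @return Data.frame with columns `start, end` (0-based trace indices),
#'   `magnitude` (signed %), `direction` (`"expansion"`/`"contraction"`);
#'   zero rows when no event qualifies.
#' @export
detect_interval_changes <- function(pct_trace, threshold) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (length(pct_trace) < 2L) stop("trace must have at least 2 entries")
  d <- diff(pct_trace)
  sgn <- sign(d)
  runs <- rle(sgn)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0
  out <- data.frame(start = integer(0), end = integer(0),
                    magnitude = numeric(0), direction = character(0),
                    stringsAsFactors = FALSE)
  for (j in which(keep)) {
    mag <- sum(d[starts[j]:ends[j]])
    if (abs(mag) > threshold) {
      out <- rbind(out, data.frame(
        start = starts[j] - 1L, end = ends[j],
        magnitude = mag,
        direction = if (mag > 0) "expansion" else "contraction",
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Classify a subject's sustained-contraction status
#'
#' A subject is `contracting` when the percent trace has a window of at least
#' `min_duration` intervals over which it is non-increasing (a zero-change
#' month does not break the window; a positive month does) and the total drop
#' strictly exceeds the threshold. `expansion_only` flags subjects with at
#' least one above-threshold expansion event but no above-threshold
#' contraction event of any duration.
#'
#' @param pct_trace Percent-of-baseline trace.
#' @param threshold Positive threshold in percentage points.
#' @param min_duration Minimum window length in intervals (months).
#' @return List with `status` (`"contracting"`/`"noncontracting"`),
#'   `expansion_only`, and `max_contraction` (most negative drop over any
#'   qualifying window, %; 0 when none qualifies).
#' @export
classify_contraction_status <- function(pct_trace, threshold, min_duration = 2L) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (min_duration < 1L) stop("min_duration must be >= 1")
  if (length(pct_trace) < 2L) stop("trace must have at least 2 entries")
  d <- diff(pct_trace)
  # maximal non-increasing runs; the deepest qualifying window inside a run
  # is the whole run, so runs of length >= min_duration decide the status
  runs <- rle(d <= 0)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  max_contraction <- 0
  contracting <- FALSE
  for (j in which(runs$values)) {
    if (runs$lengths[j] < min_duration) next
    drop <- pct_trace[starts[j]] - pct_trace[ends[j] + 1L]
    if (drop > threshold) {
      contracting <- TRUE
      max_contraction <- min(max_contraction, -drop)
    }
  }
  events <- detect_interval_changes(pct_trace, threshold)
  expansion_only <- any(events$direction == "expansion") &&
    !any(events$direction == "contraction")
  list(status = if (contracting) "contracting" else "noncontracting",
       expansion_only = expansion_only,
       max_contraction = max_contraction)
}

#' Coefficient of variation, in percent
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation; invariant
#' under positive rescaling of the volume unit.
#'
#' @param series Numeric series, length >= 2, nonzero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(series) {
  series <- series[!is.na(series)]
  if (length(series) < 2L) stop("need at least 2 observations")
  m <- mean(series)
  if (m == 0) stop("CV undefined for zero mean")
  100 * stats::sd(series) / m
}

#' Build a per-subject VV event profile
#'
#' @param subject A [subject_series()] with a `ventricle_volume` series.
#' @param threshold Positive threshold in percentage points.
#' @param min_duration Minimum sustained-contraction window, intervals.
#' @return Object of class `vv_event_profile`: percent trace, interval
#'   changes, events, contraction status, `max_contraction` over qualifying
#'   windows, `max_drop` over non-increasing runs of any length (the lollipop
#'   depth), and the CV of the raw series.
#' @export
vv_event_profile <- function(subject, threshold = 6, min_duration = 2L) {
  vv <- subject$variables$ventricle_volume
  if (is.null(vv)) stop("subject '", subject$subject_id,
                        "' has no ventricle_volume series")
  if (anyNA(vv)) stop("subject '", subject$subject_id,
                      "' has missing VV values")
  pct <- percent_change_from_baseline(vv)
  cls <- classify_contraction_status(pct, threshold, min_duration)
  d <- diff(pct)
  runs <- rle(d <= 0)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  drops <- vapply(which(runs$values),
                  function(j) pct[starts[j]] - pct[ends[j] + 1L], 1)
  structure(list(
    subject_id = subject$subject_id,
    pct_trace = pct,
    interval_changes = d,
    events = detect_interval_changes(pct, threshold),
    status = cls$status,
    expansion_only = cls$expansion_only,
    max_contraction = cls$max_contraction,
    max_drop = if (length(drops)) -max(drops) else 0,
    cv = coefficient_of_variation(vv),
    threshold = threshold
  ), class = "vv_event_profile")
}

#' @export
print.vv_event_profile <- function(x, ...) {
  cat("<vv_event_profile> ", x$subject_id, ": ", x$status,
      sprintf(" (threshold %.3g%%)\n", x$threshold), sep = "")
  cat(sprintf("  %d above-threshold events; max contraction %.3g%%; CV %.3g%%\n",
              nrow(x$events), x$max_contraction, x$cv))
  invisible(x)
}

#' Stratify a cohort by sustained-contraction status
#'
#' Partitions the cohort into contracting and noncontracting subjects (the
#' partition is disjoint and exhaustive over classifiable subjects); subjects
#' with missing VV values are excluded with a warning, mirroring a
#' completers-only analysis.
#'
#' @param cohort A [vv_cohort()].
#' @param threshold Positive threshold in percentage points (default the 6%
#'   healthy band), or a `threshold_estimate`.
#' @param min_duration Minimum sustained-contraction window, intervals.
#' @return Object of class `vv_stratification`: `profiles`, a per-subject
#'   `table` (`subject_id, status, expansion_only, max_contraction, cv,
#'   n_events`), group sizes and per-group CV, the proportion with any
#'   above-threshold single-interval change, the expansion-only count, and
#'   lollipop plotting coordinates.
#' @export
stratify_cohort <- function(cohort, threshold = 6, min_duration = 2L) {
  stopifnot(inherits(cohort, "vv_cohort"))
  if (inherits(threshold, "threshold_estimate")) threshold <- threshold$value
  usable <- vapply(cohort, function(s) {
    vv <- s$variables$ventricle_volume
    !is.null(vv) && !anyNA(vv)
  }, TRUE)
  if (any(!usable)) {
    warning(sum(!usable), " subject(s) excluded from stratification ",
            "(missing VV): ",
            paste(names(cohort)[!usable], collapse = ", "), call. = FALSE)
  }
  subjects <- unclass(cohort)[usable]
  if (!length(subjects)) stop("no classifiable subjects")
  profiles <- lapply(subjects, vv_event_profile, threshold = threshold,
                     min_duration = min_duration)
  tab <- data.frame(
    subject_id = vapply(profiles, `[[`, "", "subject_id"),
    status = vapply(profiles, `[[`, "", "status"),
    expansion_only = vapply(profiles, `[[`, TRUE, "expansion_only"),
    max_contraction = vapply(profiles, `[[`, 1, "max_contraction"),
    cv = vapply(profiles, `[[`, 1, "cv"),
    n_events = vapply(profiles, function(p) nrow(p$events), 1L),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  any_monthly <- vapply(profiles, function(p) any(abs(p$interval_changes) >
                                                    threshold), TRUE)
  lollipop <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(subject_id = p$subject_id, t = seq_along(p$pct_trace) - 1L,
               pct = p$pct_trace, status = p$status, max_drop = p$max_drop,
               stringsAsFactors = FALSE)
  }))
  rownames(lollipop) <- NULL
  structure(list(
    profiles = profiles,
    table = tab,
    threshold = threshold,
    group_sizes = c(contracting = sum(tab$status == "contracting"),
                    noncontracting = sum(tab$status == "noncontracting")),
    prop_any_monthly_change = mean(any_monthly),
    n_expansion_only = sum(tab$expansion_only),
    cv_by_group = tapply(tab$cv, tab$status, mean),
    n_excluded = sum(!usable),
    lollipop = lollipop
  ), class = "vv_stratification")
}

#' @export
print.vv_stratification <- function(x, ...) {
  n <- sum(x$group_sizes)
  cat("<vv_stratification> ", n, " subjects at threshold ",
      sprintf("%.3g%%\n", x$threshold), sep = "")
  cat(sprintf("  contracting: %d (%.0f%%), noncontracting: %d; expansion-only: %d\n",
              x$group_sizes[["contracting"]],
              100 * x$group_sizes[["contracting"]] / n,
              x$group_sizes[["noncontracting"]], x$n_expansion_only))
  cat(sprintf("  with any above-threshold monthly change: %.0f%%\n",
              100 * x$prop_any_monthly_change))
  if (x$n_excluded) cat("  excluded (missing VV):", x$n_excluded, "\n")
  invisible(x)
}

#' @export
summary.vv_stratification <- function(object, ...) {
  object$table
}

#' @export
plot.vv_stratification <- function(x, ...) {
  lp <- x$lollipop
  cols <- c(contracting = "#e08214", noncontracting = "#1b7837")
  ids <- unique(lp$subject_id)
  xi <- match(lp$subject_id, ids)
  plot(NA, xlim = c(0.5, length(ids) + 0.5),
       ylim = range(c(lp$pct, -x$threshold, x$threshold)),
       xlab = "subject", ylab = "VV change from baseline (%)", ...)
  abline(h = c(-x$threshold, x$threshold), lty = 3)
  points(jitter(xi, 0.3), lp$pct, col = cols[lp$status], pch = 16, cex = 0.5)
  drops <- lp[!duplicated(lp$subject_id), ]
  segments(match(drops$subject_id, ids), 0,
           match(drops$subject_id, ids), drops$max_drop,
           col = cols[drops$status])
  invisible(x)
}

#' Cohort-level VV change between baseline and last time point
#'
#' Summarises the whole-cohort shift the way longitudinal volumetry studies
#' report it: medians (with IQR) of the baseline and final volumes, their
#' difference in mm^3, and two percent versions — the percent difference of
#' the group medians, and the median of the per-subject percent changes
#' (reported side by side because published group percentages are frequently
#' ambiguous between the two).
#'
#' @param cohort A [vv_cohort()] whose subjects carry `ventricle_volume`.
#' @return List with `median_baseline`, `median_last`, `iqr_baseline`,
#'   `iqr_last`, `median_difference`, `pct_of_median_baseline`,
#'   `median_subject_pct_change`, and the Wilcoxon signed-rank test of the
#'   paired baseline/last volumes.
#' @export
cohort_vv_change <- function(cohort) {
  stopifnot(inherits(cohort, "vv_cohort"))
  base <- vapply(cohort, function(s) s$variables$ventricle_volume[1L], 1)
  last <- vapply(cohort, function(s) {
    vv <- s$variables$ventricle_volume
    vv[length(vv)]
  }, 1)
  ok <- !is.na(base) & !is.na(last)
  base <- base[ok]; last <- last[ok]
  md <- stats::median(last) - stats::median(base)
  list(
    median_baseline = stats::median(base),
    median_last = stats::median(last),
    iqr_baseline = unname(stats::quantile(base, c(0.25, 0.75))),
    iqr_last = unname(stats::quantile(last, c(0.25, 0.75))),
    median_difference = md,
    pct_of_median_baseline = 100 * md / stats::median(base),
    median_subject_pct_change = stats::median(100 * (last - base) / base),
    wilcoxon = wilcoxon_signed_rank(last, base)
  )
}
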