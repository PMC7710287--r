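# The screening engine: per subject, difference every series, check
# stationarity (ADF) and periodicity (ACF), cross-correlate the X variable
# against each Y variable over the lag window, pool the nominal p-values and
# apply Benjamini-Hochberg FDR across the whole coefficient grid.

#' Run the lag-limited cross-correlation screen over a cohort
#'
#' For every subject with complete series, each series is first-order
#' differenced, its stationarity asserted with the ADF test and its
#' periodicity checked with the ACF (failures are recorded, never fatal: the
#' screen continues and surfaces them in the summary). The differenced X
#' series is then cross-correlated with each differenced Y series over lags
#' `-max_lag..max_lag`, each coefficient receives a nominal two-sided
#' p-value, and the FDR correction is applied over the pooled family.
#'
#' With `fdr_pool = "all"` (default) BH runs over every defined coefficient
#' in the grid; `"nominal"` reproduces the two-stage reading in which only
#' coefficients with nominal p below `alpha` enter the BH family. Undefined
#' coefficients (zero-variance overlaps) are excluded from either pool and
#' counted. Subjects with missing or absent series are skipped with a
#' recorded reason. Ordinal variables (e.g. EDSS) must not be passed as Y
#' variables; the screen assumes continuous inputs.
#'
#' @param cohort A [vv_cohort()].
#' @param x_variable Name of the driving series (default `ventricle_volume`).
#' @param y_variables Character vector of comparison variables; `NULL` means
#'   every other variable of the first subject.
#' @param max_lag Largest |lag| in time steps (default 2).
#' @param alpha Significance / FDR level.
#' @param fdr_pool `"all"` or `"nominal"` (see above).
#' @param diagnostics Run the per-series ADF and ACF checks (default TRUE).
#' @return Object of class `ccf_screen`: `records` (one row per subject x
#'   Y-variable x lag: `subject_id, x, y, lag, coefficient, n_effective,
#'   p_nominal, q_fdr, significant`), `summary` (a `ccf_screen_summary`),
#'   `diagnostics` (per-series ADF/ACF results), and `skipped`.
#' @export
run_ccf_screen <- function(cohort, x_variable = "ventricle_volume",
                           y_variables = NULL, max_lag = 2L, alpha = 0.05,
                           fdr_pool = c("all", "nominal"),
                           diagnostics = TRUE) {
  stopifnot(inherits(cohort, "vv_cohort"))
  fdr_pool <- match.arg(fdr_pool)
  if (is.null(y_variables)) {
    y_variables <- setdiff(names(cohort[[1L]]$variables), x_variable)
  }
  if (x_variable %in% y_variables) stop("x_variable cannot also be a y_variable")
  needed <- c(x_variable, y_variables)
  nl <- 2L * max_lag + 1L

  rec_list <- list()
  diag_list <- list()
  skipped <- data.frame(subject_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (s in cohort) {
    have <- needed %in% names(s$variables)
    if (!all(have)) {
      skipped <- rbind(skipped, data.frame(
        subject_id = s$subject_id,
        reason = paste("missing series:",
                       paste(needed[!have], collapse = ", ")),
        stringsAsFactors = FALSE))
      next
    }
    if (any(vapply(s$variables[needed], anyNA, TRUE))) {
      skipped <- rbind(skipped, data.frame(
        subject_id = s$subject_id, reason = "missing values",
        stringsAsFactors = FALSE))
      next
    }
    dser <- lapply(s$variables[needed], first_difference)
    if (diagnostics) {
      for (nm in needed) {
        adf <- tryCatch(adf_stationarity_test(dser[[nm]], alpha = alpha),
                        error = function(e) NULL)
        ac <- tryCatch(autocorrelation_check(dser[[nm]], max_lag = max_lag),
                       error = function(e) NULL)
        diag_list[[length(diag_list) + 1L]] <- data.frame(
          subject_id = s$subject_id, variable = nm,
          adf_statistic = if (is.null(adf)) NA_real_ else adf$statistic,
          adf_p = if (is.null(adf)) NA_real_ else adf$p_value,
          stationary = if (is.null(adf)) NA else adf$stationary,
          periodicity = if (is.null(ac)) NA else ac$periodicity,
          stringsAsFactors = FALSE)
      }
    }
    for (yv in y_variables) {
      cc <- cross_correlation(dser[[x_variable]], dser[[yv]],
                              max_lag = max_lag)
      rec_list[[length(rec_list) + 1L]] <- data.frame(
        subject_id = s$subject_id, x = x_variable, y = yv,
        lag = cc$lag, coefficient = cc$coefficient,
        n_effective = cc$n_effective, stringsAsFactors = FALSE)
    }
  }
  if (!length(rec_list)) stop("no subject had complete series to screen")
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL
  records$p_nominal <- ccf_pvalue(records$coefficient, records$n_effective)

  records$q_fdr <- NA_real_
  records$significant <- FALSE
  in_pool <- !is.na(records$p_nominal)
  if (fdr_pool == "nominal") in_pool <- in_pool & records$p_nominal < alpha
  if (any(in_pool)) {
    fdr <- bh_fdr(records$p_nominal[in_pool], alpha = alpha)
    records$q_fdr[in_pool] <- fdr$q_values
    records$significant[in_pool] <- fdr$reject
  }

  diag_df <- if (length(diag_list)) do.call(rbind, diag_list) else NULL
  out <- structure(list(
    records = records,
    summary = NULL,
    x_variable = x_variable, y_variables = y_variables,
    max_lag = max_lag, alpha = alpha, fdr_pool = fdr_pool,
    diagnostics = diag_df,
    skipped = skipped
  ), class = "ccf_screen")
  out$summary <- summarize_screen(records, alpha = alpha,
                                  diagnostics = diag_df, skipped = skipped)
  out
}

#' Summarise a set of cross-correlation records
#'
#' @param records Record data.frame from [run_ccf_screen()].
#' @param alpha Nominal significance level used for the `n_nominal` count.
#' @param diagnostics,skipped Optional diagnostic tables to fold into the
#'   summary.
#' @return Object of class `ccf_screen_summary`: `total_coefficients`,
#'   `n_undefined`, `n_nominal` (p below `alpha`), `n_fdr_retained`,
#'   retained-count breakdowns per subject / variable / lag, lollipop
#'   coordinates of the retained records (|lag| on the depth axis,
#'   coefficient magnitude as the colour value), and diagnostic counts.
#' @export
summarize_screen <- function(records, alpha = 0.05, diagnostics = NULL,
                             skipped = NULL) {
  sig <- records[records$significant %in% TRUE, , drop = FALSE]
  count_by <- function(key) {
    tab <- table(factor(sig[[key]], levels = unique(records[[key]])))
    as.data.frame(tab, responseName = "n_retained",
                  stringsAsFactors = FALSE)
  }
  lollipop <- if (nrow(sig)) {
    data.frame(subject_id = sig$subject_id, variable = sig$y,
               abs_lag = abs(sig$lag), lag = sig$lag,
               coefficient = sig$coefficient,
               magnitude = abs(sig$coefficient), stringsAsFactors = FALSE)
  } else {
    data.frame(subject_id = character(0), variable = character(0),
               abs_lag = integer(0), lag = integer(0),
               coefficient = numeric(0), magnitude = numeric(0),
               stringsAsFactors = FALSE)
  }
  structure(list(
    total_coefficients = nrow(records),
    n_undefined = sum(is.na(records$coefficient)),
    n_nominal = sum(records$p_nominal < alpha, na.rm = TRUE),
    n_fdr_retained = nrow(sig),
    per_subject = count_by("subject_id"),
    per_variable = count_by("y"),
    per_lag = count_by("lag"),
    lollipop = lollipop,
    n_adf_failures = if (is.null(diagnostics)) NA_integer_ else
      sum(!diagnostics$stationary, na.rm = TRUE),
    n_periodicity_flags = if (is.null(diagnostics)) NA_integer_ else
      sum(diagnostics$periodicity, na.rm = TRUE),
    n_skipped = if (is.null(skipped)) 0L else nrow(skipped)
  ), class = "ccf_screen_summary")
}

#' @export
print.ccf_screen_summary <- function(x, ...) {
  cat("cross-correlation screen summary\n")
  cat(sprintf("  coefficients: %d (undefined: %d)\n",
              x$total_coefficients, x$n_undefined))
  cat(sprintf("  nominal p < alpha: %d; FDR-retained: %d\n",
              x$n_nominal, x$n_fdr_retained))
  if (!is.na(x$n_adf_failures)) {
    cat(sprintf("  ADF non-stationary flags: %d; periodicity flags: %d\n",
                x$n_adf_failures, x$n_periodicity_flags))
  }
  if (x$n_skipped) cat("  subjects skipped:", x$n_skipped, "\n")
  invisible(x)
}

#' @export
print.ccf_screen <- function(x, ...) {
  ns <- length(unique(x$records$subject_id))
  cat("<ccf_screen> ", x$x_variable, " vs ", length(x$y_variables),
      " variables, lags -", x$max_lag, "..+", x$max_lag,
      " (", ns, " subjects, FDR pool: ", x$fdr_pool, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
summary.ccf_screen <- function(object, ...) object$summary

#' Lollipop display of the FDR-retained coefficients
#'
#' Flattens the 3D lollipop view: subjects on the horizontal axis, comparison
#' variables on the vertical axis; point size scales inversely with |lag|
#' (lag 0 largest) and colour intensity with coefficient magnitude.
#'
#' @param x A `ccf_screen`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ccf_screen <- function(x, ...) {
  lp <- x$summary$lollipop
  subj <- unique(x$records$subject_id)
  vars <- x$y_variables
  plot(NA, xlim = c(0.5, length(subj) + 0.5), ylim = c(0.5, length(vars) + 0.5),
       xlab = "subject", ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = seq_along(vars), labels = vars, las = 2, cex.axis = 0.7)
  if (nrow(lp)) {
    shade <- grDevices::gray(1 - lp$magnitude)
    graphics::points(match(lp$subject_id, subj), match(lp$variable, vars),
                     pch = 21, bg = shade,
                     cex = 2.2 - 0.5 * lp$abs_lag)
  }
  invisible(x)
}
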