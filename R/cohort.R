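#' Construct a single-subject longitudinal series
#'
#' The raw unit of every analysis in the package: one subject's observation
#' grid plus a set of named variable series aligned to that grid. Ventricle
#' volume, when present, must be strictly positive wherever it is observed;
#' missing observations are carried as `NA`.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param group Cohort label, one of `"healthy"`, `"ms"`, `"eae"`.
#' @param time Strictly increasing numeric observation grid.
#' @param variables Named list of numeric vectors, each the same length as
#'   `time`. Use `NA` for missing cells.
#' @param time_unit `"months"` or `"days"`.
#'
#' @return An object of class `subject_series`.
#' @export
subject_series <- function(subject_id, group, time, variables,
                           time_unit = c("months", "days")) {
  time_unit <- match.arg(time_unit)
  group <- match.arg(group, c("healthy", "ms", "eae"))
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  time <- as.numeric(time)
  if (length(time) < 1L || anyNA(time) || any(diff(time) <= 0)) {
    stop("'time' must be a strictly increasing grid without NA")
  }
  if (!is.list(variables) || is.null(names(variables)) ||
      any(!nzchar(names(variables)))) {
    stop("'variables' must be a fully named list of numeric series")
  }
  variables <- lapply(variables, as.numeric)
  bad_len <- vapply(variables, length, 1L) != length(time)
  if (any(bad_len)) {
    stop("series not aligned to the time grid: ",
         paste(names(variables)[bad_len], collapse = ", "))
  }
  vv_names <- grep("^(vv|ventricle_volume)$", names(variables), value = TRUE)
  for (nm in vv_names) {
    v <- variables[[nm]]
    if (any(!is.na(v) & v <= 0)) {
      stop("ventricle volume must be strictly positive where observed (",
           subject_id, ")")
    }
  }
  structure(
    list(subject_id = subject_id, group = group, time = time,
         time_unit = time_unit, variables = variables),
    class = "subject_series"
  )
}

#' @export
print.subject_series <- function(x, ...) {
  cat("<subject_series> ", x$subject_id, " [", x$group, "]\n", sep = "")
  cat("  ", length(x$time), " time points (", x$time_unit, "), ",
      length(x$variables), " variables: ",
      paste(utils::head(names(x$variables), 6L), collapse = ", "),
      if (length(x$variables) > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Assemble subjects into a cohort
#'
#' @param subjects List of [subject_series()] objects with unique ids. Time
#'   units may differ across study arms (months for patients, days for mice)
#'   but are fixed within each subject.
#' @param ground_truth Optional list of generator ground truth (event days,
#'   couplings) carried alongside simulated cohorts.
#'
#' @return An object of class `vv_cohort`: a named list of subjects with the
#'   shared `time_unit` and any `ground_truth` stored as attributes.
#' @export
vv_cohort <- function(subjects, ground_truth = NULL) {
  stopifnot(is.list(subjects), length(subjects) >= 1L)
  ok <- vapply(subjects, inherits, TRUE, "subject_series")
  if (!all(ok)) stop("all elements must be subject_series objects")
  ids <- vapply(subjects, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) stop("duplicate subject ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  # units may differ across study arms (months for patients, days for mice)
  # but are fixed within a subject by construction
  units <- unique(vapply(subjects, `[[`, "", "time_unit"))
  names(subjects) <- ids
  structure(subjects, class = "vv_cohort", time_unit = units,
            ground_truth = ground_truth)
}

#' @export
print.vv_cohort <- function(x, ...) {
  groups <- table(vapply(x, `[[`, "", "group"))
  cat("<vv_cohort> ", length(x), " subjects (",
      paste(sprintf("%s: %d", names(groups), as.integer(groups)),
            collapse = ", "),
      "), time in ", paste(attr(x, "time_unit"), collapse = "/"),
      "\n", sep = "")
  if (!is.null(attr(x, "ground_truth"))) {
    cat("  carries generator ground truth\n")
  }
  invisible(x)
}

#' @export
`[.vv_cohort` <- function(x, i) {
  vv_cohort(unclass(x)[i], ground_truth = attr(x, "ground_truth"))
}

#' Flatten a cohort to a long-format table
#'
#' One row per (subject, time, variable) cell, including missing cells (value
#' `NA`), so the table round-trips losslessly through [read_cohort_csv()].
#'
#' @param cohort A [vv_cohort()].
#' @return A data.frame with columns
#'   `subject_id, group, time, time_unit, variable, value`.
#' @export
cohort_to_table <- function(cohort) {
  stopifnot(inherits(cohort, "vv_cohort"), length(cohort) >= 1L)
  pieces <- lapply(cohort, function(s) {
    nv <- length(s$variables)
    nt <- length(s$time)
    data.frame(
      subject_id = s$subject_id,
      group = s$group,
      time = rep(s$time, times = nv),
      time_unit = s$time_unit,
      variable = rep(names(s$variables), each = nt),
      value = unlist(s$variables, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Rebuild a cohort from a long-format table
#'
#' @param tab Data.frame with the schema written by [cohort_to_table()].
#' @return A [vv_cohort()].
#' @export
table_to_cohort <- function(tab) {
  need <- c("subject_id", "group", "time", "time_unit", "variable", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  key <- paste(tab$subject_id, tab$time, tab$variable, sep = "\r")
  if (anyDuplicated(key)) {
    d <- tab[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate cell: subject '%s', time %s, variable '%s'",
                 d$subject_id, format(d$time), d$variable))
  }
  sid <- factor(tab$subject_id, levels = unique(tab$subject_id))
  subjects <- lapply(split(tab, sid), function(st) {
    tm <- sort(unique(st$time))
    vnames <- factor(st$variable, levels = unique(st$variable))
    vars <- lapply(split(st, vnames), function(sv) {
      if (is.unsorted(sv$time)) {
        warning("time not sorted for subject '", sv$subject_id[1L],
                "', variable '", sv$variable[1L], "'; sorting",
                call. = FALSE)
      }
      v <- rep(NA_real_, length(tm))
      v[match(sv$time, tm)] <- sv$value
      v
    })
    subject_series(st$subject_id[1L], st$group[1L], tm, vars,
                   time_unit = st$time_unit[1L])
  })
  vv_cohort(unname(subjects))
}

#' Read / write a cohort as long-format CSV
#'
#' The on-disk schema is `subject_id,group,time,time_unit,variable,value`;
#' missing cells are empty `value` fields. `write_cohort_csv` also writes a
#' sidecar JSON (`<path>.truth.json`) when the cohort carries generator
#' ground truth.
#'
#' @param path CSV file path.
#' @param cohort A [vv_cohort()].
#' @return `read_cohort_csv` returns a [vv_cohort()]; `write_cohort_csv`
#'   returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort <- table_to_cohort(tab)
  truth_path <- paste0(path, ".truth.json")
  if (file.exists(truth_path)) {
    attr(cohort, "ground_truth") <- jsonlite::read_json(truth_path,
                                                        simplifyVector = TRUE)
  }
  cohort
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  tab <- cohort_to_table(cohort)
  # full double precision so the round trip is lossless
  tab$value <- ifelse(is.na(tab$value), "", sprintf("%.17g", tab$value))
  tab$time <- sprintf("%.17g", tab$time)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  gt <- attr(cohort, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(gt, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Extract one variable's series for one subject
#'
#' @param cohort A [vv_cohort()].
#' @param subject_id Subject identifier.
#' @param variable Variable name.
#' @return Numeric vector aligned to the subject's time grid.
#' @export
cohort_series <- function(cohort, subject_id, variable) {
  s <- cohort[[subject_id]]
  if (is.null(s)) stop("unknown subject: ", subject_id)
  v <- s$variables[[variable]]
  if (is.null(v)) stop("subject '", subject_id, "' has no variable '",
                       variable, "'")
  v
}
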