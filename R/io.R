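# Data ingestion and result serialization.

#' Standardise a long-format biomarker data frame
#'
#' Validates and standardises one-row-per-measurement data onto the columns
#' the rest of the package expects: `subject`, `group` (`"case"` /
#' `"control"`), `replicate` (positive integer), `value` (finite numeric).
#'
#' Hard errors: duplicated (subject, replicate) pairs (named in the error),
#' a subject appearing in both groups, and group labels other than
#' `case_label` / `control_label` (offenders listed).  Missing values are
#' dropped with a message under `na_policy = "drop"` (the default) or raise
#' an error under `"error"`.
#'
#' @param data A data frame.
#' @param subject,group,replicate,value Names of the corresponding columns
#'   in `data`.
#' @param case_label,control_label Values of the group column identifying
#'   cases and controls.
#' @param na_policy `"drop"` or `"error"`.
#' @return A tibble with the four standardised columns, sorted by group,
#'   subject, replicate.  The number of dropped rows is attached as
#'   attribute `n_dropped`.
#' @examples
#' as_biomarker(data.frame(id = c("a", "a", "b", "b"),
#'                         status = c("D", "D", "H", "H"),
#'                         visit = c(1, 2, 1, 2),
#'                         napap = c(3.1, 2.9, 1.2, 1.4)),
#'              subject = "id", group = "status", replicate = "visit",
#'              value = "napap", case_label = "D", control_label = "H")
#' @export
as_biomarker <- function(data, subject = "subject", group = "group",
                         replicate = "replicate", value = "value",
                         case_label = "case", control_label = "control",
                         na_policy = c("drop", "error")) {
  na_policy <- match.arg(na_policy)
  stopifnot(is.data.frame(data))
  cols <- c(subject = subject, group = group, replicate = replicate, value = value)
  missing_cols <- cols[!cols %in% names(data)]
  if (length(missing_cols)) {
    stop("column(s) not found in `data`: ",
         paste0("`", missing_cols, "`", collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    subject = as.character(data[[subject]]),
    group = as.character(data[[group]]),
    replicate = as.integer(data[[replicate]]),
    value = as.numeric(data[[value]])
  )

  bad_groups <- setdiff(unique(out$group), c(case_label, control_label))
  if (length(bad_groups)) {
    stop("unknown group label(s): ", paste(bad_groups, collapse = ", "),
         " (expected '", case_label, "' or '", control_label, "').",
         call. = FALSE)
  }
  out$group <- ifelse(out$group == case_label, "case", "control")

  n_na <- sum(is.na(out$value))
  if (n_na > 0) {
    if (na_policy == "error") {
      stop(n_na, " missing biomarker value(s); set na_policy = 'drop' to exclude them.",
           call. = FALSE)
    }
    message("dropped ", n_na, " row(s) with missing biomarker values.")
    out <- out[!is.na(out$value), , drop = FALSE]
  }
  .check_finite(out$value, "value")
  if (any(is.na(out$replicate)) || any(out$replicate < 1L)) {
    stop("`replicate` must be a positive integer for every row.", call. = FALSE)
  }

  dup <- duplicated(out[c("subject", "replicate")])
  if (any(dup)) {
    offender <- out[which(dup)[1], ]
    stop("duplicated (subject, replicate) pair: (", offender$subject, ", ",
         offender$replicate, ").", call. = FALSE)
  }
  two_groups <- tapply(out$group, out$subject, function(g) length(unique(g)))
  if (any(two_groups > 1L)) {
    stop("subject(s) present in both groups: ",
         paste(names(two_groups)[two_groups > 1L], collapse = ", "),
         call. = FALSE)
  }

  out <- out[order(out$group, out$subject, out$replicate), , drop = FALSE]
  attr(out, "n_dropped") <- n_na
  out
}

#' Read a biomarker dataset from a delimited text file
#'
#' Reads a CSV or TSV file (chosen from the extension, or forced with
#' `delim`) and standardises it with [as_biomarker()].
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter; `NULL` (default) picks `"\t"` for
#'   `.tsv`/`.txt` and `","` otherwise.
#' @inheritParams as_biomarker
#' @return A standardised biomarker tibble.
#' @export
read_biomarker_data <- function(path, subject = "subject", group = "group",
                                replicate = "replicate", value = "value",
                                case_label = "case", control_label = "control",
                                na_policy = c("drop", "error"), delim = NULL) {
  delim <- delim %||%
    (if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ",")
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  as_biomarker(raw, subject = subject, group = group, replicate = replicate,
               value = value, case_label = case_label,
               control_label = control_label, na_policy = na_policy)
}

#' Write a biomarker dataset to a delimited text file
#'
#' @param data A standardised biomarker tibble.
#' @param path Output path; `.tsv`/`.txt` write tab-separated, else CSV.
#' @return `data`, invisibly.
#' @export
write_biomarker_data <- function(data, path) {
  .check_biomarker(data)
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    readr::write_tsv(data, path, progress = FALSE)
  } else {
    readr::write_csv(data, path, progress = FALSE)
  }
  invisible(data)
}

#' Corrected-AUC report for a biomarker dataset
#'
#' Runs the requested estimators on one dataset and returns a tidy
#' one-row-per-method table: the uncorrected Mann-Whitney AUC, Reiser's
#' normal-theory correction, and the rank-based probit-shift correction
#' (plus Faraggi's known-`theta2` correction when `theta2` is supplied).
#' Replicates beyond the primary one feed only the reliability estimates.
#'
#' If the dataset has no replicated subjects in one of the groups, the
#' replicate-based corrections are skipped with a warning and only the
#' uncorrected row is returned.
#'
#' @param data A biomarker data frame (see [as_biomarker()]).
#' @param methods Subset of `c("mw", "reiser", "probit", "faraggi")`.
#' @param conf_level Two-sided confidence level, default 0.95.
#' @param theta2 Known error-to-signal variance ratio for the Faraggi row.
#' @param primary_replicate Replicate used for the observed AUC, default 1.
#' @param convention ECDF offset for the probit-scale ICCs.
#' @param variance Mann-Whitney variance estimator.
#' @return A tibble of class `auc_correction_tbl` with columns `method`,
#'   `estimate`, `conf_low`, `conf_high`, `auc_obs`, `inflation`, `theta2`,
#'   `icc_case`, `icc_control`, `n_cases`, `n_controls`, `clamped`.
#' @examples
#' dat <- simulate_biomarkers(sim_config(model = "II", m = 60, n = 60), seed = 5)
#' correct_auc(dat)
#' @export
correct_auc <- function(data, methods = c("mw", "reiser", "probit"),
                        conf_level = 0.95, theta2 = NULL,
                        primary_replicate = 1,
                        convention = c("vdw", "blom"),
                        variance = c("delong", "hanley")) {
  .check_biomarker(data)
  convention <- match.arg(convention)
  variance <- match.arg(variance)
  methods <- match.arg(methods, c("mw", "reiser", "probit", "faraggi"),
                       several.ok = TRUE)
  if ("faraggi" %in% methods && is.null(theta2)) {
    stop("the Faraggi correction needs a known `theta2`.", call. = FALSE)
  }

  obs <- estimate_auc(data, primary_replicate = primary_replicate,
                      conf_level = conf_level, variance = variance)
  has_reps <- function(g) {
    d <- data[data$group == g, , drop = FALSE]
    sum(table(d$subject) >= 2L) >= 2L
  }
  replicated <- has_reps("case") && has_reps("control")
  wants_reps <- intersect(methods, c("reiser", "probit"))
  if (length(wants_reps) && !replicated) {
    warning("no replicated measurements in one of the groups; ",
            "skipping: ", paste(wants_reps, collapse = ", "), call. = FALSE)
    methods <- setdiff(methods, wants_reps)
  }

  icc_x <- icc_y <- NULL
  if ("probit" %in% methods) {
    icc_x <- probit_icc(data, "case", convention = convention)
    icc_y <- probit_icc(data, "control", convention = convention)
  }

  row_for <- function(method) {
    switch(method,
      mw = tibble::tibble(
        method = "mann_whitney", estimate = obs$auc,
        conf_low = obs$ci_lower, conf_high = obs$ci_upper,
        auc_obs = obs$auc, inflation = 1, theta2 = NA_real_,
        icc_case = NA_real_, icc_control = NA_real_, clamped = FALSE),
      probit = {
        res <- probit_shift_ci(obs, icc_x, icc_y, conf_level = conf_level)
        tibble::tibble(
          method = "probit_shift", estimate = res$auc_corrected,
          conf_low = res$ci_lower, conf_high = res$ci_upper,
          auc_obs = res$auc_obs, inflation = res$inflation,
          theta2 = res$theta2, icc_case = icc_x$icc,
          icc_control = icc_y$icc, clamped = res$clamped)
      },
      reiser = {
        res <- reiser_correct(data, conf_level = conf_level,
                              primary_replicate = primary_replicate)
        tibble::tibble(
          method = "reiser", estimate = res$auc_corrected,
          conf_low = res$ci_lower, conf_high = res$ci_upper,
          auc_obs = res$auc_obs, inflation = res$inflation,
          theta2 = res$theta2, icc_case = NA_real_,
          icc_control = NA_real_, clamped = res$clamped)
      },
      faraggi = tibble::tibble(
        method = "faraggi", estimate = faraggi_correct(obs$auc, theta2),
        conf_low = NA_real_, conf_high = NA_real_,
        auc_obs = obs$auc, inflation = sqrt(1 + theta2), theta2 = theta2,
        icc_case = NA_real_, icc_control = NA_real_, clamped = FALSE)
    )
  }
  out <- dplyr::bind_rows(lapply(methods, row_for))
  out$n_cases <- obs$n_cases
  out$n_controls <- obs$n_controls
  class(out) <- c("auc_correction_tbl", class(out))
  attr(out, "conf_level") <- conf_level
  attr(out, "icc_case") <- icc_x
  attr(out, "icc_control") <- icc_y
  out
}

#' Write a result table to TSV or JSON
#'
#' Serialises a [correct_auc()] or [run_sim_study()] table.  Output is
#' deterministic (byte-stable) for fixed inputs.
#'
#' @param report A data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"` (default from the file extension).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, path, format = NULL) {
  stopifnot(is.data.frame(report))
  format <- format %||%
    (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv")
  format <- match.arg(format, c("tsv", "json"))
  plain <- as.data.frame(report)
  if (format == "json") {
    jsonlite::write_json(plain, path, digits = NA, pretty = TRUE)
  } else {
    readr::write_tsv(tibble::as_tibble(plain), path, progress = FALSE)
  }
  invisible(report)
}
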