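# shared validation helpers and small numeric utilities

.z_two_sided <- function(conf_level) {
  stopifnot(is.numeric(conf_level), length(conf_level) == 1L,
            conf_level > 0, conf_level < 1)
  stats::qnorm(1 - (1 - conf_level) / 2)
}

.check_finite <- function(x, what) {
  if (!is.numeric(x)) {
    stop("`", what, "` must be numeric.", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("`", what, "` contains missing or non-finite values.", call. = FALSE)
  }
  invisible(x)
}

.check_prob_open <- function(x, what) {
  .check_finite(x, what)
  if (any(x <= 0 | x >= 1)) {
    stop("`", what, "` must lie strictly inside (0, 1).", call. = FALSE)
  }
  invisible(x)
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# standardise user column names onto subject/group/replicate/value
.required_cols <- c("subject", "group", "replicate", "value")

.check_biomarker <- function(data, call_from = "this function") {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame (see `as_biomarker()`).", call. = FALSE)
  }
  missing_cols <- setdiff(.required_cols, names(data))
  if (length(missing_cols)) {
    stop("`data` is missing column(s) ", paste0("`", missing_cols, "`", collapse = ", "),
         "; use `as_biomarker()` to standardise it first.", call. = FALSE)
  }
  bad <- setdiff(unique(as.character(data$group)), c("case", "control"))
  if (length(bad)) {
    stop("`data$group` must be 'case'/'control'; found: ",
         paste(bad, collapse = ", "), ". Use `as_biomarker()` to relabel.",
         call. = FALSE)
  }
  invisible(data)
}
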