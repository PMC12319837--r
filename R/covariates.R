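HORMONE_COLUMNS <- c("estradiol", "progesterone", "testosterone", "cortisol")

#' Session-keyed covariate table
#'
#' Validates a table of session-level covariates: hormone concentrations
#' (estradiol pg/mL, progesterone ng/mL, testosterone ng/dL or pg/mL,
#' cortisol ug/dL) and the Perceived Stress Scale total (`pss_score`,
#' integer 0--40).  One row per `(subject_id, session_id)`; unknown columns
#' are preserved as generic covariates.
#'
#' @param df A data.frame with `subject_id`, `session_id` and covariate
#'   columns.
#' @return The validated table with class `covariate_table`.
#' @export
covariate_table <- function(df) {
  df <- as.data.frame(df)
  for (k in c("subject_id", "session_id")) {
    if (!k %in% names(df)) stop_axisflux("covariate table missing column '%s'", k)
    df[[k]] <- as.character(df[[k]])
  }
  key <- paste(df$subject_id, df$session_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop_axisflux("duplicate session key (%s, %s)", d$subject_id, d$session_id)
  }
  if ("pss_score" %in% names(df)) {
    s <- df$pss_score
    if (any(!is.na(s) & (s < 0 | s > 40 | s != round(s)))) {
      stop_axisflux("pss_score must be an integer in [0, 40]")
    }
    df$pss_score <- as.integer(s)
  }
  for (h in intersect(HORMONE_COLUMNS, names(df))) {
    if (any(!is.na(df[[h]]) & df[[h]] < 0)) {
      stop_axisflux("hormone column '%s' must be non-negative", h)
    }
  }
  class(df) <- c("covariate_table", "data.frame")
  df
}

#' @export
print.covariate_table <- function(x, ...) {
  covs <- setdiff(names(x), c("subject_id", "session_id"))
  cat(sprintf("covariate_table: %d sessions, covariates: %s\n",
              nrow(x), paste(covs, collapse = ", ")))
  invisible(x)
}

#' Read / write covariate tables (CSV)
#'
#' @param path File path.
#' @return `read_covariates()` returns a validated [covariate_table()].
#' @export
read_covariates <- function(path) {
  covariate_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @param cov A [covariate_table()].
#' @rdname read_covariates
#' @export
write_covariates <- function(cov, path) {
  df <- as.data.frame(cov)
  for (k in names(df)) {
    if (is.double(df[[k]])) df[[k]] <- sprintf("%.17g", df[[k]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
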