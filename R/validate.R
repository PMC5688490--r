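#' @keywords internal
"_PACKAGE"

# Typed conditions: validation errors carry the offending table/row so callers
# (and the CLI) can report exactly which input line is malformed.

ck_validation_error <- function(msg, table = NULL, row = NULL) {
  if (!is.null(table)) {
    where <- if (is.null(row)) table else sprintf("%s, row %s", table, row)
    msg <- sprintf("%s [%s]", msg, where)
  }
  stop(errorCondition(msg, table = table, row = row,
                      class = c("costkit_validation_error", "costkit_error",
                                "error", "condition")))
}

ck_domain_error <- function(msg) {
  stop(errorCondition(msg, class = c("costkit_domain_error", "costkit_error",
                                     "error", "condition")))
}

check_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    ck_validation_error(sprintf("missing column(s): %s",
                                paste(missing, collapse = ", ")), table)
  }
  invisible(df)
}

check_nonneg <- function(df, cols, table) {
  for (col in cols) {
    x <- df[[col]]
    bad <- which(!is.finite(x) | x < 0)
    if (length(bad) > 0L) {
      ck_validation_error(sprintf("column '%s' must be finite and >= 0 (got %s)",
                                  col, x[bad[1L]]), table, bad[1L])
    }
  }
  invisible(df)
}

check_fraction <- function(df, cols, table) {
  for (col in cols) {
    x <- df[[col]]
    bad <- which(!is.finite(x) | x < 0 | x > 1)
    if (length(bad) > 0L) {
      ck_validation_error(sprintf("column '%s' must lie in [0, 1] (got %s)",
                                  col, x[bad[1L]]), table, bad[1L])
    }
  }
  invisible(df)
}
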