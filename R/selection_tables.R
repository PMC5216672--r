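# Raven-dialect selection tables: tab-separated, columns "Begin Time (s)",
# "End Time (s)", "Low Freq (Hz)", "High Freq (Hz)", plus free extra columns.

.raven_cols <- c(begin = "Begin Time (s)", end = "End Time (s)",
                 low_freq = "Low Freq (Hz)", high_freq = "High Freq (Hz)")

#' Read a call-selection table
#'
#' Parses a tab-separated selection table in the Raven dialect. The four
#' standard columns are renamed to `begin`, `end`, `low_freq`, `high_freq`;
#' extra columns (e.g. annotator flags, frog ids) are kept verbatim. An
#' `overlapped` column, if present, is coerced to logical.
#'
#' @param path File path.
#' @return `data.frame` of annotations.
#' @export
read_selection_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  for (nm in names(.raven_cols)) {
    hit <- match(.raven_cols[[nm]], names(df))
    if (is.na(hit)) stop("selection table missing column: ", .raven_cols[[nm]])
    names(df)[hit] <- nm
  }
  if (!is.null(df$overlapped)) df$overlapped <- as.logical(df$overlapped)
  if (any(df$end <= df$begin)) stop("selections must satisfy end > begin")
  df
}

#' Write a call-selection table
#'
#' @param annotations `data.frame` with columns `begin`, `end`, `low_freq`,
#'   `high_freq` (extra columns preserved).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_selection_table <- function(annotations, path) {
  df <- annotations
  for (nm in rev(names(.raven_cols))) {
    hit <- match(nm, names(df))
    if (!is.na(hit)) names(df)[hit] <- .raven_cols[[nm]]
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
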