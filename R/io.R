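#' Column dictionary for subject tables
#'
#' Known columns and their expected types for cohort/score tables. `id` is
#' the mandatory key; unknown columns are preserved but flagged.
#' @return Named character vector (column -> type).
#' @export
subject_table_dictionary <- function() {
  c(id = "character", age = "numeric", sex = "numeric",
    nonverbal_iq = "numeric", group = "character",
    latent_ability = "numeric",
    phono_awareness = "numeric", sentence_recall = "numeric",
    rapid_naming_log = "numeric", reading_comp = "numeric",
    peak_latency_21 = "numeric", peak_latency_31 = "numeric",
    peak_latency_41 = "numeric", peak_latency_51 = "numeric",
    h4 = "numeric", h5 = "numeric", h6 = "numeric", h7 = "numeric",
    f1_mean_amplitude = "numeric", stability_r = "numeric",
    stability_z = "numeric", score = "numeric",
    actual = "numeric", predicted = "numeric")
}

#' Read a subject table from CSV or XLSX
#'
#' Reads a tabular cohort/score file, validates columns against
#' [subject_table_dictionary()], coerces known numeric columns, and reports
#' (rather than fails on) malformed numeric cells row by row. Multi-sheet
#' XLSX workbooks (one sheet per figure) are supported via `sheet`.
#'
#' @param path File path (.csv, or .xlsx when the readxl package is
#'   installed).
#' @param layout `"auto"` (by extension), `"csv"`, or `"xlsx"`.
#' @param sheet Sheet name or index for XLSX input.
#' @param require_id If TRUE (default), fail when the mandatory `id` key
#'   column is absent.
#' @return A tibble with attributes `unknown_columns` (names not in the
#'   dictionary) and `row_errors` (list of row index + column for malformed
#'   numeric cells; those cells become NA).
#' @export
read_subject_table <- function(path, layout = c("auto", "csv", "xlsx"),
                               sheet = 1, require_id = TRUE) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (layout == "auto")
    layout <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  if (layout == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading xlsx requires the readxl package")
    tbl <- readxl::read_excel(path, sheet = sheet)
  } else {
    tbl <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  }
  tbl <- tibble::as_tibble(tbl)
  dict <- subject_table_dictionary()
  if (require_id && !"id" %in% names(tbl))
    stop("mandatory key column missing: id")
  unknown <- setdiff(names(tbl), names(dict))
  row_errors <- list()
  for (cn in intersect(names(tbl), names(dict))) {
    if (dict[[cn]] == "numeric" && !is.numeric(tbl[[cn]])) {
      raw <- as.character(tbl[[cn]])
      num <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(num) & !is.na(raw) & nzchar(raw))
      if (length(bad))
        row_errors[[cn]] <- bad
      tbl[[cn]] <- num
    }
  }
  attr(tbl, "unknown_columns") <- unknown
  attr(tbl, "row_errors") <- row_errors
  tbl
}

#' Write a subject table to CSV
#' @param tbl Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' Write a waveform to CSV (time in ms, amplitude)
#' @param w A [waveform()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  utils::write.csv(
    data.frame(time_ms = time_axis(w), amplitude = w$samples),
    path, row.names = FALSE)
  invisible(path)
}
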