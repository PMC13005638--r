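# Reading and writing the four-file CSV layout. Files are UTF-8 with ISO-8601
# dates; readers are strict about headers and report row-level problems
# (unparseable dates, negative costs) with line numbers.

bundle_files <- c(patients = "patients.csv", dispensings = "dispensings.csv",
                  diagnoses = "diagnoses.csv", encounters = "encounters.csv")

readr_type <- c(character = "c", integer = "i", numeric = "d",
                logical = "l", Date = "D")

#' Read a claims bundle from a directory
#'
#' Expects `patients.csv`, `dispensings.csv`, `diagnoses.csv` and
#' `encounters.csv` with exactly the documented headers. A missing file or an
#' unknown/missing column is fatal; unparseable dates and negative costs are
#' collected into a row-level report (with line numbers) attached to the
#' error condition.
#'
#' @param path Directory containing the four CSV files.
#' @return A validated [claims_bundle()].
#' @export
read_bundle <- function(path) {
  if (!dir.exists(path)) abort(sprintf("directory '%s' does not exist", path))
  missing <- bundle_files[!file.exists(file.path(path, bundle_files))]
  if (length(missing)) {
    abort(sprintf("missing claims file(s): %s", paste(missing, collapse = ", ")))
  }
  issues <- list()
  tables <- purrr::imap(bundle_files, function(file, name) {
    schema <- bundle_schemas[[name]]
    fpath <- file.path(path, file)
    header <- names(readr::read_csv(fpath, n_max = 0, col_types = readr::cols(),
                                    show_col_types = FALSE, progress = FALSE))
    if (!identical(sort(header), sort(names(schema)))) {
      unknown <- setdiff(header, names(schema))
      absent <- setdiff(names(schema), header)
      abort(sprintf(
        "file '%s': unexpected header (unknown: %s; missing: %s)", file,
        paste(unknown, collapse = ", "), paste(absent, collapse = ", ")))
    }
    spec <- paste(readr_type[schema[header]], collapse = "")
    # parsing issues are collected into the row-level report below, so the
    # reader's own "call problems()" warning is redundant here
    tbl <- suppressWarnings(
      readr::read_csv(fpath, col_types = spec, show_col_types = FALSE,
                      progress = FALSE, locale = readr::locale(tz = "UTC")))
    probs <- readr::problems(tbl)
    if (nrow(probs)) {
      issues[[name]] <<- tibble::tibble(
        table = name, row = probs$row - 1L, # file rows include the header
        rule = "parse",
        message = sprintf("expected %s, got '%s'", probs$expected, probs$actual))
    }
    tbl[names(schema)]
  })
  if ("cost" %in% names(tables$dispensings)) {
    bad <- which(!is.na(tables$dispensings$cost) & tables$dispensings$cost < 0)
    if (length(bad)) {
      issues$cost <- tibble::tibble(
        table = "dispensings", row = bad, rule = "cost_nonnegative",
        message = sprintf("negative cost %s in row %d",
                          tables$dispensings$cost[bad], bad))
    }
  }
  if (length(issues)) {
    report <- dplyr::bind_rows(issues)
    abort(c("row-level errors while reading claims bundle",
            sprintf("%s row %d: %s", report$table, report$row, report$message)),
          report = report)
  }
  claims_bundle(tables$patients, tables$dispensings, tables$diagnoses,
                tables$encounters)
}

#' Write a claims bundle to a directory
#'
#' Refuses to write a bundle that fails [validate_bundle()] (including
#' referential-integrity violations). `read_bundle(write_bundle(b))`
#' reproduces `b` field for field.
#'
#' @param bundle A `claims_bundle`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  report <- validate_bundle(bundle)
  if (nrow(report)) {
    abort(c("refusing to write an invalid claims bundle",
            sprintf("%s row %d: %s", report$table, report$row,
                    report$message)[seq_len(min(10, nrow(report)))]),
          report = report)
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) abort(sprintf("cannot create directory '%s'", path))
  purrr::iwalk(bundle_files, function(file, name) {
    readr::write_csv(bundle[[name]], file.path(path, file), na = "",
                     progress = FALSE)
  })
  invisible(path)
}
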