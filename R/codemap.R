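# Optional mapping of external code systems onto the internal semantic
# vocabulary. Real claims carry local diagnosis and drug codes; the pipeline
# logic runs on semantic labels, so external codes are translated before a
# bundle is assembled.

#' Read a code-mapping file
#'
#' The YAML file has one top-level key per target column family
#' (`drug_codes`, `diagnosis_codes`), each mapping external codes to values
#' of the internal vocabulary, e.g.
#'
#' ```yaml
#' diagnosis_codes:
#'   "J45": asthma
#'   "C34": lung_malignancy
#' drug_codes:
#'   "621984801": mepolizumab
#' ```
#'
#' @param path Path to the YAML file.
#' @return A named list of named character vectors, validated against the
#'   internal vocabularies.
#' @export
read_codemap <- function(path) {
  if (!file.exists(path)) abort(sprintf("codemap '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  known <- list(drug_codes = drug_codes, diagnosis_codes = diagnosis_codes)
  bad_keys <- setdiff(names(raw), names(known))
  if (length(bad_keys)) {
    abort(sprintf("unknown codemap section(s): %s",
                  paste(bad_keys, collapse = ", ")))
  }
  purrr::imap(raw, function(map, section) {
    map <- unlist(map)
    bad <- setdiff(unname(map), known[[section]])
    if (length(bad)) {
      abort(sprintf("codemap section '%s' maps to unknown label(s): %s",
                    section, paste(unique(bad), collapse = ", ")))
    }
    map
  })
}

#' Translate external codes to the internal vocabulary
#'
#' @param x Character vector of external codes.
#' @param codemap Output of [read_codemap()].
#' @param section `"drug_codes"` or `"diagnosis_codes"`.
#' @param unmapped Value for codes absent from the map (default `"other"`).
#' @return A character vector of internal labels.
#' @export
apply_codemap <- function(x, codemap, section = c("drug_codes",
                                                  "diagnosis_codes"),
                          unmapped = "other") {
  section <- match.arg(section)
  map <- codemap[[section]]
  if (is.null(map)) abort(sprintf("codemap has no '%s' section", section))
  out <- unname(map[x])
  out[is.na(out)] <- unmapped
  out
}
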