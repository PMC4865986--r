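#' Controlled vocabularies for drug product attributes
#'
#' Closed token sets used to validate product dictionaries and measure
#' specifications. Each vocabulary carries an `other` escape token so that
#' products outside the enumerated values can still be represented.
#'
#' @format A named list of character vectors with elements `route`,
#'   `dosage_form`, `rx_status`, `drug_type` and `common_use`.
#' @export
drug_vocab <- list(
  route = c("oral", "inhalation", "topical", "transdermal", "ophthalmic",
            "subcutaneous", "sublingual", "rectal", "other"),
  dosage_form = c("tablet", "capsule", "cream", "solution", "suspension",
                  "patch", "aerosol", "other"),
  rx_status = c("prescription", "otc"),
  drug_type = c("standard", "vitamin", "herbal", "supplement", "other_cam"),
  common_use = c("regular", "as_needed")
)

# internal: assert all values belong to a vocabulary, with row context
check_vocab <- function(values, field, where = NULL) {
  bad <- !values %in% drug_vocab[[field]]
  if (any(bad)) {
    rows <- if (is.null(where)) which(bad) else where[bad]
    stop(sprintf(
      "invalid %s token(s) %s (row %s); allowed: %s",
      field,
      paste(sQuote(unique(values[bad])), collapse = ", "),
      paste(rows, collapse = ", "),
      paste(drug_vocab[[field]], collapse = ", ")
    ), call. = FALSE)
  }
  invisible(values)
}

as_iso_date <- function(x, what = "date") {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d) && !all(is.na(x))) {
    bad <- which(is.na(d) & !is.na(x) & nzchar(as.character(x)))
    if (length(bad)) {
      stop(sprintf("unparseable %s %s (expected YYYY-MM-DD)", what,
                   paste(sQuote(as.character(x)[bad][seq_len(min(3, length(bad)))]),
                         collapse = ", ")), call. = FALSE)
    }
  }
  d
}
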