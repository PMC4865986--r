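#' Read a drug product dictionary
#'
#' The dictionary maps each dispensable product to the attributes the scope
#' and uniqueness components act on. Expected CSV header:
#' `product_id,ingredients,route,dosage_form,strength,rx_status,drug_type,common_use,is_supply,is_mdi`.
#' Multiple ingredients within a cell are separated by `|` (a combination
#' product has two or more).
#'
#' @param path CSV file path.
#' @return A `drug_dictionary`: a data.frame with one row per product and an
#'   `ingredients` list-column.
#' @export
read_dictionary <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("product_id", "ingredients", "route", "dosage_form", "strength",
                "rx_status", "drug_type", "common_use", "is_supply", "is_mdi")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("dictionary schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  as_dictionary(data.frame(
    product_id = raw$product_id,
    ingredients = I(strsplit(raw$ingredients, "|", fixed = TRUE)),
    route = raw$route,
    dosage_form = raw$dosage_form,
    strength = raw$strength,
    rx_status = raw$rx_status,
    drug_type = raw$drug_type,
    common_use = raw$common_use,
    is_supply = parse_bool(raw$is_supply, "is_supply"),
    is_metered_dose_inhaler = parse_bool(raw$is_mdi, "is_mdi"),
    stringsAsFactors = FALSE
  ))
}

#' Construct / validate a drug dictionary from a data.frame
#'
#' @param df data.frame with columns `product_id`, `ingredients` (list-column
#'   of character vectors), `route`, `dosage_form`, `strength`, `rx_status`,
#'   `drug_type`, `common_use`, `is_supply`, `is_metered_dose_inhaler`.
#' @return The validated data.frame with class `drug_dictionary`.
#' @export
as_dictionary <- function(df) {
  rows <- seq_len(nrow(df))
  if (anyDuplicated(df$product_id))
    stop("duplicate product_id in dictionary: ",
         paste(unique(df$product_id[duplicated(df$product_id)]), collapse = ", "),
         call. = FALSE)
  n_ing <- vapply(df$ingredients, function(v) sum(nzchar(trimws(v))), 0L)
  if (any(n_ing < 1))
    stop("dictionary validation error: empty ingredients (row ",
         paste(rows[n_ing < 1], collapse = ", "), ")", call. = FALSE)
  df$ingredients <- I(lapply(df$ingredients, function(v) trimws(v[nzchar(trimws(v))])))
  check_vocab(df$route, "route", rows)
  check_vocab(df$dosage_form, "dosage_form", rows)
  check_vocab(df$rx_status, "rx_status", rows)
  check_vocab(df$drug_type, "drug_type", rows)
  check_vocab(df$common_use, "common_use", rows)
  stopifnot(is.logical(df$is_supply), is.logical(df$is_metered_dose_inhaler))
  class(df) <- c("drug_dictionary", "data.frame")
  df
}

parse_bool <- function(x, field) {
  v <- tolower(trimws(x))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "")] <- FALSE
  if (anyNA(out))
    stop(sprintf("invalid boolean in %s (row %s)", field,
                 paste(which(is.na(out)), collapse = ", ")), call. = FALSE)
  out
}

#' Write a drug dictionary to CSV
#' @param dictionary a `drug_dictionary`.
#' @param path output CSV path.
#' @export
write_dictionary <- function(dictionary, path) {
  out <- data.frame(
    product_id = dictionary$product_id,
    ingredients = vapply(dictionary$ingredients, paste, "", collapse = "|"),
    route = dictionary$route,
    dosage_form = dictionary$dosage_form,
    strength = dictionary$strength,
    rx_status = dictionary$rx_status,
    drug_type = dictionary$drug_type,
    common_use = dictionary$common_use,
    is_supply = tolower(dictionary$is_supply),
    is_mdi = tolower(dictionary$is_metered_dose_inhaler),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and preprocess pharmacy fill records
#'
#' Expected CSV header: `patient_id,product_id,fill_date,days_supply,quantity`.
#' Rows are screened the way refill-claims preprocessing screens prescription
#' drug events: fills of products flagged as medical supplies, fills whose
#' product is not in the dictionary, and fills with days-supply values of 0 or
#' 999 (sentinel codes in claims data) are rejected, not fatal. Unparseable
#' dates and non-numeric days-supply values are likewise collected in the
#' rejection report.
#'
#' @param path CSV file path.
#' @param dictionary a `drug_dictionary` used to resolve products.
#' @return A list with `fills` (retained rows, `fill_date` as `Date`) and
#'   `report` (named integer rejection counts by reason).
#' @export
read_fills <- function(path, dictionary) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("patient_id", "product_id", "fill_date", "days_supply", "quantity")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("fills schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  report <- c(unparseable_date = 0L, unmatched_product = 0L, is_supply = 0L,
              days_supply_0 = 0L, days_supply_999 = 0L,
              invalid_days_supply = 0L)
  if (nrow(raw) == 0) {
    return(list(fills = empty_fills(), report = report))
  }
  dates <- as.Date(raw$fill_date, format = "%Y-%m-%d")
  ds <- suppressWarnings(as.numeric(raw$days_supply))
  qty <- suppressWarnings(as.numeric(raw$quantity))
  midx <- match(raw$product_id, dictionary$product_id)

  reason <- rep(NA_character_, nrow(raw))
  flag <- function(cond, why) reason[is.na(reason) & cond] <<- why
  flag(is.na(dates), "unparseable_date")
  flag(is.na(midx), "unmatched_product")
  flag(!is.na(midx) & dictionary$is_supply[midx], "is_supply")
  flag(!is.na(ds) & ds == 0, "days_supply_0")
  flag(!is.na(ds) & ds == 999, "days_supply_999")
  flag(is.na(ds) | ds < 0 | ds != round(ds), "invalid_days_supply")

  tab <- table(reason)
  report[names(tab)] <- as.integer(tab)
  keep <- is.na(reason)
  fills <- data.frame(patient_id = raw$patient_id[keep],
                      product_id = raw$product_id[keep],
                      fill_date = dates[keep],
                      days_supply = as.integer(ds[keep]),
                      quantity = qty[keep],
                      stringsAsFactors = FALSE)
  list(fills = fills, report = report)
}

empty_fills <- function() {
  data.frame(patient_id = character(), product_id = character(),
             fill_date = as.Date(character()), days_supply = integer(),
             quantity = numeric(), stringsAsFactors = FALSE)
}

#' Write fill records to CSV
#' @param fills data.frame of fill records.
#' @param path output CSV path.
#' @export
write_fills <- function(fills, path) {
  out <- fills
  out$fill_date <- format(out$fill_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read hospitalization episodes
#'
#' Expected CSV header: `patient_id,admit_date,discharge_date`.
#' @param path CSV file path.
#' @return data.frame with `Date` columns; errors if a discharge precedes its
#'   admission.
#' @export
read_hospitalizations <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("patient_id", "admit_date", "discharge_date")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("hospitalizations schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- data.frame(patient_id = raw$patient_id,
                    admit_date = as_iso_date(raw$admit_date, "admit_date"),
                    discharge_date = as_iso_date(raw$discharge_date,
                                                 "discharge_date"),
                    stringsAsFactors = FALSE)
  bad <- which(out$admit_date > out$discharge_date)
  if (length(bad))
    stop("hospitalization with discharge before admission (row ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  out
}

#' Write hospitalization episodes to CSV
#' @param hospitalizations data.frame of episodes.
#' @param path output CSV path.
#' @export
write_hospitalizations <- function(hospitalizations, path) {
  out <- hospitalizations
  out$admit_date <- format(out$admit_date, "%Y-%m-%d")
  out$discharge_date <- format(out$discharge_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read index events
#'
#' Expected CSV header: `patient_id,index_date`. One index event per patient.
#' @param path CSV file path.
#' @return data.frame with a `Date` index column.
#' @export
read_index_events <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("patient_id", "index_date")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("index schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  data.frame(patient_id = raw$patient_id,
             index_date = as_iso_date(raw$index_date, "index_date"),
             stringsAsFactors = FALSE)
}

#' Write index events to CSV
#' @param index_events data.frame of index events.
#' @param path output CSV path.
#' @export
write_index_events <- function(index_events, path) {
  out <- index_events
  out$index_date <- format(out$index_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble per-patient histories
#'
#' Joins preprocessed fills, hospitalizations and index events into one
#' `patient_history` per patient with an index event. Patients with an index
#' event but no fills are retained (their count is 0). Fills are sorted by
#' date, then product id, so the result is invariant to input row order.
#'
#' @param fills data.frame of retained fill records.
#' @param hospitalizations data.frame of episodes (may be `NULL` or empty).
#' @param index_events data.frame with one row per patient.
#' @return Named list of `patient_history` objects, keyed by patient id.
#' @export
assemble_histories <- function(fills, hospitalizations = NULL, index_events) {
  if (anyDuplicated(index_events$patient_id))
    stop("duplicate index events for patient(s): ",
         paste(unique(index_events$patient_id[
           duplicated(index_events$patient_id)]), collapse = ", "),
         call. = FALSE)
  ids <- sort(index_events$patient_id)
  out <- lapply(ids, function(pid) {
    f <- fills[fills$patient_id == pid, , drop = FALSE]
    f <- f[order(f$fill_date, f$product_id), , drop = FALSE]
    rownames(f) <- NULL
    h <- if (is.null(hospitalizations)) {
      data.frame(patient_id = character(), admit_date = as.Date(character()),
                 discharge_date = as.Date(character()))
    } else {
      hh <- hospitalizations[hospitalizations$patient_id == pid, , drop = FALSE]
      hh <- hh[order(hh$admit_date, hh$discharge_date), , drop = FALSE]
      rownames(hh) <- NULL
      hh
    }
    structure(list(patient_id = pid, fills = f, hospitalizations = h,
                   index_date = index_events$index_date[
                     index_events$patient_id == pid]),
              class = "patient_history")
  })
  names(out) <- ids
  out
}

#' @export
print.patient_history <- function(x, ...) {
  cat("<patient_history>", x$patient_id, "| index", format(x$index_date),
      "|", nrow(x$fills), "fill(s),", nrow(x$hospitalizations),
      "hospitalization(s)\n")
  invisible(x)
}
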