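# Independent oracles and small builders shared across tests.

# Day-by-day supply simulation: walk the calendar from the first windowed fill
# to the anchor, adding each day's dispensed supply and consuming one day of
# supply per day (floored at zero). Returns the days on hand at the anchor.
oracle_cabinet <- function(fills, anchor_date, lookback_days) {
  keep <- fills$fill_date >= anchor_date - lookback_days &
    fills$fill_date < anchor_date
  fills <- fills[keep, , drop = FALSE]
  if (nrow(fills) == 0) return(0)
  supply <- 0
  for (d in seq(min(fills$fill_date), anchor_date - 1, by = "day")) {
    supply <- supply + sum(fills$days_supply[as.numeric(fills$fill_date) == d])
    supply <- max(0, supply - 1)
  }
  supply
}

# Brute-force enumeration of inpatient days strictly inside (anchor, index).
oracle_inpatient <- function(hosp, anchor_date, index_date,
                             convention = "admit_only") {
  if (index_date - anchor_date < 2) return(0L)
  days <- seq(anchor_date + 1, index_date - 1, by = "day")
  inpatient <- vapply(days, function(d) {
    any(hosp$admit_date <= d &
          (if (convention == "admit_only") d < hosp$discharge_date
           else d <= hosp$discharge_date))
  }, TRUE)
  sum(inpatient)
}

# Minimal single-product dictionary for engine unit tests.
tiny_dictionary <- function(products = list(
  list(product_id = "A", ingredients = "drug a", route = "oral",
       dosage_form = "tablet", strength = "10 mg", rx_status = "prescription",
       drug_type = "standard", common_use = "regular", is_supply = FALSE,
       is_metered_dose_inhaler = FALSE))) {
  as_dictionary(data.frame(
    product_id = vapply(products, `[[`, "", "product_id"),
    ingredients = I(lapply(products, `[[`, "ingredients")),
    route = vapply(products, `[[`, "", "route"),
    dosage_form = vapply(products, `[[`, "", "dosage_form"),
    strength = vapply(products, `[[`, "", "strength"),
    rx_status = vapply(products, `[[`, "", "rx_status"),
    drug_type = vapply(products, `[[`, "", "drug_type"),
    common_use = vapply(products, `[[`, "", "common_use"),
    is_supply = vapply(products, `[[`, TRUE, "is_supply"),
    is_metered_dose_inhaler = vapply(products, `[[`, TRUE,
                                     "is_metered_dose_inhaler"),
    stringsAsFactors = FALSE
  ))
}

# Build a patient_history from bare fill tuples.
make_history <- function(fill_tuples, index_date, hosp = NULL,
                         patient_id = "pt1") {
  fills <- if (length(fill_tuples)) {
    do.call(rbind, lapply(fill_tuples, function(t)
      data.frame(patient_id = patient_id, product_id = t[[1]],
                 fill_date = as.Date(t[[2]]),
                 days_supply = as.integer(t[[3]]),
                 quantity = as.numeric(t[[3]]), stringsAsFactors = FALSE)))
  } else {
    data.frame(patient_id = character(), product_id = character(),
               fill_date = as.Date(character()), days_supply = integer(),
               quantity = numeric(), stringsAsFactors = FALSE)
  }
  idx <- data.frame(patient_id = patient_id,
                    index_date = as.Date(index_date),
                    stringsAsFactors = FALSE)
  if (!is.null(hosp)) hosp$patient_id <- patient_id
  assemble_histories(fills, hosp, idx)[[patient_id]]
}

# Random same-drug fill sets for cabinet-supply property testing.
random_fill_set <- function() {
  n <- sample(0:6, 1)
  anchor <- as.Date("2008-07-01")
  fills <- data.frame(
    fill_date = anchor - sample(1:220, max(n, 1), replace = TRUE),
    days_supply = sample(c(5, 9, 14, 28, 30, 90), max(n, 1), replace = TRUE)
  )[seq_len(n), , drop = FALSE]
  list(fills = fills, anchor = anchor,
       lookback = sample(c(30, 90, 180), 1))
}

expected_fixture_counts <- c(
  default = 3L, v1 = 3L, v2 = 2L, v3 = 3L, v4 = 3L, v5 = 4L, v6 = 4L,
  v7 = 3L, v8 = 4L, v9 = 4L, v10 = 3L, v11 = 3L, v12 = 3L, v13 = 4L,
  v14 = 3L
)
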