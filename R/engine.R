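#' Is a product within a measure's scope?
#'
#' A product qualifies when every scope subcomponent filter passes:
#' prescription status, drug type, route (inclusion or exclusion set),
#' dosage form, and common use.
#'
#' @param product a one-row `drug_dictionary` slice or an equivalent list.
#' @param scope a [scope_spec()].
#' @return `TRUE` or `FALSE`.
#' @export
in_scope <- function(product, scope) {
  ok <- product$rx_status %in% scope$rx_statuses &
    product$drug_type %in% scope$drug_types &
    product$common_use %in% scope$common_uses
  if (!identical(scope$routes_include, "all"))
    ok <- ok & product$route %in% scope$routes_include
  if (length(scope$routes_exclude))
    ok <- ok & !product$route %in% scope$routes_exclude
  if (!identical(scope$dosage_forms, "all"))
    ok <- ok & product$dosage_form %in% scope$dosage_forms
  unname(ok)
}

#' Drug keys for a product under a uniqueness setting
#'
#' Product basis yields one key per product: the sorted, lower-cased
#' ingredient list (joined with `/`) plus route / form / strength detail as
#' the level demands. Ingredient basis yields one key per ingredient, each
#' carrying the same level detail — so a combination product contributes at
#' least two keys.
#'
#' @param product a one-row `drug_dictionary` slice or an equivalent list.
#' @param uniq a [uniqueness_spec()].
#' @return Character vector of canonical key strings.
#' @examples
#' p <- list(ingredients = list(c("Ezetimibe", "Simvastatin")), route = "oral",
#'           dosage_form = "tablet", strength = "10/10 mg")
#' drug_keys(p, uniqueness_spec("ingredient", "ingredient"))
#' @export
drug_keys <- function(product, uniq) {
  ings <- product$ingredients
  if (is.list(ings)) ings <- ings[[1]]
  ings <- sort(tolower(ings))
  extras <- switch(uniq$level,
    ingredient = character(),
    ingredient_route = product$route,
    ingredient_route_form = c(product$route, product$dosage_form),
    ingredient_route_form_strength = c(product$route, product$dosage_form,
                                       tolower(trimws(product$strength))))
  heads <- if (uniq$basis == "product") paste(ings, collapse = "/") else ings
  unique(vapply(heads, function(h) paste(c(h, extras), collapse = "|"), "",
                USE.NAMES = FALSE))
}

#' Observed index gap
#'
#' Days between the last fill prior to the index date and the index date.
#' A fill on the index date is not "prior", so the anchor must predate the
#' index strictly.
#'
#' @param anchor_fill a fill record (anything with `fill_date`) or a `Date`.
#' @param index_date the index `Date`.
#' @return Integer days (> 0).
#' @export
observed_index_gap <- function(anchor_fill, index_date) {
  d <- anchor_date_of(anchor_fill)
  if (d >= index_date)
    stop("anchor fill must precede the index date strictly", call. = FALSE)
  as.integer(index_date - d)
}

anchor_date_of <- function(x) {
  if (inherits(x, "Date")) x else as.Date(x$fill_date)
}

#' Cabinet supply on hand at the anchor fill
#'
#' Estimates leftover days of a drug's supply at the time of its last fill
#' prior to index, accumulated from earlier fills of the same drug within a
#' look-back window. Supply is consumed one day per calendar day and refills
#' stack; the carry never drops below zero and is not capped.
#'
#' @param key_fills_before_anchor data.frame of earlier fills of the same drug
#'   (`fill_date`, `days_supply`), any order.
#' @param anchor_fill the anchor fill record or its `Date`.
#' @param lookback_days window length before the anchor, in days.
#' @return Days on hand at the anchor (non-negative real).
#' @examples
#' cabinet_days_on_hand(
#'   data.frame(fill_date = as.Date("2008-01-01"), days_supply = 30),
#'   as.Date("2008-01-28"), 180)  # 3 days left over
#' @export
cabinet_days_on_hand <- function(key_fills_before_anchor, anchor_fill,
                                 lookback_days) {
  anchor <- anchor_date_of(anchor_fill)
  f <- key_fills_before_anchor
  if (is.null(f) || nrow(f) == 0) return(0)
  keep <- f$fill_date >= anchor - lookback_days & f$fill_date < anchor
  f <- f[keep, , drop = FALSE]
  if (nrow(f) == 0) return(0)
  ds <- tapply(f$days_supply, f$fill_date, sum)  # same-day split fills pool
  dates <- as.Date(names(ds))
  o <- order(dates)
  dates <- c(dates[o], anchor)
  ds <- as.numeric(ds[o])
  carry <- 0
  for (i in seq_along(ds))
    carry <- max(0, carry + ds[i] - as.numeric(dates[i + 1] - dates[i]))
  carry
}

#' Inpatient days within the observed index gap
#'
#' Counts calendar days strictly between the anchor fill and the index date
#' spent in hospital, where the home drug supply is not consumed. Overlapping
#' stays are unioned. By convention `"admit_only"` (the default) a stay
#' occupies `[admit, discharge)`: the admission day is inpatient, the
#' discharge day is not; `"admit_discharge"` counts both endpoints.
#'
#' @param hospitalizations data.frame with `admit_date`, `discharge_date`.
#' @param anchor_date anchor fill `Date`.
#' @param index_date index `Date` (must follow the anchor).
#' @param convention `"admit_only"` or `"admit_discharge"`.
#' @return Integer count of distinct inpatient days in the open interval.
#' @export
inpatient_days_in_gap <- function(hospitalizations, anchor_date, index_date,
                                  convention = c("admit_only",
                                                 "admit_discharge")) {
  convention <- match.arg(convention)
  stopifnot(anchor_date < index_date)
  if (is.null(hospitalizations) || nrow(hospitalizations) == 0) return(0L)
  lo <- as.integer(anchor_date) + 1L
  hi <- as.integer(index_date) - 1L
  if (hi < lo) return(0L)
  end_off <- if (convention == "admit_only") -1L else 0L
  days <- unlist(lapply(seq_len(nrow(hospitalizations)), function(i) {
    a <- max(as.integer(hospitalizations$admit_date[i]), lo)
    b <- min(as.integer(hospitalizations$discharge_date[i]) + end_off, hi)
    if (a > b) integer() else a:b
  }))
  length(unique(days))
}

gap_allowance <- function(rule, days_supply) {
  if (rule$mode == "flexible") rule$multiplier * days_supply
  else as.numeric(rule$fixed_days)
}

predicate_matches <- function(product, predicate) {
  all(vapply(names(predicate), function(f) {
    isTRUE(product[[f]] == predicate[[f]])
  }, TRUE))
}

product_at <- function(dictionary, i) {
  list(product_id = dictionary$product_id[i],
       ingredients = dictionary$ingredients[i],
       route = dictionary$route[i],
       dosage_form = dictionary$dosage_form[i],
       strength = dictionary$strength[i],
       rx_status = dictionary$rx_status[i],
       drug_type = dictionary$drug_type[i],
       common_use = dictionary$common_use[i],
       is_supply = dictionary$is_supply[i],
       is_metered_dose_inhaler = dictionary$is_metered_dose_inhaler[i])
}

# Timeframe evaluation for one drug unit: fills of one key (product basis) or
# one product (ingredient basis). Returns a one-row evidence list.
evaluate_unit <- function(dates, ds, pids, index_date, tf, dictionary,
                          hospitalizations, convention) {
  # pool split fills of the same drug dispensed on one date
  ord <- order(dates, pids)
  dates <- dates[ord]
  ds <- ds[ord]
  pids <- pids[ord]
  dn <- as.numeric(dates)
  first_of_day <- !duplicated(dn)
  agg_dates <- dates[first_of_day]
  agg_ds <- as.numeric(rowsum(ds, dn)[, 1])
  last_pid <- pids[rev(!duplicated(rev(dn)))]

  ev <- list(counted = FALSE, rule_fired = "none",
             anchor_fill_date = as.Date(NA), days_supply = NA_integer_,
             observed_index_gap = NA_real_, allowable_index_gap = NA_real_,
             cabinet_days = 0, inpatient_days_in_gap = 0L,
             observed_pre_post_gap = NA_real_)

  pre <- which(agg_dates < index_date)
  if (!length(pre)) return(ev)
  ai <- pre[length(pre)]
  anchor_date <- agg_dates[ai]
  anchor_ds <- agg_ds[ai]

  gap <- as.numeric(index_date - anchor_date)
  extra <- 0
  if (isTRUE(tf$cabinet$enabled)) {
    prior <- data.frame(fill_date = agg_dates[seq_len(ai - 1)],
                        days_supply = agg_ds[seq_len(ai - 1)])
    ev$cabinet_days <- cabinet_days_on_hand(prior, anchor_date,
                                            tf$cabinet$lookback_days)
    extra <- extra + ev$cabinet_days
  }
  if (isTRUE(tf$hospitalization_adjustment)) {
    ev$inpatient_days_in_gap <- inpatient_days_in_gap(
      hospitalizations, anchor_date, index_date, convention)
    extra <- extra + ev$inpatient_days_in_gap
  }
  base_allow <- gap_allowance(tf$index_gap, anchor_ds) + extra
  ev$anchor_fill_date <- anchor_date
  ev$days_supply <- as.integer(anchor_ds)
  ev$observed_index_gap <- gap
  ev$allowable_index_gap <- base_allow

  if (gap < base_allow) {
    ev$counted <- TRUE
    ev$rule_fired <- "base_gap"
    return(ev)
  }
  anchor_product <- if (length(tf$overrides))
    product_at(dictionary, match(last_pid[ai], dictionary$product_id))
  for (o in tf$overrides) {
    if (predicate_matches(anchor_product, o$predicate)) {
      allow_o <- gap_allowance(o$rule, anchor_ds) + extra
      if (gap < allow_o) {
        ev$counted <- TRUE
        ev$rule_fired <- "override_gap"
        ev$allowable_index_gap <- allow_o
        return(ev)
      }
    }
  }
  if (isTRUE(tf$post_index$enabled)) {
    post <- which(agg_dates > index_date)
    if (length(post)) {
      first_post <- agg_dates[post[1]]
      pp_gap <- as.numeric(first_post - anchor_date)
      ev$observed_pre_post_gap <- pp_gap
      pp_rule <- list(mode = tf$post_index$gap_mode,
                      multiplier = tf$post_index$multiplier,
                      fixed_days = tf$post_index$fixed_days)
      if (pp_gap < gap_allowance(pp_rule, anchor_ds)) {
        ev$counted <- TRUE
        ev$rule_fired <- "post_index"
        return(ev)
      }
    }
  }
  ev
}

# one data.frame from a list of per-unit evidence lists (keys give row order)
evidence_df <- function(keys, evs) {
  pull <- function(field, template)
    unname(vapply(evs, `[[`, template, field))
  cols <- list(
    key = as.character(keys),
    counted = pull("counted", TRUE),
    rule_fired = pull("rule_fired", ""),
    anchor_fill_date = as.Date(pull("anchor_fill_date", 0),
                               origin = "1970-01-01"),
    days_supply = pull("days_supply", 0L),
    observed_index_gap = pull("observed_index_gap", 0),
    allowable_index_gap = pull("allowable_index_gap", 0),
    cabinet_days = pull("cabinet_days", 0),
    inpatient_days_in_gap = pull("inpatient_days_in_gap", 0L),
    observed_pre_post_gap = pull("observed_pre_post_gap", 0)
  )
  structure(cols, class = "data.frame",
            row.names = if (length(keys)) seq_along(keys) else integer(0))
}

longitudinal_ev <- function() {
  list(counted = TRUE, rule_fired = "longitudinal",
       anchor_fill_date = as.Date(NA), days_supply = NA_integer_,
       observed_index_gap = NA_real_, allowable_index_gap = NA_real_,
       cabinet_days = 0, inpatient_days_in_gap = 0L,
       observed_pre_post_gap = NA_real_)
}

#' Count the drugs a patient uses under one measure
#'
#' Applies a measure to a patient history: scope filters fills by product
#' attributes; uniqueness maps fills to drug keys; the timeframe decides, per
#' drug, whether it belongs to the regimen at the index date. Under the
#' cross-sectional orientation a drug counts when its observed index gap is
#' strictly less than the allowable gap (base rule, plus cabinet supply and
#' inpatient days when enabled), or when a per-drug override or the
#' post-index rescue rule admits it. Under the longitudinal orientation a
#' drug counts when any in-scope fill falls inside the window (inclusive
#' ends).
#'
#' @param history a `patient_history` from [assemble_histories()].
#' @param measure a [measure_spec()].
#' @param dictionary a `drug_dictionary` resolving the history's products.
#' @param hospital_day_convention how hospital-stay days are counted; see
#'   [inpatient_days_in_gap()].
#' @return A `count_result`: list with `patient_id`, `measure_id`, `count`,
#'   and an `evidence` data.frame with one row per candidate drug key.
#' @examples
#' fix <- table3_fixture()
#' count_drugs(fix$history, preset("default"), fix$dictionary)$count  # 3
#' @export
count_drugs <- function(history, measure, dictionary,
                        hospital_day_convention = c("admit_only",
                                                    "admit_discharge")) {
  if (!inherits(history, "patient_history") ||
      !inherits(measure, "measure_spec") ||
      !inherits(dictionary, "drug_dictionary"))
    stop("count_drugs needs a patient_history, a measure_spec and a drug_dictionary",
         call. = FALSE)
  convention <- hospital_day_convention[1]
  if (!convention %in% c("admit_only", "admit_discharge"))
    stop("unknown hospital_day_convention ", sQuote(convention), call. = FALSE)
  tf <- measure$timeframe
  fills <- history$fills
  result <- function(count, evidence) {
    structure(list(patient_id = history$patient_id,
                   measure_id = measure$measure_id,
                   count = as.integer(count), evidence = evidence),
              class = "count_result")
  }
  empty_ev <- evidence_df(character(0), list())
  if (nrow(fills) == 0) return(result(0L, empty_ev))

  pidx <- match(fills$product_id, dictionary$product_id)
  if (anyNA(pidx))
    stop("fills reference product(s) absent from the dictionary: ",
         paste(unique(fills$product_id[is.na(pidx)]), collapse = ", "),
         call. = FALSE)

  # scope decided per dictionary row (in_scope is vectorized), mapped to fills
  scope_mask <- in_scope(dictionary, measure$scope)
  keep <- scope_mask[pidx]
  fills <- fills[keep, , drop = FALSE]
  pidx <- pidx[keep]
  if (nrow(fills) == 0) return(result(0L, empty_ev))

  keys_of_row <- function(r) drug_keys(product_at(dictionary, r),
                                       measure$uniqueness)

  if (tf$orientation == "longitudinal") {
    w <- history$index_date + tf$longitudinal_window
    sel <- fills$fill_date >= w[1] & fills$fill_date <= w[2]
    keys <- sort(unique(unlist(lapply(unique(pidx[sel]), keys_of_row))))
    ev <- evidence_df(keys, rep(list(longitudinal_ev()), length(keys)))
    return(result(length(keys), ev))
  }

  if (measure$uniqueness$basis == "product") {
    urows <- unique(pidx)
    row_key <- vapply(urows, function(r) keys_of_row(r)[1], "")
    units <- split(seq_len(nrow(fills)), row_key[match(pidx, urows)])
  } else {
    units <- split(seq_len(nrow(fills)), fills$product_id)
  }

  evs <- lapply(units, function(ix) {
    evaluate_unit(fills$fill_date[ix], fills$days_supply[ix],
                  fills$product_id[ix], history$index_date, tf, dictionary,
                  history$hospitalizations, convention)
  })

  if (measure$uniqueness$basis == "product") {
    keys <- sort(names(units))
    ev <- evidence_df(keys, evs[keys])
  } else {
    # an ingredient counts if ANY product containing it passes the timeframe
    unit_keys <- lapply(names(units), function(p)
      keys_of_row(match(p, dictionary$product_id)))
    names(unit_keys) <- names(units)
    keys <- sort(unique(unlist(unit_keys)))
    reps <- lapply(keys, function(k) {
      holders <- names(units)[vapply(unit_keys, function(ks) k %in% ks, TRUE)]
      # representative unit: prefer counted, then latest anchor, then id order
      counted <- vapply(holders, function(p) evs[[p]]$counted, TRUE)
      pool <- if (any(counted)) holders[counted] else holders
      adates <- vapply(pool, function(p)
        as.numeric(evs[[p]]$anchor_fill_date), 0)
      adates[is.na(adates)] <- -Inf
      evs[[pool[order(-adates, pool)][1]]]
    })
    ev <- evidence_df(keys, reps)
  }
  result(sum(ev$counted), ev)
}

#' @export
print.count_result <- function(x, ...) {
  cat("<count_result>", x$patient_id, "| measure", x$measure_id, "| count",
      x$count, "\n")
  if (nrow(x$evidence)) {
    print(x$evidence[, c("key", "counted", "rule_fired", "observed_index_gap",
                         "allowable_index_gap")], row.names = FALSE)
  }
  invisible(x)
}

#' Count drugs for every patient in a cohort
#'
#' @param histories list of `patient_history` objects.
#' @param measure a [measure_spec()].
#' @param dictionary a `drug_dictionary`.
#' @param ... passed to [count_drugs()].
#' @return data.frame with `patient_id`, `measure_id`, `count`.
#' @export
count_cohort <- function(histories, measure, dictionary, ...) {
  counts <- vapply(histories, function(h)
    count_drugs(h, measure, dictionary, ...)$count, 0L)
  data.frame(patient_id = vapply(histories, `[[`, "", "patient_id"),
             measure_id = measure$measure_id,
             count = as.integer(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}
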