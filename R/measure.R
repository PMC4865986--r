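#' Scope component of a drug-count measure
#'
#' Scope decides which dictionary products qualify as drugs. Each argument is
#' a filter on one product attribute; a product must pass every filter.
#' Routes may be restricted either with an inclusion set (`routes_include`) or
#' an exclusion set (`routes_exclude`), never both.
#'
#' @param rx_statuses character, subset of `drug_vocab$rx_status`.
#' @param drug_types character, subset of `drug_vocab$drug_type`.
#' @param routes_include `"all"` or a subset of `drug_vocab$route`.
#' @param routes_exclude character, subset of `drug_vocab$route` (empty unless
#'   `routes_include == "all"`).
#' @param dosage_forms `"all"` or a subset of `drug_vocab$dosage_form`.
#' @param common_uses character, subset of `drug_vocab$common_use`.
#' @return An object of class `scope_spec`.
#' @export
scope_spec <- function(rx_statuses = "prescription",
                       drug_types = drug_vocab$drug_type,
                       routes_include = "all",
                       routes_exclude = character(),
                       dosage_forms = "all",
                       common_uses = drug_vocab$common_use) {
  stopifnot(length(rx_statuses) >= 1, length(drug_types) >= 1,
            length(common_uses) >= 1)
  check_vocab(rx_statuses, "rx_status")
  check_vocab(drug_types, "drug_type")
  if (!identical(routes_include, "all")) {
    check_vocab(routes_include, "route")
    if (length(routes_exclude) > 0)
      stop("use either routes_include or routes_exclude, not both", call. = FALSE)
  }
  if (length(routes_exclude) > 0) check_vocab(routes_exclude, "route")
  if (!identical(dosage_forms, "all")) check_vocab(dosage_forms, "dosage_form")
  structure(list(rx_statuses = sort(unique(rx_statuses)),
                 drug_types = sort(unique(drug_types)),
                 routes_include = if (identical(routes_include, "all")) "all"
                                  else sort(unique(routes_include)),
                 routes_exclude = sort(unique(routes_exclude)),
                 dosage_forms = if (identical(dosage_forms, "all")) "all"
                                else sort(unique(dosage_forms)),
                 common_uses = sort(unique(common_uses))),
            class = "scope_spec")
}

#' Uniqueness component of a drug-count measure
#'
#' Uniqueness decides how fills are de-duplicated into countable drugs.
#' Under the product basis a combination product contributes one drug; under
#' the ingredient basis it is dissected and each ingredient contributes one.
#' The level appends route / form / strength detail to the key, so coarser
#' levels merge more fills.
#'
#' @param basis `"product"` or `"ingredient"`.
#' @param level one of `"ingredient"`, `"ingredient_route"`,
#'   `"ingredient_route_form"`, `"ingredient_route_form_strength"`.
#' @return An object of class `uniqueness_spec`.
#' @export
uniqueness_spec <- function(basis = c("product", "ingredient"),
                            level = c("ingredient_route_form", "ingredient",
                                      "ingredient_route",
                                      "ingredient_route_form_strength")) {
  basis <- match.arg(basis)
  level <- match.arg(level)
  structure(list(basis = basis, level = level), class = "uniqueness_spec")
}

#' Allowable index-gap rule
#'
#' The allowable index gap is the longest time before the index date in which
#' a drug's last fill may fall and still count. A flexible rule scales with
#' the anchor fill's days supply; a fixed rule is a constant look-back.
#'
#' @param mode `"flexible"` or `"fixed"`.
#' @param multiplier positive real; allowable gap = multiplier x days supply
#'   (flexible mode only).
#' @param fixed_days positive integer look-back (fixed mode only).
#' @return An object of class `index_gap_rule`.
#' @export
index_gap_rule <- function(mode = c("flexible", "fixed"), multiplier = NULL,
                           fixed_days = NULL) {
  mode <- match.arg(mode)
  if (mode == "flexible") {
    if (is.null(multiplier)) multiplier <- 1.0
    if (!is.null(fixed_days))
      stop("flexible index-gap rule must not set fixed_days", call. = FALSE)
    if (!is.numeric(multiplier) || length(multiplier) != 1 || multiplier <= 0)
      stop("multiplier must be a positive number", call. = FALSE)
    out <- list(mode = mode, multiplier = as.numeric(multiplier))
  } else {
    if (is.null(fixed_days))
      stop("fixed index-gap rule requires fixed_days", call. = FALSE)
    if (!is.null(multiplier))
      stop("fixed index-gap rule must not set multiplier", call. = FALSE)
    if (!is.numeric(fixed_days) || length(fixed_days) != 1 || fixed_days <= 0 ||
        fixed_days != round(fixed_days))
      stop("fixed_days must be a positive integer", call. = FALSE)
    out <- list(mode = mode, fixed_days = as.integer(fixed_days))
  }
  structure(out, class = "index_gap_rule")
}

#' Post-index rescue rule
#'
#' When enabled, a drug that fails the index-gap test may still count if the
#' gap between its last pre-index fill and its first post-index fill is below
#' the allowable pre-post fill gap.
#'
#' @param enabled logical.
#' @param gap_mode `"flexible"` or `"fixed"`.
#' @param multiplier positive real (flexible mode).
#' @param fixed_days positive integer (fixed mode).
#' @return An object of class `post_index_rule`.
#' @export
post_index_rule <- function(enabled = FALSE, gap_mode = "flexible",
                            multiplier = NULL, fixed_days = NULL) {
  if (!enabled)
    return(structure(list(enabled = FALSE), class = "post_index_rule"))
  rule <- index_gap_rule(gap_mode, multiplier = multiplier,
                         fixed_days = fixed_days)
  structure(c(list(enabled = TRUE, gap_mode = rule$mode),
              rule[setdiff(names(rule), "mode")]),
            class = "post_index_rule")
}

#' Cabinet-supply (prior fill history) rule
#'
#' When enabled, leftover days of supply accumulated from fills in a look-back
#' window before the anchor fill are added to the allowable index gap.
#'
#' @param enabled logical.
#' @param lookback_days positive integer window before the last pre-index fill.
#' @return An object of class `cabinet_rule`.
#' @export
cabinet_rule <- function(enabled = FALSE, lookback_days = 180L) {
  if (enabled && (!is.numeric(lookback_days) || lookback_days <= 0))
    stop("lookback_days must be positive when the cabinet rule is enabled",
         call. = FALSE)
  structure(list(enabled = isTRUE(enabled),
                 lookback_days = as.integer(lookback_days)),
            class = "cabinet_rule")
}

#' Per-drug override of the index-gap rule
#'
#' Applies an alternative index-gap rule to products matching an attribute
#' predicate (for example `common_use = "as_needed"` or
#' `is_metered_dose_inhaler = TRUE`). A matching drug counts if it satisfies
#' either the base rule or the override rule.
#'
#' @param predicate named list of DrugProduct field = value pairs; a product
#'   matches when every listed field equals the given value.
#' @param rule an [index_gap_rule()].
#' @return An object of class `override_rule`.
#' @export
override_rule <- function(predicate, rule) {
  allowed <- c("rx_status", "drug_type", "route", "dosage_form", "common_use",
               "is_supply", "is_metered_dose_inhaler")
  if (!is.list(predicate) || is.null(names(predicate)) ||
      any(!nzchar(names(predicate))))
    stop("predicate must be a named list of product fields", call. = FALSE)
  bad <- setdiff(names(predicate), allowed)
  if (length(bad))
    stop("predicate references unknown product field(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!inherits(rule, "index_gap_rule"))
    stop("rule must be an index_gap_rule", call. = FALSE)
  structure(list(predicate = predicate, rule = rule), class = "override_rule")
}

#' Timeframe component of a drug-count measure
#'
#' @param orientation `"cross_sectional"` or `"longitudinal"`.
#' @param index_gap an [index_gap_rule()] (cross-sectional only).
#' @param post_index a [post_index_rule()].
#' @param cabinet a [cabinet_rule()].
#' @param hospitalization_adjustment logical; add inpatient days falling in the
#'   observed index gap to the allowable gap.
#' @param overrides list of [override_rule()] objects.
#' @param longitudinal_window integer length-2 vector of day offsets relative
#'   to the index date (start, end), required for longitudinal orientation.
#' @return An object of class `timeframe_spec`.
#' @export
timeframe_spec <- function(orientation = c("cross_sectional", "longitudinal"),
                           index_gap = index_gap_rule("flexible"),
                           post_index = post_index_rule(FALSE),
                           cabinet = cabinet_rule(FALSE),
                           hospitalization_adjustment = FALSE,
                           overrides = list(),
                           longitudinal_window = NULL) {
  orientation <- match.arg(orientation)
  if (orientation == "cross_sectional") {
    if (!inherits(index_gap, "index_gap_rule"))
      stop("cross-sectional timeframe requires an index_gap rule", call. = FALSE)
  } else {
    if (is.null(longitudinal_window) || length(longitudinal_window) != 2 ||
        longitudinal_window[1] > longitudinal_window[2])
      stop("longitudinal timeframe requires longitudinal_window = c(start, end)",
           call. = FALSE)
    longitudinal_window <- as.integer(longitudinal_window)
  }
  stopifnot(inherits(post_index, "post_index_rule"),
            inherits(cabinet, "cabinet_rule"),
            is.logical(hospitalization_adjustment))
  if (length(overrides) && !all(vapply(overrides, inherits, TRUE, "override_rule")))
    stop("overrides must be a list of override_rule objects", call. = FALSE)
  structure(list(orientation = orientation, index_gap = index_gap,
                 post_index = post_index, cabinet = cabinet,
                 hospitalization_adjustment = isTRUE(hospitalization_adjustment),
                 overrides = overrides,
                 longitudinal_window = longitudinal_window),
            class = "timeframe_spec")
}

#' A complete drug-count measure
#'
#' Bundles the three framework components — scope, uniqueness, timeframe —
#' under a measure id.
#'
#' @param measure_id short unique name.
#' @param scope a [scope_spec()].
#' @param uniqueness a [uniqueness_spec()].
#' @param timeframe a [timeframe_spec()].
#' @param description free-text description.
#' @return An object of class `measure_spec`.
#' @export
measure_spec <- function(measure_id, scope = scope_spec(),
                         uniqueness = uniqueness_spec(),
                         timeframe = timeframe_spec(),
                         description = "") {
  stopifnot(is.character(measure_id), length(measure_id) == 1,
            nzchar(measure_id),
            inherits(scope, "scope_spec"),
            inherits(uniqueness, "uniqueness_spec"),
            inherits(timeframe, "timeframe_spec"))
  structure(list(measure_id = measure_id, scope = scope,
                 uniqueness = uniqueness, timeframe = timeframe,
                 description = description),
            class = "measure_spec")
}

#' @export
print.measure_spec <- function(x, ...) {
  cat("<measure_spec>", x$measure_id, "\n")
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  cat("  scope:      rx_status {", paste(x$scope$rx_statuses, collapse = ","),
      "}", sep = "")
  if (!identical(x$scope$routes_include, "all"))
    cat("; routes {", paste(x$scope$routes_include, collapse = ","), "}", sep = "")
  if (length(x$scope$routes_exclude))
    cat("; routes excluded {", paste(x$scope$routes_exclude, collapse = ","), "}",
        sep = "")
  if (!setequal(x$scope$common_uses, drug_vocab$common_use))
    cat("; common_use {", paste(x$scope$common_uses, collapse = ","), "}", sep = "")
  cat("\n  uniqueness: ", x$uniqueness$basis, " basis at ", x$uniqueness$level,
      " level\n", sep = "")
  tf <- x$timeframe
  cat("  timeframe:  ", tf$orientation, sep = "")
  if (tf$orientation == "cross_sectional") {
    ig <- tf$index_gap
    cat(", index gap ",
        if (ig$mode == "flexible") paste0(ig$multiplier, " x days supply")
        else paste0("fixed ", ig$fixed_days, " d"), sep = "")
    if (isTRUE(tf$post_index$enabled)) cat(", post-index rescue")
    if (isTRUE(tf$cabinet$enabled))
      cat(", cabinet supply (", tf$cabinet$lookback_days, " d look-back)", sep = "")
    if (tf$hospitalization_adjustment) cat(", hospitalization adjustment")
    if (length(tf$overrides)) cat(", ", length(tf$overrides), " override(s)", sep = "")
  } else {
    cat(", window [", tf$longitudinal_window[1], ", ",
        tf$longitudinal_window[2], "] d around index", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Preset drug-count measures
#'
#' Returns one of the fifteen packaged measures: `"default"` plus variants
#' `"v1"`-`"v14"`, each differing from the default in exactly one framework
#' component.
#'
#' The default counts prescription products, product-based at the
#' ingredient(s)-route-form level, cross-sectionally with a flexible allowable
#' index gap of 1.0 x days supply. Variants: v1 adds OTC products; v2 keeps
#' oral routes only; v3 excludes the topical route; v4 keeps regularly-used
#' products only; v5/v6 switch to ingredient-based uniqueness at the
#' ingredient / ingredient-route level; v7 widens the flexible gap to 1.2 x
#' days supply; v8/v9 use fixed 90/180-day gaps; v10 enables post-index rescue
#' with a flexible pre-post gap of 2 x days supply; v11 adds a 180-day cabinet
#' supply; v12 adds inpatient days in the gap; v13/v14 apply a fixed 180-day
#' gap to as-needed drugs / metered-dose inhalers.
#'
#' @param name preset name.
#' @return A [measure_spec()].
#' @examples
#' preset("v9")$timeframe$index_gap
#' @export
preset <- function(name) {
  valid <- preset_names()
  if (length(name) != 1 || !name %in% valid)
    stop("unknown preset ", sQuote(name), "; valid presets: ",
         paste(valid, collapse = ", "), call. = FALSE)
  base <- function(id, desc, scope = scope_spec(),
                   uniqueness = uniqueness_spec(),
                   timeframe = timeframe_spec()) {
    measure_spec(id, scope, uniqueness, timeframe, desc)
  }
  switch(name,
    default = base("default", "Prescription products; product basis at ingredient(s)-route-form; flexible index gap of the days supply"),
    v1 = base("v1", "Rx and OTC products",
              scope = scope_spec(rx_statuses = c("prescription", "otc"))),
    v2 = base("v2", "Oral Rx products",
              scope = scope_spec(routes_include = "oral")),
    v3 = base("v3", "Non-topical Rx products",
              scope = scope_spec(routes_exclude = "topical")),
    v4 = base("v4", "Regularly used Rx products",
              scope = scope_spec(common_uses = "regular")),
    v5 = base("v5", "Ingredient basis at ingredient level",
              uniqueness = uniqueness_spec("ingredient", "ingredient")),
    v6 = base("v6", "Ingredient basis at ingredient-route level",
              uniqueness = uniqueness_spec("ingredient", "ingredient_route")),
    v7 = base("v7", "Flexible index gap of 1.2 x days supply",
              timeframe = timeframe_spec(index_gap = index_gap_rule("flexible", multiplier = 1.2))),
    v8 = base("v8", "Fixed index gap of 90 days",
              timeframe = timeframe_spec(index_gap = index_gap_rule("fixed", fixed_days = 90))),
    v9 = base("v9", "Fixed index gap of 180 days",
              timeframe = timeframe_spec(index_gap = index_gap_rule("fixed", fixed_days = 180))),
    v10 = base("v10", "Post-index rescue with flexible pre-post gap of 2 x days supply",
               timeframe = timeframe_spec(post_index = post_index_rule(TRUE, "flexible", multiplier = 2))),
    v11 = base("v11", "Cabinet supply from 180-day prior fill history",
               timeframe = timeframe_spec(cabinet = cabinet_rule(TRUE, 180))),
    v12 = base("v12", "Hospitalization adjustment during the index gap",
               timeframe = timeframe_spec(hospitalization_adjustment = TRUE)),
    v13 = base("v13", "Fixed 180-day index gap for as-needed drugs",
               timeframe = timeframe_spec(overrides = list(
                 override_rule(list(common_use = "as_needed"),
                               index_gap_rule("fixed", fixed_days = 180))))),
    v14 = base("v14", "Fixed 180-day index gap for metered-dose inhalers",
               timeframe = timeframe_spec(overrides = list(
                 override_rule(list(is_metered_dose_inhaler = TRUE),
                               index_gap_rule("fixed", fixed_days = 180)))))
  )
}

#' Names of the packaged preset measures
#' @return Character vector `c("default", "v1", ..., "v14")`.
#' @export
preset_names <- function() c("default", paste0("v", 1:14))
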