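#' Serialize a measure to a plain list / JSON
#'
#' Produces a fully explicit configuration document (no preset reference) that
#' [parse_measure()] maps back to an identical `measure_spec`.
#'
#' @param spec a [measure_spec()].
#' @return A named list ready for [jsonlite::toJSON()].
#' @export
serialize_measure <- function(spec) {
  stopifnot(inherits(spec, "measure_spec"))
  tf <- spec$timeframe
  ser_gap <- function(r) {
    if (r$mode == "flexible") list(mode = "flexible", multiplier = r$multiplier)
    else list(mode = "fixed", fixed_days = r$fixed_days)
  }
  pi <- if (isTRUE(tf$post_index$enabled)) {
    out <- list(enabled = TRUE, gap_mode = tf$post_index$gap_mode)
    if (tf$post_index$gap_mode == "flexible")
      out$multiplier <- tf$post_index$multiplier
    else out$fixed_days <- tf$post_index$fixed_days
    out
  } else list(enabled = FALSE)
  list(
    measure_id = spec$measure_id,
    description = spec$description,
    scope = list(
      rx_statuses = spec$scope$rx_statuses,
      drug_types = spec$scope$drug_types,
      routes_include = spec$scope$routes_include,
      routes_exclude = spec$scope$routes_exclude,
      dosage_forms = spec$scope$dosage_forms,
      common_uses = spec$scope$common_uses
    ),
    uniqueness = list(basis = spec$uniqueness$basis, level = spec$uniqueness$level),
    timeframe = list(
      orientation = tf$orientation,
      index_gap = if (tf$orientation == "cross_sectional") ser_gap(tf$index_gap),
      post_index = pi,
      cabinet = list(enabled = tf$cabinet$enabled,
                     lookback_days = tf$cabinet$lookback_days),
      hospitalization_adjustment = tf$hospitalization_adjustment,
      overrides = lapply(tf$overrides, function(o)
        list(predicate = o$predicate, rule = ser_gap(o$rule))),
      longitudinal_window = tf$longitudinal_window
    )
  )
}

#' Write a measure configuration to a JSON file
#' @param spec a [measure_spec()].
#' @param path output file path.
#' @export
write_measure <- function(spec, path) {
  jsonlite::write_json(serialize_measure(spec), path, auto_unbox = TRUE,
                       null = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

cfg_fail <- function(path, msg) {
  stop(sprintf("measure config error at %s: %s", path, msg), call. = FALSE)
}

cfg_fields <- function(x, allowed, where) {
  if (!is.list(x)) cfg_fail(where, "expected an object")
  bad <- setdiff(names(x), allowed)
  if (length(bad)) cfg_fail(paste0(where, "/", bad[1]), "unknown field")
  invisible(x)
}

cfg_token <- function(value, vocab_field, where, allow_all = FALSE) {
  value <- as.character(value)
  if (allow_all && identical(value, "all")) return("all")
  bad <- setdiff(value, drug_vocab[[vocab_field]])
  if (length(bad))
    cfg_fail(where, paste0("invalid token ", sQuote(bad[1]), "; allowed: ",
                           paste(drug_vocab[[vocab_field]], collapse = ", ")))
  value
}

parse_gap_rule <- function(x, where) {
  cfg_fields(x, c("mode", "multiplier", "fixed_days"), where)
  if (is.null(x$mode)) cfg_fail(paste0(where, "/mode"), "missing")
  if (!x$mode %in% c("flexible", "fixed"))
    cfg_fail(paste0(where, "/mode"), "must be 'flexible' or 'fixed'")
  tryCatch(index_gap_rule(x$mode, multiplier = x$multiplier,
                          fixed_days = x$fixed_days),
           error = function(e) cfg_fail(where, conditionMessage(e)))
}

#' Parse a measure configuration
#'
#' Accepts a measure configuration as an R list, a JSON string, or a path to a
#' JSON file. The document either spells out all three components or names a
#' `preset` and overrides individual fields; overrides replace whole rules
#' (e.g. a new `index_gap` replaces mode and parameters together).
#'
#' @param config list, JSON string, or file path.
#' @return A [measure_spec()].
#' @examples
#' parse_measure(list(preset = "default",
#'                    timeframe = list(index_gap = list(mode = "fixed",
#'                                                      fixed_days = 90))))
#' @export
parse_measure <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (file.exists(config)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE,
                         simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
    } else if (config %in% preset_names()) {
      return(preset(config))
    } else if (grepl("^\\s*\\{", config)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE,
                         simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
    } else {
      stop("measure ", sQuote(config),
           " is neither a preset name nor a readable JSON file", call. = FALSE)
    }
  }
  cfg_fields(config, c("preset", "measure_id", "description", "scope",
                       "uniqueness", "timeframe"), "")
  base <- if (!is.null(config$preset)) {
    if (!config$preset %in% preset_names())
      cfg_fail("/preset", paste0("unknown preset ", sQuote(config$preset)))
    preset(config$preset)
  } else {
    for (f in c("scope", "uniqueness", "timeframe"))
      if (is.null(config[[f]]))
        cfg_fail(paste0("/", f), "missing (required without a preset)")
    preset("default")
  }

  sc <- base$scope
  if (!is.null(config$scope)) {
    s <- cfg_fields(config$scope,
                    c("rx_statuses", "drug_types", "routes_include",
                      "routes_exclude", "dosage_forms", "common_uses"), "/scope")
    args <- list(
      rx_statuses = if (!is.null(s$rx_statuses))
        cfg_token(s$rx_statuses, "rx_status", "/scope/rx_statuses")
        else sc$rx_statuses,
      drug_types = if (!is.null(s$drug_types))
        cfg_token(s$drug_types, "drug_type", "/scope/drug_types")
        else sc$drug_types,
      dosage_forms = if (!is.null(s$dosage_forms))
        cfg_token(s$dosage_forms, "dosage_form", "/scope/dosage_forms", TRUE)
        else sc$dosage_forms,
      common_uses = if (!is.null(s$common_uses))
        cfg_token(s$common_uses, "common_use", "/scope/common_uses")
        else sc$common_uses
    )
    # route mechanisms are exclusive: specifying one resets the other
    if (!is.null(s$routes_include)) {
      args$routes_include <- cfg_token(s$routes_include, "route",
                                       "/scope/routes_include", TRUE)
      args$routes_exclude <- if (!is.null(s$routes_exclude))
        cfg_token(s$routes_exclude, "route", "/scope/routes_exclude")
        else character()
    } else if (!is.null(s$routes_exclude)) {
      args$routes_include <- "all"
      args$routes_exclude <- cfg_token(s$routes_exclude, "route",
                                       "/scope/routes_exclude")
    } else {
      args$routes_include <- sc$routes_include
      args$routes_exclude <- sc$routes_exclude
    }
    sc <- tryCatch(do.call(scope_spec, args),
                   error = function(e) cfg_fail("/scope", conditionMessage(e)))
  }

  un <- base$uniqueness
  if (!is.null(config$uniqueness)) {
    u <- cfg_fields(config$uniqueness, c("basis", "level"), "/uniqueness")
    basis <- if (!is.null(u$basis)) u$basis else un$basis
    level <- if (!is.null(u$level)) u$level else un$level
    if (!basis %in% c("product", "ingredient"))
      cfg_fail("/uniqueness/basis", paste0("invalid token ", sQuote(basis)))
    if (!level %in% c("ingredient", "ingredient_route", "ingredient_route_form",
                      "ingredient_route_form_strength"))
      cfg_fail("/uniqueness/level", paste0("invalid token ", sQuote(level)))
    un <- uniqueness_spec(basis, level)
  }

  tf <- base$timeframe
  if (!is.null(config$timeframe)) {
    t <- cfg_fields(config$timeframe,
                    c("orientation", "index_gap", "post_index", "cabinet",
                      "hospitalization_adjustment", "overrides",
                      "longitudinal_window"), "/timeframe")
    orientation <- if (!is.null(t$orientation)) t$orientation else tf$orientation
    if (!orientation %in% c("cross_sectional", "longitudinal"))
      cfg_fail("/timeframe/orientation", paste0("invalid token ",
                                                sQuote(orientation)))
    index_gap <- if (!is.null(t$index_gap))
      parse_gap_rule(t$index_gap, "/timeframe/index_gap") else tf$index_gap
    post_index <- if (!is.null(t$post_index)) {
      p <- cfg_fields(t$post_index,
                      c("enabled", "gap_mode", "multiplier", "fixed_days"),
                      "/timeframe/post_index")
      if (isTRUE(p$enabled)) {
        tryCatch(post_index_rule(TRUE,
                                 gap_mode = if (is.null(p$gap_mode)) "flexible"
                                            else p$gap_mode,
                                 multiplier = p$multiplier,
                                 fixed_days = p$fixed_days),
                 error = function(e) cfg_fail("/timeframe/post_index",
                                              conditionMessage(e)))
      } else post_index_rule(FALSE)
    } else tf$post_index
    cabinet <- if (!is.null(t$cabinet)) {
      cb <- cfg_fields(t$cabinet, c("enabled", "lookback_days"),
                       "/timeframe/cabinet")
      tryCatch(cabinet_rule(isTRUE(cb$enabled),
                            lookback_days = if (is.null(cb$lookback_days)) 180L
                                            else cb$lookback_days),
               error = function(e) cfg_fail("/timeframe/cabinet",
                                            conditionMessage(e)))
    } else tf$cabinet
    overrides <- if (!is.null(t$overrides)) {
      lapply(seq_along(t$overrides), function(i) {
        o <- cfg_fields(t$overrides[[i]], c("predicate", "rule"),
                        sprintf("/timeframe/overrides/%d", i))
        if (is.null(o$predicate) || is.null(o$rule))
          cfg_fail(sprintf("/timeframe/overrides/%d", i),
                   "needs both predicate and rule")
        tryCatch(override_rule(as.list(o$predicate),
                               parse_gap_rule(o$rule,
                                 sprintf("/timeframe/overrides/%d/rule", i))),
                 error = function(e)
                   cfg_fail(sprintf("/timeframe/overrides/%d", i),
                            conditionMessage(e)))
      })
    } else tf$overrides
    window <- if (!is.null(t$longitudinal_window)) t$longitudinal_window
              else tf$longitudinal_window
    hosp <- if (!is.null(t$hospitalization_adjustment))
      isTRUE(t$hospitalization_adjustment) else tf$hospitalization_adjustment
    tf <- tryCatch(
      timeframe_spec(orientation, index_gap = index_gap,
                     post_index = post_index, cabinet = cabinet,
                     hospitalization_adjustment = hosp, overrides = overrides,
                     longitudinal_window = window),
      error = function(e) cfg_fail("/timeframe", conditionMessage(e)))
  }

  id <- if (!is.null(config$measure_id)) config$measure_id else base$measure_id
  desc <- if (!is.null(config$description)) config$description else base$description
  measure_spec(id, sc, un, tf, desc)
}

#' Which framework components differ between two measures
#'
#' Compares the scope, uniqueness and timeframe components field-wise,
#' ignoring measure id and description.
#'
#' @param a,b [measure_spec()] objects.
#' @return Character vector among `c("scope", "uniqueness", "timeframe")`.
#' @export
measure_components_differing <- function(a, b) {
  comp <- c("scope", "uniqueness", "timeframe")
  comp[!vapply(comp, function(f) identical(unclass_deep(a[[f]]),
                                           unclass_deep(b[[f]])), TRUE)]
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
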