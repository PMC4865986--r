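#' Percentile summary of a cohort's drug counts
#'
#' Summarises a vector of per-patient counts by the 25th, 50th, 75th and 95th
#' percentiles. The default convention is nearest-rank (the value at index
#' `ceiling(p * n)` of the sorted counts), which maps integer counts to
#' integer percentiles; `"linear"` uses the usual interpolating quantile.
#'
#' @param counts integer vector of per-patient counts (n >= 1).
#' @param measure_id label for the summarised measure.
#' @param convention `"nearest_rank"` or `"linear"`.
#' @return One-row data.frame: `measure_id`, `n_patients`, `p25`, `p50`,
#'   `p75`, `p95`.
#' @export
percentile_summary <- function(counts, measure_id,
                               convention = c("nearest_rank", "linear")) {
  convention <- match.arg(convention)
  if (length(counts) == 0) stop("counts must be non-empty", call. = FALSE)
  p <- c(0.25, 0.50, 0.75, 0.95)
  q <- if (convention == "nearest_rank") {
    s <- sort(counts)
    s[pmin(length(s), ceiling(p * length(s)))]
  } else {
    unname(stats::quantile(counts, p, type = 7))
  }
  data.frame(measure_id = measure_id, n_patients = length(counts),
             p25 = q[1], p50 = q[2], p75 = q[3], p95 = q[4],
             stringsAsFactors = FALSE)
}

#' Change-from-reference distribution
#'
#' Bins each patient's absolute change in count between a reference measure
#' and a variant into 0 / 1 / >= 2 drugs, and reports the percentage of
#' patients in each bin.
#'
#' @param reference_counts,variant_counts aligned per-patient count vectors
#'   (same patients, same order).
#' @param measure_id,reference_id labels for the report row.
#' @return One-row data.frame: `measure_id`, `reference_id`, `pct_no_change`,
#'   `pct_change_1`, `pct_change_ge2` (percentages summing to 100).
#' @export
change_distribution <- function(reference_counts, variant_counts,
                                measure_id = "variant",
                                reference_id = "default") {
  if (length(reference_counts) != length(variant_counts))
    stop("reference and variant count vectors must have equal length",
         call. = FALSE)
  if (length(reference_counts) == 0)
    stop("count vectors must be non-empty", call. = FALSE)
  bin <- pmin(abs(variant_counts - reference_counts), 2)
  n <- length(bin)
  data.frame(measure_id = measure_id, reference_id = reference_id,
             pct_no_change = 100 * sum(bin == 0) / n,
             pct_change_1 = 100 * sum(bin == 1) / n,
             pct_change_ge2 = 100 * sum(bin == 2) / n,
             stringsAsFactors = FALSE)
}

#' Measure comparison report over a cohort
#'
#' Runs every measure over the cohort and produces one row per measure with
#' the count percentiles and the change-from-reference distribution — the
#' shape of a measure sensitivity table.
#'
#' @param histories list of `patient_history` objects.
#' @param measures list of [measure_spec()] objects (unique ids; must include
#'   the reference).
#' @param reference_id measure id used as the change reference.
#' @param dictionary a `drug_dictionary`.
#' @param convention percentile convention, see [percentile_summary()].
#' @param ... passed to [count_drugs()].
#' @return data.frame with one row per measure: percentiles plus change bins.
#' @export
comparison_report <- function(histories, measures, reference_id, dictionary,
                              convention = "nearest_rank", ...) {
  ids <- vapply(measures, `[[`, "", "measure_id")
  if (anyDuplicated(ids))
    stop("duplicate measure_id: ", paste(unique(ids[duplicated(ids)]),
                                         collapse = ", "), call. = FALSE)
  if (!reference_id %in% ids)
    stop("reference_id ", sQuote(reference_id), " not among the measures",
         call. = FALSE)
  counts <- lapply(measures, function(m)
    count_cohort(histories, m, dictionary, ...)$count)
  names(counts) <- ids
  ref <- counts[[reference_id]]
  rows <- lapply(ids, function(id) {
    cbind(percentile_summary(counts[[id]], id, convention),
          change_distribution(ref, counts[[id]], id, reference_id)[
            , c("pct_no_change", "pct_change_1", "pct_change_ge2")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a comparison report as aligned text
#'
#' Human-readable view of [comparison_report()] output. Percentages are shown
#' to one decimal; values strictly between 0 and 1 are rendered `"<1"`.
#'
#' @param report data.frame from [comparison_report()].
#' @return Character vector of lines.
#' @export
render_report_text <- function(report) {
  fmt_pct <- function(x) ifelse(x > 0 & x < 1, "<1", sprintf("%.1f", x))
  body <- data.frame(
    measure = report$measure_id,
    n = report$n_patients,
    `p25 p50 p75 p95` = sprintf("%g %g %g %g", report$p25, report$p50,
                                report$p75, report$p95),
    `no change / 1 / >=2 (%)` = sprintf("%s / %s / %s",
                                        fmt_pct(report$pct_no_change),
                                        fmt_pct(report$pct_change_1),
                                        fmt_pct(report$pct_change_ge2)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  c("Drug count measure comparison",
    utils::capture.output(print(body, row.names = FALSE)))
}
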