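#' A dosimetric recurrence case
#'
#' Bundles the planning dose grid, the prescription dose, and the recurrent
#' tumor volume (V_recur) already registered to the planning grid, together
#' with optional clinical annotations. Registration is an input contract,
#' not a computation: masks must arrive on the dose grid.
#'
#' @param dose an [image_volume()] in Gy (nonnegative).
#' @param prescription_gy prescribed dose in Gy.
#' @param recur_mask a [roi_mask()] (V_recur), nonempty and congruent with
#'   `dose`.
#' @param site `"local"`, `"regional"` or `"local_regional"` (optional).
#' @param time_to_failure_months months from treatment to failure
#'   (optional).
#' @return A `recurrence_case` object.
#' @export
recurrence_case <- function(dose, prescription_gy, recur_mask,
                            site = NA_character_,
                            time_to_failure_months = NA_real_) {
  stopifnot(inherits(dose, "image_volume"), inherits(recur_mask, "roi_mask"))
  if (any(dose$values < 0)) stop("dose must be nonnegative")
  if (prescription_gy <= 0) stop("prescription_gy must be positive")
  check_congruent(dose, recur_mask)
  if (mask_is_empty(recur_mask)) stop("recurrence mask is empty")
  structure(
    list(dose = dose, prescription_gy = prescription_gy,
         recur_mask = recur_mask, site = site,
         time_to_failure_months = time_to_failure_months),
    class = "recurrence_case"
  )
}

#' Fraction of the recurrence volume inside an isodose level
#'
#' Evaluates the dose-volume histogram of V_recur at the given isodose:
#' the proportion of recurrence-mask voxels receiving at least
#' `isodose_fraction * prescription` (threshold inclusive; voxels count
#' equally after isotropic resampling).
#'
#' @param case a [recurrence_case()].
#' @param isodose_fraction isodose level as a fraction of prescription
#'   (default 0.95, the 95 percent prescription isodose).
#' @return Proportion in \[0, 1\].
#' @export
fraction_in_isodose <- function(case, isodose_fraction = 0.95) {
  stopifnot(inherits(case, "recurrence_case"))
  level <- isodose_fraction * case$prescription_gy
  mean(case$dose$values[case$recur_mask$values] >= level)
}

#' Classify a recurrence as in-field, marginal, or out-of-field
#'
#' Applies the coverage rule: in-field if 95 percent or more of V_recur
#' lies within the 95 percent prescription isodose; marginal if 20 to 95
#' percent; out-of-field if less than 20 percent. Boundaries: 0.95 maps to
#' in-field, 0.20 to marginal.
#'
#' @param fraction_in proportion(s) of V_recur inside the isodose, in
#'   \[0, 1\].
#' @return Character vector: `"in_field"`, `"marginal"` or
#'   `"out_of_field"`.
#' @export
classify_pattern <- function(fraction_in) {
  if (any(!is.finite(fraction_in)) ||
      any(fraction_in < 0) || any(fraction_in > 1))
    stop("`fraction_in` must lie in [0, 1]")
  ifelse(fraction_in >= 0.95, "in_field",
         ifelse(fraction_in >= 0.20, "marginal", "out_of_field"))
}

#' Read a clinical recurrence table
#'
#' Reads a cohort CSV with one row per recurrent patient: `id`, `stage`,
#' `rt_dose`, `concurrent_chemotherapy`, `time_to_failure_months`, `site`
#' (`local` / `regional` / `local_regional`) and `pattern` (`in_field` /
#' `marginal` / `out_of_field`). The packaged example
#' (`system.file("extdata", "table2_clinical.csv", package = "radrecur")`)
#' holds the 20-patient reference cohort.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_clinical_table <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Tabulate failure patterns and sites of a recurrence cohort
#'
#' Summarizes a clinical table: counts by failure pattern and by site of
#' recurrence, and the median and range of time to failure. Rows with
#' missing site or time are flagged, not dropped silently.
#'
#' @param clinical a data frame as from [read_clinical_table()].
#' @return A `cohort_summary`: list with tibbles `pattern_counts` and
#'   `site_counts`, a `time_to_failure` tibble (median, min, max, n), and
#'   `flagged_rows` (row indices with missing site or time).
#' @export
tabulate_cohort <- function(clinical) {
  clinical <- tibble::as_tibble(clinical)
  flagged <- which(is.na(clinical$site) | is.na(clinical$time_to_failure_months))
  count_of <- function(col, levels) {
    v <- clinical[[col]]
    out <- tibble::tibble(
      level = levels,
      n = unname(vapply(levels, function(l) sum(v == l, na.rm = TRUE), 0L)))
    names(out)[1] <- col
    out
  }
  ttf <- clinical$time_to_failure_months
  ttf_ok <- ttf[!is.na(ttf)]
  structure(list(
    pattern_counts = count_of("pattern",
                              c("in_field", "marginal", "out_of_field")),
    site_counts = count_of("site", c("local", "regional", "local_regional")),
    time_to_failure = tibble::tibble(
      median = if (length(ttf_ok)) median(ttf_ok) else NA_real_,
      min = if (length(ttf_ok)) min(ttf_ok) else NA_real_,
      max = if (length(ttf_ok)) max(ttf_ok) else NA_real_,
      n = length(ttf_ok)),
    flagged_rows = flagged,
    n = nrow(clinical)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> n =", x$n, "\n")
  cat("patterns:", paste(x$pattern_counts$pattern, x$pattern_counts$n,
                         sep = "=", collapse = ", "), "\n")
  cat("sites:   ", paste(x$site_counts$site, x$site_counts$n,
                         sep = "=", collapse = ", "), "\n")
  cat("time to failure: median", x$time_to_failure$median, "(range",
      x$time_to_failure$min, "-", x$time_to_failure$max, ") months\n")
  if (length(x$flagged_rows))
    cat("flagged rows:", paste(x$flagged_rows, collapse = ", "), "\n")
  invisible(x)
}

#' Classify every case of a dosimetric cohort
#'
#' Computes the isodose coverage fraction and failure-pattern class for a
#' list of [recurrence_case()] objects.
#'
#' @param cases list of [recurrence_case()] objects.
#' @param isodose_fraction see [fraction_in_isodose()].
#' @return A tibble: `case`, `fraction_in`, `pattern`, `site`,
#'   `time_to_failure_months`.
#' @export
classify_recurrences <- function(cases, isodose_fraction = 0.95) {
  fr <- vapply(cases, fraction_in_isodose, 0, isodose_fraction)
  tibble::tibble(
    case = seq_along(cases),
    fraction_in = fr,
    pattern = classify_pattern(fr),
    site = vapply(cases, function(cs) as.character(cs$site), ""),
    time_to_failure_months =
      vapply(cases, function(cs) as.numeric(cs$time_to_failure_months), 0)
  )
}
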