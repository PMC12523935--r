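# Preprocessing: coarse-graining, panel merging, plausibility filtering and
# the analyte-wise transforms between native units and Gaussian space.

#' Coarse-grain repeated measurements by month
#'
#' Multiple readings of the same analyte for one patient within one calendar
#' month are averaged to a single value, reducing the bias toward severely
#' ill, frequently tested individuals.
#'
#' @param raw long tibble with columns `patient_id`, `year`, `month`,
#'   `analyte`, `value` (extra columns such as sex/age are carried through;
#'   they must be constant within a patient).
#' @return long tibble with one row per (patient, analyte, year, month).
#' @export
coarse_grain <- function(raw) {
  need <- c("patient_id", "year", "month", "analyte", "value")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(raw$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(raw$value))))
    stop("non-numeric values at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  carry <- intersect(c("sex", "age"), names(raw))
  raw |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("patient_id", carry, "year", "month", "analyte")))) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}

#' Merge analyte panels into a wide biomarker table
#'
#' Inner-joins coarse-grained long tables by (patient, year, month) and
#' pivots to one column per analyte. Only rows complete in all requested
#' analytes are retained for joint modeling; partially observed rows are
#' returned in attribute `"incomplete"` for univariate use.
#'
#' @param ... one or more coarse-grained long tables (or a single combined
#'   one).
#' @param analytes character vector of analytes a complete row must carry.
#' @return wide tibble: patient_id, sex, age, year, month, one column per
#'   analyte.
#' @export
merge_panels <- function(..., analytes = ALL_ANALYTES) {
  long <- dplyr::bind_rows(...)
  demo <- intersect(c("sex", "age"), names(long))
  if (length(demo)) {
    conflicts <- long |>
      dplyr::distinct(dplyr::across(dplyr::all_of(
        c("patient_id", "year", "month", demo)))) |>
      dplyr::count(.data$patient_id, .data$year, .data$month) |>
      dplyr::filter(.data$n > 1)
    if (nrow(conflicts)) {
      stop("conflicting sex/age for patient-month(s): ",
           paste(utils::head(conflicts$patient_id, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  wide <- long |>
    dplyr::filter(.data$analyte %in% analytes) |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "value")
  present <- intersect(analytes, names(wide))
  if (length(present) < length(analytes)) {
    wide[setdiff(analytes, present)] <- NA_real_
  }
  complete <- stats::complete.cases(wide[analytes])
  out <- wide[complete, c("patient_id", demo, "year", "month", analytes)]
  attr(out, "incomplete") <- wide[!complete, ]
  out
}

#' Filter physiologically implausible values
#'
#' Removes rows with any analyte outside its plausibility bounds and reports
#' removals per analyte. Bounds exclude unit errors, not outliers: natural
#' population variability is preserved.
#'
#' @param table wide biomarker table (see [merge_panels()]).
#' @param specs analyte specification, [default_analyte_specs()].
#' @return list with `table` (filtered) and `report` (tibble: analyte,
#'   n_removed_low, n_removed_high).
#' @export
filter_implausible <- function(table, specs = default_analyte_specs()) {
  analytes <- intersect(specs$analyte, names(table))
  uncovered <- setdiff(intersect(ALL_ANALYTES, names(table)), specs$analyte)
  if (length(uncovered)) {
    stop("specs do not cover analyte column(s): ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  keep <- rep(TRUE, nrow(table))
  report <- lapply(analytes, function(a) {
    sp <- spec_for(specs, a)
    x <- table[[a]]
    low <- !is.na(x) & x < sp$plausible_low
    high <- !is.na(x) & x > sp$plausible_high
    keep <<- keep & !low & !high
    tibble::tibble(analyte = a, n_removed_low = sum(low), n_removed_high = sum(high))
  })
  list(table = table[keep, ], report = dplyr::bind_rows(report))
}

#' Map a biomarker table to Gaussian space
#'
#' Applies each analyte's monotone transform column-wise (log for lipids,
#' identity for A1C/CREA by default), yielding the matrix the mixture model
#' is fitted to.
#'
#' @param table wide biomarker table or numeric matrix with analyte columns.
#' @param specs analyte specification.
#' @param analytes columns to transform (default: all spec analytes present).
#' @return numeric matrix with one column per analyte, transformed.
#' @export
to_gaussian_space <- function(table, specs = default_analyte_specs(),
                              analytes = NULL) {
  analytes <- analytes %||% intersect(specs$analyte, colnames(table))
  grab <- function(a) {
    x <- if (is.data.frame(table)) table[[a]] else table[, a]
    apply_transform(as.numeric(x), spec_for(specs, a)$transform, a)
  }
  z <- vapply(analytes, grab, numeric(max(nrow(table), 0)))
  matrix(z, ncol = length(analytes), dimnames = list(NULL, analytes))
}

#' Map a Gaussian-space matrix back to native units
#'
#' Inverse of [to_gaussian_space()]; the round trip is exact to numerical
#' tolerance.
#'
#' @param z numeric matrix with analyte columns in Gaussian space.
#' @param specs analyte specification.
#' @return numeric matrix in native units.
#' @export
from_gaussian_space <- function(z, specs = default_analyte_specs()) {
  if (is.vector(z)) z <- matrix(z, nrow = 1, dimnames = list(NULL, names(z)))
  out <- z
  for (a in colnames(z)) {
    out[, a] <- invert_transform(z[, a], spec_for(specs, a)$transform)
  }
  out
}
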