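#' Analyte panel specification
#'
#' The seven biomarkers modeled jointly are the lipid panel (total cholesterol
#' CHOL, triglycerides TRIG, HDL, LDL, VLDL, all in mg/dL) plus the two
#' comorbidity markers from the metabolic panel: glycated hemoglobin A1C (%)
#' and serum creatinine CREA (mg/dL). Lipid concentrations show multiplicative
#' variability and are modeled lognormally (transform `"log"`); A1C and CREA
#' are homeostatically regulated and kept on their native scale
#' (transform `"identity"`).
#'
#' Plausibility bounds are deliberately wide: they exclude unit errors and
#' physically impossible values while preserving the natural variability of
#' the population. The defaults are package choices (overridable), not
#' clinical cutoffs.
#'
#' @param overrides optional tibble/data.frame with columns among
#'   `analyte`, `transform`, `plausible_low`, `plausible_high`, `units`;
#'   rows replace the defaults for matching analytes.
#' @return a tibble with columns `analyte`, `transform`, `plausible_low`,
#'   `plausible_high`, `units`.
#' @export
#' @examples
#' default_analyte_specs()
default_analyte_specs <- function(overrides = NULL) {
  specs <- tibble::tribble(
    ~analyte, ~transform, ~plausible_low, ~plausible_high, ~units,
    "CHOL", "log",      50,    1000, "mg/dL",
    "TRIG", "log",      20,    5000, "mg/dL",
    "HDL",  "log",       5,     200, "mg/dL",
    "LDL",  "log",      10,     800, "mg/dL",
    "VLDL", "log",       2,     500, "mg/dL",
    "A1C",  "identity",  3,      20, "%",
    "CREA", "identity",  0.1,    25, "mg/dL"
  )
  if (!is.null(overrides)) {
    overrides <- tibble::as_tibble(overrides)
    stopifnot("analyte" %in% names(overrides))
    for (i in seq_len(nrow(overrides))) {
      j <- match(overrides$analyte[i], specs$analyte)
      if (is.na(j)) {
        specs <- dplyr::bind_rows(specs, overrides[i, ])
      } else {
        for (col in setdiff(names(overrides), "analyte")) {
          specs[[col]][j] <- overrides[[col]][i]
        }
      }
    }
  }
  validate_analyte_specs(specs)
  specs
}

validate_analyte_specs <- function(specs) {
  stopifnot(all(c("analyte", "transform", "plausible_low", "plausible_high") %in%
                  names(specs)))
  if (!all(specs$transform %in% c("log", "identity"))) {
    stop("unknown transform kind; must be 'log' or 'identity'", call. = FALSE)
  }
  if (any(specs$plausible_low >= specs$plausible_high)) {
    stop("plausible_low must be < plausible_high for every analyte", call. = FALSE)
  }
  bad <- specs$transform == "log" & specs$plausible_low <= 0
  if (any(bad)) {
    stop("log transform requires plausible_low > 0 for: ",
         paste(specs$analyte[bad], collapse = ", "), call. = FALSE)
  }
  invisible(specs)
}

# Transform lookup for one analyte.
spec_for <- function(specs, analyte) {
  j <- match(analyte, specs$analyte)
  if (is.na(j)) stop("unknown analyte: ", analyte, call. = FALSE)
  specs[j, ]
}

# Forward transform of a numeric vector under a transform kind.
apply_transform <- function(x, kind, analyte = "<analyte>") {
  switch(kind,
    identity = x,
    log = {
      bad <- which(!is.na(x) & x <= 0)
      if (length(bad)) {
        stop("non-positive value under log transform for analyte ", analyte,
             " at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
             call. = FALSE)
      }
      log(x)
    },
    stop("unknown transform kind: ", kind, call. = FALSE)
  )
}

invert_transform <- function(z, kind) {
  switch(kind,
    identity = z,
    log = exp(z),
    stop("unknown transform kind: ", kind, call. = FALSE)
  )
}
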