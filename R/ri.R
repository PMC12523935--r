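# Sex/age-stratified reference-interval estimation: overall,
# comorbidity-conditioned, healthy-constrained; bootstrap uncertainties;
# Friedewald-derived analytes.

#' Default scenario conditioning values
#'
#' Diabetic sub-cohort: A1C fixed at 9.0% (well inside the unhealthy range);
#' renal sub-cohort: creatinine 2.0 mg/dL; healthy-constrained: comorbidity
#' markers pinned to healthy values A1C 5.7%, CREA 1.0 mg/dL.
#'
#' @export
default_scenarios <- function() {
  list(
    overall = NULL,
    mixture = NULL,
    diabetic = c(A1C = 9.0),
    renal = c(CREA = 2.0),
    healthy = c(A1C = 5.7, CREA = 1.0)
  )
}

scenario_distribution <- function(model, analyte, scenario, conditioning,
                                  mode = "mixture") {
  if (scenario == "overall") {
    marginal_dist(principal_component(model), analyte)
  } else if (scenario == "mixture") {
    marginal_dist(model, analyte)
  } else {
    b <- conditioning[[scenario]]
    if (is.null(b)) stop("no conditioning values for scenario: ", scenario,
                         call. = FALSE)
    mixture_conditional(model, A = analyte, b = b, mode = mode)
  }
}

#' Sex/age-stratified reference-interval curves
#'
#' For each (sex, age) stratum a Bayesian Gaussian mixture is fitted to the
#' transformed joint panel inside a sliding age window; per analyte and
#' scenario a univariate distribution is built and its central-`coverage`
#' limits are mapped back to native units:
#' * `overall`: marginal of the principal (healthy) component;
#' * `mixture`: marginal of the full mixture (includes pathological modes);
#' * `diabetic` / `renal` / `healthy`: mixture conditionals at the scenario's
#'   comorbidity-marker values (full-mixture reweighting by default).
#'
#' @param cohort wide biomarker table in native units (see [merge_panels()]).
#' @param analytes analytes to report intervals for.
#' @param scenarios subset of `names(default_scenarios())`.
#' @param ages integer ages at which to center strata.
#' @param sexes sexes to fit.
#' @param window sliding-window half-width in years.
#' @param coverage central probability mass (0.95 by convention).
#' @param conditioning named list of scenario conditioning vectors.
#' @param fit_analytes analytes entering the joint fit (defaults to the five
#'   assayed analytes; calculated LDL/VLDL are deterministic Friedewald
#'   functions of them).
#' @param specs analyte specification.
#' @param hyperparams a [fit_hyperparams()].
#' @param mode conditioning mode, `"mixture"` or `"principal"`.
#' @param models optional pre-fitted stratum models (as returned in the
#'   attribute of [weights_by_stratum()]) to avoid refitting.
#' @return tibble with columns sex, age, analyte, scenario, low, high, mean,
#'   n (stratum size). Skipped strata are absent, with a logged reason.
#' @export
estimate_ri_curves <- function(cohort,
                               analytes = c("CHOL", "TRIG", "HDL"),
                               scenarios = c("overall", "diabetic", "renal", "healthy"),
                               ages,
                               sexes = c("M", "F"),
                               window = 2,
                               coverage = 0.95,
                               conditioning = default_scenarios(),
                               fit_analytes = ASSAYED_ANALYTES,
                               specs = default_analyte_specs(),
                               hyperparams = fit_hyperparams(),
                               mode = c("mixture", "principal"),
                               models = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(scenarios %in% names(conditioning)))
  models <- models %||% fit_stratum_models(cohort, ages, sexes, window,
                                           fit_analytes, specs, hyperparams)
  rows <- list()
  for (key in names(models)) {
    model <- models[[key]]
    for (an in analytes) {
      if (!an %in% model$analytes) next
      for (sc in scenarios) {
        dist <- scenario_distribution(model, an, sc, conditioning, mode)
        qi <- quantile_interval(dist, coverage)
        rows[[length(rows) + 1]] <- tibble::tibble(
          sex = model$stratum$sex, age = model$stratum$age, analyte = an,
          scenario = sc, low = qi[["low"]], high = qi[["high"]],
          mean = attr(qi, "mean"), n = model$n_obs)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Bootstrap uncertainty of reference-interval limits
#'
#' Draws `n_boot` patient-level subsamples (without replacement, fraction
#' `frac` of patients — resampling patients rather than rows respects
#' repeated measures), refits the stratum model on each, and recomputes the
#' scenario limits. The reported limits are the bootstrap means; the errors
#' are the bootstrap standard deviations.
#'
#' @param cohort wide biomarker table in native units.
#' @param analyte single analyte.
#' @param scenario one of the scenario names.
#' @param sex,age,window stratum definition.
#' @param n_boot number of resamples (study settings: 100).
#' @param frac subsample fraction in (0, 1]; study settings: 0.5.
#' @param seed integer seed; deterministic given it.
#' @param coverage central probability mass.
#' @param conditioning scenario conditioning values.
#' @param fit_analytes,specs,hyperparams,mode as in [estimate_ri_curves()].
#' @return one-row tibble: low_mean, high_mean, low_sd, high_sd, n_ok (number
#'   of successful replicates), n_skipped.
#' @export
bootstrap_ri <- function(cohort, analyte, scenario = "overall", sex, age,
                         window = 2, n_boot = 100, frac = 0.5, seed = 1L,
                         coverage = 0.95, conditioning = default_scenarios(),
                         fit_analytes = ASSAYED_ANALYTES,
                         specs = default_analyte_specs(),
                         hyperparams = fit_hyperparams(),
                         mode = "mixture") {
  stopifnot(n_boot >= 2, frac > 0, frac <= 1)
  stratum <- cohort[cohort$sex == sex & abs(cohort$age - age) <= window, ]
  patients <- unique(stratum$patient_id)
  lims <- matrix(NA_real_, n_boot, 2)
  n_skipped <- 0
  for (i in seq_len(n_boot)) {
    set.seed(derive_seed(seed, paste0("boot", i)))
    keep <- sample(patients, floor(frac * length(patients)))
    sub <- stratum[stratum$patient_id %in% keep, ]
    hp <- hyperparams
    # one fit seed for all replicates: variability must come from the
    # resampling alone (frac = 1 then reproduces one fit exactly)
    hp$seed <- derive_seed(seed, "bootfit")
    z <- to_gaussian_space(sub, specs, fit_analytes)
    model <- suppressWarnings(fit_bgmm(z, hp, specs,
                                       stratum = list(sex = sex, age = age)))
    if (is.null(model)) {
      n_skipped <- n_skipped + 1
      next
    }
    dist <- scenario_distribution(model, analyte, scenario, conditioning, mode)
    lims[i, ] <- quantile_interval(dist, coverage)
  }
  if (n_skipped) {
    message(n_skipped, " bootstrap replicate(s) skipped (stratum too small ",
            "after subsampling)")
  }
  ok <- stats::complete.cases(lims)
  tibble::tibble(
    analyte = analyte, scenario = scenario, sex = sex, age = age,
    low_mean = mean(lims[ok, 1]), high_mean = mean(lims[ok, 2]),
    low_sd = stats::sd(lims[ok, 1]), high_sd = stats::sd(lims[ok, 2]),
    n_ok = sum(ok), n_skipped = n_skipped)
}

#' Friedewald calculation of VLDL and LDL
#'
#' `VLDL = TRIG / 5` and `LDL = CHOL - HDL - VLDL` (all mg/dL), the standard
#' calculated-LDL relations used by clinical laboratories. The estimate is
#' unreliable above a triglyceride ceiling (default 400 mg/dL; warned), and
#' a negative LDL result is flagged but retained.
#'
#' @param chol,hdl,trig positive numeric vectors, mg/dL.
#' @param trig_ceiling validity ceiling for triglycerides.
#' @return tibble with columns `vldl`, `ldl`, `ldl_flagged`.
#' @export
#' @examples
#' friedewald(200, 50, 150)  # vldl 30, ldl 120
friedewald <- function(chol, hdl, trig, trig_ceiling = 400) {
  if (any(chol <= 0) || any(hdl <= 0) || any(trig <= 0)) {
    stop("chol, hdl and trig must be positive", call. = FALSE)
  }
  if (any(trig > trig_ceiling)) {
    warning("triglycerides above ", trig_ceiling,
            " mg/dL: Friedewald LDL is unreliable")
  }
  vldl <- trig / 5
  ldl <- chol - hdl - vldl
  flagged <- ldl < 0
  if (any(flagged)) {
    warning(sum(flagged), " negative LDL result(s) flagged (value retained)")
  }
  tibble::tibble(vldl = vldl, ldl = ldl, ldl_flagged = flagged)
}
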