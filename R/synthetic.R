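# Synthetic cohort generator.
#
# Replaces the proprietary clinical datalake with a generator whose ground
# truth is known: per (sex, age) the population is a mixture of a dominant
# healthy component and a small number of pathological "satellite" components
# (diabetic-like, renal-like) in the transformed space of the five assayed
# analytes; LDL and VLDL are then derived exactly by the Friedewald relations,
# as clinical laboratories do. Pathological prevalence increases with age and
# a Gompertz mortality process removes high-risk individuals preferentially.

ASSAYED_ANALYTES <- c("CHOL", "TRIG", "HDL", "A1C", "CREA")
ALL_ANALYTES <- c("CHOL", "TRIG", "HDL", "LDL", "VLDL", "A1C", "CREA")

default_corr <- function() {
  nm <- ASSAYED_ANALYTES
  r <- diag(5)
  dimnames(r) <- list(nm, nm)
  set_r <- function(a, b, v) {
    r[a, b] <<- v
    r[b, a] <<- v
  }
  set_r("CHOL", "TRIG", 0.30); set_r("CHOL", "HDL", 0.05)
  set_r("CHOL", "A1C", 0.10);  set_r("CHOL", "CREA", 0.05)
  set_r("TRIG", "HDL", -0.40); set_r("TRIG", "A1C", 0.25)
  set_r("TRIG", "CREA", 0.10); set_r("HDL", "A1C", -0.10)
  set_r("HDL", "CREA", -0.05); set_r("A1C", "CREA", 0.05)
  r
}

cov_from <- function(sds, corr = default_corr()) {
  s <- diag(sds, nrow = length(sds))
  m <- s %*% corr %*% s
  dimnames(m) <- dimnames(corr)
  m
}

#' Default Gompertz mortality parameters
#'
#' Hazard model `h(x) = intercept * exp(slope * x)` at age `x` (annual death
#' probability), multiplied by `risk_multiplier` for patients belonging to a
#' pathological mixture component. Defaults give an annual rate of about
#' 5e-5 at birth and 5% at age 80, a realistic human Gompertz regime; the
#' multiplier of 3 encodes the excess mortality of the high-risk subgroups.
#'
#' @param gompertz_intercept baseline annual rate at age 0 (non-negative).
#' @param gompertz_slope log-hazard increase per year of age (non-negative).
#' @param risk_multiplier hazard ratio for satellite-labeled patients.
#' @export
default_mortality_params <- function(gompertz_intercept = 5.5e-5,
                                     gompertz_slope = 0.085,
                                     risk_multiplier = 3) {
  p <- list(gompertz_intercept = gompertz_intercept,
            gompertz_slope = gompertz_slope,
            risk_multiplier = risk_multiplier)
  if (p$gompertz_intercept < 0 || p$gompertz_slope < 0) {
    stop("hazard parameters must be non-negative", call. = FALSE)
  }
  if (p$risk_multiplier < 0) stop("risk_multiplier must be >= 0", call. = FALSE)
  p
}

default_satellites <- function() {
  list(
    diabetic = list(
      weight_base = 0.20, weight_slope = 0.0033,
      mean_offset = c(CHOL = 0.15, TRIG = 0.55, HDL = -0.25, A1C = 3.1, CREA = 0.05),
      sds = c(CHOL = 0.20, TRIG = 0.40, HDL = 0.24, A1C = 1.30, CREA = 0.15)
    ),
    renal = list(
      weight_base = 0.10, weight_slope = 0.0020,
      mean_offset = c(CHOL = 0.22, TRIG = 0.45, HDL = -0.10, A1C = 0.30, CREA = 1.15),
      sds = c(CHOL = 0.20, TRIG = 0.40, HDL = 0.24, A1C = 0.45, CREA = 0.55)
    )
  )
}

default_healthy <- function() {
  list(
    base_means = list(
      M = c(CHOL = log(175), TRIG = log(100), HDL = log(48), A1C = 5.20, CREA = 0.95),
      F = c(CHOL = log(170), TRIG = log(85),  HDL = log(58), A1C = 5.15, CREA = 0.75)
    ),
    # piecewise-linear rise from rise_ages[1] to rise_ages[2], flat after
    midlife_rise = c(CHOL = 0.13, TRIG = 0.35, HDL = 0, A1C = 0.5, CREA = 0),
    rise_ages = c(20, 55),
    sds = c(CHOL = 0.17, TRIG = 0.35, HDL = 0.22, A1C = 0.35, CREA = 0.13)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' The stated world: a dominant approximately (log)normal healthy component
#' per sex with lipid means rising piecewise-linearly to midlife, plus
#' pathological satellites whose prevalence increases with age
#' (weight `= base + slope * (age - 50)`, clamped to `[0, 0.95]`), and a
#' Gompertz mortality process with elevated hazard for satellite members.
#' Mean offsets place the diabetic satellite around A1C 8.5% and the renal
#' satellite around CREA 2.1 mg/dL so that the conditioning values used for
#' comorbidity-conditioned reference intervals (A1C 9.0, CREA 2.0) land
#' inside the respective satellite.
#'
#' @param n_patients number of patients to simulate.
#' @param age_range inclusive integer age range in years.
#' @param sex_ratio fraction male in `[0, 1]`.
#' @param healthy list with `base_means` (per sex, transformed space, assayed
#'   analytes CHOL/TRIG/HDL/A1C/CREA), `midlife_rise`, `rise_ages`, `sds`,
#'   and optionally `corr`.
#' @param satellites named list of satellite components, each with
#'   `weight_base`, `weight_slope`, `mean_offset` (transformed space),
#'   `sds`, optionally `corr`.
#' @param mortality see [default_mortality_params()].
#' @param separation scalar multiplying all satellite mean offsets; exposes
#'   the (unknown in real data) healthy/pathological overlap as a parameter.
#' @param repeat_fraction fraction of patients receiving 2-4 same-month
#'   readings (exercises coarse-graining).
#' @param years calendar years tests may fall in.
#' @param seed master integer seed; all randomness derives from it.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 20000,
                          age_range = c(20, 85),
                          sex_ratio = 0.42,
                          healthy = default_healthy(),
                          satellites = default_satellites(),
                          mortality = default_mortality_params(),
                          separation = 1,
                          repeat_fraction = 0.05,
                          years = 2019:2024,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), age_range = as.integer(age_range),
              sex_ratio = sex_ratio, healthy = healthy, satellites = satellites,
              mortality = mortality, separation = separation,
              repeat_fraction = repeat_fraction, years = years,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_patients > 0, length(cfg$age_range) == 2,
            cfg$age_range[1] <= cfg$age_range[2],
            cfg$sex_ratio >= 0, cfg$sex_ratio <= 1,
            cfg$repeat_fraction >= 0, cfg$repeat_fraction <= 1)
  hc <- cov_from(cfg$healthy$sds, cfg$healthy$corr %||% default_corr())
  if (!is_spd(hc)) stop("healthy covariance is not positive definite", call. = FALSE)
  ages <- seq(cfg$age_range[1], cfg$age_range[2])
  for (nm in names(cfg$satellites)) {
    wb <- cfg$satellites[[nm]]$weight_base
    if (wb < 0 || wb > 1) {
      stop("satellite weight_base must be in [0,1]: ", nm, call. = FALSE)
    }
  }
  wsat <- sapply(cfg$satellites, function(s) satellite_weight(s, ages))
  if (length(cfg$satellites)) {
    wsat <- matrix(wsat, nrow = length(ages))
    if (any(wsat < 0) || any(rowSums(wsat) > 1)) {
      stop("satellite weights must be in [0,1] and sum to <= 1 at every age",
           call. = FALSE)
    }
    for (nm in names(cfg$satellites)) {
      sc <- cov_from(cfg$satellites[[nm]]$sds,
                     cfg$satellites[[nm]]$corr %||% default_corr())
      if (!is_spd(sc)) {
        stop("satellite covariance not positive definite: ", nm, call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

satellite_weight <- function(sat, age) {
  pmin(pmax(sat$weight_base + sat$weight_slope * (age - 50), 0), 0.95)
}

healthy_mean <- function(healthy, sex, age) {
  r <- healthy$rise_ages
  frac <- pmin(pmax((age - r[1]) / (r[2] - r[1]), 0), 1)
  healthy$base_means[[sex]] + healthy$midlife_rise * frac
}

#' True mixture parameters of the generator at one stratum
#'
#' @param config a [cohort_config()].
#' @param sex `"M"` or `"F"`.
#' @param age integer age in years.
#' @return list with `components` (names), `weights`, `means` (list of
#'   transformed-space mean vectors over the assayed analytes), `covs`.
#' @export
true_component_params <- function(config, sex, age) {
  wsat <- vapply(config$satellites, satellite_weight, numeric(1), age = age)
  w <- c(healthy = 1 - sum(wsat), wsat)
  mu_h <- healthy_mean(config$healthy, sex, age)
  means <- c(list(healthy = mu_h),
             lapply(config$satellites, function(s) {
               mu_h + config$separation * s$mean_offset[names(mu_h)]
             }))
  covs <- c(list(healthy = cov_from(config$healthy$sds,
                                    config$healthy$corr %||% default_corr())),
            lapply(config$satellites, function(s) {
              cov_from(s$sds, s$corr %||% default_corr())
            }))
  list(components = names(w), weights = w, means = means, covs = covs)
}

# Draw assayed-analyte values (native units) for given component labels,
# redrawing the few rows whose implied Friedewald LDL would fall below
# ldl_min (keeps LDL positive so the log transform is defined).
draw_native <- function(config, sex, age, component, ldl_min = 10) {
  n <- length(sex)
  z <- matrix(NA_real_, n, 5, dimnames = list(NULL, ASSAYED_ANALYTES))
  comps <- unique(component)
  for (cmp in comps) {
    idx <- which(component == cmp)
    # stratum means differ by (sex, age); build per-row means, shared cov
    if (cmp == "healthy") {
      sds <- config$healthy$sds
      corr <- config$healthy$corr %||% default_corr()
      off <- rep(0, 5)
    } else {
      s <- config$satellites[[cmp]]
      sds <- s$sds
      corr <- s$corr %||% default_corr()
      off <- config$separation * s$mean_offset[ASSAYED_ANALYTES]
    }
    U <- chol(cov_from(sds, corr))
    eps <- matrix(stats::rnorm(length(idx) * 5), ncol = 5) %*% U
    mu <- t(vapply(idx, function(i) {
      healthy_mean(config$healthy, sex[i], age[i]) + off
    }, numeric(5)))
    z[idx, ] <- mu + eps
  }
  native <- z
  for (j in c("CHOL", "TRIG", "HDL")) native[, j] <- exp(z[, j])
  ldl <- native[, "CHOL"] - native[, "HDL"] - native[, "TRIG"] / 5
  bad <- which(ldl < ldl_min)
  guard <- 0
  while (length(bad) && guard < 100) {
    redraw <- draw_native(config, sex[bad], age[bad], component[bad], ldl_min)
    native[bad, ] <- redraw
    ldl <- native[, "CHOL"] - native[, "HDL"] - native[, "TRIG"] / 5
    bad <- which(ldl < ldl_min)
    guard <- guard + 1
  }
  native
}

#' Generate a synthetic laboratory cohort with ground truth
#'
#' Produces a long-format result table (one row per patient per analyte per
#' reading) over the seven-analyte panel. LDL and VLDL satisfy the Friedewald
#' identities `VLDL = TRIG/5`, `LDL = CHOL - HDL - VLDL` exactly on every
#' generated row. Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with `results` (tibble: patient_id, sex, age, year, month,
#'   analyte, value) and `truth` (list: `labels` tibble with the true
#'   component of each patient, plus the generating `config`).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(derive_seed(config$seed, "cohort"))
  n <- config$n_patients
  patient_id <- sprintf("P%07d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "M", "F")
  ages_avail <- seq(config$age_range[1], config$age_range[2])
  age <- ages_avail[sample.int(length(ages_avail), n, replace = TRUE)]
  year <- config$years[sample.int(length(config$years), n, replace = TRUE)]
  month <- sample.int(12, n, replace = TRUE)

  # component label per patient from the age-dependent weights
  sat_names <- names(config$satellites)
  wmat <- cbind(healthy = 1, vapply(config$satellites, satellite_weight,
                                    numeric(n), age = age))
  if (length(sat_names)) wmat[, 1] <- 1 - rowSums(wmat[, -1, drop = FALSE])
  u <- stats::runif(n)
  cum <- wmat
  if (ncol(wmat) > 1) for (j in 2:ncol(wmat)) cum[, j] <- cum[, j - 1] + wmat[, j]
  component <- colnames(wmat)[max.col(u <= cum, ties.method = "first")]

  native <- draw_native(config, sex, age, component)

  n_extra <- integer(n)
  if (config$repeat_fraction > 0) {
    rep_idx <- which(stats::runif(n) < config$repeat_fraction)
    n_extra[rep_idx] <- sample(1:3, length(rep_idx), replace = TRUE)
  }
  reading_of <- rep(seq_len(n), 1 + n_extra)
  vals <- native[reading_of, , drop = FALSE]
  extra <- which(duplicated(reading_of))
  if (length(extra)) {
    # within-month repeat readings jitter the assayed analytes slightly
    jit <- matrix(stats::rnorm(length(extra) * 5, sd = 0.03), ncol = 5)
    for (j in 1:3) vals[extra, j] <- vals[extra, j] * exp(jit[, j])  # lipids
    vals[extra, 4] <- pmax(vals[extra, 4] * (1 + jit[, 4]), 3.2)     # A1C
    vals[extra, 5] <- pmax(vals[extra, 5] * (1 + jit[, 5]), 0.15)    # CREA
  }
  vldl <- vals[, "TRIG"] / 5
  ldl <- vals[, "CHOL"] - vals[, "HDL"] - vldl
  wide <- cbind(vals[, c("CHOL", "TRIG", "HDL"), drop = FALSE],
                LDL = ldl, VLDL = vldl,
                vals[, c("A1C", "CREA"), drop = FALSE])

  m <- nrow(wide)
  results <- tibble::tibble(
    patient_id = rep(patient_id[reading_of], each = 7),
    sex = rep(sex[reading_of], each = 7),
    age = rep(age[reading_of], each = 7),
    year = rep(year[reading_of], each = 7),
    month = rep(month[reading_of], each = 7),
    analyte = rep(ALL_ANALYTES, m),
    value = as.vector(t(wide))
  )
  results <- dplyr::arrange(results, .data$patient_id, .data$analyte)

  truth <- list(
    labels = tibble::tibble(patient_id = patient_id, sex = sex, age = age,
                            component = component),
    config = config
  )
  list(results = results, truth = truth)
}

#' Thin a cohort by selective Gompertz mortality
#'
#' Each patient survives to their test age with probability
#' `prod_x (1 - min(1, h(x) * m_i))` over ages `x = 0 .. age-1`, where
#' `h(x) = intercept * exp(slope * x)` and `m_i` is `risk_multiplier` for
#' satellite-labeled patients (1 for healthy). The least healthy are thereby
#' removed preferentially at older ages, shifting the observed distribution
#' toward healthier values.
#'
#' @param cohort long result table from [generate_cohort()].
#' @param ground_truth the `truth` element from [generate_cohort()].
#' @param mortality_params see [default_mortality_params()].
#' @param seed integer seed for the survival draws.
#' @return the survivors-only long table; survivor ids in attribute
#'   `"survivors"`.
#' @export
apply_selective_mortality <- function(cohort, ground_truth,
                                      mortality_params = default_mortality_params(),
                                      seed = 1L) {
  p <- mortality_params
  if (p$gompertz_intercept < 0 || p$gompertz_slope < 0) {
    stop("hazard parameters must be non-negative", call. = FALSE)
  }
  labels <- ground_truth$labels
  set.seed(derive_seed(seed, "mortality"))
  max_age <- max(labels$age)
  haz <- p$gompertz_intercept * exp(p$gompertz_slope * (0:(max_age - 1)))
  logS <- function(mult) c(0, cumsum(log1p(-pmin(haz * mult, 1))))
  ls_healthy <- logS(1)
  ls_risk <- logS(p$risk_multiplier)
  surv_prob <- ifelse(labels$component == "healthy",
                      exp(ls_healthy[labels$age + 1]),
                      exp(ls_risk[labels$age + 1]))
  alive <- stats::runif(nrow(labels)) < surv_prob
  survivors <- labels$patient_id[alive]
  out <- dplyr::filter(cohort, .data$patient_id %in% survivors)
  attr(out, "survivors") <- survivors
  out
}

#' Generate census-style population counts
#'
#' Simulates year-over-year population tables (sex, age, year, count) that
#' decrement by the same Gompertz hazard used for selective mortality, so the
#' mortality-estimation module can be validated against known parameters. A
#' constant birth inflow keeps age 0 full each year. In deterministic mode
#' counts are exact (fractional) products; in stochastic mode survivors are
#' binomially sampled.
#'
#' @param population_size total initial population across ages and sexes.
#' @param mortality_params either a single parameter list (see
#'   [default_mortality_params()]) applied to both sexes, with female hazard
#'   scaled by `female_factor`, or a named list `list(M = ..., F = ...)`.
#' @param years at least two consecutive calendar years.
#' @param seed integer seed (stochastic mode).
#' @param stochastic logical; binomial sampling of survivor counts.
#' @param age_range inclusive integer ages covered.
#' @param female_factor hazard scale for females when one parameter set given.
#' @return tibble with columns sex, age, year, count.
#' @export
generate_census_counts <- function(population_size = 2e6,
                                   mortality_params = default_mortality_params(),
                                   years = 2020:2024,
                                   seed = 1L,
                                   stochastic = TRUE,
                                   age_range = c(0, 100),
                                   female_factor = 0.6) {
  years <- sort(as.integer(years))
  if (length(years) < 2) {
    stop("at least 2 consecutive years are required (no successive-year pairs)",
         call. = FALSE)
  }
  if (!all(diff(years) == 1)) stop("years must be consecutive", call. = FALSE)
  if (!is.null(mortality_params$gompertz_intercept)) {
    pf <- mortality_params
    pf$gompertz_intercept <- pf$gompertz_intercept * female_factor
    mortality_params <- list(M = mortality_params, F = pf)
  }
  set.seed(derive_seed(seed, "census"))
  ages <- seq(age_range[1], age_range[2])
  n_age <- length(ages)
  init <- population_size / (n_age * 2)
  out <- list()
  for (sx in c("M", "F")) {
    p <- mortality_params[[sx]]
    if (p$gompertz_intercept < 0 || p$gompertz_slope < 0) {
      stop("hazard parameters must be non-negative", call. = FALSE)
    }
    rate <- pmin(p$gompertz_intercept * exp(p$gompertz_slope * ages), 1)
    counts <- matrix(NA_real_, n_age, length(years),
                     dimnames = list(ages, years))
    counts[, 1] <- if (stochastic) round(init) else init
    for (t in seq_along(years)[-1]) {
      prev <- counts[, t - 1]
      surv <- if (stochastic) {
        stats::rbinom(n_age - 1, round(prev[-n_age]), 1 - rate[-n_age])
      } else {
        prev[-n_age] * (1 - rate[-n_age])
      }
      counts[, t] <- c(counts[1, 1], surv)
    }
    out[[sx]] <- tibble::tibble(
      sex = sx,
      age = rep(ages, length(years)),
      year = rep(years, each = n_age),
      count = as.vector(counts)
    )
  }
  dplyr::bind_rows(out)
}
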