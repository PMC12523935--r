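# Generator: determinism, mixture structure, Friedewald identities,
# selective mortality, census counts.

test_that("cohort generation is deterministic and labels follow the mixture", {
  cfg <- cohort_config(n_patients = 2000, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$results, b$results)
  expect_identical(a$truth$labels, b$truth$labels)

  # zero satellite weight -> everyone healthy
  cfg0 <- cohort_config(n_patients = 1000, satellites = list(), seed = 2)
  sim0 <- generate_cohort(cfg0)
  expect_true(all(sim0$truth$labels$component == "healthy"))

  # constant satellite weight 0.3 -> empirical fraction within 0.3 +- 0.01
  sat <- list(one = list(weight_base = 0.3, weight_slope = 0,
                         mean_offset = c(CHOL = 0.2, TRIG = 0.4, HDL = -0.2,
                                         A1C = 2, CREA = 0.5),
                         sds = refmix:::default_satellites()$diabetic$sds))
  cfg3 <- cohort_config(n_patients = 50000, satellites = sat,
                        repeat_fraction = 0, seed = 3)
  sim3 <- generate_cohort(cfg3)
  expect_equal(mean(sim3$truth$labels$component == "one"), 0.3,
               tolerance = 0.01 / 0.3)
})

test_that("Friedewald identities hold exactly on every generated row", {
  sim <- fixture_small_cohort()$sim
  wide <- sim$results |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "value",
                       values_fn = list)  |>
    tidyr::unnest(cols = dplyr::all_of(refmix:::ALL_ANALYTES))
  expect_equal(wide$VLDL, wide$TRIG / 5, tolerance = 0)
  expect_equal(wide$LDL, wide$CHOL - wide$HDL - wide$VLDL, tolerance = 0)
  expect_true(all(wide$LDL > 0))
})

test_that("healthy-labeled stratum means converge to configured truth", {
  cfg <- cohort_config(n_patients = 20000, age_range = c(50, 50), sex_ratio = 1,
                       satellites = list(), repeat_fraction = 0, seed = 4)
  sim <- generate_cohort(cfg)
  wide <- merge_panels(coarse_grain(sim$results))
  z <- to_gaussian_space(wide, analytes = refmix:::ASSAYED_ANALYTES)
  tp <- true_component_params(cfg, "M", 50)
  se <- sqrt(diag(tp$covs$healthy) / nrow(z))
  expect_true(all(abs(colMeans(z) - tp$means$healthy) < 3 * se))
  # covariance close too (relative, loose)
  expect_equal(unname(stats::cov(z)), unname(tp$covs$healthy), tolerance = 0.1)
})

test_that("selective mortality: null case, strong culling, zero hazard", {
  fx <- fixture_stratum()   # ages 50-54, labels known
  labels <- fx$sim$truth$labels

  # risk_multiplier = 1: survival independent of component
  p1 <- default_mortality_params(risk_multiplier = 1)
  thin1 <- apply_selective_mortality(fx$sim$results, fx$sim$truth, p1, seed = 9)
  alive <- labels$patient_id %in% attr(thin1, "survivors")
  tab <- table(labels$component == "healthy", alive)
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.01)

  # zero hazard: everyone survives
  p0 <- default_mortality_params(0, 0, 3)
  thin0 <- apply_selective_mortality(fx$sim$results, fx$sim$truth, p0, seed = 9)
  expect_identical(nrow(thin0), nrow(fx$sim$results))

  # negative hazard parameters rejected
  expect_error(default_mortality_params(-1e-4, 0.08), "non-negative")

  # determinism
  thin1b <- apply_selective_mortality(fx$sim$results, fx$sim$truth, p1, seed = 9)
  expect_identical(as.data.frame(thin1), as.data.frame(thin1b))
})

test_that("strong selective mortality lowers old-age survivor cholesterol", {
  cfg <- cohort_config(n_patients = 15000, age_range = c(60, 85), seed = 6,
                       repeat_fraction = 0)
  sim <- generate_cohort(cfg)
  pbig <- default_mortality_params(risk_multiplier = 10)
  thin <- apply_selective_mortality(sim$results, sim$truth, pbig, seed = 6)
  pre <- sim$results
  old_chol <- function(tab) {
    mean(tab$value[tab$analyte == "CHOL" & tab$age > 70])
  }
  expect_lt(old_chol(thin), old_chol(pre))
})

test_that("census counts follow the configured decrement", {
  # deterministic mode with flat 1% mortality: exact 0.99 ratio
  p <- default_mortality_params(0.01, 0, 1)
  cen <- generate_census_counts(1e6, p, years = 2020:2022, stochastic = FALSE,
                                age_range = c(0, 30), female_factor = 1)
  c60 <- cen$count[cen$sex == "M" & cen$age == 10 & cen$year == 2020]
  c61 <- cen$count[cen$sex == "M" & cen$age == 11 & cen$year == 2021]
  expect_equal(c61, 0.99 * c60, tolerance = 1e-12)

  # single year: no successive pairs
  expect_error(generate_census_counts(1e5, p, years = 2020), "2 consecutive")

  # seed determinism (stochastic mode)
  a <- generate_census_counts(1e5, years = 2020:2021, seed = 5)
  b <- generate_census_counts(1e5, years = 2020:2021, seed = 5)
  expect_identical(a, b)
})

test_that("survivor fraction matches the product of annual survival", {
  cfg <- cohort_config(n_patients = 30000, age_range = c(80, 80),
                       satellites = list(), repeat_fraction = 0, seed = 8)
  sim <- generate_cohort(cfg)
  p <- default_mortality_params()
  thin <- apply_selective_mortality(sim$results, sim$truth, p, seed = 8)
  frac <- length(attr(thin, "survivors")) / 30000
  haz <- pmin(p$gompertz_intercept * exp(p$gompertz_slope * (0:79)), 1)
  s80 <- prod(1 - haz)
  expect_equal(frac, s80, tolerance = 4 * sqrt(s80 * (1 - s80) / 30000) / s80)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(sex_ratio = 1.2))
  bad_sat <- list(x = list(weight_base = 1.2, weight_slope = 0,
                           mean_offset = c(CHOL = 0, TRIG = 0, HDL = 0,
                                           A1C = 0, CREA = 0),
                           sds = rep(0.1, 5)))
  expect_error(cohort_config(satellites = bad_sat), "sum to <= 1|\\[0,1\\]")
  bad_cov <- refmix:::default_healthy()
  bad_cov$corr <- matrix(1, 5, 5)  # singular
  expect_error(cohort_config(healthy = bad_cov), "positive definite")
})
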