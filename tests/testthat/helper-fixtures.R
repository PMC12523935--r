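# Shared fixtures, built in code and cached for the session (several test
# files reuse the same seeded cohort and fitted model).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# satellites with age-constant weights (0.2 diabetic, 0.1 renal)
const_satellites <- function() {
  sats <- refmix:::default_satellites()
  sats$diabetic$weight_slope <- 0
  sats$renal$weight_slope <- 0
  sats
}

# one single-sex 20k stratum with constant satellite weights; the standard
# parameter-recovery world (healthy fraction 0.70, satellites 0.2/0.1)
fixture_stratum <- function() {
  cached("stratum", function() {
    cfg <- cohort_config(n_patients = 20000, age_range = c(50, 54),
                         sex_ratio = 1, satellites = const_satellites(),
                         repeat_fraction = 0, seed = 1)
    sim <- generate_cohort(cfg)
    wide <- merge_panels(coarse_grain(sim$results))
    list(config = cfg, sim = sim, wide = wide)
  })
}

# mixture model fitted to the fixture stratum (single restart for runtime)
fixture_model <- function() {
  cached("stratum_model", function() {
    fx <- fixture_stratum()
    z <- to_gaussian_space(fx$wide, analytes = refmix:::ASSAYED_ANALYTES)
    fit_bgmm(z, fit_hyperparams(seed = 1, n_restarts = 1))
  })
}

# small mixed two-sex cohort for RI-curve and network tests
fixture_small_cohort <- function() {
  cached("small_cohort", function() {
    cfg <- cohort_config(n_patients = 6000, age_range = c(40, 70), seed = 5)
    sim <- generate_cohort(cfg)
    wide <- merge_panels(coarse_grain(sim$results))
    list(config = cfg, sim = sim, wide = wide)
  })
}

# hand-built mixture_model object (no fitting) for selection-rule tests
toy_model <- function(weights, dets = rep(1, length(weights))) {
  K <- length(weights)
  means <- matrix(seq_len(K), K, 2)
  colnames(means) <- c("x", "y")
  covs <- lapply(dets, function(d) diag(c(d, 1)))
  covs <- lapply(covs, function(m) { dimnames(m) <- list(c("x", "y"), c("x", "y")); m })
  structure(list(analytes = c("x", "y"), specs = NULL, weights = weights,
                 means = means, covariances = covs, stratum = NULL,
                 n_obs = 100, hyperparams = fit_hyperparams(), n_iter = 1,
                 converged = TRUE, lower_bound = 0, lb_trace = 0),
            class = "mixture_model")
}
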