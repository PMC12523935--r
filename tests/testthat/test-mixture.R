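# Bayesian Gaussian mixture: parameter recovery, determinism, principal
# component selection, stratified weight profiles, serialization, and a
# cross-check against an independent variational implementation.

test_that("a single 7-D Gaussian is recovered as one dominant component", {
  set.seed(101)
  mu <- c(5.2, 4.8, 3.9, 5.5, 0.9, 4.7, 3.2)
  A <- matrix(stats::rnorm(49, sd = 0.1), 7, 7)
  sigma <- crossprod(A) + diag(0.05, 7)
  z <- refmix:::rmvnorm_chol(20000, mu, sigma)
  colnames(z) <- paste0("v", 1:7)
  m <- fit_bgmm(z, fit_hyperparams(seed = 1, n_restarts = 1))
  pc <- principal_component(m)
  expect_gt(attr(pc, "weight"), 0.95)
  se <- sqrt(diag(sigma) / 20000)
  expect_true(all(abs(pc$mean - mu) < 3 * se))
})

test_that("two well-separated components are recovered with correct weights", {
  set.seed(202)
  n <- 20000
  lab <- stats::runif(n) < 0.7
  z <- cbind(a = ifelse(lab, 0, 5) + stats::rnorm(n),
             b = ifelse(lab, 0, 5) + stats::rnorm(n))
  m <- fit_bgmm(z, fit_hyperparams(seed = 1, n_restarts = 1))
  w <- sort(m$weights, decreasing = TRUE)
  expect_equal(sum(m$weights > 0.05), 2)
  expect_equal(w[1], mean(lab), tolerance = 0.02 / w[1])
  expect_equal(w[2], 1 - mean(lab), tolerance = 0.02 / w[2])

  # determinism: same seed twice -> identical weights to machine precision
  m2 <- fit_bgmm(z, fit_hyperparams(seed = 1, n_restarts = 1))
  expect_identical(m$weights, m2$weights)
  expect_identical(m$means, m2$means)
})

test_that("fit guards: small strata and singular covariance", {
  z <- matrix(stats::rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(out <- fit_bgmm(z, fit_hyperparams(min_stratum_n = 500)),
                 "below minimum")
  expect_null(out)
  zs <- cbind(a = stats::rnorm(1000), b = 0)
  zs <- cbind(zs, c = zs[, "a"])   # exactly collinear
  expect_error(fit_bgmm(zs, fit_hyperparams()), "singular")
})

test_that("principal component selection: argmax weight, det tie-break", {
  m <- toy_model(c(0.6, 0.3, 0.1))
  expect_equal(attr(principal_component(m), "component"), 1)
  m1 <- toy_model(1)
  expect_equal(attr(principal_component(m1), "component"), 1)
  # exact tie 0.5/0.5; det 2 vs det 1 -> the det-1 component wins
  mt <- toy_model(c(0.5, 0.5), dets = c(2, 1))
  expect_equal(attr(principal_component(mt), "component"), 2)
})

test_that("stratified weight profiles track pathological prevalence", {
  fx <- fixture_small_cohort()   # age-increasing satellite weights
  hp <- fit_hyperparams(seed = 1, n_restarts = 1)
  wbs <- weights_by_stratum(fx$wide, ages = c(45, 55, 65), sexes = "F",
                            window = 4, hyperparams = hp)
  sums <- tapply(wbs$weight, wbs$age, sum)
  expect_true(all(abs(sums - 1) < 1e-8))
  r1 <- wbs$weight[wbs$rank == 1]
  expect_lt(stats::cor(r1, c(45, 55, 65), method = "spearman"), 0)

  # no satellites: rank-1 weight > 0.9 at every age
  cfg0 <- cohort_config(n_patients = 5000, age_range = c(40, 70),
                        satellites = list(), seed = 12)
  wide0 <- merge_panels(coarse_grain(generate_cohort(cfg0)$results))
  wbs0 <- weights_by_stratum(wide0, ages = c(50, 60), sexes = "F", window = 4,
                             hyperparams = hp)
  expect_true(all(wbs0$weight[wbs0$rank == 1] > 0.9))
})

test_that("healthy points are likelier under the principal component", {
  fx <- fixture_stratum()
  m <- fixture_model()
  z <- to_gaussian_space(fx$wide, analytes = refmix:::ASSAYED_ANALYTES)
  healthy <- fx$sim$truth$labels$component[
    match(fx$wide$patient_id, fx$sim$truth$labels$patient_id)] == "healthy"
  k_pc <- attr(principal_component(m), "component")
  active <- which(m$weights > 0.05)
  ll <- vapply(active, function(k) {
    refmix:::dmvnorm_log(z[healthy, ], m$means[k, ], m$covariances[[k]])
  }, numeric(sum(healthy)))
  best <- active[max.col(ll)]
  expect_gt(mean(best == k_pc), 0.95)
  # principal weight in the observed 40-80% band for healthy fraction 0.7
  expect_gt(max(m$weights), 0.40)
  expect_lt(max(m$weights), 0.80)
})

test_that("model serialization round-trips", {
  m <- fixture_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_mixture_model(m, path)
  m2 <- read_mixture_model(path)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  expect_equal(m2$means, m$means, tolerance = 1e-12)
  expect_equal(m2$covariances, m$covariances, tolerance = 1e-12)
  expect_identical(m2$analytes, m$analytes)
})

test_that("fit agrees with an independent variational implementation", {
  # scikit-learn's BayesianGaussianMixture, same priors, as external oracle
  set.seed(33)
  n <- 3000
  lab <- stats::runif(n) < 0.65
  z <- cbind(x = ifelse(lab, 0, 4) + stats::rnorm(n),
             y = ifelse(lab, 1, -3) + stats::rnorm(n))
  m <- fit_bgmm(z, fit_hyperparams(seed = 1))
  csv <- withr::local_tempfile(fileext = ".csv")
  out <- withr::local_tempfile(fileext = ".json")
  utils::write.csv(z, csv, row.names = FALSE)
  script <- sprintf('
import json, numpy as np, pandas as pd
from sklearn.mixture import BayesianGaussianMixture
z = pd.read_csv("%s").values
S = np.cov(z.T)
bg = BayesianGaussianMixture(n_components=7, covariance_type="full",
    weight_concentration_prior_type="dirichlet_process",
    weight_concentration_prior=1e-6, mean_precision_prior=200.0,
    mean_prior=np.median(z, axis=0),
    covariance_prior=S + 1e-3*np.diag(np.diag(S)),
    degrees_of_freedom_prior=2, max_iter=2000, tol=1e-4, n_init=3,
    random_state=1)
bg.fit(z)
o = np.argsort(bg.weights_)[::-1][:2]
json.dump({"w": bg.weights_[o].tolist(), "m": bg.means_[o].tolist()},
          open("%s", "w"))
', csv, out)
  status <- system2("python", "-", input = script,
                    stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  ref <- jsonlite::read_json(out, simplifyVector = TRUE)
  ord <- order(m$weights, decreasing = TRUE)[1:2]
  expect_equal(unname(m$weights[ord]), ref$w, tolerance = 0.02)
  expect_equal(unname(m$means[ord, ]), ref$m, tolerance = 0.05)
})
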