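# Variational Bayesian Gaussian mixture with a Dirichlet-process
# (stick-breaking) prior over the weights.
#
# The population distribution in transformed space is modeled as
#   p(x) = sum_k w_k N(x | mu_k, Sigma_k),  sum_k w_k = 1,
# and fitted by variational inference with a truncated stick-breaking prior:
# redundant components are suppressed rather than selected, so K_max is an
# upper bound, not a choice of K. The prior scheme deliberately biases the
# fit toward one dominant central component (the healthy subpopulation):
# a very small weight-concentration prior encourages sparsity, a large mean
# precision keeps component means near the prior mean (the feature-wise
# median, robust to outliers), and the covariance prior carries diagonal
# shrinkage for stability in seven dimensions.

#' Hyperparameters of the Bayesian Gaussian mixture fit
#'
#' Defaults follow the scheme used for the lipid-panel analysis: up to
#' `K_max = 7` components, Dirichlet/stick concentration `1e-6`
#' (strong sparsity), mean precision `200` (means constrained near the
#' feature-wise median), covariance prior equal to the empirical covariance
#' plus `covariance_shrinkage` times its diagonal.
#'
#' @param K_max maximum number of mixture components.
#' @param weight_concentration_prior stick-breaking concentration gamma.
#' @param mean_precision_prior prior precision beta0 on component means.
#' @param prior_mean_rule only `"median"` (feature-wise median) supported.
#' @param covariance_shrinkage diagonal shrinkage factor added to the prior
#'   scale matrix.
#' @param reg_covar jitter added to component covariance diagonals each
#'   M-step for numerical stability.
#' @param max_iterations,tolerance variational stopping rule; `tolerance`
#'   applies to the absolute change of the variational lower bound between
#'   iterations.
#' @param n_restarts number of seeded initializations; best lower bound wins.
#' @param min_stratum_n smallest stratum size that will be fitted.
#' @param seed integer seed (restart r uses `seed + r - 1`).
#' @export
fit_hyperparams <- function(K_max = 7,
                            weight_concentration_prior = 1e-6,
                            mean_precision_prior = 200,
                            prior_mean_rule = "median",
                            covariance_shrinkage = 1e-3,
                            reg_covar = 1e-6,
                            max_iterations = 1000,
                            tolerance = 1e-4,
                            n_restarts = 3,
                            min_stratum_n = 500,
                            seed = 1L) {
  hp <- list(K_max = as.integer(K_max),
             weight_concentration_prior = weight_concentration_prior,
             mean_precision_prior = mean_precision_prior,
             prior_mean_rule = match.arg(prior_mean_rule, "median"),
             covariance_shrinkage = covariance_shrinkage,
             reg_covar = reg_covar,
             max_iterations = as.integer(max_iterations),
             tolerance = tolerance,
             n_restarts = as.integer(n_restarts),
             min_stratum_n = as.integer(min_stratum_n),
             seed = as.integer(seed))
  stopifnot(hp$K_max >= 1, hp$weight_concentration_prior > 0,
            hp$mean_precision_prior > 0, hp$covariance_shrinkage >= 0,
            hp$max_iterations >= 1, hp$tolerance > 0, hp$n_restarts >= 1)
  class(hp) <- "fit_hyperparams"
  hp
}

# One VB run from a given initial responsibility matrix.
vb_run <- function(z, resp, hp, prior) {
  n <- nrow(z); d <- ncol(z); K <- ncol(resp)
  m0 <- prior$m0; beta0 <- prior$beta0; nu0 <- prior$nu0
  Psi0 <- prior$Psi0; gamma0 <- prior$gamma0
  const <- -0.5 * d * log(2 * pi)
  lb_prev <- -Inf
  lb_trace <- numeric(0)
  converged <- FALSE
  it <- 0
  params <- NULL
  while (it < hp$max_iterations) {
    it <- it + 1
    # ---- M-step (update variational posteriors from responsibilities)
    nk <- colSums(resp) + 10 * .Machine$double.eps
    xbar <- crossprod(resp, z) / nk                       # K x d
    beta_k <- beta0 + nk
    nu_k <- nu0 + nk
    m_k <- (beta0 * matrix(m0, K, d, byrow = TRUE) + nk * xbar) / beta_k
    Psi <- vector("list", K)
    for (k in seq_len(K)) {
      zc <- sweep(z, 2, xbar[k, ])
      Sk <- crossprod(zc * resp[, k], zc)
      diffk <- xbar[k, ] - m0
      Psi[[k]] <- Psi0 + Sk + (beta0 * nk[k] / beta_k[k]) * tcrossprod(diffk) +
        diag(hp$reg_covar * nk[k], d)
    }
    # stick-breaking posterior
    tailk <- c(rev(cumsum(rev(nk)))[-1], 0)               # sum_{j>k} n_j
    g1 <- 1 + nk
    g2 <- gamma0 + tailk
    # ---- E-step
    dig_sum <- digamma(g1 + g2)
    Elogv <- digamma(g1) - dig_sum
    Elog1mv <- digamma(g2) - dig_sum
    Elogw <- Elogv + c(0, cumsum(Elog1mv)[-K])
    log_gauss <- matrix(0, n, K)
    logdetPsi <- numeric(K)
    for (k in seq_len(K)) {
      U <- chol(Psi[[k]])
      logdetPsi[k] <- 2 * sum(log(diag(U)))
      Elogdet <- sum(digamma((nu_k[k] + 1 - seq_len(d)) / 2)) +
        d * log(2) - logdetPsi[k]
      w <- backsolve(U, t(sweep(z, 2, m_k[k, ])), transpose = TRUE)
      maha <- colSums(w^2)
      log_gauss[, k] <- const + 0.5 * Elogdet - 0.5 * d / beta_k[k] -
        0.5 * nu_k[k] * maha
    }
    log_rho <- sweep(log_gauss, 2, Elogw, `+`)
    log_norm <- logsumexp_rows(log_rho)
    log_resp <- log_rho - log_norm
    resp <- exp(log_resp)
    # ---- variational lower-bound surrogate (monitored for convergence)
    ent_terms <- resp * log_resp
    ent_terms[resp == 0] <- 0
    log_wishart <- -(nu_k * (-0.5 * logdetPsi) + nu_k * d * 0.5 * log(2) +
                       vapply(seq_len(K), function(k) {
                         sum(lgamma(0.5 * (nu_k[k] - (0:(d - 1)))))
                       }, numeric(1)))
    lb <- -sum(ent_terms) - sum(log_wishart) + sum(lbeta(g1, g2)) -
      0.5 * d * sum(log(beta_k))
    lb_trace <- c(lb_trace, lb)
    params <- list(nk = nk, beta_k = beta_k, nu_k = nu_k, m_k = m_k,
                   Psi = Psi, g1 = g1, g2 = g2)
    if (is.finite(lb_prev) && abs(lb - lb_prev) < hp$tolerance) {
      converged <- TRUE
      break
    }
    lb_prev <- lb
  }
  list(params = params, lb = lb_trace[length(lb_trace)], lb_trace = lb_trace,
       n_iter = it, converged = converged)
}

init_responsibilities <- function(z, K) {
  n <- nrow(z)
  assign <- tryCatch(
    suppressWarnings(stats::kmeans(z, centers = min(K, n), iter.max = 30,
                                   nstart = 1, algorithm = "Lloyd")$cluster),
    error = function(e) sample.int(min(K, n), n, replace = TRUE)
  )
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), assign)] <- 1
  resp
}

#' Fit the Bayesian Gaussian mixture to a transformed data matrix
#'
#' @param z numeric matrix (observations x analytes) in Gaussian space, with
#'   analyte column names.
#' @param hyperparams a [fit_hyperparams()] list.
#' @param specs analyte specification carried into the model for
#'   back-transformation (optional but needed for native-unit intervals).
#' @param stratum optional list/label describing the (sex, age window) the
#'   model belongs to.
#' @return a `mixture_model`: weights, means, covariances (in transformed
#'   space), analyte order, fit diagnostics. Deterministic given the seed;
#'   best of `n_restarts` by variational lower bound.
#' @export
fit_bgmm <- function(z, hyperparams = fit_hyperparams(),
                     specs = default_analyte_specs(), stratum = NULL) {
  hp <- hyperparams
  z <- as.matrix(z)
  storage.mode(z) <- "double"
  if (is.null(colnames(z))) {
    stop("z must have analyte column names", call. = FALSE)
  }
  n <- nrow(z); d <- ncol(z)
  if (n < hp$min_stratum_n) {
    warning(sprintf("stratum skipped: n = %d below minimum %d", n, hp$min_stratum_n))
    return(NULL)
  }
  S_emp <- stats::cov(z)
  ev <- eigen(S_emp, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / max(min(ev), 1e-300) > 1e14) {
    stop("singular or near-singular empirical covariance; increase ",
         "covariance_shrinkage or drop linearly dependent analytes", call. = FALSE)
  }
  prior <- list(
    m0 = apply(z, 2, stats::median),
    beta0 = hp$mean_precision_prior,
    nu0 = d,
    Psi0 = S_emp + hp$covariance_shrinkage * diag(diag(S_emp), d),
    gamma0 = hp$weight_concentration_prior
  )
  best <- NULL
  for (r in seq_len(hp$n_restarts)) {
    set.seed((hp$seed + r - 1) %% 2147483647)
    resp <- init_responsibilities(z, hp$K_max)
    run <- vb_run(z, resp, hp, prior)
    if (is.null(best) || run$lb > best$lb) best <- run
  }
  p <- best$params
  K <- hp$K_max
  v <- p$g1 / (p$g1 + p$g2)
  w <- v * cumprod(c(1, 1 - v))[seq_len(K)]
  w <- w / sum(w)
  covs <- lapply(seq_len(K), function(k) {
    m <- p$Psi[[k]] / p$nu_k[k]
    dimnames(m) <- list(colnames(z), colnames(z))
    (m + t(m)) / 2
  })
  means <- p$m_k
  dimnames(means) <- list(NULL, colnames(z))
  model <- list(
    analytes = colnames(z),
    specs = specs,
    weights = w,
    means = means,
    covariances = covs,
    stratum = stratum,
    n_obs = n,
    hyperparams = hp,
    n_iter = best$n_iter,
    converged = best$converged,
    lower_bound = best$lb,
    lb_trace = best$lb_trace
  )
  class(model) <- "mixture_model"
  model
}

#' @export
print.mixture_model <- function(x, ...) {
  active <- sum(x$weights > 0.01)
  cat(sprintf("Bayesian Gaussian mixture: %d analytes, %d/%d active components\n",
              length(x$analytes), active, length(x$weights)))
  cat("  analytes:", paste(x$analytes, collapse = ", "), "\n")
  cat("  weights: ", paste(sprintf("%.3f", sort(x$weights, decreasing = TRUE)[
    seq_len(min(4, length(x$weights)))]), collapse = ", "), "...\n")
  if (!is.null(x$stratum)) {
    cat("  stratum: ", paste(unlist(x$stratum), collapse = " "), "\n")
  }
  cat(sprintf("  n = %d, %d iterations, converged: %s\n",
              x$n_obs, x$n_iter, x$converged))
  invisible(x)
}

#' Extract the principal (healthy) component of a fitted mixture
#'
#' The healthy reference distribution is the mixture element with the
#' largest weight, which captures the central tendency of the majority
#' population. Exact weight ties are broken toward the smallest generalized
#' variance (determinant of the covariance).
#'
#' @param model a fitted `mixture_model`.
#' @return a [gaussian_dist()] over the model's analytes; the component
#'   weight is in attribute `"weight"`, its index in `"component"`.
#' @export
principal_component <- function(model) {
  stopifnot(inherits(model, "mixture_model"))
  w <- model$weights
  top <- which(w >= max(w) - 1e-12)
  if (length(top) > 1) {
    dets <- vapply(model$covariances[top], det, numeric(1))
    top <- top[which.min(dets)]
  }
  k <- top[1]
  out <- gaussian_dist(model$analytes, model$means[k, ], model$covariances[[k]],
                       specs = model$specs)
  attr(out, "weight") <- w[k]
  attr(out, "component") <- k
  out
}

# Fit one model per (sex, age-window) stratum of a wide biomarker table.
# Returns a named list "SEX_AGE" -> mixture_model (NULL entries dropped).
fit_stratum_models <- function(wide, ages, sexes = c("M", "F"), window = 2,
                               analytes = ASSAYED_ANALYTES,
                               specs = default_analyte_specs(),
                               hyperparams = fit_hyperparams()) {
  models <- list()
  for (sx in sexes) {
    for (a in ages) {
      rows <- wide$sex == sx & abs(wide$age - a) <= window
      zi <- to_gaussian_space(wide[rows, , drop = FALSE], specs, analytes)
      hp <- hyperparams
      hp$seed <- derive_seed(hyperparams$seed, paste0("stratum_", sx, "_", a))
      model <- withCallingHandlers(
        fit_bgmm(zi, hp, specs, stratum = list(sex = sx, age = a, window = window)),
        warning = function(w) {
          message(sprintf("stratum %s/%d: %s", sx, a, conditionMessage(w)))
          invokeRestart("muffleWarning")
        }
      )
      if (!is.null(model)) models[[paste0(sx, "_", a)]] <- model
    }
  }
  models
}

#' Component-weight profiles by sex and age
#'
#' Fits the mixture per (sex, sliding age window) stratum and tabulates the
#' component weights ranked within stratum, the age-resolved view of how the
#' healthy/pathological balance shifts across the population.
#'
#' @param cohort wide biomarker table in native units.
#' @param ages integer ages at which to center strata.
#' @param sexes sexes to fit.
#' @param window half-width (years) of the sliding age window.
#' @param analytes analytes entering the joint fit.
#' @param specs analyte specification.
#' @param hyperparams a [fit_hyperparams()].
#' @param n_top how many ranked components to report per stratum.
#' @return tibble: sex, age, rank, weight (ranked descending; weights of all
#'   fitted components in a stratum sum to 1). Fitted models are attached as
#'   attribute `"models"`.
#' @export
weights_by_stratum <- function(cohort, ages, sexes = c("M", "F"), window = 2,
                               analytes = ASSAYED_ANALYTES,
                               specs = default_analyte_specs(),
                               hyperparams = fit_hyperparams(),
                               n_top = NULL) {
  models <- fit_stratum_models(cohort, ages, sexes, window, analytes, specs,
                               hyperparams)
  rows <- purrr::imap(models, function(m, key) {
    w <- sort(m$weights, decreasing = TRUE)
    if (!is.null(n_top)) w <- w[seq_len(min(n_top, length(w)))]
    tibble::tibble(sex = m$stratum$sex, age = m$stratum$age,
                   rank = seq_along(w), weight = w)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "models") <- models
  out
}
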