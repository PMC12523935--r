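# Exact Gaussian algebra: marginals, conditionals, mixture conditioning,
# transform-aware quantile intervals and percentiles.
#
# For a joint normal X ~ N(mu, Sigma) partitioned into query block A and
# conditioning block B, the marginal is the sub-vector/sub-matrix restriction
# and the conditional is the Schur complement:
#   mu_{A|B}    = mu_A + Sigma_AB Sigma_BB^-1 (b - mu_B)
#   Sigma_{A|B} = Sigma_AA - Sigma_AB Sigma_BB^-1 Sigma_BA
# Conditioning values are supplied in native units and mapped to Gaussian
# space through the analyte transforms; interval limits are mapped back.

#' A Gaussian block over a subset of analytes
#'
#' @param analytes character vector naming the coordinates.
#' @param mean numeric mean vector (transformed space).
#' @param cov symmetric positive-definite covariance matrix.
#' @param specs optional analyte specification (for native-unit mapping).
#' @return object of class `gaussian_dist`.
#' @export
gaussian_dist <- function(analytes, mean, cov, specs = NULL) {
  cov <- as.matrix(cov)
  stopifnot(length(analytes) == length(mean), all(dim(cov) == length(mean)))
  if (!is_spd(cov)) stop("covariance must be symmetric positive definite",
                         call. = FALSE)
  mean <- stats::setNames(as.numeric(mean), analytes)
  dimnames(cov) <- list(analytes, analytes)
  structure(list(analytes = analytes, mean = mean, cov = cov, specs = specs),
            class = "gaussian_dist")
}

#' @export
print.gaussian_dist <- function(x, ...) {
  cat("Gaussian over:", paste(x$analytes, collapse = ", "), "\n")
  cat("  mean:", paste(sprintf("%.4g", x$mean), collapse = ", "), "\n")
  cat("  sd:  ", paste(sprintf("%.4g", sqrt(diag(x$cov))), collapse = ", "), "\n")
  invisible(x)
}

#' A finite mixture of Gaussian blocks over a common analyte set
#'
#' @param weights non-negative weights (normalized internally).
#' @param components list of [gaussian_dist()] objects on the same analytes.
#' @param specs optional analyte specification.
#' @return object of class `mixture_dist`.
#' @export
mixture_dist <- function(weights, components, specs = NULL) {
  stopifnot(length(weights) == length(components), all(weights >= 0),
            sum(weights) > 0)
  analytes <- components[[1]]$analytes
  ok <- vapply(components, function(c) identical(c$analytes, analytes), logical(1))
  if (!all(ok)) stop("components must share one analyte set", call. = FALSE)
  structure(list(analytes = analytes, weights = weights / sum(weights),
                 components = components,
                 specs = specs %||% components[[1]]$specs),
            class = "mixture_dist")
}

as_mixture <- function(model) {
  stopifnot(inherits(model, "mixture_model"))
  comps <- lapply(seq_along(model$weights), function(k) {
    gaussian_dist(model$analytes, model$means[k, ], model$covariances[[k]],
                  specs = model$specs)
  })
  mixture_dist(model$weights, comps, specs = model$specs)
}

check_analytes <- function(have, want) {
  unknown <- setdiff(want, have)
  if (length(unknown)) {
    stop("unknown analyte name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
}

#' Marginal distribution of an analyte subset
#'
#' @param dist a `gaussian_dist`, `mixture_dist` or fitted `mixture_model`.
#' @param A non-empty character vector of analytes to keep.
#' @return an object of the same family restricted to `A`.
#' @export
marginal_dist <- function(dist, A) {
  stopifnot(length(A) >= 1)
  if (inherits(dist, "mixture_model")) dist <- as_mixture(dist)
  check_analytes(dist$analytes, A)
  if (inherits(dist, "gaussian_dist")) {
    gaussian_dist(A, dist$mean[A], dist$cov[A, A, drop = FALSE], dist$specs)
  } else {
    mixture_dist(dist$weights, lapply(dist$components, marginal_dist, A = A),
                 dist$specs)
  }
}

# Map named native-unit conditioning values to Gaussian space.
conditioning_to_gaussian <- function(b, specs) {
  if (is.null(specs)) return(b)
  out <- b
  for (a in names(b)) {
    if (a %in% specs$analyte) {
      out[a] <- apply_transform(b[[a]], spec_for(specs, a)$transform, a)
    }
  }
  out
}

#' Conditional distribution of a single Gaussian block
#'
#' @param dist a `gaussian_dist`.
#' @param A analytes to retain (disjoint from the conditioning set); defaults
#'   to all analytes not conditioned on.
#' @param b named numeric vector of conditioning values. Native units when
#'   the distribution carries analyte specs (they are transformed first);
#'   otherwise taken as Gaussian-space values.
#' @param native set to `FALSE` to force `b` to be read in Gaussian space.
#' @return a `gaussian_dist` over `A` with the Schur-complement parameters.
#'   Conditioning never inflates variance.
#' @export
conditional_dist <- function(dist, A = NULL, b, native = TRUE) {
  stopifnot(inherits(dist, "gaussian_dist"))
  B <- names(b)
  if (is.null(B) || any(!nzchar(B))) stop("b must be a named vector", call. = FALSE)
  A <- A %||% setdiff(dist$analytes, B)
  check_analytes(dist$analytes, c(A, B))
  if (length(intersect(A, B))) {
    stop("query and conditioning sets must be disjoint", call. = FALSE)
  }
  bG <- if (native) conditioning_to_gaussian(b, dist$specs) else b
  SBB <- dist$cov[B, B, drop = FALSE]
  if (kappa(SBB, exact = TRUE) > 1e12) {
    stop("ill-conditioned conditioning covariance (condition number > 1e12)",
         call. = FALSE)
  }
  SAB <- dist$cov[A, B, drop = FALSE]
  U <- chol(SBB)
  solve_BB <- function(v) backsolve(U, backsolve(U, v, transpose = TRUE))
  mu_ab <- dist$mean[A] + as.vector(SAB %*% solve_BB(as.numeric(bG[B] - dist$mean[B])))
  S_ab <- dist$cov[A, A, drop = FALSE] - SAB %*% solve_BB(t(SAB))
  S_ab <- (S_ab + t(S_ab)) / 2
  ev_min <- min(eigen(S_ab, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) {
    jit <- 1e-10 * sum(diag(S_ab)) / nrow(S_ab)
    message("conditional covariance jittered by ", signif(jit, 3),
            " to restore positive definiteness")
    S_ab <- S_ab + diag(jit - ev_min, nrow(S_ab))
  }
  gaussian_dist(A, mu_ab, S_ab, dist$specs)
}

#' Conditional distribution of a Gaussian mixture
#'
#' Conditions every component via [conditional_dist()] and reweights by the
#' component densities at the conditioning point,
#' `w_k' = w_k N(b_G; mu_{B,k}, Sigma_{BB,k})` (normalized). The
#' `"principal"` mode instead conditions only the largest-weight component,
#' without reweighting.
#'
#' @param model a fitted `mixture_model` or a `mixture_dist`.
#' @param A analytes to retain; defaults to all not conditioned on.
#' @param b named conditioning values (native units when specs available).
#' @param mode `"mixture"` (default, full reweighting) or `"principal"`.
#' @param native interpret `b` in native units (see [conditional_dist()]).
#' @return a `mixture_dist` over `A` (a single-component mixture in
#'   principal mode).
#' @export
mixture_conditional <- function(model, A = NULL, b, mode = c("mixture", "principal"),
                                native = TRUE) {
  mode <- match.arg(mode)
  if (mode == "principal" && inherits(model, "mixture_model")) {
    pc <- principal_component(model)
    return(mixture_dist(1, list(conditional_dist(pc, A, b, native)), model$specs))
  }
  mix <- if (inherits(model, "mixture_model")) as_mixture(model) else model
  stopifnot(inherits(mix, "mixture_dist"))
  if (mode == "principal") {
    k <- which.max(mix$weights)
    return(mixture_dist(1, list(conditional_dist(mix$components[[k]], A, b, native)),
                        mix$specs))
  }
  B <- names(b)
  A <- A %||% setdiff(mix$analytes, B)
  bG <- if (native) conditioning_to_gaussian(b, mix$specs) else b
  logw <- vapply(seq_along(mix$weights), function(k) {
    comp <- mix$components[[k]]
    log(mix$weights[k]) +
      dmvnorm_log(as.numeric(bG[B]), comp$mean[B],
                  comp$cov[B, B, drop = FALSE])
  }, numeric(1))
  if (!any(is.finite(logw)) || max(logw, na.rm = TRUE) < log(1e-300)) {
    stop("conditioning point lies outside the model support ",
         "(all component densities numerically zero)", call. = FALSE)
  }
  w <- exp(logw - max(logw))
  comps <- lapply(mix$components, conditional_dist, A = A, b = b, native = native)
  mixture_dist(w, comps, mix$specs)
}

# --- univariate machinery ---------------------------------------------------

univariate_params <- function(dist) {
  if (inherits(dist, "gaussian_dist")) {
    stopifnot(length(dist$analytes) == 1)
    list(w = 1, mu = unname(dist$mean), sd = sqrt(unname(dist$cov[1, 1])),
         analyte = dist$analytes, specs = dist$specs)
  } else if (inherits(dist, "mixture_dist")) {
    stopifnot(length(dist$analytes) == 1)
    list(w = dist$weights,
         mu = vapply(dist$components, function(c) unname(c$mean), numeric(1)),
         sd = vapply(dist$components, function(c) sqrt(unname(c$cov[1, 1])),
                     numeric(1)),
         analyte = dist$analytes, specs = dist$specs)
  } else {
    stop("dist must be a univariate gaussian_dist or mixture_dist", call. = FALSE)
  }
}

dist_cdf <- function(p, z) {
  vapply(z, function(zz) sum(p$w * stats::pnorm(zz, p$mu, p$sd)), numeric(1))
}

dist_quantile <- function(p, prob, tol = 1e-10) {
  if (length(p$w) == 1) return(stats::qnorm(prob, p$mu, p$sd))
  lo <- min(p$mu - 10 * max(p$sd))
  hi <- max(p$mu + 10 * max(p$sd))
  vapply(prob, function(pr) {
    a <- lo; b <- hi
    # bisection to tolerance tol in probability
    for (i in 1:200) {
      mid <- (a + b) / 2
      cm <- dist_cdf(p, mid)
      if (abs(cm - pr) < tol) break
      if (cm < pr) a <- mid else b <- mid
    }
    mid
  }, numeric(1))
}

transform_kind_of <- function(p, transform = NULL) {
  if (!is.null(transform)) return(transform)
  if (!is.null(p$specs) && p$analyte %in% p$specs$analyte) {
    spec_for(p$specs, p$analyte)$transform
  } else {
    "identity"
  }
}

#' Equal-tailed interval of a univariate distribution in native units
#'
#' Computes the limits enclosing the central `coverage` fraction of the
#' distribution at probabilities `(1-coverage)/2` and `1-(1-coverage)/2` in
#' Gaussian space, then maps them back through the analyte transform. The
#' conventional reference interval is `coverage = 0.95`, which for a pure
#' Gaussian equals `mu -/+ 1.96 sigma`.
#'
#' @param dist univariate `gaussian_dist` or `mixture_dist`.
#' @param coverage central probability mass in (0, 1).
#' @param transform override of the transform kind (`"log"`/`"identity"`);
#'   defaults to the analyte's spec when available.
#' @return named numeric `c(low, high)` in native units, with the
#'   back-transformed distribution mean in attribute `"mean"`.
#' @export
quantile_interval <- function(dist, coverage = 0.95, transform = NULL) {
  if (!is.numeric(coverage) || coverage <= 0 || coverage >= 1) {
    stop("coverage must lie in (0, 1)", call. = FALSE)
  }
  p <- univariate_params(dist)
  kind <- transform_kind_of(p, transform)
  probs <- c((1 - coverage) / 2, 1 - (1 - coverage) / 2)
  qz <- dist_quantile(p, probs)
  out <- stats::setNames(invert_transform(qz, kind), c("low", "high"))
  attr(out, "mean") <- invert_transform(sum(p$w * p$mu), kind)
  out
}

#' Percentile of a measurement under a distribution
#'
#' Places an individual native-unit result on the continuous 0-100 scale
#' `100 * CDF(T(value))`, a graded alternative to the binary abnormal flag.
#'
#' @param value numeric native-unit value(s).
#' @param dist univariate `gaussian_dist` or `mixture_dist`.
#' @param transform optional transform-kind override.
#' @return percentile(s) in (0, 100); strictly increasing in `value`.
#' @export
percentile_of <- function(value, dist, transform = NULL) {
  p <- univariate_params(dist)
  kind <- transform_kind_of(p, transform)
  z <- apply_transform(value, kind, p$analyte)
  100 * dist_cdf(p, z)
}
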