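# Flat-text (JSON) serialization of fitted mixture models: analyte order,
# transforms, per-component weight/mean/covariance (row-major), fit
# hyperparameters and seed — sufficient to reload the model exactly.

#' Write a fitted mixture model to a JSON file
#'
#' @param model a `mixture_model`.
#' @param path output file path.
#' @export
write_mixture_model <- function(model, path) {
  stopifnot(inherits(model, "mixture_model"))
  obj <- list(
    analytes = model$analytes,
    transforms = if (!is.null(model$specs)) {
      vapply(model$analytes, function(a) {
        if (a %in% model$specs$analyte) spec_for(model$specs, a)$transform
        else "identity"
      }, character(1))
    } else NULL,
    weights = model$weights,
    means = lapply(seq_len(nrow(model$means)), function(k) model$means[k, ]),
    covariances = lapply(model$covariances, function(m) as.vector(t(m))),
    stratum = model$stratum,
    n_obs = model$n_obs,
    hyperparams = unclass(model$hyperparams),
    n_iter = model$n_iter,
    converged = model$converged,
    lower_bound = model$lower_bound
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a mixture model written by [write_mixture_model()]
#'
#' @param path file path.
#' @return a `mixture_model`.
#' @export
read_mixture_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- length(obj$analytes)
  K <- length(obj$weights)
  # jsonlite may simplify the per-component lists to a matrix already
  means <- if (is.matrix(obj$means) || is.data.frame(obj$means)) {
    as.matrix(obj$means)
  } else {
    do.call(rbind, lapply(obj$means, as.numeric))
  }
  dimnames(means) <- list(NULL, obj$analytes)
  cov_rows <- if (is.matrix(obj$covariances)) {
    lapply(seq_len(K), function(k) obj$covariances[k, ])
  } else {
    obj$covariances
  }
  covs <- lapply(cov_rows, function(v) {
    m <- matrix(as.numeric(v), d, d, byrow = TRUE)
    dimnames(m) <- list(obj$analytes, obj$analytes)
    m
  })
  specs <- if (!is.null(obj$transforms)) {
    base <- default_analyte_specs()
    keep <- base[base$analyte %in% obj$analytes, ]
    keep$transform <- unname(obj$transforms[match(keep$analyte, obj$analytes)])
    keep
  } else NULL
  hp <- obj$hyperparams
  if (!is.null(hp)) class(hp) <- "fit_hyperparams"
  model <- list(analytes = obj$analytes, specs = specs,
                weights = as.numeric(obj$weights), means = means,
                covariances = covs, stratum = obj$stratum,
                n_obs = obj$n_obs, hyperparams = hp, n_iter = obj$n_iter,
                converged = obj$converged, lower_bound = obj$lower_bound,
                lb_trace = NULL)
  class(model) <- "mixture_model"
  model
}
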