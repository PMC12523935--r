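# Mortality estimation from census-style counts: annual rates, cumulative
# survival, and the exponential (Gompertz) regime check.

#' Annual mortality rates from census counts
#'
#' For each sex and year pair (y, y+1) present, the survival ratio
#' `count(age+1, y+1) / count(age, y)` is computed, clipped to `[0, 1]`
#' (ratios above 1 arise from migration and other demographic noise), and
#' averaged across year pairs. The annual mortality rate is one minus the
#' mean survival ratio.
#'
#' @param census tibble with columns sex, age, year, count.
#' @return tibble: sex, age, rate, n_pairs (year pairs contributing).
#' @export
annual_mortality <- function(census) {
  stopifnot(all(c("sex", "age", "year", "count") %in% names(census)))
  if (any(census$count < 0)) stop("counts must be non-negative", call. = FALSE)
  out <- list()
  n_clipped <- 0
  for (sx in unique(census$sex)) {
    cs <- census[census$sex == sx, ]
    years <- sort(unique(cs$year))
    pairs <- years[(years + 1) %in% years]
    if (!length(pairs)) {
      stop("need at least 2 consecutive years per sex", call. = FALSE)
    }
    look <- function(a, y) {
      v <- cs$count[cs$age == a & cs$year == y]
      if (length(v)) v[1] else NA_real_
    }
    ages <- sort(unique(cs$age))
    ages <- ages[(ages + 1) %in% ages]
    surv <- vapply(ages, function(a) {
      r <- vapply(pairs, function(y) {
        denom <- look(a, y)
        num <- look(a + 1, y + 1)
        if (is.na(denom) || is.na(num) || denom == 0) return(NA_real_)
        num / denom
      }, numeric(1))
      r <- r[!is.na(r)]
      if (!length(r)) return(NA_real_)
      n_clipped <<- n_clipped + sum(r > 1)
      mean(pmin(pmax(r, 0), 1))
    }, numeric(1))
    skipped <- is.na(surv)
    if (any(skipped)) {
      warning("age(s) skipped (zero or missing denominator): ",
              paste(utils::head(ages[skipped], 5), collapse = ", "))
    }
    out[[sx]] <- tibble::tibble(sex = sx, age = ages[!skipped],
                                rate = 1 - surv[!skipped],
                                n_pairs = length(pairs))
  }
  if (n_clipped) message(n_clipped, " survival ratio(s) > 1 clipped to 1")
  dplyr::bind_rows(out)
}

#' Cumulative survival function from annual rates
#'
#' `S(x0) = 1`, `S(x+1) = S(x) * (1 - rate(x))`: the fraction of the
#' population surviving to each age, per sex.
#'
#' @param rates tibble from [annual_mortality()] (columns sex, age, rate),
#'   contiguous in age per sex.
#' @return tibble: sex, age, survival; monotone non-increasing in age.
#' @export
survival_function <- function(rates) {
  stopifnot(all(c("sex", "age", "rate") %in% names(rates)))
  if (any(rates$rate < 0 | rates$rate > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  rates |>
    dplyr::group_by(.data$sex) |>
    dplyr::arrange(.data$age, .by_group = TRUE) |>
    dplyr::mutate(survival = cumprod(c(1, 1 - .data$rate[-dplyr::n()]))) |>
    dplyr::ungroup() |>
    dplyr::select("sex", "age", "survival")
}

#' Check the Gompertz (exponential) mortality regime
#'
#' Ordinary least squares of `log(rate)` on age for ages at or above
#' `age_min` (midlife onward, where adult mortality rises exponentially).
#'
#' @param rates tibble with columns age, rate and optionally sex.
#' @param age_min youngest age entering the fit (default 50).
#' @return tibble per sex: intercept, slope, r_squared, n_ages. The slope is
#'   the log-hazard increase per year; the intercept is `log(rate)` at age 0.
#' @export
gompertz_check <- function(rates, age_min = 50) {
  stopifnot(all(c("age", "rate") %in% names(rates)))
  if (!"sex" %in% names(rates)) rates$sex <- "all"
  out <- lapply(unique(rates$sex), function(sx) {
    r <- rates[rates$sex == sx & rates$age >= age_min, ]
    bad <- r$rate <= 0
    if (any(bad)) {
      warning(sum(bad), " non-positive rate(s) dropped from Gompertz fit")
      r <- r[!bad, ]
    }
    if (nrow(r) < 3) {
      stop("fewer than 3 ages with positive rates above age_min", call. = FALSE)
    }
    fit <- stats::lm(log(rate) ~ age, data = r)
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((log(r$rate) - mean(log(r$rate)))^2)
    tibble::tibble(sex = sx,
                   intercept = unname(stats::coef(fit)[1]),
                   slope = unname(stats::coef(fit)[2]),
                   r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                   n_ages = nrow(r))
  })
  dplyr::bind_rows(out)
}
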