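# Laboratory-only diagnostic rules, the conditional-probability implication
# matrix, HITS hub/authority scoring and edge pruning for the comorbidity
# network.

#' Default laboratory diagnostic rules
#'
#' Threshold and ratio criteria over same-date analyte values defining
#' cardiovascular conditions and comorbidities from laboratory biomarkers
#' alone (no diagnostic codes). All inequalities are strict, exactly as
#' specified:
#' * Hypercholesterolemia: `CHOL > 200`
#' * Hypertriglyceridemia: `TRIG > 150`
#' * CVD (High Risk): `CHOL/HDL > 5.0` or `LDL/HDL > 3.5`
#' * CVD (Moderate Risk): `4.0 < CHOL/HDL < 5.0` or `2.5 < LDL/HDL < 3.5`
#' * Diabetes Mellitus: `A1C > 6.5`
#' * Chronic Kidney Disease: `CREA > 1.3`
#'
#' CVD Moderate and High Risk are mutually exclusive; High takes precedence
#' when both predicates hold.
#'
#' @return a `diagnosis_rules` list; each rule has `condition`, `expr`
#'   (predicate text over analyte columns) and `requires`.
#' @export
default_rules <- function() {
  spec <- c(
    "Hypercholesterolemia"    = "CHOL > 200",
    "Hypertriglyceridemia"    = "TRIG > 150",
    "CVD (High Risk)"         = "(CHOL / HDL > 5.0) | (LDL / HDL > 3.5)",
    "CVD (Moderate Risk)"     = "((CHOL / HDL > 4.0) & (CHOL / HDL < 5.0)) | ((LDL / HDL > 2.5) & (LDL / HDL < 3.5))",
    "Diabetes Mellitus"       = "A1C > 6.5",
    "Chronic Kidney Disease"  = "CREA > 1.3"
  )
  rules <- purrr::imap(spec, function(expr, nm) {
    e <- parse(text = expr)[[1]]
    list(condition = nm, expr = expr, requires = all.vars(e))
  })
  structure(unname(rules), class = "diagnosis_rules")
}

#' Read diagnostic rules from a text config
#'
#' One rule per line, `condition name: predicate`, predicates written over
#' analyte column names (e.g. `Diabetes Mellitus: A1C > 6.5`). Lines starting
#' with `#` are comments.
#'
#' @param path file path.
#' @return a `diagnosis_rules` list.
#' @export
read_rules <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rules <- lapply(lines, function(l) {
    i <- regexpr(":", l, fixed = TRUE)
    if (i < 0) stop("malformed rule line (missing ':'): ", l, call. = FALSE)
    nm <- trimws(substr(l, 1, i - 1))
    expr <- trimws(substr(l, i + 1, nchar(l)))
    list(condition = nm, expr = expr, requires = all.vars(parse(text = expr)[[1]]))
  })
  structure(rules, class = "diagnosis_rules")
}

#' Apply diagnostic rules to a biomarker table
#'
#' Evaluates each rule on every patient-month row; a patient carries a
#' condition flag if any qualifying row triggers it (lifetime prevalence
#' reading; `cooccurrence = "same_month"` restricts the returned flags to
#' per-row values aggregated only within one month). Rows with a required
#' analyte missing (NA) never qualify. CVD High Risk takes precedence over
#' Moderate on rows where both predicates hold, and a patient flagged High
#' is not also flagged Moderate.
#'
#' @param table wide biomarker table with a `patient_id` column and the
#'   analyte columns the rules need.
#' @param rules a `diagnosis_rules` list, [default_rules()] by default.
#' @param cooccurrence `"lifetime"` (default) or `"same_month"`.
#' @return tibble with `patient_id` (plus `year`, `month` when
#'   `"same_month"`) and one logical column per condition.
#' @export
diagnose <- function(table, rules = default_rules(),
                     cooccurrence = c("lifetime", "same_month")) {
  cooccurrence <- match.arg(cooccurrence)
  stopifnot("patient_id" %in% names(table))
  for (r in rules) {
    absent <- setdiff(r$requires, names(table))
    if (length(absent)) {
      stop("rule '", r$condition, "' references absent analyte(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  row_flags <- lapply(rules, function(r) {
    v <- eval(parse(text = r$expr), envir = table)
    v & !is.na(v)
  })
  names(row_flags) <- vapply(rules, `[[`, character(1), "condition")
  # High-risk precedence on rows where both CVD predicates hold
  if (all(c("CVD (High Risk)", "CVD (Moderate Risk)") %in% names(row_flags))) {
    row_flags[["CVD (Moderate Risk)"]] <-
      row_flags[["CVD (Moderate Risk)"]] & !row_flags[["CVD (High Risk)"]]
  }
  flags <- tibble::as_tibble(row_flags)
  flags$patient_id <- table$patient_id
  if (cooccurrence == "same_month") {
    flags$year <- table$year
    flags$month <- table$month
    out <- flags |>
      dplyr::group_by(.data$patient_id, .data$year, .data$month) |>
      dplyr::summarise(dplyr::across(dplyr::where(is.logical), any),
                       .groups = "drop")
  } else {
    out <- flags |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(dplyr::across(dplyr::where(is.logical), any),
                       .groups = "drop")
  }
  if (all(c("CVD (High Risk)", "CVD (Moderate Risk)") %in% names(out))) {
    out[["CVD (Moderate Risk)"]] <-
      out[["CVD (Moderate Risk)"]] & !out[["CVD (High Risk)"]]
  }
  out
}

#' Conditional-probability implication matrix
#'
#' Entry (A, B) is `P(B | A) = N_{A and B} / N_A`, the fraction of patients
#' with condition A who also have condition B. Conditions no patient has
#' yield a zero row (with a warning); the diagonal is 1 for conditions with
#' `N_A > 0`. The matrix is the adjacency matrix of the directed comorbidity
#' network: the edge A -> B carries `P(B | A)` ("A implies B"), the reading
#' under which hubs act as precursors. Set `direction = "reverse"` for the
#' transposed convention.
#'
#' @param flags per-patient condition flags from [diagnose()].
#' @param direction `"forward"` (edge weight `P(B|A)`) or `"reverse"`.
#' @return an `implication_matrix`: list with `P` (square matrix), `n_a`
#'   (per-condition counts), `n_ab` (pair counts), `conditions`.
#' @export
implication_matrix <- function(flags, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  conds <- setdiff(names(flags), c("patient_id", "year", "month"))
  if (!nrow(flags)) stop("at least one patient is required", call. = FALSE)
  m <- as.matrix(flags[conds]) * 1
  n_ab <- crossprod(m)                       # N_{A and B}
  n_a <- diag(n_ab)
  if (any(n_a == 0)) {
    warning("condition(s) with zero prevalence: ",
            paste(conds[n_a == 0], collapse = ", "),
            " (implication rows set to 0)")
  }
  P <- n_ab / ifelse(n_a == 0, Inf, n_a)     # row A, col B: P(B|A)
  if (direction == "reverse") P <- t(P)
  dimnames(P) <- list(conds, conds)
  structure(list(P = P, n_a = stats::setNames(n_a, conds), n_ab = n_ab,
                 conditions = conds, direction = direction),
            class = "implication_matrix")
}

#' @export
print.implication_matrix <- function(x, ...) {
  cat("Implication matrix over", length(x$conditions), "conditions",
      sprintf("(edge A->B = P(B|A), %s)\n", x$direction))
  print(round(x$P, 3))
  invisible(x)
}

#' HITS hub and authority scores of the comorbidity network
#'
#' Power iteration `h <- M a`, `a <- M' h` with L2 normalization each step,
#' on the implication matrix with the diagonal excluded; equivalently the
#' dominant eigenvectors of `M M'` and `M' M`. High-hub conditions act as
#' precursors (point to many downstream comorbidities); high-authority
#' conditions are common complications/endpoints.
#'
#' @param matrix an `implication_matrix` or a non-negative square matrix.
#' @param tol convergence tolerance on the score change (default 1e-12).
#' @param max_iter iteration cap.
#' @return tibble: condition, hub, authority; each score vector has unit
#'   L2 norm.
#' @export
hits_scores <- function(matrix, tol = 1e-12, max_iter = 10000) {
  M <- if (inherits(matrix, "implication_matrix")) matrix$P else as.matrix(matrix)
  if (nrow(M) != ncol(M)) stop("matrix must be square", call. = FALSE)
  diag(M) <- 0
  if (all(M == 0)) stop("all-zero matrix: no edges to score", call. = FALSE)
  n <- nrow(M)
  h <- rep(1 / sqrt(n), n)
  a <- h
  for (i in seq_len(max_iter)) {
    h_new <- as.vector(M %*% a)
    h_new <- h_new / sqrt(sum(h_new^2))
    a_new <- as.vector(crossprod(M, h_new))
    a_new <- a_new / sqrt(sum(a_new^2))
    if (max(abs(h_new - h)) < tol && max(abs(a_new - a)) < tol) {
      h <- h_new; a <- a_new
      break
    }
    h <- h_new; a <- a_new
  }
  tibble::tibble(condition = rownames(M) %||% paste0("node", seq_len(n)),
                 hub = h, authority = a)
}

#' Prune the weakest edges of the implication network
#'
#' Off-diagonal positive-weight edges are sorted by weight descending and the
#' strongest `ceiling(keep_fraction * E)` retained; ties at the cut weight
#' are all retained.
#'
#' @param matrix an `implication_matrix` or non-negative square matrix.
#' @param keep_fraction fraction of edges to keep, in (0, 1].
#' @return tibble edge list: source, target, weight (sorted by weight
#'   descending).
#' @export
prune_edges <- function(matrix, keep_fraction = 0.75) {
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1) {
    stop("keep_fraction must lie in (0, 1]", call. = FALSE)
  }
  M <- if (inherits(matrix, "implication_matrix")) matrix$P else as.matrix(matrix)
  nm <- rownames(M) %||% paste0("node", seq_len(nrow(M)))
  idx <- which(M > 0 & row(M) != col(M), arr.ind = TRUE)
  edges <- tibble::tibble(source = nm[idx[, 1]], target = nm[idx[, 2]],
                          weight = M[idx])
  edges <- dplyr::arrange(edges, dplyr::desc(.data$weight),
                          .data$source, .data$target)
  n_keep <- ceiling(keep_fraction * nrow(edges))
  if (n_keep < nrow(edges)) {
    cut_w <- edges$weight[n_keep]
    n_keep <- max(which(edges$weight >= cut_w))   # ties at the cut retained
  }
  edges[seq_len(n_keep), ]
}
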