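# Rule-based diagnoses, implication matrix, HITS scores, edge pruning.

panel_row <- function(id, CHOL = NA, TRIG = NA, HDL = NA, LDL = NA,
                      VLDL = NA, A1C = NA, CREA = NA) {
  tibble::tibble(patient_id = id, year = 2020, month = 1, CHOL = CHOL,
                 TRIG = TRIG, HDL = HDL, LDL = LDL, VLDL = VLDL,
                 A1C = A1C, CREA = CREA)
}

test_that("diagnostic rules apply strict inequalities exactly", {
  tab <- dplyr::bind_rows(
    panel_row("a", A1C = 7.0),
    panel_row("b", A1C = 6.5),     # boundary: strict >, not flagged
    panel_row("c", CHOL = 210, HDL = 40, LDL = 40),  # ratio 5.25 -> high risk
    panel_row("d", CHOL = 200),    # boundary
    panel_row("e", CHOL = 200.5),
    panel_row("f", CREA = 1.3),
    panel_row("g", TRIG = 150))
  fl <- diagnose(tab)
  get <- function(id, cond) fl[[cond]][fl$patient_id == id]
  expect_true(get("a", "Diabetes Mellitus"))
  expect_false(get("b", "Diabetes Mellitus"))
  expect_true(get("c", "CVD (High Risk)"))
  expect_false(get("c", "CVD (Moderate Risk)"))
  expect_false(get("d", "Hypercholesterolemia"))
  expect_true(get("e", "Hypercholesterolemia"))
  expect_false(get("f", "Chronic Kidney Disease"))
  expect_false(get("g", "Hypertriglyceridemia"))

  # CVD moderate band: 4 < ratio < 5
  mid <- panel_row("m", CHOL = 225, HDL = 50, LDL = 50)   # ratio 4.5
  flm <- diagnose(mid)
  expect_true(flm[["CVD (Moderate Risk)"]])
  expect_false(flm[["CVD (High Risk)"]])

  # absent analyte column: error names the rule
  expect_error(diagnose(tab[, c("patient_id", "A1C")]),
               "Hypercholesterolemia.*CHOL")
})

test_that("lifetime aggregation flags any qualifying month; high beats moderate", {
  tab <- dplyr::bind_rows(
    panel_row("p", CHOL = 225, HDL = 50, LDL = 50),             # moderate
    dplyr::mutate(panel_row("p", CHOL = 300, HDL = 50, LDL = 50),
                  month = 2))                                   # high
  fl <- diagnose(tab)
  expect_true(fl[["CVD (High Risk)"]])
  expect_false(fl[["CVD (Moderate Risk)"]])    # mutually exclusive flags
  flm <- diagnose(tab, cooccurrence = "same_month")
  expect_equal(nrow(flm), 2)
  expect_true(flm[["CVD (Moderate Risk)"]][flm$month == 1])
})

test_that("implication matrix equals brute-force pairwise counting", {
  # P(B|A) arithmetic: 10 patients with A, 4 of them also B
  flags <- tibble::tibble(patient_id = sprintf("p%02d", 1:12),
                          A = c(rep(TRUE, 10), FALSE, FALSE),
                          B = c(rep(TRUE, 4), rep(FALSE, 6), TRUE, FALSE))
  im <- implication_matrix(flags)
  expect_equal(im$P["A", "B"], 0.4)
  expect_equal(im$P["A", "A"], 1)
  # A subset of B implies P(B|A) = 1
  flags$C <- flags$A
  expect_equal(implication_matrix(flags)$P["A", "C"], 1)

  # brute-force double loop over patients on a random 50-patient fixture
  set.seed(14)
  f50 <- tibble::tibble(patient_id = sprintf("q%02d", 1:50))
  for (cond in c("c1", "c2", "c3", "c4")) {
    f50[[cond]] <- stats::runif(50) < 0.4
  }
  im50 <- implication_matrix(f50)
  conds <- c("c1", "c2", "c3", "c4")
  brute <- matrix(0, 4, 4, dimnames = list(conds, conds))
  for (a in conds) {
    for (b in conds) {
      na <- 0; nab <- 0
      for (i in 1:50) {
        if (f50[[a]][i]) {
          na <- na + 1
          if (f50[[b]][i]) nab <- nab + 1
        }
      }
      brute[a, b] <- if (na > 0) nab / na else 0
    }
  }
  expect_equal(im50$P, brute)

  # zero-prevalence condition: warning and zero row
  f50$none <- FALSE
  expect_warning(imz <- implication_matrix(f50), "zero prevalence")
  expect_true(all(imz$P["none", ] == 0))

  # reverse direction is the transpose
  expect_equal(implication_matrix(f50[1:5], direction = "reverse")$P,
               t(implication_matrix(f50[1:5])$P))
})

test_that("HITS matches the eigen decomposition and its invariances", {
  # single edge A -> B
  m <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  h <- hits_scores(m)
  expect_equal(h$hub, c(1, 0))
  expect_equal(h$authority, c(0, 1))

  # symmetric matrix: hub == authority
  set.seed(15)
  s <- matrix(stats::runif(16), 4)
  s <- s + t(s)
  hs <- hits_scores(s)
  expect_equal(hs$hub, hs$authority, tolerance = 1e-9)

  # random 6x6 non-negative matrix vs dominant eigenvectors of M'M / MM'
  M <- matrix(stats::runif(36), 6)
  h6 <- hits_scores(M)
  M0 <- M; diag(M0) <- 0
  ea <- eigen(crossprod(M0))$vectors[, 1]
  eh <- eigen(tcrossprod(M0))$vectors[, 1]
  cos_sim <- function(u, v) abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  expect_gt(cos_sim(h6$authority, ea), 1 - 1e-8)
  expect_gt(cos_sim(h6$hub, eh), 1 - 1e-8)

  # invariant to uniform scaling
  h6b <- hits_scores(10 * M)
  expect_equal(h6$hub, h6b$hub, tolerance = 1e-10)

  expect_error(hits_scores(matrix(0, 3, 3)), "all-zero")
})

test_that("edge pruning keeps the strongest fraction with ties", {
  m <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m[1, 2] <- 0.9; m[1, 3] <- 0.8; m[2, 1] <- 0.7; m[2, 3] <- 0.6
  m[3, 1] <- 0.5; m[3, 2] <- 0.4
  e6 <- prune_edges(m, 1.0)
  expect_equal(nrow(e6), 6)
  e <- prune_edges(m, 0.5)
  expect_equal(nrow(e), 3)
  expect_equal(e$weight, c(0.9, 0.8, 0.7))

  # 8 edges, keep 0.75 -> ceiling gives 6
  m8 <- matrix(0, 4, 4)
  m8[cbind(c(1, 1, 1, 2, 2, 3, 3, 4), c(2, 3, 4, 1, 3, 1, 2, 1))] <- (8:1) / 10
  expect_equal(nrow(prune_edges(m8, 0.75)), 6)

  # all weights equal: ties at the cut keep everything
  meq <- matrix(0.5, 3, 3); diag(meq) <- 0
  expect_equal(nrow(prune_edges(meq, 0.5)), 6)
  expect_error(prune_edges(m, 0), "keep_fraction")
})

test_that("diabetes implies elevated triglycerides on the synthetic cohort", {
  fx <- fixture_small_cohort()
  fl <- diagnose(fx$wide)
  p_htg <- mean(fl[["Hypertriglyceridemia"]])
  im <- implication_matrix(fl)
  expect_gt(im$P["Diabetes Mellitus", "Hypertriglyceridemia"], p_htg)
})

test_that("rules round-trip through the text config", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "Diabetes Mellitus: A1C > 6.5",
               "Custom: CHOL / HDL > 4"), path)
  rules <- read_rules(path)
  expect_length(rules, 2)
  expect_equal(rules[[2]]$condition, "Custom")
  expect_setequal(rules[[2]]$requires, c("CHOL", "HDL"))
  fl <- diagnose(panel_row("x", CHOL = 210, HDL = 50, A1C = 7), rules)
  expect_true(fl[["Diabetes Mellitus"]])
  expect_true(fl[["Custom"]])
})
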