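# End-to-end orchestration: simulate -> preprocess -> fit/RI -> mortality ->
# network, with one master seed fanned out per stage and a run manifest.

#' Pipeline run configuration
#'
#' A single master seed propagates to every stochastic stage through named
#' substreams ([derive_seed()]), so e.g. changing bootstrap settings never
#' perturbs cohort generation.
#'
#' @param cohort a [cohort_config()] (its seed is overridden by `seed`).
#' @param hyperparams a [fit_hyperparams()].
#' @param ages stratum center ages for the RI curves.
#' @param analytes analytes reported in the RI table.
#' @param scenarios RI scenarios to compute.
#' @param window sliding age-window half-width.
#' @param conditioning scenario conditioning values.
#' @param bootstrap list with `n_boot` and `frac` (study defaults 100, 0.5);
#'   set `n_boot = 0` to skip bootstrap errors in the pipeline run.
#' @param apply_mortality thin the simulated cohort by selective mortality
#'   before analysis.
#' @param census list with `population_size` and `years` for the synthetic
#'   census table.
#' @param input_csv optional path to a long-format results CSV to analyze
#'   instead of simulating.
#' @param rules_file optional path to a diagnostic-rules text file.
#' @param seed master integer seed.
#' @export
run_config <- function(cohort = cohort_config(),
                       hyperparams = fit_hyperparams(),
                       ages = c(30, 45, 60, 75),
                       analytes = c("CHOL", "TRIG", "HDL", "LDL"),
                       scenarios = c("overall", "diabetic", "renal", "healthy"),
                       window = 2,
                       conditioning = default_scenarios(),
                       bootstrap = list(n_boot = 0, frac = 0.5),
                       apply_mortality = TRUE,
                       census = list(population_size = 2e6, years = 2020:2024),
                       input_csv = NULL,
                       rules_file = NULL,
                       seed = 1L) {
  cfg <- list(cohort = cohort, hyperparams = hyperparams, ages = ages,
              analytes = analytes, scenarios = scenarios, window = window,
              conditioning = conditioning, bootstrap = bootstrap,
              apply_mortality = apply_mortality, census = census,
              input_csv = input_csv, rules_file = rules_file,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

write_table <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: `simulate` (cohort + census with ground truth, unless an input CSV
#' is supplied), `preprocess` (coarse-grain, merge, plausibility filter),
#' `ri` (stratified mixture fits and RI curves, optional bootstrap errors),
#' `mortality` (annual rates, survival, Gompertz check), `network`
#' (diagnoses, implication matrix, HITS scores, pruned edge list). All
#' tables are written as CSV under `out_dir` together with a `manifest.json`
#' recording the config hash, seed, stage timings and row counts. Reruns
#' with the same config and seed reproduce all outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory artifacts and the manifest.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("refmix_run")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = rlang::hash(unclass(config)),
                   seed = config$seed, stages = list())
  artifacts <- list()
  t_all <- Sys.time()

  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      rows = if (is.data.frame(res)) nrow(res) else NA)
    res
  }

  specs <- default_analyte_specs()

  # ---- simulate
  if (is.null(config$input_csv)) {
    sim <- run_stage("simulate", function() {
      cc <- config$cohort
      cc$seed <- derive_seed(config$seed, "cohort_stage")
      sim <- generate_cohort(cc)
      if (config$apply_mortality) {
        sim$results <- apply_selective_mortality(
          sim$results, sim$truth, cc$mortality,
          seed = derive_seed(config$seed, "mortality_stage"))
      }
      sim$census <- generate_census_counts(
        population_size = config$census$population_size,
        mortality_params = cc$mortality,
        years = config$census$years,
        seed = derive_seed(config$seed, "census_stage"))
      sim
    })
    raw <- sim$results
    census <- sim$census
    write_table(raw, out_dir, "cohort.csv")
    write_table(sim$truth$labels, out_dir, "truth_labels.csv")
    write_table(census, out_dir, "census.csv")
  } else {
    raw <- NULL
    census <- NULL
  }

  # ---- preprocess
  wide <- run_stage("preprocess", function() {
    if (!is.null(config$input_csv)) {
      raw <<- tibble::as_tibble(utils::read.csv(config$input_csv))
      need <- c("patient_id", "year", "month", "analyte", "value")
      if (!all(need %in% names(raw))) {
        stop("input CSV lacks required columns: ",
             paste(setdiff(need, names(raw)), collapse = ", "))
      }
    }
    cg <- coarse_grain(raw)
    merged <- merge_panels(cg)
    filter_implausible(merged, specs)
  })
  write_table(wide$report, out_dir, "rejections.csv")
  wide <- wide$table
  artifacts$biomarkers <- wide

  # ---- ri
  ri <- run_stage("ri", function() {
    hp <- config$hyperparams
    hp$seed <- derive_seed(config$seed, "fit_stage")
    models <- fit_stratum_models(wide, config$ages, c("M", "F"), config$window,
                                 ASSAYED_ANALYTES, specs, hp)
    for (key in names(models)) {
      write_mixture_model(models[[key]], file.path(out_dir,
                                                   paste0("model_", key, ".json")))
    }
    tab <- estimate_ri_curves(wide, config$analytes, config$scenarios,
                              config$ages, window = config$window,
                              conditioning = config$conditioning,
                              specs = specs, hyperparams = hp, models = models)
    if (config$bootstrap$n_boot >= 2) {
      bs <- dplyr::bind_rows(lapply(seq_len(nrow(tab)), function(i) {
        bootstrap_ri(wide, tab$analyte[i], tab$scenario[i], tab$sex[i],
                     tab$age[i], config$window,
                     n_boot = config$bootstrap$n_boot,
                     frac = config$bootstrap$frac,
                     seed = derive_seed(config$seed, "boot_stage"),
                     conditioning = config$conditioning, specs = specs,
                     hyperparams = hp)
      }))
      tab$boot_low_sd <- bs$low_sd
      tab$boot_high_sd <- bs$high_sd
    }
    tab
  })
  write_table(ri, out_dir, "reference_intervals.csv")
  artifacts$ri <- ri

  # ---- mortality
  if (!is.null(census)) {
    mort <- run_stage("mortality", function() {
      rates <- annual_mortality(census)
      surv <- survival_function(rates)
      gomp <- gompertz_check(rates)
      list(rates = rates, survival = surv, gompertz = gomp)
    })
    write_table(dplyr::left_join(mort$rates, mort$survival,
                                 by = c("sex", "age")),
                out_dir, "mortality.csv")
    write_table(mort$gompertz, out_dir, "gompertz.csv")
    artifacts$mortality <- mort
  }

  # ---- network
  net <- run_stage("network", function() {
    rules <- if (!is.null(config$rules_file)) read_rules(config$rules_file)
             else default_rules()
    flags <- diagnose(wide, rules)
    imat <- implication_matrix(flags)
    list(flags = flags, imat = imat,
         hits = hits_scores(imat),
         edges = prune_edges(imat, 0.75))
  })
  utils::write.csv(net$imat$P, file.path(out_dir, "implication_matrix.csv"))
  write_table(net$hits, out_dir, "hits_scores.csv")
  write_table(net$edges, out_dir, "network_edges.csv")
  artifacts$network <- net

  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  artifacts$manifest <- manifest
  artifacts$out_dir <- out_dir
  invisible(artifacts)
}
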