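#' Pipeline configuration
#'
#' Collects every stage's settings into one serializable list. Either the
#' synthetic generators supply the data (the default) or `visits_csv` /
#' `posts_jsonl` point at user files. The global seed fans out to the
#' stages by fixed offsets (simulation +0, classifier training +11,
#' permutations +23), so any stage can be re-run in isolation.
#'
#' @param seed Global seed.
#' @param sim A [sim_config()] for the synthetic stage.
#' @param visits_csv,posts_jsonl Optional paths to real inputs
#'   (`month,visits,enrollment` CSV; JSONL post stream).
#' @param outcomes Outcomes to classify and use downstream.
#' @param exog_outcomes Outcomes whose prevalence enters model M1
#'   (psychosis is excluded by default).
#' @param window Decomposition moving-window width (months).
#' @param max_lag Largest lag scanned.
#' @param k,anchor Cross-validation folds and anchor months.
#' @param exog_combine How M1's covariates enter the model: `"pc1"`
#'   (default: first principal component of the shifted prevalence series)
#'   or `"none"` (raw columns); see [cv_predict()].
#' @param grid_preset SARIMA order grid preset (see [sarima_order_grid()]).
#' @param n_perm Permutations for the forecast null.
#' @param top_k Salient terms reported per direction.
#' @param sage_max_terms Vocabulary cap for the SAGE contrast (most frequent
#'   n-grams kept).
#' @param lexicon_path Path to a `.dic` lexicon; defaults to the small open
#'   demonstration lexicon shipped with the package.
#' @param prevalence_from `"classifier"` (label posts with the trained SVMs)
#'   or `"lexicon"` (direct symptom-lexicon token frequency; cheap, no
#'   training stage).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            visits_csv = NULL, posts_jsonl = NULL,
                            outcomes = c("depression", "anxiety", "stress",
                                         "suicidal_ideation", "psychosis"),
                            exog_outcomes = c("depression", "anxiety",
                                              "stress", "suicidal_ideation"),
                            window = 12L, max_lag = 6L,
                            k = 10L, anchor = 12L, exog_combine = "pc1",
                            grid_preset = "small",
                            n_perm = 1000L, top_k = 25L,
                            sage_max_terms = 4000L,
                            lexicon_path = system.file("extdata",
                                                       "demo_lexicon.dic",
                                                       package = "campusmh"),
                            prevalence_from = c("classifier", "lexicon")) {
  structure(list(seed = as.integer(seed), sim = sim, visits_csv = visits_csv,
                 posts_jsonl = posts_jsonl, outcomes = outcomes,
                 exog_outcomes = exog_outcomes, window = as.integer(window),
                 max_lag = as.integer(max_lag), k = as.integer(k),
                 anchor = as.integer(anchor), exog_combine = exog_combine,
                 grid_preset = grid_preset,
                 n_perm = as.integer(n_perm), top_k = as.integer(top_k),
                 sage_max_terms = as.integer(sage_max_terms),
                 lexicon_path = lexicon_path,
                 prevalence_from = match.arg(prevalence_from)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [pipeline_config()] (and of its `sim` block) may be set
#' in a YAML file; unknown keys are rejected.
#'
#' @param path YAML file.
#' @param seed Optional seed overriding the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim
  raw$sim <- NULL
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop(sprintf("unknown config keys: %s",
                                paste(bad, collapse = ", ")))
  if (!is.null(seed)) raw$seed <- seed
  if (!is.null(sim_args)) {
    if (!is.null(raw$seed)) sim_args$seed <- raw$seed
    raw$sim <- do.call(sim_config, sim_args)
  }
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Sequences simulate (or ingest) -> train -> label -> analyze -> forecast
#' -> salience and returns a consolidated report: per-outcome prevalence
#' summaries, the lag-scan table, baseline vs augmented SARIMA metrics with
#' comparison statistics and permutation null, top salient n-grams in Hi/Lo
#' consultation months, and the FDR-controlled category comparison. The
#' covariates of model M1 are shifted by each outcome's best scanned lag
#' when that lag is positive. Deterministic given the config.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, writes the simulated
#'   inputs, prevalence/predictions CSVs and the JSON report there.
#' @param verbose Print stage progress.
#' @return A `run_report` list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  cfg <- config$sim
  # -- data: simulate or ingest ------------------------------------------
  if (!is.null(config$visits_csv)) {
    if (!file.exists(config$visits_csv))
      stop(sprintf("pipeline stage 'ingest' failed: visits file not found: %s",
                   config$visits_csv), call. = FALSE)
    vt <- stage("ingest", read_consultations_csv(config$visits_csv))
    consult <- normalize_consultations(vt$visits, vt$enrollment, vt$month)
    cal <- stage("ingest", make_calendar(nrow(consult), cfg$seed,
                                         consult$month[1L]))
  } else {
    say("simulate: %d months", cfg$n_months)
    cal <- stage("simulate", make_calendar(cfg$n_months, cfg$seed, cfg$start,
                                           cfg$peak_months, cfg$trough_months,
                                           cfg$seasonal_amplitude,
                                           cfg$trend_slope))
    consult <- stage("simulate", gen_consultations(cal, cfg))
  }
  if (!is.null(config$posts_jsonl)) {
    if (!file.exists(config$posts_jsonl))
      stop(sprintf("pipeline stage 'ingest' failed: posts file not found: %s",
                   config$posts_jsonl), call. = FALSE)
    posts <- stage("ingest", read_posts_jsonl(config$posts_jsonl))
  } else {
    posts <- stage("simulate", gen_posts(cal, consult, cfg))
  }
  # -- train + label ------------------------------------------------------
  outcomes <- intersect(config$outcomes, names(cfg$lexicons))
  classifiers <- NULL
  if (config$prevalence_from == "classifier") {
    say("train: %d outcome classifiers", length(outcomes))
    corp <- stage("train", gen_training_corpora(cfg))
    classifiers <- stage("train", lapply(outcomes, function(o)
      train_classifier(corp$positives[[o]], corp$negatives, outcome = o,
                       seed = config$seed + 11L)))
    names(classifiers) <- outcomes
    say("label: %d posts", nrow(posts))
    posts <- stage("label", label_posts(classifiers, posts))
    prevalence <- lapply(outcomes, function(o)
      monthly_prevalence(posts, o))
  } else {
    prevalence <- lapply(outcomes, function(o)
      monthly_term_frequency(posts, cfg$lexicons[[o]]))
  }
  names(prevalence) <- outcomes
  prevalence <- lapply(prevalence, fill_month_gaps)
  # -- analyze: residualize + lag scan -----------------------------------
  say("analyze: residualize and lag scan")
  vres <- stage("analyze",
                suppressWarnings(residualize(consult, config$window)))
  scans <- stage("analyze", lapply(prevalence, function(s) {
    er <- suppressWarnings(residualize(s, config$window))
    lag_scan(vres, er, config$max_lag)
  }))
  best_lag <- vapply(scans, function(sc) sc$lag[which.max(sc$e)], 0L)
  # -- forecast -----------------------------------------------------------
  say("forecast: anchored %d-fold CV", config$k)
  grid <- sarima_order_grid(config$grid_preset)
  exog_outcomes <- intersect(config$exog_outcomes, outcomes)
  exog <- prevalence[exog_outcomes]
  pred0 <- stage("forecast", cv_predict(consult, NULL, k = config$k,
                                        anchor = config$anchor, grid = grid))
  pred1 <- stage("forecast", cv_predict(consult, exog, k = config$k,
                                        anchor = config$anchor, grid = grid,
                                        exog_lag = pmax(best_lag[exog_outcomes],
                                                        0L),
                                        exog_combine = config$exog_combine))
  comparison <- stage("forecast",
                      compare_models(pred0, pred1, n_perm = config$n_perm,
                                     seed = config$seed + 23L))
  # -- salience -----------------------------------------------------------
  say("salience: median split, SAGE, lexicon profiling")
  split <- stage("salience", median_split(consult, posts))
  hi_counts <- corpus_ngram_counts(split$hi_docs)
  lo_counts <- corpus_ngram_counts(split$lo_docs)
  shared <- intersect(names(hi_counts), names(lo_counts))
  shared <- shared[order(-(hi_counts[shared] + lo_counts[shared]))]
  shared <- utils::head(shared, config$sage_max_terms)
  sage <- stage("salience",
                fit_sage(hi_counts[shared], lo_counts[shared],
                         max_iter = 2000L))
  lex <- stage("salience", read_dic(config$lexicon_path))
  hi_prof <- stage("salience", lexicon_profile(split$hi_docs, lex))
  lo_prof <- stage("salience", lexicon_profile(split$lo_docs, lex))
  categories <- stage("salience", compare_categories(hi_prof, lo_prof))
  # -- report -------------------------------------------------------------
  report <- structure(list(
    config = config,
    months = consult$month,
    consultations = consult,
    prevalence_summary = data.frame(
      outcome = outcomes,
      mean_prevalence = vapply(prevalence, function(s) mean(s$value), 0),
      row.names = NULL),
    lag_scan = do.call(rbind, lapply(outcomes, function(o)
      cbind(outcome = o, scans[[o]]))),
    best_lag = best_lag,
    classifier_accuracy = if (!is.null(classifiers))
      vapply(classifiers, `[[`, 0, "heldout_accuracy") else NULL,
    predictions = data.frame(month = pred0$month, actual = pred0$actual,
                             pred_m0 = pred0$predicted,
                             pred_m1 = pred1$predicted),
    comparison = comparison,
    sage_top_hi = top_salient(sage, config$top_k, "positive"),
    sage_top_lo = top_salient(sage, config$top_k, "negative"),
    category_comparison = categories,
    provenance = list(seed = config$seed,
                      package_version =
                        as.character(utils::packageVersion("campusmh")))),
    class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir,
                                          prevalence = prevalence)
  report
}

# serialize report artifacts; every number in the JSON comes from the
# report object itself
write_run_report <- function(report, out_dir, prevalence = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(prevalence))
    write_series_csv(prevalence, file.path(out_dir, "prevalence.csv"))
  utils::write.csv(report$predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$lag_scan, file.path(out_dir, "lag_scan.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$category_comparison,
                   file.path(out_dir, "category_comparison.csv"),
                   row.names = FALSE, quote = FALSE)
  cmp <- report$comparison
  js <- list(
    seed = report$provenance$seed,
    package_version = report$provenance$package_version,
    prevalence_summary = report$prevalence_summary,
    classifier_accuracy = report$classifier_accuracy,
    best_lag = as.list(report$best_lag),
    metrics = list(
      M0 = cmp$metrics_m0[c("pearson_r", "mae", "smape")],
      M1 = cmp$metrics_m1[c("pearson_r", "mae", "smape")]),
    delta_r_percent = cmp$delta_r_percent,
    delta_error_percent = cmp$delta_error_percent,
    steiger_t = cmp$steiger$t,
    steiger_p = cmp$steiger$p_value,
    permutation = list(mean_r = cmp$permutation_m1$mean_r,
                       mean_smape = cmp$permutation_m1$mean_smape,
                       prob_better_m0 = cmp$permutation_m0$prob_better,
                       prob_better_m1 = cmp$permutation_m1$prob_better),
    sage_top_hi = report$sage_top_hi,
    sage_top_lo = report$sage_top_lo)
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @exportS3Method base::print
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d months, seed %d\n", length(x$months),
              x$provenance$seed))
  cat("\nPrevalence (mean monthly share):\n")
  print(x$prevalence_summary, row.names = FALSE)
  cat("\nForecast comparison:\n")
  print(x$comparison)
  cat("\nTop Hi-month terms: ",
      paste(utils::head(x$sage_top_hi$term, 8L), collapse = ", "), "\n")
  cat("Top Lo-month terms: ",
      paste(utils::head(x$sage_top_lo$term, 8L), collapse = ", "), "\n")
  sig <- x$category_comparison$category[x$category_comparison$significant]
  cat("FDR-significant categories:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}
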