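# End-to-end pipeline: simulate -> impute -> fit GRM -> features ->
# train -> threshold -> evaluate, with reproducible artifacts.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full screening pipeline on a synthetic cohort
#'
#' Stages: simulate the cohort (see [cohort_config()]), impute missing
#' responses ([iterative_impute()]), fit one graded response model per
#' scale ([fit_grm()]), build the low-quality-response feature table
#' ([build_feature_table()]), split train/test with matched prevalence
#' ([stratified_split()]), train the requested risk model, select the
#' referral threshold on the pooled cross-validation validation
#' predictions (never on the test set), and evaluate on the held-out test
#' partition ([stratified_report()], rule-based comparators). Identical
#' configurations reproduce identical artifacts byte for byte.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, all artifacts (CSV
#'   responses and cohort, JSON banks/decision/report/manifest, split
#'   manifest, model file) are written there.
#' @return list with the simulated data, fitted banks, feature table,
#'   split, trained `model`, threshold `decision`, test-set `report` and
#'   rule comparator points.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  seeds <- derive_seeds(config$seed, 5L)

  sim <- .stage("simulate", {
    cc <- cohort_config(
      n_respondents = config$n_respondents,
      prevalence = config$prevalence,
      careless_rate_normal = config$careless_rate_normal,
      careless_rate_impaired = config$careless_rate_impaired,
      skip_rate_normal = config$skip_rate_normal,
      skip_rate_impaired = config$skip_rate_impaired,
      straightline_fraction = config$straightline_fraction,
      reverse_keyed = config$reverse_keyed,
      trait_impairment_shift = config$trait_impairment_shift,
      age_impairment_association = config$age_impairment_association,
      seed = seeds[1])
    out <- simulate_cohort(cc)
    out$cohort <- assign_cognition_scores(out$cohort, seeds[2])
    out
  })
  labels <- derive_ci_label(sim$cohort$cognition_score)$binary_ci
  stopifnot(identical(as.integer(labels), sim$cohort$impairment))

  imputed <- .stage("impute", iterative_impute(sim$responses))
  scales_used <- if (identical(config$scale, "all"))
    unique(itemScales(imputed)) else config$scale
  fits <- .stage("fit-grm", {
    lapply(stats::setNames(scales_used, scales_used), function(s)
      fit_grm(scaleItems(imputed, s)))
  })
  banks <- lapply(fits, `[[`, "bank")
  features <- .stage("features", build_feature_table(
    imputed, banks, cohort = sim$cohort, scales = scales_used,
    include_demographics = config$include_demographics,
    aggregate = config$aggregate,
    log_probability = config$log_probability))

  split <- .stage("split", stratified_split(
    sim$cohort, split_spec(config$test_fraction, "impairment", seeds[3])))
  tr <- sim$cohort$respondent_id %in% split$train
  y <- as.integer(labels)
  cv <- cv_config(config$cv_folds)

  model <- .stage("train", switch(config$model,
    mlp = train_mlp(features[tr, , drop = FALSE], y[tr],
                    mlp_config(max_epochs = config$mlp_max_epochs),
                    cv, seed = seeds[4]),
    raw_response = train_raw_response_baseline(
      imputed[tr, , drop = FALSE], y[tr], cv, seed = seeds[4]),
    train_baseline(config$model, features[tr, , drop = FALSE], y[tr],
                   cv = cv, seed = seeds[4])))

  # referral threshold tuned on pooled CV validation predictions
  decision <- .stage("threshold", select_threshold(
    model$validation_scores, y[tr], config$cost_ratio))

  te <- !tr
  test_features <- if (config$model == "raw_response")
    unclass(as.matrix(imputed))[te, , drop = FALSE]
  else features[te, , drop = FALSE]
  scores_test <- .stage("predict", predict_risk(model, test_features))
  report <- .stage("evaluate", stratified_report(
    scores_test, y[te], sim$cohort[te, , drop = FALSE],
    cost_ratio = config$cost_ratio, threshold = decision$threshold))

  rules <- c("age65", "diabetes", "high_blood_pressure", "heart_disease",
             "stroke")
  rule_points <- list(
    test = lapply(stats::setNames(rules, rules), function(r)
      rule_point(sim$cohort[te, , drop = FALSE], r)),
    full = lapply(stats::setNames(rules, rules), function(r)
      rule_point(sim$cohort, r)))

  result <- list(config = config, responses = sim$responses,
                 imputed = imputed, cohort = sim$cohort, fits = fits,
                 banks = banks, features = features, split = split,
                 model = model, decision = decision,
                 scores_test = scores_test, report = report,
                 rule_points = rule_points)
  if (!is.null(out_dir)) .write_pipeline_artifacts(result, out_dir)
  result
}

.write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_responses(result$responses, p("responses.csv"))
  write_cohort(result$cohort, p("cohort.csv"))
  utils::write.csv(result$split$manifest, p("split.csv"),
                   row.names = FALSE)
  for (s in names(result$banks))
    write_item_bank(result$banks[[s]], p(sprintf("bank_%s.json", s)))
  utils::write.csv(data.frame(respondent_id = rownames(result$features),
                              result$features, check.names = FALSE),
                   p("features.csv"), row.names = FALSE)
  save_model(result$model, p("model.rds"))
  write_decision(result$decision, p("decision.json"))
  write_report(result$report, p("report.json"))
  jsonlite::write_json(result$rule_points, p("rule_points.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c("responses.csv", "cohort.csv", "split.csv",
             sprintf("bank_%s.json", names(result$banks)),
             "features.csv", "model.rds", "decision.json", "report.json",
             "rule_points.json")
  hashes <- tools::md5sum(file.path(out_dir, files))
  names(hashes) <- files
  manifest <- list(
    package = "lqrscreen",
    version = as.character(utils::packageVersion("lqrscreen")),
    config = unclass(result$config),
    files = as.list(hashes))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
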