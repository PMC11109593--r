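# End-to-end orchestration: simulate -> train -> tag -> resolve arms ->
# evaluate extraction -> run the prediction experiment, with seeded stages
# and machine-readable reports. The extraction and prediction evaluations
# are deliberately independent: prediction always consumes gold
# annotations, so tagging errors cannot confound the model comparison.

#' Run the extraction pipeline over documents
#'
#' Tags every document, resolves arms and entity-arm associations, and --
#' when gold studies are supplied -- scores entity F1 and arm-assignment
#' accuracy.
#'
#' @param docs list of `document` objects.
#' @param model a trained `tagger_model`.
#' @param schema the `entity_schema`.
#' @param config an [arm_config()].
#' @param gold optional gold `annotated_study` list over the same docs.
#' @return List with `studies` (predicted `annotated_study` per document),
#'   and, if gold was given, `report` (an `eval_report`) and
#'   `arm_accuracy`.
#' @export
run_extraction <- function(docs, model, schema, config = arm_config(),
                           gold = NULL) {
  abort_if(!inherits(model, "tagger_model"),
           "a trained tagger model is required; train one with train_tagger()",
           class = "trialminer_usage_error")
  studies <- lapply(docs, function(d)
    resolve_document(d, tag_document(model, d), schema, config))
  out <- list(studies = studies)
  if (!is.null(gold)) {
    out$report <- evaluate_extraction(gold, studies, schema)
    out$arm_accuracy <- arm_assignment_accuracy(gold, studies, schema)
  }
  out
}

#' Run the outcome-prediction experiment
#'
#' Five-fold (by default) cross-validation of the four model families over
#' gold-annotated studies, reported as mean RMSE per model.
#'
#' @param studies gold `annotated_study` list.
#' @param schema the `entity_schema`.
#' @param k number of folds.
#' @param seed master seed (folds and all stochastic stages derive from it).
#' @param models model rows to include.
#' @param config a [prediction_config()].
#' @param outcome_entity see [build_feature_vectors()].
#' @return An `rmse_report`.
#' @export
run_prediction_experiment <- function(studies, schema, k = 5L, seed = 1L,
                                      models = c("grand_mean", "linear",
                                                 "entities_only",
                                                 "entities_plus_text"),
                                      config = prediction_config(seed = seed),
                                      outcome_entity = NULL) {
  ids <- vapply(studies, function(st) st$doc$doc_id, character(1))
  abort_if(length(ids) < k, "fewer studies (", length(ids), ") than folds (",
           k, ")", class = "trialminer_usage_error")
  folds <- make_cv_folds(ids, k = k, seed = derive_seed(seed, 999L))
  config$seed <- as.integer(seed)
  evaluate_prediction(studies, folds, schema, models = models, config = config,
                      outcome_entity = outcome_entity)
}

#' Write an evaluation or RMSE report as JSON
#'
#' @param report an `eval_report` or `rmse_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  obj <- if (inherits(report, "eval_report")) {
    list(summary = report$summary, per_entity = report$per_entity)
  } else if (inherits(report, "rmse_report")) {
    list(per_model = report$per_model, per_fold = report$per_fold,
         seed = report$seed, k = report$k)
  } else stop("unknown report type")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Extraction evaluation (per-entity F1 summary)\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s F1 %.2f", s$statistic[i], s$f1[i]))
    if ("benchmark_f1" %in% names(s))
      cat(sprintf("   benchmark %.2f", s$benchmark_f1[i]))
    cat("\n")
  }
  cat(sprintf("  (%d entities scored)\n", nrow(x$per_entity)))
  invisible(x)
}

#' @export
print.rmse_report <- function(x, ...) {
  cat(sprintf("Outcome prediction, %d-fold cross-validated RMSE (seed %d)\n",
              x$k, x$seed))
  labels <- c(grand_mean = "Grand mean",
              linear = "Linear regression",
              entities_only = "ML algorithm, entities only",
              entities_plus_text = "ML algorithm, entities plus text")
  for (i in seq_len(nrow(x$per_model)))
    cat(sprintf("  %-34s %6.2f\n", labels[x$per_model$model[i]],
                x$per_model$rmse[i]))
  invisible(x)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Krippendorff's alpha (nominal): %.3f over %d items%s\n",
              x$alpha, x$n_items,
              if (x$undefined) " [undefined; single category]" else ""))
  invisible(x)
}
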