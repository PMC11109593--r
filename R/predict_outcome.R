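# Per-arm outcome prediction: feature vectors from annotations, a
# grand-mean baseline, an additive linear baseline, and a stacked-LSTM
# regressor over graph-embedded entity sequences, compared by
# cross-validated RMSE.
#
# By design the experiment consumes *gold* annotations, never the tagger's
# output, so extraction errors cannot confound the prediction comparison.

#' Prediction model configuration
#'
#' @param family one of `grand_mean`, `linear`, `recurrent_stack`.
#' @param layers hidden sizes of the stacked recurrent layers (>= 1 layer).
#' @param feature_mode `entities_only`, or `entities_plus_text` to
#'   concatenate mean-pooled context-text embeddings.
#' @param epochs,lr recurrent training schedule.
#' @param graph a [graph_embedding_config()] for the entity co-occurrence
#'   embeddings.
#' @param text_dim dimension of the locally trained context-text skip-gram.
#' @param seed master seed; per-fold and per-stage seeds derive from it.
#' @export
prediction_config <- function(family = c("recurrent_stack", "grand_mean", "linear"),
                              layers = c(16L, 16L),
                              feature_mode = c("entities_only", "entities_plus_text"),
                              epochs = 120L, lr = 0.02,
                              graph = graph_embedding_config(dimensions = 8L),
                              text_dim = 8L, seed = 1L) {
  family <- match.arg(family)
  abort_if(family == "recurrent_stack" && length(layers) < 1,
           "recurrent_stack requires at least one layer")
  structure(list(family = family, layers = as.integer(layers),
                 feature_mode = match.arg(feature_mode),
                 epochs = as.integer(epochs), lr = lr, graph = graph,
                 text_dim = as.integer(text_dim), seed = as.integer(seed)),
            class = "prediction_config")
}

#' Root-mean-square error
#'
#' @param predicted,gold numeric vectors of equal length.
#' @export
rmse <- function(predicted, gold) {
  abort_if(length(predicted) != length(gold), "length mismatch")
  sqrt(mean((predicted - gold)^2))
}

#' Build per-arm feature vectors from gold annotations
#'
#' One sample per arm that has an outcome record. Presence-absence entities
#' become 0/1 flags; value-bearing entities (other than the outcome
#' entities) become raw numeric features, `NA` when unreported.
#' Whole-study annotations propagate to every arm of their study. When an
#' arm reports several outcome entities and none is named explicitly, the
#' one latest in schema order is used (follow-ups are listed
#' shortest-to-longest in the shipped schema).
#'
#' @param studies list of `annotated_study` with outcome records.
#' @param schema the `entity_schema`.
#' @param outcome_entity entity id of the outcome to predict, or `NULL` for
#'   the schema-order rule above.
#' @return A `feature_set`: `samples` (study_id, arm_id, outcome),
#'   `presence` and `numeric` matrices, the feature entity ids, and pooled
#'   context text per sample.
#' @export
build_feature_vectors <- function(studies, schema, outcome_entity = NULL) {
  outcome_ids <- unique(c(outcome_entity,
                          unlist(lapply(studies, function(st) st$outcomes$entity_id))))
  presence_ids <- schema$entity_id[schema$kind == "presence_absence"]
  value_ids <- setdiff(schema$entity_id[schema$kind %in% c("value", "complex_component")],
                       outcome_ids)
  rows <- list()
  for (st in studies) {
    oc <- st$outcomes
    if (!is.null(outcome_entity)) oc <- oc[oc$entity_id == outcome_entity, , drop = FALSE]
    if (nrow(oc) == 0) {
      warning("study ", st$doc$doc_id, " has no outcome record; skipped")
      next
    }
    # per arm: keep the outcome entity latest in schema order
    oc <- oc[order(match(oc$entity_id, schema$entity_id)), , drop = FALSE]
    oc <- oc[!duplicated(oc$arm_id, fromLast = TRUE), , drop = FALSE]
    ent_of <- vapply(st$annotations, function(a) a$entity_id, character(1))
    arm_of <- vapply(st$annotations, function(a) a$arm_ref, character(1))
    val_of <- vapply(st$annotations, function(a) a$value, numeric(1))
    ctx_of <- vapply(st$annotations, function(a) a$context_text, character(1))
    for (k in seq_len(nrow(oc))) {
      aid <- oc$arm_id[k]
      vis <- arm_of == aid | arm_of == WHOLE_STUDY
      pres <- as.numeric(presence_ids %in% ent_of[vis])
      num <- vapply(value_ids, function(e) {
        own <- which(vis & ent_of == e & arm_of == aid)
        ws <- which(vis & ent_of == e)
        i <- if (length(own) > 0) own[1] else if (length(ws) > 0) ws[1] else NA
        if (is.na(i)) NA_real_ else val_of[i]
      }, numeric(1))
      rows[[length(rows) + 1L]] <- list(
        study_id = st$doc$doc_id, arm_id = aid, outcome = oc$value[k],
        pres = pres, num = num,
        context = paste(unique(ctx_of[vis & nzchar(ctx_of)]), collapse = " "))
    }
  }
  abort_if(length(rows) == 0, "no arm has an outcome record",
           class = "trialminer_usage_error")
  structure(list(
    samples = data.frame(
      study_id = vapply(rows, `[[`, character(1), "study_id"),
      arm_id = vapply(rows, `[[`, character(1), "arm_id"),
      outcome = vapply(rows, `[[`, numeric(1), "outcome"),
      stringsAsFactors = FALSE),
    presence = do.call(rbind, lapply(rows, `[[`, "pres")),
    numeric = do.call(rbind, lapply(rows, `[[`, "num")),
    presence_ids = presence_ids, value_ids = value_ids,
    contexts = vapply(rows, `[[`, character(1), "context")),
    class = "feature_set")
}

#' Standardize a feature set
#'
#' Numeric features are centred and scaled; missing values become a
#' missingness flag plus 0 after standardization. Statistics come from the
#' (training) set passed in `stats`, or are computed here -- callers doing
#' cross-validation must fit them on the training fold only.
#'
#' @param fs a `feature_set`.
#' @param stats optional list `(mean, sd)` from a training fold.
#' @return List with the design matrix `X` (presence flags, standardized
#'   numerics, missingness flags -- length = #presence + 2 x #value), the
#'   per-timestep `values`/`missing` matrices used by the recurrent model,
#'   and `stats`.
#' @export
standardize_features <- function(fs, stats = NULL) {
  Z <- fs$numeric
  if (is.null(stats)) {
    mu <- apply(Z, 2, function(x) if (all(is.na(x))) 0 else mean(x, na.rm = TRUE))
    sd_ <- apply(Z, 2, function(x) {
      s <- stats::sd(x, na.rm = TRUE)
      if (is.na(s) || s == 0) 1 else s
    })
    stats <- list(mean = mu, sd = sd_)
  }
  M <- is.na(Z) * 1
  Zs <- sweep(sweep(Z, 2, stats$mean), 2, stats$sd, "/")
  Zs[is.na(Zs)] <- 0
  X <- cbind(fs$presence, Zs, M)
  colnames(X) <- c(paste0("p_", fs$presence_ids), paste0("z_", fs$value_ids),
                   paste0("m_", fs$value_ids))
  list(X = X, presence = fs$presence, z = Zs, missing = M, stats = stats)
}

# ---- model families ----------------------------------------------------------

#' Grand-mean baseline
#'
#' Predicts the training-outcome mean for every input; its training RMSE is
#' the population SD of the training outcomes.
#'
#' @param train_outcomes numeric vector of training outcomes.
#' @return A `grand_mean_model`.
#' @export
fit_grand_mean <- function(train_outcomes) {
  abort_if(length(train_outcomes) < 1, "no training outcomes",
           class = "trialminer_training_error")
  structure(list(mean = mean(train_outcomes)), class = "grand_mean_model")
}

#' @export
predict.grand_mean_model <- function(object, newdata, ...) {
  n <- if (is.matrix(newdata)) nrow(newdata) else
    if (is.numeric(newdata) && length(newdata) == 1) newdata else length(newdata)
  rep(object$mean, n)
}

#' Additive linear baseline
#'
#' Ordinary least squares of the outcome on all features jointly, solved by
#' the minimum-norm pseudoinverse so rank-deficient (e.g. duplicated)
#' designs are handled. Coefficient standard errors use the same
#' pseudoinverse.
#'
#' @param X design matrix (no intercept column; one is added).
#' @param y outcomes.
#' @return A `linear_baseline_model` with `coef` and `se`.
#' @export
fit_linear_baseline <- function(X, y) {
  abort_if(nrow(X) < 2, "need at least 2 training rows",
           class = "trialminer_training_error")
  Xi <- cbind(`(Intercept)` = 1, X)
  sv <- svd(Xi)
  tol <- max(dim(Xi)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  dinv <- ifelse(pos, 1 / sv$d, 0)
  coef <- sv$v %*% (dinv * (t(sv$u) %*% y))
  fitted <- as.numeric(Xi %*% coef)
  df_res <- max(1, nrow(Xi) - sum(pos))
  sigma2 <- sum((y - fitted)^2) / df_res
  xtx_pinv <- sv$v %*% (dinv^2 * t(sv$v))
  se <- sqrt(pmax(0, diag(xtx_pinv)) * sigma2)
  structure(list(coef = setNames(as.numeric(coef), colnames(Xi)),
                 se = setNames(se, colnames(Xi)), sigma2 = sigma2),
            class = "linear_baseline_model")
}

#' @export
predict.linear_baseline_model <- function(object, newdata, ...) {
  as.numeric(cbind(1, newdata) %*% object$coef)
}

# assemble the per-timestep input list for the recurrent model
recurrent_inputs <- function(std, fs, emb, text_vec = NULL) {
  ids <- c(fs$presence_ids, fs$value_ids)
  d <- ncol(emb)
  xs <- vector("list", length(ids))
  for (t in seq_along(ids)) {
    e <- ids[t]
    ev <- if (e %in% rownames(emb)) emb[e, ] else rep(0, d)
    val <- if (t <= length(fs$presence_ids)) std$presence[, t]
    else std$z[, t - length(fs$presence_ids)]
    miss <- if (t <= length(fs$presence_ids)) rep(0, length(val))
    else std$missing[, t - length(fs$presence_ids)]
    x <- cbind(outer(val, ev), val, miss)
    if (!is.null(text_vec)) x <- cbind(x, text_vec)
    xs[[t]] <- x
  }
  xs
}

pool_text <- function(contexts, text_emb) {
  if (is.null(text_emb)) return(NULL)
  t(vapply(contexts, function(ctx) {
    toks <- tolower(tokenize(ctx)$surface)
    hit <- toks[toks %in% rownames(text_emb)]
    if (length(hit) == 0) rep(0, ncol(text_emb))
    else colMeans(text_emb[hit, , drop = FALSE])
  }, numeric(ncol(text_emb)), USE.NAMES = FALSE))
}

#' Fit the stacked recurrent outcome model
#'
#' Entities, in schema order, form the input sequence: each timestep is
#' that entity's co-occurrence-graph embedding scaled by its presence flag
#' or standardized value (plus the scalar and its missingness flag); in
#' `entities_plus_text` mode the sample's mean-pooled context-text
#' embedding is concatenated at every step. A stacked LSTM reads the
#' sequence and a linear readout emits the outcome, trained on standardized
#' targets and clipped to [0, 100] at prediction time.
#'
#' @param fs a `feature_set` of training samples.
#' @param schema the `entity_schema`.
#' @param train_studies the training studies (for the co-occurrence graph
#'   and text embeddings).
#' @param config a [prediction_config()].
#' @return A `recurrent_outcome_model`.
#' @export
fit_recurrent_model <- function(fs, schema, train_studies,
                                config = prediction_config()) {
  abort_if(nrow(fs$samples) == 0, "no training data",
           class = "trialminer_training_error")
  std <- standardize_features(fs)
  gcfg <- config$graph
  gcfg$seed <- derive_seed(config$seed, 7L)
  graph <- build_cooccurrence_graph(train_studies)
  emb <- if (length(graph$nodes) > 0) learn_graph_embeddings(graph, gcfg)
  else matrix(0, 0, gcfg$dimensions)
  text_emb <- NULL
  if (config$feature_mode == "entities_plus_text")
    text_emb <- learn_text_embeddings(train_studies, dimensions = config$text_dim,
                                      seed = derive_seed(config$seed, 11L))
  text_vec <- pool_text(fs$contexts, text_emb)
  y <- fs$samples$outcome
  y_mu <- mean(y); y_sd <- stats::sd(y); if (is.na(y_sd) || y_sd == 0) y_sd <- 1
  xs <- recurrent_inputs(std, fs, emb, text_vec)
  net <- lstm_fit(xs, (y - y_mu) / y_sd, layers = config$layers,
                  epochs = config$epochs, lr = config$lr,
                  seed = derive_seed(config$seed, 13L))
  structure(list(net = net, emb = emb, text_emb = text_emb,
                 feat_stats = std$stats, y_mu = y_mu, y_sd = y_sd,
                 config = config),
            class = "recurrent_outcome_model")
}

#' @export
predict.recurrent_outcome_model <- function(object, newdata, ...) {
  fs <- newdata
  std <- standardize_features(fs, stats = object$feat_stats)
  text_vec <- pool_text(fs$contexts, object$text_emb)
  xs <- recurrent_inputs(std, fs, object$emb, text_vec)
  raw <- lstm_predict(object$net, xs) * object$y_sd + object$y_mu
  pmin(100, pmax(0, raw))
}

#' Cross-validated RMSE comparison of the prediction models
#'
#' For each fold: fit on the other folds, predict the held-out studies,
#' score by RMSE; report the per-model mean over folds in the fixed row
#' order grand_mean, linear, entities_only, entities_plus_text. Feature
#' standardization, graph embeddings and text embeddings are all fitted on
#' the training fold only.
#'
#' @param studies gold `annotated_study` list (the experiment never uses
#'   tagger output).
#' @param folds a `cv_folds` over the study ids (see [make_cv_folds()]).
#' @param schema the `entity_schema`.
#' @param models subset of the four model rows to run.
#' @param config a [prediction_config()] (supplies the recurrent/graph
#'   settings and the master seed).
#' @param outcome_entity passed to [build_feature_vectors()].
#' @return An `rmse_report`: `per_model` (model, rmse) and `per_fold`
#'   detail.
#' @export
evaluate_prediction <- function(studies, folds, schema,
                                models = c("grand_mean", "linear",
                                           "entities_only", "entities_plus_text"),
                                config = prediction_config(),
                                outcome_entity = NULL) {
  all_models <- c("grand_mean", "linear", "entities_only", "entities_plus_text")
  models <- all_models[all_models %in% models]
  ids <- vapply(studies, function(st) st$doc$doc_id, character(1))
  detail <- list()
  for (f in seq_along(folds$folds)) {
    test_ids <- folds$folds[[f]]
    train <- studies[!ids %in% test_ids]
    test <- studies[ids %in% test_ids]
    train_ids <- vapply(train, function(st) st$doc$doc_id, character(1))
    stopifnot(length(intersect(train_ids, test_ids)) == 0)  # leakage guard
    fs_tr <- build_feature_vectors(train, schema, outcome_entity)
    fs_te <- build_feature_vectors(test, schema, outcome_entity)
    std_tr <- standardize_features(fs_tr)
    std_te <- standardize_features(fs_te, stats = std_tr$stats)
    y_tr <- fs_tr$samples$outcome; y_te <- fs_te$samples$outcome
    fold_seed <- derive_seed(config$seed, f)
    for (mname in models) {
      pred <- switch(
        mname,
        grand_mean = predict(fit_grand_mean(y_tr), length(y_te)),
        linear = predict(fit_linear_baseline(std_tr$X, y_tr), std_te$X),
        entities_only = ,
        entities_plus_text = {
          cfg <- config
          cfg$family <- "recurrent_stack"
          cfg$feature_mode <- if (mname == "entities_only") "entities_only"
          else "entities_plus_text"
          cfg$seed <- fold_seed
          predict(fit_recurrent_model(fs_tr, schema, train, cfg), fs_te)
        })
      detail[[length(detail) + 1L]] <- data.frame(
        model = mname, fold = f, rmse = rmse(pred, y_te), n = length(y_te),
        stringsAsFactors = FALSE)
    }
  }
  detail <- do.call(rbind, detail)
  per_model <- do.call(rbind, lapply(models, function(mname)
    data.frame(model = mname,
               rmse = mean(detail$rmse[detail$model == mname]),
               stringsAsFactors = FALSE)))
  structure(list(per_model = per_model, per_fold = detail,
                 seed = config$seed, k = folds$k),
            class = "rmse_report")
}
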