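# Extraction evaluation: instance matching, per-entity precision / recall /
# F1, Table-shaped summaries, a two-coder human benchmark, nominal
# Krippendorff's alpha, and seeded cross-validation folds.

ann_key <- function(a, schema, criterion) {
  kind <- schema$kind[match(a$entity_id, schema$entity_id)]
  valpart <- if (!is.na(kind) && kind %in% c("value", "complex_component"))
    format(a$value, digits = 15) else ""
  spanpart <- if (criterion == "strict" && !is.null(a$span))
    paste(a$span, collapse = ":") else ""
  paste(a$doc_id, a$entity_id, valpart, spanpart, sep = "\r")
}

flatten_annotations <- function(studies) {
  anns <- unlist(lapply(studies, function(st) st$annotations), recursive = FALSE)
  Filter(function(a) a$entity_id != ARM_NAME, anns %||% list())
}

#' Match predicted against gold annotations
#'
#' Instance-level, 1-to-1 greedy matching in document order. Under the
#' default `"entity"` criterion a predicted instance matches a gold
#' instance with the same document and entity and (for value-bearing
#' entities) the same normalized value; `"strict"` additionally requires
#' identical character spans. Unmatched predictions count as false
#' positives, unmatched gold as false negatives.
#'
#' @param gold,predicted lists of `annotated_study` over the same documents.
#' @param schema the `entity_schema`; annotations referencing unknown
#'   entities are rejected.
#' @param criterion `"entity"` or `"strict"`.
#' @return Data frame (`eval_counts`) with columns `entity_id`, `tp`, `fp`,
#'   `fn`, one row per entity observed on either side.
#' @export
match_annotations <- function(gold, predicted, schema,
                              criterion = c("entity", "strict")) {
  criterion <- match.arg(criterion)
  g <- flatten_annotations(gold)
  p <- flatten_annotations(predicted)
  ids <- unique(vapply(c(g, p), function(a) a$entity_id, character(1)))
  unknown <- setdiff(ids, schema$entity_id)
  abort_if(length(unknown) > 0, "unknown entity_id in annotations: ",
           paste(unknown, collapse = ", "),
           class = "trialminer_validation_error")
  gkey <- vapply(g, ann_key, character(1), schema = schema, criterion = criterion)
  pkey <- vapply(p, ann_key, character(1), schema = schema, criterion = criterion)
  gent <- vapply(g, function(a) a$entity_id, character(1))
  pent <- vapply(p, function(a) a$entity_id, character(1))
  ents <- sort(unique(c(gent, pent)))
  tp <- fp <- fn <- setNames(integer(length(ents)), ents)
  for (e in ents) {
    gt <- table(gkey[gent == e])
    pt <- table(pkey[pent == e])
    shared <- intersect(names(gt), names(pt))
    ntp <- sum(pmin(gt[shared], pt[shared]))
    tp[e] <- ntp
    fp[e] <- sum(pt) - ntp
    fn[e] <- sum(gt) - ntp
  }
  structure(data.frame(entity_id = ents, tp = as.integer(tp),
                       fp = as.integer(fp), fn = as.integer(fn),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("eval_counts", "data.frame"))
}

#' Precision, recall and F1 from match counts
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R); a zero denominator
#' yields 0 (not NaN), so summaries stay total.
#'
#' @param counts an `eval_counts` data frame (or any frame with `tp`, `fp`,
#'   `fn`).
#' @return Data frame with `precision`, `recall`, `f1` per row of `counts`.
#' @export
precision_recall_f1 <- function(counts) {
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  p <- safe_div(counts$tp, counts$tp + counts$fp)
  r <- safe_div(counts$tp, counts$tp + counts$fn)
  f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  out <- counts
  out$precision <- p; out$recall <- r; out$f1 <- f1
  out
}

#' Summarize per-entity scores into an evaluation report
#'
#' Mean, median, maximum and minimum of per-entity F1; when a benchmark
#' score table is supplied (e.g. the human annotator benchmark) the report
#' carries both columns.
#'
#' @param scores data frame from [precision_recall_f1()].
#' @param benchmark optional second score table over the same entities.
#' @return An `eval_report`: list with `per_entity` and `summary`.
#' @export
summarize_scores <- function(scores, benchmark = NULL) {
  abort_if(is.null(scores) || nrow(scores) == 0, "no entity scores to summarize",
           class = "trialminer_usage_error")
  stat <- function(f1) c(mean = mean(f1), median = stats::median(f1),
                         maximum = max(f1), minimum = min(f1))
  s <- data.frame(statistic = c("mean", "median", "maximum", "minimum"),
                  f1 = unname(stat(scores$f1)), stringsAsFactors = FALSE)
  if (!is.null(benchmark)) s$benchmark_f1 <- unname(stat(benchmark$f1))
  structure(list(per_entity = scores, summary = s,
                 benchmark = benchmark), class = "eval_report")
}

#' Score one tagged corpus against gold
#'
#' @param gold,predicted lists of `annotated_study`.
#' @param schema the `entity_schema`.
#' @param criterion matching criterion, see [match_annotations()].
#' @return An `eval_report`.
#' @export
evaluate_extraction <- function(gold, predicted, schema,
                                criterion = c("entity", "strict")) {
  counts <- match_annotations(gold, predicted, schema, criterion)
  summarize_scores(precision_recall_f1(counts))
}

#' Micro-averaged F1 over all entities
#'
#' @param counts an `eval_counts` data frame.
#' @return A list with `precision`, `recall`, `f1` pooled over entities.
#' @export
micro_f1 <- function(counts) {
  pooled <- data.frame(tp = sum(counts$tp), fp = sum(counts$fp),
                       fn = sum(counts$fn))
  s <- precision_recall_f1(pooled)
  list(precision = s$precision, recall = s$recall, f1 = s$f1)
}

#' Benchmark one human coder against another
#'
#' Scores coder B's annotations treating coder A's (pre-consensus) as gold;
#' swapping the coders swaps precision and recall and leaves F1 unchanged.
#'
#' @param annotator_a,annotator_b lists of `annotated_study` covering the
#'   same documents.
#' @param schema the `entity_schema`.
#' @param criterion matching criterion.
#' @return An `eval_report`.
#' @export
human_benchmark <- function(annotator_a, annotator_b, schema,
                            criterion = c("entity", "strict")) {
  docs_a <- vapply(annotator_a, function(st) st$doc$doc_id, character(1))
  docs_b <- vapply(annotator_b, function(st) st$doc$doc_id, character(1))
  abort_if(length(intersect(docs_a, docs_b)) == 0,
           "annotators cover disjoint document sets",
           class = "trialminer_usage_error")
  evaluate_extraction(annotator_a, annotator_b, schema, criterion)
}

#' Krippendorff's alpha for two coders, nominal data
#'
#' Chance-corrected agreement `alpha = 1 - Do/De` from the coincidence
#' matrix: `Do` the observed and `De` the expected disagreement. Items
#' missing a code from either coder are dropped. When every item carries
#' the single same category, alpha is undefined; it is reported as 1 with a
#' warning.
#'
#' @param codes1,codes2 equal-length vectors of nominal codes (`NA`
#'   allowed).
#' @return An `agreement_report`: list with `alpha`, `n_items`,
#'   `undefined`.
#' @export
krippendorff_alpha <- function(codes1, codes2) {
  abort_if(length(codes1) != length(codes2), "coders must code the same items",
           class = "trialminer_usage_error")
  keep <- !is.na(codes1) & !is.na(codes2)
  c1 <- as.character(codes1[keep]); c2 <- as.character(codes2[keep])
  abort_if(length(c1) < 2, "need at least 2 pairable items",
           class = "trialminer_usage_error")
  cats <- sort(unique(c(c1, c2)))
  K <- length(cats)
  # coincidence matrix: each item contributes both ordered pairs of its codes
  o <- matrix(0, K, K, dimnames = list(cats, cats))
  for (i in seq_along(c1)) {
    a <- c1[i]; b <- c2[i]
    o[a, b] <- o[a, b] + 1
    o[b, a] <- o[b, a] + 1
  }
  n <- sum(o)
  nc <- rowSums(o)
  do_ <- sum(o) - sum(diag(o))
  de_ <- (sum(outer(nc, nc)) - sum(nc^2)) / (n - 1)
  if (de_ == 0) {
    warning("alpha undefined: a single category across all items; reporting 1")
    return(structure(list(alpha = 1, n_items = length(c1), undefined = TRUE),
                     class = "agreement_report"))
  }
  structure(list(alpha = 1 - (do_ / n) / (de_ / n), n_items = length(c1),
                 undefined = FALSE),
            class = "agreement_report")
}

#' Inter-annotator agreement over a double-coded corpus
#'
#' Codes each (document, entity) item as present/absent per coder and
#' computes overall and per-entity nominal alpha.
#'
#' @param annotator_a,annotator_b lists of `annotated_study` over the same
#'   documents.
#' @param schema the `entity_schema`.
#' @return List with `overall` (an `agreement_report`) and `per_entity`
#'   data frame.
#' @export
human_agreement <- function(annotator_a, annotator_b, schema) {
  docs <- intersect(vapply(annotator_a, function(s) s$doc$doc_id, character(1)),
                    vapply(annotator_b, function(s) s$doc$doc_id, character(1)))
  code <- function(studies) {
    have <- unique(do.call(rbind, lapply(studies, function(st)
      if (length(st$annotations) == 0) NULL else
        data.frame(doc = st$doc$doc_id,
                   ent = vapply(st$annotations, function(a) a$entity_id,
                                character(1))))))
    grid <- expand.grid(doc = docs, ent = schema$entity_id,
                        stringsAsFactors = FALSE)
    as.integer(paste(grid$doc, grid$ent) %in% paste(have$doc, have$ent))
  }
  ca <- code(annotator_a); cb <- code(annotator_b)
  grid <- expand.grid(doc = docs, ent = schema$entity_id, stringsAsFactors = FALSE)
  per <- do.call(rbind, lapply(schema$entity_id, function(e) {
    sel <- grid$ent == e
    a <- tryCatch(suppressWarnings(krippendorff_alpha(ca[sel], cb[sel]))$alpha,
                  error = function(err) NA_real_)
    data.frame(entity_id = e, alpha = a, stringsAsFactors = FALSE)
  }))
  list(overall = suppressWarnings(krippendorff_alpha(ca, cb)), per_entity = per)
}

#' Seeded cross-validation folds
#'
#' Shuffles the study ids with the given seed, then deals them round-robin
#' into `k` folds: folds are disjoint, cover every study exactly once, and
#' differ in size by at most one.
#'
#' @param study_ids character vector of study/document ids.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return A `cv_folds` object: list with `folds` (list of id vectors),
#'   `k`, `seed`.
#' @export
make_cv_folds <- function(study_ids, k = 5L, seed = 1L) {
  n <- length(study_ids)
  abort_if(k > n, "more folds (", k, ") than studies (", n, ")",
           class = "trialminer_usage_error")
  if (k == 1L) warning("k = 1 gives a single degenerate fold")
  shuffled <- with_seed(seed, sample(study_ids))
  folds <- split(shuffled, rep_len(seq_len(k), n))
  names(folds) <- NULL
  structure(list(folds = folds, k = as.integer(k), seed = as.integer(seed)),
            class = "cv_folds")
}

#' Arm-assignment accuracy
#'
#' The extraction F1 above deliberately ignores arm linkage; this reports
#' it separately: the fraction of key-matched entity instances whose
#' predicted arm corresponds to the gold arm. Predicted arms are mapped to
#' gold arms through shared member surface forms.
#'
#' @param gold,predicted lists of `annotated_study` over the same documents.
#' @param schema the `entity_schema`.
#' @return List with `accuracy` and `n` (number of matched instances).
#' @export
arm_assignment_accuracy <- function(gold, predicted, schema) {
  pred_by_doc <- setNames(predicted,
                          vapply(predicted, function(s) s$doc$doc_id, character(1)))
  correct <- 0L; total <- 0L
  for (gs in gold) {
    ps <- pred_by_doc[[gs$doc$doc_id]]
    if (is.null(ps)) next
    # map predicted arm id -> gold arm id via member surfaces
    gold_surf <- list()
    for (a in gs$arms)
      for (s in tolower(a$members$surface)) gold_surf[[s]] <- a$arm_id
    arm_map <- list()
    for (a in ps$arms) {
      hits <- unique(unlist(lapply(tolower(a$members$surface),
                                   function(s) gold_surf[[s]])))
      if (length(hits) == 1) arm_map[[a$arm_id]] <- hits
    }
    ganns <- Filter(function(a) a$entity_id != ARM_NAME, gs$annotations)
    panns <- Filter(function(a) a$entity_id != ARM_NAME, ps$annotations)
    gkeys <- vapply(ganns, ann_key, character(1), schema = schema,
                    criterion = "entity")
    pkeys <- vapply(panns, ann_key, character(1), schema = schema,
                    criterion = "entity")
    used <- rep(FALSE, length(panns))
    for (i in seq_along(ganns)) {
      j <- which(pkeys == gkeys[i] & !used)[1]
      if (is.na(j)) next
      used[j] <- TRUE
      total <- total + 1L
      pred_arm <- panns[[j]]$arm_ref
      mapped <- if (pred_arm == WHOLE_STUDY) WHOLE_STUDY
      else arm_map[[pred_arm]] %||% NA_character_
      if (identical(mapped, ganns[[i]]$arm_ref)) correct <- correct + 1L
    }
  }
  list(accuracy = if (total > 0) correct / total else NA_real_, n = total)
}
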