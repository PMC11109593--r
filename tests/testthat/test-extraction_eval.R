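# Matching, scores, agreement, and cross-validation folds.

sch <- generator_schema()

mini_study <- function(doc_id, entities, values = NULL) {
  doc <- build_document(doc_id, "Placeholder text for matching tests .")
  anns <- lapply(seq_along(entities), function(i)
    annotation(doc_id, entities[i], span = NULL, raw_text = "x",
               context_text = "ctx",
               value = if (is.null(values)) NA_real_ else values[i]))
  annotated_study(doc, annotations = anns)
}

test_that("match_annotations counts TP/FP/FN with value equality", {
  g <- list(mini_study("d1", c("bct_goal_setting", "pop_mean_age"), c(NA, 44.5)))
  p_same <- list(mini_study("d1", c("bct_goal_setting", "pop_mean_age"), c(NA, 44.5)))
  counts <- match_annotations(g, p_same, sch)
  expect_equal(sum(counts$fp), 0); expect_equal(sum(counts$fn), 0)
  expect_equal(sum(counts$tp), 2)
  # differing value is both an FP and an FN
  p_diff <- list(mini_study("d1", c("pop_mean_age"), c(44.6)))
  counts <- match_annotations(g, p_diff, sch)
  row <- counts[counts$entity_id == "pop_mean_age", ]
  expect_equal(c(row$tp, row$fp, row$fn), c(0L, 1L, 1L))
  # 2 gold instances, 1 matching prediction
  g2 <- list(mini_study("d1", rep("bct_goal_setting", 2)))
  p2 <- list(mini_study("d1", "bct_goal_setting"))
  counts <- match_annotations(g2, p2, sch)
  expect_equal(c(counts$tp, counts$fp, counts$fn), c(1L, 0L, 1L))
  expect_error(match_annotations(g, list(mini_study("d1", "mystery_entity")), sch),
               class = "trialminer_validation_error")
})

test_that("matching conserves instance counts on random corpora", {
  corpus <- tiny_corpus(6, seed = 21)
  degraded <- corrupt_annotations(corpus, drop_rate = 0.3, relabel_rate = 0.2,
                                  seed = 5)
  counts <- match_annotations(corpus, degraded, sch)
  n_gold <- length(trialminer:::flatten_annotations(corpus))
  n_pred <- length(trialminer:::flatten_annotations(degraded))
  expect_equal(sum(counts$tp) + sum(counts$fn), n_gold)
  expect_equal(sum(counts$tp) + sum(counts$fp), n_pred)
})

test_that("precision_recall_f1 matches the formula oracle", {
  s <- precision_recall_f1(data.frame(tp = 2, fp = 0, fn = 0))
  expect_equal(c(s$precision, s$recall, s$f1), c(1, 1, 1))
  expect_equal(precision_recall_f1(data.frame(tp = 0, fp = 3, fn = 5))$f1, 0)
  s <- precision_recall_f1(data.frame(tp = 3, fp = 2, fn = 7))
  expect_equal(c(s$precision, s$recall), c(0.6, 0.3))
  expect_equal(s$f1, 2 * 0.6 * 0.3 / 0.9)
  # F1 = P = R when FP = FN
  s <- precision_recall_f1(data.frame(tp = 4, fp = 3, fn = 3))
  expect_equal(s$precision, s$recall)
  expect_equal(s$f1, s$precision)
})

test_that("summaries mirror the four-row report shape", {
  scores <- data.frame(entity_id = c("a", "b", "c"), tp = 1, fp = 1, fn = 1,
                       f1 = c(0.2, 0.4, 0.6))
  rep <- summarize_scores(scores)
  expect_equal(rep$summary$f1, c(0.4, 0.4, 0.6, 0.2))
  single <- summarize_scores(scores[1, ])
  expect_true(all(single$summary$f1 == 0.2))
  two_col <- summarize_scores(scores, benchmark = data.frame(f1 = c(1, 1, 0.7)))
  expect_true("benchmark_f1" %in% names(two_col$summary))
  expect_error(summarize_scores(scores[0, ]), class = "trialminer_usage_error")
})

test_that("human benchmark is symmetric in F1", {
  corpus <- tiny_corpus(6, seed = 31)
  b <- corrupt_annotations(corpus, drop_rate = 0.25, seed = 2)
  same <- human_benchmark(corpus, corpus, sch)
  expect_true(all(same$per_entity$f1 == 1))
  empty_b <- lapply(corpus, function(st) { st$annotations <- list(); st })
  zero <- human_benchmark(corpus, empty_b, sch)
  expect_true(all(zero$per_entity$f1 == 0))
  ab <- human_benchmark(corpus, b, sch)
  ba <- human_benchmark(b, corpus, sch)
  expect_equal(ab$per_entity$f1, ba$per_entity$f1)
  expect_equal(ab$per_entity$precision, ba$per_entity$recall)
  other_docs <- lapply(b, function(st) { st$doc$doc_id <- paste0(st$doc$doc_id, "_z"); st })
  expect_error(human_benchmark(corpus, other_docs, sch),
               class = "trialminer_usage_error")
})

test_that("krippendorff alpha matches its oracle and behaves at the edges", {
  expect_equal(krippendorff_alpha(c(1, 0, 1, 0), c(1, 0, 1, 0))$alpha, 1)
  got <- krippendorff_alpha(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(got$alpha, oracle_alpha(c(1, 1, 0, 0), c(1, 0, 0, 0)))
  # statistically independent coding -> alpha near 0 at large n
  set.seed(99)
  c1 <- sample(0:1, 10000, replace = TRUE)
  c2 <- sample(0:1, 10000, replace = TRUE)
  expect_lt(abs(krippendorff_alpha(c1, c2)$alpha), 0.05)
  # degenerate: one category only
  expect_warning(deg <- krippendorff_alpha(rep("a", 5), rep("a", 5)))
  expect_equal(deg$alpha, 1)
  expect_true(deg$undefined)
  expect_error(krippendorff_alpha(1, 1), class = "trialminer_usage_error")
})

test_that("alpha decreases monotonically under corruption of a double coding", {
  corpus <- tiny_corpus(8, seed = 41)
  alphas <- vapply(c(0, 0.2, 0.5, 0.9), function(rate) {
    b <- corrupt_annotations(corpus, drop_rate = rate, seed = 3)
    human_agreement(corpus, b, sch)$overall$alpha
  }, numeric(1))
  expect_equal(alphas[1], 1)
  expect_true(all(diff(alphas) < 0))
})

test_that("cv folds partition the studies deterministically", {
  folds <- make_cv_folds(paste0("s", 1:10), k = 5, seed = 3)
  expect_equal(lengths(folds$folds), rep(2L, 5))
  expect_setequal(unlist(folds$folds), paste0("s", 1:10))
  expect_equal(anyDuplicated(unlist(folds$folds)), 0)
  folds2 <- make_cv_folds(paste0("s", 1:10), k = 5, seed = 3)
  expect_identical(folds, folds2)
  expect_error(make_cv_folds(paste0("s", 1:3), k = 5),
               class = "trialminer_usage_error")
  expect_warning(single <- make_cv_folds(paste0("s", 1:4), k = 1))
  expect_equal(lengths(single$folds), 4L)
  # sizes differ by at most one on uneven splits
  f7 <- make_cv_folds(paste0("s", 1:17), k = 5, seed = 1)
  expect_lte(diff(range(lengths(f7$folds))), 1)
})
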