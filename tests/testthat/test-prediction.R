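# Feature building, graph embeddings, baselines, and the recurrent model.

sch <- generator_schema()

test_that("feature vectors propagate whole-study values and skip outcome-less arms", {
  doc <- build_document("d1", "Text .")
  arms <- list(arm("arm_1", "patch", data.frame(surface = "patch", count = 1,
                                                first_start = 0)),
               arm("arm_2", "control", data.frame(surface = "control", count = 1,
                                                  first_start = 9)))
  anns <- list(
    annotation("d1", "pop_mean_age", span = NULL, raw_text = "44.5 years",
               value = 44.5, arm_ref = "WHOLE_STUDY"),
    annotation("d1", "bct_goal_setting", span = NULL, raw_text = "goal setting",
               arm_ref = "arm_1"))
  st <- annotated_study(doc, arms, anns,
                        outcomes = data.frame(arm_id = c("arm_1", "arm_2"),
                                              entity_id = "outcome_abstinence_12m",
                                              value = c(20, 10)))
  fs <- build_feature_vectors(list(st), sch)
  expect_equal(nrow(fs$samples), 2)
  age_col <- match("pop_mean_age", fs$value_ids)
  expect_equal(fs$numeric[, age_col], c(44.5, 44.5))  # propagated to both arms
  gs_col <- match("bct_goal_setting", fs$presence_ids)
  expect_equal(fs$presence[, gs_col], c(1, 0))        # arm-scoped stays per arm

  # arm without an outcome record contributes no vector
  st2 <- st
  st2$outcomes <- st$outcomes[1, ]
  fs2 <- build_feature_vectors(list(st2), sch)
  expect_equal(fs2$samples$arm_id, "arm_1")

  # design-matrix width: presence + 2 x numeric (value + missingness flag)
  X <- standardize_features(fs)$X
  expect_equal(ncol(X), length(fs$presence_ids) + 2 * length(fs$value_ids))
})

test_that("co-occurrence graph counts document-level pairs", {
  mk <- function(id, ents) {
    doc <- build_document(id, "Text .")
    annotated_study(doc, annotations = lapply(ents, function(e)
      annotation(id, e, span = NULL, raw_text = "x")))
  }
  g <- build_cooccurrence_graph(list(mk("d1", c("A", "B")),
                                     mk("d2", c("A", "B", "C"))))
  w <- function(a, b) {
    i <- match(a, g$nodes); j <- match(b, g$nodes)
    hit <- (g$edges$i == min(i, j)) & (g$edges$j == max(i, j))
    if (any(hit)) g$edges$w[hit] else 0L
  }
  expect_equal(w("A", "B"), 2L)
  expect_equal(w("A", "C"), 1L)
  expect_equal(w("B", "C"), 1L)
  expect_equal(nrow(build_cooccurrence_graph(list(mk("d", "A")))$edges), 0)
  empty <- build_cooccurrence_graph(list())
  expect_equal(length(empty$nodes), 0)
})

test_that("graph embeddings separate disjoint cliques and are deterministic", {
  # two disjoint 5-cliques
  nodes <- c(paste0("a", 1:5), paste0("b", 1:5))
  edges <- do.call(rbind, lapply(list(1:5, 6:10), function(idx)
    do.call(rbind, lapply(utils::combn(idx, 2, simplify = FALSE), function(p)
      data.frame(i = p[1], j = p[2], w = 1L)))))
  graph <- structure(list(nodes = nodes, edges = edges),
                     class = "cooccurrence_graph")
  cfg <- graph_embedding_config(dimensions = 16L, seed = 5)
  emb <- learn_graph_embeddings(graph, cfg)
  expect_equal(dim(emb), c(10, 16))
  cos <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  pairs <- utils::combn(10, 2)
  sims <- apply(pairs, 2, function(p) cos(emb[p[1], ], emb[p[2], ]))
  same <- apply(pairs, 2, function(p) (p[1] <= 5) == (p[2] <= 5))
  expect_gt(mean(sims[same]), mean(sims[!same]))
  emb2 <- learn_graph_embeddings(graph, cfg)
  expect_identical(emb, emb2)
  expect_error(learn_graph_embeddings(build_cooccurrence_graph(list()), cfg),
               class = "trialminer_usage_error")
})

test_that("grand-mean predictor equals the training mean, RMSE its SD", {
  m <- fit_grand_mean(c(10, 20, 30))
  expect_equal(predict(m, 5), rep(20, 5))
  expect_equal(predict(fit_grand_mean(7), 3), rep(7, 3))
  # training RMSE equals the population SD of the outcomes
  set.seed(2)
  y <- rnorm(40, 30, 8)
  m <- fit_grand_mean(y)
  expect_equal(rmse(predict(m, length(y)), y),
               sqrt(mean((y - mean(y))^2)))
  expect_error(fit_grand_mean(numeric(0)), class = "trialminer_training_error")
})

test_that("linear baseline solves exactly, handles rank deficiency", {
  x <- matrix(seq(0, 10, length.out = 20), ncol = 1, dimnames = list(NULL, "x"))
  y <- 2 + 3 * x[, 1]
  fit <- fit_linear_baseline(x, y)
  expect_equal(unname(fit$coef), c(2, 3), tolerance = 1e-8)
  expect_equal(rmse(predict(fit, x), y), 0, tolerance = 1e-8)

  const <- fit_linear_baseline(x, rep(5, 20))
  expect_equal(unname(const$coef[2]), 0, tolerance = 1e-8)
  expect_equal(predict(const, x), rep(5, 20), tolerance = 1e-8)

  # duplicated column: minimum-norm solution leaves predictions unchanged
  x2 <- cbind(x, x)
  fit2 <- fit_linear_baseline(x2, y)
  expect_equal(predict(fit2, x2), predict(fit, x), tolerance = 1e-8)
  expect_error(fit_linear_baseline(x[1, , drop = FALSE], y[1]),
               class = "trialminer_training_error")
})

test_that("LSTM analytic gradients match numeric differentiation", {
  set.seed(13)
  N <- 4; T_ <- 3; D <- 2
  xs <- lapply(1:T_, function(t) matrix(rnorm(N * D), N, D))
  y <- rnorm(N)
  model <- trialminer:::lstm_init(D, c(3, 2), seed = 8)
  gr <- trialminer:::lstm_gradients(model, xs, y)
  theta <- trialminer:::flatten_params(model)
  g_analytic <- trialminer:::flatten_params(gr$grads)
  eps <- 1e-6
  idx <- sample(length(theta), 25)
  for (i in idx) {
    th_p <- theta; th_p[i] <- th_p[i] + eps
    th_m <- theta; th_m[i] <- th_m[i] - eps
    lp <- trialminer:::lstm_gradients(trialminer:::relist_like(th_p, model), xs, y)$loss
    lm_ <- trialminer:::lstm_gradients(trialminer:::relist_like(th_m, model), xs, y)$loss
    expect_equal(g_analytic[i], (lp - lm_) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("recurrent model handles degenerate targets and is seed-deterministic", {
  cfg0 <- generator_config(seed = 4, n_docs = 15, sigma = 0, intercept = 30,
                           beta = c(bct_goal_setting = 0, bct_problem_solving = 0,
                                    bct_social_support = 0, bct_self_monitoring = 0,
                                    bct_financial_incentive = 0),
                           gamma = c(pop_mean_age = 0, pop_cigarettes_per_day = 0))
  corpus <- generate_corpus(cfg0)
  fs <- build_feature_vectors(corpus, sch)
  expect_true(all(fs$samples$outcome == 30))
  m <- fit_recurrent_model(fs, sch, corpus, prediction_config(epochs = 40, seed = 1))
  expect_true(all(abs(predict(m, fs) - 30) < 0.5))

  corpus2 <- tiny_corpus(12, seed = 6)
  fs2 <- build_feature_vectors(corpus2, sch)
  m1 <- fit_recurrent_model(fs2, sch, corpus2, prediction_config(epochs = 30, seed = 9))
  m2 <- fit_recurrent_model(fs2, sch, corpus2, prediction_config(epochs = 30, seed = 9))
  expect_identical(predict(m1, fs2), predict(m2, fs2))
})

test_that("rmse matches its direct formula", {
  expect_equal(rmse(c(10, 10), c(10, 10)), 0)
  expect_equal(rmse(c(12, 8), c(10, 10)), 2)
  set.seed(3)
  p <- rnorm(50); g <- rnorm(50)
  expect_equal(rmse(p, g), oracle_rmse(p, g))
  expect_error(rmse(1:3, 1:2))
})

test_that("evaluate_prediction reports the configured rows in fixed order", {
  corpus <- tiny_corpus(15, seed = 8)
  ids <- vapply(corpus, function(s) s$doc$doc_id, character(1))
  folds <- make_cv_folds(ids, k = 3, seed = 2)
  rep <- evaluate_prediction(corpus, folds, sch,
                             models = c("linear", "grand_mean"),
                             config = prediction_config(seed = 2))
  expect_equal(rep$per_model$model, c("grand_mean", "linear"))
  expect_true(all(rep$per_model$rmse >= 0))
  expect_equal(nrow(rep$per_fold), 6)
})
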