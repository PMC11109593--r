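# Tokenization, BIO encoding/decoding, and the two tagger families.

test_that("tokenize keeps decimals intact and reconstructs offsets", {
  t1 <- tokenize("randomised into 3 groups.")
  expect_equal(t1$surface, c("randomised", "into", "3", "groups", "."))
  expect_equal(nrow(tokenize("")), 0)
  fixtures <- list("44.5 years" = c("44.5", "years"),
                   "26.7" = "26.7",
                   "12.5 %" = c("12.5", "%"),
                   "0.5mg dose" = c("0.5", "mg", "dose"),
                   "ages 18-65 only" = c("ages", "18", "-", "65", "only"),
                   "3 groups ( n = 120 )" = c("3", "groups", "(", "n", "=", "120", ")"),
                   "p<0.05" = c("p", "<", "0.05"),
                   "a 2x2 design" = c("a", "2", "x", "2", "design"),
                   "quit-line support" = c("quit", "-", "line", "support"),
                   "CO verified" = c("CO", "verified"))
  for (txt in names(fixtures)) {
    toks <- tokenize(txt)
    expect_equal(toks$surface, fixtures[[txt]], label = txt)
    for (i in seq_len(nrow(toks)))
      expect_equal(substr(txt, toks$start[i] + 1, toks$end[i]), toks$surface[i])
  }
})

test_that("encode_bio produces B/I patterns and rejects bad alignments", {
  toks <- tokenize("one two three four five")
  m <- data.frame(label = "X", start = toks$start[3], end = toks$end[4])
  expect_equal(encode_bio(toks, m)$tags, c("O", "O", "B-X", "I-X", "O"))
  expect_equal(encode_bio(toks, NULL)$tags, rep("O", 5))
  # adjacent same-label mentions stay separate
  m2 <- data.frame(label = "X", start = toks$start[1:2], end = toks$end[1:2])
  expect_equal(encode_bio(toks, m2)$tags[1:2], c("B-X", "B-X"))
  # overlap and misalignment
  m3 <- data.frame(label = c("X", "Y"), start = c(toks$start[1], toks$start[2]),
                   end = c(toks$end[2], toks$end[3]))
  expect_error(encode_bio(toks, m3), class = "trialminer_alignment_error")
  m4 <- data.frame(label = "X", start = toks$start[2] + 1, end = toks$end[2])
  expect_error(encode_bio(toks, m4), class = "trialminer_alignment_error")
})

test_that("decode_bio inverts encode_bio and repairs leading I tags", {
  toks <- toy_tokens(5)
  men <- decode_bio(tag_sequence(toks, c("O", "B-X", "I-X", "O", "B-Y")))
  expect_equal(men$label, c("X", "Y"))
  expect_equal(men$tok_start, c(1, 4)); expect_equal(men$tok_end, c(3, 5))
  men2 <- decode_bio(tag_sequence(toy_tokens(2), c("I-X", "O")))
  expect_equal(nrow(men2), 1)
  expect_equal(men2$tok_start, 0)
  # property: encode -> decode is the identity on 200 random layouts
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(3:12, 1)
    toks <- toy_tokens(n)
    lay <- random_mention_layout(n)
    ts <- tag_sequence(toks, lay$tags)
    expect_true(is_valid_bio(ts$tags))
    men <- decode_bio(ts)
    expect_equal(nrow(men), length(lay$mentions))
    if (length(lay$mentions) > 0) {
      expect_equal(men$label, vapply(lay$mentions, `[[`, character(1), "label"))
      expect_equal(men$tok_start, vapply(lay$mentions, `[[`, numeric(1), "tok_start"))
      # re-encoding from character spans reproduces the tags
      ts2 <- encode_bio(toks, men[c("label", "start", "end")])
      expect_equal(ts2$tags, lay$tags)
    }
  }
})

test_that("gazetteer tagger equals exact longest-match search on its training set", {
  toks <- tokenize("given nicotine patch daily")
  ts <- encode_bio(toks, data.frame(label = "rx_nrt_patch", start = 6, end = 20))
  gaz <- train_tagger(list(ts), tagger_config(family = "gazetteer"))
  men <- decode_bio(tag_sentence(gaz, "patients were given nicotine patch daily"))
  expect_equal(men$label, "rx_nrt_patch")
  expect_equal(men$surface, "nicotine patch")
  # leftmost-longest: "nicotine patch" wins over a shorter "patch" entry
  toks2 <- tokenize("the patch group")
  ts2 <- encode_bio(toks2, data.frame(label = "ARM_NAME", start = 4, end = 9))
  gaz2 <- train_tagger(list(ts, ts2), tagger_config(family = "gazetteer"))
  men2 <- decode_bio(tag_sentence(gaz2, "got nicotine patch today"))
  expect_equal(men2$surface, "nicotine patch")
  expect_equal(men2$label, "rx_nrt_patch")
})

test_that("training validates its corpus", {
  expect_error(train_tagger(list(), tagger_config()),
               class = "trialminer_training_error")
  toks <- tokenize("goal setting")
  ts <- encode_bio(toks, data.frame(label = "not_in_schema", start = 0, end = 12))
  expect_error(train_tagger(list(ts), tagger_config(), labels = c("a", "b")),
               class = "trialminer_validation_error")
})

test_that("statistical tagger is deterministic and accurate on held-out docs", {
  corpus <- tiny_corpus(60, seed = 501)
  train <- corpus[1:50]; test <- corpus[51:60]
  seqs <- unlist(lapply(train, study_tag_sequences), recursive = FALSE)
  m1 <- train_tagger(seqs, tagger_config(family = "statistical", seed = 1))
  m2 <- train_tagger(seqs, tagger_config(family = "statistical", seed = 1))
  held_out <- "The quitline arm received problem solving and goal setting ."
  expect_identical(tag_sentence(m1, held_out)$tags, tag_sentence(m2, held_out)$tags)
  pred <- lapply(test, function(st)
    resolve_document(st$doc, tag_document(m1, st$doc), generator_schema()))
  mf <- micro_f1(match_annotations(test, pred, generator_schema()))
  expect_gte(mf$f1, 0.9)
})

test_that("tag_document covers tables and orders mentions", {
  corpus <- tiny_corpus(20, seed = 9, table_prob = 1, table_only = TRUE)
  seqs <- unlist(lapply(corpus, study_tag_sequences), recursive = FALSE)
  gaz <- train_tagger(seqs, tagger_config(family = "gazetteer"))
  st <- corpus[[1]]
  men <- tag_document(gaz, st$doc)
  outc <- men[men$label == "outcome_abstinence_12m", ]
  expect_gt(nrow(outc), 0)
  expect_true(all(outc$source == "table"))  # outcome appears only in tables
  expect_true(all(diff(men$start[men$source == "body"]) > 0))
  # empty document
  expect_equal(nrow(tag_document(gaz, build_document("e", ""))), 0)
})
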