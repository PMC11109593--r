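# Sequence taggers: a deterministic gazetteer reference tagger and a
# trainable count-feature tagger decoded with a BIO-constrained Viterbi
# search.
#
# The statistical family stands in, at desk scale, for a neural
# BiLSTM-CRF: per-token emission scores come from smoothed conditional
# frequencies of lexical/context/shape features, and the transition matrix
# plays the CRF's role of forbidding label sequences that violate the BIO
# scheme. Both families expose the same contract: train on gold tag
# sequences, then map a sentence to a `tag_sequence`.

#' Tagger configuration
#'
#' @param family `"gazetteer"` (longest-match dictionary over training
#'   mention surfaces) or `"statistical"` (feature-count model with
#'   BIO-constrained Viterbi decoding).
#' @param seed integer seed recorded in the model (training is
#'   deterministic, the seed is part of the artefact's provenance).
#' @param epochs training passes; the count-based model needs one, the field
#'   exists so alternative trainable families keep the same config surface.
#' @param embedding_dim,pretrained_vectors plug-in point for dense word
#'   vectors to concatenate to the feature set; `NULL` disables (the default
#'   -- tests run without any pretrained resources).
#' @param smoothing additive smoothing constant for feature counts.
#' @export
tagger_config <- function(family = c("statistical", "gazetteer"), seed = 1L,
                          epochs = 1L, embedding_dim = 0L,
                          pretrained_vectors = NULL, smoothing = 0.1) {
  family <- match.arg(family)
  abort_if(embedding_dim < 0, "embedding_dim must be non-negative")
  structure(list(family = family, seed = as.integer(seed),
                 epochs = as.integer(epochs), embedding_dim = as.integer(embedding_dim),
                 pretrained_vectors = pretrained_vectors, smoothing = smoothing),
            class = "tagger_config")
}

token_shape <- function(w) {
  s <- gsub("[A-Z]", "X", w)
  s <- gsub("[a-z]", "x", s)
  s <- gsub("[0-9]", "d", s)
  gsub("(.)\\1+", "\\1", s)  # collapse runs: "44.5" -> "d.d"
}

bos <- "<S>"; eos <- "</S>"

position_features <- function(surfaces) {
  n <- length(surfaces)
  lo <- tolower(surfaces)
  pad <- function(v, k) {
    if (k < 0) c(rep(bos, -k), lo)[seq_len(n)]
    else c(lo[-seq_len(k)], rep(eos, k))
  }
  list(w0 = lo, sh0 = token_shape(surfaces),
       wm1 = pad(lo, -1L), wm2 = pad(lo, -2L),
       wp1 = c(lo[-1L], eos), wp2 = c(lo[-(1:2)], eos, eos)[seq_len(n)])
}

#' Train a tagger
#'
#' @param corpus non-empty list of `tag_sequence` objects (see
#'   [encode_bio()], [study_tag_sequences()]).
#' @param config a [tagger_config()].
#' @param labels optional character vector of permitted labels (schema
#'   entity ids plus `ARM_NAME`); training fails on a tag outside it.
#' @return A `tagger_model` exposing [tag_sentence()] / [tag_document()].
#' @export
train_tagger <- function(corpus, config = tagger_config(), labels = NULL) {
  abort_if(length(corpus) == 0, "training corpus is empty",
           class = "trialminer_training_error")
  seen <- sort(unique(unlist(lapply(corpus, function(ts) tag_label(ts$tags)))))
  seen <- setdiff(seen, "O")
  if (!is.null(labels)) {
    unknown <- setdiff(seen, labels)
    abort_if(length(unknown) > 0, "labels not in schema: ",
             paste(unknown, collapse = ", "),
             class = "trialminer_validation_error")
  }
  model <- if (config$family == "gazetteer") train_gazetteer(corpus)
  else train_statistical(corpus, config)
  model$config <- config
  model$labels <- seen
  class(model) <- c(paste0("tagger_", config$family), "tagger_model")
  model
}

train_gazetteer <- function(corpus) {
  keys <- character(0); labs <- character(0)
  for (ts in corpus) {
    men <- decode_bio(ts)
    if (nrow(men) == 0) next
    for (k in seq_len(nrow(men))) {
      idx <- (men$tok_start[k] + 1L):men$tok_end[k]
      keys <- c(keys, paste(tolower(ts$tokens$surface[idx]), collapse = " "))
      labs <- c(labs, men$label[k])
    }
  }
  by_key <- split(labs, keys)
  dict <- vapply(by_key, function(ls) {
    tb <- table(ls)
    sort(names(tb)[tb == max(tb)])[1]  # deterministic majority, ties lexicographic
  }, character(1))
  maxlen <- if (length(dict) == 0) 1L else
    max(vapply(strsplit(names(dict), " ", fixed = TRUE), length, integer(1)))
  list(dict = dict, maxlen = maxlen)
}

train_statistical <- function(corpus, config) {
  tags_all <- character(0)
  feats_all <- list(w0 = character(0), sh0 = character(0), wm1 = character(0),
                    wm2 = character(0), wp1 = character(0), wp2 = character(0))
  trans_from <- character(0); trans_to <- character(0)
  for (ts in corpus) {
    if (nrow(ts$tokens) == 0) next
    f <- position_features(ts$tokens$surface)
    for (g in names(feats_all)) feats_all[[g]] <- c(feats_all[[g]], f[[g]])
    tags_all <- c(tags_all, ts$tags)
    seq_tags <- c(bos, ts$tags)
    trans_from <- c(trans_from, seq_tags[-length(seq_tags)])
    trans_to <- c(trans_to, seq_tags[-1])
  }
  tagset <- sort(unique(tags_all))
  prior <- table(factor(tags_all, levels = tagset))
  emis <- lapply(feats_all, function(v) {
    tb <- table(v, factor(tags_all, levels = tagset))
    m <- matrix(as.numeric(tb), nrow(tb), ncol(tb), dimnames = dimnames(tb))
    m
  })
  trans <- table(factor(trans_from, levels = c(bos, tagset)),
                 factor(trans_to, levels = tagset))
  trans <- matrix(as.numeric(trans), nrow(trans), ncol(trans),
                  dimnames = dimnames(trans))
  list(tagset = tagset, prior = as.numeric(prior), emis = emis, trans = trans,
       n_tag = as.numeric(prior), alpha = config$smoothing)
}

# Hard BIO constraint: I-X may only follow B-X or I-X.
allowed_transition <- function(from, to) {
  if (!startsWith(to, "I-")) return(TRUE)
  lab <- tag_label(to)
  from %in% paste0(c("B-", "I-"), lab)
}

#' Tag one sentence
#'
#' @param model a trained `tagger_model`.
#' @param text sentence text.
#' @return A `tag_sequence` over [tokenize()]d tokens.
#' @export
tag_sentence <- function(model, text) {
  toks <- tokenize(text)
  if (nrow(toks) == 0) return(tag_sequence(toks, character(0)))
  tags <- if (inherits(model, "tagger_gazetteer")) gazetteer_tags(model, toks)
  else viterbi_tags(model, toks)
  tag_sequence(toks, tags)
}

gazetteer_tags <- function(model, toks) {
  n <- nrow(toks)
  lo <- tolower(toks$surface)
  tags <- rep("O", n)
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (L in seq(min(model$maxlen, n - i + 1L), 1L)) {
      key <- paste(lo[i:(i + L - 1L)], collapse = " ")
      lab <- model$dict[key]
      if (!is.na(lab)) {
        tags[i] <- paste0("B-", lab)
        if (L > 1L) tags[(i + 1L):(i + L - 1L)] <- paste0("I-", lab)
        hit <- L
        break
      }
    }
    i <- i + max(hit, 1L)
  }
  tags
}

viterbi_tags <- function(model, toks) {
  n <- nrow(toks)
  tagset <- model$tagset
  K <- length(tagset)
  alpha <- model$alpha
  f <- position_features(toks$surface)
  n_tag <- model$n_tag
  # emission log-scores: sum over feature families of log P(feature | tag)
  score <- matrix(log(model$prior / sum(model$prior)), n, K, byrow = TRUE)
  for (g in names(model$emis)) {
    m <- model$emis[[g]]
    Vg <- nrow(m) + 1  # +1 for unseen value mass
    idx <- match(f[[g]], rownames(m))
    cnt <- matrix(0, n, K)
    seen <- !is.na(idx)
    if (any(seen)) cnt[seen, ] <- m[idx[seen], , drop = FALSE]
    score <- score + log(cnt + alpha) -
      matrix(log(n_tag + alpha * Vg), n, K, byrow = TRUE)
  }
  # transition log-scores with BIO hard constraints
  allow <- outer(c(bos, tagset), tagset,
                 Vectorize(function(a, b) allowed_transition(a, b)))
  ltr <- log(model$trans + alpha) -
    log(rowSums(model$trans) + alpha * K)
  ltr[!allow] <- -Inf
  rownames(ltr) <- c(bos, tagset)
  # Viterbi
  delta <- matrix(-Inf, n, K)
  back <- matrix(0L, n, K)
  delta[1, ] <- score[1, ] + ltr[bos, ]
  if (n > 1) for (t in 2:n) {
    for (k in seq_len(K)) {
      cand <- delta[t - 1, ] + ltr[tagset, tagset[k]]
      b <- which.max(cand)
      delta[t, k] <- cand[b] + score[t, k]
      back[t, k] <- b
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in seq(n - 1L, 1L)) path[t] <- back[t + 1L, path[t + 1L]]
  tagset[path]
}

empty_mentions <- function() {
  data.frame(label = character(0), start = integer(0), end = integer(0),
             surface = character(0), source = character(0),
             sent_id = integer(0), ps_id = integer(0),
             tok_start = integer(0), tok_end = integer(0),
             confidence = numeric(0), stringsAsFactors = FALSE)
}

#' Tag a whole document
#'
#' Applies the tagger to every sentence and every table pseudo-sentence.
#' Body mentions carry character spans into the body text and global token
#' indices; table mentions carry spans and token indices local to their
#' pseudo-sentence (`ps_id`).
#'
#' @param model a trained `tagger_model`.
#' @param doc a `document` from [build_document()].
#' @return Mention data frame ordered by (source: body first, span start).
#' @export
tag_document <- function(model, doc) {
  out <- list()
  tok_base <- 0L
  sents <- doc$sentences
  for (i in seq_len(nrow(sents))) {
    stext <- span_text(doc$body_text, sents$start[i], sents$end[i])
    ts <- tag_sentence(model, stext)
    men <- decode_bio(ts)
    if (nrow(men) > 0) {
      men$start <- men$start + sents$start[i]
      men$end <- men$end + sents$start[i]
      men$tok_start <- men$tok_start + tok_base
      men$tok_end <- men$tok_end + tok_base
      men$source <- "body"; men$sent_id <- i; men$ps_id <- NA_integer_
      men$confidence <- 1
      out[[length(out) + 1L]] <- men
    }
    tok_base <- tok_base + nrow(ts$tokens)
  }
  ps <- doc$pseudo_sentences
  for (i in seq_len(nrow(ps))) {
    ts <- tag_sentence(model, ps$text[i])
    men <- decode_bio(ts)
    if (nrow(men) > 0) {
      men$source <- "table"; men$sent_id <- NA_integer_; men$ps_id <- i
      men$confidence <- 1
      out[[length(out) + 1L]] <- men
    }
  }
  if (length(out) == 0) return(empty_mentions())
  res <- do.call(rbind, out)
  res <- res[order(res$source, res$start), ]
  rownames(res) <- NULL
  res[names(empty_mentions())]
}

#' Gold tag sequences for a study
#'
#' Converts a study's gold annotations (including `ARM_NAME` instances)
#' into per-sentence and per-pseudo-sentence BIO tag sequences, the
#' training format for [train_tagger()]. Table-derived annotations (null
#' span) are located by exact search within their recorded context
#' pseudo-sentence.
#'
#' @param study an `annotated_study` with gold annotations.
#' @return List of `tag_sequence` objects.
#' @export
study_tag_sequences <- function(study) {
  doc <- study$doc
  sents <- doc$sentences
  spanned <- Filter(function(a) !is.null(a$span), study$annotations)
  tabular <- Filter(function(a) is.null(a$span), study$annotations)
  out <- list()
  for (i in seq_len(nrow(sents))) {
    s0 <- sents$start[i]; e0 <- sents$end[i]
    stext <- span_text(doc$body_text, s0, e0)
    toks <- tokenize(stext)
    hits <- Filter(function(a) a$span[1] >= s0 && a$span[2] <= e0, spanned)
    mentions <- if (length(hits) == 0)
      data.frame(label = character(0), start = integer(0), end = integer(0))
    else do.call(rbind, lapply(hits, function(a)
      data.frame(label = a$entity_id, start = a$span[1] - s0,
                 end = a$span[2] - s0, stringsAsFactors = FALSE)))
    out[[length(out) + 1L]] <- encode_bio(toks, mentions)
  }
  if (length(tabular) > 0) {
    ctxs <- vapply(tabular, function(a) a$context_text, character(1))
    for (ctx in unique(ctxs)) {
      toks <- tokenize(ctx)
      anns <- tabular[ctxs == ctx]
      used_up_to <- 0L
      rows <- list()
      for (a in anns) {
        pos <- regexpr(a$raw_text, substr(ctx, used_up_to + 1L, nchar(ctx)),
                       fixed = TRUE)
        if (pos == -1) next
        st <- used_up_to + as.integer(pos) - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          label = a$entity_id, start = st, end = st + nchar(a$raw_text),
          stringsAsFactors = FALSE)
        used_up_to <- st + nchar(a$raw_text)
      }
      mentions <- if (length(rows) == 0)
        data.frame(label = character(0), start = integer(0), end = integer(0))
      else do.call(rbind, rows)
      out[[length(out) + 1L]] <- encode_bio(toks, mentions)
    }
  }
  out
}

#' Save / load a trained tagger
#'
#' The artefact embeds the full config, including the training seed.
#'
#' @param model a `tagger_model`.
#' @param path artefact file path.
#' @export
save_tagger <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) readRDS(path)
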