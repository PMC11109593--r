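# Entity co-occurrence graph and random-walk (node2vec-style) embeddings.
#
# Nodes are schema entities; an edge weight counts the documents in which
# both entities are annotated. Embeddings come from second-order biased
# random walks (return parameter p, in-out parameter q) fed to a
# negative-sampling skip-gram trained by minibatch SGD -- the same
# skip-gram is reused for locally trained text embeddings.

#' Build the annotation co-occurrence graph
#'
#' @param studies list of `annotated_study`; each document contributes one
#'   co-occurrence per unordered pair of entities annotated in it.
#' @return A `cooccurrence_graph`: list with `nodes` and `edges`
#'   (`data.frame(i, j, w)` over node indices, `i < j`).
#' @export
build_cooccurrence_graph <- function(studies) {
  per_doc <- lapply(studies, function(st)
    sort(unique(vapply(Filter(function(a) a$entity_id != ARM_NAME,
                              st$annotations),
                       function(a) a$entity_id, character(1)))))
  nodes <- sort(unique(unlist(per_doc)))
  pair_keys <- unlist(lapply(per_doc, function(ents) {
    if (length(ents) < 2) return(character(0))
    cmb <- utils::combn(ents, 2)
    paste(cmb[1, ], cmb[2, ], sep = "\r")
  }))
  if (length(pair_keys) == 0) {
    edges <- data.frame(i = integer(0), j = integer(0), w = integer(0))
  } else {
    tab <- table(pair_keys)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    edges <- data.frame(
      i = match(vapply(parts, `[`, character(1), 1), nodes),
      j = match(vapply(parts, `[`, character(1), 2), nodes),
      w = as.integer(tab))
  }
  structure(list(nodes = nodes, edges = edges), class = "cooccurrence_graph")
}

graph_adjacency <- function(graph) {
  n <- length(graph$nodes)
  A <- matrix(0, n, n)
  if (nrow(graph$edges) > 0) {
    A[cbind(graph$edges$i, graph$edges$j)] <- graph$edges$w
    A[cbind(graph$edges$j, graph$edges$i)] <- graph$edges$w
  }
  A
}

#' Graph embedding configuration
#'
#' @param dimensions embedding dimension.
#' @param walks_per_node,walk_length random-walk schedule.
#' @param p,q return and in-out bias parameters of the second-order walk
#'   (p = q = 1 reduces to a plain weighted random walk).
#' @param window skip-gram context window (in walk positions).
#' @param epochs skip-gram passes over the walk corpus.
#' @param negatives negative samples per positive pair.
#' @param lr SGD learning rate.
#' @param seed integer seed; all walk and SGD randomness derives from it.
#' @export
graph_embedding_config <- function(dimensions = 16L, walks_per_node = 10L,
                                   walk_length = 20L, p = 1, q = 1,
                                   window = 4L, epochs = 3L, negatives = 5L,
                                   lr = 0.05, seed = 1L) {
  abort_if(dimensions <= 0 || walks_per_node <= 0 || walk_length <= 0 ||
             p <= 0 || q <= 0 || window <= 0 || epochs <= 0,
           "all graph embedding parameters must be positive")
  structure(list(dimensions = as.integer(dimensions),
                 walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length), p = p, q = q,
                 window = as.integer(window), epochs = as.integer(epochs),
                 negatives = as.integer(negatives), lr = lr,
                 seed = as.integer(seed)),
            class = "graph_embedding_config")
}

# One biased second-order walk from `start` over adjacency A.
node2vec_walk <- function(A, start, length, p, q) {
  walk <- integer(length)
  walk[1] <- start
  for (t in 2:length) {
    cur <- walk[t - 1L]
    w <- A[cur, ]
    nbr <- which(w > 0)
    if (length(nbr) == 0) return(walk[seq_len(t - 1L)])
    probs <- w[nbr]
    if (t > 2) {
      prev <- walk[t - 2L]
      bias <- ifelse(nbr == prev, 1 / p, ifelse(A[prev, nbr] > 0, 1, 1 / q))
      probs <- probs * bias
    }
    walk[t] <- if (length(nbr) == 1) nbr else
      sample(nbr, 1L, prob = probs)
  }
  walk
}

#' Skip-gram embeddings over token sequences
#'
#' Negative-sampling skip-gram trained with minibatch SGD; the noise
#' distribution is the unigram distribution raised to 3/4. Deterministic
#' given the seed.
#'
#' @param sequences list of integer vectors (indices into `vocab`) or
#'   character vectors.
#' @param vocab character vector naming the vocabulary; inferred when
#'   sequences are character.
#' @param dimensions,window,epochs,negatives,lr,seed training parameters.
#' @return Matrix (|vocab| x dimensions) with rownames `vocab`.
#' @export
skipgram_embed <- function(sequences, vocab = NULL, dimensions = 16L,
                           window = 4L, epochs = 3L, negatives = 5L,
                           lr = 0.05, seed = 1L) {
  if (is.character(sequences[[1]])) {
    vocab <- vocab %||% sort(unique(unlist(sequences)))
    sequences <- lapply(sequences, function(s) match(s, vocab))
  }
  abort_if(is.null(vocab) || length(vocab) == 0, "empty vocabulary",
           class = "trialminer_usage_error")
  V <- length(vocab)
  # positive pairs from all windows
  centers <- integer(0); contexts <- integer(0)
  for (s in sequences) {
    n <- length(s)
    if (n < 2) next
    for (d in seq_len(min(window, n - 1L))) {
      centers <- c(centers, s[seq_len(n - d)], s[(d + 1):n])
      contexts <- c(contexts, s[(d + 1):n], s[seq_len(n - d)])
    }
  }
  counts <- tabulate(unlist(sequences), nbins = V)
  noise <- (counts + 1)^0.75
  noise <- noise / sum(noise)
  with_seed(seed, {
    U <- matrix(stats::runif(V * dimensions, -0.5, 0.5) / dimensions, V, dimensions)
    Cm <- matrix(0, V, dimensions)
    np <- length(centers)
    if (np > 0) for (ep in seq_len(epochs)) {
      ord <- sample.int(np)
      batches <- split(ord, ceiling(seq_along(ord) / 512))
      for (b in batches) {
        ci <- centers[b]; oi <- contexts[b]
        # positive update
        sc <- stats::plogis(rowSums(U[ci, , drop = FALSE] * Cm[oi, , drop = FALSE]))
        g <- (1 - sc) * lr
        dU <- Cm[oi, , drop = FALSE] * g
        dC <- U[ci, , drop = FALSE] * g
        # negative updates
        for (k in seq_len(negatives)) {
          ni <- sample.int(V, length(b), replace = TRUE, prob = noise)
          scn <- stats::plogis(rowSums(U[ci, , drop = FALSE] * Cm[ni, , drop = FALSE]))
          gn <- -scn * lr
          dU <- dU + Cm[ni, , drop = FALSE] * gn
          dCn <- U[ci, , drop = FALSE] * gn
          Cm <- Cm + rowsum_into(dCn, ni, V)
        }
        U <- U + rowsum_into(dU, ci, V)
        Cm <- Cm + rowsum_into(dC, oi, V)
      }
    }
    rownames(U) <- vocab
    U
  })
}

# Scatter-add rows of m into an (n x ncol) matrix grouped by idx.
rowsum_into <- function(m, idx, n) {
  out <- matrix(0, n, ncol(m))
  rs <- rowsum(m, group = idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Learn node embeddings from the co-occurrence graph
#'
#' Generates biased random walks and trains the skip-gram over them.
#'
#' @param graph a `cooccurrence_graph`.
#' @param config a [graph_embedding_config()].
#' @return Matrix (nodes x dimensions) with node-name rownames.
#' @export
learn_graph_embeddings <- function(graph, config = graph_embedding_config()) {
  abort_if(length(graph$nodes) == 0, "cannot embed an empty graph",
           class = "trialminer_usage_error")
  A <- graph_adjacency(graph)
  n <- length(graph$nodes)
  walks <- with_seed(config$seed, {
    out <- list()
    for (r in seq_len(config$walks_per_node))
      for (v in seq_len(n))
        out[[length(out) + 1L]] <-
          node2vec_walk(A, v, config$walk_length, config$p, config$q)
    out
  })
  skipgram_embed(walks, vocab = graph$nodes, dimensions = config$dimensions,
                 window = config$window, epochs = config$epochs,
                 negatives = config$negatives, lr = config$lr,
                 seed = derive_seed(config$seed, 101L))
}

#' Train text embeddings on the corpus's own context sentences
#'
#' A stand-in for externally pretrained biomedical vectors: the same
#' skip-gram, trained on the tokenized context sentences recorded with the
#' annotations.
#'
#' @param studies list of `annotated_study`.
#' @param dimensions,window,epochs,seed skip-gram parameters.
#' @return Matrix (vocabulary x dimensions), or `NULL` when there is no
#'   context text.
#' @export
learn_text_embeddings <- function(studies, dimensions = 8L, window = 4L,
                                  epochs = 3L, seed = 1L) {
  sents <- unique(unlist(lapply(studies, function(st)
    vapply(st$annotations, function(a) a$context_text, character(1)))))
  sents <- sents[nzchar(sents)]
  if (length(sents) == 0) return(NULL)
  toks <- lapply(sents, function(s) tolower(tokenize(s)$surface))
  toks <- Filter(length, toks)
  skipgram_embed(toks, dimensions = dimensions, window = window,
                 epochs = epochs, seed = seed)
}
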