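# Independent oracles, written before the implementations they check and
# kept free of any package internals.

# precision/recall/F1 straight from the definitions
oracle_prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(p = p, r = r, f1 = f1)
}

# RMSE by explicit loop
oracle_rmse <- function(pred, gold) {
  acc <- 0
  for (i in seq_along(pred)) acc <- acc + (pred[i] - gold[i])^2
  sqrt(acc / length(pred))
}

# Nominal two-coder Krippendorff alpha from the coincidence-matrix
# definition: each pairable item contributes both ordered pairs of its two
# codes; Do sums off-diagonal coincidences, De is the chance expectation.
oracle_alpha <- function(c1, c2) {
  keep <- !is.na(c1) & !is.na(c2)
  c1 <- as.character(c1[keep]); c2 <- as.character(c2[keep])
  cats <- sort(unique(c(c1, c2)))
  o <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  for (i in seq_along(c1)) {
    o[c1[i], c2[i]] <- o[c1[i], c2[i]] + 1
    o[c2[i], c1[i]] <- o[c2[i], c1[i]] + 1
  }
  n <- sum(o)
  nc <- rowSums(o)
  Do <- (n - sum(diag(o))) / n
  De <- (sum(outer(nc, nc)) - sum(nc^2)) / (n * (n - 1))
  if (De == 0) return(1)
  1 - Do / De
}

# Greedy complete-link agglomeration, coded independently: O(n^2) scan per
# merge, recomputing min cross-pair similarity from scratch; ties broken by
# the lexicographically smallest (smallest-member, smallest-member) pair.
oracle_complete_link <- function(S, labels, n) {
  clusters <- lapply(seq_along(labels), identity)
  while (length(clusters) > n) {
    best_s <- -Inf; best <- NULL; best_key <- c("￿", "￿")
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        s <- min(S[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(labels[clusters[[i]]]), min(labels[clusters[[j]]])))
        better <- s > best_s ||
          (s == best_s && (key[1] < best_key[1] ||
                             (key[1] == best_key[1] && key[2] < best_key[2])))
        if (better) { best_s <- s; best <- c(i, j); best_key <- key }
      }
    }
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- clusters[-best[2]]
  }
  # canonical form: sorted member sets
  sets <- lapply(clusters, function(cl) sort(labels[cl]))
  sets[order(vapply(sets, `[`, character(1), 1))]
}

# random valid BIO mention layout over n tokens
random_mention_layout <- function(n_tokens, labels = c("X", "Y", "Z")) {
  tags <- rep("O", n_tokens)
  i <- 1
  mentions <- list()
  while (i <= n_tokens) {
    if (stats::runif(1) < 0.4) {
      len <- sample(1:min(3, n_tokens - i + 1), 1)
      lab <- sample(labels, 1)
      tags[i] <- paste0("B-", lab)
      if (len > 1) tags[(i + 1):(i + len - 1)] <- paste0("I-", lab)
      mentions[[length(mentions) + 1]] <- list(label = lab, tok_start = i - 1,
                                               tok_end = i + len - 1)
      i <- i + len
    } else i <- i + 1
  }
  list(tags = tags, mentions = mentions)
}

# simple token frame for synthetic sentences of single-char words
toy_tokens <- function(n) {
  data.frame(surface = letters[(seq_len(n) - 1) %% 26 + 1],
             start = (seq_len(n) - 1) * 2L,
             end = (seq_len(n) - 1) * 2L + 1L, stringsAsFactors = FALSE)
}

# small clean generator world shared across tests
tiny_corpus <- function(n = 10, seed = 101, ...) {
  generate_corpus(generator_config(seed = seed, n_docs = n, ...))
}
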