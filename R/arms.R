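# Study-arm resolution.
#
# Trial reports refer to the same arm with many surface forms ("patch",
# "patch group", "nicotine patch"). The machinery here: (1) detect the
# number of arms n from the conventional "randomised into/in n groups"
# phrase; (2) cluster arm-name mentions with complete-link agglomerative
# clustering into n clusters (the similarity of two clusters is the
# similarity of their most dissimilar members); (3) label each cluster with
# its most frequent member; (4) attach each entity mention to the arm of
# the nearest arm-name mention within a token window t, falling back to the
# whole study when none is near enough.

NUMBER_WORDS <- c(one = 1L, two = 2L, three = 3L, four = 4L, five = 5L,
                  six = 6L, seven = 7L, eight = 8L, nine = 9L, ten = 10L)

#' Arm-resolution configuration
#'
#' @param window `t`, the association window in tokens; it has to be tuned
#'   empirically per corpus, 30 is this package's documented default.
#' @param tie_break which arm wins when mentions before and after an entity
#'   are equidistant.
#' @param sim_floor when the arm count cannot be detected, clustering stops
#'   once the best complete-link similarity drops below this floor.
#' @export
arm_config <- function(window = 30L,
                       tie_break = c("prefer_preceding", "prefer_following"),
                       sim_floor = 0.2) {
  abort_if(window < 0, "window must be non-negative")
  structure(list(window = as.integer(window), tie_break = match.arg(tie_break),
                 sim_floor = sim_floor),
            class = "arm_config")
}

#' Detect the number of study arms from text
#'
#' Scans for the conventional pattern `(into|in) <n> (groups|arms|conditions)`
#' with `n` a digit or a number word one..ten, and returns the numeral of
#' the first match.
#'
#' @param text document body text.
#' @return A positive integer, or `NULL` when no pattern matches (callers
#'   then fall back to similarity-floor clustering).
#' @export
detect_arm_count <- function(text) {
  pat <- paste0("\\b(?:into|in)\\s+([0-9]+|",
                paste(names(NUMBER_WORDS), collapse = "|"),
                ")\\s+(?:groups?|arms?|conditions?)\\b")
  m <- regexpr(pat, text, perl = TRUE, ignore.case = TRUE)
  if (m == -1) return(NULL)
  hit <- regmatches(text, m)
  num <- regmatches(hit, regexpr("[0-9]+|[A-Za-z]+(?=\\s+(groups?|arms?|conditions?))",
                                 hit, perl = TRUE, ignore.case = TRUE))
  num <- tolower(num[1])
  n <- if (grepl("^[0-9]+$", num)) as.integer(num) else NUMBER_WORDS[[num]]
  if (is.na(n) || n < 1) NULL else as.integer(n)
}

sim_tokens <- function(x) {
  unique(regmatches(tolower(x), gregexpr("[a-z0-9]+", tolower(x)))[[1]])
}

#' Similarity of two arm-name surface forms
#'
#' Token-set Jaccard similarity over lowercased, punctuation-stripped
#' tokens: symmetric, in `[0, 1]`, and 1 for identical normalized forms.
#'
#' @param a,b non-empty strings.
#' @export
mention_similarity <- function(a, b) {
  abort_if(!nzchar(a) || !nzchar(b), "mention surfaces must be non-empty",
           class = "trialminer_usage_error")
  ta <- sim_tokens(a); tb <- sim_tokens(b)
  if (length(ta) == 0 && length(tb) == 0) return(1)
  length(intersect(ta, tb)) / length(union(ta, tb))
}

# Distinct surface forms with occurrence counts and earliest position.
distinct_mentions <- function(mentions) {
  agg <- split(seq_len(nrow(mentions)), mentions$surface)
  df <- data.frame(surface = names(agg),
                   count = vapply(agg, length, integer(1)),
                   first_start = vapply(agg, function(i)
                     as.integer(min(mentions$start[i])), integer(1)),
                   stringsAsFactors = FALSE)
  df[order(df$first_start), , drop = FALSE]
}

# Complete-link similarity between two clusters (index vectors) under S.
complete_link <- function(S, c1, c2) min(S[c1, c2])

# Agglomeration core over an explicit similarity matrix: merge the pair of
# clusters with the highest complete-link similarity until `n` remain (or,
# with n NULL, until the best merge falls below `floor`). Ties break on the
# lexicographically smallest pair of cluster keys (key = smallest label).
cluster_indices <- function(S, labels, n, floor = 0.2) {
  clusters <- as.list(seq_along(labels))
  target <- if (is.null(n)) 1L else as.integer(n)
  while (length(clusters) > target) {
    best <- -Inf; best_pair <- NULL; best_key <- NULL
    nc <- length(clusters)
    keys <- vapply(clusters, function(cl) min(labels[cl]), character(1))
    for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc) {
      s <- complete_link(S, clusters[[i]], clusters[[j]])
      key <- sort(c(keys[i], keys[j]))
      if (s > best ||
          (s == best && (key[1] < best_key[1] ||
                          (key[1] == best_key[1] && key[2] < best_key[2])))) {
        best <- s; best_pair <- c(i, j); best_key <- key
      }
    }
    if (is.null(n) && best < floor) break
    clusters[[best_pair[1]]] <- c(clusters[[best_pair[1]]], clusters[[best_pair[2]]])
    clusters[[best_pair[2]]] <- NULL
  }
  clusters
}

#' Cluster arm-name mentions into arms
#'
#' Agglomerative complete-link clustering: repeatedly merge the pair of
#' clusters with the highest complete-link similarity until `n` clusters
#' remain, or -- when `n` is `NULL` -- until the best merge similarity falls
#' below `config$sim_floor`. Ties in merge order are broken by the
#' lexicographically smallest pair of cluster keys (a cluster's key is its
#' smallest member surface), so clustering is deterministic. Each cluster
#' becomes an [arm()] labelled by its most frequent member (ties: earliest
#' first occurrence).
#'
#' @param mentions data frame of arm-name mention occurrences with columns
#'   `surface` and `start` (character offset, used for tie-breaking and
#'   reading-order arm ids).
#' @param n target number of arms, or `NULL` to use the similarity floor.
#' @param config an [arm_config()].
#' @return List of `arm` objects in reading order (`arm_1`, `arm_2`, ...).
#' @export
cluster_arm_mentions <- function(mentions, n = NULL, config = arm_config()) {
  abort_if(nrow(mentions) == 0, "at least one arm mention is required",
           class = "trialminer_clustering_error")
  d <- distinct_mentions(mentions)
  m <- nrow(d)
  abort_if(!is.null(n) && n > m,
           "cannot form ", n, " arms from ", m, " distinct mentions",
           class = "trialminer_clustering_error")
  S <- outer(seq_len(m), seq_len(m),
             Vectorize(function(i, j) mention_similarity(d$surface[i], d$surface[j])))
  clusters <- cluster_indices(S, d$surface, n, floor = config$sim_floor)
  # reading order: by earliest member occurrence
  ord <- order(vapply(clusters, function(cl) min(d$first_start[cl]), integer(1)))
  clusters <- clusters[ord]
  lapply(seq_along(clusters), function(k) {
    mem <- d[clusters[[k]], , drop = FALSE]
    arm(paste0("arm_", k), label_cluster(mem), mem)
  })
}

#' Choose a cluster's canonical label
#'
#' The most frequent member surface form; ties go to the member occurring
#' earliest in the document.
#'
#' @param members data frame with columns `surface`, `count`, `first_start`.
#' @return A surface form.
#' @export
label_cluster <- function(members) {
  abort_if(nrow(members) == 0, "empty cluster",
           class = "trialminer_clustering_error")
  best <- members[members$count == max(members$count), , drop = FALSE]
  best$surface[which.min(best$first_start)]
}

# token-boundary distance between two mentions (see associate_entities)
mention_distance <- function(ent_start, ent_end, arm_start, arm_end) {
  as.integer(
    if (arm_end <= ent_start) ent_start - (arm_end - 1)       # arm precedes
    else if (ent_end <= arm_start) arm_start - (ent_end - 1)  # arm follows
    else 0)                                                   # overlap
}

#' Associate entity mentions with arms
#'
#' Each entity mention is assigned to the arm of the nearest arm-name
#' mention within `config$window` tokens (distance between nearest token
#' boundaries); if none is near enough the entity is associated to the
#' whole study. Table (pseudo-sentence) mentions measure distance only
#' within their own pseudo-sentence. Equidistant candidates on both sides
#' are resolved by `config$tie_break`.
#'
#' @param entity_mentions,arm_mentions mention data frames (as produced by
#'   [tag_document()]) carrying `tok_start`, `tok_end`, `source`, `ps_id`;
#'   `arm_mentions` additionally needs `surface`.
#' @param arms list of `arm` objects from [cluster_arm_mentions()].
#' @param config an [arm_config()].
#' @return Data frame with one row per entity mention: `target` (arm id or
#'   `WHOLE_STUDY`) and `distance` (NA when unassigned).
#' @export
associate_entities <- function(entity_mentions, arm_mentions, arms,
                               config = arm_config()) {
  surface_to_arm <- list()
  for (a in arms)
    for (s in a$members$surface) surface_to_arm[[tolower(s)]] <- a$arm_id
  n <- nrow(entity_mentions)
  target <- rep(WHOLE_STUDY, n)
  distance <- rep(NA_integer_, n)
  if (n == 0 || nrow(arm_mentions) == 0)
    return(data.frame(target = target, distance = distance,
                      stringsAsFactors = FALSE))
  arm_ids <- vapply(arm_mentions$surface, function(s)
    surface_to_arm[[tolower(s)]] %||% NA_character_, character(1))
  for (i in seq_len(n)) {
    same_space <- if (identical(entity_mentions$source[i], "table"))
      arm_mentions$source == "table" & arm_mentions$ps_id == entity_mentions$ps_id[i]
    else arm_mentions$source == "body"
    cand <- which(same_space & !is.na(arm_ids))
    if (length(cand) == 0) next
    ds <- vapply(cand, function(j)
      mention_distance(entity_mentions$tok_start[i], entity_mentions$tok_end[i],
                       arm_mentions$tok_start[j], arm_mentions$tok_end[j]),
      integer(1))
    ok <- ds <= config$window
    if (!any(ok)) next
    cand <- cand[ok]; ds <- ds[ok]
    best <- which(ds == min(ds))
    if (length(best) > 1) {
      preceding <- arm_mentions$tok_end[cand[best]] <= entity_mentions$tok_start[i]
      pick <- if (config$tie_break == "prefer_preceding" && any(preceding))
        best[preceding][1]
      else if (config$tie_break == "prefer_following" && any(!preceding))
        best[!preceding][1]
      else best[1]
    } else pick <- best
    target[i] <- arm_ids[cand[pick]]
    distance[i] <- ds[pick]
  }
  data.frame(target = target, distance = distance, stringsAsFactors = FALSE)
}

#' Resolve arms for a tagged document
#'
#' Full per-document arm machinery: detect the arm count, cluster the
#' `ARM_NAME` mentions, associate every other mention with an arm, and
#' package the result as an `annotated_study` with predicted annotations.
#'
#' @param doc a `document`.
#' @param mentions output of [tag_document()].
#' @param schema the `entity_schema` (used to normalize values of
#'   value-bearing entities).
#' @param config an [arm_config()].
#' @return An `annotated_study`.
#' @export
resolve_document <- function(doc, mentions, schema, config = arm_config()) {
  is_arm <- mentions$label == ARM_NAME
  arm_mentions <- mentions[is_arm, , drop = FALSE]
  entity_mentions <- mentions[!is_arm, , drop = FALSE]
  arms <- list()
  if (nrow(arm_mentions) > 0) {
    n <- detect_arm_count(doc$body_text)
    n_distinct <- nrow(distinct_mentions(arm_mentions))
    if (!is.null(n)) n <- min(n, n_distinct)
    arms <- cluster_arm_mentions(arm_mentions, n, config)
  }
  assign <- associate_entities(entity_mentions, arm_mentions, arms, config)
  anns <- lapply(seq_len(nrow(entity_mentions)), function(i) {
    mi <- entity_mentions[i, ]
    spec <- schema[match(mi$label, schema$entity_id), , drop = FALSE]
    val <- NA_real_
    if (nrow(spec) == 1 && !is.na(spec$kind) &&
        spec$kind %in% c("value", "complex_component"))
      val <- tryCatch(normalize_value(mi$surface, spec), error = function(e) NA_real_)
    if (identical(mi$source, "table")) {
      annotation(doc$doc_id, mi$label, span = NULL, raw_text = mi$surface,
                 context_text = doc$pseudo_sentences$text[mi$ps_id],
                 value = val, arm_ref = assign$target[i])
    } else {
      ctx <- if (!is.na(mi$sent_id))
        span_text(doc$body_text, doc$sentences$start[mi$sent_id],
                  doc$sentences$end[mi$sent_id])
      else ""
      annotation(doc$doc_id, mi$label, span = c(mi$start, mi$end),
                 raw_text = mi$surface, context_text = ctx,
                 value = val, arm_ref = assign$target[i])
    }
  })
  annotated_study(doc, arms = arms, annotations = anns)
}
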