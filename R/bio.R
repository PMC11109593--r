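# Tokenization and BIO tag-sequence encoding/decoding.
#
# BIO labelling marks the Beginning, Inside and Outside of entity spans at
# the token level; encode/decode are mutually inverse on valid input, and
# decoding repairs invalid sequences (a leading I-X becomes B-X) so it is
# total.

#' Tokenize a sentence
#'
#' Splits on whitespace, keeping decimal numbers intact ("44.5" is one
#' token) and isolating punctuation. Offsets are 0-based half-open into the
#' input string, so each surface equals the text at its span.
#'
#' @param text a character scalar.
#' @return Data frame with columns `surface`, `start`, `end`.
#' @export
tokenize <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(text))
    return(data.frame(surface = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  m <- gregexpr("[0-9]+\\.[0-9]+|[0-9]+|[A-Za-z]+|[^A-Za-z0-9 \t\r\n]",
                text, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(surface = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(surface = substring(text, starts, starts + lens - 1L),
             start = starts - 1L, end = starts + lens - 1L,
             stringsAsFactors = FALSE)
}

#' Encode mentions as a BIO tag sequence
#'
#' @param tokens token data frame from [tokenize()].
#' @param mentions data frame with columns `label`, `start`, `end`
#'   (character offsets); mentions must align with token boundaries and must
#'   not overlap.
#' @return A `tag_sequence`: list with `tokens` and `tags`.
#' @export
encode_bio <- function(tokens, mentions) {
  tags <- rep("O", nrow(tokens))
  if (!is.null(mentions) && nrow(mentions) > 0) {
    mentions <- mentions[order(mentions$start), , drop = FALSE]
    abort_if(any(mentions$end[-nrow(mentions)] > mentions$start[-1]),
             "overlapping mentions cannot be BIO-encoded",
             class = "trialminer_alignment_error")
    for (i in seq_len(nrow(mentions))) {
      inside <- which(tokens$start >= mentions$start[i] &
                        tokens$end <= mentions$end[i])
      crosses <- which(tokens$start < mentions$end[i] &
                         tokens$end > mentions$start[i])
      abort_if(length(inside) == 0 || !identical(inside, crosses),
               "mention [", mentions$start[i], ",", mentions$end[i],
               ") does not align with token boundaries",
               class = "trialminer_alignment_error")
      tags[inside[1]] <- paste0("B-", mentions$label[i])
      if (length(inside) > 1)
        tags[inside[-1]] <- paste0("I-", mentions$label[i])
    }
  }
  tag_sequence(tokens, tags)
}

#' @rdname encode_bio
#' @param tags character vector of BIO tags, same length as `tokens`.
#' @export
tag_sequence <- function(tokens, tags) {
  abort_if(length(tags) != nrow(tokens),
           "tags and tokens must have the same length",
           class = "trialminer_validation_error")
  structure(list(tokens = tokens, tags = as.character(tags)),
            class = "tag_sequence")
}

tag_label <- function(tag) sub("^[BI]-", "", tag)

#' Decode a BIO tag sequence into mentions
#'
#' Total inverse of [encode_bio()]: invalid sequences are repaired first (an
#' I-X preceded by O or by a different label is promoted to B-X).
#'
#' @param ts a `tag_sequence`.
#' @return Data frame of mentions: `label`, `start`, `end` (character
#'   offsets), `tok_start`, `tok_end` (0-based token indices, half-open),
#'   `surface`.
#' @export
decode_bio <- function(ts) {
  tags <- repair_bio(ts$tags)
  toks <- ts$tokens
  out <- list()
  i <- 1L
  while (i <= length(tags)) {
    if (startsWith(tags[i], "B-")) {
      lab <- tag_label(tags[i])
      j <- i
      while (j + 1L <= length(tags) && tags[j + 1L] == paste0("I-", lab)) j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(
        label = lab, start = toks$start[i], end = toks$end[j],
        tok_start = i - 1L, tok_end = j, stringsAsFactors = FALSE)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(out) == 0)
    return(data.frame(label = character(0), start = integer(0), end = integer(0),
                      tok_start = integer(0), tok_end = integer(0),
                      surface = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$surface <- mention_surface(toks, res$tok_start, res$tok_end)
  res
}

# Surface text of a token range, preserving original spacing when the tokens
# carry character offsets into a common string (offset gaps become spaces).
mention_surface <- function(toks, tok_start, tok_end) {
  vapply(seq_along(tok_start), function(k) {
    idx <- (tok_start[k] + 1L):tok_end[k]
    pieces <- toks$surface[idx]
    if (length(idx) == 1) return(pieces)
    gaps <- toks$start[idx[-1]] - toks$end[idx[-length(idx)]]
    paste0(pieces[1], paste0(vapply(seq_along(gaps), function(g)
      paste0(strrep(" ", max(0L, gaps[g])), pieces[g + 1L]), character(1)),
      collapse = ""))
  }, character(1))
}

#' Repair a BIO tag vector
#'
#' @param tags character vector over `O`, `B-X`, `I-X`.
#' @return A valid BIO vector: every `I-X` follows `B-X` or `I-X`.
#' @export
repair_bio <- function(tags) {
  for (i in seq_along(tags)) {
    if (startsWith(tags[i], "I-")) {
      lab <- tag_label(tags[i])
      prev_ok <- i > 1L && tags[i - 1L] %in% paste0(c("B-", "I-"), lab)
      if (!prev_ok) tags[i] <- paste0("B-", lab)
    }
  }
  tags
}

#' Check BIO validity
#'
#' @param tags character vector of tags.
#' @return TRUE iff no `I-X` is preceded by `O`, sequence start, or a tag of
#'   a different label.
#' @export
is_valid_bio <- function(tags) identical(tags, repair_bio(tags))
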