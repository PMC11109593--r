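# Document ingestion: sentence segmentation and table linearization.
#
# Trial reports arrive pre-extracted as plain text plus structured table
# objects (PDF layout parsing is out of scope). Tables are turned into
# "pseudo-sentences" -- one templated sentence per data cell -- so that
# tabular content can flow through the same sequence tagger as running text.

# Abbreviations after which a period never ends a sentence.
ABBREVIATIONS <- c("al", "fig", "figs", "eq", "dr", "mr", "mrs", "ms", "prof",
                   "vs", "etc", "no", "approx", "ref", "refs", "st", "cf",
                   "e.g", "i.e", "resp")

#' Segment text into sentences
#'
#' Rule-based, deterministic segmentation: a sentence ends at a run of
#' sentence-final punctuation (`.?!`) followed by whitespace and an
#' uppercase letter, unless the word before the period is a known
#' abbreviation ("et al.", "Fig.", ...). Offsets are 0-based half-open;
#' every character of `text` falls in exactly one sentence or in
#' inter-sentence whitespace.
#'
#' @param text a character scalar.
#' @return Data frame with integer columns `start`, `end` (one row per
#'   sentence); zero rows for empty/blank text.
#' @export
segment_sentences <- function(text) {
  abort_if(is.null(text) || is.na(text), "text must be a string")
  out <- data.frame(start = integer(0), end = integer(0))
  if (!nzchar(trimws(text))) return(out)
  m <- gregexpr("[.?!]+(?=[ \t\r\n]+[A-Z])", text, perl = TRUE)[[1]]
  breaks <- integer(0)
  if (m[1] != -1) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L  # 1-based last punct char
    for (k in seq_along(ends)) {
      pos <- as.integer(m[k])
      before <- substr(text, max(1L, pos - 12L), pos - 1L)
      word <- regmatches(before, regexpr("[A-Za-z]+(\\.[A-Za-z]+)*$", before))
      if (length(word) == 1 && tolower(word) %in% ABBREVIATIONS) next
      breaks <- c(breaks, ends[k])
    }
  }
  starts_at <- c(1L, breaks + 1L)
  ends_at <- c(breaks, nchar(text))
  for (k in seq_along(starts_at)) {
    seg <- substr(text, starts_at[k], ends_at[k])
    lead <- nchar(seg) - nchar(sub("^[ \t\r\n]+", "", seg))
    trail <- nchar(seg) - nchar(sub("[ \t\r\n]+$", "", seg))
    s <- starts_at[k] + lead
    e <- ends_at[k] - trail
    if (e >= s) out <- rbind(out, data.frame(start = s - 1L, end = e))
  }
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  out
}

#' Construct a table object
#'
#' @param table_id identifier, unique within a document.
#' @param cells character matrix (rectangular grid; use `""` for empty cells).
#' @param header_row_count,header_col_count numbers of leading header
#'   rows/columns; must be strictly smaller than the grid dimensions.
#' @param caption optional caption text (not linearized).
#' @export
table_grid <- function(table_id, cells, header_row_count = 1L,
                       header_col_count = 1L, caption = "") {
  abort_if(!is.matrix(cells), "cells must be a rectangular character matrix",
           class = "trialminer_validation_error")
  abort_if(header_row_count >= nrow(cells) || header_col_count >= ncol(cells),
           "header counts must be smaller than the grid dimensions",
           class = "trialminer_validation_error")
  structure(list(table_id = as.character(table_id), caption = as.character(caption),
                 cells = matrix(as.character(cells), nrow(cells), ncol(cells)),
                 header_row_count = as.integer(header_row_count),
                 header_col_count = as.integer(header_col_count)),
            class = "table_grid")
}

#' Linearize a table into pseudo-sentences
#'
#' Each non-empty data cell becomes one pseudo-sentence
#' `"<row header> : <column header> is <cell> ."`, with multi-level headers
#' joined by `" , "`. Captions are not included. Provenance (table id and
#' 1-based cell coordinates) is recorded per pseudo-sentence.
#'
#' @param tab a `table_grid`.
#' @return Data frame with columns `text`, `table_id`, `row`, `col`.
#' @export
linearize_table <- function(tab) {
  abort_if(!inherits(tab, "table_grid"), "expected a table_grid",
           class = "trialminer_validation_error")
  cells <- tab$cells
  hr <- tab$header_row_count; hc <- tab$header_col_count
  out <- list()
  for (r in seq_len(nrow(cells))) {
    if (r <= hr) next
    for (cl in seq_len(ncol(cells))) {
      if (cl <= hc) next
      cell <- trimws(cells[r, cl])
      if (!nzchar(cell)) next
      rh <- trimws(cells[r, seq_len(hc)])
      ch <- trimws(cells[seq_len(hr), cl])
      rh <- paste(rh[nzchar(rh)], collapse = " , ")
      ch <- paste(ch[nzchar(ch)], collapse = " , ")
      out[[length(out) + 1L]] <- data.frame(
        text = paste0(rh, " : ", ch, " is ", cell, " ."),
        table_id = tab$table_id, row = r, col = cl, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(text = character(0), table_id = character(0),
                      row = integer(0), col = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Build a processable document
#'
#' Segments the body text and linearizes every table; deterministic for
#' fixed inputs.
#'
#' @param doc_id document identifier.
#' @param text body text.
#' @param tables list of `table_grid` objects with distinct ids.
#' @return A `document` with fields `doc_id`, `body_text`, `sentences`
#'   (offset data frame), `tables`, `pseudo_sentences`.
#' @export
build_document <- function(doc_id, text, tables = list()) {
  ids <- vapply(tables, function(t) t$table_id, character(1))
  abort_if(anyDuplicated(ids) > 0, "duplicate table ids",
           class = "trialminer_validation_error")
  ps <- if (length(tables) == 0)
    data.frame(text = character(0), table_id = character(0),
               row = integer(0), col = integer(0), stringsAsFactors = FALSE)
  else do.call(rbind, lapply(tables, linearize_table))
  rownames(ps) <- NULL
  structure(list(doc_id = as.character(doc_id), body_text = as.character(text),
                 sentences = segment_sentences(text), tables = tables,
                 pseudo_sentences = ps),
            class = "document")
}

document_to_list <- function(d) {
  list(doc_id = d$doc_id, text = d$body_text,
       tables = lapply(d$tables, function(t)
         list(table_id = t$table_id, caption = t$caption,
              cells = apply(t$cells, 1, as.list, simplify = FALSE),
              header_row_count = t$header_row_count,
              header_col_count = t$header_col_count)))
}

list_to_document <- function(l) {
  tabs <- lapply(l$tables %||% list(), function(t) {
    rows <- lapply(t$cells, unlist)
    cells <- matrix(unlist(rows), nrow = length(rows), byrow = TRUE)
    table_grid(t$table_id, cells, t$header_row_count, t$header_col_count,
               t$caption %||% "")
  })
  build_document(l$doc_id, l$text, tabs)
}

#' Read documents from a JSON-lines file
#'
#' Each line holds `{doc_id, text, tables:[{table_id, caption, cells,
#' header_row_count, header_col_count}]}`; `cells` is a list of rows.
#'
#' @param path input file.
#' @return List of `document` objects.
#' @export
read_documents <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lapply(lines[nzchar(lines)], function(ln)
    list_to_document(jsonlite::fromJSON(ln, simplifyVector = FALSE)))
}
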