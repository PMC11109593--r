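# Annotation data model and JSON-lines corpus IO.
#
# An annotation grounds one entity instance in a document: where it was said
# (a 0-based half-open character span, or a table cell for table-derived
# instances), what was said, the normalized numeric value for value-bearing
# entities, and which study arm it belongs to (or the WHOLE_STUDY sentinel).

#' Create an annotation
#'
#' @param doc_id document identifier.
#' @param entity_id schema entity id (or `ARM_NAME`).
#' @param span integer vector `c(start, end)`, 0-based half-open offsets into
#'   the document body, or `NULL` for table-derived instances.
#' @param raw_text verbatim annotated string.
#' @param context_text the sentence (or pseudo-sentence) around the span.
#' @param value numeric value or `NA` for presence-absence entities.
#' @param arm_ref arm id or `WHOLE_STUDY`.
#' @return An object of class `annotation`.
#' @export
annotation <- function(doc_id, entity_id, span = NULL, raw_text = "",
                       context_text = "", value = NA_real_,
                       arm_ref = WHOLE_STUDY) {
  structure(list(doc_id = as.character(doc_id),
                 entity_id = as.character(entity_id),
                 span = if (is.null(span)) NULL else as.integer(span),
                 raw_text = as.character(raw_text),
                 context_text = as.character(context_text),
                 value = as.numeric(value),
                 arm_ref = as.character(arm_ref)),
            class = "annotation")
}

#' Create a study arm
#'
#' @param arm_id stable identifier within the study.
#' @param label canonical label; must be one of the member surface forms.
#' @param members data frame with columns `surface`, `count`, `first_start`.
#' @export
arm <- function(arm_id, label, members) {
  members <- as.data.frame(members)
  abort_if(nrow(members) == 0, "an arm needs at least one member mention",
           class = "trialminer_validation_error")
  abort_if(!label %in% members$surface,
           "arm label must be a member surface form",
           class = "trialminer_validation_error")
  structure(list(arm_id = as.character(arm_id), label = as.character(label),
                 members = data.frame(surface = as.character(members$surface),
                                      count = as.integer(members$count),
                                      first_start = as.integer(members$first_start),
                                      stringsAsFactors = FALSE)),
            class = "arm")
}

#' Assemble an annotated study
#'
#' Container for one study's extraction: the document, its resolved arms,
#' grounded annotations, and per-arm outcome records.
#'
#' @param doc a `document` (see [build_document()]).
#' @param arms list of `arm` objects.
#' @param annotations list of `annotation` objects.
#' @param outcomes data frame with columns `arm_id`, `entity_id`, `value`
#'   (cessation percentage on the 0-100 scale).
#' @param validate check invariants (spans in bounds, arm refs known).
#' @return An `annotated_study`.
#' @export
annotated_study <- function(doc, arms = list(), annotations = list(),
                            outcomes = empty_outcomes(), validate = TRUE) {
  outcomes <- as.data.frame(outcomes)
  if (nrow(outcomes) > 0) {
    outcomes <- data.frame(arm_id = as.character(outcomes$arm_id),
                           entity_id = as.character(outcomes$entity_id),
                           value = as.numeric(outcomes$value),
                           stringsAsFactors = FALSE)
  } else outcomes <- empty_outcomes()
  st <- structure(list(doc = doc, arms = arms, annotations = annotations,
                       outcomes = outcomes),
                  class = "annotated_study")
  if (validate) validate_study(st)
  st
}

empty_outcomes <- function() {
  data.frame(arm_id = character(0), entity_id = character(0),
             value = numeric(0), stringsAsFactors = FALSE)
}

validate_study <- function(st) {
  arm_ids <- vapply(st$arms, function(a) a$arm_id, character(1))
  text_len <- nchar(st$doc$body_text)
  for (a in st$annotations) {
    if (!is.null(a$span)) {
      abort_if(a$span[1] < 0 || a$span[2] > text_len || a$span[1] >= a$span[2],
               "annotation span [", a$span[1], ",", a$span[2],
               ") out of bounds for doc ", st$doc$doc_id,
               class = "trialminer_validation_error")
      abort_if(span_text(st$doc$body_text, a$span[1], a$span[2]) != a$raw_text,
               "raw_text does not match document text at span in doc ",
               st$doc$doc_id, class = "trialminer_validation_error")
    }
    abort_if(!(a$arm_ref == WHOLE_STUDY || a$arm_ref %in% arm_ids),
             "annotation arm_ref ", a$arm_ref, " not among study arms",
             class = "trialminer_validation_error")
  }
  if (nrow(st$outcomes) > 0) {
    dup <- duplicated(st$outcomes[c("arm_id", "entity_id")])
    abort_if(any(dup), "more than one outcome record per arm and entity",
             class = "trialminer_validation_error")
  }
  invisible(st)
}

# ---- JSON-lines serialization ------------------------------------------------

annotation_to_list <- function(a) {
  list(doc_id = a$doc_id, entity_id = a$entity_id,
       span = if (is.null(a$span)) NULL else as.list(a$span),
       raw_text = a$raw_text, context_text = a$context_text,
       value = if (is.na(a$value)) NULL else a$value,
       arm_ref = a$arm_ref)
}

list_to_annotation <- function(l) {
  annotation(doc_id = l$doc_id, entity_id = l$entity_id,
             span = if (is.null(l$span)) NULL else unlist(l$span),
             raw_text = l$raw_text %||% "", context_text = l$context_text %||% "",
             value = if (is.null(l$value)) NA_real_ else l$value,
             arm_ref = l$arm_ref %||% WHOLE_STUDY)
}

arm_to_list <- function(a) {
  list(arm_id = a$arm_id, label = a$label,
       members = lapply(seq_len(nrow(a$members)), function(i)
         list(surface = a$members$surface[i], count = a$members$count[i],
              first_start = a$members$first_start[i])))
}

list_to_arm <- function(l) {
  m <- do.call(rbind, lapply(l$members, function(x)
    data.frame(surface = x$surface, count = x$count, first_start = x$first_start,
               stringsAsFactors = FALSE)))
  arm(l$arm_id, l$label, m)
}

study_to_list <- function(st) {
  list(doc = document_to_list(st$doc),
       arms = lapply(st$arms, arm_to_list),
       annotations = lapply(st$annotations, annotation_to_list),
       outcomes = lapply(seq_len(nrow(st$outcomes)), function(i)
         list(arm_id = st$outcomes$arm_id[i], entity_id = st$outcomes$entity_id[i],
              value = st$outcomes$value[i])))
}

list_to_study <- function(l, validate = TRUE) {
  outc <- if (length(l$outcomes) == 0) empty_outcomes() else
    do.call(rbind, lapply(l$outcomes, function(x)
      data.frame(arm_id = x$arm_id, entity_id = x$entity_id, value = x$value,
                 stringsAsFactors = FALSE)))
  annotated_study(doc = list_to_document(l$doc),
                  arms = lapply(l$arms, list_to_arm),
                  annotations = lapply(l$annotations, list_to_annotation),
                  outcomes = outc, validate = validate)
}

#' Write studies to a JSON-lines corpus file
#'
#' One study per line, UTF-8. The inverse of [read_annotations()];
#' `read_annotations(write_annotations(x, p))` reproduces `x`.
#'
#' @param studies list of `annotated_study` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(studies, path) {
  lines <- vapply(studies, function(st) {
    validate_study(st)
    as.character(jsonlite::toJSON(study_to_list(st), auto_unbox = TRUE,
                                  null = "null", digits = NA))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON-lines corpus of annotated studies
#'
#' @param path file written by [write_annotations()] (or the synthetic
#'   corpus generator).
#' @param validate check study invariants on load.
#' @return List of `annotated_study` objects, in file order.
#' @export
read_annotations <- function(path, validate = TRUE) {
  abort_if(!file.exists(path), "corpus file not found: ", path,
           class = "trialminer_parse_error")
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln)
    list_to_study(jsonlite::fromJSON(ln, simplifyVector = FALSE), validate = validate))
}
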