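# Entity schema: the flat extraction vocabulary.
#
# An entity is one discrete item of information to extract from a trial
# report: the presence of a behaviour change technique, a numeric population
# descriptor such as mean age, or a component of a complex entity such as the
# percentage of participants in one ethnic group.  The schema is a flat table
# of such targets; hierarchical ontology structure is out of scope except for
# the parent link that complex components carry.

VALID_KINDS <- c("presence_absence", "value", "complex_component")

#' Construct an entity schema from a data frame
#'
#' @param df data frame with columns `entity_id`, `name`, `kind`,
#'   `parent_id`, `value_unit`, `arm_scoped`. `parent_id`/`value_unit` may
#'   contain `NA`; `arm_scoped` is logical (or "true"/"false" strings).
#' @return A validated `entity_schema` object (a data frame).
#' @export
entity_schema <- function(df) {
  req <- c("entity_id", "name", "kind", "parent_id", "value_unit", "arm_scoped")
  missing_cols <- setdiff(req, names(df))
  abort_if(length(missing_cols) > 0,
           "schema is missing columns: ", paste(missing_cols, collapse = ", "),
           class = "trialminer_parse_error")
  df <- as.data.frame(df)[req]
  df$entity_id <- as.character(df$entity_id)
  df$name <- as.character(df$name)
  df$kind <- as.character(df$kind)
  df$parent_id <- as.character(df$parent_id)
  df$parent_id[!is.na(df$parent_id) & df$parent_id == ""] <- NA_character_
  df$value_unit <- as.character(df$value_unit)
  df$value_unit[!is.na(df$value_unit) & df$value_unit == ""] <- NA_character_
  if (!is.logical(df$arm_scoped))
    df$arm_scoped <- tolower(as.character(df$arm_scoped)) %in% c("true", "1", "yes")

  dup <- unique(df$entity_id[duplicated(df$entity_id)])
  abort_if(length(dup) > 0, "duplicate entity_id: ", paste(dup, collapse = ", "),
           class = "trialminer_validation_error")
  bad_kind <- setdiff(df$kind, VALID_KINDS)
  abort_if(length(bad_kind) > 0, "unknown kind: ", paste(bad_kind, collapse = ", "),
           class = "trialminer_validation_error")
  cc <- df$kind == "complex_component"
  abort_if(any(cc & is.na(df$parent_id)),
           "complex_component entities must have a parent_id",
           class = "trialminer_validation_error")
  abort_if(any(df$kind == "presence_absence" & !is.na(df$value_unit)),
           "presence_absence entities must not carry a value_unit",
           class = "trialminer_validation_error")
  # parent links must form a forest over schema ids
  known <- df$parent_id %in% df$entity_id | is.na(df$parent_id)
  abort_if(any(!known), "parent_id not in schema: ",
           paste(unique(df$parent_id[!known]), collapse = ", "),
           class = "trialminer_validation_error")
  for (id in df$entity_id) {
    seen <- character(0)
    cur <- id
    while (!is.na(cur)) {
      abort_if(cur %in% seen, "cycle in parent_id links at ", cur,
               class = "trialminer_validation_error")
      seen <- c(seen, cur)
      cur <- df$parent_id[match(cur, df$entity_id)]
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("entity_schema", "data.frame"))
}

#' Load an entity schema from CSV or JSON
#'
#' The schema file defines the extraction targets: one row per entity with
#' columns `entity_id`, `name`, `kind` (one of `presence_absence`, `value`,
#' `complex_component`), `parent_id`, `value_unit`, `arm_scoped`. The
#' package ships a 70-entity example under `inst/extdata/`; it is a
#' *synthetic* stand-in list composed for testing, not a published
#' extraction schema.
#'
#' @param path path to a `.csv` or `.json` schema file.
#' @return An `entity_schema` data frame (possibly with zero rows).
#' @examples
#' path <- system.file("extdata", "synthetic_smoking_cessation_schema.csv",
#'                     package = "trialminer")
#' sch <- load_entity_schema(path)
#' nrow(sch)  # 70
#' @export
load_entity_schema <- function(path) {
  abort_if(!file.exists(path), "schema file not found: ", path,
           class = "trialminer_parse_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    df <- tryCatch(jsonlite::fromJSON(path),
                   error = function(e) stop(errorCondition(
                     paste0("cannot parse schema JSON ", path, ": ", conditionMessage(e)),
                     class = c("trialminer_parse_error", "error"))))
    if (length(df) == 0) df <- empty_schema_df()
  } else {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (length(first) == 0) return(entity_schema(empty_schema_df()))
    df <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
      error = function(e) stop(errorCondition(
        paste0("cannot parse schema CSV ", path, ": ", conditionMessage(e)),
        class = c("trialminer_parse_error", "error"))))
  }
  entity_schema(df)
}

empty_schema_df <- function() {
  data.frame(entity_id = character(0), name = character(0), kind = character(0),
             parent_id = character(0), value_unit = character(0),
             arm_scoped = logical(0), stringsAsFactors = FALSE)
}

schema_row <- function(schema, entity_id) {
  i <- match(entity_id, schema$entity_id)
  abort_if(is.na(i), "unknown entity_id: ", entity_id,
           class = "trialminer_validation_error")
  schema[i, , drop = FALSE]
}

#' Parse the numeric value out of an annotated phrase
#'
#' Annotated spans for value-type entities are short phrases that lead with a
#' number and may trail a unit word ("44.5 years" annotates a mean age of
#' 44.5). The first decimal numeral in the string is returned; word numerals
#' ("forty-five") are not supported. Percentages stay on the 0-100 scale.
#'
#' @param raw_text the annotated string.
#' @param spec a one-row slice of an `entity_schema`; must be a `value` or
#'   `complex_component` entity.
#' @return The parsed number.
#' @export
normalize_value <- function(raw_text, spec) {
  abort_if(!spec$kind %in% c("value", "complex_component"),
           "normalize_value is only defined for value-bearing entities, got kind ",
           spec$kind, class = "trialminer_usage_error")
  m <- regmatches(raw_text, regexpr("-?[0-9]+(\\.[0-9]+)?", raw_text))
  abort_if(length(m) == 0 || is.na(raw_text),
           "no numeral found in ", shQuote(raw_text),
           class = "trialminer_normalization_error")
  as.numeric(m)
}
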