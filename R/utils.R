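# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-unit seed from a master seed; stays below 2^31 - 1.
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + as.double(i) * 16807) %% 2147483629 + 1)
}

# Extract text at a 0-based half-open character span.
span_text <- function(text, start, end) substr(text, start + 1L, end)

abort_if <- function(cond, ..., class = "trialminer_error") {
  if (cond) stop(errorCondition(paste0(...), class = c(class, "error")))
  invisible(NULL)
}

WHOLE_STUDY <- "WHOLE_STUDY"
ARM_NAME <- "ARM_NAME"
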