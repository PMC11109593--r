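# Synthetic trial-report generator.
#
# Emits templated reports of randomised smoking-cessation trials with known
# arms, gold annotations (entity spans into the generated text, or table
# provenance), and a known linear outcome model
#   outcome = b0 + sum(beta * presence) + sum(gamma * numeric) + N(0, sigma)
# clipped to [0, 100]. Every hard case real trial reports present is a
# toggle: synonymous arm mentions, table-only entities, and arm mentions
# placed beyond the association window. Toggles default off so the default
# world is the clean one; tests switch them on deliberately.

ARM_LEXICON <- list(
  patch = c("patch", "patch group", "patch condition"),
  control = c("control", "control group", "control condition"),
  counselling = c("counselling", "counselling group", "counselling condition"),
  quitline = c("quitline", "quitline group", "quitline condition"))

BCT_PHRASES <- c(bct_goal_setting = "goal setting",
                 bct_problem_solving = "problem solving",
                 bct_social_support = "social support",
                 bct_self_monitoring = "self monitoring",
                 bct_financial_incentive = "financial incentives")

#' Schema used by the synthetic generator
#'
#' A compact slice of the full extraction schema: five arm-scoped
#' behaviour-change-technique presence entities, two study-level numeric
#' population descriptors, one complex entity (ethnic group) with two
#' percentage components, and the 12-month abstinence outcome.
#'
#' @return An `entity_schema`.
#' @export
generator_schema <- function() {
  entity_schema(data.frame(
    entity_id = c(names(BCT_PHRASES), "pop_mean_age", "pop_cigarettes_per_day",
                  "pop_ethnicity", "pop_pct_white", "pop_pct_asian",
                  "outcome_abstinence_12m"),
    name = c(unname(BCT_PHRASES), "mean age of participants",
             "mean cigarettes smoked per day", "ethnic group",
             "percentage of White participants",
             "percentage of Asian participants",
             "percentage achieving 12-month abstinence"),
    kind = c(rep("presence_absence", 5), "value", "value", "presence_absence",
             "complex_component", "complex_component", "value"),
    parent_id = c(rep(NA, 8), "pop_ethnicity", "pop_ethnicity", NA),
    value_unit = c(rep(NA, 5), "years", "cigarettes", NA, "%", "%", "percent"),
    arm_scoped = c(rep(TRUE, 5), FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE))
}

#' Generator configuration
#'
#' @param seed master seed; per-study seeds derive from it.
#' @param n_docs number of studies.
#' @param arm_count_probs probabilities over 1..4 arms.
#' @param include_prob named per-entity inclusion probabilities; entities
#'   not named are always included.
#' @param synonyms when TRUE, arm mentions outside the arm's defining
#'   sentence are sampled from the arm's synonym set (the defining sentence
#'   always uses the canonical head form, as trial prose does).
#' @param table_prob probability that a study reports its outcomes in a
#'   results table as well as in text.
#' @param table_only when TRUE, a study that emits a table reports outcome
#'   values *only* there (the table-only hard case).
#' @param arm_in_window when FALSE, arm names are listed once early in the
#'   report and entity sentences never name an arm, so every entity sits
#'   beyond any reasonable association window.
#' @param intercept,beta,gamma,sigma the outcome model: `beta` is named by
#'   presence entity, `gamma` by numeric entity, `sigma` is the noise SD in
#'   percentage points. Defaults give a signal R^2 of about 0.8 with
#'   realistic cessation percentages (mean ~30, SD ~7).
#' @export
generator_config <- function(seed = 1L, n_docs = 100L,
                             arm_count_probs = c(0.05, 0.55, 0.30, 0.10),
                             include_prob = c(bct_goal_setting = 0.5,
                                              bct_problem_solving = 0.5,
                                              bct_social_support = 0.5,
                                              bct_self_monitoring = 0.5,
                                              bct_financial_incentive = 0.5,
                                              pop_pct_white = 0.6,
                                              pop_pct_asian = 0.6),
                             synonyms = FALSE, table_prob = 0.3,
                             table_only = FALSE, arm_in_window = TRUE,
                             intercept = 25,
                             beta = c(bct_goal_setting = 8,
                                      bct_problem_solving = -6,
                                      bct_social_support = 5,
                                      bct_self_monitoring = -4,
                                      bct_financial_incentive = 3),
                             gamma = c(pop_mean_age = 0.2,
                                       pop_cigarettes_per_day = -0.3),
                             sigma = 3.25) {
  abort_if(any(include_prob < 0 | include_prob > 1),
           "inclusion probabilities must lie in [0, 1]")
  abort_if(sigma < 0, "sigma must be non-negative")
  abort_if(length(arm_count_probs) != 4 || any(arm_count_probs < 0),
           "arm_count_probs must be 4 non-negative weights over 1..4 arms")
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 arm_count_probs = arm_count_probs / sum(arm_count_probs),
                 include_prob = include_prob, synonyms = synonyms,
                 table_prob = table_prob, table_only = table_only,
                 arm_in_window = arm_in_window, intercept = intercept,
                 beta = beta, gamma = gamma, sigma = sigma,
                 schema = generator_schema()),
            class = "generator_config")
}

# sentence builder: accumulates text and annotations with exact offsets
new_builder <- function(doc_id) {
  env <- new.env(parent = emptyenv())
  env$doc_id <- doc_id; env$text <- ""; env$anns <- list()
  env
}

# parts: character scalars, or list(text=, entity=, value=, arm=) mentions
add_sentence <- function(b, parts) {
  base <- nchar(b$text) + if (nzchar(b$text)) 1L else 0L  # + joining space
  pieces <- character(length(parts))
  offs <- integer(length(parts))
  pos <- 0L
  for (i in seq_along(parts)) {
    piece <- if (is.list(parts[[i]])) parts[[i]]$text else parts[[i]]
    if (i > 1) pos <- pos + 1L  # single space between pieces
    offs[i] <- pos
    pieces[i] <- piece
    pos <- pos + nchar(piece)
  }
  sentence <- paste(pieces, collapse = " ")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (!is.list(p)) next
    st <- base + offs[i]
    b$anns[[length(b$anns) + 1L]] <- annotation(
      b$doc_id, p$entity, span = c(st, st + nchar(p$text)), raw_text = p$text,
      context_text = sentence, value = p$value %||% NA_real_,
      arm_ref = p$arm %||% WHOLE_STUDY)
  }
  b$text <- if (nzchar(b$text)) paste(b$text, sentence) else sentence
  invisible(b)
}

FILLER <- c(paste("The study protocol was approved by the institutional review",
                  "board and all participants provided written informed consent",
                  "before enrolment in accordance with national research",
                  "governance guidelines and the declaration of good practice",
                  "for behavioural trials of this kind ."),
            paste("Follow up assessments were carried out by telephone and",
                  "postal questionnaire with biochemical verification of",
                  "self reported smoking status carried out whenever",
                  "feasible according to the procedures described in the",
                  "published protocol for this randomised evaluation ."))

# short buffers keeping adjacent template blocks apart, so that an entity's
# nearest arm-name mention is the one in its own sentence
BUFFER <- paste("Delivery of all programme components was supervised by",
                "trained cessation advisors throughout the treatment period .")
ASSESS <- paste("Outcomes were assessed at twelve months after the target",
                "quit date using intention to treat analysis .")

render_num <- function(x, digits = 1) formatC(x, format = "f", digits = digits)

num_word_or_digit <- function(n) {
  if (stats::runif(1) < 0.5) as.character(n)
  else names(NUMBER_WORDS)[match(n, NUMBER_WORDS)]
}

#' Generate one gold-annotated study
#'
#' Deterministic given `(config, study_seed)`. The returned
#' `annotated_study` carries a `truth` attribute with the noise-free linear
#' predictor per arm.
#'
#' @param config a [generator_config()].
#' @param study_seed integer seed for this study.
#' @param doc_id document identifier.
#' @return An `annotated_study` (gold).
#' @export
generate_study <- function(config, study_seed, doc_id = paste0("doc_", study_seed)) {
  schema <- config$schema
  inc <- function(e) {
    p <- config$include_prob[e]
    if (is.na(p)) TRUE else stats::runif(1) < p
  }
  with_seed(study_seed, {
    b <- new_builder(doc_id)
    n_arms <- sample.int(4L, 1L, prob = config$arm_count_probs)
    arm_sets <- ARM_LEXICON[sample(names(ARM_LEXICON), n_arms)]
    arm_ids <- paste0("arm_", seq_len(n_arms))
    canon <- vapply(arm_sets, `[`, character(1), 1)
    pick_surface <- function(k) {
      if (config$synonyms) sample(arm_sets[[k]], 1L) else canon[k]
    }
    add_sentence(b, list("This randomised controlled trial recruited adult",
                         "smokers attending community health services ."))
    nw <- num_word_or_digit(n_arms)
    noun <- if (n_arms == 1) sample(c("group", "arm"), 1) else
      sample(c("groups", "arms"), 1)
    add_sentence(b, list(sample(c("Participants were randomised into",
                                  "Participants were divided in"), 1),
                         nw, noun, "."))
    if (!config$arm_in_window) {
      naming <- list("The study compared")
      for (k in seq_len(n_arms)) {
        if (k > 1) naming <- c(naming, if (k == n_arms) "and" else ",")
        naming <- c(naming, list(list(text = canon[k], entity = ARM_NAME,
                                      arm = arm_ids[k])))
      }
      add_sentence(b, c(naming, "."))
      add_sentence(b, list(FILLER[1]))
    }
    # study-level numerics
    numerics <- c(pop_mean_age = NA_real_, pop_cigarettes_per_day = NA_real_)
    if (inc("pop_mean_age")) {
      age <- as.numeric(render_num(stats::runif(1, 35, 55)))
      numerics["pop_mean_age"] <- age
      add_sentence(b, list("The mean age of participants was",
                           list(text = paste(render_num(age), "years"),
                                entity = "pop_mean_age", value = age), "."))
    }
    if (inc("pop_cigarettes_per_day")) {
      cig <- as.numeric(render_num(stats::runif(1, 10, 30)))
      numerics["pop_cigarettes_per_day"] <- cig
      add_sentence(b, list("Participants smoked an average of",
                           list(text = paste(render_num(cig), "cigarettes"),
                                entity = "pop_cigarettes_per_day", value = cig),
                           "per day ."))
    }
    if (inc("pop_pct_white") && inc("pop_pct_asian")) {
      w <- as.numeric(render_num(stats::runif(1, 40, 90)))
      a <- as.numeric(render_num(stats::runif(1, 1, 20)))
      add_sentence(b, list("Overall ,",
                           list(text = paste(render_num(w), "% White"),
                                entity = "pop_pct_white", value = w), "and",
                           list(text = paste(render_num(a), "% Asian"),
                                entity = "pop_pct_asian", value = a),
                           "participants were enrolled ."))
    }
    # per-arm intervention content; the long filler keeps the study-level
    # block outside the association window of the first arm mention, and
    # buffers between arm blocks keep each entity nearest its own arm
    add_sentence(b, list(FILLER[1]))
    presence <- matrix(FALSE, n_arms, length(BCT_PHRASES),
                       dimnames = list(arm_ids, names(BCT_PHRASES)))
    for (k in seq_len(n_arms)) {
      for (e in names(BCT_PHRASES)) presence[k, e] <- inc(e)
      on <- names(BCT_PHRASES)[presence[k, ]]
      parts <- if (config$arm_in_window)
        list("The", list(text = canon[k], entity = ARM_NAME, arm = arm_ids[k]),
             "arm received")
      else list("One intervention consisted of")
      if (length(on) == 0) parts <- c(parts, "brief advice only")
      else for (j in seq_along(on)) {
        if (j > 1) parts <- c(parts, if (j == length(on)) "and" else ",")
        parts <- c(parts, list(list(text = unname(BCT_PHRASES[on[j]]),
                                    entity = on[j], arm = arm_ids[k])))
      }
      add_sentence(b, c(parts, "."))
      if (k < n_arms) add_sentence(b, list(BUFFER))
    }
    add_sentence(b, list(ASSESS))
    if (!config$arm_in_window) add_sentence(b, list(FILLER[2]))
    # outcomes from the linear model
    lp <- vapply(seq_len(n_arms), function(k) {
      config$intercept +
        sum(config$beta[names(BCT_PHRASES)] * presence[k, ], na.rm = TRUE) +
        sum(config$gamma * ifelse(is.na(numerics[names(config$gamma)]), 0,
                                  numerics[names(config$gamma)]))
    }, numeric(1))
    y <- pmin(100, pmax(0, lp + stats::rnorm(n_arms, 0, config$sigma)))
    y <- as.numeric(render_num(y))
    emit_table <- stats::runif(1) < config$table_prob
    outcome_in_body <- !(emit_table && config$table_only)
    if (outcome_in_body) {
      for (k in seq_len(n_arms)) {
        val_part <- list(text = paste(render_num(y[k]), "percent"),
                         entity = "outcome_abstinence_12m", value = y[k],
                         arm = arm_ids[k])
        parts <- if (config$arm_in_window)
          list("In the",
               list(text = pick_surface(k), entity = ARM_NAME, arm = arm_ids[k]),
               ",", val_part,
               "of participants achieved abstinence at 12 months .")
        else
          list("Overall ,", val_part,
               "of participants achieved abstinence at 12 months .")
        add_sentence(b, parts)
      }
    } else {
      add_sentence(b, list("Abstinence outcomes for each arm are shown in the",
                           "results table ."))
    }
    tables <- list()
    table_anns <- list()
    if (emit_table) {
      cells <- rbind(c("Arm", "Abstinence"),
                     cbind(canon, render_num(y)))
      tab <- table_grid("t1", cells, header_row_count = 1L, header_col_count = 1L,
                        caption = "Twelve month abstinence by arm")
      tables <- list(tab)
      ps <- linearize_table(tab)
      for (k in seq_len(n_arms)) {
        table_anns[[length(table_anns) + 1L]] <- annotation(
          doc_id, ARM_NAME, span = NULL, raw_text = canon[k],
          context_text = ps$text[k], arm_ref = arm_ids[k])
        table_anns[[length(table_anns) + 1L]] <- annotation(
          doc_id, "outcome_abstinence_12m", span = NULL,
          raw_text = render_num(y[k]), context_text = ps$text[k],
          value = y[k], arm_ref = arm_ids[k])
      }
    }
    add_sentence(b, list(FILLER[sample.int(2, 1)]))
    doc <- build_document(doc_id, b$text, tables)
    anns <- c(b$anns, table_anns)
    # arms with realized member surfaces
    arm_objs <- lapply(seq_len(n_arms), function(k) {
      men <- Filter(function(a) a$entity_id == ARM_NAME && a$arm_ref == arm_ids[k],
                    anns)
      surfaces <- vapply(men, function(a) a$raw_text, character(1))
      firsts <- vapply(men, function(a)
        if (is.null(a$span)) 0L else a$span[1], integer(1))
      d <- data.frame(surface = surfaces, start = firsts, stringsAsFactors = FALSE)
      dm <- distinct_mentions(d)
      arm(arm_ids[k], canon[k], dm)
    })
    outcomes <- data.frame(arm_id = arm_ids,
                           entity_id = "outcome_abstinence_12m",
                           value = y, stringsAsFactors = FALSE)
    st <- annotated_study(doc, arms = arm_objs, annotations = anns,
                          outcomes = outcomes)
    attr(st, "truth") <- list(lp = data.frame(arm_id = arm_ids, lp = lp,
                                              outcome = y),
                              presence = presence, numerics = numerics)
    st
  })
}

#' Generate a gold-annotated synthetic corpus
#'
#' @param config a [generator_config()].
#' @return List of gold `annotated_study` objects; the
#'   `entity_frequencies` attribute tabulates realized per-entity document
#'   frequencies (for sparsity control in stress tests).
#' @export
generate_corpus <- function(config = generator_config()) {
  abort_if(config$n_docs < 1, "n_docs must be at least 1")
  width <- max(4L, nchar(as.character(config$n_docs)))
  studies <- lapply(seq_len(config$n_docs), function(i)
    generate_study(config, derive_seed(config$seed, i),
                   doc_id = sprintf(paste0("doc_%0", width, "d"), i)))
  freq <- table(unlist(lapply(studies, function(st)
    unique(vapply(st$annotations, function(a) a$entity_id, character(1))))))
  attr(studies, "entity_frequencies") <- freq
  studies
}

#' Corrupt gold annotations
#'
#' Deterministically degrades a gold annotation set -- dropping instances,
#' relabelling them to a random same-kind entity, and jittering values --
#' to emulate a pre-consensus human coder and to verify that F1 and alpha
#' degrade monotonically.
#'
#' @param studies gold `annotated_study` list.
#' @param drop_rate,relabel_rate probabilities per entity annotation.
#' @param value_jitter_sd SD of Gaussian noise added to values.
#' @param seed integer seed.
#' @param schema schema used to find same-kind relabel targets.
#' @return The degraded study list.
#' @export
corrupt_annotations <- function(studies, drop_rate = 0, relabel_rate = 0,
                                value_jitter_sd = 0, seed = 1L,
                                schema = generator_schema()) {
  abort_if(drop_rate < 0 || drop_rate > 1 || relabel_rate < 0 || relabel_rate > 1,
           "rates must lie in [0, 1]")
  with_seed(seed, lapply(studies, function(st) {
    keep <- list()
    for (a in st$annotations) {
      if (a$entity_id == ARM_NAME) { keep[[length(keep) + 1L]] <- a; next }
      if (stats::runif(1) < drop_rate) next
      if (stats::runif(1) < relabel_rate) {
        kind <- schema$kind[match(a$entity_id, schema$entity_id)]
        pool <- setdiff(schema$entity_id[schema$kind == kind], a$entity_id)
        if (length(pool) > 0) a$entity_id <- sample(pool, 1L)
      }
      if (value_jitter_sd > 0 && !is.na(a$value))
        a$value <- a$value + stats::rnorm(1, 0, value_jitter_sd)
      keep[[length(keep) + 1L]] <- a
    }
    st$annotations <- keep
    st
  }))
}
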