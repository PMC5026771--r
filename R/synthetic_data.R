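# Synthetic corpus generator: desk-scale documents with the structures the
# extractor assumes - protein mentions (some multi-word), single- and
# multi-word triggers of the nine event types, template-derived dependency
# trees and lexical analyses, nested and merged events, and controllable
# trigger-span inconsistency (the same semantic pattern annotated under a
# head-word or a modifier-word span convention).

#' Synthetic corpus configuration
#'
#' @param n_documents,sentences_per_document corpus shape.
#' @param template_weights sampling weights of the five sentence families:
#'   `plain` (one plain protein-taking event), `reg_nested` (a regulation
#'   event over a nested expression event, optionally with a protein
#'   CAUSE), `reg_mw` (a regulation event with a multi-word trigger such
#'   as "increased levels", the inconsistency-eligible family), `binding`
#'   (one Binding event with two protein THEMEs) and `merged_loop` (a Gene
#'   Expression / Positive Regulation pair sharing one trigger).
#' @param cause_prob probability that a `reg_nested` event carries a
#'   protein CAUSE.
#' @param span_inconsistency_rate fraction of eligible multi-word triggers
#'   re-annotated under the modifier-word convention (applied via
#'   [inject_span_inconsistency()]).
#' @param protein_pool protein name pool (names may be multi-word).
#' @param vocab trigger vocabularies; see defaults in the source.
#' @param seed integer seed; identical seeds give identical corpora.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_documents = 30L, sentences_per_document = 10L,
                             template_weights = c(plain = 0.25,
                                                  reg_nested = 0.2,
                                                  reg_mw = 0.3,
                                                  binding = 0.15,
                                                  merged_loop = 0.1),
                             cause_prob = 0.4,
                             span_inconsistency_rate = 0,
                             protein_pool = c("IL-2", "VDR", "STAT1", "NFAT",
                                              "TNF", "CD40", "JAK2", "c-jun",
                                              "E-selectin", "NF kappaB",
                                              "IkB alpha"),
                             vocab = NULL, seed = 1L) {
  stopifnot(all(template_weights >= 0), sum(template_weights) > 0,
            span_inconsistency_rate >= 0, span_inconsistency_rate <= 1,
            length(protein_pool) >= 2L)
  if (is.null(vocab)) vocab <- .default_vocab()
  structure(list(n_documents = as.integer(n_documents),
                 sentences_per_document = as.integer(sentences_per_document),
                 template_weights = template_weights,
                 cause_prob = cause_prob,
                 span_inconsistency_rate = span_inconsistency_rate,
                 protein_pool = protein_pool, vocab = vocab,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# surface / baseform / POS triples per trigger family; "expressed" appears
# for both Gene_expression and Transcription so the corpus exercises
# multi-label anchor words
.default_vocab <- function() {
  v3 <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(surface = m[, 1], baseform = m[, 2], pos = m[, 3],
               stringsAsFactors = FALSE)
  }
  list(
    plain = list(
      Gene_expression = v3("expressed", "express", "VBN",
                           "produced", "produce", "VBN",
                           "synthesized", "synthesize", "VBN"),
      Transcription = v3("transcribed", "transcribe", "VBN",
                         "expressed", "express", "VBN"),
      Phosphorylation = v3("phosphorylated", "phosphorylate", "VBN"),
      Protein_catabolism = v3("degraded", "degrade", "VBN"),
      Localization = v3("secreted", "secrete", "VBN",
                        "localized", "localize", "VBN")
    ),
    reg_verb = list(
      Positive_regulation = v3("induces", "induce", "VBZ",
                               "enhances", "enhance", "VBZ",
                               "stimulates", "stimulate", "VBZ"),
      Negative_regulation = v3("inhibits", "inhibit", "VBZ",
                               "suppresses", "suppress", "VBZ",
                               "blocks", "block", "VBZ"),
      Regulation = v3("regulates", "regulate", "VBZ",
                      "controls", "control", "VBZ",
                      "modulates", "modulate", "VBZ")
    ),
    inner_noun = list(
      Gene_expression = v3("expression", "expression", "NN"),
      Transcription = v3("transcription", "transcription", "NN")
    ),
    mw_adj = list(
      Positive_regulation = v3("increased", "increase", "VBN",
                               "elevated", "elevate", "VBN"),
      Negative_regulation = v3("decreased", "decrease", "VBN",
                               "reduced", "reduce", "VBN")
    ),
    mw_noun = v3("levels", "level", "NNS", "numbers", "number", "NNS"),
    binding = v3("binds", "bind", "VBZ", "associates", "associate", "VBZ"),
    merged = v3("overexpressed", "overexpress", "VBN",
                "coexpressed", "coexpress", "VBN")
  )
}

.pick_row <- function(df) df[sample.int(nrow(df), 1L), , drop = FALSE]

# a sentence spec: token table, 0-based deps, protein token ranges, and
# abstract events over local references P<k> / local event list indices
.tok <- function(surface, baseform, pos)
  data.frame(surface = surface, baseform = baseform, pos = pos,
             stringsAsFactors = FALSE)

.protein_tokens <- function(name) {
  words <- strsplit(name, " ", fixed = TRUE)[[1]]
  .tok(words, tolower(words), "NN")
}

# internal nn() chain for a multi-word protein; head is its last token
.protein_deps <- function(first, last) {
  if (last == first) return(NULL)
  data.frame(gov = last, dep = first:(last - 1L), rel = "nn",
             stringsAsFactors = FALSE)
}

.gen_sentence <- function(template, cfg) {
  v <- cfg$vocab
  prots <- sample(cfg$protein_pool, 2L)
  p1 <- .protein_tokens(prots[1]); p2 <- .protein_tokens(prots[2])

  if (template == "plain") {
    ty <- sample(names(v$plain), 1L)
    tr <- .pick_row(v$plain[[ty]])
    n1 <- nrow(p1)
    tokens <- rbind(p1,
                    .tok(c("was", tr$surface, "in", "T", "cells", "."),
                         c("be", tr$baseform, "in", "t", "cell", "."),
                         c("VBD", tr$pos, "IN", "NN", "NNS", ".")))
    trig <- n1 + 1L  # 0-based index of the trigger token
    deps <- rbind(.protein_deps(0L, n1 - 1L),
                  data.frame(gov = trig,
                             dep = c(n1 - 1L, n1, trig + 1L, trig + 4L),
                             rel = c("nsubjpass", "auxpass", "prep", "punct"),
                             stringsAsFactors = FALSE),
                  data.frame(gov = trig + 1L, dep = trig + 3L, rel = "pobj"),
                  data.frame(gov = trig + 3L, dep = trig + 2L, rel = "nn"))
    events <- list(list(type = ty, trig = c(trig, trig),
                        args = list(list(role = "THEME", target = "P1"))))
  } else if (template == "merged_loop") {
    tr <- .pick_row(v$merged)
    n1 <- nrow(p1)
    tokens <- rbind(p1,
                    .tok(c("was", tr$surface, "in", "T", "cells", "."),
                         c("be", tr$baseform, "in", "t", "cell", "."),
                         c("VBD", tr$pos, "IN", "NN", "NNS", ".")))
    trig <- n1 + 1L
    deps <- rbind(.protein_deps(0L, n1 - 1L),
                  data.frame(gov = trig,
                             dep = c(n1 - 1L, n1, trig + 1L, trig + 4L),
                             rel = c("nsubjpass", "auxpass", "prep", "punct"),
                             stringsAsFactors = FALSE),
                  data.frame(gov = trig + 1L, dep = trig + 3L, rel = "pobj"),
                  data.frame(gov = trig + 3L, dep = trig + 2L, rel = "nn"))
    events <- list(
      list(type = "Gene_expression", trig = c(trig, trig),
           args = list(list(role = "THEME", target = "P1"))),
      list(type = "Positive_regulation", trig = c(trig, trig),
           args = list(list(role = "THEME", target = "E1"))))
  } else if (template == "reg_nested") {
    rty <- sample(names(v$reg_verb), 1L)
    ity <- sample(names(v$inner_noun), 1L)
    rv <- .pick_row(v$reg_verb[[rty]])
    nn <- .pick_row(v$inner_noun[[ity]])
    n1 <- nrow(p1); n2 <- nrow(p2)
    tokens <- rbind(p1,
                    .tok(c(rv$surface, "the", nn$surface, "of"),
                         c(rv$baseform, "the", nn$baseform, "of"),
                         c(rv$pos, "DT", nn$pos, "IN")),
                    p2,
                    .tok(".", ".", "."))
    verb <- n1; noun <- n1 + 2L; of <- n1 + 3L
    p2_last <- n1 + 3L + n2
    deps <- rbind(.protein_deps(0L, n1 - 1L),
                  data.frame(gov = verb,
                             dep = c(n1 - 1L, noun, p2_last + 1L),
                             rel = c("nsubj", "dobj", "punct"),
                             stringsAsFactors = FALSE),
                  data.frame(gov = noun, dep = c(noun - 1L, of),
                             rel = c("det", "prep")),
                  data.frame(gov = of, dep = p2_last, rel = "pobj"),
                  .protein_deps(n1 + 4L, p2_last))
    args <- list(list(role = "THEME", target = "E1"))
    if (stats::runif(1) < cfg$cause_prob)
      args <- c(args, list(list(role = "CAUSE", target = "P1")))
    events <- list(
      list(type = ity, trig = c(noun, noun),
           args = list(list(role = "THEME", target = "P2"))),
      list(type = rty, trig = c(verb, verb), args = args))
  } else if (template == "reg_mw") {
    rty <- sample(names(v$mw_adj), 1L)
    adj <- .pick_row(v$mw_adj[[rty]])
    noun <- .pick_row(v$mw_noun)
    n1 <- nrow(p1); n2 <- nrow(p2)
    tokens <- rbind(p1,
                    .tok(c("showed", adj$surface, noun$surface, "of"),
                         c("show", adj$baseform, noun$baseform, "of"),
                         c("VBD", adj$pos, noun$pos, "IN")),
                    p2,
                    .tok(".", ".", "."))
    verb <- n1; a <- n1 + 1L; nidx <- n1 + 2L; of <- n1 + 3L
    p2_last <- n1 + 3L + n2
    deps <- rbind(.protein_deps(0L, n1 - 1L),
                  data.frame(gov = verb,
                             dep = c(n1 - 1L, nidx, p2_last + 1L),
                             rel = c("nsubj", "dobj", "punct"),
                             stringsAsFactors = FALSE),
                  data.frame(gov = nidx, dep = c(a, of),
                             rel = c("amod", "prep")),
                  data.frame(gov = of, dep = p2_last, rel = "pobj"),
                  .protein_deps(n1 + 4L, p2_last))
    events <- list(
      list(type = rty, trig = c(a, nidx), mw_eligible = TRUE,
           args = list(list(role = "THEME", target = "P2"))))
  } else if (template == "binding") {
    tr <- .pick_row(v$binding)
    n1 <- nrow(p1); n2 <- nrow(p2)
    tokens <- rbind(p1,
                    .tok(tr$surface, tr$baseform, tr$pos),
                    p2,
                    .tok(".", ".", "."))
    verb <- n1; p2_last <- n1 + n2
    deps <- rbind(.protein_deps(0L, n1 - 1L),
                  data.frame(gov = verb,
                             dep = c(n1 - 1L, p2_last, p2_last + 1L),
                             rel = c("nsubj", "dobj", "punct"),
                             stringsAsFactors = FALSE),
                  .protein_deps(n1 + 1L, p2_last))
    events <- list(
      list(type = "Binding", trig = c(verb, verb),
           args = list(list(role = "THEME", target = "P1"),
                       list(role = "THEME", target = "P2"))))
  } else stop(sprintf("unknown template '%s'", template))

  rownames(tokens) <- NULL
  prot_ranges <- list()
  # locate protein token runs: P1 always starts at 0; P2 (if present)
  # starts after the connective tokens
  prot_ranges$P1 <- c(0L, nrow(p1) - 1L)
  if (template %in% c("reg_nested", "reg_mw")) {
    prot_ranges$P2 <- c(nrow(p1) + 4L, nrow(p1) + 3L + nrow(p2))
  } else if (template == "binding") {
    prot_ranges$P2 <- c(nrow(p1) + 1L, nrow(p1) + nrow(p2))
  }
  list(tokens = tokens, deps = deps, proteins = prot_ranges,
       events = events, template = template)
}

#' Generate a synthetic standoff corpus
#'
#' Builds documents from sentence templates with deterministic
#' template-derived dependency trees and lexical analyses, assembles the
#' standoff text/a1/a2 components, and reads them back through the corpus
#' readers (so every generated corpus is format-valid by construction).
#' When `cfg$span_inconsistency_rate > 0` the corresponding fraction of
#' eligible multi-word triggers is re-annotated under the modifier-word
#' convention via [inject_span_inconsistency()].
#'
#' @param cfg a [generator_config()].
#' @return list of `bio_document`.
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(cfg$seed)
  corpus <- lapply(seq_len(cfg$n_documents), function(d)
    .gen_document(cfg, d))
  if (cfg$span_inconsistency_rate > 0)
    corpus <- inject_span_inconsistency(corpus, cfg$span_inconsistency_rate,
                                        seed = cfg$seed + 10007L)
  corpus
}

.gen_document <- function(cfg, d) {
  w <- cfg$template_weights
  sens <- lapply(seq_len(cfg$sentences_per_document), function(s)
    .gen_sentence(sample(names(w), 1L, prob = w), cfg))

  # lay out text and compute token offsets
  offset <- 0L
  a1 <- character(0); tcount <- 0L
  trig_lines <- character(0); e_lines <- character(0); ecount <- 0L
  tok_blocks <- list(); dep_blocks <- list()
  text_parts <- character(0)
  pending_trigs <- list()

  for (s in seq_along(sens)) {
    sen <- sens[[s]]
    widths <- nchar(sen$tokens$surface)
    starts <- offset + c(0L, cumsum(widths[-length(widths)] + 1L))
    ends <- starts + widths
    offset <- ends[length(ends)] + 1L
    text_parts <- c(text_parts, paste(sen$tokens$surface, collapse = " "))

    pid_of <- character(0)
    for (pk in names(sen$proteins)) {
      rg <- sen$proteins[[pk]]
      tcount <- tcount + 1L
      id <- paste0("T", tcount)
      pid_of[pk] <- id
      a1 <- c(a1, sprintf("%s\tProtein %d %d\t%s", id, starts[rg[1] + 1L],
                          ends[rg[2] + 1L],
                          paste(sen$tokens$surface[(rg[1] + 1L):(rg[2] + 1L)],
                                collapse = " ")))
    }
    eid_of <- character(0)
    for (k in seq_along(sen$events)) {
      ev <- sen$events[[k]]
      ecount <- ecount + 1L
      eid_of[paste0("E", k)] <- paste0("E", ecount)
      span <- c(starts[ev$trig[1] + 1L], ends[ev$trig[2] + 1L])
      pending_trigs[[length(pending_trigs) + 1L]] <- list(
        eid = paste0("E", ecount), type = ev$type, start = span[1],
        end = span[2],
        text = paste(sen$tokens$surface[(ev$trig[1] + 1L):(ev$trig[2] + 1L)],
                     collapse = " "),
        args = lapply(ev$args, function(a) {
          tgt <- if (startsWith(a$target, "P")) pid_of[[a$target]]
          else eid_of[[a$target]]
          list(role = a$role, target = tgt)
        }))
    }
    tok_blocks[[s]] <- sen$tokens
    dp <- sen$deps
    sdep <- if (!is.null(dp) && nrow(dp))
      data.frame(gov = dp$gov, dep = dp$dep, rel = dp$rel,
                 stringsAsFactors = FALSE)
    else empty_deps()
    dep_blocks[[s]] <- unique(sdep)
  }

  # a2 trigger T lines (deduplicated over type+span) and E lines
  trig_key <- character(0); trig_id <- character(0)
  for (tg in pending_trigs) {
    key <- paste(tg$type, tg$start, tg$end)
    if (!key %in% trig_key) {
      tcount <- tcount + 1L
      trig_key <- c(trig_key, key); trig_id <- c(trig_id, paste0("T", tcount))
      trig_lines <- c(trig_lines, sprintf("%s\t%s %d %d\t%s",
                                          paste0("T", tcount), tg$type,
                                          tg$start, tg$end, tg$text))
    }
    tid <- trig_id[match(key, trig_key)]
    roles <- vapply(tg$args, `[[`, character(1), "role")
    th <- which(roles == "THEME")
    roles_out <- roles
    if (length(th) > 1L)
      roles_out[th[-1]] <- paste0("THEME", seq_along(th[-1]) + 1L)
    roles_out <- paste0(substr(roles_out, 1, 1),
                        tolower(substring(roles_out, 2)))
    tgts <- vapply(tg$args, `[[`, character(1), "target")
    e_lines <- c(e_lines, sprintf("%s\t%s:%s %s", tg$eid, tg$type, tid,
                                  paste(paste0(roles_out, ":", tgts),
                                        collapse = " ")))
  }

  text <- paste(text_parts, collapse = " ")
  doc <- read_standoff_document(text, a1, c(trig_lines, e_lines),
                                id = sprintf("SYN%03d", d))
  attach_sentences(doc, tok_blocks, dep_blocks)
}

#' Re-annotate a fraction of multi-word triggers under the modifier-word
#' convention
#'
#' Eligible triggers are those annotated with a multi-word span (the
#' head-word convention of the generator's templates). A seeded random
#' fraction `rate` of them has the annotated span switched to the
#' modifier word (the first word of the span), leaving text, tokens and
#' event structure unchanged.
#'
#' @param corpus list of `bio_document`.
#' @param rate fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return the corpus with flipped trigger spans.
#' @export
inject_span_inconsistency <- function(corpus, rate, seed = 1L) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate > 1)
    stop("rate must be a single number in [0, 1]")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  lapply(corpus, function(doc) {
    for (id in names(doc$events)) {
      e <- doc$events[[id]]
      if (!grepl(" ", e$trigger_text, fixed = TRUE)) next
      if (stats::runif(1) >= rate) next
      first <- strsplit(e$trigger_text, " ", fixed = TRUE)[[1]][1]
      e$trigger_end <- e$trigger_start + nchar(first)
      e$trigger_text <- first
      doc$events[[id]] <- e
    }
    doc
  })
}
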