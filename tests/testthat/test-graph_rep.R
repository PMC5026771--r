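# helper: document whose two Regulation events take each other as THEME
# (an artificial role cycle)
.cycle_doc <- function() {
  text <- "regulates controls IL2"
  doc <- read_standoff_document(
    text, "T1\tProtein 19 22\tIL2",
    c("T2\tRegulation 0 9\tregulates",
      "T3\tRegulation 10 18\tcontrols",
      "E1\tRegulation:T2 Theme:E2",
      "E2\tRegulation:T3 Theme:E1"))
  toks <- data.frame(surface = c("regulates", "controls", "IL2"),
                     baseform = c("regulate", "control", "il2"),
                     pos = c("VBZ", "VBZ", "NN"), stringsAsFactors = FALSE)
  attach_sentences(doc, list(toks), list(NULL))
}

test_that("head_word picks the in-span token governed from outside", {
  tokens <- sentence1_tokens(); deps <- sentence1_deps()
  # span "increased numbers": 'numbers' is governed by 'express' outside
  inc_start <- tokens$char_start[5]; num_end <- tokens$char_end[6]
  expect_equal(head_word(inc_start, num_end, tokens, deps), 5L)
  # single-token span
  expect_equal(head_word(tokens$char_start[3], tokens$char_end[3],
                         tokens, deps), 2L)
  # two governor-external tokens: rightmost wins
  nodeps <- read_dependency_parse(character(0), 8L)
  expect_equal(head_word(inc_start, num_end, tokens, nodeps), 5L)
  expect_error(head_word(0, 0, tokens, deps), "covers no token")
})

test_that("events_to_graph labels anchors and draws role edges", {
  doc <- fixture_doc()
  g <- events_to_graph(doc, 1)
  expect_s3_class(g, "event_graph")
  expect_setequal(names(g$node_labels), c("1", "3"))
  expect_equal(g$node_labels[["3"]], "Gene_expression")
  expect_equal(g$node_labels[["1"]], "Positive_regulation")
  e <- g$edges[order(g$edges$src), ]
  expect_equal(e$src, c(1L, 1L, 3L))
  expect_equal(e$tgt, c(3L, 0L, 5L))
  expect_equal(e$role, c("THEME", "CAUSE", "THEME"))
})

test_that("GE/PR trigger-sharing loops become single merged-label nodes", {
  corpus <- small_corpus(seed = 13, n_documents = 2, spd = 4,
                         weights = c(merged_loop = 1))
  doc <- corpus[[1]]
  g <- events_to_graph(doc, 1, use_merged = TRUE)
  labs <- unlist(g$node_labels)
  expect_equal(unname(labs), "Gene_expression/Positive_regulation")
  expect_true(all(g$edges$role == "THEME"))
  # merged label expands back to the GE event and the PosReg over it
  evs <- graph_to_events(g, doc$sentences[[1]]$tokens)
  types <- sort(unname(vapply(evs, `[[`, character(1), "type")))
  expect_equal(types, c("Gene_expression", "Positive_regulation"))
  pr <- Filter(function(e) e$type == "Positive_regulation", evs)[[1]]
  ge <- Filter(function(e) e$type == "Gene_expression", evs)[[1]]
  expect_equal(pr$args$target[pr$args$role == "THEME"], ge$id)

  # without merging the loop edge is removed: the regulation no longer
  # nests over the expression event but degrades to a protein THEME (the
  # incorrect-event side of the reconstruction trade-off)
  g2 <- events_to_graph(doc, 1, use_merged = FALSE)
  evs2 <- graph_to_events(g2, doc$sentences[[1]]$tokens)
  pr2 <- Filter(function(e) e$type == "Positive_regulation", evs2)
  if (length(pr2))
    expect_false(grepl("^E", pr2[[1]]$args$target[pr2[[1]]$args$role ==
                                                    "THEME"]))
  m <- match_events(doc$events, evs2, mode = "exact")
  expect_lt(m$matched, m$gold)
})

test_that("role cycles discard the sentence", {
  doc <- .cycle_doc()
  expect_warning(g <- events_to_graph(doc, 1), NA)
  expect_true(is_discarded(g))
  recon <- reconstruct_annotations(list(doc))
  expect_length(recon[[1]]$events, 0L)
})

test_that("event-taking nodes emit one event per THEME target event", {
  # 'expression' anchors two GE events (two protein THEMEs); a regulation
  # over that node yields two regulation events (enumeration oracle: the
  # cross product of 2 theme targets with no CAUSE options)
  text <- "STAT1 induces the expression of VDR and IL2 ."
  doc <- read_standoff_document(
    text,
    c("T1\tProtein 0 5\tSTAT1", "T2\tProtein 32 35\tVDR",
      "T3\tProtein 40 43\tIL2"),
    c("T4\tGene_expression 18 28\texpression",
      "T5\tPositive_regulation 6 13\tinduces",
      "E1\tGene_expression:T4 Theme:T2",
      "E2\tGene_expression:T4 Theme:T3",
      "E3\tPositive_regulation:T5 Theme:E1"))
  toks <- data.frame(
    surface = c("STAT1", "induces", "the", "expression", "of", "VDR",
                "and", "IL2", "."),
    baseform = c("stat1", "induce", "the", "expression", "of", "vdr",
                 "and", "il2", "."),
    pos = c("NN", "VBZ", "DT", "NN", "IN", "NN", "CC", "NN", "."),
    stringsAsFactors = FALSE)
  deps <- read_dependency_parse(
    c("nsubj(induces-2, STAT1-1)", "dobj(induces-2, expression-4)",
      "prep(expression-4, of-5)", "pobj(of-5, VDR-6)",
      "conj(VDR-6, IL2-8)"), 9L)
  doc <- attach_sentences(doc, list(toks), list(deps))
  g <- events_to_graph(doc, 1)
  evs <- graph_to_events(g, doc$sentences[[1]]$tokens)
  n_pr <- sum(vapply(evs, `[[`, character(1), "type") ==
                "Positive_regulation")
  expect_equal(n_pr, 2L)
  # a labeled node with no THEME edge is a contract violation
  bad <- g; bad$edges <- bad$edges[bad$edges$src != 1L, , drop = FALSE]
  expect_error(graph_to_events(bad, doc$sentences[[1]]$tokens), "no THEME")
})

test_that("graphs dump as JSON lines, discarded sentences included", {
  doc <- fixture_doc()
  g <- events_to_graph(doc, 1)
  lines <- write_graphs_jsonl(list(g, DISCARDED))
  expect_length(lines, 2L)
  j <- jsonlite::fromJSON(lines[1])
  expect_setequal(names(j$node_labels), c("1", "3"))
  expect_equal(nrow(j$edges), 3L)
  expect_true(jsonlite::fromJSON(lines[2])$discarded)
})

test_that("round-trip is the identity on acyclic loop-free corpora", {
  for (seed in c(2, 21, 77)) {
    corpus <- small_corpus(seed = seed, n_documents = 3, spd = 6,
                           weights = c(plain = 0.3, reg_nested = 0.3,
                                       reg_mw = 0.2, binding = 0.2))
    rf <- reconstruction_f1(corpus)
    expect_equal(unname(rf$overall["f1"]), 1.0)
  }
})

test_that("merged events recover loop events in reconstruction", {
  corpus <- small_corpus(seed = 9, n_documents = 4, spd = 6,
                         weights = c(plain = 0.4, merged_loop = 0.6))
  with_m <- reconstruction_f1(corpus, use_merged = TRUE)
  without <- reconstruction_f1(corpus, use_merged = FALSE)
  expect_equal(unname(with_m$overall["f1"]), 1.0)
  expect_lt(unname(without$overall["f1"]), 1.0)
  expect_gte(with_m$overall["f1"], without$overall["f1"])
})
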