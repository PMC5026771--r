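# doc with one protein and `n` copies of `word`, the first `k` of which
# are annotated as triggers of `type` events
.repeat_word_doc <- function(word, n, k, type) {
  surf <- c("IL2", rep(word, n))
  text <- paste(surf, collapse = " ")
  starts <- c(0L, cumsum(nchar(surf) + 1L))[seq_along(surf)]
  a1 <- "T1\tProtein 0 3\tIL2"
  a2 <- character(0)
  for (j in seq_len(k)) {
    s <- starts[j + 1L]
    a2 <- c(a2, sprintf("T%d\t%s %d %d\t%s", j + 1L, type, s,
                        s + nchar(word), word),
            sprintf("E%d\t%s:T%d Theme:T1", j, type, j + 1L))
  }
  doc <- read_standoff_document(text, a1, a2, id = "rep1")
  toks <- data.frame(surface = surf, baseform = tolower(surf),
                     pos = c("NN", rep("VBZ", n)), stringsAsFactors = FALSE)
  attach_sentences(doc, list(toks), list(NULL))
}

test_that("reliability scores are trigger counts over total occurrences", {
  # single occurrence, single trigger: R = 1
  doc <- .repeat_word_doc("expressed", 1, 1, "Gene_expression")
  lex <- build_trigger_lexicons(list(doc))
  expect_equal(unname(lex$counts$Gene_expression["expressed"]), 1)
  expect_equal(unname(lex$total["expressed"]), 1)
  expect_equal(unname(lexicon_reliability(lex, "Gene_expression")["expressed"]),
               1.0)

  # brute-force scan oracle: 10 occurrences, 3 in Negative_regulation
  # triggers -> R = 0.3
  doc <- .repeat_word_doc("suppresses", 10, 3, "Negative_regulation")
  lex <- build_trigger_lexicons(list(doc))
  n_trig <- 3; n_all <- 10  # counted by construction of the fixture
  expect_equal(unname(lex$counts$Negative_regulation["suppresses"]), n_trig)
  expect_equal(unname(lex$total["suppresses"]), n_all)
  expect_equal(
    unname(lexicon_reliability(lex, "Negative_regulation")["suppresses"]),
    n_trig / n_all)
})

test_that("hyphenated trigger words contribute components and the original", {
  text <- "IFNgamma-induced activation of IL2"
  doc <- read_standoff_document(
    text, "T1\tProtein 31 34\tIL2",
    c("T2\tPositive_regulation 0 16\tIFNgamma-induced",
      "E1\tPositive_regulation:T2 Theme:T1"))
  toks <- data.frame(surface = c("IFNgamma-induced", "activation", "of", "IL2"),
                     baseform = c("ifngamma-induced", "activation", "of", "il2"),
                     pos = c("VBN", "NN", "IN", "NN"), stringsAsFactors = FALSE)
  doc <- attach_sentences(doc, list(toks), list(NULL))
  lex <- build_trigger_lexicons(list(doc))
  expect_setequal(names(lex$counts$Positive_regulation),
                  c("ifngamma-induced", "ifngamma", "induced"))
  # empty corpus gives an empty lexicon
  empty <- build_trigger_lexicons(list())
  expect_length(empty$total, 0L)
})

test_that("pruning removes entries strictly below the threshold per type", {
  doc1 <- .repeat_word_doc("modulates", 1000, 9, "Regulation")
  lex <- build_trigger_lexicons(list(doc1))
  r <- lexicon_reliability(lex, "Regulation")
  expect_equal(unname(r["modulates"]), 0.009)
  expect_false("modulates" %in% names(prune(lex)$counts$Regulation))
  # R exactly at the threshold is retained (strict "below")
  doc2 <- .repeat_word_doc("modulates", 1000, 10, "Regulation")
  lex2 <- build_trigger_lexicons(list(doc2))
  expect_true("modulates" %in% names(prune(lex2)$counts$Regulation))
  # word totals are untouched by pruning
  expect_equal(prune(lex)$total, lex$total)
  # threshold 0 is the identity
  expect_equal(prune(lex, 0), lex)
  expect_error(prune(lex, 1.5), "\\[0, 1\\]")
})

test_that("pruning is idempotent and monotone in the threshold", {
  corpus <- small_corpus(seed = 5, n_documents = 4, spd = 6)
  lex <- build_trigger_lexicons(corpus)
  p1 <- prune(lex, 0.01)
  expect_equal(prune(p1, 0.01), p1)
  for (th in c(0.05, 0.2, 0.6)) {
    lo <- prune(lex, th / 2); hi <- prune(lex, th)
    for (ty in names(hi$counts))
      expect_true(all(names(hi$counts[[ty]]) %in% names(lo$counts[[ty]])))
  }
})

test_that("trigger-word counting equals a brute-force constituent scan", {
  corpus <- small_corpus(seed = 11, n_documents = 4, spd = 6)
  lex <- build_trigger_lexicons(corpus)
  # oracle: total constituent-word occurrences over deduplicated triggers,
  # before hyphen expansion, must equal the non-component mass of counts
  n_words <- 0L
  for (doc in corpus) {
    seen <- character(0)
    for (e in doc$events) {
      key <- paste(e$type, e$trigger_start, e$trigger_end)
      if (key %in% seen) next
      seen <- c(seen, key)
      n_words <- n_words + length(strsplit(e$trigger_text, " ")[[1]])
    }
  }
  # every constituent word of the synthetic vocabulary is hyphen-free, so
  # the counts (excluding protein-derived hyphen components) sum exactly
  total_cwe <- sum(unlist(lapply(lex$counts, sum)))
  expect_equal(total_cwe, n_words)
})

test_that("candidate lookup max-pools over surface, baseform, stem and components", {
  doc <- .repeat_word_doc("induced", 4, 3, "Positive_regulation")
  lex <- prune(build_trigger_lexicons(list(doc)))
  slex <- prune(build_trigger_lexicons(list(doc), stemmed = TRUE))

  expect_length(candidate_event_types("mitochondria", "mitochondrion",
                                      lex, slex), 0L)

  # inflectional variant not in the plain lexicon matches via the stem
  # (porter("inducing") == porter("induced") == "induc")
  expect_length(candidate_event_types("inducing", "inducing", lex, NULL), 0L)
  hit <- candidate_event_types("inducing", "inducing", lex, slex)
  expect_true("Positive_regulation" %in% names(hit))

  # hyphenated token whose component matches the plain lexicon
  hit <- candidate_event_types("IL2-induced", "il2-induced", lex, NULL)
  expect_true("Positive_regulation" %in% names(hit))

  # max over derivations: the stemmed entry covers 3 of 4 occurrences of
  # "induced" plus every other form conflating to "induc"
  s1 <- candidate_event_types("induced", "induce", lex, NULL)
  s2 <- candidate_event_types("induced", "induce", lex, slex)
  expect_gte(s2[["Positive_regulation"]], s1[["Positive_regulation"]])
})

test_that("lexicon TSV serialization round-trips", {
  corpus <- small_corpus(seed = 8, n_documents = 3, spd = 5)
  lex <- prune(build_trigger_lexicons(corpus))
  back <- read_lexicon_tsv(write_lexicon_tsv(lex))
  for (ty in names(lex$counts)) {
    expect_equal(sort(names(back$counts[[ty]])), sort(names(lex$counts[[ty]])))
    expect_equal(lexicon_reliability(back, ty)[names(lex$counts[[ty]])],
                 lexicon_reliability(lex, ty)[names(lex$counts[[ty]])])
  }
})
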