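test_that("standoff documents parse, validate offsets and resolve references", {
  doc <- read_standoff_document("VDR binds STAT1 .",
                                c("T1\tProtein 0 3\tVDR",
                                  "T2\tProtein 10 15\tSTAT1"),
                                character(0), id = "d1")
  expect_equal(nrow(doc$proteins), 2L)
  expect_length(doc$events, 0L)
  expect_equal(doc$proteins$text[1], "VDR")

  # mention text must equal the document substring at its offsets
  expect_error(read_standoff_document("VDR binds STAT1 .",
                                      "T1\tProtein 0 3\tXXX"),
               "document substring")
  expect_error(read_standoff_document("VDR binds STAT1 .",
                                      "T1\tProtein 0 3"),
               "malformed")

  # nested chain of depth 2 resolves
  doc <- fixture_doc()
  expect_length(doc$events, 2L)
  e2 <- doc$events[["E2"]]
  expect_equal(e2$args$target[e2$args$role == "THEME"], "E1")
  expect_equal(e2$args$target[e2$args$role == "CAUSE"], "T1")

  # dangling event reference errors
  expect_error(read_standoff_document(
    "STAT1 induces X .", "T1\tProtein 0 5\tSTAT1",
    c("T2\tPositive_regulation 6 13\tinduces",
      "E1\tPositive_regulation:T2 Theme:E9")),
    "unknown target")
})

test_that("write_a2 round-trips event structure up to id renaming", {
  doc <- fixture_doc()
  expect_length(write_a2(doc, list()), 0L)
  lines <- write_a2(doc)
  expect_length(grep("^T", lines), 2L)
  expect_length(grep("^E", lines), 2L)
  back <- read_standoff_document(doc$text,
                                 sprintf("%s\tProtein %d %d\t%s",
                                         doc$proteins$id,
                                         doc$proteins$char_start,
                                         doc$proteins$char_end,
                                         doc$proteins$text),
                                 lines, id = doc$id)
  m <- match_events(doc$events, back$events, mode = "exact")
  expect_equal(m$matched, 2L)
  expect_equal(m$gold, m$predicted)

  # an event without THEME cannot be serialized
  bad <- event_annotation("E9", "Positive_regulation", 6, 13, "induces",
                          "CAUSE", "T1")
  expect_error(write_a2(doc, list(bad)), "no THEME")
})

test_that("dependency parse lines map to 0-based edges with set semantics", {
  d <- read_dependency_parse(c("dobj(express-1, numbers-6)",
                               "amod(numbers-6, decreased-3)"), 8L)
  expect_equal(d[order(d$gov), ],
               data.frame(gov = c(0L, 5L), dep = c(5L, 2L),
                          rel = c("dobj", "amod")),
               ignore_attr = TRUE)
  expect_equal(nrow(read_dependency_parse(character(0), 5L)), 0L)
  dup <- read_dependency_parse(rep("dobj(express-1, numbers-6)", 2), 8L)
  expect_equal(nrow(dup), 1L)
  expect_error(read_dependency_parse("dobj(a-1, b-9)", 8L), "out of range")
  expect_error(read_dependency_parse("nonsense line", 8L), "malformed")
  # relation labels are lower-cased, hyphenated words parse
  d <- read_dependency_parse("AMOD(IFNgamma-induced-2, strongly-1)", 3L)
  expect_equal(d$rel, "amod")
  expect_equal(c(d$gov, d$dep), c(1L, 0L))
})

test_that("multi-word protein mentions merge into single tokens", {
  tokens <- make_tokens(c("NF", "kappaB", "activates", "IL-2", "."),
                        pos = c("NN", "NN", "VBZ", "NN", "."))
  deps <- data.frame(gov = c(1L, 2L, 2L), dep = c(0L, 1L, 3L),
                     rel = c("nn", "nsubj", "dobj"))
  mentions <- data.frame(id = c("T1", "T2"),
                         char_start = c(0L, 20L), char_end = c(9L, 24L),
                         text = c("NF kappaB", "IL-2"),
                         stringsAsFactors = FALSE)
  out <- merge_protein_tokens(tokens, deps, mentions)
  expect_equal(nrow(out$tokens), 4L)
  expect_equal(out$tokens$surface[1], "NF kappaB")
  expect_equal(out$tokens$protein_id[1], "T1")
  expect_equal(out$tokens$protein_id[3], "T2")
  # internal nn edge dropped, external edges redirected to merged token
  expect_equal(nrow(out$deps), 2L)
  expect_true(all(out$deps$gov == 1L))
  expect_setequal(out$deps$dep, c(0L, 2L))
  # merged token span tiles the mention span
  expect_equal(out$tokens$char_start[1], 0L)
  expect_equal(out$tokens$char_end[1], 9L)

  # single-token mention: structure unchanged, token flagged
  one <- merge_protein_tokens(tokens, deps, mentions[2, , drop = FALSE])
  expect_equal(nrow(one$tokens), 5L)
  expect_equal(nrow(one$deps), 3L)
  expect_equal(one$tokens$protein_id[4], "T2")

  # misaligned mention errors unless snapped
  bad <- data.frame(id = "T9", char_start = 1L, char_end = 9L,
                    text = "F kappaB", stringsAsFactors = FALSE)
  expect_error(merge_protein_tokens(tokens, deps, bad), "not aligned")
  snapped <- merge_protein_tokens(tokens, deps, bad, snap = TRUE)
  expect_equal(snapped$tokens$surface[1], "NF kappaB")
})

test_that("edges with both endpoints outside mentions are preserved", {
  tokens <- make_tokens(c("NF", "kappaB", "binds", "to", "IL-2"),
                        pos = c("NN", "NN", "VBZ", "TO", "NN"))
  deps <- data.frame(gov = c(1L, 2L, 2L, 3L), dep = c(0L, 1L, 3L, 4L),
                     rel = c("nn", "nsubj", "prep", "pobj"))
  mentions <- data.frame(id = "T1", char_start = 0L, char_end = 9L,
                         text = "NF kappaB", stringsAsFactors = FALSE)
  out <- merge_protein_tokens(tokens, deps, mentions)
  outside_before <- deps[deps$gov >= 2L & deps$dep >= 2L, ]
  outside_after <- out$deps[out$deps$gov >= 1L & out$deps$dep >= 1L, ]
  expect_equal(nrow(outside_after), nrow(outside_before))
})

test_that("a corpus written to disk reads back identically", {
  corpus <- small_corpus(seed = 31, n_documents = 3, spd = 5)
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  back <- read_corpus_dir(dir)
  expect_length(back, length(corpus))
  for (k in seq_along(corpus)) {
    expect_equal(back[[k]]$text, corpus[[k]]$text)
    expect_equal(back[[k]]$proteins, corpus[[k]]$proteins)
    m <- match_events(corpus[[k]]$events, back[[k]]$events, mode = "exact")
    expect_equal(m$matched, m$gold)
    expect_equal(m$gold, m$predicted)
    for (s in seq_along(corpus[[k]]$sentences)) {
      expect_equal(back[[k]]$sentences[[s]]$tokens,
                   corpus[[k]]$sentences[[s]]$tokens)
      a <- corpus[[k]]$sentences[[s]]$deps
      b <- back[[k]]$sentences[[s]]$deps
      expect_setequal(paste(a$gov, a$dep, a$rel), paste(b$gov, b$dep, b$rel))
    }
  }
})
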