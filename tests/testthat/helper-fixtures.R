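# Shared fixtures and independent oracles for the test suite.

# Fragment of the motivating example sentence: "express either decreased or
# increased numbers of VDR", with VDR a protein mention and the dependency
# analysis in which 'decreased' is the adjectival modifier of the direct
# object 'numbers' of 'express'.
sentence1_tokens <- function() {
  make_tokens(
    surface = c("express", "either", "decreased", "or", "increased",
                "numbers", "of", "VDR"),
    baseform = c("express", "either", "decrease", "or", "increase",
                 "number", "of", "vdr"),
    pos = c("VBP", "CC", "VBN", "CC", "VBN", "NNS", "IN", "NN"),
    protein_id = c(NA, NA, NA, NA, NA, NA, NA, "T1")
  )
}

sentence1_deps <- function() {
  read_dependency_parse(
    c("dobj(express-1, numbers-6)",
      "amod(numbers-6, decreased-3)",
      "amod(numbers-6, increased-5)",
      "prep(numbers-6, of-7)",
      "pobj(of-7, VDR-8)"),
    n_tokens = 8L)
}

# Fragment of the two-trigger example sentence: "... at relatively high
# levels , was also slightly augmented ." ('levels' and 'augmented' anchor
# two distinct Positive Regulation events; the comma does not count as a
# position).
sentence5_tokens <- function() {
  make_tokens(
    surface = c("at", "relatively", "high", "levels", ",", "was", "also",
                "slightly", "augmented"),
    baseform = c("at", "relatively", "high", "level", ",", "be", "also",
                 "slightly", "augment"),
    pos = c("IN", "RB", "JJ", "NNS", ",", "VBD", "RB", "RB", "VBN")
  )
}

# a small standoff document used across corpus_io tests: one sentence,
# one protein, a Gene Expression under a Positive Regulation
fixture_doc <- function() {
  text <- "STAT1 induces the expression of VDR ."
  a1 <- "T1\tProtein 0 5\tSTAT1"
  a2 <- c("T2\tGene_expression 18 28\texpression",
          "T3\tPositive_regulation 6 13\tinduces",
          "E1\tGene_expression:T2 Theme:T4",
          "E2\tPositive_regulation:T3 Theme:E1 Cause:T1")
  a1 <- c(a1, "T4\tProtein 32 35\tVDR")
  doc <- read_standoff_document(text, a1, a2, id = "FIX1")
  toks <- data.frame(
    surface = c("STAT1", "induces", "the", "expression", "of", "VDR", "."),
    baseform = c("stat1", "induce", "the", "expression", "of", "vdr", "."),
    pos = c("NN", "VBZ", "DT", "NN", "IN", "NN", "."),
    stringsAsFactors = FALSE)
  deps <- read_dependency_parse(
    c("nsubj(induces-2, STAT1-1)", "dobj(induces-2, expression-4)",
      "det(expression-4, the-3)", "prep(expression-4, of-5)",
      "pobj(of-5, VDR-6)", "punct(induces-2, .-7)"), 7L)
  attach_sentences(doc, list(toks), list(deps))
}

# random small decoding instance (fake prepared sentence + weights) for
# the exhaustive-enumeration oracle
random_instance <- function(seed, n_feat = 12L) {
  set.seed(seed)
  repeat {
    n_tok <- sample(3:5, 1)
    n_cand <- sample(2:min(3, n_tok - 1), 1)
    cand_tok <- sort(sample(0:(n_tok - 1), n_cand))
    protein_tok <- setdiff(0:(n_tok - 1), cand_tok)[1]
    types <- c("Gene_expression", "Positive_regulation", "Binding")
    all_labels <- c(types, paste0("EDGE:", c("THEME", "CAUSE", "NEG")))
    labels_at <- lapply(cand_tok, function(i)
      sort(sample(types, sample(1:2, 1))))
    node_slots <- do.call(rbind, lapply(seq_along(cand_tok), function(k)
      data.frame(tok = cand_tok[k], label = labels_at[[k]],
                 stringsAsFactors = FALSE)))
    node_slots$col <- match(node_slots$label, all_labels)
    edges <- do.call(rbind, lapply(cand_tok, function(i) {
      tgts <- setdiff(c(protein_tok, cand_tok), i)
      k <- min(length(tgts), sample(1:2, 1))
      tgts <- sort(tgts[sample.int(length(tgts), k)])
      data.frame(src = i, tgt = tgts)
    }))
    if (nrow(node_slots) <= 6L && nrow(edges) <= 4L) break
  }
  sparse <- function() {
    idx <- sort(sample(n_feat, 4))
    list(idx = idx, val = round(stats::rnorm(4), 2))
  }
  node_phi <- stats::setNames(lapply(cand_tok, function(i) sparse()),
                              as.character(cand_tok))
  edge_phi <- lapply(seq_len(nrow(edges)), function(k) sparse())
  W <- matrix(round(stats::rnorm(n_feat * 6), 2), n_feat, 6,
              dimnames = list(NULL, all_labels))
  prep <- list(node_slots = node_slots, node_phi = node_phi,
               edge_phi = edge_phi, edges = edges, edge_cols = 4:6,
               cand_tok = cand_tok, protein_tok = protein_tok,
               n_tokens = n_tok)
  list(prep = prep, W = W)
}

# independent exhaustive enumeration of the best valid assignment score
brute_force_best <- function(prep, W) {
  dots <- bioevent:::.sentence_dots(prep, W)
  ns <- nrow(prep$node_slots); ne <- nrow(prep$edges)
  NC <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), ns)))
  EC <- as.matrix(expand.grid(rep(list(1:3), ne)))  # 1=THEME 2=CAUSE 3=NEG
  node_scores <- as.numeric((2 * NC - 1) %*% dots$node)
  edge_scores <- rowSums(vapply(seq_len(ne), function(j)
    dots$edge[j, ][EC[, j]], numeric(nrow(EC))))
  total <- outer(node_scores, edge_scores, "+")
  valid <- matrix(TRUE, nrow(NC), nrow(EC))
  for (i in prep$cand_tok) {
    s_i <- which(prep$node_slots$tok == i)
    o_i <- which(prep$edges$src == i)
    anchor <- if (length(s_i) == 1L) NC[, s_i] else rowSums(NC[, s_i]) > 0
    theme <- if (length(o_i) == 0L) rep(FALSE, nrow(EC))
    else if (length(o_i) == 1L) EC[, o_i] == 1L
    else rowSums(EC[, o_i] == 1L) > 0
    role <- if (length(o_i) == 0L) rep(FALSE, nrow(EC))
    else if (length(o_i) == 1L) EC[, o_i] != 3L
    else rowSums(EC[, o_i] != 3L) > 0
    valid <- valid & !outer(anchor, !theme, "&") & !outer(!anchor, role, "&")
  }
  max(total[valid])
}

# small corpora for learning/evaluation tests
small_corpus <- function(seed, n_documents = 6, spd = 8, rate = 0,
                         weights = NULL) {
  cfg <- if (is.null(weights))
    generator_config(n_documents = n_documents,
                     sentences_per_document = spd,
                     span_inconsistency_rate = rate, seed = seed)
  else generator_config(n_documents = n_documents,
                        sentences_per_document = spd,
                        span_inconsistency_rate = rate,
                        template_weights = weights, seed = seed)
  generate_corpus(cfg)
}
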