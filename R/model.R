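# The multi-label linear structured model. An assignment L gives every
# (word, event type) pair in the candidate mask a positive/negative label
# and every admissible ordered word pair a THEME/CAUSE/negative label. The
# model score is the sum of node scores (+/- w_e . phi(x_i)) and edge
# scores (w_L . phi(x_i, x_j)); assignments violating the two validity
# conditions (anchors need an outgoing THEME; role edges leave anchors)
# score -Inf. Decoding is exact per source token, followed by a refinement
# pass and a cycle check.
#
# Weights live in a single numeric matrix with one column per label
# (node labels first, then THEME/CAUSE/negative edge columns) and one row
# per interned feature, so score computations are small matrix products.

EDGE_LABELS <- c("THEME", "CAUSE", "NEG")

# ---- feature interning ----------------------------------------------------

feature_index <- function() {
  e <- new.env(parent = emptyenv())
  e$map <- new.env(parent = emptyenv(), hash = TRUE)
  e$n <- 0L
  class(e) <- "feature_index"
  e
}

intern_features <- function(fidx, names, add = TRUE) {
  out <- integer(length(names))
  for (k in seq_along(names)) {
    id <- fidx$map[[names[k]]]
    if (is.null(id)) {
      if (add) {
        fidx$n <- id <- fidx$n + 1L
        fidx$map[[names[k]]] <- id
      } else id <- NA_integer_
    }
    out[k] <- id
  }
  out
}

compile_fv <- function(fv, fidx, add = TRUE) {
  idx <- intern_features(fidx, names(fv), add = add)
  keep <- !is.na(idx)
  list(idx = idx[keep], val = unname(fv)[keep])
}

# ---- assignments ----------------------------------------------------------

#' Score of one (word, event type, label) choice
#'
#' `positive` scores \eqn{w_e \cdot \Phi(x_i)}, `negative` its negation.
#'
#' @param dot value of \eqn{w_e \cdot \Phi(x_i)}.
#' @param label `"positive"` or `"negative"`.
#' @return numeric score.
#' @export
node_score <- function(dot, label) {
  switch(label, positive = dot, negative = -dot,
         stop(sprintf("unknown node label '%s'", label)))
}

#' Score of one word-pair label choice
#'
#' @param dots named numeric of \eqn{w_L \cdot \Phi(x_i, x_j)} for the
#'   three edge labels (`THEME`, `CAUSE`, `NEG`).
#' @param label one of `"THEME"`, `"CAUSE"`, `"NEG"`.
#' @return numeric score.
#' @export
edge_score <- function(dots, label) {
  if (!label %in% EDGE_LABELS)
    stop(sprintf("unknown edge label '%s'", label))
  unname(dots[[label]])
}

new_assignment <- function(node_pos, edge_lab, score = NA_real_,
                           no_events = FALSE) {
  structure(list(node_pos = node_pos, edge_lab = edge_lab, score = score,
                 no_events = no_events),
            class = "assignment")
}

assignments_equal <- function(a, b) {
  identical(a$node_pos, b$node_pos) && identical(a$edge_lab, b$edge_lab)
}

#' Structural validity of an assignment
#'
#' Checks the model's two conditions: every identified anchor word (a word
#' with at least one positive event-type label) has at least one outgoing
#' THEME edge, and every role-labeled edge starts at an anchor word.
#'
#' @param a an assignment.
#' @param prep a prepared sentence (see [prepare_corpus()]).
#' @return logical.
#' @export
is_valid <- function(a, prep) {
  slots <- prep$node_slots
  pos_tok <- unique(slots$tok[a$node_pos])
  role <- a$edge_lab != "NEG"
  for (i in pos_tok) {
    out <- which(prep$edges$src == i)
    if (!any(a$edge_lab[out] == "THEME")) return(FALSE)
  }
  if (any(role & !(prep$edges$src %in% pos_tok))) return(FALSE)
  TRUE
}

# node and edge dot products for a prepared sentence under weights W
.sentence_dots <- function(prep, W) {
  node_dot <- numeric(nrow(prep$node_slots))
  for (i in prep$cand_tok) {
    rows <- which(prep$node_slots$tok == i)
    phi <- prep$node_phi[[as.character(i)]]
    if (length(phi$idx)) {
      M <- W[phi$idx, prep$node_slots$col[rows], drop = FALSE]
      node_dot[rows] <- colSums(phi$val * M)
    }
  }
  edge_dot <- matrix(0, nrow(prep$edges), 3,
                     dimnames = list(NULL, EDGE_LABELS))
  for (k in seq_len(nrow(prep$edges))) {
    phi <- prep$edge_phi[[k]]
    if (length(phi$idx))
      edge_dot[k, ] <- colSums(phi$val * W[phi$idx, prep$edge_cols,
                                           drop = FALSE])
  }
  list(node = node_dot, edge = edge_dot)
}

#' Score of a full assignment
#'
#' Sum of node and edge scores over the candidate mask, or `-Inf` when the
#' assignment violates the validity conditions.
#'
#' @param a an assignment.
#' @param prep prepared sentence.
#' @param W weight matrix.
#' @param dots optional precomputed dot products.
#' @return numeric score (possibly `-Inf`).
#' @export
assignment_score <- function(a, prep, W, dots = NULL) {
  if (!is_valid(a, prep)) return(-Inf)
  if (is.null(dots)) dots <- .sentence_dots(prep, W)
  s <- sum(ifelse(a$node_pos, dots$node, -dots$node))
  if (nrow(prep$edges))
    s <- s + sum(dots$edge[cbind(seq_len(nrow(prep$edges)),
                                 match(a$edge_lab, EDGE_LABELS))])
  s
}

#' Decode the highest-scoring assignment of a sentence
#'
#' Pass 1 is exact and decomposes over source tokens: for each candidate
#' word the better of the anchor option (each admissible type takes its
#' better label, with one type forced positive if all prefer negative;
#' each out-edge takes its argmax label, with the least costly edge forced
#' to THEME if none prefers it) and the non-anchor option (everything
#' negative) is taken; exact ties go to the non-anchor option and to
#' negative labels. Pass 2 refines to a fixpoint: role edges into words
#' that are neither anchors nor proteins are relabeled negative, and
#' anchors thereby losing their last THEME edge are demoted. Pass 3 flags
#' the sentence as yielding no events when the remaining role-edge graph
#' contains a cycle.
#'
#' @param prep prepared sentence.
#' @param W weight matrix.
#' @return list with `pass1` (the pre-refinement assignment, attaining the
#'   maximum of [assignment_score()]), `final` (refined assignment; its
#'   `no_events` field is the pass-3 cycle flag).
#' @export
decode <- function(prep, W) {
  dots <- .sentence_dots(prep, W)
  slots <- prep$node_slots
  node_pos <- rep(FALSE, nrow(slots))
  edge_lab <- rep("NEG", nrow(prep$edges))
  total <- 0

  for (i in prep$cand_tok) {
    rows <- which(slots$tok == i)
    out <- which(prep$edges$src == i)
    d <- dots$node[rows]

    non_anchor <- sum(-d) + if (length(out)) sum(dots$edge[out, "NEG"]) else 0

    if (length(out)) {
      pos_pref <- d > 0
      node_part <- sum(ifelse(pos_pref, d, -d))
      forced_slot <- NA_integer_
      if (!any(pos_pref)) {
        forced_slot <- which.max(d)
        node_part <- node_part + 2 * d[forced_slot]
      }
      ed <- dots$edge[out, , drop = FALSE]
      # argmax label per edge; ties prefer negative, then THEME over CAUSE
      lab <- apply(ed, 1L, function(r) {
        if (r["NEG"] >= r["THEME"] && r["NEG"] >= r["CAUSE"]) "NEG"
        else if (r["THEME"] >= r["CAUSE"]) "THEME" else "CAUSE"
      })
      best <- ed[cbind(seq_along(out), match(lab, EDGE_LABELS))]
      edge_part <- sum(best)
      if (!any(lab == "THEME")) {
        forcing_cost <- unname(best - ed[, "THEME"])
        ord <- order(forcing_cost, prep$edges$tgt[out])
        k <- ord[1]
        edge_part <- edge_part - forcing_cost[k]
        lab[k] <- "THEME"
      }
      anchor <- node_part + edge_part
      if (anchor > non_anchor) {
        node_pos[rows] <- pos_pref
        if (!is.na(forced_slot)) node_pos[rows[forced_slot]] <- TRUE
        edge_lab[out] <- lab
        total <- total + anchor
        next
      }
    }
    total <- total + non_anchor
  }
  pass1 <- new_assignment(node_pos, edge_lab, score = total)

  # pass 2: refinement to fixpoint
  a <- pass1
  is_prot <- prep$protein_tok
  repeat {
    changed <- FALSE
    anchors <- unique(slots$tok[a$node_pos])
    role <- which(a$edge_lab != "NEG")
    for (k in role) {
      tgt <- prep$edges$tgt[k]
      if (!(tgt %in% is_prot) && !(tgt %in% anchors)) {
        a$edge_lab[k] <- "NEG"
        changed <- TRUE
      }
    }
    anchors <- unique(slots$tok[a$node_pos])
    for (i in anchors) {
      out <- which(prep$edges$src == i)
      if (!any(a$edge_lab[out] == "THEME")) {
        a$node_pos[slots$tok == i] <- FALSE
        a$edge_lab[out] <- "NEG"
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  a$score <- assignment_score(a, prep, W, dots)

  # pass 3: cycle check on the remaining role edges
  role <- a$edge_lab != "NEG"
  if (any(role)) {
    e <- prep$edges[role, , drop = FALSE]
    ig <- .role_igraph(e, prep$n_tokens)
    if (!igraph::is_dag(ig)) a$no_events <- TRUE
  }
  list(pass1 = pass1, final = a)
}

# ---- prepared sentences ---------------------------------------------------

# admissible node labels at a token: matching base types plus any composite
# label (from the model's label universe) all of whose components match
.admissible_labels <- function(cand_map, node_labels) {
  base <- intersect(node_labels, names(cand_map))
  comp <- node_labels[vapply(node_labels, is_composite_label, logical(1))]
  comp <- comp[vapply(comp, function(cl)
    all(label_components(cl) %in% names(cand_map)), logical(1))]
  c(base, comp)
}

#' Prepare a corpus for training or decoding
#'
#' Extracts candidate masks, node and edge feature vectors (interned into
#' the model's feature index), admissible label slots, and gold graphs and
#' assignments for every sentence.
#'
#' @param corpus list of `bio_document`.
#' @param lex,stemmed_lex pruned trigger lexicons.
#' @param node_labels node label universe; defaults to the nine event types
#'   plus every composite label observed in the gold graphs.
#' @param fidx feature index to intern into (a fresh one by default).
#' @param add intern unseen features (`TRUE` for training corpora, `FALSE`
#'   when preparing held-out data against a trained model).
#' @param use_merged,anchor_rule passed to [events_to_graph()] when deriving
#'   gold graphs.
#' @param gold derive gold graphs and assignments (requires events).
#' @return list with `sentences` (prepared records), `fidx`, `node_labels`,
#'   `all_labels` (node labels + edge labels, the weight matrix columns).
#' @export
prepare_corpus <- function(corpus, lex, stemmed_lex = NULL,
                           node_labels = NULL, fidx = feature_index(),
                           add = TRUE, use_merged = TRUE,
                           anchor_rule = head_word, gold = TRUE) {
  gold_graphs <- list()
  if (gold) {
    for (di in seq_along(corpus)) {
      for (s in seq_along(corpus[[di]]$sentences)) {
        g <- events_to_graph(corpus[[di]], s, use_merged = use_merged,
                             anchor_rule = anchor_rule)
        gold_graphs[[paste(di, s)]] <- g
      }
    }
  }
  if (is.null(node_labels)) {
    comp <- character(0)
    for (g in gold_graphs) {
      if (is_discarded(g)) next
      for (ls in g$node_labels)
        comp <- c(comp, ls[vapply(ls, is_composite_label, logical(1))])
    }
    node_labels <- c(EVENT_TYPES, sort(unique(comp)))
  }
  all_labels <- c(node_labels, paste0("EDGE:", EDGE_LABELS))

  sentences <- list()
  for (di in seq_along(corpus)) {
    doc <- corpus[[di]]
    for (s in seq_along(doc$sentences)) {
      sen <- doc$sentences[[s]]
      tokens <- sen$tokens; deps <- sen$deps
      mask <- candidate_mask(tokens, deps, lex, stemmed_lex)
      cand_tok <- as.integer(names(mask$node_candidates))

      node_phi <- list(); labels_at <- list()
      for (i in cand_tok) {
        fv <- node_feature_vector(i, tokens, deps, lex, stemmed_lex,
                                  cand = mask$cand)
        node_phi[[as.character(i)]] <- compile_fv(fv, fidx, add = add)
        labels_at[[as.character(i)]] <-
          .admissible_labels(mask$node_candidates[[as.character(i)]],
                             node_labels)
      }
      edges <- mask$edge_candidates
      edge_phi <- lapply(seq_len(nrow(edges)), function(k) {
        fv <- edge_feature_vector(edges$src[k], edges$tgt[k], tokens, deps,
                                  lex, stemmed_lex, cand = mask$cand)
        compile_fv(fv, fidx, add = add)
      })

      node_slots <- do.call(rbind, c(list(
        data.frame(tok = integer(0), label = character(0))),
        lapply(cand_tok, function(i)
          data.frame(tok = i, label = labels_at[[as.character(i)]],
                     stringsAsFactors = FALSE))))
      node_slots$col <- match(node_slots$label, all_labels)

      rec <- list(
        doc = di, sent = s, doc_id = doc$id,
        tokens = tokens, deps = deps,
        cand_tok = cand_tok,
        protein_tok = tokens$index[!is.na(tokens$protein_id)],
        node_phi = node_phi, edge_phi = edge_phi,
        edges = edges,
        node_slots = node_slots,
        edge_cols = match(paste0("EDGE:", EDGE_LABELS), all_labels),
        n_tokens = nrow(tokens)
      )
      if (gold) {
        g <- gold_graphs[[paste(di, s)]]
        rec$gold_graph <- g
        rec$gold_assign <- if (is_discarded(g)) NULL
        else graph_to_assignment(g, rec)
        rec$gold_events <- doc$events[
          vapply(doc$events, function(e)
            e$trigger_start >= min(tokens$char_start) &&
              e$trigger_end <= max(tokens$char_end), logical(1))]
      }
      sentences[[length(sentences) + 1L]] <- rec
    }
  }
  list(sentences = sentences, fidx = fidx, node_labels = node_labels,
       all_labels = all_labels)
}

#' Restrict an event graph to an assignment over a sentence's mask
#'
#' Node labels and role edges outside the candidate mask are dropped.
#'
#' @param g an `event_graph` (or [DISCARDED], giving `NULL`).
#' @param prep prepared sentence.
#' @return an assignment.
#' @export
graph_to_assignment <- function(g, prep) {
  if (is_discarded(g)) return(NULL)
  slots <- prep$node_slots
  node_pos <- vapply(seq_len(nrow(slots)), function(k)
    slots$label[k] %in% node_label_set(g, slots$tok[k]), logical(1))
  edge_lab <- rep("NEG", nrow(prep$edges))
  if (nrow(g$edges)) {
    for (k in seq_len(nrow(g$edges))) {
      hit <- which(prep$edges$src == g$edges$src[k] &
                     prep$edges$tgt == g$edges$tgt[k])
      if (length(hit)) edge_lab[hit] <- g$edges$role[k]
    }
  }
  new_assignment(node_pos, edge_lab)
}

#' Event graph of an assignment
#'
#' @param a an assignment.
#' @param prep prepared sentence.
#' @return an `event_graph` (no recorded trigger spans); empty when the
#'   assignment's `no_events` flag is set.
#' @export
assignment_to_graph <- function(a, prep) {
  if (isTRUE(a$no_events)) return(new_event_graph(prep$n_tokens))
  slots <- prep$node_slots
  node_labels <- list()
  for (k in which(a$node_pos)) {
    key <- as.character(slots$tok[k])
    node_labels[[key]] <- unique(c(node_labels[[key]], slots$label[k]))
  }
  role <- a$edge_lab != "NEG"
  edges <- data.frame(src = prep$edges$src[role], tgt = prep$edges$tgt[role],
                      role = a$edge_lab[role], stringsAsFactors = FALSE)
  new_event_graph(prep$n_tokens, node_labels, edges)
}

graphs_equal <- function(g1, g2) {
  if (is_discarded(g1) || is_discarded(g2))
    return(is_discarded(g1) && is_discarded(g2))
  k1 <- names(g1$node_labels)[vapply(g1$node_labels, length, integer(1)) > 0L]
  k2 <- names(g2$node_labels)[vapply(g2$node_labels, length, integer(1)) > 0L]
  if (!setequal(k1, k2)) return(FALSE)
  for (k in k1)
    if (!setequal(g1$node_labels[[k]], g2$node_labels[[k]])) return(FALSE)
  e1 <- paste(g1$edges$src, g1$edges$tgt, g1$edges$role)
  e2 <- paste(g2$edges$src, g2$edges$tgt, g2$edges$role)
  setequal(e1, e2)
}

# ---- model objects --------------------------------------------------------

new_iem_model <- function(W, fidx, all_labels, node_labels) {
  structure(list(W = W, fidx = fidx, all_labels = all_labels,
                 node_labels = node_labels),
            class = "iem_model")
}

#' @export
print.iem_model <- function(x, ...) {
  cat(sprintf("<iem_model: %d features x %d labels>\n", nrow(x$W),
              ncol(x$W)))
  invisible(x)
}

#' Serialize a model as TSV lines
#'
#' Versioned flat format `namespace<TAB>feature<TAB>weight` (zero weights
#' omitted), preceded by a header line.
#'
#' @param model an `iem_model`.
#' @return character vector of lines.
#' @export
write_model_tsv <- function(model) {
  names_by_id <- character(model$fidx$n)
  for (nm in ls(model$fidx$map))
    names_by_id[model$fidx$map[[nm]]] <- nm
  out <- c(sprintf("#iem-model\tv1\tlabels=%s",
                   paste(model$all_labels, collapse = ",")))
  for (col in seq_along(model$all_labels)) {
    nz <- which(model$W[, col] != 0)
    nz <- nz[nz <= length(names_by_id)]
    if (length(nz))
      out <- c(out, sprintf("%s\t%s\t%.17g", model$all_labels[col],
                            names_by_id[nz], model$W[nz, col]))
  }
  out
}

#' Read a model from TSV lines written by [write_model_tsv()]
#' @param lines character vector of lines.
#' @return an `iem_model`.
#' @export
read_model_tsv <- function(lines) {
  stopifnot(startsWith(lines[1], "#iem-model"))
  labels <- strsplit(sub("^.*labels=", "", lines[1]), ",", fixed = TRUE)[[1]]
  node_labels <- labels[!startsWith(labels, "EDGE:")]
  fidx <- feature_index()
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  rows <- strsplit(body, "\t", fixed = TRUE)
  ids <- intern_features(fidx, vapply(rows, `[`, character(1), 2))
  W <- matrix(0, max(fidx$n, 1L), length(labels),
              dimnames = list(NULL, labels))
  for (k in seq_along(rows)) {
    col <- match(rows[[k]][1], labels)
    W[ids[k], col] <- as.numeric(rows[[k]][3])
  }
  new_iem_model(W, fidx, labels, node_labels)
}

#' Predict events for a corpus with a trained model
#'
#' Prepares each sentence against the model's feature index (unseen
#' features are ignored), decodes, refines, and converts the resulting
#' graphs to event annotations.
#'
#' @param corpus list of `bio_document`.
#' @param model an `iem_model`.
#' @param lex,stemmed_lex the pruned lexicons the model was trained with.
#' @return list of `bio_document` whose events are the predictions.
#' @export
predict_events <- function(corpus, model, lex, stemmed_lex = NULL) {
  prep <- prepare_corpus(corpus, lex, stemmed_lex,
                         node_labels = model$node_labels,
                         fidx = model$fidx, add = FALSE, gold = FALSE)
  W <- model$W
  if (nrow(W) < prep$fidx$n)
    W <- rbind(W, matrix(0, prep$fidx$n - nrow(W), ncol(W)))
  out <- corpus
  by_doc <- split(seq_along(prep$sentences),
                  vapply(prep$sentences, `[[`, integer(1), "doc"))
  for (di in seq_along(corpus)) {
    all_events <- list()
    for (si in by_doc[[as.character(di)]]) {
      rec <- prep$sentences[[si]]
      a <- decode(rec, W)$final
      g <- assignment_to_graph(a, rec)
      evs <- graph_to_events(g, rec$tokens)
      pre <- sprintf("s%d.", rec$sent)
      for (e in evs) {
        e$id <- paste0(pre, e$id)
        ev_ref <- grepl("^E[0-9]+$", e$args$target)
        e$args$target[ev_ref] <- paste0(pre, e$args$target[ev_ref])
        all_events[[e$id]] <- e
      }
    }
    old <- names(all_events)
    map <- stats::setNames(sprintf("E%d", seq_along(all_events)), old)
    all_events <- lapply(all_events, function(e) {
      e$id <- unname(map[[e$id]])
      hit <- e$args$target %in% old
      e$args$target[hit] <- unname(map[e$args$target[hit]])
      e
    })
    names(all_events) <- unname(map)
    out[[di]]$events <- all_events
  }
  out
}
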