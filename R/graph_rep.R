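# Conversion between event annotations and per-sentence labeled graphs.
# Nodes are anchor words carrying sets of event-type labels (possibly a
# composite label such as "Gene_expression/Positive_regulation" standing
# for a merged event pair); edges carry a single role (THEME or CAUSE).
# Role-edge graphs must be loop-free and acyclic: loops are removed (after
# merged-event substitution) and cyclic sentences are discarded.

#' Sentinel for sentences whose role-edge graph is cyclic
#' @export
DISCARDED <- structure("DISCARDED", class = "discarded_graph")

#' @rdname DISCARDED
#' @param x object to test.
#' @export
is_discarded <- function(x) inherits(x, "discarded_graph")

new_event_graph <- function(n_tokens, node_labels = list(),
                            edges = NULL, trigger_spans = NULL) {
  if (is.null(edges))
    edges <- data.frame(src = integer(0), tgt = integer(0),
                        role = character(0), stringsAsFactors = FALSE)
  if (is.null(trigger_spans))
    trigger_spans <- data.frame(index = integer(0), label = character(0),
                                char_start = integer(0), char_end = integer(0),
                                text = character(0), stringsAsFactors = FALSE)
  structure(list(n_tokens = n_tokens, node_labels = node_labels,
                 edges = edges, trigger_spans = trigger_spans),
            class = "event_graph")
}

#' @export
print.event_graph <- function(x, ...) {
  cat(sprintf("<event_graph: %d labeled node(s), %d role edge(s)>\n",
              length(x$node_labels), nrow(x$edges)))
  for (k in names(x$node_labels))
    cat(sprintf("  node %s: %s\n", k,
                paste(x$node_labels[[k]], collapse = ", ")))
  if (nrow(x$edges))
    cat(sprintf("  edge %d -> %d: %s\n", x$edges$src, x$edges$tgt,
                x$edges$role), sep = "")
  invisible(x)
}

node_label_set <- function(g, i) {
  g$node_labels[[as.character(i)]] %||% character(0)
}

# igraph over the role edges (labeled nodes + protein targets as vertices)
.role_igraph <- function(edges, n_tokens) {
  igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$src), to = as.character(edges$tgt)),
    vertices = data.frame(name = as.character(seq_len(n_tokens) - 1L))
  )
}

#' Syntactic head word of a trigger span
#'
#' Returns the 0-based index of the in-span token whose governor lies
#' outside the span (or which has no governor); ties are broken by taking
#' the rightmost such token. This is the Head-Word rule used to anchor
#' multi-word event triggers at a single token.
#'
#' @param char_start,char_end 0-based half-open character span.
#' @param tokens sentence token table.
#' @param deps dependency edge table.
#' @return 0-based token index.
#' @export
head_word <- function(char_start, char_end, tokens, deps) {
  inside <- which(tokens$char_end > char_start & tokens$char_start < char_end)
  if (length(inside) == 0L)
    stop(sprintf("trigger span [%d,%d) covers no token", char_start, char_end))
  if (length(inside) == 1L) return(tokens$index[inside])
  idx <- tokens$index[inside]
  # a token is head-like if it has no governor, or some governor outside span
  head_like <- vapply(idx, function(i) {
    govs <- deps$gov[deps$dep == i]
    length(govs) == 0L || !all(govs %in% idx)
  }, logical(1))
  cand <- if (any(head_like)) idx[head_like] else idx
  max(cand)  # rightmost tie-break
}

# which sentence (1-based) contains a character span, NA if none fully does
.sentence_of_span <- function(doc, start, end) {
  for (s in seq_along(doc$sentences)) {
    tk <- doc$sentences[[s]]$tokens
    if (start >= min(tk$char_start) && end <= max(tk$char_end)) return(s)
  }
  NA_integer_
}

#' Convert a sentence's gold events into a labeled event graph
#'
#' Each event contributes its type label at the anchor token of its trigger
#' (per `anchor_rule`) and role edges from that anchor to each argument's
#' token (the merged protein token, or the argument event's anchor).
#' Positive Regulation events sharing a trigger with the Gene Expression
#' event they take as THEME form a loop; with `use_merged = TRUE` the pair
#' is replaced by a single composite-labeled node. Remaining loops are
#' removed; if the role-edge graph still has a cycle the sentence is
#' [DISCARDED]. Events with cross-sentence arguments are skipped with a
#' warning.
#'
#' @param doc `bio_document` with sentences attached.
#' @param sentence 1-based sentence index.
#' @param use_merged substitute composite merged labels for GE/PosReg
#'   trigger-sharing loops.
#' @param anchor_rule function (char_start, char_end, tokens, deps) ->
#'   token index; defaults to [head_word()].
#' @return an `event_graph`, or [DISCARDED].
#' @export
events_to_graph <- function(doc, sentence, use_merged = TRUE,
                            anchor_rule = head_word) {
  sen <- doc$sentences[[sentence]]
  tokens <- sen$tokens; deps <- sen$deps
  s_start <- min(tokens$char_start); s_end <- max(tokens$char_end)

  ev <- doc$events
  in_sentence <- vapply(ev, function(e)
    e$trigger_start >= s_start && e$trigger_end <= s_end, logical(1))
  ev <- ev[in_sentence]
  if (length(ev) == 0L) return(new_event_graph(nrow(tokens)))

  prot_tok <- function(pid) {
    i <- which(!is.na(tokens$protein_id) & tokens$protein_id == pid)
    if (length(i) == 1L) tokens$index[i] else NA_integer_
  }

  # iterate to a fixpoint: an event is usable iff its trigger is in the
  # sentence and every argument resolves within the sentence
  usable <- stats::setNames(rep(TRUE, length(ev)),
                            vapply(ev, `[[`, character(1), "id"))
  repeat {
    changed <- FALSE
    for (e in ev) {
      if (!usable[[e$id]]) next
      for (tgt in e$args$target) {
        ok <- if (tgt %in% doc$proteins$id) !is.na(prot_tok(tgt))
        else isTRUE(usable[tgt])
        if (!ok) {
          usable[[e$id]] <- FALSE
          warning(sprintf(
            "event %s skipped: argument %s not in sentence %d",
            e$id, tgt, sentence), call. = FALSE)
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  ev <- ev[vapply(ev, function(e) usable[[e$id]], logical(1))]
  if (length(ev) == 0L) return(new_event_graph(nrow(tokens)))

  anchors <- vapply(ev, function(e)
    anchor_rule(e$trigger_start, e$trigger_end, tokens, deps), integer(1))
  names(anchors) <- vapply(ev, `[[`, character(1), "id")

  # merged-event detection: PosReg whose THEME is a GE sharing its anchor
  merged_of <- character(0)  # PosReg id -> GE id
  if (use_merged) {
    for (e in ev) {
      if (e$type != "Positive_regulation") next
      th <- e$args$target[e$args$role == "THEME"]
      for (tgt in th) {
        ge <- if (tgt %in% names(anchors)) doc$events[[tgt]] else NULL
        if (!is.null(ge) && ge$type == "Gene_expression" &&
            anchors[[tgt]] == anchors[[e$id]]) {
          merged_of[e$id] <- tgt
        }
      }
    }
  }

  node_labels <- list(); edges <- list(); spans <- list()
  add_label <- function(i, label, e) {
    k <- as.character(i)
    node_labels[[k]] <<- unique(c(node_labels[[k]], label))
    spans[[length(spans) + 1L]] <<- data.frame(
      index = i, label = label, char_start = e$trigger_start,
      char_end = e$trigger_end, text = e$trigger_text,
      stringsAsFactors = FALSE)
  }
  add_edge <- function(src, tgt, role) {
    edges[[length(edges) + 1L]] <<- data.frame(
      src = src, tgt = tgt, role = role, stringsAsFactors = FALSE)
  }
  arg_token <- function(tgt) {
    if (tgt %in% doc$proteins$id) prot_tok(tgt) else anchors[[tgt]]
  }

  ge_merged <- unname(merged_of)
  for (e in ev) {
    i <- anchors[[e$id]]
    if (e$id %in% names(merged_of)) {
      # composite node: PosReg's CAUSE edges stay; the loop THEME edge and
      # the component GE/PosReg labels are replaced by the merged label
      add_label(i, MERGED_GE_PR, e)
      for (k in seq_len(nrow(e$args))) {
        if (e$args$role[k] == "THEME" && e$args$target[k] == merged_of[e$id])
          next
        add_edge(i, arg_token(e$args$target[k]), e$args$role[k])
      }
    } else if (e$id %in% ge_merged) {
      # the GE component of a merged pair: THEME protein edges stay on the
      # composite node, the label is subsumed by the merged label
      for (k in seq_len(nrow(e$args)))
        add_edge(i, arg_token(e$args$target[k]), e$args$role[k])
    } else {
      add_label(i, e$type, e)
      for (k in seq_len(nrow(e$args)))
        add_edge(i, arg_token(e$args$target[k]), e$args$role[k])
    }
  }

  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    new_event_graph(1L)$edges
  # at most one role per ordered pair: on conflict THEME wins
  if (nrow(edges)) {
    key <- paste(edges$src, edges$tgt)
    if (anyDuplicated(key)) {
      warning("multi-role edge collapsed to a single role", call. = FALSE)
      edges <- edges[order(key, edges$role != "THEME"), , drop = FALSE]
      edges <- edges[!duplicated(paste(edges$src, edges$tgt)), , drop = FALSE]
    }
  }
  # remove remaining loops (e.g. hyphenated protein/trigger tokens)
  edges <- edges[edges$src != edges$tgt, , drop = FALSE]
  rownames(edges) <- NULL

  # a node left without any outgoing THEME edge (e.g. a regulation whose
  # only THEME was a removed loop) cannot be encoded: its labels and
  # remaining role edges are dropped, losing those events
  repeat {
    bad <- names(node_labels)[vapply(names(node_labels), function(k)
      !any(edges$role[edges$src == as.integer(k)] == "THEME"),
      logical(1))]
    if (length(bad) == 0L) break
    for (k in bad) node_labels[[k]] <- NULL
    edges <- edges[!(edges$src %in% as.integer(bad)), , drop = FALSE]
  }

  if (nrow(edges)) {
    ig <- .role_igraph(edges, nrow(tokens))
    if (!igraph::is_dag(ig)) return(DISCARDED)
  }
  spans <- unique(do.call(rbind, spans))
  new_event_graph(nrow(tokens), node_labels, edges, spans)
}

# recorded gold trigger span for (anchor index, label), else the anchor
# token's own span
.trigger_span_for <- function(g, tokens, i, label) {
  ts <- g$trigger_spans
  hit <- which(ts$index == i & ts$label == label)
  if (length(hit)) {
    ts[hit[1], c("char_start", "char_end", "text")]
  } else {
    row <- which(tokens$index == i)
    data.frame(char_start = tokens$char_start[row],
               char_end = tokens$char_end[row],
               text = tokens$surface[row], stringsAsFactors = FALSE)
  }
}

#' Derive event annotations from a labeled event graph
#'
#' Nodes are processed in topological order of the role-edge graph
#' (argument events first). Plain protein-taking types emit one event per
#' THEME protein edge; Binding emits a single event carrying all THEME
#' protein edges; event-taking types emit one event per THEME target event
#' (or protein), crossed with the available CAUSE targets (or no CAUSE when
#' the node has none). Composite merged labels expand to a Gene Expression
#' event plus a Positive Regulation event taking it as THEME, with CAUSE
#' edges attached to the Positive Regulation component.
#'
#' @param g an `event_graph`.
#' @param tokens the sentence token table `g` refers to.
#' @return named list of `event_annotation` (empty when no node is
#'   labeled).
#' @export
graph_to_events <- function(g, tokens) {
  if (is_discarded(g) || length(g$node_labels) == 0L) return(list())
  labeled <- as.integer(names(g$node_labels))
  for (i in labeled) {
    out <- g$edges[g$edges$src == i, , drop = FALSE]
    if (!any(out$role == "THEME"))
      stop(sprintf("labeled node %d has no THEME edge", i))
  }

  if (nrow(g$edges)) {
    ig <- .role_igraph(g$edges, g$n_tokens)
    if (!igraph::is_dag(ig)) stop("role-edge graph is cyclic")
    topo <- as.integer(igraph::topo_sort(ig, mode = "in")$name)
    order_nodes <- topo[topo %in% labeled]
  } else {
    order_nodes <- sort(labeled)
  }

  counter <- 0L
  new_id <- function() { counter <<- counter + 1L; paste0("E", counter) }
  events <- list()
  at_node <- stats::setNames(vector("list", g$n_tokens),
                             as.character(seq_len(g$n_tokens) - 1L))

  is_protein <- function(j) {
    row <- which(tokens$index == j)
    length(row) == 1L && !is.na(tokens$protein_id[row])
  }
  protein_id_of <- function(j) tokens$protein_id[which(tokens$index == j)]

  emit <- function(type, span, roles, targets) {
    e <- event_annotation(new_id(), type, span$char_start, span$char_end,
                          span$text, roles, targets)
    events[[e$id]] <<- e
    e$id
  }

  for (i in order_nodes) {
    out <- g$edges[g$edges$src == i, , drop = FALSE]
    out <- out[order(out$tgt), , drop = FALSE]
    theme_t <- out$tgt[out$role == "THEME"]
    cause_t <- out$tgt[out$role == "CAUSE"]
    emitted_here <- character(0)

    cause_options <- list()
    for (j in cause_t) {
      if (is_protein(j)) cause_options <- c(cause_options, protein_id_of(j))
      else cause_options <- c(cause_options, at_node[[as.character(j)]])
    }

    for (label in sort(node_label_set(g, i))) {
      span <- .trigger_span_for(g, tokens, i, label)
      comps <- if (label == MERGED_GE_PR) label else label_components(label)

      for (comp in comps) {
        if (comp == MERGED_GE_PR) {
          for (j in theme_t[vapply(theme_t, is_protein, logical(1))]) {
            ge <- emit("Gene_expression", span, "THEME", protein_id_of(j))
            emitted_here <- c(emitted_here, ge)
            if (length(cause_options)) {
              for (co in cause_options)
                emitted_here <- c(emitted_here,
                                  emit("Positive_regulation", span,
                                       c("THEME", "CAUSE"), c(ge, co)))
            } else {
              emitted_here <- c(emitted_here,
                                emit("Positive_regulation", span, "THEME", ge))
            }
          }
        } else if (comp %in% PLAIN_TYPES) {
          for (j in theme_t[vapply(theme_t, is_protein, logical(1))])
            emitted_here <- c(emitted_here,
                              emit(comp, span, "THEME", protein_id_of(j)))
        } else if (comp %in% MULTI_PROTEIN_TYPES) {
          pj <- theme_t[vapply(theme_t, is_protein, logical(1))]
          if (length(pj))
            emitted_here <- c(emitted_here,
                              emit(comp, span, rep("THEME", length(pj)),
                                   vapply(pj, protein_id_of, character(1))))
        } else if (comp %in% EVENT_TAKING_TYPES) {
          theme_options <- list()
          for (j in theme_t) {
            if (is_protein(j)) theme_options <- c(theme_options, protein_id_of(j))
            else theme_options <- c(theme_options, at_node[[as.character(j)]])
          }
          for (th in theme_options) {
            if (length(cause_options)) {
              for (co in cause_options)
                emitted_here <- c(emitted_here,
                                  emit(comp, span, c("THEME", "CAUSE"),
                                       c(th, co)))
            } else {
              emitted_here <- c(emitted_here, emit(comp, span, "THEME", th))
            }
          }
        } else {
          stop(sprintf("unknown event type label '%s'", comp))
        }
      }
    }
    at_node[[as.character(i)]] <- as.list(emitted_here)
  }
  events
}

#' Dump event graphs as JSON lines
#'
#' One JSON object per sentence graph, with `node_labels` (token index ->
#' labels) and `edges` (src/tgt/role), for debugging and audit trails;
#' discarded graphs dump as `{"discarded": true}`.
#'
#' @param graphs list of `event_graph` (or [DISCARDED]) objects.
#' @return character vector of JSON lines.
#' @export
write_graphs_jsonl <- function(graphs) {
  vapply(graphs, function(g) {
    if (is_discarded(g))
      return(as.character(jsonlite::toJSON(list(discarded = TRUE),
                                           auto_unbox = TRUE)))
    as.character(jsonlite::toJSON(
      list(node_labels = g$node_labels,
           edges = g$edges[, c("src", "tgt", "role")]),
      auto_unbox = TRUE, dataframe = "rows"))
  }, character(1))
}

#' Reconstruct a corpus's annotations through the graph representation
#'
#' Converts each sentence's gold events into a graph and back into event
#' annotations. Sentences whose graph is [DISCARDED] (cyclic) contribute no
#' events; loops lost without merged events make the reconstruction lossy.
#' Gold trigger spans recorded during conversion are restored on the way
#' back, so the comparison measures what the graph encoding preserves.
#'
#' @inheritParams events_to_graph
#' @param corpus list of `bio_document`.
#' @return list of `bio_document` with reconstructed events.
#' @export
reconstruct_annotations <- function(corpus, use_merged = TRUE,
                                    anchor_rule = head_word) {
  lapply(corpus, function(doc) {
    all_events <- list()
    for (s in seq_along(doc$sentences)) {
      g <- events_to_graph(doc, s, use_merged = use_merged,
                           anchor_rule = anchor_rule)
      if (is_discarded(g)) next
      evs <- graph_to_events(g, doc$sentences[[s]]$tokens)
      pre <- sprintf("s%d.", s)  # make per-sentence ids document-unique
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
    doc$events <- all_events
    doc
  })
}
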