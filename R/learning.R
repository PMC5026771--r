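# Learning: the cost-sensitive Passive-Aggressive baseline and the
# Informed EM algorithm, which adjusts gold trigger annotations between
# rounds under four posterior constraints (basic, confidence,
# non-overlapping, distance). Both trainers share one M-step pass and
# store the running average of the interim weight vectors after each
# pass, using the lazy accumulator avg_T = ((T+1) W_T - U) / T with
# U = sum_t t * delta_t.

#' Training configuration
#'
#' @param passes total number of passes/rounds (default 20).
#' @param fn_cost_ratio cost multiplier for false negative triggers and
#'   edges relative to false positives (default 3.8).
#' @param init_rounds initial M-step-only rounds of Informed EM before the
#'   E step starts (default 5).
#' @param updated_cost_multiplier cost multiplier for sentences whose
#'   adjusted graph has been updated (default 10); the flag persists once
#'   set.
#' @param alpha confidence constraint constant (minimum relative score
#'   improvement of a candidate adjusted graph).
#' @param beta distance constraint constant, in word tokens.
#' @param use_noc enforce the non-overlapping constraint.
#' @param use_basic enforce the basic constraint; disabling it together
#'   with `alpha = -Inf`, `beta = Inf` and `use_noc = FALSE` gives the
#'   unconstrained (pure EM) variant.
#' @param seed integer seed (recorded; training itself iterates in fixed
#'   document order and draws no random numbers).
#' @return a `training_config` list.
#' @export
training_config <- function(passes = 20L, fn_cost_ratio = 3.8,
                            init_rounds = 5L, updated_cost_multiplier = 10,
                            alpha = 0.3, beta = 2, use_noc = FALSE,
                            use_basic = TRUE, seed = 1L) {
  stopifnot(passes >= init_rounds, beta >= 0)
  structure(list(passes = as.integer(passes), fn_cost_ratio = fn_cost_ratio,
                 init_rounds = as.integer(init_rounds),
                 updated_cost_multiplier = updated_cost_multiplier,
                 alpha = alpha, beta = beta, use_noc = use_noc,
                 use_basic = use_basic, seed = as.integer(seed)),
            class = "training_config")
}

#' Cost of predicting `pred` when `gold` is correct
#'
#' False positive node labels and role edges cost 1, false negatives cost
#' `fn_ratio` (default 3.8), and a role substitution (THEME for CAUSE or
#' vice versa) counts as one of each.
#'
#' @param gold,pred assignments over the same mask.
#' @param fn_ratio false-negative cost ratio.
#' @return non-negative cost.
#' @export
assignment_cost <- function(gold, pred, fn_ratio = 3.8) {
  if (length(gold$node_pos) != length(pred$node_pos) ||
      length(gold$edge_lab) != length(pred$edge_lab))
    stop("gold and pred are defined over different masks")
  fp <- sum(pred$node_pos & !gold$node_pos)
  fn <- sum(gold$node_pos & !pred$node_pos)
  gr <- gold$edge_lab; pr <- pred$edge_lab
  fp <- fp + sum(pr != "NEG" & gr == "NEG")
  fn <- fn + sum(gr != "NEG" & pr == "NEG")
  subst <- sum(gr != "NEG" & pr != "NEG" & gr != pr)
  fp + fn * fn_ratio + subst * (1 + fn_ratio)
}

# sparse difference Psi(gold) - Psi(pred) of the joint feature maps,
# aggregated per weight column
.assignment_delta <- function(prep, gold, pred) {
  cols <- integer(0); idxs <- list(); vals <- list()
  add <- function(col, idx, val) {
    cols[[length(cols) + 1L]] <<- col
    idxs[[length(idxs) + 1L]] <<- idx
    vals[[length(vals) + 1L]] <<- val
  }
  slots <- prep$node_slots
  for (k in which(gold$node_pos != pred$node_pos)) {
    phi <- prep$node_phi[[as.character(slots$tok[k])]]
    sign <- if (gold$node_pos[k]) 2 else -2
    add(slots$col[k], phi$idx, sign * phi$val)
  }
  for (k in which(gold$edge_lab != pred$edge_lab)) {
    phi <- prep$edge_phi[[k]]
    add(prep$edge_cols[match(gold$edge_lab[k], EDGE_LABELS)],
        phi$idx, phi$val)
    add(prep$edge_cols[match(pred$edge_lab[k], EDGE_LABELS)],
        phi$idx, -phi$val)
  }
  if (length(cols) == 0L)
    return(list(col = integer(0), idx = list(), val = list(), norm2 = 0))
  out_col <- integer(0); out_idx <- list(); out_val <- list(); norm2 <- 0
  for (col in unique(cols)) {
    sel <- which(cols == col)
    idx <- unlist(idxs[sel]); val <- unlist(vals[sel])
    agg <- rowsum(val, idx)
    ids <- as.integer(rownames(agg)); v <- as.numeric(agg)
    keep <- v != 0
    out_col <- c(out_col, col)
    out_idx[[length(out_idx) + 1L]] <- ids[keep]
    out_val[[length(out_val) + 1L]] <- v[keep]
    norm2 <- norm2 + sum(v[keep]^2)
  }
  list(col = out_col, idx = out_idx, val = out_val, norm2 = norm2)
}

#' Passive-Aggressive update
#'
#' Minimal-norm modification of the weights making the gold assignment's
#' score exceed the prediction's by at least the incurred cost:
#' \eqn{w \leftarrow w + \tau \Delta} with
#' \eqn{\Delta = \Psi(gold) - \Psi(pred)} and
#' \eqn{\tau = \max(0, score(pred) - score(gold) + cost) / \|\Delta\|^2}.
#' If the two assignments share the same feature map the weights are
#' returned unchanged.
#'
#' @param W weight matrix.
#' @param prep prepared sentence.
#' @param gold,pred assignments over the sentence's mask.
#' @param cost the cost of the mistake.
#' @return list with the updated matrix `W`, the step size `tau` and the
#'   squared norm `norm2` of the difference map.
#' @export
pa_update <- function(W, prep, gold, pred, cost) {
  d <- .assignment_delta(prep, gold, pred)
  if (d$norm2 == 0) return(list(W = W, tau = 0, norm2 = 0))
  dots <- .sentence_dots(prep, W)
  s_gold <- assignment_score(gold, prep, W, dots)
  s_pred <- assignment_score(pred, prep, W, dots)
  if (!is.finite(s_gold))
    return(list(W = W, tau = 0, norm2 = d$norm2))  # gold unreachable in mask
  tau <- max(0, s_pred - s_gold + cost) / d$norm2
  if (tau > 0)
    for (k in seq_along(d$col))
      W[d$idx[[k]], d$col[k]] <- W[d$idx[[k]], d$col[k]] + tau * d$val[[k]]
  list(W = W, tau = tau, norm2 = d$norm2)
}

# one M-step pass over the prepared sentences; golds[[si]] may be NULL
# (sentence skipped, e.g. discarded gold graph)
.m_step_pass <- function(state, prepc, golds, cost_mult, config) {
  for (si in seq_along(prepc$sentences)) {
    rec <- prepc$sentences[[si]]
    gold <- golds[[si]]
    state$t <- state$t + 1L
    if (is.null(gold)) next
    pred <- decode(rec, state$W)$pass1
    if (assignments_equal(pred, gold)) next
    cost <- assignment_cost(gold, pred, config$fn_cost_ratio) * cost_mult[si]
    d <- .assignment_delta(rec, gold, pred)
    if (d$norm2 == 0) next
    dots <- .sentence_dots(rec, state$W)
    s_gold <- assignment_score(gold, rec, state$W, dots)
    s_pred <- assignment_score(pred, rec, state$W, dots)
    if (!is.finite(s_gold)) next
    tau <- max(0, s_pred - s_gold + cost) / d$norm2
    if (tau == 0) next
    for (k in seq_along(d$col)) {
      dv <- tau * d$val[[k]]
      state$W[d$idx[[k]], d$col[k]] <- state$W[d$idx[[k]], d$col[k]] + dv
      state$U[d$idx[[k]], d$col[k]] <- state$U[d$idx[[k]], d$col[k]] +
        state$t * dv
    }
  }
  invisible(state)
}

.avg_model <- function(state, prepc) {
  W <- if (state$t > 0) ((state$t + 1) * state$W - state$U) / state$t
  else state$W
  new_iem_model(W, prepc$fidx, prepc$all_labels, prepc$node_labels)
}

.new_train_state <- function(prepc) {
  n <- max(prepc$fidx$n, 1L)
  e <- new.env(parent = emptyenv())
  e$W <- matrix(0, n, length(prepc$all_labels),
                dimnames = list(NULL, prepc$all_labels))
  e$U <- matrix(0, n, length(prepc$all_labels))
  e$t <- 0L
  e
}

#' Train the Passive-Aggressive baseline
#'
#' Starts from zero weights and takes `config$passes` passes over the
#' corpus in fixed document order; on each mistaken sentence the weights
#' receive a cost-sensitive PA update. After each pass the running average
#' of all interim weight vectors is stored as that pass's model.
#'
#' @param corpus list of `bio_document` with gold events, or a prepared
#'   corpus from [prepare_corpus()].
#' @param lex,stemmed_lex pruned trigger lexicons (ignored when `corpus`
#'   is already prepared).
#' @param config a [training_config()].
#' @return object of class `iem_fit`: list with `models` (one averaged
#'   `iem_model` per pass), `final_W`, `config`, `prep`.
#' @export
train_baseline <- function(corpus, lex = NULL, stemmed_lex = NULL,
                           config = training_config()) {
  prepc <- if (!is.null(corpus$sentences)) corpus
  else prepare_corpus(corpus, lex, stemmed_lex)
  golds <- lapply(prepc$sentences, function(rec) rec$gold_assign)
  cost_mult <- rep(1, length(prepc$sentences))
  state <- .new_train_state(prepc)
  models <- vector("list", config$passes)
  for (pass in seq_len(config$passes)) {
    .m_step_pass(state, prepc, golds, cost_mult, config)
    models[[pass]] <- .avg_model(state, prepc)
  }
  structure(list(models = models, final_W = state$W, config = config,
                 prep = prepc),
            class = "iem_fit")
}

# ---- the four posterior constraints --------------------------------------

# typed event structure of a graph: the set of event types present and the
# set of (parent type, role, child kind) triples, where child kind is a
# protein mention id or a child event type; triggers are ignored
typed_structure <- function(g, tokens) {
  evs <- graph_to_events(g, tokens)
  types <- unique(vapply(evs, `[[`, character(1), "type"))
  triples <- character(0)
  type_of <- function(id) evs[[id]]$type
  for (e in evs) {
    for (k in seq_len(nrow(e$args))) {
      tgt <- e$args$target[k]
      kind <- if (tgt %in% names(evs)) type_of(tgt) else tgt
      triples <- c(triples, paste(e$type, e$args$role[k], kind))
    }
  }
  list(types = sort(types), triples = sort(unique(triples)))
}

#' Basic constraint
#'
#' The candidate graph must encode the same event types and the same typed
#' argument structure (parent event type, role, child kind) as the gold
#' graph; event triggers are not compared.
#'
#' @param cand_struct,gold_struct typed structures (internally computed
#'   from graphs).
#' @return logical.
#' @export
basic_constraint <- function(cand_struct, gold_struct) {
  setequal(cand_struct$types, gold_struct$types) &&
    setequal(cand_struct$triples, gold_struct$triples)
}

#' Confidence constraint
#'
#' Requires the relative score improvement of the candidate graph over the
#' current adjusted graph to reach the confidence constant:
#' `(candidate - current) / max(|current|, 1e-8) >= alpha`.
#'
#' @param candidate_score,current_score finite model scores.
#' @param alpha confidence constraint constant.
#' @return logical.
#' @export
confidence_constraint <- function(candidate_score, current_score, alpha) {
  if (!is.finite(candidate_score) || !is.finite(current_score)) return(FALSE)
  (candidate_score - current_score) / max(abs(current_score), 1e-8) >= alpha
}

# distinct anchors of each base event type in a graph (composite labels
# count for every component)
.anchors_by_type <- function(g) {
  out <- list()
  for (key in names(g$node_labels)) {
    for (lab in g$node_labels[[key]])
      for (comp in label_components(lab))
        out[[comp]] <- unique(c(out[[comp]], as.integer(key)))
  }
  out
}

#' Non-overlapping constraint
#'
#' Two gold event triggers of the same type may not be mapped onto a
#' single word: for each event type, the candidate graph must carry at
#' least as many distinct anchor words of that type as there are distinct
#' gold trigger spans of that type.
#'
#' @param cand_graph candidate `event_graph`.
#' @param gold_graph gold `event_graph` (with recorded trigger spans).
#' @return logical.
#' @export
non_overlapping_constraint <- function(cand_graph, gold_graph) {
  ts <- gold_graph$trigger_spans
  if (nrow(ts) == 0L) return(TRUE)
  cand_anchors <- .anchors_by_type(cand_graph)
  comps <- lapply(ts$label, label_components)
  for (ty in unique(unlist(comps))) {
    rows <- which(vapply(comps, function(cc) ty %in% cc, logical(1)))
    n_gold <- length(unique(paste(ts$char_start[rows], ts$char_end[rows])))
    if (length(cand_anchors[[ty]] %||% integer(0)) < n_gold) return(FALSE)
  }
  TRUE
}

#' Distance constraint
#'
#' Every anchor of type `e` in the current adjusted graph must have some
#' candidate anchor of the same type within `beta` word tokens.
#'
#' @param cand_graph candidate `event_graph`.
#' @param current_graph current adjusted `event_graph`.
#' @param beta distance constant in word tokens.
#' @param tokens sentence token table.
#' @return logical.
#' @export
distance_constraint <- function(cand_graph, current_graph, beta, tokens) {
  cur <- .anchors_by_type(current_graph)
  cand <- .anchors_by_type(cand_graph)
  for (ty in names(cur)) {
    for (i in cur[[ty]]) {
      js <- cand[[ty]] %||% integer(0)
      if (length(js) == 0L) return(FALSE)
      dmin <- min(vapply(js, function(j)
        if (j == i) 0L else token_distance(i, j, tokens), integer(1)))
      if (dmin > beta) return(FALSE)
    }
  }
  TRUE
}

#' Train with the Informed EM algorithm
#'
#' Maintains an adjusted annotation set initialized from the gold graphs.
#' The first `init_rounds` rounds apply only the M step (identical to the
#' baseline). Afterwards each round first runs the E step: every
#' sentence is decoded with the current interim weights, and when the
#' predicted graph differs from the current adjusted graph and satisfies
#' the basic, confidence, (optionally) non-overlapping and distance
#' constraints, it replaces the adjusted graph and the sentence is flagged
#' as updated; the following M step penalizes errors on updated sentences
#' `updated_cost_multiplier` times more severely. With `alpha` above any
#' achievable score ratio no update is ever accepted and the model
#' sequence equals the baseline's.
#'
#' @inheritParams train_baseline
#' @return an `iem_fit` with additional elements `adjusted` (per-sentence
#'   final adjusted graphs), `updated` (logical flags) and `history`
#'   (data.frame log of accepted updates: round, sentence, scores).
#' @export
informed_em <- function(corpus, lex = NULL, stemmed_lex = NULL,
                        config = training_config()) {
  prepc <- if (!is.null(corpus$sentences)) corpus
  else prepare_corpus(corpus, lex, stemmed_lex)
  n_sen <- length(prepc$sentences)

  adj_graph <- lapply(prepc$sentences, function(rec) rec$gold_graph)
  adj_assign <- lapply(prepc$sentences, function(rec) rec$gold_assign)
  gold_struct <- lapply(prepc$sentences, function(rec) {
    if (is_discarded(rec$gold_graph)) NULL
    else typed_structure(rec$gold_graph, rec$tokens)
  })
  updated <- rep(FALSE, n_sen)
  history <- list()

  state <- .new_train_state(prepc)
  models <- vector("list", config$passes)

  for (round in seq_len(config$passes)) {
    if (round > config$init_rounds) {
      for (si in seq_len(n_sen)) {
        rec <- prepc$sentences[[si]]
        if (is.null(adj_assign[[si]])) next  # discarded gold: never adjusted
        dec <- decode(rec, state$W)
        cand_g <- assignment_to_graph(dec$final, rec)
        if (graphs_equal(cand_g, adj_graph[[si]])) next

        cand_a <- graph_to_assignment(cand_g, rec)
        dots <- .sentence_dots(rec, state$W)
        cand_score <- assignment_score(cand_a, rec, state$W, dots)
        cur_score <- assignment_score(adj_assign[[si]], rec, state$W, dots)

        ok_basic <- !isTRUE(config$use_basic) ||
          basic_constraint(typed_structure(cand_g, rec$tokens),
                           gold_struct[[si]])
        ok_conf <- ok_basic &&
          confidence_constraint(cand_score, cur_score, config$alpha)
        ok_noc <- ok_conf && (!config$use_noc ||
                                non_overlapping_constraint(cand_g,
                                                           rec$gold_graph))
        ok_dist <- ok_noc &&
          distance_constraint(cand_g, adj_graph[[si]], config$beta,
                              rec$tokens)
        if (!ok_dist) next

        history[[length(history) + 1L]] <- list(
          round = round, sentence = si, doc_id = rec$doc_id,
          sent = rec$sent, cand_score = cand_score, cur_score = cur_score,
          old_graph = adj_graph[[si]], new_graph = cand_g)
        adj_graph[[si]] <- cand_g
        adj_assign[[si]] <- cand_a
        updated[si] <- TRUE
      }
    }
    cost_mult <- ifelse(updated, config$updated_cost_multiplier, 1)
    .m_step_pass(state, prepc, adj_assign, cost_mult, config)
    models[[round]] <- .avg_model(state, prepc)
  }

  hist_df <- if (length(history)) do.call(rbind, lapply(history, function(h)
    data.frame(round = h$round, sentence = h$sentence, doc_id = h$doc_id,
               sent = h$sent, cand_score = h$cand_score,
               cur_score = h$cur_score, stringsAsFactors = FALSE)))
  else data.frame(round = integer(0), sentence = integer(0),
                  doc_id = character(0), sent = integer(0),
                  cand_score = numeric(0), cur_score = numeric(0))

  structure(list(models = models, final_W = state$W, config = config,
                 prep = prepc, adjusted = adj_graph, updated = updated,
                 history = hist_df, history_graphs = history),
            class = "iem_fit")
}

#' @export
print.iem_fit <- function(x, ...) {
  cat(sprintf("<iem_fit: %d pass(es), %d sentence(s)%s>\n",
              length(x$models), length(x$prep$sentences),
              if (!is.null(x$updated))
                sprintf(", %d adjusted", sum(x$updated)) else ""))
  invisible(x)
}

#' Evaluate each pass's averaged model on a held-out corpus
#'
#' @param fit an `iem_fit`.
#' @param heldout list of `bio_document` with gold events.
#' @param lex,stemmed_lex the lexicons used for training.
#' @param mode matching mode for [match_events()].
#' @return data.frame with one row per pass: `pass`, `recall`,
#'   `precision`, `f1`.
#' @export
evaluate_models <- function(fit, heldout, lex, stemmed_lex = NULL,
                            mode = "exact") {
  prep <- prepare_corpus(heldout, lex, stemmed_lex,
                         node_labels = fit$prep$node_labels,
                         fidx = fit$prep$fidx, add = FALSE, gold = FALSE)
  rows <- lapply(seq_along(fit$models), function(m) {
    W <- fit$models[[m]]$W
    matched <- 0L; n_gold <- 0L; n_pred <- 0L
    by_doc <- split(seq_along(prep$sentences),
                    vapply(prep$sentences, `[[`, integer(1), "doc"))
    for (di in seq_along(heldout)) {
      pred_events <- list()
      for (si in by_doc[[as.character(di)]]) {
        rec <- prep$sentences[[si]]
        a <- decode(rec, W)$final
        g <- assignment_to_graph(a, rec)
        evs <- graph_to_events(g, rec$tokens)
        pre <- sprintf("s%d.", rec$sent)
        for (e in evs) {
          e$id <- paste0(pre, e$id)
          ref <- grepl("^E[0-9]+$", e$args$target)
          e$args$target[ref] <- paste0(pre, e$args$target[ref])
          pred_events[[e$id]] <- e
        }
      }
      mres <- match_events(heldout[[di]]$events, pred_events, mode = mode)
      matched <- matched + mres$matched
      n_gold <- n_gold + mres$gold
      n_pred <- n_pred + mres$predicted
    }
    pm <- prf(list(matched = matched, gold = n_gold, predicted = n_pred))
    data.frame(pass = m, recall = pm[1], precision = pm[2], f1 = pm[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
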