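# Event-level matching and recall/precision/F-score, the reconstruction
# experiment, and the one-tailed paired t-test used to compare training
# runs pass by pass.

# does pred span [ps,pe) fall within gold span [gs,ge) extended one word
# each side? Without the document text the extension cannot be located, so
# span overlap is required instead.
.span_approx_ok <- function(gs, ge, ps, pe, text = NULL) {
  if (is.null(text)) return(ps < ge && pe > gs)
  left <- gs
  pre <- substr(text, 1, gs)
  m <- regmatches(pre, regexec("[[:alnum:]]+[^[:alnum:]]*$", pre))[[1]]
  if (length(m)) left <- gs - nchar(m[1])
  right <- ge
  post <- substring(text, ge + 1)
  m <- regmatches(post, regexec("^[^[:alnum:]]*[[:alnum:]]+", post))[[1]]
  if (length(m)) right <- ge + nchar(m[1])
  ps >= left && pe <= right
}

# recursive pairwise event match; `nested` switches to the relaxed
# type+THEME rule of approximate-recursive mode
.ev_match <- function(gid, pid, gold, pred, mode, text, nested = FALSE) {
  g <- gold[[gid]]; p <- pred[[pid]]
  if (g$type != p$type) return(FALSE)
  if (!nested) {
    span_ok <- if (mode == "approx_span")
      .span_approx_ok(g$trigger_start, g$trigger_end,
                      p$trigger_start, p$trigger_end, text)
    else g$trigger_start == p$trigger_start && g$trigger_end == p$trigger_end
    if (!span_ok) return(FALSE)
  }
  roles <- if (nested) "THEME" else c("THEME", "CAUSE")
  nested_next <- nested || mode == "approx_recursive"
  for (role in roles) {
    gt <- g$args$target[g$args$role == role]
    pt <- p$args$target[p$args$role == role]
    g_ev <- gt[gt %in% names(gold)]; g_pr <- sort(gt[!gt %in% names(gold)])
    p_ev <- pt[pt %in% names(pred)]; p_pr <- sort(pt[!pt %in% names(pred)])
    if (!identical(g_pr, p_pr)) return(FALSE)
    if (length(g_ev) != length(p_ev)) return(FALSE)
    if (length(g_ev)) {
      # bijection between nested event targets (argument lists are tiny)
      used <- rep(FALSE, length(p_ev))
      for (ge in g_ev) {
        hit <- FALSE
        for (k in seq_along(p_ev)) {
          if (used[k]) next
          if (.ev_match(ge, p_ev[k], gold, pred, mode, text,
                        nested = nested_next)) {
            used[k] <- TRUE; hit <- TRUE; break
          }
        }
        if (!hit) return(FALSE)
      }
    }
  }
  TRUE
}

#' Match predicted events against gold events
#'
#' Greedy deterministic one-to-one matching: gold events are visited in
#' order of trigger offset, type and id, and each takes the first unmatched
#' compatible prediction. In `exact` mode the type, trigger span and full
#' recursive argument structure must agree; `approx_span` relaxes the
#' trigger span to lie within the gold span extended one word each side
#' (requires `text`; plain span overlap otherwise); `approx_recursive`
#' additionally compares nested event arguments on type and THEME only.
#'
#' @param gold,pred named lists of `event_annotation` from the same
#'   document (names = event ids; event-valued arguments refer into the
#'   same list).
#' @param mode `"exact"`, `"approx_span"` or `"approx_recursive"`.
#' @param text optional document text for locating word boundaries.
#' @return list with `matched`, `gold`, `predicted` counts, the matched
#'   `pairs` (data.frame of ids) and `mode`.
#' @export
match_events <- function(gold, pred, mode = c("exact", "approx_span",
                                              "approx_recursive"),
                         text = NULL) {
  mode <- match.arg(mode)
  if (length(gold)) names(gold) <- vapply(gold, `[[`, character(1), "id")
  if (length(pred)) names(pred) <- vapply(pred, `[[`, character(1), "id")
  ord <- function(evs) {
    if (length(evs) == 0L) return(character(0))
    o <- order(vapply(evs, `[[`, integer(1), "trigger_start"),
               vapply(evs, `[[`, character(1), "type"),
               names(evs))
    names(evs)[o]
  }
  g_ids <- ord(gold); p_ids <- ord(pred)
  used <- stats::setNames(rep(FALSE, length(p_ids)), p_ids)
  pairs <- list()
  for (gid in g_ids) {
    for (pid in p_ids) {
      if (used[[pid]]) next
      if (.ev_match(gid, pid, gold, pred, mode, text)) {
        used[[pid]] <- TRUE
        pairs[[length(pairs) + 1L]] <- data.frame(
          gold_id = gid, pred_id = pid, stringsAsFactors = FALSE)
        break
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gold_id = character(0), pred_id = character(0))
  list(matched = nrow(pairs), gold = length(gold), predicted = length(pred),
       pairs = pairs, mode = mode)
}

#' Recall, precision and F1 from a match result
#'
#' Empty-set conventions: a ratio 0/0 is 1.0, and F1 is 0 when
#' recall + precision is 0.
#'
#' @param m a match result (list with `matched`, `gold`, `predicted`).
#' @return named numeric `c(recall, precision, f1)`.
#' @export
prf <- function(m) {
  r <- if (m$gold == 0L) 1 else m$matched / m$gold
  p <- if (m$predicted == 0L) 1 else m$matched / m$predicted
  f <- if (r + p == 0) 0 else 2 * r * p / (r + p)
  c(recall = r, precision = p, f1 = f)
}

#' F-score of reconstructing annotations through the graph representation
#'
#' Converts gold annotations to graphs and back (see
#' [reconstruct_annotations()]) and scores the reconstruction against the
#' originals with exact matching, overall and per event type. Events lost
#' to discarded (cyclic) graphs or removed loops lower recall; events
#' over-generated by the conversion lower precision.
#'
#' @inheritParams reconstruct_annotations
#' @return list with `overall` (named numeric recall/precision/f1),
#'   `by_type` (data.frame type/matched/gold/predicted/recall/precision/
#'   f1) and total `counts`.
#' @export
reconstruction_f1 <- function(corpus, use_merged = TRUE,
                              anchor_rule = head_word) {
  recon <- reconstruct_annotations(corpus, use_merged = use_merged,
                                   anchor_rule = anchor_rule)
  tot <- list(matched = 0L, gold = 0L, predicted = 0L)
  by_type <- list()
  bump <- function(ty, field, by = 1L) {
    cur <- by_type[[ty]] %||% c(matched = 0L, gold = 0L, predicted = 0L)
    cur[[field]] <- cur[[field]] + by
    by_type[[ty]] <<- cur
  }
  for (di in seq_along(corpus)) {
    gold <- corpus[[di]]$events; pred <- recon[[di]]$events
    m <- match_events(gold, pred, mode = "exact")
    tot$matched <- tot$matched + m$matched
    tot$gold <- tot$gold + m$gold
    tot$predicted <- tot$predicted + m$predicted
    for (e in gold) bump(e$type, "gold")
    for (e in pred) bump(e$type, "predicted")
    for (k in seq_len(nrow(m$pairs)))
      bump(gold[[m$pairs$gold_id[k]]]$type, "matched")
  }
  bt <- do.call(rbind, lapply(sort(names(by_type)), function(ty) {
    x <- as.list(by_type[[ty]])
    pm <- prf(x)
    data.frame(type = ty, matched = x$matched, gold = x$gold,
               predicted = x$predicted, recall = pm[1], precision = pm[2],
               f1 = pm[3], stringsAsFactors = FALSE)
  }))
  rownames(bt) <- NULL
  list(overall = prf(tot), by_type = bt, counts = tot)
}

#' One-tailed paired Student's t-test
#'
#' Tests H1: mean(a - b) > 0 over aligned pairs. With zero variance of the
#' differences the p-value degenerates to 0 (positive mean), 1 (negative
#' mean) or 0.5 (all differences zero, the t = 0 boundary).
#'
#' @param scores_a,scores_b equal-length numeric vectors (length >= 2),
#'   aligned by pass number.
#' @return the p-value.
#' @export
paired_one_tailed_ttest <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2L)
  d <- scores_a - scores_b
  if (stats::sd(d) == 0) {
    m <- mean(d)
    return(if (m > 0) 0 else if (m < 0) 1 else 0.5)
  }
  stats::t.test(scores_a, scores_b, paired = TRUE,
                alternative = "greater")$p.value
}
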