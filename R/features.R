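# Sparse feature vectors for words and word pairs, and the candidate masks
# that force apparently-impossible labels to 'negative'. Feature vectors are
# named numeric vectors; binary features have value 1, reliability-valued
# features lie in (0, 1].

BOUNDARY <- "<S>"

# rendering of a token inside n-grams and path sequences: protein mentions
# become the symbol PROTEIN, other tokens baseform:POS
.render_token <- function(tokens, i) {
  row <- which(tokens$index == i)
  if (!is.na(tokens$protein_id[row])) "PROTEIN"
  else paste0(tokens$baseform[row], ":", tokens$pos[row])
}

.render_all <- function(tokens) {
  ifelse(!is.na(tokens$protein_id), "PROTEIN",
         paste0(tokens$baseform, ":", tokens$pos))
}

# combine duplicate feature names by max
.fv <- function(names, values) {
  if (length(names) == 0L) return(stats::setNames(numeric(0), character(0)))
  v <- tapply(values, names, max)
  stats::setNames(as.numeric(v), names(v))
}

#' Linear distance between two tokens, skipping punctuation
#'
#' The absolute difference of word-token positions, where punctuation
#' tokens do not count as positions. This is the distance printed in the
#' `Protein-Distance` and `Trigger-Distance` feature names.
#'
#' @param i,j 0-based token indices.
#' @param tokens sentence token table.
#' @return non-negative integer.
#' @export
token_distance <- function(i, j, tokens) {
  pos <- cumsum(!is_punct_token(tokens$surface))
  ri <- which(tokens$index == i); rj <- which(tokens$index == j)
  stopifnot(length(ri) == 1L, length(rj) == 1L)
  abs(pos[ri] - pos[rj])
}

# candidate reliability maps for every token of a sentence
.sentence_candidates <- function(tokens, lex, stemmed_lex = NULL) {
  lapply(seq_len(nrow(tokens)), function(r) {
    if (!is.na(tokens$protein_id[r])) return(numeric(0))
    candidate_event_types(tokens$surface[r], tokens$baseform[r],
                          lex, stemmed_lex)
  })
}

#' Shortest dependency path between two tokens
#'
#' Edges are treated as undirected; among shortest paths the one with the
#' lexicographically smallest token-index sequence is returned. Each step
#' records the dependency relation and a direction marker: `GOV` when the
#' neighbouring path node is the perspective node's governor, `MOD` when it
#' is its dependent. The perspective node of a step is the path-interior
#' node (the right node for the first step, the left node afterwards).
#'
#' @param deps dependency edge table.
#' @param i,j distinct 0-based token indices.
#' @param n_tokens number of tokens in the sentence.
#' @return `NULL` if disconnected, else a list with `nodes` (token index
#'   sequence from `i` to `j`) and `steps` (data.frame `rel`, `dir`).
#' @export
shortest_dependency_path <- function(deps, i, j, n_tokens) {
  stopifnot(i != j)
  if (nrow(deps) == 0L) return(NULL)
  adj <- replicate(n_tokens, integer(0), simplify = FALSE)
  for (k in seq_len(nrow(deps))) {
    g <- deps$gov[k] + 1L; d <- deps$dep[k] + 1L
    adj[[g]] <- c(adj[[g]], d - 1L)
    adj[[d]] <- c(adj[[d]], g - 1L)
  }
  adj <- lapply(adj, function(x) sort(unique(x)))
  bfs <- function(src) {
    dist <- rep(NA_integer_, n_tokens)
    dist[src + 1L] <- 0L
    frontier <- src
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) for (v in adj[[u + 1L]])
        if (is.na(dist[v + 1L])) { dist[v + 1L] <- dist[u + 1L] + 1L
          nxt <- c(nxt, v) }
      frontier <- nxt
    }
    dist
  }
  di <- bfs(i); dj <- bfs(j)
  if (is.na(dj[i + 1L])) return(NULL)
  D <- dj[i + 1L]
  # greedy walk from i: smallest-index neighbour still on a shortest path
  nodes <- i
  cur <- i
  while (cur != j) {
    cand <- adj[[cur + 1L]]
    ok <- cand[!is.na(di[cand + 1L]) & !is.na(dj[cand + 1L]) &
                 di[cand + 1L] == di[cur + 1L] + 1L &
                 di[cand + 1L] + dj[cand + 1L] == D]
    cur <- min(ok)
    nodes <- c(nodes, cur)
  }
  k <- length(nodes)
  rel_of <- function(u, v) {
    hit <- deps[(deps$gov == u & deps$dep == v) |
                  (deps$gov == v & deps$dep == u), , drop = FALSE]
    hit <- hit[order(hit$rel), , drop = FALSE]
    hit[1, , drop = FALSE]
  }
  steps <- lapply(seq_len(k - 1L), function(t) {
    u <- nodes[t]; v <- nodes[t + 1L]
    e <- rel_of(u, v)
    persp <- if (t == 1L) v else u
    other <- if (t == 1L) u else v
    dir <- if (e$gov == other) "GOV" else "MOD"  # perspective node's view
    data.frame(rel = e$rel, dir = dir, stringsAsFactors = FALSE)
  })
  list(nodes = nodes, steps = do.call(rbind, steps))
}

# n-grams (n = 2..4) of a sequence of rendered items; each window is one
# feature named "<prefix><n>:item item ..."
.seq_ngrams <- function(items, prefix) {
  out <- character(0)
  L <- length(items)
  for (n in 2:4) {
    if (L < n) next
    for (s in seq_len(L - n + 1L))
      out <- c(out, paste0(prefix, n, ":",
                           paste(items[s:(s + n - 1L)], collapse = " ")))
  }
  out
}

#' Feature vector of a single word
#'
#' Lexical indicators (surface, baseform, POS), per-type lexicon
#' reliability features, center-marked n-grams (n = 2..4) over baseform:POS
#' pairs with protein mentions rendered as `PROTEIN` and sentence
#' boundaries as an explicit symbol, `Protein-Distance` indicators,
#' reliability-valued `Trigger-Distance` features, and governor/modifier
#' features for each dependency edge at the word (in both baseform-self and
#' surface-self renderings).
#'
#' @param i 0-based token index.
#' @param tokens,deps sentence token and dependency tables.
#' @param lex,stemmed_lex pruned trigger lexicons (used for reliability and
#'   trigger-distance values); may be `NULL` for purely contextual vectors.
#' @param cand optional precomputed per-token candidate reliability maps
#'   (from the internal sentence cache); computed on the fly if missing.
#' @return named numeric feature vector.
#' @export
node_feature_vector <- function(i, tokens, deps, lex = NULL,
                                stemmed_lex = NULL, cand = NULL) {
  row <- which(tokens$index == i)
  if (is.null(cand)) {
    cand <- if (is.null(lex)) replicate(nrow(tokens), numeric(0),
                                        simplify = FALSE)
    else .sentence_candidates(tokens, lex, stemmed_lex)
  }
  nm <- character(0); val <- numeric(0)
  add <- function(n, v = 1) { nm <<- c(nm, n); val <<- c(val, v) }

  add(paste0("SURF:", tolower(tokens$surface[row])))
  add(paste0("BASE:", tokens$baseform[row]))
  add(paste0("POS:", tokens$pos[row]))

  ci <- cand[[row]]
  for (ty in names(ci)) add(paste0("LEX:", ty), ci[[ty]])

  # center-marked n-grams over baseform:POS with boundary padding
  rend <- .render_all(tokens)
  rend[row] <- paste0("[", rend[row], "]")
  padded <- c(rep(BOUNDARY, 3), rend, rep(BOUNDARY, 3))
  center <- row + 3L
  for (n in 2:4) {
    for (s in (center - n + 1L):center) {
      win <- padded[s:(s + n - 1L)]
      add(paste0("NG", n, ":", paste(win, collapse = " ")))
    }
  }

  # distances to protein mentions (binary) and to other candidate words
  # (valued at the other word's best reliability)
  for (r in seq_len(nrow(tokens))) {
    if (r == row) next
    if (!is.na(tokens$protein_id[r]))
      add(paste0("Protein-Distance:",
                 token_distance(i, tokens$index[r], tokens)))
    cr <- cand[[r]]
    if (length(cr))
      add(paste0("Trigger-Distance:",
                 token_distance(i, tokens$index[r], tokens)), max(cr))
  }

  # governor and modifier features, self rendered both ways
  self_base <- paste0(tokens$baseform[row], ":", tokens$pos[row])
  self_surf <- paste0(tokens$surface[row], ":", tokens$pos[row])
  if (nrow(deps)) {
    gov_edges <- deps[deps$dep == i, , drop = FALSE]
    for (k in seq_len(nrow(gov_edges))) {
      other <- .render_token(tokens, gov_edges$gov[k])
      add(paste0(self_base, "-GOV(", gov_edges$rel[k], ")-", other))
      add(paste0(self_surf, "-GOV(", gov_edges$rel[k], ")-", other))
    }
    mod_edges <- deps[deps$gov == i, , drop = FALSE]
    for (k in seq_len(nrow(mod_edges))) {
      other <- .render_token(tokens, mod_edges$dep[k])
      add(paste0(self_base, "-MOD(", mod_edges$rel[k], ")-", other))
      add(paste0(self_surf, "-MOD(", mod_edges$rel[k], ")-", other))
    }
  }
  .fv(nm, val)
}

#' Feature vector of an ordered word pair
#'
#' Both endpoints' word features (namespaced by endpoint), a shortest-path
#' length indicator, and n-grams (n = 2..4) plus the full sequence of three
#' renderings of the shortest dependency path between the words: the token
#' sequence (baseform:POS per path token), the dependency sequence
#' (direction(relation) per step) and the interleaved token-dependency
#' sequence. Disconnected pairs carry endpoint features only.
#'
#' @inheritParams node_feature_vector
#' @param j 0-based index of the target token.
#' @param node_cache optional named list of precomputed word feature
#'   vectors (names = token indices as character).
#' @return named numeric feature vector.
#' @export
edge_feature_vector <- function(i, j, tokens, deps, lex = NULL,
                                stemmed_lex = NULL, cand = NULL,
                                node_cache = NULL) {
  get_node <- function(k) {
    if (!is.null(node_cache)) {
      v <- node_cache[[as.character(k)]]
      if (!is.null(v)) return(v)
    }
    node_feature_vector(k, tokens, deps, lex, stemmed_lex, cand)
  }
  fi <- get_node(i); fj <- get_node(j)
  out_nm <- c(paste0("SRC::", names(fi)), paste0("TGT::", names(fj)))
  out_val <- c(unname(fi), unname(fj))

  path <- shortest_dependency_path(deps, i, j, nrow(tokens))
  if (!is.null(path)) {
    tok_seq <- vapply(path$nodes, function(k) .render_token(tokens, k),
                      character(1))
    dep_seq <- paste0(path$steps$dir, "(", path$steps$rel, ")")
    inter <- character(0)
    for (t in seq_along(dep_seq))
      inter <- c(inter, tok_seq[t], dep_seq[t])
    inter <- c(inter, tok_seq[length(tok_seq)])

    nm <- c(paste0("Path-Length:", length(dep_seq)),
            paste0("TOKSEQ:", paste(tok_seq, collapse = " ")),
            paste0("DEPSEQ:", paste(dep_seq, collapse = " ")),
            paste0("TOKDEPSEQ:", paste(inter, collapse = " ")),
            .seq_ngrams(tok_seq, "TOKSEQ"),
            .seq_ngrams(dep_seq, "DEPSEQ"),
            .seq_ngrams(inter, "TOKDEPSEQ"))
    out_nm <- c(out_nm, nm)
    out_val <- c(out_val, rep(1, length(nm)))
  }
  .fv(out_nm, out_val)
}

#' Candidate mask of a sentence
#'
#' Tokens with no entry in the (pruned) trigger lexicons are fixed to the
#' label 'negative'; admissible edges run from a lexicon-candidate word to
#' a protein token or another candidate word.
#'
#' @param tokens,deps sentence tables.
#' @param lex,stemmed_lex pruned trigger lexicons.
#' @return list with `node_candidates` (named list token index ->
#'   named numeric of admissible event types with reliabilities) and
#'   `edge_candidates` (data.frame `src`, `tgt`).
#' @export
candidate_mask <- function(tokens, deps, lex, stemmed_lex = NULL) {
  cand <- .sentence_candidates(tokens, lex, stemmed_lex)
  is_cand <- vapply(cand, length, integer(1)) > 0L
  is_prot <- !is.na(tokens$protein_id)
  node_candidates <- stats::setNames(cand[is_cand],
                                     as.character(tokens$index[is_cand]))
  src <- integer(0); tgt <- integer(0)
  for (r in which(is_cand)) {
    for (r2 in which(is_cand | is_prot)) {
      if (r2 == r) next
      src <- c(src, tokens$index[r]); tgt <- c(tgt, tokens$index[r2])
    }
  }
  list(node_candidates = node_candidates,
       edge_candidates = data.frame(src = src, tgt = tgt),
       cand = cand)
}
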