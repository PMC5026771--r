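# Reading and writing BioNLP'09-style standoff annotations (.txt/.a1/.a2),
# Stanford-dependency parse lines, and per-sentence lexical analyses.
# Character offsets are 0-based half-open throughout; token indices are
# 0-based internally (the rel(gov-i, dep-j) parse format is 1-based).

#' Build a sentence token table
#'
#' @param surface character vector of token surface forms.
#' @param baseform character vector of baseforms (defaults to lower-cased
#'   surface).
#' @param pos character vector of POS tags.
#' @param char_start,char_end integer vectors of 0-based half-open document
#'   offsets; if missing, offsets are laid out with single spaces from
#'   `offset`.
#' @param protein_id optional character vector of protein mention ids
#'   (NA where the token is not a mention).
#' @param offset document offset of the first token when laying out.
#' @return a `data.frame` with one row per token, 0-based `index` column.
#' @export
make_tokens <- function(surface, baseform = tolower(surface), pos = "NN",
                        char_start = NULL, char_end = NULL,
                        protein_id = NA_character_, offset = 0L) {
  n <- length(surface)
  pos <- rep_len(pos, n)
  protein_id <- rep_len(protein_id, n)
  if (is.null(char_start)) {
    widths <- nchar(surface)
    char_start <- offset + c(0L, cumsum(widths[-n] + 1L))
    char_end <- char_start + widths
  }
  stopifnot(all(char_start < char_end))
  data.frame(
    index = seq_len(n) - 1L, surface = surface, baseform = baseform,
    pos = pos, char_start = as.integer(char_start),
    char_end = as.integer(char_end), protein_id = protein_id,
    stringsAsFactors = FALSE
  )
}

empty_deps <- function() {
  data.frame(gov = integer(0), dep = integer(0), rel = character(0),
             stringsAsFactors = FALSE)
}

#' Construct an event annotation
#'
#' @param id event id (E-id).
#' @param type one of the nine event types.
#' @param trigger_start,trigger_end 0-based half-open character offsets of
#'   the trigger span.
#' @param trigger_text trigger surface text.
#' @param roles character vector of roles (`"THEME"`/`"CAUSE"`).
#' @param targets character vector of targets (protein T-ids or event E-ids),
#'   aligned with `roles`.
#' @return an object of class `event_annotation`.
#' @export
event_annotation <- function(id, type, trigger_start, trigger_end,
                             trigger_text, roles, targets) {
  stopifnot(length(roles) == length(targets),
            all(roles %in% c("THEME", "CAUSE")))
  structure(
    list(id = id, type = type,
         trigger_start = as.integer(trigger_start),
         trigger_end = as.integer(trigger_end),
         trigger_text = trigger_text,
         args = data.frame(role = roles, target = targets,
                           stringsAsFactors = FALSE)),
    class = "event_annotation"
  )
}

#' @export
format.event_annotation <- function(x, ...) {
  args <- paste(x$args$role, x$args$target, sep = ":", collapse = " ")
  sprintf("%s %s[%d,%d) '%s' %s", x$id, x$type, x$trigger_start,
          x$trigger_end, x$trigger_text, args)
}

#' @export
print.event_annotation <- function(x, ...) cat(format(x), "\n")

new_document <- function(id, text, proteins, events, sentences = list()) {
  structure(list(id = id, text = text, proteins = proteins,
                 events = events, sentences = sentences),
            class = "bio_document")
}

#' @export
print.bio_document <- function(x, ...) {
  cat(sprintf("<bio_document %s: %d sentence(s), %d protein(s), %d event(s)>\n",
              x$id, length(x$sentences), nrow(x$proteins), length(x$events)))
  invisible(x)
}

doc_substr <- function(text, start, end) {
  # 0-based half-open offsets into text
  substr(text, start + 1L, end)
}

.parse_t_line <- function(line, lineno) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop(sprintf("line %d: malformed T line (expected 3 tab fields): %s",
                 lineno, line))
  m <- regmatches(parts[2],
                  regexec("^(\\S+) (\\d+) (\\d+)$", parts[2]))[[1]]
  if (length(m) == 0L)
    stop(sprintf("line %d: malformed T line span field: %s", lineno, parts[2]))
  list(id = parts[1], type = m[2], start = as.integer(m[3]),
       end = as.integer(m[4]), text = parts[3])
}

.parse_e_line <- function(line, lineno) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop(sprintf("line %d: malformed E line: %s", lineno, line))
  fields <- strsplit(trimws(parts[2]), " +")[[1]]
  head <- strsplit(fields[1], ":", fixed = TRUE)[[1]]
  if (length(head) != 2L)
    stop(sprintf("line %d: malformed event head '%s'", lineno, fields[1]))
  roles <- character(0); targets <- character(0)
  for (f in fields[-1]) {
    kv <- strsplit(f, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop(sprintf("line %d: malformed argument '%s'", lineno, f))
    role <- toupper(sub("[0-9]+$", "", kv[1]))
    if (!role %in% c("THEME", "CAUSE"))
      stop(sprintf("line %d: unknown role '%s'", lineno, kv[1]))
    roles <- c(roles, role); targets <- c(targets, kv[2])
  }
  list(id = parts[1], type = head[1], trigger = head[2],
       roles = roles, targets = targets)
}

#' Read a document from standoff annotation text
#'
#' Parses the `.txt` (document text), `.a1` (protein mentions) and `.a2`
#' (event triggers and events) components of a BioNLP'09-style standoff
#' document. Modification (`M`) lines in the a2 component are ignored
#' (Task 1 only). Sentences (tokens and parses) are attached separately,
#' see [attach_sentences()].
#'
#' @param txt document text (single string, or character vector of lines
#'   joined with `"\n"`).
#' @param a1 character vector of a1 lines (or single string).
#' @param a2 character vector of a2 lines (or single string); may be empty.
#' @param id document id.
#' @return a `bio_document` with `proteins` (data.frame id/char_start/
#'   char_end/text) and `events` (named list of `event_annotation`).
#' @export
read_standoff_document <- function(txt, a1, a2 = character(0), id = "doc") {
  text <- paste(txt, collapse = "\n")
  a1 <- unlist(strsplit(paste(a1, collapse = "\n"), "\n", fixed = TRUE))
  a2 <- unlist(strsplit(paste(a2, collapse = "\n"), "\n", fixed = TRUE))
  a1 <- a1[nzchar(trimws(a1))]
  a2 <- a2[nzchar(trimws(a2))]

  prot <- list()
  for (i in seq_along(a1)) {
    t <- .parse_t_line(a1[i], i)
    got <- doc_substr(text, t$start, t$end)
    if (!identical(got, t$text))
      stop(sprintf("a1 line %d: mention text '%s' != document substring '%s'",
                   i, t$text, got))
    prot[[t$id]] <- data.frame(id = t$id, char_start = t$start,
                               char_end = t$end, text = t$text,
                               stringsAsFactors = FALSE)
  }
  proteins <- if (length(prot)) do.call(rbind, unname(prot)) else
    data.frame(id = character(0), char_start = integer(0),
               char_end = integer(0), text = character(0),
               stringsAsFactors = FALSE)

  triggers <- list(); raw_events <- list()
  for (i in seq_along(a2)) {
    line <- a2[i]
    tag <- substr(line, 1, 1)
    if (tag == "T") {
      t <- .parse_t_line(line, i)
      got <- doc_substr(text, t$start, t$end)
      if (!identical(got, t$text))
        stop(sprintf("a2 line %d: trigger text '%s' != document substring '%s'",
                     i, t$text, got))
      triggers[[t$id]] <- t
    } else if (tag == "E") {
      e <- .parse_e_line(line, i)
      raw_events[[e$id]] <- e
    } else if (tag == "M") {
      next  # event modifications are out of scope (Task 1)
    } else {
      stop(sprintf("a2 line %d: unknown line type '%s'", i, tag))
    }
  }

  events <- list()
  for (e in raw_events) {
    trg <- triggers[[e$trigger]]
    if (is.null(trg))
      stop(sprintf("event %s references unknown trigger %s", e$id, e$trigger))
    for (tgt in e$targets) {
      ok <- (tgt %in% proteins$id) || !is.null(raw_events[[tgt]])
      if (!ok)
        stop(sprintf("event %s references unknown target %s", e$id, tgt))
    }
    events[[e$id]] <- event_annotation(e$id, e$type, trg$start, trg$end,
                                       trg$text, e$roles, e$targets)
  }
  new_document(id, text, proteins, events)
}

#' Serialize events to a2 standoff text
#'
#' Writes trigger (`T`) and event (`E`) lines for a set of event
#' annotations. Trigger lines are deduplicated over (type, span); event ids
#' are renumbered, and events are emitted so that any referenced event
#' appears before its referent. Reading the output back with
#' [read_standoff_document()] reproduces the same event structure up to id
#' renaming.
#'
#' @param doc a `bio_document` (supplies protein ids for reference checks).
#' @param events named list of `event_annotation` (defaults to
#'   `doc$events`).
#' @param t_start first numeric id to use for trigger T lines (a2 trigger
#'   ids must not collide with a1 ids).
#' @return character vector of a2 lines (length 0 when there are no
#'   events).
#' @export
write_a2 <- function(doc, events = doc$events, t_start = nrow(doc$proteins) + 1L) {
  if (length(events) == 0L) return(character(0))
  ids <- vapply(events, `[[`, character(1), "id")
  names(events) <- ids
  for (e in events) {
    if (!any(e$args$role == "THEME"))
      stop(sprintf("event %s has no THEME argument; cannot serialize", e$id))
    for (tgt in e$args$target) {
      if (!(tgt %in% doc$proteins$id) && !(tgt %in% ids))
        stop(sprintf("event %s references unknown target %s", e$id, tgt))
    }
  }

  # topological order: referenced events first
  order_ids <- character(0); seen <- character(0)
  visit <- function(id) {
    if (id %in% seen) return(invisible(NULL))
    seen <<- c(seen, id)
    for (tgt in events[[id]]$args$target)
      if (tgt %in% ids) visit(tgt)
    order_ids <<- c(order_ids, id)
  }
  for (id in ids) visit(id)

  trig_key <- function(e) paste(e$type, e$trigger_start, e$trigger_end)
  t_lines <- character(0); t_ids <- character(0); t_keys <- character(0)
  e_lines <- character(0); new_eid <- character(0)
  for (k in seq_along(order_ids)) new_eid[order_ids[k]] <- paste0("E", k)
  for (id in order_ids) {
    e <- events[[id]]
    key <- trig_key(e)
    pos <- match(key, t_keys)
    if (is.na(pos)) {
      tid <- paste0("T", t_start + length(t_keys))
      t_keys <- c(t_keys, key); t_ids <- c(t_ids, tid)
      t_lines <- c(t_lines, sprintf("%s\t%s %d %d\t%s", tid, e$type,
                                    e$trigger_start, e$trigger_end,
                                    e$trigger_text))
      pos <- length(t_keys)
    }
    roles <- e$args$role
    # additional THEMEs of multiple protein-taking events get numbered roles
    th <- which(roles == "THEME")
    if (length(th) > 1L)
      roles[th[-1]] <- paste0("THEME", seq_along(th[-1]) + 1L)
    targets <- e$args$target
    remap <- targets %in% ids
    targets[remap] <- new_eid[targets[remap]]
    role_txt <- paste(paste0(substr(roles, 1, 1),
                             tolower(substring(roles, 2)), ":", targets),
                      collapse = " ")
    e_lines <- c(e_lines, sprintf("%s\t%s:%s %s", new_eid[id], e$type,
                                  t_ids[pos], role_txt))
  }
  c(t_lines, e_lines)
}

#' Parse Stanford-dependency lines into a dependency edge table
#'
#' Each input line has the form `rel(gov-i, dep-j)` with 1-based token
#' indices; output indices are 0-based and relation labels are lower-cased.
#' Duplicate lines collapse to a single edge (set semantics).
#'
#' @param lines character vector of dependency lines (blank lines ignored).
#' @param n_tokens number of tokens in the sentence (for range checking).
#' @return data.frame with columns `gov`, `dep` (0-based) and `rel`.
#' @export
read_dependency_parse <- function(lines, n_tokens) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_deps())
  m <- regmatches(lines,
                  regexec("^\\s*([^()]+)\\((.+)-(\\d+)'*,\\s*(.+)-(\\d+)'*\\)\\s*$",
                          lines))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad))
    stop(sprintf("malformed dependency line %d: %s", which(bad)[1],
                 lines[which(bad)[1]]))
  rel <- tolower(vapply(m, `[`, character(1), 2))
  gov <- as.integer(vapply(m, `[`, character(1), 4)) - 1L
  dep <- as.integer(vapply(m, `[`, character(1), 6)) - 1L
  if (any(gov < 0L | gov >= n_tokens | dep < 0L | dep >= n_tokens))
    stop("dependency parse references a token index out of range")
  d <- data.frame(gov = gov, dep = dep, rel = rel, stringsAsFactors = FALSE)
  unique(d)
}

#' Merge multi-word protein mentions into single tokens
#'
#' Tokens covered by a multi-word protein mention are combined into one
#' token carrying the mention's `protein_id`; dependency edges internal to
#' the mention are dropped and edges crossing the mention boundary are
#' redirected to the merged token.
#'
#' @param tokens sentence token table (see [make_tokens()]).
#' @param deps dependency edge table for the sentence.
#' @param mentions protein mention table (id/char_start/char_end/text) whose
#'   spans fall inside this sentence.
#' @param snap if `TRUE`, mention boundaries not aligned to token boundaries
#'   are snapped outward to the covering tokens instead of raising an error.
#' @return list with elements `tokens` and `deps`.
#' @export
merge_protein_tokens <- function(tokens, deps, mentions, snap = FALSE) {
  if (nrow(mentions) == 0L) return(list(tokens = tokens, deps = deps))
  mentions <- mentions[order(mentions$char_start), , drop = FALSE]
  group <- seq_len(nrow(tokens))  # tokens with equal group collapse
  pid <- rep(NA_character_, nrow(tokens))
  for (k in seq_len(nrow(mentions))) {
    m <- mentions[k, ]
    cover <- which(tokens$char_end > m$char_start & tokens$char_start < m$char_end)
    if (length(cover) == 0L)
      stop(sprintf("mention %s [%d,%d) covers no token", m$id, m$char_start,
                   m$char_end))
    aligned <- tokens$char_start[cover[1]] == m$char_start &&
      tokens$char_end[cover[length(cover)]] == m$char_end
    if (!aligned && !snap)
      stop(sprintf(
        "mention %s [%d,%d) not aligned to token boundaries [%d,%d)",
        m$id, m$char_start, m$char_end, tokens$char_start[cover[1]],
        tokens$char_end[cover[length(cover)]]))
    group[cover] <- cover[1]
    pid[cover] <- m$id
  }
  keep <- !duplicated(group)
  new_index <- integer(nrow(tokens))
  new_index[keep] <- seq_len(sum(keep))
  new_index <- new_index[group]  # every old token -> merged row's new index

  merged <- lapply(which(keep), function(i) {
    g <- which(group == group[i])
    tk <- tokens[g, , drop = FALSE]
    surf <- paste(tk$surface, collapse = " ")
    data.frame(index = NA_integer_, surface = surf,
               baseform = if (length(g) > 1L) tolower(surf) else tk$baseform,
               pos = tk$pos[length(g)],
               char_start = min(tk$char_start), char_end = max(tk$char_end),
               protein_id = NA_character_, stringsAsFactors = FALSE)
  })
  out_tokens <- do.call(rbind, merged)
  out_tokens$index <- seq_len(nrow(out_tokens)) - 1L
  out_tokens$protein_id <- ifelse(is.na(pid[keep]),
                                  tokens$protein_id[keep], pid[keep])
  rownames(out_tokens) <- NULL

  if (nrow(deps)) {
    g2 <- new_index[deps$gov + 1L] - 1L
    d2 <- new_index[deps$dep + 1L] - 1L
    keep_e <- g2 != d2  # internal edges collapse to loops and are dropped
    out_deps <- unique(data.frame(gov = g2[keep_e], dep = d2[keep_e],
                                  rel = deps$rel[keep_e],
                                  stringsAsFactors = FALSE))
  } else {
    out_deps <- empty_deps()
  }
  list(tokens = out_tokens, deps = out_deps)
}

#' Read per-sentence lexical analyses
#'
#' Blocks of `token<TAB>baseform<TAB>POS` lines separated by blank lines,
#' one block per sentence.
#'
#' @param lines character vector.
#' @return list of data.frames (surface/baseform/pos), one per sentence.
#' @export
read_lexical_analysis <- function(lines) {
  lines <- sub("\r$", "", lines)
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  blocks <- lapply(blocks, function(b) b[nzchar(trimws(b))])
  blocks <- blocks[vapply(blocks, length, integer(1)) > 0L]
  lapply(blocks, function(b) {
    parts <- strsplit(b, "\t", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) != 3L
    if (any(bad))
      stop(sprintf("malformed lexical analysis line: %s", b[which(bad)[1]]))
    data.frame(surface = vapply(parts, `[`, character(1), 1),
               baseform = vapply(parts, `[`, character(1), 2),
               pos = vapply(parts, `[`, character(1), 3),
               stringsAsFactors = FALSE)
  })
}

#' Attach tokenized sentences and parses to a document
#'
#' Computes document character offsets for each token by scanning the text
#' left to right, merges multi-word protein mentions, and stores per-sentence
#' token tables and dependency graphs on the document.
#'
#' @param doc a `bio_document` from [read_standoff_document()].
#' @param sentence_tokens list of data.frames (surface/baseform/pos), one
#'   per sentence, e.g. from [read_lexical_analysis()].
#' @param sentence_deps list of dependency tables aligned with
#'   `sentence_tokens` (0-based, e.g. from [read_dependency_parse()]).
#' @param merge_proteins merge multi-word protein mentions into single
#'   tokens (default `TRUE`).
#' @return the document with `sentences` filled in; each sentence is a list
#'   with `tokens` and `deps`.
#' @export
attach_sentences <- function(doc, sentence_tokens, sentence_deps,
                             merge_proteins = TRUE) {
  stopifnot(length(sentence_tokens) == length(sentence_deps))
  cursor <- 0L
  sentences <- vector("list", length(sentence_tokens))
  for (s in seq_along(sentence_tokens)) {
    tk <- sentence_tokens[[s]]
    starts <- integer(nrow(tk)); ends <- integer(nrow(tk))
    for (i in seq_len(nrow(tk))) {
      hit <- regexpr(tk$surface[i], substring(doc$text, cursor + 1L),
                     fixed = TRUE)
      if (hit < 0L)
        stop(sprintf("token '%s' (sentence %d) not found in document text",
                     tk$surface[i], s))
      starts[i] <- cursor + as.integer(hit) - 1L
      ends[i] <- starts[i] + nchar(tk$surface[i])
      cursor <- ends[i]
    }
    tokens <- make_tokens(tk$surface, tk$baseform, tk$pos,
                          char_start = starts, char_end = ends)
    deps <- sentence_deps[[s]]
    if (is.null(deps)) deps <- empty_deps()
    if (merge_proteins && nrow(doc$proteins)) {
      inside <- doc$proteins$char_start >= min(starts) &
        doc$proteins$char_end <= max(ends)
      mg <- merge_protein_tokens(tokens, deps,
                                 doc$proteins[inside, , drop = FALSE])
      tokens <- mg$tokens; deps <- mg$deps
    } else {
      hitp <- match_mention_tokens(tokens, doc$proteins)
      tokens$protein_id[hitp$token] <- hitp$id
    }
    sentences[[s]] <- list(tokens = tokens, deps = deps)
  }
  doc$sentences <- sentences
  doc
}

# single-token protein mention flags (used when merging is off)
match_mention_tokens <- function(tokens, mentions) {
  tok <- integer(0); id <- character(0)
  for (k in seq_len(nrow(mentions))) {
    i <- which(tokens$char_start == mentions$char_start[k] &
                 tokens$char_end == mentions$char_end[k])
    if (length(i) == 1L) { tok <- c(tok, i); id <- c(id, mentions$id[k]) }
  }
  list(token = tok, id = id)
}

#' Write a corpus to a directory in standoff format
#'
#' For each document writes `<id>.txt`, `<id>.a1`, `<id>.a2`, `<id>.tok`
#' (lexical analyses) and `<id>.dep` (dependency parses, 1-based
#' `rel(word-i, word-j)` lines, sentences separated by blank lines).
#'
#' @param corpus list of `bio_document`.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc in corpus) {
    base <- file.path(dir, doc$id)
    writeLines(doc$text, paste0(base, ".txt"))
    a1 <- sprintf("%s\tProtein %d %d\t%s", doc$proteins$id,
                  doc$proteins$char_start, doc$proteins$char_end,
                  doc$proteins$text)
    writeLines(a1, paste0(base, ".a1"))
    writeLines(write_a2(doc), paste0(base, ".a2"))
    tok <- character(0); dep <- character(0)
    for (s in doc$sentences) {
      tk <- s$tokens
      tok <- c(tok, sprintf("%s\t%s\t%s", tk$surface, tk$baseform, tk$pos), "")
      if (nrow(s$deps)) {
        dl <- sprintf("%s(%s-%d, %s-%d)", s$deps$rel,
                      tk$surface[s$deps$gov + 1L], s$deps$gov + 1L,
                      tk$surface[s$deps$dep + 1L], s$deps$dep + 1L)
      } else dl <- character(0)
      dep <- c(dep, dl, "")
    }
    writeLines(tok, paste0(base, ".tok"))
    writeLines(dep, paste0(base, ".dep"))
  }
  invisible(dir)
}

#' Read a standoff corpus directory
#'
#' Counterpart of [write_corpus()]: reads every `*.txt` with its `.a1`,
#' `.a2`, `.tok` and `.dep` companions.
#'
#' @param dir directory path.
#' @param merge_proteins see [attach_sentences()].
#' @return list of `bio_document`.
#' @export
read_corpus_dir <- function(dir, merge_proteins = TRUE) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, function(tf) {
    base <- sub("\\.txt$", "", tf)
    id <- basename(base)
    rl <- function(p) if (file.exists(p)) readLines(p, warn = FALSE) else character(0)
    doc <- read_standoff_document(paste(rl(tf), collapse = "\n"),
                                  rl(paste0(base, ".a1")),
                                  rl(paste0(base, ".a2")), id = id)
    toks <- read_lexical_analysis(rl(paste0(base, ".tok")))
    # dependency blocks align 1:1 with token blocks (the writer emits one
    # blank-line-terminated block, possibly empty, per sentence)
    deps <- .split_dep_blocks(rl(paste0(base, ".dep")), toks)
    attach_sentences(doc, toks, deps, merge_proteins = merge_proteins)
  })
}

.split_dep_blocks <- function(dep_lines, toks) {
  # writer emits (lines..., "") per sentence; an empty sentence contributes
  # a single "" separator
  n <- length(toks)
  out <- replicate(n, character(0), simplify = FALSE)
  s <- 1L
  for (ln in dep_lines) {
    if (!nzchar(trimws(ln))) { s <- s + 1L; next }
    if (s <= n) out[[s]] <- c(out[[s]], ln)
  }
  lapply(seq_len(n), function(s)
    read_dependency_parse(out[[s]], nrow(toks[[s]])))
}
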