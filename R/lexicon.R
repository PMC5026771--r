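# Per-event-type trigger lexicons with reliability scores
# R_{w,e} = C_{w,e} / C_w, where C_{w,e} counts occurrences of entry w
# inside annotated triggers of type e and C_w counts all occurrences of w
# in the corpus (as a token or as a hyphen component of one). Entries are
# lower-cased; hyphenated words contribute both their components and the
# original word.

hyphen_components <- function(word) {
  if (!grepl("-", word, fixed = TRUE)) return(character(0))
  parts <- strsplit(word, "-", fixed = TRUE)[[1]]
  parts[nzchar(parts)]
}

# all lexicon entries a single word form gives rise to (itself + components)
.entry_forms <- function(word, stemmed) {
  word <- tolower(word)
  forms <- unique(c(word, hyphen_components(word)))
  if (stemmed) forms <- unique(porter_stem(forms))
  forms
}

.count_into <- function(env, keys, by = 1) {
  for (k in keys) {
    cur <- env[[k]]
    env[[k]] <- if (is.null(cur)) by else cur + by
  }
}

#' Build trigger lexicons from a gold-annotated corpus
#'
#' Constituent words of every annotated event trigger are scanned one by
#' one into the lexicon of the trigger's event type; hyphenated words also
#' contribute their components. The denominator count \eqn{C_w} is taken
#' over all token occurrences in the corpus, so the reliability
#' \eqn{R_{w,e} = C_{w,e}/C_w} is the fraction of occurrences of `w` that
#' fall inside triggers of type `e`.
#'
#' @param corpus list of `bio_document` with gold events and attached
#'   sentences.
#' @param stemmed if `TRUE`, entries are Porter-stemmed before counting.
#' @return object of class `trigger_lexicon`: list with `counts` (per event
#'   type, named numeric \eqn{C_{w,e}}), `total` (named numeric \eqn{C_w})
#'   and `stemmed` flag.
#' @export
build_trigger_lexicons <- function(corpus, stemmed = FALSE) {
  total <- new.env(parent = emptyenv())
  per_type <- list()

  for (doc in corpus) {
    for (s in doc$sentences) {
      for (w in s$tokens$surface) {
        .count_into(total, .entry_forms(w, stemmed))
      }
    }
    seen_trig <- character(0)
    for (e in doc$events) {
      key <- paste(e$type, e$trigger_start, e$trigger_end)
      if (key %in% seen_trig) next  # one count per annotated trigger
      seen_trig <- c(seen_trig, key)
      words <- strsplit(trimws(e$trigger_text), "\\s+")[[1]]
      if (is.null(per_type[[e$type]]))
        per_type[[e$type]] <- new.env(parent = emptyenv())
      for (w in words)
        .count_into(per_type[[e$type]], .entry_forms(w, stemmed))
    }
  }

  counts <- lapply(per_type, function(env) unlist(as.list(env)) %||% numeric(0))
  counts <- lapply(counts, function(x) x[order(names(x))])
  tot <- unlist(as.list(total))
  if (is.null(tot)) tot <- numeric(0) else tot <- tot[order(names(tot))]
  structure(list(counts = counts, total = tot, stemmed = stemmed),
            class = "trigger_lexicon")
}

#' @export
print.trigger_lexicon <- function(x, ...) {
  n <- sum(vapply(x$counts, length, integer(1)))
  cat(sprintf("<trigger_lexicon%s: %d entries over %d event types, %d words>\n",
              if (x$stemmed) " (stemmed)" else "", n, length(x$counts),
              length(x$total)))
  invisible(x)
}

#' Reliability scores of lexicon entries
#'
#' @param lex a `trigger_lexicon`.
#' @param type event type.
#' @return named numeric of \eqn{R_{w,e}} for all entries of that type.
#' @export
lexicon_reliability <- function(lex, type) {
  cwe <- lex$counts[[type]]
  if (is.null(cwe) || length(cwe) == 0L) return(numeric(0))
  cw <- lex$total[names(cwe)]
  cw[is.na(cw)] <- Inf  # defensive; cannot happen for corpus-built lexicons
  cwe / cw
}

#' Prune unreliable lexicon entries
#'
#' Removes entries whose reliability falls strictly below `threshold` from
#' each event type's lexicon. Word totals \eqn{C_w} are untouched.
#'
#' @param lex a `trigger_lexicon`.
#' @param threshold fraction in `[0, 1]` (default 0.01, i.e. 1 percent).
#' @return pruned `trigger_lexicon`.
#' @export
prune <- function(lex, threshold = 0.01) {
  stopifnot(inherits(lex, "trigger_lexicon"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("threshold must be a single number in [0, 1]")
  lex$counts <- lapply(stats::setNames(names(lex$counts), names(lex$counts)),
                       function(ty) {
                         r <- lexicon_reliability(lex, ty)
                         lex$counts[[ty]][r >= threshold]
                       })
  lex
}

#' Candidate event types of a token
#'
#' Looks the token up in both the plain and the stemmed trigger lexicons
#' under every derivable form (lower-cased surface, baseform, hyphen
#' components, and their Porter stems for the stemmed lexicon) and returns,
#' per event type, the maximum reliability over all matching entries.
#'
#' @param surface token surface form.
#' @param baseform token baseform.
#' @param lex pruned plain `trigger_lexicon`.
#' @param stemmed_lex pruned stemmed `trigger_lexicon` (optional).
#' @return named numeric, one element per matching event type (empty when
#'   nothing matches).
#' @export
candidate_event_types <- function(surface, baseform, lex, stemmed_lex = NULL) {
  plain_forms <- unique(c(.entry_forms(surface, FALSE),
                          .entry_forms(baseform, FALSE)))
  best <- numeric(0)
  lookup <- function(lx, forms) {
    for (ty in names(lx$counts)) {
      r <- lexicon_reliability(lx, ty)
      hit <- r[names(r) %in% forms]
      if (length(hit)) {
        m <- max(hit)
        if (is.null(best[ty]) || is.na(best[ty]) || m > best[ty])
          best[ty] <<- m
      }
    }
  }
  lookup(lex, plain_forms)
  if (!is.null(stemmed_lex)) {
    stem_forms <- unique(porter_stem(plain_forms))
    lookup(stemmed_lex, stem_forms)
  }
  if (length(best) == 0L) return(stats::setNames(numeric(0), character(0)))
  best[order(names(best))]
}

#' Serialize a lexicon as TSV
#'
#' Lines of `event_type<TAB>entry<TAB>C_we<TAB>C_w<TAB>R`.
#'
#' @param lex a `trigger_lexicon`.
#' @return character vector of TSV lines.
#' @export
write_lexicon_tsv <- function(lex) {
  out <- character(0)
  for (ty in sort(names(lex$counts))) {
    cwe <- lex$counts[[ty]]
    if (length(cwe) == 0L) next
    r <- lexicon_reliability(lex, ty)
    out <- c(out, sprintf("%s\t%s\t%g\t%g\t%.6g", ty, names(cwe), cwe,
                          lex$total[names(cwe)], r))
  }
  out
}

#' Read a lexicon from TSV lines written by [write_lexicon_tsv()]
#'
#' @param lines character vector of TSV lines.
#' @param stemmed stemmed flag to record on the result.
#' @return a `trigger_lexicon`.
#' @export
read_lexicon_tsv <- function(lines, stemmed = FALSE) {
  lines <- lines[nzchar(trimws(lines))]
  counts <- list(); total <- numeric(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 5L) stop(sprintf("malformed lexicon line: %s", ln))
    ty <- f[1]; w <- f[2]
    counts[[ty]][w] <- as.numeric(f[3])
    total[w] <- as.numeric(f[4])
  }
  structure(list(counts = counts, total = total, stemmed = stemmed),
            class = "trigger_lexicon")
}
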