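#' Read a document corpus from TSV
#'
#' Expects a UTF-8 TSV with a header row and columns
#' `doc_id`, `title`, `abstract`. Tabs are not permitted inside fields.
#' Each row plays the role of one bibliographic record (the `doc_id`
#' standing in for a PMID); the abstract may be empty.
#'
#' @param path Path to the corpus TSV.
#' @return Data frame with character columns `doc_id`, `title`, `abstract`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          na.strings = NULL, encoding = "UTF-8",
                          check.names = FALSE)
  need <- c("doc_id", "title", "abstract")
  if (!all(need %in% names(df))) {
    stop("corpus TSV must have columns: ", paste(need, collapse = ", "))
  }
  df[need]
}

#' Build an inverted index over title + abstract
#'
#' Title and abstract are concatenated and tokenized into one single
#' indexed field per document. The index keeps, for every token, the
#' positions at which it occurs in each document's (stopword-filtered)
#' token stream — enough for exact phrase matching — plus per-document
#' token counts for length normalization. The original text is not
#' stored and is not recoverable in its surface form (case, punctuation
#' and stopwords are lost).
#'
#' @param corpus Data frame with columns `doc_id`, `title`, `abstract`
#'   (as returned by [read_corpus()]), or a list of such records.
#' @param stopwords Stopword list passed to [tokenize()].
#' @return An object of class `inverted_index` with elements `n_docs`,
#'   `doc_len` (named integer), `postings` (token -> named list of
#'   integer position vectors) and `stopwords`.
#' @export
build_index <- function(corpus, stopwords = default_stopwords()) {
  if (is.data.frame(corpus)) {
    ids <- as.character(corpus$doc_id)
    titles <- as.character(corpus$title)
    abstracts <- as.character(corpus$abstract)
  } else {
    ids <- vapply(corpus, function(d) as.character(d$doc_id), character(1))
    titles <- vapply(corpus, function(d) as.character(d$title), character(1))
    abstracts <- vapply(corpus, function(d) as.character(d$abstract), character(1))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate doc_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  postings <- new.env(parent = emptyenv())
  doc_len <- integer(length(ids))
  names(doc_len) <- ids
  for (i in seq_along(ids)) {
    toks <- tokenize(paste(titles[i], abstracts[i]), stopwords = stopwords)
    doc_len[[i]] <- length(toks)
    if (!length(toks)) next
    pos_by_tok <- split(seq_along(toks), toks)
    for (tok in names(pos_by_tok)) {
      cur <- postings[[tok]]
      if (is.null(cur)) cur <- list()
      cur[[ids[i]]] <- pos_by_tok[[tok]]
      postings[[tok]] <- cur
    }
  }
  structure(list(n_docs = length(ids),
                 doc_len = doc_len,
                 postings = as.list(postings),
                 stopwords = stopwords),
            class = "inverted_index")
}

#' @export
print.inverted_index <- function(x, ...) {
  cat("<inverted_index> ", x$n_docs, " docs, ",
      length(x$postings), " distinct tokens\n", sep = "")
  invisible(x)
}

# Phrase occurrence counts for a tokenized term across all documents.
# Returns a named numeric vector (doc_id -> frequency > 0).
.phrase_freqs <- function(index, toks) {
  first <- index$postings[[toks[1L]]]
  if (is.null(first)) return(numeric(0))
  docs <- names(first)
  if (length(toks) > 1L) {
    for (k in 2:length(toks)) {
      pk <- index$postings[[toks[k]]]
      if (is.null(pk)) return(numeric(0))
      docs <- intersect(docs, names(pk))
      if (!length(docs)) return(numeric(0))
    }
  }
  freqs <- vapply(docs, function(d) {
    pos <- index$postings[[toks[1L]]][[d]]
    if (length(toks) > 1L) {
      for (k in 2:length(toks)) {
        pos <- pos[(pos + (k - 1L)) %in% index$postings[[toks[k]]][[d]]]
        if (!length(pos)) break
      }
    }
    length(pos)
  }, numeric(1))
  freqs[freqs > 0]
}

#' Score a single weighted term against the index
#'
#' A multi-word term is matched as an exact phrase (consecutive tokens in
#' order, positions counted after stopword removal); a single-word term as
#' a plain token match. For each matching document the score is
#' \deqn{boost \times \sqrt{tf} \times idf^2 / \sqrt{doclen}}
#' with \eqn{idf = 1 + \ln(N / (df + 1))}, where `tf` is the phrase (or
#' token) frequency in the document, `df` the number of documents
#' containing the phrase/token and `N` the corpus size. This mirrors the
#' structure of the classic Lucene similarity (sqrt term frequency,
#' smoothed squared idf, inverse-square-root length norm) without a
#' query norm, so scores are reproducible bit-for-bit from the formula.
#'
#' @param index An `inverted_index`.
#' @param text Term text; may be multi-word.
#' @param boost Positive multiplier (default 1).
#' @return Data frame with columns `doc_id`, `score`; zero rows if the
#'   term matches nothing. A term that tokenizes to nothing is skipped
#'   with a warning and returns zero rows.
#' @export
score_term_query <- function(index, text, boost = 1) {
  stopifnot(inherits(index, "inverted_index"))
  toks <- tokenize(text, stopwords = index$stopwords)
  if (!length(toks)) {
    warning("term '", text, "' has no tokens after analysis; skipped")
    return(data.frame(doc_id = character(0), score = numeric(0)))
  }
  freqs <- .phrase_freqs(index, toks)
  if (!length(freqs)) {
    return(data.frame(doc_id = character(0), score = numeric(0)))
  }
  df <- length(freqs)
  idf <- 1 + log(index$n_docs / (df + 1))
  docs <- names(freqs)
  score <- boost * sqrt(freqs) * idf^2 / sqrt(index$doc_len[docs])
  data.frame(doc_id = docs, score = unname(score),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Score a disjunctive class query
#'
#' Runs one retrieval for a whole concept class: the per-document score is
#' the sum of the matching terms' [score_term_query()] contributions,
#' multiplied by a coordination factor (number of distinct query terms
#' matched divided by the number of query terms), which rewards documents
#' matching more of the class's terms. Documents matching no term are
#' absent from the result (absent = zero by convention).
#'
#' @param index An `inverted_index`.
#' @param terms Data frame with columns `text` and `boost` (a class slot
#'   of an [expand_query()] result), or a character vector (boost 1).
#' @return Named numeric vector mapping `doc_id` to a strictly positive
#'   score; empty for an empty term list.
#' @export
score_class_query <- function(index, terms) {
  stopifnot(inherits(index, "inverted_index"))
  .bump_retrieval_count()
  if (is.character(terms)) terms <- data.frame(text = terms, boost = 1)
  if (is.null(terms) || nrow(terms) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  total <- new.env(parent = emptyenv())
  nmatched <- new.env(parent = emptyenv())
  n_valid <- 0L
  for (i in seq_len(nrow(terms))) {
    toks <- tokenize(terms$text[i], stopwords = index$stopwords)
    if (!length(toks)) {
      warning("term '", terms$text[i], "' has no tokens after analysis; skipped")
      next
    }
    n_valid <- n_valid + 1L
    freqs <- .phrase_freqs(index, toks)
    if (!length(freqs)) next
    idf <- 1 + log(index$n_docs / (length(freqs) + 1))
    contrib <- terms$boost[i] * sqrt(freqs) * idf^2 /
      sqrt(index$doc_len[names(freqs)])
    for (d in names(freqs)) {
      total[[d]] <- (total[[d]] %||% 0) + contrib[[d]]
      nmatched[[d]] <- (nmatched[[d]] %||% 0L) + 1L
    }
  }
  docs <- ls(total)
  if (!length(docs) || n_valid == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  out <- vapply(docs, function(d) total[[d]] * nmatched[[d]] / n_valid,
                numeric(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist / restore an inverted index
#'
#' The on-disk format is R's native serialization (RDS). The round trip
#' `build -> save -> load` reproduces identical scores for any query.
#'
#' @param index An `inverted_index`.
#' @param path Destination file.
#' @return `save_index` returns `path` invisibly; `load_index` returns the
#'   `inverted_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "inverted_index"))
  saveRDS(index, path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path)
  index <- readRDS(path)
  if (!inherits(index, "inverted_index")) stop("not an index file: ", path)
  index
}

# -- retrieval instrumentation ------------------------------------------
# A process-wide counter of class-query executions. Used to verify the
# re-ranking contract: changing fusion weights must not trigger retrieval.
.litexpand_counters <- new.env(parent = emptyenv())
.litexpand_counters$class_queries <- 0L

.bump_retrieval_count <- function() {
  .litexpand_counters$class_queries <- .litexpand_counters$class_queries + 1L
  invisible(NULL)
}

#' Retrieval instrumentation hook
#'
#' `retrieval_count()` returns how many class-query retrievals have been
#' executed in this session; `reset_retrieval_count()` zeroes the counter.
#' Weight changes re-rank stored score tables, so a weight sweep performed
#' after retrieval must leave this counter untouched.
#'
#' @return Integer count (or previous count, invisibly, for the reset).
#' @export
retrieval_count <- function() .litexpand_counters$class_queries

#' @rdname retrieval_count
#' @export
reset_retrieval_count <- function() {
  old <- .litexpand_counters$class_queries
  .litexpand_counters$class_queries <- 0L
  invisible(old)
}
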