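#' Read TREC-format relevance judgments (qrels)
#'
#' Whitespace-delimited lines `topic_id iteration doc_id relevance`; the
#' iteration column is ignored. Graded judgments are kept as integers;
#' a document counts as relevant when its grade is > 0. Duplicate
#' (topic, doc) pairs with different grades are an integrity error;
#' exact duplicate lines are collapsed.
#'
#' @param path Path to the qrels file.
#' @return Data frame of class `qrels` with columns `topic_id`, `doc_id`,
#'   `relevance` (integer).
#' @export
read_qrels <- function(path) {
  if (!file.exists(path)) stop("qrels file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- data.frame(topic_id = character(0), doc_id = character(0),
                      relevance = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("qrels", "data.frame")
    return(out)
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) {
    stop("malformed qrels line ", bad[1L], ": expected 4 fields")
  }
  m <- do.call(rbind, parts)
  rel <- suppressWarnings(as.integer(m[, 4L]))
  if (anyNA(rel) || any(m[, 4L] != as.character(rel))) {
    stop("non-integer relevance grade at qrels line ",
         which(is.na(rel) | m[, 4L] != as.character(rel))[1L])
  }
  out <- data.frame(topic_id = m[, 1L], doc_id = m[, 3L], relevance = rel,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  key <- paste(out$topic_id, out$doc_id)
  if (anyDuplicated(key)) {
    stop("integrity error: conflicting relevance grades for (topic, doc) ",
         key[duplicated(key)][1L])
  }
  class(out) <- c("qrels", "data.frame")
  out
}

#' Relevant documents of one topic
#' @param qrels A `qrels` data frame.
#' @param topic Topic id.
#' @return Character vector of relevant doc ids (grade > 0).
#' @export
relevant_docs <- function(qrels, topic) {
  qrels$doc_id[qrels$topic_id == topic & qrels$relevance > 0]
}

#' Average precision of one ranking
#'
#' \deqn{AP = \frac{1}{|R|} \sum_{r : d_r \in R} \frac{|R \cap top_r|}{r}}
#' where `R` is the full set of judged-relevant documents (the trec_eval
#' convention: the denominator is all relevant documents, so relevant
#' documents that were never retrieved contribute zero).
#'
#' @param ranking Character vector of doc ids in rank order, or a
#'   `ranked_result`.
#' @param relevant Character vector (or set) of relevant doc ids;
#'   must be non-empty.
#' @return AP in \[0, 1\].
#' @export
average_precision <- function(ranking, relevant) {
  if (inherits(ranking, "ranked_result")) ranking <- ranking$doc_id
  relevant <- unique(as.character(relevant))
  if (!length(relevant)) stop("relevant set is empty; AP is undefined")
  hit <- ranking %in% relevant
  if (!any(hit)) return(0)
  r <- which(hit)
  sum(seq_along(r) / r) / length(relevant)
}

#' Evaluate a multi-topic run against qrels
#'
#' Computes per-topic average precision, the mean average precision (MAP)
#' over topics, and for each cutoff `k` the count of relevant documents
#' in the top k and the corresponding precision P@k. Topics without any
#' relevant document in the qrels are excluded from the averages with a
#' warning.
#'
#' @param rankings Named list mapping topic id to a ranking (character
#'   vector of doc ids in rank order, or a `ranked_result`).
#' @param qrels A `qrels` data frame.
#' @param ks Integer cutoffs (default `c(10, 100)`).
#' @return List of class `eval_report`: `per_topic` (data frame with
#'   `topic_id`, `ap`, `rel_in_top_<k>`, `p_at_<k>` columns), `map`,
#'   `mean_rel_in_top` (named by k), `mean_p_at` (named by k), `ks`.
#' @export
evaluate_run <- function(rankings, qrels, ks = c(10, 100)) {
  stopifnot(is.list(rankings), !is.null(names(rankings)))
  ks <- as.integer(ks)
  rows <- list()
  for (topic in names(rankings)) {
    rel <- relevant_docs(qrels, topic)
    if (!length(rel)) {
      warning("topic '", topic, "' has no relevant documents in qrels; skipped")
      next
    }
    ranking <- rankings[[topic]]
    if (inherits(ranking, "ranked_result")) ranking <- ranking$doc_id
    row <- list(topic_id = topic, ap = average_precision(ranking, rel))
    for (k in ks) {
      nrel <- sum(utils::head(ranking, k) %in% rel)
      row[[paste0("rel_in_top_", k)]] <- nrel
      row[[paste0("p_at_", k)]] <- nrel / k
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no evaluable topics (none with relevant documents)")
  per_topic <- do.call(rbind, rows)
  report <- list(per_topic = per_topic,
                 map = mean(per_topic$ap),
                 mean_rel_in_top = stats::setNames(
                   vapply(ks, function(k)
                     mean(per_topic[[paste0("rel_in_top_", k)]]), numeric(1)),
                   as.character(ks)),
                 mean_p_at = stats::setNames(
                   vapply(ks, function(k)
                     mean(per_topic[[paste0("p_at_", k)]]), numeric(1)),
                   as.character(ks)),
                 ks = ks)
  class(report) <- "eval_report"
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", nrow(x$per_topic), " topic(s)\n", sep = "")
  cat(sprintf("  MAP: %.4f\n", x$map))
  for (k in x$ks) {
    cat(sprintf("  mean relevant in top %d: %.2f (P@%d = %.4f)\n",
                k, x$mean_rel_in_top[[as.character(k)]],
                k, x$mean_p_at[[as.character(k)]]))
  }
  invisible(x)
}

#' Read a topics file
#'
#' TSV with header `topic_id organism gene_list`; `gene_list` is
#' `|`-separated. This is the gene-name-only reduction of an information
#' request: each topic is just an organism plus a list of gene symbols.
#'
#' @param path Path to the topics TSV.
#' @return Data frame with `topic_id`, `organism` (character) and
#'   `genes` (list column of character vectors).
#' @export
read_topics <- function(path) {
  if (!file.exists(path)) stop("topics file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          na.strings = NULL, encoding = "UTF-8")
  need <- c("topic_id", "organism", "gene_list")
  if (!all(need %in% names(df))) {
    stop("topics TSV must have columns: ", paste(need, collapse = ", "))
  }
  data.frame(topic_id = df$topic_id, organism = df$organism,
             genes = I(strsplit(df$gene_list, "|", fixed = TRUE)),
             stringsAsFactors = FALSE)
}

#' Write an evaluation report to TSV + JSON
#'
#' @param report An `eval_report`.
#' @param prefix Output path prefix; writes `<prefix>_per_topic.tsv` and
#'   `<prefix>_summary.json`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_eval_report <- function(report, prefix) {
  stopifnot(inherits(report, "eval_report"))
  tsv <- paste0(prefix, "_per_topic.tsv")
  jsn <- paste0(prefix, "_summary.json")
  utils::write.table(report$per_topic, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(map = report$map,
                            mean_rel_in_top = as.list(report$mean_rel_in_top),
                            mean_p_at = as.list(report$mean_p_at)),
                       jsn, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, jsn))
}
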