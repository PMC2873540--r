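#' Fusion weights for the four concept classes
#'
#' The user-settable class weights \eqn{W_j} of the score-fusion rule
#' \eqn{final_i = \sum_j W_j s_{ij}}. Weights are raw non-negative reals:
#' because the final ranking is normalized by its maximum, only ratios
#' matter and no sum-to-one constraint is imposed (a UI would typically
#' present them as 0-100 sliders). At least one weight must be positive
#' to produce a usable ranking; this is checked at fusion time.
#'
#' @param gene,protein,pathway,disease Non-negative reals. The defaults
#'   (0.5, 0.3, 0.1, 0.1) favour direct gene-name evidence while still
#'   letting protein, pathway and disease mentions contribute.
#' @return Named numeric vector of class `fusion_weights`.
#' @export
fusion_weights <- function(gene = 0.5, protein = 0.3,
                           pathway = 0.1, disease = 0.1) {
  w <- c(gene = gene, protein = protein, pathway = pathway, disease = disease)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("fusion weights must be finite and >= 0")
  }
  structure(w, class = "fusion_weights")
}

#' Assemble per-class retrieval results into one score table
#'
#' Takes the four per-class retrieval results (documents and scores are
#' kept in separate lists, one per concept class) and aligns them on the
#' union of document ids, filling a class's score with 0 for documents it
#' did not retrieve.
#'
#' @param gene,protein,pathway,disease Named numeric vectors
#'   (doc_id -> score) as returned by [score_class_query()].
#' @return Data frame of class `class_score_table` with columns `doc_id`,
#'   `s_gene`, `s_protein`, `s_pathway`, `s_disease`.
#' @export
assemble_scores <- function(gene = numeric(0), protein = numeric(0),
                            pathway = numeric(0), disease = numeric(0)) {
  cls <- list(gene = gene, protein = protein,
              pathway = pathway, disease = disease)
  ids <- sort(unique(unlist(lapply(cls, names), use.names = FALSE)))
  if (is.null(ids)) ids <- character(0)
  fill <- function(v) {
    out <- stats::setNames(numeric(length(ids)), ids)
    if (length(v)) out[names(v)] <- v
    unname(out)
  }
  tab <- data.frame(doc_id = ids,
                    s_gene = fill(gene), s_protein = fill(protein),
                    s_pathway = fill(pathway), s_disease = fill(disease),
                    stringsAsFactors = FALSE)
  class(tab) <- c("class_score_table", "data.frame")
  tab
}

#' Fuse per-class scores into a final ranking
#'
#' Computes, for every document, the weighted sum of its four concept
#' class scores, \eqn{final_i = \sum_j W_j s_{ij}}, then normalizes by
#' the highest final score to obtain a relative score in \[0, 1\].
#' Documents are sorted by decreasing final score; ties are broken by
#' descending document id (for zero-padded PMID-style ids this prefers
#' the more recent record). If every final score is zero the relative
#' scores are defined as all zero.
#'
#' @param table A `class_score_table` from [assemble_scores()].
#' @param weights A `fusion_weights` vector (or anything coercible via
#'   `fusion_weights()` defaults). All-zero weights are an error: no
#'   active concept classes.
#' @return Data frame of class `ranked_result` with columns `rank`,
#'   `doc_id`, `final_score`, `relative_score`, `s_gene`, `s_protein`,
#'   `s_pathway`, `s_disease`.
#' @export
fuse <- function(table, weights = fusion_weights()) {
  stopifnot(inherits(table, "class_score_table"))
  if (!inherits(weights, "fusion_weights")) {
    weights <- do.call(fusion_weights, as.list(weights))
  }
  if (all(weights == 0)) stop("no active concept classes: all weights are zero")
  s <- as.matrix(table[c("s_gene", "s_protein", "s_pathway", "s_disease")])
  final <- as.numeric(s %*% unclass(weights))
  top <- if (length(final)) max(final) else 0
  rel <- if (top > 0) final / top else rep(0, length(final))
  ord <- order(final, table$doc_id, decreasing = TRUE, method = "radix")
  out <- data.frame(rank = seq_along(ord),
                    doc_id = table$doc_id[ord],
                    final_score = final[ord],
                    relative_score = rel[ord],
                    stringsAsFactors = FALSE)
  out <- cbind(out, table[ord, c("s_gene", "s_protein", "s_pathway",
                                 "s_disease")])
  rownames(out) <- NULL
  class(out) <- c("ranked_result", "data.frame")
  out
}

#' Re-rank a stored score table under new weights
#'
#' Re-ranking is a pure function of the stored class score table and the
#' new weights: it performs no thesaurus lookup, no query expansion and
#' no index access, which is what makes interactive weight changes
#' instantaneous. Identical to [fuse()] by construction.
#'
#' @inheritParams fuse
#' @return A `ranked_result`.
#' @export
rerank <- function(table, weights) fuse(table, weights)

#' @export
print.ranked_result <- function(x, n = 10L, ...) {
  cat("<ranked_result> ", nrow(x), " documents\n", sep = "")
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more rows\n", sep = "")
  invisible(x)
}

#' Write a ranked result to TSV
#'
#' Columns: `rank doc_id final_score relative_score s_gene s_protein
#' s_pathway s_disease`.
#'
#' @param ranked A `ranked_result`.
#' @param path Destination TSV.
#' @param top_n Optional cap on the number of rows written (applied after
#'   fusion, so normalization is unaffected).
#' @return `path`, invisibly.
#' @export
write_ranked <- function(ranked, path, top_n = NULL) {
  stopifnot(inherits(ranked, "ranked_result"))
  if (!is.null(top_n)) ranked <- utils::head(ranked, top_n)
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
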