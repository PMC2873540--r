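#' Retrieve the per-class score table for a gene list
#'
#' Composes the full retrieval half of the pipeline: gene mapping,
#' query expansion, one class query per concept class, and assembly of
#' the four result lists into a single score table. Fusion is kept
#' separate so that weight changes can re-rank the returned table
#' without touching the index again.
#'
#' @param index An `inverted_index`.
#' @param thesaurus A `concept_thesaurus`.
#' @param organism Organism tag.
#' @param genes Character vector of gene identifiers/symbols.
#' @param classes Concept classes to search; default all four. Passing
#'   `"gene"` gives the gene-terms-only baseline (no concept expansion
#'   beyond gene names and synonyms).
#' @param boost_fun Passed to [expand_query()].
#' @return List with `table` (a `class_score_table`), `expansion` (the
#'   `expanded_query`) and `unmatched` (from [map_genes()]).
#' @export
retrieve_class_scores <- function(index, thesaurus, organism, genes,
                                  classes = concept_classes(),
                                  boost_fun = identity) {
  stopifnot(all(classes %in% concept_classes()))
  mapped <- map_genes(genes, organism, thesaurus)
  eq <- expand_query(mapped$records, boost_fun = boost_fun)
  per_class <- lapply(concept_classes(), function(cl) {
    if (cl %in% classes) score_class_query(index, eq[[cl]])
    else stats::setNames(numeric(0), character(0))
  })
  names(per_class) <- concept_classes()
  list(table = do.call(assemble_scores, per_class),
       expansion = eq,
       unmatched = mapped$unmatched)
}

#' Run retrieval for every topic of a benchmark
#'
#' @param index An `inverted_index`.
#' @param thesaurus A `concept_thesaurus`.
#' @param topics Data frame from [read_topics()].
#' @param classes Concept classes to search (see
#'   [retrieve_class_scores()]).
#' @return Named list (by topic id) of `class_score_table`s.
#' @export
run_topics <- function(index, thesaurus, topics,
                       classes = concept_classes()) {
  tables <- lapply(seq_len(nrow(topics)), function(i) {
    retrieve_class_scores(index, thesaurus, topics$organism[i],
                          topics$genes[[i]], classes = classes)$table
  })
  names(tables) <- topics$topic_id
  tables
}

#' Rank stored score tables and evaluate against qrels
#'
#' Pure re-ranking plus scoring: fuses every topic's stored table under
#' `weights` and evaluates the resulting rankings. No retrieval happens
#' here, which is what makes weight sweeps cheap.
#'
#' @param tables Named list of `class_score_table`s (from [run_topics()]).
#' @param weights A `fusion_weights`.
#' @param qrels A `qrels` data frame.
#' @param ks Cutoffs for [evaluate_run()].
#' @return An `eval_report`.
#' @export
evaluate_tables <- function(tables, weights, qrels, ks = c(10, 100)) {
  rankings <- lapply(tables, rerank, weights = weights)
  evaluate_run(rankings, qrels, ks = ks)
}

#' Sweep fusion-weight configurations over stored score tables
#'
#' Re-ranks the stored per-topic tables under each weight configuration
#' and reports MAP (and mean relevant-in-top-k) per configuration. Uses
#' only [rerank()], so the sweep costs no retrieval regardless of how
#' many configurations are tried.
#'
#' @param tables Named list of `class_score_table`s.
#' @param weight_list List of `fusion_weights` (or 4-vectors in gene,
#'   protein, pathway, disease order).
#' @param qrels A `qrels` data frame.
#' @param ks Cutoffs.
#' @return Data frame: one row per configuration with the four weights,
#'   `map`, and `mean_rel_in_top_<k>` columns.
#' @export
weight_sweep <- function(tables, weight_list, qrels, ks = c(10, 100)) {
  rows <- lapply(weight_list, function(w) {
    if (!inherits(w, "fusion_weights")) {
      w <- fusion_weights(w[[1L]], w[[2L]], w[[3L]], w[[4L]])
    }
    rep <- evaluate_tables(tables, w, qrels, ks = ks)
    row <- data.frame(w_gene = w[["gene"]], w_protein = w[["protein"]],
                      w_pathway = w[["pathway"]], w_disease = w[["disease"]],
                      map = rep$map)
    for (k in ks) {
      row[[paste0("mean_rel_in_top_", k)]] <-
        rep$mean_rel_in_top[[as.character(k)]]
    }
    row
  })
  do.call(rbind, rows)
}
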