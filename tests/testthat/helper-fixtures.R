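# Small in-code fixture builders shared across test files.

write_thesaurus_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- paste("internal_id", "organism", "primary_symbol", "gene_terms",
                  "protein_terms", "pathway_terms", "disease_terms",
                  sep = "\t")
  writeLines(c(header, rows), path)
  path
}

# One human gene: CAT, synonym "catalase gene symbol"? keep simple: the
# canonical single-gene fixture used throughout the thesaurus tests.
cat_thesaurus <- function() {
  load_thesaurus(write_thesaurus_tsv(paste(
    "Q1", "human", "CAT", "catalase",
    "catalase protein", "peroxisome pathway", "acatalasemia",
    sep = "\t")))
}

make_corpus <- function(...) {
  docs <- list(...)
  data.frame(doc_id = vapply(docs, `[[`, character(1), 1L),
             title = vapply(docs, `[[`, character(1), 2L),
             abstract = vapply(docs, function(d)
               if (length(d) > 2L) d[[3L]] else "", character(1)),
             stringsAsFactors = FALSE)
}

terms_df <- function(text, boost = 1) {
  data.frame(text = text, boost = rep(boost, length.out = length(text)),
             stringsAsFactors = FALSE)
}

gene_rec <- function(id, organism = "human", symbol = id,
                     gene = character(0), protein = character(0),
                     pathway = character(0), disease = character(0)) {
  structure(list(internal_id = id, organism = organism,
                 primary_symbol = symbol,
                 gene_terms = unique(c(symbol, gene)),
                 protein_terms = protein, pathway_terms = pathway,
                 disease_terms = disease),
            class = "gene_record")
}
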