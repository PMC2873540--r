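#' Expand mapped genes into four concept-class term sets
#'
#' For each gene the expansion collects all alternative gene names and
#' symbols, protein names, and the associated pathway and disease names,
#' accumulated into four separate per-class term lists. Gene and protein
#' terms always carry boost 1. A pathway or disease term linked to more
#' than one input gene is given an increased weight so that documents
#' containing it score higher: with the default linear scheme the boost
#' equals the number of distinct input genes linked to the term (three
#' genes sharing a pathway give its name boost 3). Within a class, terms
#' are deduplicated case-insensitively, keeping the maximal boost.
#'
#' @param genes Non-empty list of `gene_record`s, all from one organism
#'   (as returned by [map_genes()]).
#' @param boost_fun Function mapping the count of distinct linked input
#'   genes to a boost for pathway/disease terms. Default is `identity`
#'   (linear multiplicity); must return values >= 1.
#' @return An object of class `expanded_query`: a list with data-frame
#'   slots `gene`, `protein`, `pathway`, `disease` (columns `text`,
#'   `boost`, `source_genes`) and `source_genes`, the internal ids of the
#'   input genes.
#' @export
expand_query <- function(genes, boost_fun = identity) {
  if (length(genes) == 0L) stop("gene list is empty; nothing to expand")
  ok <- vapply(genes, inherits, logical(1), what = "gene_record")
  if (!all(ok)) stop("expand_query() expects a list of gene records")
  orgs <- unique(vapply(genes, `[[`, character(1), "organism"))
  if (length(orgs) > 1L) {
    stop("all genes must come from one organism; got: ",
         paste(orgs, collapse = ", "))
  }
  ids <- vapply(genes, `[[`, character(1), "internal_id")

  # per-class accumulation: lowercased key -> (first-seen text, sources)
  collect <- function(field) {
    texts <- character(0); key_of <- character(0); sources <- list()
    for (g in genes) {
      for (term in g[[field]]) {
        k <- tolower(term)
        i <- match(k, key_of)
        if (is.na(i)) {
          key_of <- c(key_of, k)
          texts <- c(texts, term)
          sources[[length(sources) + 1L]] <- g$internal_id
        } else {
          sources[[i]] <- unique(c(sources[[i]], g$internal_id))
        }
      }
    }
    list(text = texts, sources = sources)
  }

  as_terms <- function(acc, boosted) {
    n <- length(acc$text)
    boost <- rep(1, n)
    if (boosted && n) {
      boost <- vapply(acc$sources, function(s) boost_fun(length(s)), numeric(1))
      if (any(boost < 1)) stop("boost_fun must return values >= 1")
    }
    data.frame(text = acc$text, boost = boost,
               source_genes = vapply(acc$sources, paste, character(1),
                                     collapse = "|"),
               stringsAsFactors = FALSE)
  }

  eq <- list(gene = as_terms(collect("gene_terms"), boosted = FALSE),
             protein = as_terms(collect("protein_terms"), boosted = FALSE),
             pathway = as_terms(collect("pathway_terms"), boosted = TRUE),
             disease = as_terms(collect("disease_terms"), boosted = TRUE),
             source_genes = ids)
  class(eq) <- "expanded_query"
  eq
}

#' Concept classes in canonical order
#' @return `c("gene", "protein", "pathway", "disease")`
#' @export
concept_classes <- function() c("gene", "protein", "pathway", "disease")

#' Extract the four class term lists from an expanded query
#'
#' Returns the four per-class weighted term lists in fixed order (gene,
#' protein, pathway, disease); empty classes are preserved as zero-row
#' data frames so downstream code always sees all four classes.
#'
#' @param eq An `expanded_query`.
#' @return Named list of four data frames with columns `text`, `boost`,
#'   `source_genes`.
#' @export
class_queries <- function(eq) {
  stopifnot(inherits(eq, "expanded_query"))
  eq[concept_classes()]
}

#' @export
print.expanded_query <- function(x, ...) {
  cat("<expanded_query> from ", length(x$source_genes), " gene(s): ",
      paste(vapply(concept_classes(),
                   function(cl) paste0(nrow(x[[cl]]), " ", cl),
                   character(1)), collapse = ", "), " terms\n", sep = "")
  invisible(x)
}

#' Dump an expanded query as JSON
#'
#' Machine-readable listing of class, term, boost and source gene ids —
#' the expansion panel a user would inspect to see which terms the query
#' grew into.
#'
#' @param eq An `expanded_query`.
#' @param path Destination JSON file.
#' @return `path`, invisibly.
#' @export
dump_expansion <- function(eq, path) {
  stopifnot(inherits(eq, "expanded_query"))
  out <- lapply(class_queries(eq), function(df) {
    lapply(seq_len(nrow(df)), function(i) {
      list(term = df$text[i], boost = df$boost[i],
           source_genes = strsplit(df$source_genes[i], "|", fixed = TRUE)[[1L]])
    })
  })
  jsonlite::write_json(list(source_genes = eq$source_genes, classes = out),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
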