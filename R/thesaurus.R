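#' Reference organisms
#'
#' Default controlled list of organism tags accepted in thesaurus files
#' and queries: human, mouse, rat, Candida albicans, Saccharomyces
#' cerevisiae, Drosophila melanogaster and Apis mellifera.
#'
#' @return Character vector of organism tags.
#' @export
default_organisms <- function() {
  c("human", "mouse", "rat", "c_albicans", "s_cerevisiae",
    "d_melanogaster", "a_mellifera")
}

#' Load a concept thesaurus from TSV
#'
#' The thesaurus maps organism-scoped gene identifiers and symbols to an
#' internal identifier and to its four concept-class term lists (gene
#' names/symbols including synonyms, protein names, pathway names,
#' disease names) — the role played, in a production system, by an
#' integration of Entrez Gene, UniProt, KEGG and OMIM.
#'
#' File format: UTF-8 TSV with header row and columns
#' `internal_id organism primary_symbol gene_terms protein_terms
#' pathway_terms disease_terms`. Multi-valued columns are `|`-separated;
#' an empty cell is an empty set. Terms may contain spaces but not tabs
#' or `|`. Rows sharing an `internal_id` extend the same record; a
#' duplicate `internal_id` with a conflicting organism is an integrity
#' error.
#'
#' Lookup keys for each record are its internal id, primary symbol and
#' every gene term, all lowercased and scoped per organism.
#'
#' @param path Path to the thesaurus TSV.
#' @param organisms Controlled list of admissible organism tags.
#' @return An object of class `concept_thesaurus` with elements
#'   `records` (internal_id -> gene record) and `lookup`
#'   (organism -> lowercased key -> character vector of internal ids).
#' @export
load_thesaurus <- function(path, organisms = default_organisms()) {
  if (!file.exists(path)) stop("thesaurus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("thesaurus file is empty (no header): ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  expected <- c("internal_id", "organism", "primary_symbol", "gene_terms",
                "protein_terms", "pathway_terms", "disease_terms")
  if (!identical(header, expected)) {
    stop("thesaurus header must be: ", paste(expected, collapse = "\t"))
  }
  records <- list()
  for (ln in seq_along(lines)[-1L]) {
    row <- lines[[ln]]
    if (!nzchar(row)) next
    cells <- strsplit(row, "\t", fixed = TRUE)[[1L]]
    # a trailing empty cell is dropped by strsplit; pad back
    if (length(cells) < 7L) cells <- c(cells, rep("", 7L - length(cells)))
    if (length(cells) != 7L) {
      stop("malformed thesaurus row at line ", ln, ": expected 7 columns")
    }
    id <- cells[[1L]]; org <- cells[[2L]]; sym <- cells[[3L]]
    if (!nzchar(id) || !nzchar(sym)) {
      stop("malformed thesaurus row at line ", ln,
           ": internal_id and primary_symbol are required")
    }
    if (!(org %in% organisms)) {
      stop("unknown organism '", org, "' at line ", ln,
           " (expected one of: ", paste(organisms, collapse = ", "), ")")
    }
    split_terms <- function(cell) {
      if (!nzchar(cell)) return(character(0))
      terms <- strsplit(cell, "|", fixed = TRUE)[[1L]]
      trimws(terms[nzchar(trimws(terms))])
    }
    gene_terms <- unique(c(sym, split_terms(cells[[4L]])))
    rec <- records[[id]]
    if (is.null(rec)) {
      rec <- list(internal_id = id, organism = org, primary_symbol = sym,
                  gene_terms = gene_terms,
                  protein_terms = split_terms(cells[[5L]]),
                  pathway_terms = split_terms(cells[[6L]]),
                  disease_terms = split_terms(cells[[7L]]))
      class(rec) <- "gene_record"
    } else {
      if (!identical(rec$organism, org)) {
        stop("integrity error at line ", ln, ": internal_id '", id,
             "' already defined for organism '", rec$organism, "'")
      }
      rec$gene_terms <- unique(c(rec$gene_terms, gene_terms))
      rec$protein_terms <- unique(c(rec$protein_terms, split_terms(cells[[5L]])))
      rec$pathway_terms <- unique(c(rec$pathway_terms, split_terms(cells[[6L]])))
      rec$disease_terms <- unique(c(rec$disease_terms, split_terms(cells[[7L]])))
    }
    records[[id]] <- rec
  }
  lookup <- list()
  for (rec in records) {
    org <- rec$organism
    if (is.null(lookup[[org]])) lookup[[org]] <- list()
    keys <- unique(tolower(c(rec$internal_id, rec$primary_symbol,
                             rec$gene_terms)))
    for (k in keys) {
      lookup[[org]][[k]] <- unique(c(lookup[[org]][[k]], rec$internal_id))
    }
  }
  structure(list(records = records, lookup = lookup, organisms = organisms),
            class = "concept_thesaurus")
}

#' @export
print.concept_thesaurus <- function(x, ...) {
  cat("<concept_thesaurus> ", length(x$records), " gene records across ",
      length(x$lookup), " organism(s)\n", sep = "")
  invisible(x)
}

#' @export
print.gene_record <- function(x, ...) {
  cat("<gene_record> ", x$internal_id, " (", x$organism, ") ",
      x$primary_symbol, ": ",
      length(x$gene_terms), " gene / ",
      length(x$protein_terms), " protein / ",
      length(x$pathway_terms), " pathway / ",
      length(x$disease_terms), " disease terms\n", sep = "")
  invisible(x)
}

#' Map user-supplied gene identifiers to thesaurus records
#'
#' Each input is matched case-insensitively, by exact string match, against
#' the lookup keys of the chosen organism only — scoping by organism is
#' what resolves cross-organism homonyms. Matched inputs yield their gene
#' records, deduplicated by internal id with input order preserved over
#' first occurrences. Inputs that match nothing, and inputs that are
#' ambiguous within the organism (one string naming two distinct internal
#' ids), are returned in the `unmatched` table with a reason tag — never
#' silently dropped. No fuzzy matching is attempted.
#'
#' @param inputs Non-empty character vector of gene identifiers/symbols.
#' @param organism Organism tag (must be in the thesaurus's controlled list).
#' @param thesaurus A `concept_thesaurus` from [load_thesaurus()].
#' @return List with `records` (list of `gene_record`) and `unmatched`
#'   (data frame with columns `input`, `reason`; reasons are
#'   `"not_found"` or `"ambiguous"`).
#' @export
map_genes <- function(inputs, organism, thesaurus) {
  stopifnot(inherits(thesaurus, "concept_thesaurus"))
  if (length(inputs) == 0L) stop("gene input list is empty")
  if (!(organism %in% thesaurus$organisms)) {
    stop("unknown organism '", organism, "'")
  }
  tab <- thesaurus$lookup[[organism]]
  seen <- character(0)
  records <- list()
  unmatched <- data.frame(input = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  for (g in inputs) {
    ids <- tab[[tolower(g)]]
    if (is.null(ids)) {
      unmatched <- rbind(unmatched, data.frame(input = g, reason = "not_found"))
    } else if (length(ids) > 1L) {
      unmatched <- rbind(unmatched, data.frame(input = g, reason = "ambiguous"))
    } else if (!(ids %in% seen)) {
      seen <- c(seen, ids)
      records[[length(records) + 1L]] <- thesaurus$records[[ids]]
    }
  }
  if (!length(records)) {
    cnd <- simpleError(paste0("no genes mapped for organism '", organism,
                              "'; unmatched: ",
                              paste(unmatched$input, collapse = ", ")))
    class(cnd) <- c("litexpand_no_genes_mapped", class(cnd))
    cnd$unmatched <- unmatched
    stop(cnd)
  }
  list(records = records, unmatched = unmatched)
}
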