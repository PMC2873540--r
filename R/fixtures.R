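#' Specification for a synthetic retrieval benchmark
#'
#' Describes a fully synthetic, download-free benchmark: a concept
#' thesaurus, an abstract corpus with planted term occurrences, a topics
#' file and TREC-format qrels. The same seed always yields byte-identical
#' files.
#'
#' Relevant documents for a topic always contain at least one term from
#' the expansion of the topic's genes. A controlled subset of them
#' (`expansion_only_fraction`) contains only protein/pathway/disease
#' terms and no gene name or synonym: these documents are unreachable by
#' a gene-terms-only query, which is what makes the
#' expansion-beats-baseline comparison non-vacuous. Irrelevant documents
#' are drawn from a disjoint background vocabulary, with a configurable
#' low `collision_rate` at which a single expansion term of some random
#' gene is planted into an otherwise irrelevant document (emulating
#' incidental mentions that retrieval must rank below truly relevant
#' documents).
#'
#' @param n_genes Number of genes in the thesaurus.
#' @param synonyms_per_gene Gene-name synonyms per gene (besides the
#'   primary symbol).
#' @param proteins_per_gene Protein names per gene (two-word phrases).
#' @param n_shared_pathways Pathway names, each linked to 2-3 genes.
#' @param n_shared_diseases Disease names, each linked to 2-3 genes.
#' @param n_docs Corpus size.
#' @param relevant_fraction Fraction of the corpus that is relevant to
#'   each topic (per-topic relevant count = `round(relevant_fraction *
#'   n_docs)`).
#' @param expansion_only_fraction Fraction of each topic's relevant
#'   documents that carry no gene-class term
#'   (count = `round(fraction * n_relevant)`).
#' @param background_vocab_size Size of the background word pool.
#' @param doc_length_range Two integers: min/max document length in
#'   tokens before planting.
#' @param n_topics Number of evaluation topics.
#' @param genes_per_topic Genes per topic.
#' @param collision_rate Probability that an irrelevant document receives
#'   one planted expansion term.
#' @param organism Organism tag used throughout.
#' @param seed Integer seed; fixes everything.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 12, synonyms_per_gene = 2,
                         proteins_per_gene = 2, n_shared_pathways = 4,
                         n_shared_diseases = 3, n_docs = 240,
                         relevant_fraction = 0.05,
                         expansion_only_fraction = 0.3,
                         background_vocab_size = 500,
                         doc_length_range = c(40L, 120L),
                         n_topics = 4, genes_per_topic = 3,
                         collision_rate = 0.02,
                         organism = "human", seed = 42L) {
  spec <- list(n_genes = as.integer(n_genes),
               synonyms_per_gene = as.integer(synonyms_per_gene),
               proteins_per_gene = as.integer(proteins_per_gene),
               n_shared_pathways = as.integer(n_shared_pathways),
               n_shared_diseases = as.integer(n_shared_diseases),
               n_docs = as.integer(n_docs),
               relevant_fraction = relevant_fraction,
               expansion_only_fraction = expansion_only_fraction,
               background_vocab_size = as.integer(background_vocab_size),
               doc_length_range = as.integer(doc_length_range),
               n_topics = as.integer(n_topics),
               genes_per_topic = as.integer(genes_per_topic),
               collision_rate = collision_rate,
               organism = organism,
               seed = as.integer(seed))
  counts <- c(spec$n_genes, spec$synonyms_per_gene, spec$proteins_per_gene,
              spec$n_shared_pathways, spec$n_shared_diseases, spec$n_docs,
              spec$background_vocab_size, spec$n_topics,
              spec$genes_per_topic)
  if (any(counts < 0)) stop("fixture counts must be >= 0")
  if (spec$n_genes < 1 || spec$n_topics < 1 || spec$n_docs < 1) {
    stop("n_genes, n_topics and n_docs must be >= 1")
  }
  if (spec$relevant_fraction <= 0 || spec$relevant_fraction >= 1) {
    stop("relevant_fraction must lie in (0, 1)")
  }
  if (spec$expansion_only_fraction < 0 || spec$expansion_only_fraction > 1) {
    stop("expansion_only_fraction must lie in [0, 1]")
  }
  if (spec$collision_rate < 0 || spec$collision_rate > 1) {
    stop("collision_rate must lie in [0, 1]")
  }
  if (length(spec$doc_length_range) != 2L ||
      spec$doc_length_range[1L] < 1L ||
      diff(spec$doc_length_range) < 0L) {
    stop("doc_length_range must be two increasing positive integers")
  }
  if (spec$genes_per_topic > spec$n_genes) {
    stop("genes_per_topic cannot exceed n_genes")
  }
  n_rel <- round(spec$relevant_fraction * spec$n_docs)
  if (spec$n_topics * n_rel > spec$n_docs) {
    stop("n_topics * round(relevant_fraction * n_docs) exceeds n_docs")
  }
  structure(spec, class = "fixture_spec")
}

# Build the in-memory gene table for a spec (terms only, no I/O).
.fixture_genes <- function(spec) {
  genes <- lapply(seq_len(spec$n_genes), function(i) {
    list(internal_id = sprintf("GX%03d", i),
         symbol = sprintf("gsym%03d", i),
         synonyms = if (spec$synonyms_per_gene > 0)
           sprintf("gsyn%03dv%d", i, seq_len(spec$synonyms_per_gene))
         else character(0),
         proteins = if (spec$proteins_per_gene > 0)
           sprintf("prtn%03dv%d protein", i, seq_len(spec$proteins_per_gene))
         else character(0),
         pathways = character(0),
         diseases = character(0))
  })
  link <- function(genes, n, namer) {
    for (k in seq_len(n)) {
      members <- sample(spec$n_genes, min(sample(2:3, 1L), spec$n_genes))
      for (i in members) {
        slot <- if (identical(namer, "pathway")) "pathways" else "diseases"
        term <- if (identical(namer, "pathway"))
          sprintf("pthw%03d signaling", k) else sprintf("dise%03d syndrome", k)
        genes[[i]][[slot]] <- c(genes[[i]][[slot]], term)
      }
    }
    genes
  }
  genes <- link(genes, spec$n_shared_pathways, "pathway")
  link(genes, spec$n_shared_diseases, "disease")
}

#' Generate a synthetic benchmark (thesaurus, corpus, topics, qrels)
#'
#' Writes the four files in the TSV/TREC dialects consumed by
#' [load_thesaurus()], [read_corpus()], [read_topics()] and
#' [read_qrels()]. Deterministic under the spec's seed; the caller's RNG
#' state is left untouched.
#'
#' Document ids are zero-padded integers assigned in shuffled order, so
#' that the descending-id tie-break of [fuse()] is exercised
#' deterministically and relevance is uncorrelated with id.
#'
#' @param spec A `fixture_spec`.
#' @param dir Output directory (created if missing).
#' @return List with paths `thesaurus`, `corpus`, `topics`, `qrels` and a
#'   `truth` list (per-topic relevant and expansion-only doc ids),
#'   invisibly.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  genes <- .fixture_genes(spec)
  vocab <- sprintf("bgwrd%04d", seq_len(spec$background_vocab_size))

  # topics: sampled gene subsets, one organism throughout
  topics <- lapply(seq_len(spec$n_topics), function(t) {
    idx <- sample(spec$n_genes, spec$genes_per_topic)
    list(topic_id = as.character(t), gene_idx = idx,
         symbols = vapply(genes[idx], `[[`, character(1), "symbol"))
  })

  n_rel <- round(spec$relevant_fraction * spec$n_docs)
  n_exp_only <- round(spec$expansion_only_fraction * n_rel)

  gene_class_terms <- function(idx) {
    unlist(lapply(genes[idx], function(g) c(g$symbol, g$synonyms)))
  }
  nongene_terms <- function(idx) {
    unlist(lapply(genes[idx], function(g) c(g$proteins, g$pathways,
                                            g$diseases)))
  }
  all_terms <- function(idx) c(gene_class_terms(idx), nongene_terms(idx))

  rand_len <- function() {
    sample(seq(spec$doc_length_range[1L], spec$doc_length_range[2L]), 1L)
  }
  plant <- function(base, terms) {
    # insert each term (itself possibly multi-word) at a random gap of the
    # original base; blocks may touch but can never interleave, so a
    # planted phrase is always matchable
    gaps <- sample(length(base) + 1L, length(terms), replace = TRUE)
    out <- vector("list", 0L)
    for (g in seq_len(length(base) + 1L)) {
      for (k in which(gaps == g)) {
        out[[length(out) + 1L]] <- strsplit(terms[k], " ", fixed = TRUE)[[1L]]
      }
      if (g <= length(base)) out[[length(out) + 1L]] <- base[g]
    }
    unlist(out)
  }

  docs <- vector("list", spec$n_docs)
  relevant <- lapply(topics, function(t) character(0))
  names(relevant) <- vapply(topics, `[[`, character(1), "topic_id")
  exp_only <- relevant
  slot <- 1L
  for (t in topics) {
    pool_ng <- nongene_terms(t$gene_idx)
    pool_g <- gene_class_terms(t$gene_idx)
    for (j in seq_len(n_rel)) {
      base <- sample(vocab, rand_len(), replace = TRUE)
      if (j <= n_exp_only && length(pool_ng)) {
        planted <- sample(pool_ng, min(sample(1:2, 1L), length(pool_ng)))
        is_exp_only <- TRUE
      } else {
        planted <- sample(pool_g, 1L)
        if (stats::runif(1) < 0.7 && length(pool_ng)) {
          planted <- c(planted, sample(pool_ng, 1L))
        }
        is_exp_only <- FALSE
      }
      docs[[slot]] <- list(tokens = plant(base, planted),
                           topic = t$topic_id, exp_only = is_exp_only)
      slot <- slot + 1L
    }
  }
  all_idx <- seq_len(spec$n_genes)
  while (slot <= spec$n_docs) {
    base <- sample(vocab, rand_len(), replace = TRUE)
    if (stats::runif(1) < spec$collision_rate) {
      base <- plant(base, sample(all_terms(all_idx), 1L))
    }
    docs[[slot]] <- list(tokens = base, topic = NA_character_,
                         exp_only = FALSE)
    slot <- slot + 1L
  }

  ids <- sprintf("%08d", sample(spec$n_docs))
  for (i in seq_len(spec$n_docs)) {
    d <- docs[[i]]
    if (!is.na(d$topic)) {
      relevant[[d$topic]] <- c(relevant[[d$topic]], ids[i])
      if (d$exp_only) exp_only[[d$topic]] <- c(exp_only[[d$topic]], ids[i])
    }
  }

  paths <- list(thesaurus = file.path(dir, "thesaurus.tsv"),
                corpus = file.path(dir, "corpus.tsv"),
                topics = file.path(dir, "topics.tsv"),
                qrels = file.path(dir, "qrels.txt"))

  th_rows <- vapply(genes, function(g) {
    paste(g$internal_id, spec$organism, g$symbol,
          paste(g$synonyms, collapse = "|"),
          paste(g$proteins, collapse = "|"),
          paste(unique(g$pathways), collapse = "|"),
          paste(unique(g$diseases), collapse = "|"),
          sep = "\t")
  }, character(1))
  writeLines(c(paste("internal_id", "organism", "primary_symbol",
                     "gene_terms", "protein_terms", "pathway_terms",
                     "disease_terms", sep = "\t"), th_rows),
             paths$thesaurus)

  corpus_rows <- vapply(seq_len(spec$n_docs), function(i) {
    toks <- docs[[i]]$tokens
    n_title <- min(6L, length(toks))
    paste(ids[i], paste(toks[seq_len(n_title)], collapse = " "),
          paste(toks[-seq_len(n_title)], collapse = " "), sep = "\t")
  }, character(1))
  writeLines(c(paste("doc_id", "title", "abstract", sep = "\t"), corpus_rows),
             paths$corpus)

  topic_rows <- vapply(topics, function(t) {
    paste(t$topic_id, spec$organism, paste(t$symbols, collapse = "|"),
          sep = "\t")
  }, character(1))
  writeLines(c(paste("topic_id", "organism", "gene_list", sep = "\t"),
               topic_rows), paths$topics)

  qrels_rows <- unlist(lapply(names(relevant), function(tp) {
    if (!length(relevant[[tp]])) return(character(0))
    paste(tp, 0, sort(relevant[[tp]]), 1)
  }))
  writeLines(qrels_rows, paths$qrels)

  paths$truth <- list(relevant = lapply(relevant, sort),
                      expansion_only = lapply(exp_only, sort))
  invisible(paths)
}
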