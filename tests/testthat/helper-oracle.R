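# Independent brute-force scoring oracle: linear scan over raw documents
# plus direct application of the similarity formula. Shares no code with
# the package's index path.

oracle_stopwords <- c(
  "a", "an", "and", "are", "as", "at", "be", "but", "by", "for", "if",
  "in", "into", "is", "it", "no", "not", "of", "on", "or", "such",
  "that", "the", "their", "then", "there", "these", "they", "this",
  "to", "was", "will", "with")

oracle_tokens <- function(text) {
  t <- unlist(strsplit(tolower(text), "[^a-z0-9]+"))
  t <- t[nzchar(t)]
  t[!(t %in% oracle_stopwords)]
}

oracle_phrase_count <- function(toks, words) {
  k <- length(words)
  if (length(toks) < k) return(0L)
  n <- 0L
  for (i in seq_len(length(toks) - k + 1L)) {
    if (all(toks[i:(i + k - 1L)] == words)) n <- n + 1L
  }
  n
}

# terms: data.frame(text, boost). Returns named numeric doc_id -> score.
oracle_class_scores <- function(corpus, terms) {
  doc_toks <- lapply(seq_len(nrow(corpus)), function(i) {
    oracle_tokens(paste(corpus$title[i], corpus$abstract[i]))
  })
  names(doc_toks) <- corpus$doc_id
  n_docs <- nrow(corpus)
  total <- setNames(numeric(n_docs), corpus$doc_id)
  nmatch <- setNames(integer(n_docs), corpus$doc_id)
  n_valid <- 0L
  for (i in seq_len(nrow(terms))) {
    words <- oracle_tokens(terms$text[i])
    if (!length(words)) next
    n_valid <- n_valid + 1L
    freq <- vapply(doc_toks, oracle_phrase_count, integer(1), words = words)
    df <- sum(freq > 0)
    if (df == 0) next
    idf <- 1 + log(n_docs / (df + 1))
    for (d in corpus$doc_id[freq > 0]) {
      total[[d]] <- total[[d]] +
        terms$boost[i] * sqrt(freq[[d]]) * idf^2 / sqrt(length(doc_toks[[d]]))
      nmatch[[d]] <- nmatch[[d]] + 1L
    }
  }
  if (n_valid == 0L) return(setNames(numeric(0), character(0)))
  out <- total * nmatch / n_valid
  out[out > 0]
}

# Random small corpus + query for oracle-equivalence checks. Small shared
# vocabulary forces heavy term/document collisions.
oracle_random_case <- function(max_docs = 50) {
  vocab <- c("cat", "catalase", "oxidative", "stress", "gene", "protein",
             "pathway", "insulin", "signaling", "tumor", "growth", "cell",
             "membrane", "factor", "kinase", "receptor", "binding", "dna")
  n_docs <- sample(2:max_docs, 1)
  corpus <- data.frame(
    doc_id = sprintf("D%03d", seq_len(n_docs)),
    title = vapply(seq_len(n_docs), function(i)
      paste(sample(vocab, sample(2:5, 1), replace = TRUE), collapse = " "),
      character(1)),
    abstract = vapply(seq_len(n_docs), function(i)
      paste(sample(vocab, sample(3:15, 1), replace = TRUE), collapse = " "),
      character(1)),
    stringsAsFactors = FALSE)
  n_terms <- sample(1:4, 1)
  terms <- data.frame(
    text = vapply(seq_len(n_terms), function(i)
      paste(sample(vocab, sample(1:2, 1)), collapse = " "), character(1)),
    boost = sample(1:3, n_terms, replace = TRUE),
    stringsAsFactors = FALSE)
  list(corpus = corpus, terms = terms)
}

expect_scores_match_oracle <- function(corpus, terms, tol = 1e-9) {
  idx <- build_index(corpus)
  got <- score_class_query(idx, terms)
  want <- oracle_class_scores(corpus, terms)
  expect_setequal(names(got), names(want))
  if (length(want)) {
    got <- got[names(want)]
    expect_true(all(abs(got - want) <= tol * pmax(abs(want), 1e-300)))
  }
}
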