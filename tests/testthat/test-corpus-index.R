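test_that("tokenizer lowercases, splits on punctuation and drops stopwords", {
  expect_identical(tokenize("ATP-binding cassette sub-family A member 1"),
                   c("atp", "binding", "cassette", "sub", "family",
                     "member", "1"))
  expect_identical(tokenize(""), character(0))
  expect_identical(tokenize("The CAT gene"), c("cat", "gene"))
  expect_identical(tokenize("ABC-1"), c("abc", "1"))
})

test_that("tokenizer is idempotent on its own output", {
  for (txt in c("Oxidative stress in the cell!", "ABC-1 and ABC 1",
                "insulin-signaling pathway")) {
    once <- tokenize(txt)
    expect_identical(tokenize(paste(once, collapse = " ")), once)
  }
})

test_that("index counts documents, postings and field lengths", {
  idx <- build_index(make_corpus(list("1", "cat"), list("2", "cat")))
  expect_identical(idx$n_docs, 2L)
  expect_length(idx$postings[["cat"]], 2)

  empty <- build_index(make_corpus())
  expect_identical(empty$n_docs, 0L)
  expect_length(empty$postings, 0)

  # empty abstract: length counts title tokens only
  idx2 <- build_index(make_corpus(list("7", "oxidative stress response")))
  expect_identical(unname(idx2$doc_len["7"]), 3L)

  expect_error(build_index(make_corpus(list("1", "a"), list("1", "b"))),
               "duplicate doc_id")
})

test_that("single-term score follows the documented formula exactly", {
  # one doc, 4 tokens, one occurrence of "cat": sqrt(1) * (1+ln(1/2))^2 * 1/2
  idx <- build_index(make_corpus(list("d1", "cat dog fish bird")))
  got <- score_term_query(idx, "cat")
  expect_identical(got$doc_id, "d1")
  expect_equal(got$score, (1 + log(1 / 2))^2 / 2, tolerance = 1e-12)

  # boost is a plain multiplier
  expect_equal(score_term_query(idx, "cat", boost = 3)$score,
               3 * got$score, tolerance = 1e-12)

  expect_identical(nrow(score_term_query(idx, "zebra")), 0L)
  expect_warning(out <- score_term_query(idx, "the of and"), "no tokens")
  expect_identical(nrow(out), 0L)
})

test_that("multi-word terms match only as consecutive in-order phrases", {
  idx <- build_index(make_corpus(
    list("adjacent", "oxidative stress damages cells"),
    list("gapped", "oxidative cellular stress"),
    list("reversed", "stress oxidative response"),
    list("stopgap", "oxidative the stress")))  # stopword removed -> adjacent
  got <- score_term_query(idx, "oxidative stress")
  expect_setequal(got$doc_id, c("adjacent", "stopgap"))
})

test_that("class query applies the coordination factor", {
  idx <- build_index(make_corpus(
    list("both", "cat dog"), list("one", "cat fish")))
  single <- score_class_query(idx, terms_df("cat"))
  pair <- score_class_query(idx, terms_df(c("cat", "dog")))
  # "one" matches 1 of 2 terms: halved relative to its single-term score
  expect_equal(pair[["one"]], single[["one"]] / 2, tolerance = 1e-12)
  # "both" matches 2 of 2: coordination 1 (sum of both contributions)
  dog <- score_class_query(idx, terms_df("dog"))
  expect_equal(pair[["both"]], single[["both"]] + dog[["both"]],
               tolerance = 1e-12)
  expect_length(score_class_query(idx, terms_df(character(0))), 0)
})

test_that("shorter documents outscore longer ones on the same term", {
  idx <- build_index(make_corpus(
    list("short", "cat dog"),
    list("long", "cat dog bird fish mouse horse")))
  s <- score_class_query(idx, terms_df("cat"))
  expect_gt(s[["short"]], s[["long"]])
})

test_that("all returned scores are strictly positive", {
  set.seed(101)
  for (i in 1:20) {
    case <- oracle_random_case(max_docs = 15)
    idx <- build_index(case$corpus)
    s <- score_class_query(idx, case$terms)
    expect_true(all(s > 0))
  }
})

test_that("a non-matching document changes scores only through idf", {
  idx <- build_index(make_corpus(
    list("a", "cat dog fish"), list("b", "cat bird")))
  before <- score_class_query(idx, terms_df("cat"))
  idx2 <- build_index(make_corpus(
    list("a", "cat dog fish"), list("b", "cat bird"),
    list("c", "zebra lion")))
  after <- score_class_query(idx2, terms_df("cat"))
  # df fixed at 2; only n_docs moved 2 -> 3, so every score scales by the
  # squared idf ratio
  ratio <- (1 + log(3 / 3))^2 / (1 + log(2 / 3))^2
  expect_equal(after[names(before)], before * ratio, tolerance = 1e-12)
})

test_that("class scores match the brute-force oracle on random corpora", {
  set.seed(202)
  for (i in 1:40) {
    case <- oracle_random_case(max_docs = 25)
    expect_scores_match_oracle(case$corpus, case$terms)
  }
})

test_that("index save/load round-trip reproduces identical scores", {
  set.seed(303)
  case <- oracle_random_case(max_docs = 20)
  idx <- build_index(case$corpus)
  path <- tempfile(fileext = ".idx")
  save_index(idx, path)
  idx2 <- load_index(path)
  s1 <- score_class_query(idx, case$terms)
  s2 <- score_class_query(idx2, case$terms)
  expect_identical(s1, s2)
})
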