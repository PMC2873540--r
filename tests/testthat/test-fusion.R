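test_that("score tables align on the union of doc ids, filling zeros", {
  tab <- assemble_scores(gene = c(a = 5.0),
                         protein = c(a = 3.47, b = 1.2),
                         disease = c(a = 3.0, c = 0.4))
  expect_setequal(tab$doc_id, c("a", "b", "c"))
  arow <- tab[tab$doc_id == "a", ]
  expect_equal(unlist(arow[c("s_gene", "s_protein", "s_pathway",
                             "s_disease")], use.names = FALSE),
               c(5.0, 3.47, 0, 3.0))
  brow <- tab[tab$doc_id == "b", ]
  expect_equal(unlist(brow[c("s_gene", "s_protein", "s_pathway",
                             "s_disease")], use.names = FALSE),
               c(0, 1.2, 0, 0))
})

test_that("weighted fusion reproduces the worked example", {
  tab <- assemble_scores(gene = c(d = 5.00), protein = c(d = 3.47),
                         disease = c(d = 3.00))
  out <- fuse(tab, fusion_weights(0.5, 0.3, 0.1, 0.1))
  expect_equal(out$final_score, 5.0 * 0.5 + 3.47 * 0.3 + 3.0 * 0.1,
               tolerance = 1e-12)
  expect_identical(sprintf("%.2f", out$final_score), "3.84")
  expect_identical(out$relative_score, 1)
})

test_that("unit weight on one class projects that class's scores", {
  tab <- assemble_scores(gene = c(a = 2, b = 7), protein = c(a = 9),
                         pathway = c(b = 1), disease = c(a = 4, b = 5))
  out <- fuse(tab, fusion_weights(1, 0, 0, 0))
  expect_equal(setNames(out$final_score, out$doc_id)[c("a", "b")],
               c(a = 2, b = 7))
  dis <- fuse(tab, fusion_weights(0, 0, 0, 1))
  expect_identical(dis$doc_id[1], "b")
  expect_equal(dis$final_score, c(5, 4))
})

test_that("results are sorted with ties broken by descending doc id", {
  tab <- assemble_scores(gene = c(`00000003` = 1, `00000009` = 1,
                                  `00000005` = 2))
  out <- fuse(tab, fusion_weights(1, 0, 0, 0))
  expect_identical(out$doc_id, c("00000005", "00000009", "00000003"))
  expect_identical(out$rank, 1:3)
  expect_identical(out$relative_score[1], 1)
})

test_that("fusion is linear in the weights", {
  set.seed(505)
  ids <- sprintf("%05d", 1:20)
  tab <- assemble_scores(
    gene = setNames(runif(20), ids), protein = setNames(runif(20), ids),
    pathway = setNames(runif(20), ids), disease = setNames(runif(20), ids))
  w1 <- c(0.5, 0.3, 0.1, 0.1); w2 <- c(1, 0, 2, 0.5)
  a <- 0.7; b <- 1.9
  mix <- a * w1 + b * w2
  f_mix <- fuse(tab, do.call(fusion_weights, as.list(mix)))
  f1 <- fuse(tab, do.call(fusion_weights, as.list(w1)))
  f2 <- fuse(tab, do.call(fusion_weights, as.list(w2)))
  key <- function(r) setNames(r$final_score, r$doc_id)[ids]
  expect_equal(key(f_mix), a * key(f1) + b * key(f2), tolerance = 1e-12)
})

test_that("scaling all weights leaves order and relative scores unchanged", {
  set.seed(506)
  ids <- sprintf("%05d", 1:15)
  tab <- assemble_scores(gene = setNames(runif(15), ids),
                         protein = setNames(runif(15), ids))
  base <- fuse(tab, fusion_weights(0.5, 0.3, 0.1, 0.1))
  scaled <- fuse(tab, fusion_weights(5, 3, 1, 1))
  expect_identical(scaled$doc_id, base$doc_id)
  expect_equal(scaled$relative_score, base$relative_score, tolerance = 1e-12)
})

test_that("raising one class weight never hurts docs scoring in that class", {
  set.seed(507)
  ids <- sprintf("%05d", 1:12)
  tab <- assemble_scores(gene = setNames(runif(12), ids),
                         pathway = setNames(runif(12), ids))
  lo <- fuse(tab, fusion_weights(0.5, 0.3, 0.1, 0.1))
  hi <- fuse(tab, fusion_weights(0.5, 0.3, 0.9, 0.1))
  key <- function(r) setNames(r$final_score, r$doc_id)[ids]
  expect_true(all(key(hi) >= key(lo)))
})

test_that("re-ranking is pure and reproduces fusion exactly", {
  tab <- assemble_scores(gene = c(a = 1, b = 3), protein = c(a = 2))
  w <- fusion_weights()
  expect_identical(rerank(tab, w), fuse(tab, w))
  reset_retrieval_count()
  for (i in 1:5) rerank(tab, fusion_weights(i, 1, 0, 0))
  expect_identical(retrieval_count(), 0L)
})

test_that("degenerate inputs: zero weights error, all-zero scores rank flat", {
  tab <- assemble_scores(gene = c(a = 1))
  expect_error(fuse(tab, fusion_weights(0, 0, 0, 0)), "no active")
  expect_error(fusion_weights(-1, 0, 0, 0), ">= 0")
  # a table whose active classes carry no weight: all finals zero
  out <- fuse(assemble_scores(gene = c(a = 1, b = 2)),
              fusion_weights(0, 1, 0, 0))
  expect_true(all(out$final_score == 0))
  expect_true(all(out$relative_score == 0))
})

test_that("ranked TSV has the documented columns", {
  tab <- assemble_scores(gene = c(a = 1, b = 3))
  path <- tempfile(fileext = ".tsv")
  write_ranked(fuse(tab, fusion_weights()), path)
  got <- read.delim(path)
  expect_identical(names(got),
                   c("rank", "doc_id", "final_score", "relative_score",
                     "s_gene", "s_protein", "s_pathway", "s_disease"))
  expect_identical(nrow(got), 2L)
})
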