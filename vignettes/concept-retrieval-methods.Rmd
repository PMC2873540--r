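---
title: "Methods: concept-based expansion, per-class scoring and weighted fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concept-based expansion, per-class scoring and weighted fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litexpand)
```

## The retrieval model

`litexpand` ranks literature abstracts for a *set* of genes rather than a
single keyword. The pipeline has a retrieval half and a ranking half, and
the boundary between them is deliberate: everything up to the per-class
score table is computed once per query, while the final ranking is a
cheap, pure function of that table and the user's weights.

**Gene mapping.** Inputs are matched case-insensitively, by exact string
match, against the lookup keys (internal id, primary symbol, every gene
synonym) of the selected organism only. Exact matching is a considered
choice: fuzzy or string-similarity matching of gene symbols is a research
problem of its own and silently "correcting" user input is worse than
reporting it unmatched. Organism scoping resolves cross-organism homonyms
(the same symbol naming different genes in human and mouse). For homonyms
*within* an organism — one string naming two internal ids — we refuse to
guess and return the input tagged `ambiguous`; any other convention would
pick a gene the user may not mean.

**Concept expansion.** Each mapped gene contributes its terms to four
separate class queries: gene names/symbols, protein names, pathway names,
disease names. Gene and protein terms always carry boost 1. Pathway and
disease terms carry boost equal to the number of *distinct* input genes
linked to them: shared biology is exactly what a gene-list query is
after, so a pathway tying three of the input genes together should, and
does, weigh three times a private one. Linear multiplicity is the
simplest monotone scheme with that property; `expand_query(boost_fun =)`
accepts any alternative (e.g. `function(k) 1 + log(k)`) for users who
find linear growth too aggressive on large lists. Duplicate terms within
a class are merged case-insensitively keeping the maximal boost, which
never lowers a term's influence.

**Per-class scoring.** Title and abstract are tokenized (lowercased
maximal runs of letters/digits — hyphens split, so "ABC-1" matches "abc
1"; a fixed 33-word English stopword list, shipped as a replaceable text
file, is removed; no stemming) and indexed as one single field. A
multi-word term matches only as an exact phrase, with adjacency counted
after stopword removal; phrase semantics keep long protein names from
degenerating into bags of common words. For a term with boost $b$ the
per-document contribution is

$$ b \cdot \sqrt{tf} \cdot \left(1 + \ln\frac{N}{df+1}\right)^2 \cdot
   \frac{1}{\sqrt{|d|}} $$

with $tf$ the phrase/token frequency, $df$ the document frequency of the
phrase, $N$ the corpus size and $|d|$ the document's token count. A class
query is the disjunction of its terms: contributions are summed and
multiplied by a coordination factor (distinct terms matched / terms in
the query). This is the classic structure of Lucene-style TF–IDF
similarity (square-root tf saturation, smoothed squared idf,
inverse-square-root length normalization, coordination reward,
multiplicative boost). We deliberately fix our own self-contained variant
rather than chase parity with any particular engine version: no query
norm is applied, since it does not affect ranking order and leaving it
out makes every score reproducible bit-for-bit from the formula above —
the correctness claim is equivalence with an independent brute-force
linear-scan scorer, which the test suite checks to 1e-9 relative on
hundreds of random corpora. Note that $1 + \ln(N/(df+1)) > 0$ whenever
$df \le N$, so every returned score is strictly positive; absence means
zero by convention. All matching documents are returned (no internal
top-K cut), so fusion always sees complete class tables; display capping
is applied only after fusion.

Title and abstract tokens are indexed uniformly — a single field admits
no per-field weighting, and we saw no principled constant to prefer
titles by.

**Weighted fusion.** With per-class scores $s_{ij}$ and class weights
$W_j$,

$$ final_i = \sum_j W_j \, s_{ij}, $$

then all final scores are divided by the maximum to give relative scores
in $[0,1]$ (at full precision; rounding is a display concern). Weights
are raw non-negative reals with no sum-to-one constraint: normalization
makes only their ratios matter, so a UI is free to present 0–100 sliders.
The default `fusion_weights()` of 0.5/0.3/0.1/0.1 favours direct
gene-name evidence while keeping the other classes audible. Ties in the
final score are broken by descending document id — for zero-padded
PMID-style ids a recency proxy; some deterministic rule is needed and
recency is the least arbitrary. Degenerate cases are defined, not
errors-by-accident: all-zero weights raise "no active concept classes",
while a table whose active classes are all zero ranks flat with every
relative score 0 (no division by zero). Because `rerank()` is a pure
function of the stored table and the weights, weight sweeps cost no
retrieval; an instrumentation counter (`retrieval_count()`) lets tests
assert exactly that.

## Evaluation harness

`evaluate_run()` follows trec_eval conventions: average precision uses
the *total* number of judged-relevant documents as denominator (so
unretrieved relevant documents count against the run), graded judgments
binarize at grade > 0, MAP is the unweighted mean of per-topic APs, and
topics with no relevant documents are excluded with a warning rather
than polluting the mean. Relevant-in-top-k is reported both as a raw
count and as P@k. Topic files are inputs, not shipped artifacts: a topic
is just an organism plus a gene list, the gene-name-only reduction of a
full information request.

## What the synthetic benchmark emulates — and what it does not

`generate_fixture()` builds a thesaurus, a corpus, topics and qrels with
*planted* term occurrences. Its defaults define the study conditions
used throughout the tests and the acceptance script: 12 genes with 2
synonyms and 2 protein names each, 4 shared pathways and 3 shared
diseases (each linked to 2–3 genes), 240 documents of 40–120 background
tokens, 4 topics of 3 genes, per-topic relevant fraction 0.05 (12
relevant documents per topic), and a 2% collision rate at which an
otherwise irrelevant document receives one incidental expansion term.
These sizes are large enough for idf, length normalization and the
coordination factor to matter, while keeping the whole suite fast.

Two construction guarantees make the benchmark informative rather than
decorative. Every relevant document contains at least one term from its
topic's expansion, so the fully expanded query has recall 1 by
construction. And a controlled 30% of each topic's relevant documents
contain *only* protein/pathway/disease terms — no gene name or synonym —
so they are provably unreachable by a gene-terms-only query. That is
what makes the expanded-beats-baseline comparison non-vacuous: the
baseline's MAP is strictly lower because part of the relevant set is
invisible to it, which is the qualitative phenomenon concept expansion
exists to fix. Setting `expansion_only_fraction = 0` collapses the two
runs to identical relevant sets, and the tests check both directions.
The "gene-terms-only baseline" is implemented as retrieval restricted to
the gene concept class (names and synonyms included); restricting
further to the literal user input would only widen the gap.

The generator does *not* model real abstracts: background tokens are
drawn uniformly from a synthetic vocabulary disjoint from all concept
terms, so there is no Zipfian word distribution, no morphological
variation of gene symbols, no polysemy between concept terms and
ordinary English, and planted terms appear verbatim. Passing tests
therefore demonstrate that the machinery — mapping, expansion, phrase
matching, scoring, fusion, evaluation — is correct and that expansion
recovers documents gene names cannot, on corpora where term occurrence
is controlled. They do not certify retrieval quality on MEDLINE-scale
text, where tokenization variants and ambiguous symbols dominate the
error budget; symbol normalization at indexing time is the natural next
step and is out of scope here.

Determinism is taken seriously end to end: a fixture spec's seed fixes
every file byte-for-byte (the generator restores the caller's RNG
state), document ids are zero-padded integers assigned in shuffled order
so the descending-id tie-break is exercised, and identical inputs give
byte-identical CLI outputs.

## Problem sizes and tolerances

The test suite compares the scorer against the brute-force oracle on 200
random corpora of up to 50 documents at 1e-9 relative tolerance (the two
paths share only the formula, not code); checks AP monotonicity
exhaustively over all 720 orderings of 6-document rankings; and verifies
fusion algebra (linearity, scale invariance of the ranking, per-weight
monotonicity, single-class projection) at 1e-12 on randomized tables.
The acceptance script reruns the planted benchmark at its default sizes
and reports MAP for the expanded and baseline runs, mean
relevant-in-top-10/100, the worked fusion example and the oracle
deviation, all recomputed from scratch under the given seed.

## Known limitations

- Exact string matching only; morphological variants of symbols ("ABC1"
  vs "ABC-1" vs "ABC 1") are handled by the tokenizer's punctuation
  splitting but genuine lexical variation is not.
- The thesaurus is a file the user supplies (or the generator plants);
  building one from live databases is out of scope.
- The similarity is a fixed classic TF–IDF variant; no BM25, no learned
  ranking, no per-term user weights (only per-class).
- Index persistence uses R serialization; the index is a build artifact,
  not an interchange format.
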