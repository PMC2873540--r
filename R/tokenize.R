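#' Default English stopword list
#'
#' The classic 33-word English stopword list used by standard IR analyzers.
#' Shipped as a plain-text file under `inst/extdata/stopwords_en.txt` so it
#' can be inspected or replaced.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "litexpand")
  if (!nzchar(path)) stop("stopword file not found in installed package")
  readLines(path, encoding = "UTF-8")
}

#' Tokenize text for indexing and querying
#'
#' Lowercases the input, splits it into maximal runs of ASCII letters and
#' digits (so hyphens and all other punctuation break tokens: "ABC-1"
#' becomes "abc", "1"), and removes stopwords. No stemming is applied.
#' Token order is preserved; positions in the returned vector are the
#' positions used for phrase matching, i.e. they are counted after
#' stopword removal.
#'
#' @param text Character scalar (NA treated as empty).
#' @param stopwords Character vector of stopwords to drop; defaults to
#'   [default_stopwords()].
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize("ATP-binding cassette sub-family A member 1")
#' @export
tokenize <- function(text, stopwords = default_stopwords()) {
  if (length(text) != 1L) stop("tokenize() expects a single string")
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1L]]
  toks <- toks[nzchar(toks)]
  toks[!(toks %in% stopwords)]
}
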