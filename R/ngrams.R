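#' Tokenize raw text
#'
#' Lowercases, splits on runs of non-alphanumeric characters, and keeps
#' tokens of length >= 2. The simplest reproducible scheme; every text stage
#' in the package shares it.
#'
#' @param text Character vector of documents.
#' @return List of character token vectors, one per document.
#' @export
tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")
  lapply(toks, function(t) t[nchar(t) >= 2L])
}

#' Extract n-gram counts from one token sequence
#'
#' Every contiguous n-gram for n = 1..`max_n`, joined with `_`, with its
#' count. Order-insensitive (a bag of n-grams). Empty input gives an empty
#' vector.
#'
#' @param tokens Character vector of tokens (one document).
#' @param max_n Largest n-gram order (>= 1).
#' @return Named integer vector of counts.
#' @examples
#' extract_ngrams(c("a1", "b1", "c1"), 3)
#' @export
extract_ngrams <- function(tokens, max_n = 3L) {
  if (max_n < 1L) stop("max_n must be >= 1")
  m <- length(tokens)
  if (m == 0L) return(stats::setNames(integer(0), character(0)))
  grams <- vector("list", max_n)
  for (n in seq_len(max_n)) {
    if (m < n) break
    k <- m - n + 1L
    g <- tokens[seq_len(k)]
    if (n > 1L) for (j in 2:n) g <- paste(g, tokens[j:(k + j - 1L)], sep = "_")
    grams[[n]] <- g
  }
  tab <- table(unlist(grams))
  stats::setNames(as.integer(tab), names(tab))
}

# n-gram document-term matrix over a corpus.
# vocabulary NULL: build it, dropping n-grams seen in fewer than min_df
# documents; otherwise project onto the given vocabulary.
build_dtm <- function(docs, max_n = 3L, min_df = 2L, vocabulary = NULL,
                      sublinear = FALSE) {
  tok <- tokenize(docs)
  counts <- lapply(tok, extract_ngrams, max_n = max_n)
  terms <- unlist(lapply(counts, names), use.names = FALSE)
  if (is.null(vocabulary)) {
    dfreq <- table(terms)  # names are unique within a document
    vocabulary <- sort(names(dfreq)[dfreq >= min_df])
    if (length(vocabulary) == 0L)
      stop("vocabulary empty after document-frequency pruning")
  }
  i <- rep.int(seq_along(counts), lengths(counts))
  j <- match(terms, vocabulary)
  keep <- !is.na(j)
  x <- unlist(counts, use.names = FALSE)[keep]
  if (sublinear) x <- 1 + log(x)
  m <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = as.numeric(x),
                            dims = c(length(docs), length(vocabulary)),
                            dimnames = list(NULL, vocabulary))
  list(matrix = m, vocabulary = vocabulary)
}

# aggregate n-gram counts over a corpus (no per-document matrix)
corpus_ngram_counts <- function(docs, max_n = 3L) {
  tok <- tokenize(docs)
  counts <- lapply(tok, extract_ngrams, max_n = max_n)
  terms <- unlist(lapply(counts, names), use.names = FALSE)
  x <- unlist(counts, use.names = FALSE)
  agg <- rowsum(as.numeric(x), terms)
  stats::setNames(as.numeric(agg), rownames(agg))
}
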