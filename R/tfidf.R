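#' Build word documents from enriched-term lists
#'
#' Each screen contributes one "document": its enriched terms (e.g.
#' `GOBP_LYSOSOME_ORGANIZATION`) are split on underscores, the first token
#' (the ontology prefix) is dropped, the remaining words are lower-cased and
#' pooled into a word multiset. Terms reduced to nothing by prefix removal
#' are skipped with a warning.
#'
#' @param term_lists Named list of character vectors, one per screen.
#' @return Named list of word multisets (character vectors).
#' @export
build_documents <- function(term_lists) {
  stopifnot(is.list(term_lists), !is.null(names(term_lists)))
  lapply(term_lists, function(terms) {
    words <- lapply(strsplit(tolower(terms), "_", fixed = TRUE),
                    function(tok) tok[-1L])
    empty <- lengths(words) == 0L
    if (any(empty)) {
      warning(sum(empty), " term(s) empty after prefix removal; skipped",
              call. = FALSE)
    }
    out <- unlist(words, use.names = FALSE)
    out[nzchar(out)]
  })
}

#' TF-IDF scores for term-word documents
#'
#' `score(t, d) = TF(t, d) * (log10(D / DF(t)) + 1)`, where `TF(t, d)` is
#' the number of occurrences of word `t` in document `d`, `DF(t)` the number
#' of documents containing `t`, and `D` the number of documents (2 for a
#' pairwise screen contrast).
#'
#' @param documents Named list of word multisets from [build_documents()].
#' @return A list of class `tfidf_matrix` with matrices `tf` and `score`
#'   (word x document), vector `df` and `n_docs`.
#' @export
tfidf <- function(documents) {
  stopifnot(length(documents) >= 1L)
  words <- sort(unique(unlist(documents, use.names = FALSE)))
  if (length(words) == 0L) stop("all documents are empty", call. = FALSE)
  tf <- vapply(documents,
               function(d) as.integer(table(factor(d, levels = words))),
               integer(length(words)))
  if (is.null(dim(tf))) tf <- matrix(tf, nrow = 1L)
  dimnames(tf) <- list(words, names(documents))
  df <- rowSums(tf > 0L)
  n_docs <- length(documents)
  score <- tf * (log10(n_docs / df) + 1)
  structure(list(tf = tf, df = df, score = score, n_docs = n_docs),
            class = "tfidf_matrix")
}

#' Zero-protected log2 TF-IDF ratio between two documents
#'
#' Zero scores in a document are replaced by half that document's minimal
#' positive score before taking `log2(score_a / score_b)` word-wise, so a
#' word absent from one document yields a finite ratio.
#'
#' @param mat A [tfidf()] result.
#' @param doc_a,doc_b Document names (numerator / denominator).
#' @return Named numeric vector of per-word log2 ratios.
#' @export
tfidf_log2_ratio <- function(mat, doc_a, doc_b) {
  stopifnot(inherits(mat, "tfidf_matrix"),
            all(c(doc_a, doc_b) %in% colnames(mat$score)))
  protect <- function(x) {
    pos <- x[x > 0]
    if (length(pos) == 0L) {
      stop("document with all-zero TF-IDF scores", call. = FALSE)
    }
    x[x == 0] <- min(pos) / 2
    x
  }
  a <- protect(mat$score[, doc_a])
  b <- protect(mat$score[, doc_b])
  log2(a / b)
}
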