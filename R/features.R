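# Lexical feature extraction: unigram document-term matrices and TF-IDF.
#
# TF-IDF dialect (fixed so rankings are reproducible): unigrams over
# lowercased alphanumeric tokens, minimum document frequency 1, smoothed
# IDF log((1 + n) / (1 + df)) + 1, rows L2-normalized.  Feature extractors
# are fitted on the full corpus; labels only ever drive the classifier.

tokenize <- function(text) {
  toks <- strsplit(tolower(ifelse(is.na(text), "", text)), "[^a-z0-9]+")
  lapply(toks, function(t) t[nzchar(t)])
}

record_text <- function(records) {
  paste(ifelse(is.na(records$title), "", records$title),
        ifelse(is.na(records$abstract), "", records$abstract))
}

# counts matrix over a fixed or derived vocabulary; docs x terms, sparse
build_dtm <- function(texts, vocab = NULL) {
  toks <- tokenize(texts)
  if (is.null(vocab)) vocab <- sort(unique(unlist(toks)))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (d in seq_along(toks)) {
    idx <- match(toks[[d]], vocab)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) next
    tab <- tabulate(idx, nbins = length(vocab))
    nz <- which(tab > 0)
    ii <- c(ii, rep.int(d, length(nz))); jj <- c(jj, nz); xx <- c(xx, tab[nz])
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(toks), length(vocab)))
  list(M = M, vocab = vocab)
}

idf_weights <- function(M) {
  n <- nrow(M)
  df <- Matrix::colSums(M > 0)
  log((1 + n) / (1 + df)) + 1
}

apply_tfidf <- function(M, idf) {
  X <- M %*% Matrix::Diagonal(x = idf)
  nrm <- sqrt(Matrix::rowSums(X^2))
  nrm[nrm == 0] <- 1
  Matrix::Diagonal(x = 1 / nrm) %*% X
}

#' Precompute lexical features for a corpus
#'
#' Builds the document-term matrix, IDF weights and TF-IDF matrix for a
#' corpus once; the result is an environment shared by reference, so the
#' truncated-SVD embedding used by the alternative model family is computed
#' lazily and cached.  Fitting a model with `features` supplied skips all
#' text processing.
#'
#' @param corpus a `safe_corpus`.
#' @return an environment with fields `ids`, `vocab`, `idf`, `X` (TF-IDF),
#'   and on demand `embedding`.
#' @export
corpus_features <- function(corpus) {
  env <- new.env(parent = emptyenv())
  d <- build_dtm(record_text(corpus))
  env$ids <- corpus$record_id
  env$vocab <- d$vocab
  env$idf <- idf_weights(d$M)
  env$X <- apply_tfidf(d$M, env$idf)
  env
}

# rows of the cached TF-IDF matrix for given record ids
feature_rows <- function(features, ids) {
  idx <- match(ids, features$ids)
  if (anyNA(idx)) stop("record id(s) absent from feature cache: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  features$X[idx, , drop = FALSE]
}

# lazily computed truncated-SVD embedding of the corpus TF-IDF matrix,
# via the eigendecomposition of the document Gram matrix (n x n, so the
# cost is independent of vocabulary size); V maps new documents into the
# latent space
feature_embedding <- function(features, n_components) {
  d <- max(1L, min(n_components, dim(features$X) - 1L))
  key <- paste0("emb", d)
  if (is.null(features[[key]])) {
    K <- as.matrix(Matrix::tcrossprod(features$X))
    e <- eigen(K, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(d)], 1e-12)
    U <- e$vectors[, seq_len(d), drop = FALSE]
    E <- U %*% diag(sqrt(lam), d)
    V <- as.matrix(Matrix::crossprod(features$X, U) %*% diag(1 / sqrt(lam), d))
    features[[key]] <- list(V = V, E = E)
  }
  features[[key]]
}
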