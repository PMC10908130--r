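# Ranking-model families for active-learning screening.
#
# Two built-in families:
#   simple_lexical  -- TF-IDF features + multinomial naive Bayes or
#                      ridge-penalized (kernel) logistic regression.
#                      Computationally cheap; the workhorse of the active
#                      learning phase.
#   svd_kernel      -- "alternative" family with a structurally different
#                      inductive bias: truncated-SVD document embedding of
#                      the corpus TF-IDF matrix plus an RBF-kernel
#                      mean-difference (Parzen window) scorer.  Because the
#                      embedding is fitted on the whole corpus, records whose
#                      vocabulary diverges from the labeled relevants' topic
#                      still receive a distinctive position in the latent
#                      space, and score above records that closely resemble
#                      the labeled irrelevants.
# Scores are monotone relevance scores, not calibrated probabilities; only
# the order matters downstream.

.model_registry <- new.env(parent = emptyenv())

#' Register a user-supplied ranking-model family
#'
#' @param kind identifier for the family.
#' @param constructor function `(seed, ...)` returning a `safe_model`.
#' @return `kind`, invisibly.
#' @export
register_model_family <- function(kind, constructor) {
  stopifnot(is.character(kind), is.function(constructor))
  assign(kind, constructor, envir = .model_registry)
  invisible(kind)
}

new_safe_model <- function(family, kind, seed, hyperparameters, class) {
  structure(list(family = family, kind = kind, seed = as.integer(seed),
                 fitted = FALSE, hyperparameters = hyperparameters,
                 vectorizer = NULL, scorer = NULL, features = NULL),
            class = c(class, "safe_model"))
}

#' Create a simple lexical ranking model
#'
#' TF-IDF features over title + abstract with a cheap linear-ish classifier,
#' the model family used in the main active-learning phase.
#'
#' @param classifier `"naive_bayes"` (multinomial, default) or `"logistic"`
#'   (ridge-penalized kernel logistic regression).
#' @param seed integer seed (the models are deterministic; the seed is kept
#'   for provenance and registry-supplied stochastic families).
#' @param ... hyperparameters: `alpha` (NB smoothing, default 1),
#'   `lambda` (logistic ridge penalty, default 0.01).
#' @return an unfitted `safe_model`.
#' @export
make_simple_model <- function(classifier = c("naive_bayes", "logistic"), seed = 1, ...) {
  if (is.character(classifier) && length(classifier) == 1 &&
      !classifier %in% c("naive_bayes", "logistic"))
    stop("unknown classifier: ", classifier)
  classifier <- match.arg(classifier)
  hp <- utils::modifyList(list(alpha = 1, lambda = 0.01), list(...))
  m <- new_safe_model("simple_lexical", classifier, seed, hp, "simple_lexical")
  m
}

#' Create an alternative-family ranking model
#'
#' The model-switch phase re-ranks the unscreened pool with a family whose
#' feature space differs structurally from the simple lexical model.  The
#' built-in `"svd_kernel"` family embeds every document by truncated SVD of
#' the corpus TF-IDF matrix and scores by the difference of RBF-kernel mean
#' similarities to the labeled relevant and labeled irrelevant embeddings.
#' It is deterministic and needs no pretrained weights; a genuinely neural
#' family can be plugged in via [register_model_family()].
#'
#' @param kind `"svd_kernel"` or a registered family identifier.
#' @param seed integer seed.
#' @param ... hyperparameters: `n_components` (embedding dimension,
#'   default 32).
#' @return an unfitted `safe_model`.
#' @export
make_alternative_model <- function(kind = "svd_kernel", seed = 1, ...) {
  if (kind == "svd_kernel") {
    hp <- utils::modifyList(list(n_components = 32), list(...))
    return(new_safe_model("alternative", kind, seed, hp, "svd_kernel"))
  }
  if (exists(kind, envir = .model_registry, inherits = FALSE))
    return(get(kind, envir = .model_registry)(seed = seed, ...))
  stop("unknown alternative model kind: ", kind)
}

#' Fit a ranking model
#'
#' @param model an unfitted or fitted `safe_model`.
#' @param labeled data.frame of labeled records (corpus rows).
#' @param labels character vector of screening labels
#'   (`"relevant"`/`"irrelevant"`); defaults to `labeled$label`.
#' @param pool optional full corpus used to fit the feature extractor
#'   (IDF weights, SVD basis); defaults to `labeled`.
#' @param features optional precomputed [corpus_features()] cache covering
#'   the pool; skips all text processing.
#' @param ... unused.
#' @return the fitted model.
#' @export
fit <- function(model, labeled, labels = NULL, pool = NULL, features = NULL, ...) {
  UseMethod("fit")
}

prepare_fit <- function(model, labeled, labels, pool, features) {
  labels <- labels %||% labeled$label
  stopifnot(length(labels) == nrow(labeled))
  if (!any(labels == "relevant"))
    stop("training set has no relevant example")
  if (!any(labels == "irrelevant"))
    stop("training set has no irrelevant example")
  if (is.null(features)) {
    features <- corpus_features(pool %||% labeled)
  }
  list(features = features, ids = labeled$record_id, labels = labels)
}

#' @export
fit.simple_lexical <- function(model, labeled, labels = NULL, pool = NULL,
                               features = NULL, ...) {
  p <- prepare_fit(model, labeled, labels, pool, features)
  X <- feature_rows(p$features, p$ids)
  y <- p$labels == "relevant"
  model$features <- p$features
  if (model$kind == "naive_bayes") {
    # multinomial NB over TF-IDF mass with class-balanced smoothing: the
    # class-conditional term distribution is estimated from the class
    # centroid (per-document mean), so a term unseen in both classes scores
    # exactly zero regardless of how unbalanced the labeled classes are --
    # absence of evidence is not evidence of relevance
    a <- model$hyperparameters$alpha / ncol(X)
    mr <- Matrix::colSums(X[y, , drop = FALSE]) / sum(y)
    mi <- Matrix::colSums(X[!y, , drop = FALSE]) / sum(!y)
    w <- log(mr + a) - log(mi + a)
    model$scorer <- list(type = "linear", w = w,
                         b = log(sum(y)) - log(sum(!y)))
  } else {
    kl <- klr_train(X, y, lambda = model$hyperparameters$lambda)
    model$scorer <- c(list(type = "klr", Xtrain = X), kl)
  }
  model$fitted <- TRUE
  model
}

# ridge-penalized kernel logistic regression (linear kernel + intercept via
# an implicit constant feature), trained by IRLS; handles the minimum viable
# training set of one record per class
klr_train <- function(X, y, lambda = 0.01, maxit = 50, tol = 1e-8) {
  n <- nrow(X)
  K <- as.matrix(Matrix::tcrossprod(X)) + 1
  a <- rep(0, n)
  yn <- as.numeric(y)
  for (it in seq_len(maxit)) {
    f <- K %*% a
    pr <- 1 / (1 + exp(-pmin(pmax(f, -30), 30)))
    w <- pmax(pr * (1 - pr), 1e-6)
    z <- f + (yn - pr) / w
    a_new <- solve(K + diag(as.vector(lambda / w), nrow = n), z)
    if (max(abs(a_new - a)) < tol) { a <- a_new; break }
    a <- a_new
  }
  list(a = as.vector(a))
}

#' @export
fit.svd_kernel <- function(model, labeled, labels = NULL, pool = NULL,
                           features = NULL, ...) {
  p <- prepare_fit(model, labeled, labels, pool, features)
  emb <- feature_embedding(p$features, model$hyperparameters$n_components)
  idx <- match(p$ids, p$features$ids)
  E <- emb$E[idx, , drop = FALSE]
  # bandwidth: median nearest-neighbour distance among the labeled
  # embeddings -- a local scale, so the scorer responds to cluster
  # structure instead of the global spread (deterministic)
  D <- as.matrix(stats::dist(E))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  h <- stats::median(nn[is.finite(nn) & nn > 0])
  if (is.na(h) || h == 0) h <- 1
  model$features <- p$features
  model$scorer <- list(type = "kernel_mean", E = E,
                       y = p$labels == "relevant", h = h)
  model$fitted <- TRUE
  model
}

model_scores <- function(model, records) {
  feats <- model$features
  cached <- !is.null(feats) && all(records$record_id %in% feats$ids)
  sc <- model$scorer
  if (sc$type %in% c("linear", "klr")) {
    X <- if (cached) feature_rows(feats, records$record_id) else {
      d <- build_dtm(record_text(records), vocab = feats$vocab)
      apply_tfidf(d$M, feats$idf)
    }
    if (sc$type == "linear") {
      as.vector(X %*% sc$w) + sc$b
    } else {
      Kn <- as.matrix(X %*% Matrix::t(sc$Xtrain)) + 1
      as.vector(Kn %*% sc$a)
    }
  } else {
    emb <- feature_embedding(feats, model$hyperparameters$n_components)
    Eu <- if (cached) emb$E[match(records$record_id, feats$ids), , drop = FALSE] else {
      d <- build_dtm(record_text(records), vocab = feats$vocab)
      as.matrix(apply_tfidf(d$M, feats$idf) %*% emb$V)
    }
    rbf_mean <- function(E1) {
      # mean RBF similarity of each row of Eu to the rows of E1
      d2 <- outer(rowSums(Eu^2), rowSums(E1^2), "+") - 2 * Eu %*% t(E1)
      rowMeans(exp(-pmax(d2, 0) / (2 * sc$h^2)))
    }
    rbf_mean(sc$E[sc$y, , drop = FALSE]) - rbf_mean(sc$E[!sc$y, , drop = FALSE])
  }
}

#' Rank unlabeled records by predicted relevance
#'
#' @param model a fitted `safe_model`.
#' @param unlabeled data.frame of records to rank.
#' @return data.frame with columns `record_id` and `score`, in descending
#'   score order; ties broken by ascending `record_id`.  Empty input gives
#'   an empty ranking.
#' @export
rank_records <- function(model, unlabeled) {
  stopifnot(inherits(model, "safe_model"))
  if (!isTRUE(model$fitted)) stop("model must be fitted before ranking")
  if (is.null(unlabeled) || nrow(unlabeled) == 0L)
    return(data.frame(record_id = character(), score = numeric()))
  s <- model_scores(model, unlabeled)
  ord <- order(-s, unlabeled$record_id)
  data.frame(record_id = unlabeled$record_id[ord], score = s[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.safe_model <- function(x, ...) {
  cat(sprintf("<safe_model> family=%s kind=%s %s\n", x$family, x$kind,
              if (x$fitted) "(fitted)" else "(unfitted)"))
  invisible(x)
}
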