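# Synthetic labeled-corpus generator.
#
# Documents are synthetic token streams over an integer vocabulary rendered
# as pseudo-words ("w0137"); no natural-language realism is claimed -- only
# the ranking geometry matters to the screening procedure.  Each document
# mixes a shared Zipf-weighted background distribution with a class topic:
# relevant records draw topic tokens from the main relevant topic or, for the
# "hard" subpopulation, from a disjoint divergent topic; irrelevant records
# are pure background.  The topic mixing weight is
# separability / (1 + separability): separability 0 makes the classes
# lexically indistinguishable, large values make a simple lexical ranker
# nearly perfect.

#' Specification of a synthetic screening corpus
#'
#' @param n_records total number of records `T`.
#' @param prevalence fraction of relevant records in (0, 1); the relevant
#'   count is exact, `round(prevalence * n_records)`, so the true `R` is
#'   known for recall denominators.
#' @param vocab_size number of distinct background terms.
#' @param n_topic_terms terms per topic (main and hard topics are disjoint
#'   from each other and from the background support).
#' @param separability non-negative weight; topic-token probability is
#'   `separability / (1 + separability)`.
#' @param hard_fraction fraction of relevant records drawn from the
#'   divergent-vocabulary hard topic, in `[0, 1)`.
#' @param n_key_papers key papers, drawn from main-topic relevants only.
#' @param doc_length_mean mean token count per document (Poisson, floor 10).
#' @param year_range integer vector `c(min, max)` of publication years.
#' @param missing_abstract_rate,duplicate_rate noise rates applied by
#'   [inject_noise()] after generation; both default to 0.
#' @param seed integer seed; identical seeds give identical corpora.
#' @return a `corpus_spec` list.
#' @export
corpus_spec <- function(n_records = 1000, prevalence = 0.05, vocab_size = 20000,
                        n_topic_terms = 40, separability = 3, hard_fraction = 0,
                        n_key_papers = 3, doc_length_mean = 60,
                        year_range = c(1990, 2024), missing_abstract_rate = 0,
                        duplicate_rate = 0, seed = 1) {
  spec <- list(n_records = as.integer(n_records), prevalence = prevalence,
               vocab_size = as.integer(vocab_size),
               n_topic_terms = as.integer(n_topic_terms),
               separability = separability, hard_fraction = hard_fraction,
               n_key_papers = as.integer(n_key_papers),
               doc_length_mean = doc_length_mean,
               year_range = as.integer(year_range),
               missing_abstract_rate = missing_abstract_rate,
               duplicate_rate = duplicate_rate, seed = as.integer(seed))
  n_rel <- round(spec$prevalence * spec$n_records)
  n_hard <- round(spec$hard_fraction * n_rel)
  if (spec$n_records < 2L) stop("n_records must be at least 2")
  if (n_rel < 1L) stop("round(prevalence * n_records) must be >= 1")
  if (n_rel >= spec$n_records) stop("prevalence leaves no irrelevant records")
  if (spec$hard_fraction < 0 || spec$hard_fraction >= 1)
    stop("hard_fraction must be in [0, 1)")
  if (spec$separability < 0) stop("separability must be >= 0")
  if (spec$n_key_papers > n_rel - n_hard)
    stop("n_key_papers (", spec$n_key_papers,
         ") exceeds the number of main-topic relevant records (", n_rel - n_hard, ")")
  if (spec$missing_abstract_rate < 0 || spec$missing_abstract_rate >= 1 ||
      spec$duplicate_rate < 0 || spec$duplicate_rate >= 1)
    stop("noise rates must be in [0, 1)")
  structure(spec, class = "corpus_spec")
}

# token ids rendered as fixed-width pseudo-words
render_tokens <- function(ids) sprintf("w%05d", ids)

#' Generate a synthetic labeled corpus
#'
#' Produces exactly `round(prevalence * n_records)` relevant records, of
#' which `round(hard_fraction * n_relevant)` come from the hard
#' (divergent-vocabulary) topic whose terms share nothing with the main
#' relevant topic.  Exactly `n_key_papers` main-topic relevant records are
#' flagged as key papers (hard records are never key papers, so the
#' model-switch phase has something only it can find).  Years are uniform
#' over `year_range`.  Deterministic given `spec$seed`.
#'
#' @param spec a [corpus_spec()].
#' @return a `safe_corpus`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  n <- spec$n_records
  n_rel <- round(spec$prevalence * n)
  n_hard <- round(spec$hard_fraction * n_rel)
  # disjoint vocabulary blocks: Zipf background | main relevant topic | two
  # irrelevant subtopics.  The heavy-tailed background means every document
  # carries some rare, training-unseen terms, as real titles/abstracts do.
  # Hard relevant records operationalize concept ambiguity: their topic
  # tokens come from the UNION of the two irrelevant subtopics, vocabulary
  # a lexical model has every reason to score as irrelevant -- only the
  # co-occurrence of both subtopics in one document marks them, which is
  # invisible to a bag-of-terms ranker but shifts their position in a
  # latent co-occurrence embedding.  They share no terms with the main
  # relevant topic.
  bg_ids <- seq_len(spec$vocab_size)
  main_ids <- spec$vocab_size + seq_len(spec$n_topic_terms)
  sub1_ids <- spec$vocab_size + spec$n_topic_terms + seq_len(spec$n_topic_terms)
  sub2_ids <- spec$vocab_size + 2L * spec$n_topic_terms + seq_len(spec$n_topic_terms)
  subtopic_frac <- 0.15   # fraction of irrelevant records per subtopic
  bg_prob <- 1 / seq_len(spec$vocab_size)
  bg_prob <- bg_prob / sum(bg_prob)
  w_topic <- spec$separability / (1 + spec$separability)

  with_seed(derive_seed(spec$seed, "generate_corpus"), {
    # class assignment, shuffled so relevants are scattered through the file
    n_irr <- n - n_rel
    n_sub <- round(subtopic_frac * n_irr)
    cls <- c(rep("hard", n_hard), rep("main", n_rel - n_hard),
             rep("sub1", n_sub), rep("sub2", n_sub),
             rep("none", n_irr - 2L * n_sub))
    cls <- sample(cls)
    lens <- pmax(10L, stats::rpois(n, spec$doc_length_mean))
    years <- sample(seq(spec$year_range[1], spec$year_range[2]), n, replace = TRUE)
    docs <- character(n)
    for (i in seq_len(n)) {
      li <- lens[i]
      tok <- sample(bg_ids, li, replace = TRUE, prob = bg_prob)
      if (cls[i] != "none" && w_topic > 0) {
        topic <- switch(cls[i], main = main_ids, sub1 = sub1_ids,
                        sub2 = sub2_ids, hard = c(sub1_ids, sub2_ids))
        from_topic <- stats::runif(li) < w_topic
        tok[from_topic] <- sample(topic, sum(from_topic), replace = TRUE)
      }
      docs[i] <- paste(render_tokens(tok), collapse = " ")
    }
    n_title <- pmin(8L, lens)
    title <- vapply(seq_len(n), function(i) {
      paste(strsplit(docs[i], " ", fixed = TRUE)[[1]][seq_len(n_title[i])],
            collapse = " ")
    }, character(1))
    abstract <- vapply(seq_len(n), function(i) {
      toks <- strsplit(docs[i], " ", fixed = TRUE)[[1]]
      paste(toks[-seq_len(n_title[i])], collapse = " ")
    }, character(1))
    key <- rep(FALSE, n)
    key[sample(which(cls == "main"), spec$n_key_papers)] <- TRUE
    corpus <- safe_corpus(data.frame(
      record_id = sprintf("rec%05d", seq_len(n)),
      title = title, abstract = abstract, year = years,
      label = ifelse(cls %in% c("main", "hard"), "relevant", "irrelevant"),
      key_paper = key, stringsAsFactors = FALSE))
    attr(corpus, "hard_ids") <- corpus$record_id[cls == "hard"]
    if (spec$missing_abstract_rate > 0 || spec$duplicate_rate > 0) {
      corpus <- inject_noise(corpus, spec$missing_abstract_rate,
                             spec$duplicate_rate,
                             seed = derive_seed(spec$seed, "inject_noise"))
    }
    corpus
  })
}

#' Inject input-quality noise into a corpus
#'
#' Blanks abstracts and appends near-duplicate records at the stated rates,
#' deterministically under `seed`; oracle labels are untouched.  Duplicates
#' copy the title and abstract of a seeded sample of existing records (so
#' text-pair duplicate detection finds them) under fresh record ids; a
#' duplicate of a key paper is not itself flagged as key.
#'
#' @param corpus a `safe_corpus`.
#' @param missing_abstract_rate,duplicate_rate rates in `[0, 1)`.
#' @param seed integer seed.
#' @return a `safe_corpus` with the noise applied.
#' @export
inject_noise <- function(corpus, missing_abstract_rate = 0, duplicate_rate = 0,
                         seed = 1) {
  stopifnot(inherits(corpus, "safe_corpus"))
  if (missing_abstract_rate < 0 || missing_abstract_rate >= 1 ||
      duplicate_rate < 0 || duplicate_rate >= 1)
    stop("noise rates must be in [0, 1)")
  if (missing_abstract_rate == 0 && duplicate_rate == 0) return(corpus)
  n <- nrow(corpus)
  hard <- attr(corpus, "hard_ids")
  out <- as.data.frame(corpus)
  with_seed(seed, {
    n_blank <- round(missing_abstract_rate * n)
    if (n_blank > 0) out$abstract[sample(n, n_blank)] <- ""
    n_dup <- round(duplicate_rate * n)
    if (n_dup > 0) {
      src <- sample(n, n_dup, replace = TRUE)
      dup <- out[src, , drop = FALSE]
      dup$record_id <- sprintf("dup%05d", seq_len(n_dup))
      dup$key_paper <- FALSE
      out <- rbind(out, dup)
    }
  })
  res <- safe_corpus(out)
  attr(res, "hard_ids") <- hard
  res
}

#' Record ids of the hard (divergent-topic) relevant subpopulation
#'
#' @param corpus a corpus from [generate_corpus()].
#' @return character vector of record ids (empty if `hard_fraction = 0`).
#' @export
hard_record_ids <- function(corpus) attr(corpus, "hard_ids") %||% character()
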