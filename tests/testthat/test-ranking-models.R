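# Ranking-model contract: minimum training sets, determinism, tie-breaks,
# order invariance, and the separable-fixture oracle.

test_that("factories validate their arguments", {
  expect_s3_class(make_simple_model("naive_bayes"), "safe_model")
  expect_s3_class(make_simple_model("logistic"), "safe_model")
  expect_error(make_simple_model("perceptron"), "unknown classifier")
  expect_s3_class(make_alternative_model("svd_kernel"), "safe_model")
  expect_error(make_alternative_model("bert"), "unknown alternative")
  expect_false(make_simple_model()$fitted)
})

test_that("user model families can be registered and constructed", {
  register_model_family("reverse_id", function(seed, ...) {
    m <- make_simple_model(seed = seed)
    m$kind <- "reverse_id"
    m
  })
  m <- make_alternative_model("reverse_id", seed = 4)
  expect_equal(m$kind, "reverse_id")
})

test_that("fitting requires one example of each class and works at the minimum", {
  corpus <- toy_corpus()
  for (mk in list(make_simple_model("naive_bayes"),
                  make_simple_model("logistic"),
                  make_alternative_model())) {
    m <- fit(mk, corpus[c(1, 4), ], pool = corpus)
    expect_true(m$fitted)
    expect_error(fit(mk, corpus[4:6, ], pool = corpus), "no relevant")
    expect_error(fit(mk, corpus[1:3, ], pool = corpus), "no irrelevant")
  }
})

test_that("ranking is unavailable before fitting and empty input gives empty output", {
  m <- make_simple_model()
  expect_error(rank_records(m, toy_corpus()), "fitted")
  mf <- fit(m, toy_corpus()[c(1, 4), ], pool = toy_corpus())
  out <- rank_records(mf, toy_corpus()[0, ])
  expect_equal(nrow(out), 0L)
  expect_named(out, c("record_id", "score"))
})

test_that("on a separable toy fixture the remaining topic docs rank first", {
  corpus <- toy_corpus()
  # independent oracle: count shared terms with the relevant training doc
  shared_terms <- function(a, b) {
    ta <- unique(strsplit(tolower(a), "[^a-z0-9]+")[[1]])
    tb <- unique(strsplit(tolower(b), "[^a-z0-9]+")[[1]])
    length(intersect(ta, tb))
  }
  txt <- paste(corpus$title, corpus$abstract)
  overlap <- vapply(txt[c(2, 3, 5, 6)], shared_terms, numeric(1), b = txt[1])
  expect_true(all(overlap[1:2] > overlap[3:4]))  # fixture is separable

  for (mk in list(make_simple_model("naive_bayes"),
                  make_simple_model("logistic"))) {
    m <- fit(mk, corpus[c(1, 4), ], pool = corpus)
    rk <- rank_records(m, corpus[c(2, 3, 5, 6), ])
    expect_setequal(rk$record_id[1:2], c("t02", "t03"))
  }
})

test_that("refitting on the same data reproduces identical rankings", {
  corpus <- generate_corpus(corpus_spec(n_records = 80, prevalence = 0.1,
                                        n_key_papers = 1, seed = 31))
  feats <- corpus_features(corpus)
  train <- c(which(corpus$label == "relevant")[1:2], 3:12)
  for (mk in list(make_simple_model("naive_bayes", seed = 1),
                  make_simple_model("logistic", seed = 1),
                  make_alternative_model(seed = 1))) {
    r1 <- rank_records(fit(mk, corpus[train, ], features = feats),
                       corpus[-train, ])
    r2 <- rank_records(fit(mk, corpus[train, ], features = feats),
                       corpus[-train, ])
    expect_identical(r1, r2)
  }
})

test_that("rankings are invariant to input order and ties break by record id", {
  corpus <- generate_corpus(corpus_spec(n_records = 80, prevalence = 0.1,
                                        n_key_papers = 1, seed = 32))
  feats <- corpus_features(corpus)
  train <- c(which(corpus$label == "relevant")[1], 5:14)
  withr::with_seed(99, {
    for (mk in list(make_simple_model(), make_alternative_model())) {
      m <- fit(mk, corpus[train, ], features = feats)
      pool <- corpus[-train, ]
      r1 <- rank_records(m, pool)
      r2 <- rank_records(m, pool[sample(nrow(pool)), ])
      expect_equal(r1, r2)
    }
  })
  # exact duplicates must come out adjacent, ascending by id
  dup <- toy_corpus()
  dup$title[5] <- dup$title[6] <- "identical twin"
  dup$abstract[5] <- dup$abstract[6] <- "identical twin text"
  m <- fit(make_simple_model(), dup[c(1, 4), ], pool = dup)
  rk <- rank_records(m, dup[c(6, 5), ])
  i5 <- which(rk$record_id == "t05"); i6 <- which(rk$record_id == "t06")
  expect_equal(i6, i5 + 1L)
})

test_that("duplicating a labeled relevant document never lowers its own score", {
  corpus <- toy_corpus()
  m1 <- fit(make_simple_model(), corpus[c(1, 4), ], pool = corpus)
  s1 <- rank_records(m1, corpus[1, ])$score
  dup <- rbind(as.data.frame(corpus)[c(1, 1, 4), ])
  dup$record_id <- c("t01", "t01b", "t04")
  pool2 <- rbind(as.data.frame(corpus), dup[2, ])
  m2 <- fit(make_simple_model(), dup,
            labels = c("relevant", "relevant", "irrelevant"), pool = pool2)
  s2 <- rank_records(m2, corpus[1, ])$score
  expect_gte(s2, s1)
})

test_that("the alternative family has a genuinely different inductive bias", {
  corpus <- generate_corpus(corpus_spec(n_records = 150, prevalence = 0.1,
                                        hard_fraction = 0.3, n_key_papers = 2,
                                        seed = 33))
  feats <- corpus_features(corpus)
  hard <- hard_record_ids(corpus)
  main_rel <- setdiff(corpus$record_id[corpus$label == "relevant"], hard)
  train <- match(c(main_rel, corpus$record_id[corpus$label == "irrelevant"][1:40]),
                 corpus$record_id)
  pool <- corpus[-train, ]
  rk_s <- rank_records(fit(make_simple_model(), corpus[train, ], features = feats), pool)
  rk_a <- rank_records(fit(make_alternative_model(), corpus[train, ], features = feats), pool)
  pos_s <- stats::median(match(intersect(hard, pool$record_id), rk_s$record_id))
  pos_a <- stats::median(match(intersect(hard, pool$record_id), rk_a$record_id))
  # the embedding family pulls divergent-vocabulary relevants far forward
  expect_lt(pos_a, pos_s / 2)
})
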