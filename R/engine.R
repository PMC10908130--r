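# The four-phase screening engine, run against a simulated (oracle)
# screener:
#   phase 1  screen a random or date-stratified training set; estimate the
#            fraction of relevant records.
#   phase 2  active learning with the simple lexical model; stop on the
#            four-fold composite rule.
#   phase 3  model switch: re-rank the residual pool with the alternative
#            family; stop on a phase-scoped consecutive-irrelevant window.
#   phase 4  quality check: an error-free second screener revisits the
#            excluded records, ranked by a simple model trained on
#            pseudo-labels from the phase-3 ranking; stop on the window.
# Every phase appends to a single append-only log; the whole run is
# deterministic given (corpus, config).

#' Run configuration for a SAFE simulation
#'
#' @param seed master integer seed; expands via [derive_seed()] into
#'   per-component seeds (sampling, models, oracle, baselines).
#' @param classifier simple-model classifier, `"naive_bayes"` or
#'   `"logistic"`.
#' @param alternative alternative-model family for the model-switch phase.
#' @param oracle `"perfect"` or `"noisy"` first screener.
#' @param false_negative_rate probability the noisy screener misses a truly
#'   relevant record (default 0.10, the rate human screeners are commonly
#'   observed to miss); irrelevant records are never flipped.
#' @param sampling phase-1 selection: `"stratified"` (oldest + newest +
#'   random intermediates) or `"random"`.
#' @param stopping a [stopping_config()].
#' @return a `safe_config` list.
#' @export
safe_config <- function(seed = 1,
                        classifier = c("naive_bayes", "logistic"),
                        alternative = "svd_kernel",
                        oracle = c("perfect", "noisy"),
                        false_negative_rate = 0.10,
                        sampling = c("stratified", "random"),
                        stopping = stopping_config()) {
  structure(list(seed = as.integer(seed), classifier = match.arg(classifier),
                 alternative = alternative, oracle = match.arg(oracle),
                 false_negative_rate = false_negative_rate,
                 sampling = match.arg(sampling), stopping = stopping),
            class = "safe_config")
}

#' Simulated screener
#'
#' In `"perfect"` mode the screener returns the oracle label.  In `"noisy"`
#' mode a truly relevant record is marked irrelevant with probability
#' `false_negative_rate`; irrelevant records are never marked relevant.
#' The flip decision is a deterministic per-record draw (seed + record id),
#' so it does not depend on presentation order; flipped ids are recorded on
#' the oracle object.
#'
#' @param mode `"perfect"` or `"noisy"`.
#' @param false_negative_rate flip probability for relevant records.
#' @param seed integer seed.
#' @return a `safe_oracle` environment.
#' @export
make_oracle <- function(mode = c("perfect", "noisy"), false_negative_rate = 0.10,
                        seed = 1) {
  mode <- match.arg(mode)
  stopifnot(false_negative_rate >= 0, false_negative_rate < 1)
  o <- new.env(parent = emptyenv())
  o$mode <- mode
  o$fn_rate <- false_negative_rate
  o$seed <- as.integer(seed)
  o$flipped <- character()
  class(o) <- "safe_oracle"
  o
}

#' Query a simulated screener for one record
#'
#' @param oracle a [make_oracle()] screener.
#' @param record one corpus row (with `record_id` and oracle `label`).
#' @return the assigned label, `"relevant"` or `"irrelevant"`.
#' @export
oracle_query <- function(oracle, record) {
  truth <- record$label
  if (oracle$mode == "perfect" || truth == "irrelevant") return(truth)
  u <- with_seed(derive_seed(oracle$seed, record$record_id), stats::runif(1))
  if (u < oracle$fn_rate) {
    if (!record$record_id %in% oracle$flipped)
      oracle$flipped <- c(oracle$flipped, record$record_id)
    "irrelevant"
  } else truth
}

# ---- internal mutable screening environment --------------------------------

new_screen_env <- function(corpus, seed) {
  S <- new.env(parent = emptyenv())
  S$corpus <- corpus
  S$n <- 0L
  cap <- 2L * nrow(corpus) + 8L
  S$rec <- character(cap); S$phase <- integer(cap)
  S$rank <- integer(cap); S$lab <- character(cap)
  S$assigned <- rep(NA_character_, nrow(corpus))   # final label per row
  S$screened123 <- rep(FALSE, nrow(corpus))
  S$seed <- as.integer(seed)
  S$diagnostics <- list()
  S$phase3_ranking <- NULL
  S
}

push_decision <- function(S, row, phase, rank, label) {
  S$n <- S$n + 1L
  i <- S$n
  S$rec[i] <- S$corpus$record_id[row]
  S$phase[i] <- phase
  S$rank[i] <- rank
  S$lab[i] <- label
  S$assigned[row] <- label
  if (phase <= 3L) S$screened123[row] <- TRUE
  invisible(S)
}

snapshot_state <- function(S) {
  n <- S$n
  log <- data.frame(step = seq_len(n), record_id = S$rec[seq_len(n)],
                    phase = S$phase[seq_len(n)],
                    rank_presented = S$rank[seq_len(n)],
                    label = S$lab[seq_len(n)], stringsAsFactors = FALSE)
  bounds <- lapply(split(seq_len(n), log$phase), range)
  structure(list(log = log,
                 phase_boundaries = bounds,
                 labeled_ids = unique(log$record_id),
                 found_relevant = length(unique(log$record_id[log$label == "relevant"])),
                 assigned = stats::setNames(S$assigned, S$corpus$record_id),
                 diagnostics = S$diagnostics,
                 phase3_ranking = S$phase3_ranking,
                 rng_seed = S$seed),
            class = "screening_state")
}

# rebuild the mutable environment from a snapshot (phases are composable:
# each run_phaseN accepts the state returned by the previous one)
env_from_state <- function(state, corpus) {
  S <- new_screen_env(corpus, state$rng_seed)
  log <- state$log
  for (i in seq_len(nrow(log))) {
    row <- match(log$record_id[i], corpus$record_id)
    if (is.na(row)) stop("log references unknown record_id: ", log$record_id[i])
    push_decision(S, row, log$phase[i], log$rank_presented[i], log$label[i])
  }
  S$diagnostics <- state$diagnostics %||% list()
  S$phase3_ranking <- state$phase3_ranking
  S
}

#' The screening log of a state
#'
#' @param state a `screening_state` (or a `safe_result`).
#' @return data.frame with columns `step`, `record_id`, `phase`,
#'   `rank_presented`, `label`.
#' @export
screening_log <- function(state) {
  if (inherits(state, "safe_result")) state <- state$state
  stopifnot(inherits(state, "screening_state"))
  state$log
}

# ---- phase 1 ---------------------------------------------------------------

#' Phase 1: screen a training set and estimate prevalence
#'
#' Screens `n1 = max(phase1_min, ceiling(phase1_fraction * T))` records.
#' Stratified selection takes the `k = ceiling(n1 / 10)` oldest and `k`
#' newest records by year plus seeded random intermediates (records with a
#' missing year are eligible only for the random stratum); random selection
#' is a plain seeded sample.  If after `n1` records either class is still
#' missing, screening continues with seeded random draws until both a
#' relevant and an irrelevant label exist.  The prevalence estimate is
#' computed from all phase-1 labels.
#'
#' @param corpus a validated `safe_corpus`.
#' @param config a [safe_config()].
#' @param oracle a [make_oracle()] screener.
#' @param sampling overrides `config$sampling` when given.
#' @return list with elements `state` (a `screening_state`) and `phase1`
#'   (a `phase1_result` with fields `t`, `RR_t`, `FRR_t`, `RR_T_hat`,
#'   `screened_ids`).
#' @export
run_phase1 <- function(corpus, config, oracle, sampling = NULL) {
  stopifnot(inherits(corpus, "safe_corpus"))
  sampling <- sampling %||% config$sampling
  sc <- config$stopping
  Tn <- nrow(corpus)
  n1 <- min(Tn, max(sc$phase1_min, ceiling(sc$phase1_fraction * Tn)))
  S <- new_screen_env(corpus, config$seed)
  sel <- with_seed(derive_seed(config$seed, "phase1"), {
    if (sampling == "stratified") {
      k <- ceiling(n1 / 10)
      with_year <- which(!is.na(corpus$year))
      ord <- with_year[order(corpus$year[with_year])]
      oldest <- utils::head(ord, k)
      newest <- utils::head(rev(ord), k)
      fixed <- unique(c(oldest, newest))
      rest <- setdiff(seq_len(Tn), fixed)
      c(fixed, sample(rest, min(length(rest), n1 - length(fixed))))
    } else {
      sample(Tn, n1)
    }
  })
  for (row in sel) {
    push_decision(S, row, 1L, NA_integer_,
                  oracle_query(oracle, corpus[row, , drop = FALSE]))
  }
  # continue past n1 until both classes are present in the training labels
  extra_seed <- derive_seed(config$seed, "phase1_extra")
  draw <- 0L
  while (!all(c("relevant", "irrelevant") %in% S$lab[seq_len(S$n)])) {
    pool <- which(is.na(S$assigned))
    if (!length(pool)) {
      miss <- setdiff(c("relevant", "irrelevant"), S$lab[seq_len(S$n)])
      stop("corpus exhausted with no ", miss[1], " record found; degenerate corpus")
    }
    draw <- draw + 1L
    row <- with_seed(derive_seed(extra_seed, as.character(draw)),
                     pool[sample.int(length(pool), 1L)])
    push_decision(S, row, 1L, NA_integer_,
                  oracle_query(oracle, corpus[row, , drop = FALSE]))
  }
  t <- S$n
  RR_t <- sum(S$lab[seq_len(t)] == "relevant")
  FRR_t <- estimate_frr(RR_t, t)
  phase1 <- structure(list(t = t, RR_t = RR_t, FRR_t = FRR_t,
                           RR_T_hat = estimate_total_relevant(FRR_t, Tn),
                           screened_ids = S$rec[seq_len(t)]),
                      class = "phase1_result")
  list(state = snapshot_state(S), phase1 = phase1)
}

#' @export
print.phase1_result <- function(x, ...) {
  cat(sprintf("<phase1> t=%d RR_t=%d FRR_t=%.4f RR_T_hat=%d\n",
              x$t, x$RR_t, x$FRR_t, x$RR_T_hat))
  invisible(x)
}

# shared present-top/label loop for phases 2-4.  Phases 2-3 refit the model
# every refit_interval labels and draw from the unlabeled pool; phase 4 walks
# a single static ranking over the previously-excluded pool.
phase_loop <- function(S, corpus, phase, oracle, model, features, config,
                       stop_fun, pool_rows = NULL, static_ranking = FALSE) {
  sc <- config$stopping
  labels_since_fit <- Inf   # force a fit before the first presentation
  ranking_rows <- integer()
  ptr <- 0L
  done <- rep(FALSE, nrow(corpus))   # presented within this phase
  current_pool <- function() {
    if (is.null(pool_rows)) which(is.na(S$assigned)) else pool_rows[!done[pool_rows]]
  }
  repeat {
    pool <- current_pool()
    if (!length(pool)) {
      S$diagnostics[[as.character(phase)]] <-
        c(S$diagnostics[[as.character(phase)]], list(census = TRUE))
      break
    }
    if (static_ranking) {
      if (!length(ranking_rows)) {
        rk <- rank_records(model, corpus[pool, , drop = FALSE])
        ranking_rows <- match(rk$record_id, corpus$record_id)
      }
    } else if (labels_since_fit >= sc$refit_interval || ptr >= length(ranking_rows)) {
      lab_rows <- which(S$screened123)
      model <- fit(model, corpus[lab_rows, , drop = FALSE],
                   labels = S$assigned[lab_rows], features = features)
      rk <- rank_records(model, corpus[pool, , drop = FALSE])
      ranking_rows <- match(rk$record_id, corpus$record_id)
      ptr <- 0L
      labels_since_fit <- 0L
    }
    if (ptr >= length(ranking_rows)) break
    ptr <- ptr + 1L
    row <- ranking_rows[ptr]
    if (done[row] || (is.null(pool_rows) && !is.na(S$assigned[row]))) next
    done[row] <- TRUE
    push_decision(S, row, phase, ptr,
                  oracle_query(oracle, corpus[row, , drop = FALSE]))
    labels_since_fit <- labels_since_fit + 1L
    res <- stop_fun(snapshot_state(S))
    if (res$stop) {
      S$diagnostics[[as.character(phase)]] <-
        c(S$diagnostics[[as.character(phase)]], res$diagnostics)
      break
    }
  }
  model
}

# ---- phase 2 ---------------------------------------------------------------

#' Phase 2: active learning with the simple model
#'
#' Repeatedly fits the simple lexical model on all labels so far, presents
#' the top-ranked unlabeled record to the screener, and stops at the first
#' record where the four-fold composite holds: all key papers found AND
#' cumulative screening at least `rrt_multiplier * RR_T_hat` AND at least
#' `ceiling(min_fraction * T)` screened AND `window` consecutive
#' irrelevant decisions in this phase.  If the pool empties first, the
#' phase records a census stop with the unmet conditions.
#'
#' @param state `screening_state` from [run_phase1()].
#' @param corpus the corpus.
#' @param phase1 the `phase1_result`.
#' @param config a [safe_config()].
#' @param oracle the first screener.
#' @param model a `simple_lexical` model (default built from `config`).
#' @param features optional [corpus_features()] cache.
#' @return the updated `screening_state`.
#' @export
run_phase2 <- function(state, corpus, phase1, config, oracle, model = NULL,
                       features = NULL) {
  S <- env_from_state(state, corpus)
  features <- features %||% corpus_features(corpus)
  model <- model %||% make_simple_model(config$classifier,
                                        derive_seed(config$seed, "simple"))
  stop_fun <- function(st) {
    comp <- composite_all(list(
      key_papers_found(st, corpus),
      min_screened_vs_estimate(st, phase1, config$stopping),
      min_fraction_screened(st, corpus, config$stopping),
      consecutive_irrelevant(st, config$stopping)))
    list(stop = comp$satisfied, diagnostics = list(composite = comp))
  }
  phase_loop(S, corpus, 2L, oracle, model, features, config, stop_fun)
  # census stop: report which of the four conditions were left unmet
  if (isTRUE(S$diagnostics[["2"]]$census)) {
    st <- snapshot_state(S)
    S$diagnostics[["2"]]$composite <- composite_all(list(
      key_papers_found(st, corpus),
      min_screened_vs_estimate(st, phase1, config$stopping),
      min_fraction_screened(st, corpus, config$stopping),
      consecutive_irrelevant(st, config$stopping)))
  }
  snapshot_state(S)
}

# ---- phase 3 ---------------------------------------------------------------

#' Phase 3: model switch
#'
#' Re-ranks the residual unlabeled pool with the alternative model family,
#' trained on all labeling decisions so far, and continues the
#' present-top/label loop.  Stops when `window` consecutive decisions in
#' this phase are irrelevant (or at census).  On exit the final
#' alternative-model ranking over the whole corpus is stored on the state
#' for the phase-4 pseudo-labels.
#'
#' @inheritParams run_phase2
#' @param model an `alternative`-family model (default from `config`).
#' @return the updated `screening_state`.
#' @export
run_phase3 <- function(state, corpus, config, oracle, model = NULL,
                       features = NULL) {
  S <- env_from_state(state, corpus)
  features <- features %||% corpus_features(corpus)
  model <- model %||% make_alternative_model(config$alternative,
                                             derive_seed(config$seed, "alternative"))
  stop_fun <- function(st) {
    crit <- consecutive_irrelevant(st, config$stopping)
    list(stop = crit$satisfied, diagnostics = list(criterion = crit))
  }
  model <- phase_loop(S, corpus, 3L, oracle, model, features, config, stop_fun)
  # final ranking over all records, for the phase-4 pseudo-label seed sets
  lab_rows <- which(!is.na(S$assigned))
  model <- fit(model, corpus[lab_rows, , drop = FALSE],
               labels = S$assigned[lab_rows], features = features)
  S$phase3_ranking <- rank_records(model, corpus)
  snapshot_state(S)
}

# ---- phase 4 ---------------------------------------------------------------

#' Phase 4: quality check of the excluded records
#'
#' Builds a training set from the 10 highest-ranked records of the final
#' phase-3 ranking (pseudo-labeled relevant) and the 10 lowest-ranked
#' (pseudo-labeled irrelevant); with fewer than 20 ranked records the split
#' degrades to halves, with a warning.  A simple lexical model fitted on
#' these pseudo-labels ranks every record previously labeled irrelevant,
#' and an error-free second screener walks down that ranking.  A relevant
#' find flips the record's final label (logged as a phase-4 correction).
#' Stops on `window` consecutive irrelevant decisions or census.
#'
#' @inheritParams run_phase2
#' @param second_oracle the independent second screener; must be error-free
#'   (default a perfect oracle).
#' @return the updated `screening_state`.
#' @export
run_phase4 <- function(state, corpus, config, second_oracle = NULL,
                       model = NULL, features = NULL) {
  S <- env_from_state(state, corpus)
  features <- features %||% corpus_features(corpus)
  second_oracle <- second_oracle %||% make_oracle("perfect")
  if (second_oracle$mode != "perfect")
    stop("the phase-4 second screener must be error-free")
  ranking <- S$phase3_ranking
  if (is.null(ranking)) {
    alt <- make_alternative_model(config$alternative,
                                  derive_seed(config$seed, "alternative"))
    lab_rows <- which(!is.na(S$assigned))
    alt <- fit(alt, corpus[lab_rows, , drop = FALSE],
               labels = S$assigned[lab_rows], features = features)
    ranking <- rank_records(alt, corpus)
  }
  nr <- nrow(ranking)
  if (nr >= 20L) {
    n_top <- 10L; n_bot <- 10L
  } else {
    n_top <- as.integer(ceiling(nr / 2)); n_bot <- nr - n_top
    warning("fewer than 20 ranked records; pseudo-label sets degraded to ",
            n_top, " + ", n_bot)
  }
  pseudo_ids <- c(utils::head(ranking$record_id, n_top),
                  utils::tail(ranking$record_id, n_bot))
  pseudo_lab <- c(rep("relevant", n_top), rep("irrelevant", n_bot))
  pm <- model %||% make_simple_model(config$classifier,
                                     derive_seed(config$seed, "phase4"))
  pm <- fit(pm, corpus[match(pseudo_ids, corpus$record_id), , drop = FALSE],
            labels = pseudo_lab, features = features)
  pool_rows <- which(!is.na(S$assigned) & S$assigned == "irrelevant")
  stop_fun <- function(st) {
    crit <- consecutive_irrelevant(st, config$stopping)
    list(stop = crit$satisfied, diagnostics = list(criterion = crit))
  }
  phase_loop(S, corpus, 4L, second_oracle, pm, features, config, stop_fun,
             pool_rows = pool_rows, static_ranking = TRUE)
  snapshot_state(S)
}

# ---- full procedure --------------------------------------------------------

#' Run the full four-phase screening simulation
#'
#' Executes phases 1-4 against the configured oracles and models and
#' returns a `safe_result` holding the complete screening log, per-phase
#' diagnostics, the prevalence estimate, the final inclusion set, the
#' recall curve and evaluation metrics.  Fully deterministic given
#' `(corpus, config)`.
#'
#' @param corpus a `safe_corpus`; validated on entry if not already.
#' @param config a [safe_config()].
#' @return a `safe_result`.
#' @export
run_safe <- function(corpus, config = safe_config()) {
  stopifnot(inherits(corpus, "safe_corpus"), inherits(config, "safe_config"))
  if (!isTRUE(attr(corpus, "validated"))) corpus <- validate_corpus(corpus)
  features <- corpus_features(corpus)
  oracle <- make_oracle(config$oracle, config$false_negative_rate,
                        derive_seed(config$seed, "oracle"))
  second <- make_oracle("perfect")
  p1 <- run_phase1(corpus, config, oracle)
  state <- run_phase2(p1$state, corpus, p1$phase1, config, oracle,
                      features = features)
  state <- run_phase3(state, corpus, config, oracle, features = features)
  state <- run_phase4(state, corpus, config, second_oracle = second,
                      features = features)
  log <- state$log
  included <- names(state$assigned)[!is.na(state$assigned) &
                                      state$assigned == "relevant"]
  corrections <- log$record_id[log$phase == 4 & log$label == "relevant"]
  per_phase <- table(factor(log$phase, levels = 1:4))
  per_phase_rel <- tapply(log$label == "relevant",
                          factor(log$phase, levels = 1:4),
                          sum, default = 0L)
  structure(list(
    state = state,
    phase1 = p1$phase1,
    config = config,
    screened_per_phase = stats::setNames(as.integer(per_phase), paste0("phase", 1:4)),
    relevant_per_phase = stats::setNames(as.integer(per_phase_rel), paste0("phase", 1:4)),
    included_ids = included,
    corrections = corrections,
    stop_diagnostics = state$diagnostics,
    oracle_flipped = oracle$flipped,
    recall_curve = recall_curve(state),
    metrics = compute_metrics(state, corpus,
                              seed = derive_seed(config$seed, "baseline"))
  ), class = "safe_result")
}
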