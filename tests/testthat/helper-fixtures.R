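# Fixture builders and independent brute-force reference implementations
# used across the suite.  All fixtures are built in code.

# a tiny hand-written corpus; topic docs share the word "enzyme kinetics",
# background docs are about unrelated subjects
toy_corpus <- function() {
  safe_corpus(data.frame(
    record_id = sprintf("t%02d", 1:6),
    title = c("enzyme kinetics assay", "enzyme kinetics model",
              "enzyme kinetics review", "forest bird migration",
              "volcanic rock dating", "urban traffic flow"),
    abstract = c("enzyme kinetics substrate binding rate",
                 "enzyme kinetics inhibition substrate model",
                 "enzyme kinetics substrate turnover review",
                 "bird migration routes forest canopy",
                 "rock dating isotope volcanic layers",
                 "traffic flow congestion urban network"),
    year = 2001:2006,
    label = c(rep("relevant", 3), rep("irrelevant", 3)),
    key_paper = FALSE,
    stringsAsFactors = FALSE))
}

# build a screening_state directly from label/phase vectors (for criteria
# tests that do not need a full engine run)
state_from_labels <- function(labels, phases = rep(1L, length(labels)),
                              ids = sprintf("r%03d", seq_along(labels))) {
  log <- data.frame(step = seq_along(labels), record_id = ids,
                    phase = as.integer(phases),
                    rank_presented = rep(NA_integer_, length(labels)),
                    label = as.character(ifelse(labels == 1 | labels == "relevant",
                                                "relevant", "irrelevant")),
                    stringsAsFactors = FALSE)
  structure(list(log = log,
                 phase_boundaries = lapply(split(log$step, log$phase), range),
                 labeled_ids = unique(log$record_id),
                 found_relevant = length(unique(log$record_id[log$label == "relevant"])),
                 assigned = NULL, diagnostics = list(), rng_seed = 0L),
            class = "screening_state")
}

# corpus shell for criteria tests: n records, given key-paper ids
corpus_shell <- function(n, key_ids = character(),
                         ids = sprintf("r%03d", seq_len(n))) {
  safe_corpus(data.frame(
    record_id = ids, title = paste("doc", ids), abstract = "",
    year = 2000L,
    label = ifelse(ids %in% key_ids | seq_len(n) == 1L,
                   "relevant", "irrelevant"),
    key_paper = ids %in% key_ids, stringsAsFactors = FALSE))
}

# ---- independent brute-force references (kept deliberately naive) ---------

bf_key_papers <- function(log, key_ids) {
  all(vapply(key_ids, function(k) {
    any(log$record_id == k & log$label == "relevant")
  }, logical(1)))
}

bf_streak <- function(log, window) {
  cur <- log$phase[nrow(log)]
  lab <- log$label[log$phase == cur]
  if (length(lab) < window) return(FALSE)
  all(lab[(length(lab) - window + 1L):length(lab)] == "irrelevant")
}

bf_min_fraction <- function(log, Tn, frac) nrow(log) >= ceiling(frac * Tn)

bf_min_vs_estimate <- function(log, rrt_hat, mult) nrow(log) >= mult * rrt_hat

# step-by-step replay of the phase-2/3/4 stop rules against a finished log:
# returns TRUE when the recorded stop step is the first step at which the
# rule holds (census stops are checked as pool exhaustion)
replay_stop_consistent <- function(result, corpus, config) {
  log <- screening_log(result)
  sc <- config$stopping
  kp <- corpus$record_id[corpus$key_paper]
  rrt <- result$phase1$RR_T_hat
  ok <- TRUE
  for (ph in 2:4) {
    steps <- which(log$phase == ph)
    if (!length(steps)) next
    stop_at <- NA_integer_
    for (s in steps) {
      sub <- log[seq_len(s), , drop = FALSE]
      hold <- if (ph == 2) {
        bf_key_papers(sub, kp) &&
          bf_min_vs_estimate(sub, rrt, sc$rrt_multiplier) &&
          bf_min_fraction(sub, nrow(corpus), sc$min_fraction) &&
          bf_streak(sub, sc$window)
      } else bf_streak(sub, sc$window)
      if (hold) { stop_at <- s; break }
    }
    last <- steps[length(steps)]
    census <- isTRUE(result$stop_diagnostics[[as.character(ph)]]$census)
    if (census) {
      # rule must not have held before the pool emptied
      if (!is.na(stop_at) && stop_at < last) ok <- FALSE
    } else if (is.na(stop_at) || stop_at != last) ok <- FALSE
  }
  ok
}
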