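# Evaluation metrics: recall curves, work saved over sampling (WSS),
# random-order baselines, PRISMA-style flow counts.
#
# WSS at the achieved recall is (T - n_viewed) / T - (1 - recall): the
# fraction of screening effort saved relative to exhaustive screening,
# penalized by the recall shortfall.  n_viewed counts screening decisions
# (the phase-4 re-screen of an excluded record is a decision, so effort is
# charged for it).

#' Cumulative recall curve of a screening run
#'
#' One point per screening decision: records viewed so far against relevant
#' records found so far.
#'
#' @param state a `screening_state`, `safe_result`, or a screening-log
#'   data.frame (as from [read_screening_log()]).
#' @return a `recall_curve` data.frame with columns `n_viewed` and
#'   `n_relevant_found`.
#' @export
recall_curve <- function(state) {
  log <- if (is.data.frame(state)) state else screening_log(state)
  if (nrow(log) == 0L) stop("screening log is empty")
  structure(data.frame(n_viewed = seq_len(nrow(log)),
                       n_relevant_found = cumsum(log$label == "relevant")),
            class = c("recall_curve", "data.frame"))
}

#' @export
plot.recall_curve <- function(x, ..., main = "Recall curve") {
  graphics::plot(x$n_viewed, x$n_relevant_found, type = "s",
                 xlab = "records viewed", ylab = "relevant records found",
                 main = main, ...)
  invisible(x)
}

# records a uniform-random screening order needs to view to find k of the
# R relevant records: seeded Monte Carlo mean with standard error
random_baseline_viewed <- function(labels, k, n_mc = 200, seed = 1) {
  n <- length(labels)
  rel <- which(labels == "relevant")
  if (k == 0) return(list(mean = 0, se = 0))
  draws <- with_seed(seed, vapply(seq_len(n_mc), function(i) {
    pos <- sort(sample.int(n, length(rel)))  # positions of relevants in a random order
    pos[k]
  }, numeric(1)))
  list(mean = mean(draws), se = stats::sd(draws) / sqrt(n_mc))
}

#' Evaluation metrics for a completed (or partial) screening run
#'
#' @param state a `screening_state` or `safe_result`.
#' @param corpus the corpus with oracle labels (simulation mode).
#' @param n_mc Monte-Carlo replicates for the random-order baseline.
#' @param seed seed for the baseline simulation.
#' @return a `safe_metrics` list: `recall_at_stop`, `loss` (missed relevant
#'   count), `wss_at_stop`, `wss_at_95` (`NA` until recall 0.95 is
#'   reached), `screened_total`, `screened_per_phase`,
#'   `random_baseline_expected_viewed` and its standard error.
#' @export
compute_metrics <- function(state, corpus, n_mc = 200, seed = 1) {
  log <- if (is.data.frame(state)) state else screening_log(state)
  R <- sum(corpus$label == "relevant")
  if (R == 0) stop("corpus has zero relevant records")
  Tn <- nrow(corpus)
  found_ids <- unique(log$record_id[log$label == "relevant"])
  found <- length(found_ids)
  viewed <- nrow(log)
  recall <- found / R
  wss <- (Tn - viewed) / Tn - (1 - recall)
  cum <- cumsum(log$label == "relevant")
  k95 <- ceiling(0.95 * R)
  at95 <- match(TRUE, cum >= k95)
  wss95 <- if (is.na(at95)) NA_real_ else (Tn - at95) / Tn - (1 - 0.95)
  rb <- random_baseline_viewed(corpus$label, found, n_mc = n_mc, seed = seed)
  per_phase <- table(factor(log$phase, levels = 1:4))
  structure(list(recall_at_stop = recall, loss = R - found,
                 wss_at_stop = wss, wss_at_95 = wss95,
                 screened_total = viewed,
                 screened_per_phase = stats::setNames(as.integer(per_phase),
                                                      paste0("phase", 1:4)),
                 true_relevant = R,
                 random_baseline_expected_viewed = rb$mean,
                 random_baseline_se = rb$se),
            class = "safe_metrics")
}

#' @export
print.safe_metrics <- function(x, ...) {
  cat(sprintf("recall at stop:    %.3f (missed %d of %d relevant)\n",
              x$recall_at_stop, x$loss, x$true_relevant))
  cat(sprintf("records viewed:    %d (%s)\n", x$screened_total,
              paste(sprintf("%s=%d", names(x$screened_per_phase),
                            x$screened_per_phase), collapse = ", ")))
  cat(sprintf("WSS at stop:       %.3f\n", x$wss_at_stop))
  if (!is.na(x$wss_at_95)) cat(sprintf("WSS at recall .95: %.3f\n", x$wss_at_95))
  cat(sprintf("random baseline:   %.1f records (se %.1f) to match achieved recall\n",
              x$random_baseline_expected_viewed, x$random_baseline_se))
  invisible(x)
}

#' PRISMA-style flow counts for a completed run
#'
#' A flat mapping of the counts a PRISMA flow diagram needs:
#' `identified`, per-phase `screened`, `included`, `excluded`,
#' `never_viewed`, and `phase4_corrections`.  The counts satisfy
#' `identified = included + excluded + never_viewed`.
#'
#' @param result a `safe_result`.
#' @return a named list of counts.
#' @export
prisma_counts <- function(result) {
  stopifnot(inherits(result, "safe_result"))
  log <- screening_log(result)
  Tn <- length(result$state$assigned)
  viewed_ids <- unique(log$record_id)
  included <- length(result$included_ids)
  excluded <- length(viewed_ids) - included
  out <- c(list(identified = Tn),
           as.list(result$screened_per_phase),
           list(included = included, excluded = excluded,
                never_viewed = Tn - length(viewed_ids),
                phase4_corrections = length(result$corrections)))
  out
}

#' @export
print.safe_result <- function(x, ...) {
  cat("SAFE screening simulation\n")
  cat(sprintf("  corpus: %d records, %d relevant\n",
              length(x$state$assigned), x$metrics$true_relevant))
  cat(sprintf("  phase 1: t=%d, RR_t=%d, FRR_t=%.4f, RR_T_hat=%d\n",
              x$phase1$t, x$phase1$RR_t, x$phase1$FRR_t, x$phase1$RR_T_hat))
  for (p in 1:4) {
    cat(sprintf("  phase %d: %d screened, %d relevant found\n", p,
                x$screened_per_phase[[p]], x$relevant_per_phase[[p]]))
  }
  cat(sprintf("  included: %d records (%d phase-4 corrections)\n",
              length(x$included_ids), length(x$corrections)))
  print(x$metrics)
  invisible(x)
}

#' @export
summary.safe_result <- function(object, ...) {
  comp <- object$stop_diagnostics[["2"]]$composite
  cat("Stop diagnostics\n")
  if (!is.null(comp)) {
    cat("  phase 2 composite:",
        if (comp$satisfied) "all four conditions satisfied" else "stopped at census with unmet conditions", "\n")
    for (m in comp$diagnostics$members) {
      cat(sprintf("    - %-26s %s\n", m$name,
                  if (m$satisfied) "satisfied" else "unsatisfied"))
    }
  }
  for (p in c("3", "4")) {
    d <- object$stop_diagnostics[[p]]
    if (is.null(d)) next
    cat(sprintf("  phase %s: %s\n", p,
                if (isTRUE(d$census)) "census (pool exhausted)"
                else sprintf("window rule (streak %d)",
                             d$criterion$diagnostics$streak)))
  }
  pc <- prisma_counts(object)
  cat("PRISMA counts: ", paste(sprintf("%s=%s", names(pc), unlist(pc)),
                               collapse = ", "), "\n")
  invisible(object)
}

#' @export
plot.safe_result <- function(x, ...) {
  plot(x$recall_curve, main = "SAFE screening recall", ...)
  bounds <- x$state$phase_boundaries
  for (p in names(bounds)) {
    graphics::abline(v = bounds[[p]][2], lty = 3, col = "grey50")
  }
  graphics::abline(h = x$metrics$true_relevant, lty = 2, col = "red")
  invisible(x)
}
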