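# Composable stopping criteria.
#
# Every criterion is a pure function of (state, corpus, phase1, config)
# returning a criterion_result whose diagnostics are always sufficient to
# explain the decision.  The active-learning phase stops at the first
# record where the four-fold composite (key papers found AND screening
# floor vs the prevalence estimate AND minimum fraction screened AND a
# consecutive-irrelevant window) holds; the window criterion is
# phase-scoped and resets at phase boundaries, because each phase re-ranks
# with a different model.

#' Stopping-rule configuration
#'
#' All values are deliberately user-configurable; the defaults are the
#' customary example settings (a 50-record irrelevant window, a 10% minimum
#' fraction, twice the estimated relevant count, a 1% / 50-record training
#' phase), not universal rules.
#'
#' @param window consecutive-irrelevant window length (default 50).
#' @param min_fraction minimum fraction of the dataset screened (default 0.10).
#' @param rrt_multiplier multiplier on the estimated relevant count
#'   (default 2).
#' @param phase1_fraction fraction of the dataset screened in the training
#'   phase (default 0.01).
#' @param phase1_min minimum training-phase size in records (default 50);
#'   guards against unrepresentative estimates on small datasets.
#' @param plateau_window trailing records inspected for a recall plateau
#'   (default 100).
#' @param plateau_slope_max maximum new-relevant-per-record slope still
#'   called a plateau (default 0.01).
#' @param refit_interval labels between model refits (default 1).
#' @return a `stopping_config` list.
#' @export
stopping_config <- function(window = 50, min_fraction = 0.10, rrt_multiplier = 2,
                            phase1_fraction = 0.01, phase1_min = 50,
                            plateau_window = 100, plateau_slope_max = 0.01,
                            refit_interval = 1) {
  stopifnot(window >= 1, min_fraction > 0, min_fraction <= 1,
            rrt_multiplier > 0, phase1_fraction > 0, phase1_min >= 1,
            plateau_window >= 1, plateau_slope_max >= 0, refit_interval >= 1)
  structure(list(window = as.integer(window), min_fraction = min_fraction,
                 rrt_multiplier = rrt_multiplier,
                 phase1_fraction = phase1_fraction,
                 phase1_min = as.integer(phase1_min),
                 plateau_window = as.integer(plateau_window),
                 plateau_slope_max = plateau_slope_max,
                 refit_interval = as.integer(refit_interval)),
            class = "stopping_config")
}

new_criterion <- function(name, satisfied, diagnostics) {
  structure(list(name = name, satisfied = isTRUE(satisfied),
                 diagnostics = diagnostics),
            class = "criterion_result")
}

#' @export
print.criterion_result <- function(x, ...) {
  cat(sprintf("<criterion> %-26s %s\n", x$name,
              if (x$satisfied) "satisfied" else "NOT satisfied"))
  invisible(x)
}

#' All key papers marked relevant?
#'
#' Satisfied iff every key paper in the corpus appears in the screening log
#' with an assigned label of relevant.  A corpus without key papers is
#' vacuously satisfied, flagged by a warning in the diagnostics.
#'
#' @param state a `screening_state`.
#' @param corpus the corpus being screened.
#' @return a `criterion_result`; diagnostics name any missing key papers.
#' @export
key_papers_found <- function(state, corpus) {
  log <- screening_log(state)
  kp <- corpus$record_id[corpus$key_paper]
  found <- log$record_id[log$label == "relevant"]
  missing <- setdiff(kp, found)
  diag <- list(n_key_papers = length(kp), missing_ids = missing)
  if (length(kp) == 0L) diag$warning <- "corpus has no key papers; criterion is vacuously satisfied"
  new_criterion("key_papers_found", length(missing) == 0L, diag)
}

#' Screening floor relative to the estimated relevant count
#'
#' Satisfied iff the cumulative number of screening decisions (training
#' phase included) is at least `rrt_multiplier * RR_T_hat`.
#'
#' @param state a `screening_state`.
#' @param phase1 a `phase1_result`.
#' @param config a [stopping_config()].
#' @return a `criterion_result`.
#' @export
min_screened_vs_estimate <- function(state, phase1, config) {
  screened <- nrow(screening_log(state))
  needed <- config$rrt_multiplier * phase1$RR_T_hat
  new_criterion("min_screened_vs_estimate", screened >= needed,
                list(screened = screened, required = needed,
                     RR_T_hat = phase1$RR_T_hat,
                     multiplier = config$rrt_multiplier))
}

#' Minimum fraction of the dataset screened
#'
#' Satisfied iff cumulative screening decisions reach
#' `ceiling(min_fraction * T)`.
#'
#' @inheritParams min_screened_vs_estimate
#' @param corpus the corpus being screened.
#' @return a `criterion_result`.
#' @export
min_fraction_screened <- function(state, corpus, config) {
  screened <- nrow(screening_log(state))
  needed <- ceiling(config$min_fraction * nrow(corpus))
  new_criterion("min_fraction_screened", screened >= needed,
                list(screened = screened, required = needed,
                     min_fraction = config$min_fraction, T = nrow(corpus)))
}

#' Consecutive-irrelevant window within the current phase
#'
#' Satisfied iff the last `window` decisions of the current phase are all
#' irrelevant; a phase with fewer than `window` decisions is never
#' satisfied.  A relevant find resets the streak (this criterion is
#' deliberately non-monotone).
#'
#' @inheritParams min_screened_vs_estimate
#' @param scope streak scope; only `"current_phase"` is supported — streaks
#'   never carry across phase boundaries.
#' @return a `criterion_result`; diagnostics report the current streak.
#' @export
consecutive_irrelevant <- function(state, config, scope = "current_phase") {
  scope <- match.arg(scope, "current_phase")
  log <- screening_log(state)
  if (nrow(log) == 0L)
    return(new_criterion("consecutive_irrelevant", FALSE,
                         list(streak = 0L, window = config$window, phase = NA)))
  cur <- log$phase[nrow(log)]
  lab <- log$label[log$phase == cur]
  irr <- rev(lab) == "irrelevant"
  streak <- if (all(irr)) length(irr) else which(!irr)[1] - 1L
  new_criterion("consecutive_irrelevant", streak >= config$window,
                list(streak = as.integer(streak), window = config$window,
                     phase = cur, decisions_in_phase = length(lab)))
}

#' Conjunction of stopping criteria
#'
#' @param criteria non-empty list of `criterion_result`s.
#' @return a `criterion_result` satisfied iff every member is, with the
#'   members' diagnostics aggregated.
#' @export
composite_all <- function(criteria) {
  if (length(criteria) == 0L) stop("composite_all needs at least one criterion")
  stopifnot(all(vapply(criteria, inherits, logical(1), "criterion_result")))
  sat <- vapply(criteria, `[[`, logical(1), "satisfied")
  names(criteria) <- vapply(criteria, `[[`, character(1), "name")
  new_criterion("composite_all", all(sat),
                list(satisfied = sat, members = criteria))
}

#' Recall-curve plateau (advisory)
#'
#' Satisfied iff the number of new relevant records over the trailing
#' `plateau_window` viewed records, per record, is at most
#' `plateau_slope_max`.  Advisory only: plateau inspection signals that it
#' is worth checking the binding criteria, and never gates stopping by
#' itself.
#'
#' @param curve a `recall_curve` (see [recall_curve()]).
#' @param config a [stopping_config()].
#' @return a `criterion_result`.
#' @export
plateau_reached <- function(curve, config) {
  n <- nrow(curve)
  w <- config$plateau_window
  if (n < w)
    return(new_criterion("plateau_reached", FALSE,
                         list(points = n, plateau_window = w,
                          reason = "curve shorter than plateau window")))
  prev <- if (n - w >= 1L) curve$n_relevant_found[n - w] else 0
  gained <- curve$n_relevant_found[n] - prev
  slope <- gained / w
  new_criterion("plateau_reached", slope <= config$plateau_slope_max,
                list(new_relevant = gained, plateau_window = w,
                     slope = slope, slope_max = config$plateau_slope_max))
}
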