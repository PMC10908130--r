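# Prevalence estimation from the random training phase.
#
# The training phase yields RR_t relevant records among t screened; the
# fraction FRR_t = RR_t / t extrapolates to a crude estimate of the number
# of relevant records in the full dataset, RR_T_hat = ceiling(FRR_t * T),
# which parameterizes the screening floor of the active-learning phase.
# Ceiling (not rounding) keeps the floor conservative.  An optional
# hypergeometric upper confidence bound is provided for users who want a
# conservative alternative to the point estimate; it is off by default.

#' Fraction of relevant records in the training set
#'
#' @param RR_t number of relevant records in the training set (>= 1; the
#'   training phase cannot end without at least one relevant record).
#' @param t training-set size.
#' @return `RR_t / t`.
#' @export
estimate_frr <- function(RR_t, t) {
  if (t < 1) stop("t must be >= 1")
  if (RR_t < 1) stop("RR_t must be >= 1 (phase 1 ends with at least one relevant record)")
  if (RR_t > t) stop("RR_t cannot exceed t")
  RR_t / t
}

#' Estimated number of relevant records in the full dataset
#'
#' @param FRR_t fraction of relevant records in the training set, in (0, 1].
#' @param T_total total number of records.
#' @return `ceiling(FRR_t * T_total)`.
#' @export
estimate_total_relevant <- function(FRR_t, T_total) {
  if (!is.finite(FRR_t) || FRR_t <= 0 || FRR_t > 1)
    stop("FRR_t must be in (0, 1]")
  if (T_total < 1) stop("T_total must be >= 1")
  as.integer(ceiling(FRR_t * T_total))
}

#' Hypergeometric upper confidence bound on the number of relevant records
#'
#' The largest population relevant count `R` such that observing at most
#' `RR_t` relevant records in a simple random sample of `t` from `T_total`
#' still has probability at least `1 - confidence`.  A conservative,
#' optional alternative to the crude point estimate; at a census
#' (`t == T_total`) the bound equals the observed count.
#'
#' @param RR_t observed relevant count in the sample (>= 1).
#' @param t sample size.
#' @param T_total population size.
#' @param confidence confidence level in (0, 1), default 0.95.
#' @return integer upper bound, always >= the point estimate rounded down
#'   to the feasible range.
#' @export
upper_bound_relevant <- function(RR_t, t, T_total, confidence = 0.95) {
  if (t < 1 || RR_t < 1 || RR_t > t) stop("need 1 <= RR_t <= t")
  if (T_total < t) stop("T_total must be >= t")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  if (t == T_total) return(as.integer(RR_t))
  alpha <- 1 - confidence
  # P(X <= RR_t | R) is non-increasing in R: binary search for the largest
  # feasible R with tail probability still >= alpha
  tail_ok <- function(R) stats::phyper(RR_t, R, T_total - R, t) >= alpha
  lo <- RR_t                      # always feasible: P = 1
  hi <- T_total - (t - RR_t)      # cannot exceed population minus observed irrelevants
  if (tail_ok(hi)) return(as.integer(hi))
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (tail_ok(mid)) lo <- mid else hi <- mid
  }
  as.integer(lo)
}
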