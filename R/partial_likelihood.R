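#' Cox partial likelihood of fixed subject scores
#'
#' The tree-search engine scores candidate interaction trees by the Cox
#' partial likelihood of per-subject log-hazard scores entered as offsets
#' (no free regression parameters). This file implements that likelihood and
#' its gradient with respect to the scores, vectorised over risk sets via
#' cumulative sums, with Efron or Breslow handling of tied event times.
#'
#' @name partial_likelihood
NULL

# Precompute the risk-set structure for (time, event): sort order, tied event
# groups, risk-set start indices, and the (group, within-tie) expansion used
# by Efron's correction. Reused across many score evaluations.
cox_prep <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (sum(event != 0) < 1) stop("no events")
  n <- length(time)
  ord <- order(time)
  ts <- time[ord]
  es <- event[ord] != 0
  ev_all <- which(es)                      # sorted indices of all events
  ev_t <- ts[ev_all]
  ev_times <- unique(ev_t)
  ng <- length(ev_times)
  grp_of_ev <- match(ev_t, ev_times)       # group id per event (1..ng)
  d <- tabulate(grp_of_ev, nbins = ng)     # events per group
  # first sorted index with ts >= event time (start of the risk set)
  risk_starts <- findInterval(ev_times, ts, left.open = TRUE) + 1L
  # Efron expansion for tied groups: one row per (group, l), l = 0..d-1
  tie_grp <- which(d > 1L)
  rep_j <- rep(tie_grp, d[tie_grp])
  lfrac <- unlist(lapply(d[tie_grp], function(dd) (seq_len(dd) - 1) / dd),
                  use.names = FALSE)
  if (is.null(lfrac)) lfrac <- numeric(0)
  list(n = n, ord = ord, ts = ts, es = es, ev_all = ev_all,
       grp_of_ev = grp_of_ev, d = d, ng = ng, risk_starts = risk_starts,
       tie_grp = tie_grp, rep_j = rep_j, lfrac = lfrac,
       single_grp = which(d == 1L))
}

#' Log partial likelihood (and gradient) of subject scores as offsets
#'
#' @param prep Structure from `cox_prep(time, event)`.
#' @param scores Numeric per-subject log-hazard scores (original order).
#' @param ties `"efron"` or `"breslow"`.
#' @param grad Also return the gradient with respect to `scores`.
#' @return List: `ll`, and `grad` (original order) if requested.
#' @keywords internal
cox_pl <- function(prep, scores, ties = c("efron", "breslow"), grad = FALSE) {
  ties <- match.arg(ties)
  out <- cox_pl_sorted(scores[prep$ord], prep$ev_all, prep$grp_of_ev, prep$d,
                       prep$risk_starts, efron = (ties == "efron"),
                       want_grad = grad)
  if (grad) {
    g <- numeric(prep$n)
    g[prep$ord] <- out$grad
    out$grad <- g
  }
  out
}

# pure-R reference implementation of cox_pl (kept as the independent oracle
# for the compiled kernel)
cox_pl_r <- function(prep, scores, ties = c("efron", "breslow"), grad = FALSE) {
  ties <- match.arg(ties)
  ss <- scores[prep$ord]
  w <- exp(ss)
  revcum <- rev(cumsum(rev(w)))
  S <- revcum[prep$risk_starts]            # risk-set totals per group
  ll_num <- sum(ss[prep$ev_all])
  A <- numeric(prep$ng)                    # d log-denominator / d (risk-set sum)
  C <- numeric(prep$ng)                    # Efron event-side correction
  if (ties == "breslow" || length(prep$tie_grp) == 0L) {
    ll <- ll_num - sum(prep$d * log(S))
    A <- prep$d / S
  } else {
    Tg <- as.numeric(rowsum(w[prep$ev_all], prep$grp_of_ev, reorder = TRUE))
    sg <- prep$single_grp
    tg <- prep$tie_grp
    denom <- S[prep$rep_j] - prep$lfrac * Tg[prep$rep_j]
    ll <- ll_num - sum(log(S[sg])) - sum(log(denom))
    A[sg] <- 1 / S[sg]
    if (length(tg)) {
      A[tg] <- as.numeric(rowsum(1 / denom, prep$rep_j, reorder = TRUE))
      C[tg] <- as.numeric(rowsum(prep$lfrac / denom, prep$rep_j, reorder = TRUE))
    }
  }
  out <- list(ll = ll)
  if (grad) {
    cumA <- cumsum(A)
    # G_k = sum of A_j over groups whose risk set contains sorted index k,
    # i.e. groups with risk_start <= k
    gidx <- findInterval(seq_len(prep$n), prep$risk_starts)
    G <- c(0, cumA)[gidx + 1L]
    gs <- -w * G
    gs[prep$ev_all] <- gs[prep$ev_all] + 1 + w[prep$ev_all] * C[prep$grp_of_ev]
    gout <- numeric(prep$n)
    gout[prep$ord] <- gs
    out$grad <- gout
  }
  out
}

#' Log partial likelihood of fixed per-subject log hazards
#'
#' Public entry point: ties-corrected Cox log partial likelihood of given
#' subject scores (offsets only, no free parameters).
#'
#' @param loghazards Numeric per-subject log-hazard scores.
#' @param outcomes Data frame with `time_days` and `event`.
#' @param ties `"efron"` or `"breslow"`.
#' @return The log partial likelihood (a scalar).
#' @export
log_partial_likelihood <- function(loghazards, outcomes,
                                   ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(length(loghazards) == nrow(outcomes))
  prep <- cox_prep(outcomes$time_days, outcomes$event)
  cox_pl(prep, loghazards, ties = ties)$ll
}
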