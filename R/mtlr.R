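# Multi-task logistic regression (MTLR) survival machinery: time
# discretization, monotone survival-label encoding with censoring,
# the normalized configuration likelihood
#   P(y | x) = exp(sum_i y_i y'_i) / sum_{j=0}^{m} exp(sum_{i=j+1}^{m} y'_i),
# survival curves, discrete hazards, and risk scores.
#
# Configurations are indexed j = 0..m: configuration j has its first event
# indicator at position j+1 (j = m is the all-zero "survived past the
# grid" vector), so there are m+1 valid monotone label vectors and the
# exponent of configuration j is the suffix score s_j = sum_{i>j} y'_i.

#' Build a discrete time grid for MTLR
#'
#' Splits the time axis into m intervals \eqn{l_i = [t_{i-1}, t_i)} with
#' \eqn{t_0 = 0}. The default \code{"quantile"} strategy places interior
#' boundaries at empirical quantiles of the supplied event times (so
#' intervals carry comparable event mass); \code{"uniform"} uses equal
#' widths. The last boundary is \code{max(times)} inflated by a relative
#' 1e-9 so the largest observed time falls inside the grid. Duplicate
#' boundaries from heavily tied times are collapsed, reducing m with a
#' warning.
#'
#' @param times non-empty vector of non-negative observed times (use event
#'   times when available).
#' @param mIntervals requested number of intervals (>= 1).
#' @param strategy \code{"quantile"} or \code{"uniform"}.
#' @return A [TimeGrid-class] with at most \code{mIntervals} intervals.
#' @export
makeTimeGrid <- function(times, mIntervals = 10L,
                         strategy = c("quantile", "uniform")) {
  strategy <- match.arg(strategy)
  if (mIntervals < 1L) stop("mIntervals must be >= 1")
  times <- times[!is.na(times)]
  if (!length(times) || any(times < 0))
    stop("times must be non-empty and non-negative")
  tMax <- max(times)
  if (tMax <= 0) stop("all times are zero; cannot build a grid")
  inner <- if (mIntervals == 1L) numeric(0) else if (strategy == "quantile")
    unname(quantile(times, probs = seq_len(mIntervals - 1L) / mIntervals))
  else
    seq(0, tMax, length.out = mIntervals + 1L)[2:mIntervals]
  b <- c(0, inner, tMax * (1 + 1e-9))
  bu <- unique(b[c(TRUE, diff(b) > 0)])
  bu <- bu[bu >= 0]
  keep <- c(TRUE, diff(bu) > 0)
  bu <- bu[keep]
  if (length(bu) < length(b))
    warning(sprintf("tied boundaries collapsed: m reduced from %d to %d",
                    mIntervals, length(bu) - 1L))
  new("TimeGrid", boundaries = bu)
}

.intervalOf <- function(time, grid) {
  b <- boundaries(grid)
  m <- length(b) - 1L
  j <- findInterval(time, b)       # b[j] <= time < b[j+1]
  if (j > m) {
    warning("time beyond the grid; assigned to the last interval")
    j <- m
  }
  if (j < 1L) j <- 1L
  as.integer(j)
}

#' Encode a subject's survival label on a time grid
#'
#' For an observed event (E = 1) in interval j, the m-dimensional label is
#' \eqn{y_i = 0} for \eqn{i < j} and \eqn{y_i = 1} for \eqn{i \ge j}
#' (the event has occurred by \eqn{t_i}). For a censored subject (E = 0)
#' the censoring interval is stored instead; its likelihood contribution
#' is marginalized over all monotone configurations compatible with
#' survival up to the censoring interval (switch index >= censoring
#' interval, or never).
#'
#' @param time observed time, >= 0 (beyond the grid it is assigned to the
#'   last interval with a warning).
#' @param event 0 or 1.
#' @param grid a [TimeGrid-class].
#' @return list of class \code{SurvivalLabel} with fields \code{y}
#'   (0/1 vector for events, NA for censored), \code{event},
#'   \code{interval} (event or censoring interval, 1-based), and
#'   \code{switch} (first 1 position for events).
#' @export
encodeSurvivalLabel <- function(time, event, grid) {
  stopifnot(event %in% c(0, 1), time >= 0)
  m <- nIntervals(grid)
  j <- .intervalOf(time, grid)
  y <- if (event == 1) as.integer(seq_len(m) >= j) else rep(NA_integer_, m)
  structure(list(y = y, event = as.integer(event), interval = j,
                 switch = if (event == 1) j else NA_integer_),
            class = "SurvivalLabel")
}

.suffixScores <- function(yScores) {
  # s_j = sum_{i > j} y'_i for j = 0..m
  m <- length(yScores)
  c(rev(cumsum(rev(yScores))), 0)
}

#' MTLR log-probability of a monotone label vector
#'
#' \deqn{\log P(y|x) = \sum_i y_i y'_i -
#'   \log \sum_{j=0}^{m} \exp\big(\sum_{i=j+1}^{m} y'_i\big),}
#' computed with a log-sum-exp guard. The j = m denominator term is
#' \eqn{\exp(0) = 1}.
#'
#' @param y monotone non-decreasing 0/1 vector of length m (at most one
#'   0 to 1 switch).
#' @param yScores numeric score vector y' of length m.
#' @return scalar log-probability.
#' @export
mtlrLogProbability <- function(y, yScores) {
  stopifnot(length(y) == length(yScores))
  if (any(!y %in% c(0, 1)) || any(diff(y) < 0))
    stop("y must be a monotone non-decreasing 0/1 vector")
  s <- .suffixScores(yScores)
  sum(y * yScores) - .logSumExp(s)
}

#' Batch MTLR survival loss with censoring marginalization
#'
#' For an uncensored subject the loss is the negative MTLR log-likelihood
#' of its label configuration. For a censored subject it is the negative
#' log of the summed probabilities of all configurations compatible with
#' survival to the censoring interval (event interval >= censoring
#' interval, or no event within the grid). The batch mean is returned.
#'
#' @param labels list of \code{SurvivalLabel}s from
#'   [encodeSurvivalLabel()].
#' @param yScoresBatch numeric matrix, one row of scores per label (a
#'   single vector is accepted for a batch of one).
#' @return scalar loss.
#' @export
survivalLoss <- function(labels, yScoresBatch) {
  if (inherits(labels, "SurvivalLabel")) labels <- list(labels)
  if (!length(labels)) stop("empty batch")
  if (!is.matrix(yScoresBatch)) yScoresBatch <- matrix(yScoresBatch, nrow = 1)
  stopifnot(nrow(yScoresBatch) == length(labels))
  losses <- vapply(seq_along(labels), function(i) {
    lab <- labels[[i]]
    s <- .suffixScores(yScoresBatch[i, ])
    logZ <- .logSumExp(s)
    if (lab$event == 1) {
      logZ - s[lab$interval - 1L + 1L]  # config index j = interval - 1
    } else {
      compat <- seq(lab$interval - 1L, length(s) - 1L) + 1L
      logZ - .logSumExp(s[compat])
    }
  }, numeric(1))
  mean(losses)
}

#' Predicted survival curve from MTLR scores
#'
#' \eqn{S(t_i)} is the summed probability of all configurations whose
#' event interval lies beyond \eqn{t_i}. The curve is non-increasing,
#' starts below \eqn{S(t_0) = 1}, and lives on the grid's upper
#' boundaries.
#'
#' @param yScores score vector y' of length m.
#' @param grid the matching [TimeGrid-class].
#' @return numeric vector \code{S(t_1), ..., S(t_m)} with names set to
#'   the boundary times.
#' @export
predictSurvivalCurve <- function(yScores, grid) {
  m <- nIntervals(grid)
  stopifnot(length(yScores) == m)
  s <- .suffixScores(yScores)
  logZ <- .logSumExp(s)
  p <- exp(s - logZ)                     # P(config j), j = 0..m
  S <- rev(cumsum(rev(p)))[-1]           # S(t_i) = sum_{j >= i} p_j
  names(S) <- boundaries(grid)[-1]
  S
}

#' MTLR risk score
#'
#' Discrete hazards are taken from the predicted survival curve,
#' \eqn{h_i = (S(t_{i-1}) - S(t_i)) / S(t_{i-1})} with \eqn{S(t_0) = 1}
#' (and \eqn{h_i = 1} where \eqn{S(t_{i-1}) = 0}), and summed over the
#' grid: \eqn{r(x) = \sum_i h_i}. Higher risk means an earlier expected
#' event. The score is invariant to adding a constant to all scores.
#'
#' @param yScores score vector y' of length m.
#' @param grid the matching [TimeGrid-class].
#' @return scalar risk score in [0, m].
#' @export
riskScore <- function(yScores, grid) {
  S <- predictSurvivalCurve(yScores, grid)
  Sprev <- c(1, S[-length(S)])
  h <- ifelse(Sprev > 0, (Sprev - S) / Sprev, 1)
  sum(h)
}
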