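## Large-scale observables: polarisation, outcome distributions, KL/G-test
## quality-of-fit, and the locality diagnostic.

#' Polarisation of a group
#'
#' `|2c - n| / n` where `c` is the clockwise count: 1 when everyone travels
#' the same way, 0 when the group is evenly split.
#'
#' @param c clockwise count (vectorised)
#' @param n group size
#' @return polarisation in `[0, 1]`
#' @export
polarisation <- function(c, n) {
  if (any(c < 0 | c > n)) stop("need 0 <= c <= n")
  abs(2 * c - n) / n
}

#' Expected polarisation of randomly oriented individuals
#'
#' `E |2X - n| / n` with `X ~ Binomial(n, 1/2)`, by exact enumeration;
#' larger for smaller groups.
#'
#' @param n group size
#' @return expected polarisation
#' @examples
#' expectedRandomPolarisation(6)   # 0.3125
#' @export
expectedRandomPolarisation <- function(n) {
  if (n < 1) stop("n must be >= 1")
  x <- 0:n
  sum(dbinom(x, n, 0.5) * abs(2 * x - n) / n)
}

#' Clockwise-count series of a record
#' @param rec an [OrientationRecord-class] or [SimResult-class]
#' @return integer vector of per-frame clockwise counts
#' @export
cwCountSeries <- function(rec) {
  if (is(rec, "SimResult")) return(rec@cwCount)
  as.integer(rowSums(stateMatrix(rec) == -1L))
}

#' Excess polarisation over time
#'
#' Mean over trials of the per-frame polarisation minus the binomial
#' expectation for randomly oriented individuals of the same group size.
#' All trials must share one group size and duration.
#'
#' @param recs list of [OrientationRecord-class] or [SimResult-class] for
#'   one group size
#' @return numeric time series of excess polarisation
#' @export
excessPolarisationSeries <- function(recs) {
  if (!is.list(recs)) recs <- list(recs)
  cw <- lapply(recs, cwCountSeries)
  if (length(unique(vapply(cw, length, 1L))) != 1)
    stop("trials must have equal durations")
  n <- unique(vapply(recs, function(r)
    if (is(r, "SimResult")) nPrawns(r@orientation) else nPrawns(r), 1L))
  if (length(n) != 1) stop("trials must share one group size")
  pol <- vapply(cw, function(x) polarisation(x, n), numeric(length(cw[[1]])))
  rowMeans(matrix(pol, ncol = length(cw))) - expectedRandomPolarisation(n)
}

#' Distribution of final clockwise counts over trials
#'
#' Per trial, the clockwise count is averaged over the closing `window`
#' seconds and rounded half-up to an integer category; the distribution of
#' these categories over trials is returned.
#'
#' @param recs list of [OrientationRecord-class] or [SimResult-class]
#' @param window closing window in seconds (default 10)
#' @return an [OutcomeDistribution-class]
#' @export
finalOutcomeDistribution <- function(recs, window = 10) {
  if (!is.list(recs)) recs <- list(recs)
  getDt <- function(r) if (is(r, "SimResult")) r@orientation@dt else r@dt
  getN <- function(r)
    if (is(r, "SimResult")) nPrawns(r@orientation) else nPrawns(r)
  n <- unique(vapply(recs, getN, 1L))
  if (length(n) != 1) stop("trials must share one group size")
  cats <- vapply(recs, function(r) {
    cw <- cwCountSeries(r)
    nw <- round(window / getDt(r))
    if (length(cw) < nw)
      stop("trial '", trialId(if (is(r, "SimResult")) r@orientation else r),
           "' is shorter than the ", window, " s window")
    floor(mean(cw[(length(cw) - nw + 1):length(cw)]) + 0.5)  # round half up
  }, 1)
  outcomeDistribution(n, tabulate(cats + 1L, nbins = n + 1) / length(cats),
                      length(cats))
}

#' Kullback-Leibler divergence between outcome distributions
#'
#' `sum_c p_c log(p_c / q_c)` in nats, with `0 log 0 = 0`. Categories where
#' the simulated distribution `q` has zero mass but `p` does not receive
#' pseudo-mass `1 / (2 * nTrials(q))` before renormalisation, keeping the
#' divergence (and the G statistic) finite for finite simulation ensembles.
#'
#' @param p the reference (experimental) [OutcomeDistribution-class]
#' @param q the approximating (simulated) [OutcomeDistribution-class]
#' @return KL divergence in nats
#' @export
klDivergence <- function(p, q) {
  if (p@n != q@n) stop("distributions must share the group size")
  pp <- p@proportions
  qq <- q@proportions
  zero <- qq == 0 & pp > 0
  if (any(zero)) {
    qq[zero] <- 1 / (2 * q@nTrials)
    qq <- qq / sum(qq)
  }
  pos <- pp > 0
  sum(pp[pos] * log(pp[pos] / qq[pos]))
}

#' G-test of fit between experimental and simulated outcomes
#'
#' `G = 2 m KL` (natural logs) with `m` the number of experimental trials,
#' referred to a chi-squared distribution with `n` degrees of freedom
#' (categories `0..n` minus one).
#'
#' @param p experimental [OutcomeDistribution-class] (its `nTrials` is `m`)
#' @param q simulated [OutcomeDistribution-class]
#' @return a [FitTestResult-class]
#' @export
gTest <- function(p, q) {
  kl <- klDivergence(p, q)
  G <- 2 * p@nTrials * kl
  df <- p@n
  new("FitTestResult", kl = kl, G = G, df = df,
      p = pchisq(G, df, lower.tail = FALSE))
}

#' Direction-change frequency versus distance to the nearest opponent
#'
#' For every decision step and focal individual that has at least one
#' opposite-facing individual in the trial, records the signed angular
#' separation to the nearest one (positive = ahead along the focal heading)
#' and whether the focal changed direction at that step, then bins the
#' separations and reports the per-bin empirical turn frequency. A spatially
#' local interaction shows up as a central peak; a non-spatial one gives a
#' flat curve at the baseline rate.
#'
#' @param records list of [OrientationRecord-class]
#' @param trajs matching list of [TrialTrajectory-class]
#' @param binWidth bin width in radians (default 0.05)
#' @return data.frame with columns `mid`, `count`, `turns`, `frequency`
#' @export
turnFrequencyVsNearestOpponent <- function(records, trajs, binWidth = 0.05) {
  if (is(records, "OrientationRecord")) records <- list(records)
  if (is(trajs, "TrialTrajectory")) trajs <- list(trajs)
  d <- numeric(0)
  e <- integer(0)
  for (k in seq_along(records)) {
    th <- .alignPair(records[[k]], trajs[[k]])
    sep <- .nearest_opp_cpp(th, stateMatrix(records[[k]]))
    ev <- eventMatrix(records[[k]])
    keep <- !is.na(sep)
    d <- c(d, sep[keep])
    e <- c(e, ev[keep])
  }
  if (!length(d)) {
    warning("no opposite-facing pairs anywhere; empty curve")
    return(data.frame(mid = numeric(0), count = integer(0),
                      turns = integer(0), frequency = numeric(0)))
  }
  half <- ceiling(pi / binWidth)
  breaks <- seq(-half * binWidth, half * binWidth, by = binWidth)
  bin <- cut(d, breaks = breaks, include.lowest = TRUE)
  count <- as.integer(tapply(e, bin, length, default = 0L))
  turns <- as.integer(tapply(e, bin, sum, default = 0L))
  data.frame(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
             count = count, turns = turns,
             frequency = ifelse(count > 0, turns / count, NA_real_))
}

#' Validate a fitted model against an outcome distribution
#'
#' Simulates `nSets` independent sets of `setSize` trials at the matched
#' group size and duration under the fitted model, builds each set's
#' simulated outcome distribution, and G-tests the experimental distribution
#' against it. The model is flagged consistent when the median p-value
#' exceeds 0.05.
#'
#' @param outcome experimental [OutcomeDistribution-class]
#' @param model a [ModelSpec-class] or id
#' @param params fitted (MAP) [ParamSet-class]
#' @param duration trial length in seconds (default 360)
#' @param dt time step (default 1/7.5)
#' @param nSets,setSize simulation protocol (default 10 sets of 100)
#' @param seed master seed
#' @param speedMean,speedSd,memoryDialect simulator settings
#' @param window closing window for the simulated outcomes, in seconds
#' @return `list(tests = list of FitTestResult, p = per-set p-values,
#'   medianP = , consistent = )`
#' @export
validateModel <- function(outcome, model, params, duration = 360,
                          dt = 1 / 7.5, nSets = 10, setSize = 100, seed = 1,
                          speedMean = 0.8, speedSd = 0.4,
                          memoryDialect = "trace", window = 10) {
  st <- simSettings(outcome@n, model, params, dt = dt, duration = duration,
                    speedMean = speedMean, speedSd = speedSd,
                    memoryDialect = memoryDialect)
  tests <- lapply(seq_len(nSets), function(s) {
    sims <- runEnsemble(st, setSize, seed = seed, offset = (s - 1) * setSize)
    gTest(outcome, finalOutcomeDistribution(sims, window = window))
  })
  p <- vapply(tests, function(t) t@p, 1)
  list(tests = tests, p = p, medianP = median(p),
       consistent = median(p) > 0.05)
}
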