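## Event likelihood of the eleven models and the pinned-baseline estimate.

.zoneCode <- c(none = 0L, global = 1L, nearest = 2L, symmetric = 3L,
               forward = 4L)

## Trim a trajectory's theta to the frames covered by a (possibly one frame
## shorter, HMM-decoded) orientation record, and check alignment.
.alignPair <- function(rec, traj) {
  th <- thetaMatrix(traj)
  Tr <- nFrames(rec)
  if (nrow(th) == Tr + 1L) th <- th[seq_len(Tr), , drop = FALSE]
  if (nrow(th) != Tr)
    stop("record and trajectory '", trialId(rec), "' have incompatible lengths")
  if (ncol(th) != nPrawns(rec))
    stop("record and trajectory '", trialId(rec), "' have different group sizes")
  th
}

#' Log-likelihood of direction-change events under a model
#'
#' The probability of the binary event "individual i changes direction
#' between frames t and t+1" is the logistic of the model's turning
#' intensity, computed from the frame-t snapshot of every individual's
#' position and orientation. The log-likelihood is the sum of the Bernoulli
#' log-probabilities over all trials, individuals and steps. For memory
#' models the per-focal memory state starts empty at the first frame of each
#' trial, is propagated forward, and is cleared after the focal's own turns.
#'
#' Probabilities are clamped at `1e-12` away from 0 and 1 before taking
#' logs; the number of observations that actually hit the clamp (an event
#' with essentially zero predicted probability, or vice versa) is reported
#' and a warning is raised when it is non-zero.
#'
#' @param records list of [OrientationRecord-class] (or a single one)
#' @param trajs matching list of [TrialTrajectory-class]
#' @param model a [ModelSpec-class] or id
#' @param params a [ParamSet-class]
#' @param dialect memory aggregation dialect, "trace" or "aggregate"
#' @return the log-likelihood (numeric scalar) with attribute `"clamped"`
#' @export
logLikelihood <- function(records, trajs, model, params, dialect = "trace") {
  if (is(records, "OrientationRecord")) records <- list(records)
  if (is(trajs, "TrialTrajectory")) trajs <- list(trajs)
  if (length(records) != length(trajs))
    stop("records and trajs must have the same length")
  if (is.character(model)) model <- modelSpec(model)
  ll <- 0
  clamped <- 0L
  for (k in seq_along(records)) {
    th <- .alignPair(records[[k]], trajs[[k]])
    r <- .loglik_cpp(th, stateMatrix(records[[k]]), eventMatrix(records[[k]]),
                     .zoneCode[[model@zone]], model@usesPositive, model@memory,
                     params@lambda0,
                     if (is.na(params@wNeg)) 0 else params@wNeg,
                     if (is.na(params@wPos)) 0 else params@wPos,
                     if (is.na(params@R)) 0 else params@R,
                     if (is.na(params@K)) 0L else as.integer(params@K),
                     if (is.na(params@alpha)) 0 else params@alpha,
                     if (dialect == "trace") 0L else 1L)
    ll <- ll + r$loglik
    clamped <- clamped + r$clamped
  }
  if (clamped > 0)
    warning(clamped, " observation(s) hit the 1e-12 probability clamp")
  structure(ll, clamped = clamped)
}

#' Baseline turning intensity from single-individual records
#'
#' The overall direction-change rate `r` (total events over total decision
#' steps) of the single-individual recordings, mapped to log-odds:
#' `lambda0 = log(r / (1 - r))`.
#'
#' @param records list of single-individual [OrientationRecord-class]
#' @return the baseline intensity lambda0
#' @export
estimateBaseline <- function(records) {
  if (is(records, "OrientationRecord")) records <- list(records)
  if (!length(records)) stop("need at least one record")
  ev <- sum(vapply(records, function(r) sum(eventMatrix(r)), 1))
  steps <- sum(vapply(records, function(r) length(eventMatrix(r)), 1))
  if (steps < 1) stop("records contain no decision steps")
  r <- ev / steps
  if (r == 0)
    stop("no direction changes observed; longer single-individual ",
         "recordings are needed to estimate the baseline rate")
  if (r == 1) stop("every step is a direction change; baseline logit infinite")
  stats::qlogis(r)
}

#' Log prior density of a parameter set
#'
#' Sum of the log densities of the model's free parameters under the
#' [PriorSpec-class]. The pinned `lambda0` contributes 0 when it equals the
#' prior's value and `-Inf` otherwise; any free parameter outside its
#' support gives `-Inf`.
#'
#' @param params a [ParamSet-class]
#' @param prior a [PriorSpec-class]
#' @param model a [ModelSpec-class] or id
#' @return log prior density
#' @export
logPrior <- function(params, prior, model) {
  if (is.character(model)) model <- modelSpec(model)
  free <- setdiff(modelParams(model), "lambda0")
  if (!isTRUE(all.equal(params@lambda0, prior@lambda0))) return(-Inf)
  lp <- 0
  for (nm in free) {
    v <- slot(params, nm)
    lp <- lp + switch(nm,
      wNeg = if (v >= 0 && v <= prior@wMax) -log(prior@wMax) else -Inf,
      wPos = if (abs(v) <= prior@wMax) -log(2 * prior@wMax) else -Inf,
      R = if (v > 0 && v <= prior@rMax) -log(prior@rMax) else -Inf,
      K = if (v >= 1 && v <= prior@nAgents - 1 && v == round(v))
        -log(prior@nAgents - 1) else -Inf,
      alpha = if (v >= 0 && v < 1) 0 else -Inf)
  }
  lp
}

## ---- fast likelihood evaluation via sufficient statistics ----------------
##
## For the models whose zone has no continuous parameter (Null, MF,
## topological with each K), the likelihood depends on the data only through
## the cross-tabulation of (number of negative neighbours, event). These
## tables make each likelihood evaluation O(N), which is what lets annealed
## importance sampling run thousands of chains.

## counts[event + 1, nneg + 1] summed over trials
.countTable <- function(records, trajs, zone, K = 0L) {
  tab <- NULL
  for (k in seq_along(records)) {
    th <- .alignPair(records[[k]], trajs[[k]])
    st <- stateMatrix(records[[k]])
    N <- ncol(st)
    if (zone == "global") {
      Tn <- nrow(st)
      nACW <- rowSums(st == 1L)[-Tn]
      nn <- ifelse(st[-Tn, , drop = FALSE] == 1L, N - nACW, nACW)
    } else {
      nn <- .negcounts_cpp(th, st, .zoneCode[[zone]], 0, as.integer(K))$nNeg
    }
    ev <- eventMatrix(records[[k]])
    t0 <- matrix(0, 2, N)
    for (e in 0:1)
      t0[e + 1, ] <- tabulate(nn[ev == e] + 1L, nbins = N)
    if (is.null(tab)) tab <- t0 else {
      if (ncol(t0) != ncol(tab)) stop("records mix group sizes")
      tab <- tab + t0
    }
  }
  tab
}

## log-likelihood from a count table, matching the clamping of the C++ path
.loglikFromTable <- function(tab, lambda0, wNeg) {
  n <- 0:(ncol(tab) - 1)
  lam <- lambda0 + wNeg * n
  logp <- pmax(stats::plogis(lam, log.p = TRUE), log(1e-12))
  log1mp <- pmax(stats::plogis(-lam, log.p = TRUE), log(1e-12))
  sum(tab[2, ] * logp + tab[1, ] * log1mp)
}
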