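## Orientation classification: symmetric two-state Gaussian HMM on signed
## per-frame angular displacements, plus despiking of double switches.

.hmmCheck <- function(params) {
  stopifnot(is(params, "HmmParams"))
  validObject(params)
}

#' Fit the symmetric two-state HMM by Baum-Welch
#'
#' Expectation-maximisation for the two-state orientation HMM. The model is
#' symmetric by construction and the symmetry is enforced at every M-step by
#' parameter tying: both states share the switch probability and the
#' emission distributions are mirrored Gaussians `(+mu, sigma)` (ACW) and
#' `(-mu, sigma)` (CW). The initial state distribution is uniform. Iteration
#' stops when the relative log-likelihood improvement falls below `tol` or
#' after `maxIter` iterations.
#'
#' @param obs list of numeric displacement sequences (radians/frame), each of
#'   length >= 2
#' @param init an [HmmParams-class] starting point; by default a moment-based
#'   guess from the pooled displacements
#' @param maxIter maximum EM iterations (default 500)
#' @param tol relative log-likelihood tolerance (default 1e-8)
#' @return `list(params = HmmParams, trace = HmmFitTrace)`
#' @export
baumWelch <- function(obs, init = NULL, maxIter = 500, tol = 1e-8) {
  if (!is.list(obs)) obs <- list(obs)
  if (!length(obs) || any(vapply(obs, length, 1L) < 2))
    stop("need at least one displacement sequence of length >= 2")
  if (is.null(init)) {
    pooled <- unlist(obs)
    init <- hmmParams(pSwitch = 0.05,
                      mu = max(mean(abs(pooled)), 1e-3),
                      sigma = max(sd(pooled), 1e-3))
  }
  .hmmCheck(init)
  p <- init@pSwitch; mu <- init@mu; sigma <- init@sigma
  nTot <- sum(vapply(obs, length, 1L))
  llTrace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    ll <- 0
    xi <- matrix(0, 2, 2)
    sGx <- 0      # sum over t of (gamma_ACW - gamma_CW) * x
    sSq <- 0      # accumulated for the tied variance given the new mu
    gammas <- vector("list", length(obs))
    for (s in seq_along(obs)) {
      fb <- .fb_cpp(obs[[s]], p, mu, sigma)
      ll <- ll + fb$loglik
      xi <- xi + fb$xi
      gammas[[s]] <- fb$gamma
      sGx <- sGx + sum((fb$gamma[, 1] - fb$gamma[, 2]) * obs[[s]])
    }
    llTrace <- c(llTrace, ll)
    if (it > 1) {
      rel <- (ll - llTrace[it - 1]) / max(abs(llTrace[it - 1]), 1)
      if (abs(rel) < tol) { converged <- TRUE; break }
    }
    ## tied M-step
    p <- min(max((xi[1, 2] + xi[2, 1]) / sum(xi), 1e-10), 1 - 1e-10)
    mu <- sGx / nTot
    for (s in seq_along(obs)) {
      g <- gammas[[s]]
      x <- obs[[s]]
      sSq <- sSq + sum(g[, 1] * (x - mu)^2 + g[, 2] * (x + mu)^2)
    }
    sigma <- sqrt(sSq / nTot)
    if (sigma < 1e-6)
      stop("emission standard deviation collapsed below 1e-6 rad; ",
           "the data are degenerate - provide more or noisier sequences")
  }
  if (mu < 0) mu <- -mu  # fix the label convention: ACW state has mean > 0
  list(params = hmmParams(pSwitch = p, mu = mu, sigma = sigma),
       trace = new("HmmFitTrace", logLik = llTrace, converged = converged,
                   iterations = length(llTrace)))
}

#' Viterbi decoding of an orientation sequence
#'
#' Most probable joint state path for one displacement sequence under the
#' symmetric HMM, with ties broken toward the previous step's state
#' (persistence).
#'
#' @param obs numeric displacement sequence (radians/frame)
#' @param params an [HmmParams-class]
#' @return integer vector of orientations, +1 = ACW, -1 = CW
#' @export
viterbiDecode <- function(obs, params) {
  .hmmCheck(params)
  .viterbi_cpp(as.numeric(obs), params@pSwitch, params@mu, params@sigma)
}

#' Remove artifactual double direction changes
#'
#' Scans forward in time and, whenever two consecutive direction changes
#' fall closer together than `window` seconds, removes both by reverting the
#' short-lived intervening segment to the preceding state. The pass is
#' repeated until no such pair remains, so the output has no two consecutive
#' changes closer than `window`. Idempotent.
#'
#' @param states integer vector of orientations (+1/-1)
#' @param dt frame spacing in seconds
#' @param window minimum allowed spacing between changes, in seconds
#'   (default 1)
#' @return the cleaned state vector
#' @export
despike <- function(states, dt, window = 1.0) {
  if (dt <= 0) stop("dt must be positive")
  s <- as.integer(states)
  repeat {
    ch <- which(diff(s) != 0L)   # change k sits between frames ch[k], ch[k]+1
    removed <- FALSE
    j <- 1L
    while (j < length(ch)) {
      if ((ch[j + 1L] - ch[j]) * dt < window) {
        s[(ch[j] + 1L):ch[j + 1L]] <- s[ch[j]]
        removed <- TRUE
        j <- j + 2L
      } else {
        j <- j + 1L
      }
    }
    if (!removed) break
  }
  s
}

#' Classify trajectories into orientation records
#'
#' The full preprocessing stage: fits the symmetric HMM on the pooled
#' displacement sequences of the *single-individual* training trajectories,
#' then Viterbi-decodes every individual of every trial, despikes the decoded
#' states, and assembles [OrientationRecord-class] objects with events
#' derived from the cleaned states.
#'
#' A decoded record has one frame fewer than its trajectory: each state
#' belongs to a between-frame displacement, attributed to the frame at the
#' start of the interval.
#'
#' @param trajs list of [TrialTrajectory-class] to decode
#' @param training list of single-individual [TrialTrajectory-class] used to
#'   fit the HMM
#' @param init,maxIter,tol passed to [baumWelch()]
#' @param window despiking window in seconds (default 1)
#' @return `list(params = HmmParams, records = list of OrientationRecord,
#'   trace = HmmFitTrace)`
#' @export
classifyOrientations <- function(trajs, training, init = NULL, maxIter = 500,
                                 tol = 1e-8, window = 1.0) {
  if (!length(training)) stop("training set must be non-empty")
  if (any(vapply(training, nPrawns, 1L) != 1L))
    stop("training trajectories must contain a single individual")
  fit <- baumWelch(lapply(training, function(tr) as.numeric(displacements(tr))),
                   init = init, maxIter = maxIter, tol = tol)
  records <- lapply(trajs, function(tr) {
    d <- displacements(tr)
    dt <- 1 / frameRate(tr)
    st <- apply(d, 2L, function(col)
      despike(viterbiDecode(col, fit$params), dt, window))
    orientationRecord(matrix(st, ncol = ncol(d)), dt = dt,
                      trialId = trialId(tr))
  })
  list(params = fit$params, records = records, trace = fit$trace)
}
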