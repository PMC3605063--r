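## Forward simulation of the ring models.

#' Simulate one trial of a turning-intensity model on the ring
#'
#' Agents start at i.i.d. uniform positions with i.i.d. fair-coin
#' orientations. Per step, each agent (taken in a fresh uniformly random
#' order) moves by a Gaussian signed step of mean `speedMean * dt` and s.d.
#' `speedSd * sqrt(dt)` along its orientation - negative draws are allowed,
#' giving the occasional backward drift seen in real tracking data. After
#' all agents have moved, every agent's turn decision is drawn with the
#' logistic of the model's intensity evaluated on the post-move positions
#' with all orientations frozen at their pre-decision values; memory models
#' propagate their per-neighbour traces across steps and clear them after
#' the agent's own turn. A fixed seed gives bit-identical output.
#'
#' @param settings a [SimSettings-class]
#' @param seed optional integer seed
#' @return a [SimResult-class] (noise-free trajectory, true orientations,
#'   per-frame clockwise count)
#' @examples
#' s <- simSettings(6, "MF", paramSet("MF", lambda0 = -7.5, wNeg = 0.76),
#'                  duration = 60)
#' simulateTrial(s, seed = 1)
#' @export
simulateTrial <- function(settings, seed = NULL) {
  validObject(settings)
  if (!is.null(seed)) set.seed(seed)
  m <- settings@model
  p <- settings@params
  Tn <- max(2L, as.integer(round(settings@duration / settings@dt)))
  sim <- .simulate_cpp(as.integer(settings@nAgents), Tn, settings@dt,
                       settings@speedMean, settings@speedSd,
                       .zoneCode[[m@zone]], m@usesPositive, m@memory,
                       p@lambda0,
                       if (is.na(p@wNeg)) 0 else p@wNeg,
                       if (is.na(p@wPos)) 0 else p@wPos,
                       if (is.na(p@R)) 0 else p@R,
                       if (is.na(p@K)) 0L else as.integer(p@K),
                       if (is.na(p@alpha)) 0 else p@alpha,
                       if (settings@memoryDialect == "trace") 0L else 1L)
  traj <- trialTrajectory(sim$theta, frameRate = 1 / settings@dt)
  rec <- orientationRecord(sim$state, dt = settings@dt)
  new("SimResult", trajectory = traj, orientation = rec,
      cwCount = as.integer(rowSums(sim$state == -1L)))
}

#' Simulate an ensemble of independent trials
#'
#' Trial seeds are derived deterministically from the master seed by a
#' counter, so an ensemble can be split across calls: trials `offset + 1 ..
#' offset + nTrials` of the master-seeded sequence are produced, and
#' `runEnsemble(s, 100, seed)` followed by `runEnsemble(s, 100, seed,
#' offset = 100)` reproduces `runEnsemble(s, 200, seed)` exactly.
#'
#' @param settings a [SimSettings-class]
#' @param nTrials number of trials
#' @param seed master seed
#' @param offset trial counter offset (default 0)
#' @return list of [SimResult-class]
#' @export
runEnsemble <- function(settings, nTrials, seed = 1, offset = 0) {
  if (nTrials < 1) stop("nTrials must be >= 1")
  lapply(seq_len(nTrials) + offset, function(i)
    simulateTrial(settings, seed = .deriveSeed(seed, i)))
}
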