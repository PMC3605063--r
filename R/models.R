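#' Zone membership of a neighbour
#'
#' Spatial zones on the ring. A *symmetric* zone of extent `R` covers total
#' angular width `R` centred on the focal individual (half-width `R/2` on
#' each side, boundary inclusive; a neighbour at the exact focal position
#' counts). A *forward* zone covers the interval `(0, R]` ahead of the focal
#' individual along its heading (a neighbour at the exact focal position does
#' not count). Global and nearest-K "zones" are handled by
#' [neighbourCounts()], not here.
#'
#' @param focalTheta focal angular position (radians)
#' @param focalOrient focal orientation, +1 = ACW, -1 = CW
#' @param otherTheta neighbour position(s)
#' @param zone "symmetric" or "forward"
#' @param R zone extent in radians
#' @return logical vector, TRUE where the neighbour is in the zone
#' @export
inZone <- function(focalTheta, focalOrient, otherTheta, zone, R) {
  if (!zone %in% c("symmetric", "forward"))
    stop("inZone applies to 'symmetric' or 'forward' zones only")
  if (zone == "symmetric") {
    angularSeparation(otherTheta, focalTheta) <= R / 2
  } else {
    ahead <- wrapSigned(otherTheta - focalTheta) * focalOrient
    ahead > 0 & ahead <= R
  }
}

#' Count negative and positive neighbours of a focal individual
#'
#' Given the positions and orientations of all individuals at one frame,
#' counts the neighbours of the focal individual that are inside its
#' interaction zone, split into opposite-direction ("negative") and
#' same-direction ("positive") individuals. The focal individual is never
#' its own neighbour. For the nearest-K zone the K smallest angular
#' separations are selected, ties broken by ascending individual index.
#'
#' @param thetas positions of all N individuals (radians)
#' @param orients orientations of all individuals (+1/-1)
#' @param focal index (1-based) of the focal individual
#' @param zone "global", "nearest", "symmetric" or "forward"
#' @param R zone extent in radians (symmetric/forward)
#' @param K neighbour count (nearest); must satisfy K <= N - 1
#' @return named integer vector `c(nNeg, nPos)`
#' @export
neighbourCounts <- function(thetas, orients, focal, zone, R = NA, K = NA) {
  N <- length(thetas)
  others <- setdiff(seq_len(N), focal)
  if (zone == "none") return(c(nNeg = 0L, nPos = 0L))
  sel <- switch(zone,
    global = others,
    nearest = {
      if (is.na(K) || K >= N) stop("nearest-K zone requires K < N")
      sep <- angularSeparation(thetas[others], thetas[focal])
      others[order(sep, others)[seq_len(K)]]
    },
    symmetric = ,
    forward = others[inZone(thetas[focal], orients[focal], thetas[others],
                            zone, R)],
    stop("unknown zone kind '", zone, "'"))
  opp <- orients[sel] != orients[focal]
  c(nNeg = sum(opp), nPos = sum(!opp))
}

#' Markovian turning intensity
#'
#' The latent turning intensity (log-odds of a direction change this step)
#' for the memoryless models: `lambda0` for the null model;
#' `lambda0 + wNeg * nNeg` for the mean-field, topological and negative-only
#' spatial models; plus `wPos * nPos` where same-direction neighbours enter.
#'
#' @param model a [ModelSpec-class] (or id) with `memory = FALSE`
#' @param params a [ParamSet-class]
#' @param counts `c(nNeg, nPos)` as from [neighbourCounts()]
#' @return the turning intensity lambda
#' @examples
#' intensityMarkov("MF", paramSet("MF", lambda0 = -7.5, wNeg = 0.76), c(5, 0))
#' @export
intensityMarkov <- function(model, params, counts) {
  if (is.character(model)) model <- modelSpec(model)
  if (model@memory) stop("intensityMarkov applies to memoryless models")
  lam <- params@lambda0
  if (model@zone != "none") lam <- lam + params@wNeg * counts[[1]]
  if (model@usesPositive) lam <- lam + params@wPos * counts[[2]]
  unname(lam)
}

#' Create an empty memory state for a focal individual
#'
#' @param n total number of individuals in the trial
#' @param lambda0 baseline intensity (starting point of the aggregate dialect)
#' @return a memory-state list with per-neighbour traces all zero
#' @export
emptyMemory <- function(n, lambda0)
  list(traces = numeric(n), lambdaPrev = lambda0)

#' One step of the non-Markovian turning intensity
#'
#' Advances the memory state of one focal individual by one frame and returns
#' the resulting intensity. Two dialects are provided:
#'
#' * `"trace"` (default): each neighbour carries a trace. While the
#'   neighbour is in the zone its trace equals its full current weight
#'   (`wNeg` or `wPos` by relative orientation, re-evaluated every frame);
#'   after it leaves, the trace decays geometrically by `alpha` per step.
#'   The intensity is `lambda0 + sum(traces)`.
#' * `"aggregate"`: a single autoregressive intensity,
#'   `lambda = lambda0 + alpha * (lambdaPrev - lambda0) + wNeg*nNeg + wPos*nPos`
#'   with the counts taken over the current zone occupancy.
#'
#' In both dialects a direction change by the focal individual erases the
#' accumulated memory: the carried traces (or carried intensity) are cleared
#' at the next step, so the intensity returns to `lambda0` plus whatever
#' neighbours are currently in the zone. With `alpha = 0` both dialects
#' reduce exactly to the Markovian spatial model.
#'
#' @param model a [ModelSpec-class] (or id) with `memory = TRUE`
#' @param params a [ParamSet-class] including `alpha`
#' @param mem memory state from [emptyMemory()] or a previous call
#' @param negIn,posIn integer indices of the opposite-/same-direction
#'   neighbours currently in the zone
#' @param turned did the focal individual change direction last step?
#' @param dialect "trace" or "aggregate"
#' @return `list(lambda = , mem = )` with the updated memory state
#' @export
intensityMemoryStep <- function(model, params, mem, negIn, posIn,
                                turned = FALSE, dialect = "trace") {
  if (is.character(model)) model <- modelSpec(model)
  if (!model@memory) stop("intensityMemoryStep applies to memory models")
  a <- params@alpha
  if (is.na(a) || a < 0 || a >= 1) stop("alpha must be in [0, 1)")
  wp <- if (model@usesPositive) params@wPos else 0
  if (dialect == "trace") {
    tr <- mem$traces
    if (turned) tr[] <- 0
    inz <- logical(length(tr))
    inz[negIn] <- TRUE
    inz[posIn] <- TRUE
    tr[!inz] <- a * tr[!inz]
    tr[negIn] <- params@wNeg
    tr[posIn] <- wp
    lam <- params@lambda0 + sum(tr)
    list(lambda = unname(lam), mem = list(traces = tr, lambdaPrev = lam))
  } else if (dialect == "aggregate") {
    carry <- if (turned) 0 else a * (mem$lambdaPrev - params@lambda0)
    lam <- params@lambda0 + carry + params@wNeg * length(negIn) +
      wp * length(posIn)
    list(lambda = unname(lam), mem = list(traces = mem$traces, lambdaPrev = lam))
  } else {
    stop("dialect must be 'trace' or 'aggregate'")
  }
}

#' Logistic link from intensity to probability
#'
#' @param lambda turning intensity (log-odds)
#' @return `1 / (1 + exp(-lambda))`
#' @examples
#' turnProbability(0)      # 0.5
#' turnProbability(-7.5)   # 5.5277e-4
#' @export
turnProbability <- function(lambda) stats::plogis(lambda)

## Reference MAP parameter sets for each model, as published for the glass
## prawn system; used as generator defaults by the preset configuration.
.PRESET_PARAMS <- list(
  Null = list(lambda0 = -7.5),
  MF  = list(lambda0 = -7.5, wNeg = 0.76),
  T   = list(lambda0 = -7.5, wNeg = 0.77, K = 5),
  S1  = list(lambda0 = -7.5, wNeg = 1.35, R = 0.20),
  S2  = list(lambda0 = -7.5, wNeg = 1.37, R = 0.16),
  S3  = list(lambda0 = -7.5, wNeg = 1.72, wPos = 0.23, R = 0.20),
  S4  = list(lambda0 = -7.5, wNeg = 1.69, wPos = 0.52, R = 0.19),
  D1  = list(lambda0 = -7.5, wNeg = 1.08, R = 0.18, alpha = 0.87),
  D2  = list(lambda0 = -7.5, wNeg = 0.75, R = 0.19, alpha = 0.94),
  D3  = list(lambda0 = -7.5, wNeg = 0.99, wPos = -3.59, R = 0.19, alpha = 0.92),
  D4  = list(lambda0 = -7.5, wNeg = 1.08, wPos = 0.32, R = 0.19, alpha = 0.92))

#' Reference parameter set for a model
#'
#' Published maximum a posteriori parameter values for the glass prawn system
#' under each of the eleven models (baseline intensity -7.5 throughout).
#' These drive the bundled preset generator and are convenient defaults for
#' simulation studies.
#'
#' @param id a model id
#' @return a [ParamSet-class]
#' @examples
#' presetParams("D3")
#' @export
presetParams <- function(id) {
  p <- .PRESET_PARAMS[[id]]
  if (is.null(p)) stop("unknown model id '", id, "'")
  do.call(paramSet, c(list(model = id), p))
}

#' Memory half-life implied by a decay factor
#'
#' The per-step geometric decay `alpha` halves a memory trace every
#' `dt * log(0.5) / log(alpha)` seconds.
#'
#' @param alpha decay factor in (0, 1)
#' @param dt time step in seconds
#' @return half-life in seconds
#' @examples
#' memoryHalfLife(0.92, 1 / 7.5)   # about 1.1 s
#' @export
memoryHalfLife <- function(alpha, dt = 1 / 7.5) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  dt * log(0.5) / log(alpha)
}
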