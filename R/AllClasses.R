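#' @useDynLib ringmotion, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats dnorm dbinom pchisq rnorm runif rbinom setNames median sd
#' @importFrom utils read.csv write.csv head
NULL

## Orientation coding used throughout: integer +1 = anti-clockwise (ACW,
## increasing angle), -1 = clockwise (CW, decreasing angle).

#' ArenaSpec: geometry of the annular arena
#'
#' Describes the annulus the animals move in. All models in this package are
#' purely angular: positions are angles on the annulus midline and the radial
#' coordinate is discarded, so the arena geometry only documents the physical
#' setting (and fixes the midline radius used when converting linear speeds).
#'
#' @slot outerDiameter outer diameter in mm (default 200)
#' @slot innerDiameter inner diameter in mm (default 70)
#' @export
setClass("ArenaSpec",
         representation(outerDiameter = "numeric", innerDiameter = "numeric"),
         prototype(outerDiameter = 200, innerDiameter = 70),
         validity = function(object) {
           if (length(object@outerDiameter) != 1L || length(object@innerDiameter) != 1L)
             return("diameters must be scalars")
           if (!(object@outerDiameter > object@innerDiameter &&
                 object@innerDiameter > 0))
             return("must have outerDiameter > innerDiameter > 0")
           TRUE
         })

#' Construct an ArenaSpec
#'
#' @param outerDiameter outer diameter in mm
#' @param innerDiameter inner diameter in mm
#' @return an [ArenaSpec-class] object
#' @examples
#' arenaSpec()                       # the standard 200/70 mm annulus
#' midlineRadius(arenaSpec())        # 67.5 mm
#' @export
arenaSpec <- function(outerDiameter = 200, innerDiameter = 70) {
  new("ArenaSpec", outerDiameter = outerDiameter, innerDiameter = innerDiameter)
}

#' TrialTrajectory: angular positions of one trial
#'
#' A T x N matrix of angular positions (radians, wrapped to `[0, 2pi)`) on the
#' annulus midline, one column per individual, sampled at a constant frame
#' rate. Times must be strictly increasing with uniform spacing and no cell
#' may be missing.
#'
#' @slot trialId trial identifier
#' @slot frameRate frames per second
#' @slot times vector of frame times in seconds, length T
#' @slot theta T x N numeric matrix of angles in `[0, 2pi)`
#' @export
setClass("TrialTrajectory",
         representation(trialId = "character", frameRate = "numeric",
                        times = "numeric", theta = "matrix"),
         validity = function(object) {
           T <- length(object@times)
           if (nrow(object@theta) != T)
             return("theta must have one row per time point")
           if (T >= 2) {
             dts <- diff(object@times)
             if (any(dts <= 0)) return("times must be strictly increasing")
             if (max(abs(dts - 1 / object@frameRate)) > 1e-6)
               return("times must be uniformly spaced at 1/frameRate")
           }
           if (anyNA(object@theta)) return("theta must not contain missing values")
           if (any(object@theta < 0 | object@theta >= 2 * pi))
             return("angles must lie in [0, 2*pi)")
           TRUE
         })

#' Construct a TrialTrajectory
#'
#' Angles are wrapped into `[0, 2pi)`; times default to `0, 1/frameRate, ...`.
#'
#' @param theta T x N matrix (or vector for N = 1) of angles in radians
#' @param frameRate frames per second
#' @param trialId trial identifier
#' @param times optional explicit frame times in seconds
#' @return a [TrialTrajectory-class]
#' @export
trialTrajectory <- function(theta, frameRate, trialId = "trial", times = NULL) {
  if (is.null(dim(theta))) theta <- matrix(theta, ncol = 1L)
  storage.mode(theta) <- "double"
  theta <- wrapAngle(theta)
  if (is.null(times)) times <- (seq_len(nrow(theta)) - 1) / frameRate
  new("TrialTrajectory", trialId = as.character(trialId),
      frameRate = frameRate, times = as.numeric(times), theta = theta)
}

#' OrientationRecord: decoded binary orientations of one trial
#'
#' Holds the frame-by-frame orientation state of each individual (+1 = ACW,
#' -1 = CW) together with the direction-change event indicator matrix, which
#' is by construction the finite difference of the state matrix: entry
#' `(t, i)` of `events` is 1 iff individual `i` changes orientation between
#' frames `t` and `t + 1`.
#'
#' @slot trialId trial identifier
#' @slot dt time step between frames in seconds
#' @slot state T x N integer matrix with values in `{-1, +1}`
#' @slot events (T-1) x N binary integer matrix of direction changes
#' @export
setClass("OrientationRecord",
         representation(trialId = "character", dt = "numeric",
                        state = "matrix", events = "matrix"),
         validity = function(object) {
           st <- object@state
           if (!all(st %in% c(-1L, 1L))) return("state values must be -1 (CW) or +1 (ACW)")
           ev <- object@events
           if (nrow(st) >= 2) {
             expected <- (st[-1, , drop = FALSE] != st[-nrow(st), , drop = FALSE]) * 1L
             if (!identical(dim(ev), dim(expected)) || any(ev != expected))
               return("events must be the finite difference of state")
           } else if (nrow(ev) != 0L) {
             return("events must have T-1 rows")
           }
           if (object@dt <= 0) return("dt must be positive")
           TRUE
         })

#' Construct an OrientationRecord
#'
#' The event matrix is derived from the states; it cannot be supplied
#' independently.
#'
#' @param state T x N matrix of orientations, either integer `{-1, +1}` or
#'   character `{"CW", "ACW"}`
#' @param dt frame spacing in seconds
#' @param trialId trial identifier
#' @return an [OrientationRecord-class]
#' @export
orientationRecord <- function(state, dt, trialId = "trial") {
  if (is.null(dim(state))) state <- matrix(state, ncol = 1L)
  if (is.character(state)) {
    if (!all(state %in% c("CW", "ACW"))) stop("state labels must be 'CW' or 'ACW'")
    state <- matrix(ifelse(state == "ACW", 1L, -1L), nrow = nrow(state))
  }
  storage.mode(state) <- "integer"
  Tn <- nrow(state)
  ev <- if (Tn >= 2) {
    (state[-1, , drop = FALSE] != state[-Tn, , drop = FALSE]) * 1L
  } else {
    matrix(integer(0), nrow = 0, ncol = ncol(state))
  }
  new("OrientationRecord", trialId = as.character(trialId), dt = dt,
      state = state, events = ev)
}

#' ModelSpec: one of the eleven turning-intensity model structures
#'
#' The model id fixes the interaction zone, whether same-direction
#' ("positive") neighbours enter the intensity, and whether the model carries
#' a decaying memory of past encounters:
#'
#' \tabular{lllll}{
#'   id   \tab zone        \tab positive \tab memory \cr
#'   Null \tab none        \tab no  \tab no \cr
#'   MF   \tab global      \tab no  \tab no \cr
#'   T    \tab K nearest   \tab no  \tab no \cr
#'   S1   \tab symmetric   \tab no  \tab no \cr
#'   S2   \tab forward     \tab no  \tab no \cr
#'   S3   \tab symmetric   \tab yes \tab no \cr
#'   S4   \tab forward     \tab yes \tab no \cr
#'   D1   \tab symmetric   \tab no  \tab yes \cr
#'   D2   \tab forward     \tab no  \tab yes \cr
#'   D3   \tab symmetric   \tab yes \tab yes \cr
#'   D4   \tab forward     \tab yes \tab yes \cr
#' }
#'
#' @slot id model identifier
#' @slot zone one of "none", "global", "nearest", "symmetric", "forward"
#' @slot usesPositive does the model weight same-direction neighbours?
#' @slot memory non-Markovian memory of past encounters?
#' @export
setClass("ModelSpec",
         representation(id = "character", zone = "character",
                        usesPositive = "logical", memory = "logical"))

.MODEL_TABLE <- data.frame(
  id = c("Null", "MF", "T", "S1", "S2", "S3", "S4", "D1", "D2", "D3", "D4"),
  zone = c("none", "global", "nearest", "symmetric", "forward", "symmetric",
           "forward", "symmetric", "forward", "symmetric", "forward"),
  usesPositive = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                   FALSE, FALSE, TRUE, TRUE),
  memory = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
             TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE)

#' All available model identifiers
#' @return character vector of the eleven model ids
#' @export
modelIds <- function() .MODEL_TABLE$id

#' Construct a ModelSpec from its id
#'
#' @param id one of `modelIds()`
#' @return a [ModelSpec-class]
#' @examples
#' modelSpec("D3")
#' @export
modelSpec <- function(id) {
  row <- .MODEL_TABLE[.MODEL_TABLE$id == id, ]
  if (nrow(row) != 1L)
    stop("unknown model id '", id, "'; see modelIds()")
  new("ModelSpec", id = row$id, zone = row$zone,
      usesPositive = row$usesPositive, memory = row$memory)
}

#' ParamSet: parameter vector for a turning-intensity model
#'
#' Unused parameters are `NA`. `lambda0` is the baseline turning intensity in
#' log-odds units; `wNeg`/`wPos` the per-neighbour increments for opposite-
#' and same-direction neighbours; `R` the zone extent in radians (total width
#' for symmetric zones, length ahead for forward zones); `K` the neighbour
#' count for the topological model; `alpha` the per-step geometric memory
#' decay in `[0, 1)`.
#'
#' @slot lambda0,wNeg,wPos,R,K,alpha numeric scalars (NA when unused)
#' @export
setClass("ParamSet",
         representation(lambda0 = "numeric", wNeg = "numeric", wPos = "numeric",
                        R = "numeric", K = "numeric", alpha = "numeric"),
         prototype(lambda0 = NA_real_, wNeg = NA_real_, wPos = NA_real_,
                   R = NA_real_, K = NA_real_, alpha = NA_real_))

#' Parameters used by a model
#' @param model a [ModelSpec-class] or model id
#' @return character vector of parameter names the model uses
#' @export
modelParams <- function(model) {
  if (is.character(model)) model <- modelSpec(model)
  p <- "lambda0"
  if (model@zone != "none") p <- c(p, "wNeg")
  if (model@zone == "nearest") p <- c(p, "K")
  if (model@zone %in% c("symmetric", "forward")) p <- c(p, "R")
  if (model@usesPositive) p <- c(p, "wPos")
  if (model@memory) p <- c(p, "alpha")
  p
}

#' Construct a ParamSet for a model
#'
#' Checks that exactly the parameters the model uses are supplied, that
#' `wNeg >= 0` and that `alpha` lies in `[0, 1)`. `wPos` is unconstrained in
#' sign.
#'
#' @param model a [ModelSpec-class] or model id
#' @param lambda0,wNeg,wPos,R,K,alpha parameter values
#' @return a [ParamSet-class]
#' @examples
#' paramSet("MF", lambda0 = -7.5, wNeg = 0.76)
#' @export
paramSet <- function(model, lambda0 = NA_real_, wNeg = NA_real_,
                     wPos = NA_real_, R = NA_real_, K = NA_real_,
                     alpha = NA_real_) {
  if (is.character(model)) model <- modelSpec(model)
  vals <- list(lambda0 = lambda0, wNeg = wNeg, wPos = wPos,
               R = R, K = K, alpha = alpha)
  need <- modelParams(model)
  for (nm in need)
    if (is.na(vals[[nm]]))
      stop("model ", model@id, " requires parameter '", nm, "'")
  for (nm in setdiff(names(vals), need))
    if (!is.na(vals[[nm]]))
      stop("model ", model@id, " does not use parameter '", nm, "'")
  if (!is.na(wNeg) && wNeg < 0) stop("wNeg must be non-negative")
  if (!is.na(alpha) && (alpha < 0 || alpha >= 1)) stop("alpha must be in [0, 1)")
  if (!is.na(R) && R <= 0) stop("R must be positive")
  if (!is.na(K) && (K < 1 || K != round(K))) stop("K must be a positive integer")
  do.call(new, c(list("ParamSet"), lapply(vals, as.numeric)))
}

#' HmmParams: symmetric two-state Gaussian HMM parameters
#'
#' The two hidden states are the ACW and CW orientations. Per-frame signed
#' angular displacements are emitted as Gaussian(+mu, sigma) in the ACW state
#' and, by the model's mirror symmetry, Gaussian(-mu, sigma) in the CW state.
#' A single transition probability `pSwitch` is shared by both directions.
#'
#' @slot pSwitch per-step probability of switching state, in (0, 1)
#' @slot mu mean signed displacement in the ACW state (rad/frame, > 0)
#' @slot sigma displacement standard deviation (rad/frame, > 0)
#' @export
setClass("HmmParams",
         representation(pSwitch = "numeric", mu = "numeric", sigma = "numeric"),
         validity = function(object) {
           if (!(object@pSwitch > 0 && object@pSwitch < 1))
             return("pSwitch must be in (0, 1)")
           if (object@sigma <= 0) return("sigma must be positive")
           TRUE
         })

#' @rdname HmmParams-class
#' @param pSwitch,mu,sigma see slots
#' @return a [HmmParams-class]
#' @export
hmmParams <- function(pSwitch, mu, sigma)
  new("HmmParams", pSwitch = pSwitch, mu = mu, sigma = sigma)

#' HmmFitTrace: Baum-Welch convergence diagnostics
#' @slot logLik per-iteration log-likelihood (non-decreasing)
#' @slot converged did the fit meet the tolerance before max iterations?
#' @slot iterations iterations used
#' @export
setClass("HmmFitTrace",
         representation(logLik = "numeric", converged = "logical",
                        iterations = "integer"))

#' PriorSpec: prior distributions for model parameters
#'
#' `lambda0` carries a point-mass (Dirac) prior at the value estimated from
#' single-individual data; `wNeg` is uniform on `[0, wMax]`; `wPos` uniform on
#' `[-wMax, wMax]`; `R` uniform on `(0, rMax]`; `K` discrete uniform on
#' `{1, ..., N-1}`; `alpha` uniform on `[0, 1)`. The same prior is used for a
#' given parameter across all models so marginal likelihoods are comparable.
#'
#' @slot lambda0 pinned baseline intensity
#' @slot wMax upper bound of the interaction-weight priors (default 5)
#' @slot rMax upper bound of the zone-extent prior in radians (default 0.5)
#' @slot nAgents group size, fixing the support of the K prior
#' @export
setClass("PriorSpec",
         representation(lambda0 = "numeric", wMax = "numeric",
                        rMax = "numeric", nAgents = "numeric"),
         validity = function(object) {
           if (object@wMax <= 0 || object@rMax <= 0) return("bounds must be positive")
           if (object@nAgents < 1) return("nAgents must be >= 1")
           TRUE
         })

#' @rdname PriorSpec-class
#' @param lambda0,wMax,rMax,nAgents see slots
#' @return a [PriorSpec-class]
#' @export
priorSpec <- function(lambda0, nAgents, wMax = 5, rMax = 0.5)
  new("PriorSpec", lambda0 = lambda0, wMax = wMax, rMax = rMax,
      nAgents = as.numeric(nAgents))

#' AisSettings: annealed importance sampling controls
#'
#' `nSamples` independent annealing chains are run through `nTemperatures`
#' tempered targets prior x likelihood^beta along the schedule
#' `beta_k = (k/(K-1))^schedulePower` (denser near 0, where the integrand
#' changes fastest), with `sweeps` Metropolis sweeps per temperature and
#' Gaussian proposals scaled to `proposalFrac` of each prior range (reflected
#' at the bounds; the discrete K moves by +-1 steps).
#'
#' @slot nSamples number of annealing chains (default 1000)
#' @slot nTemperatures ladder length (default 100)
#' @slot sweeps Metropolis sweeps per temperature (default 1)
#' @slot proposalFrac proposal s.d. as a fraction of the prior range
#' @slot schedulePower exponent of the geometric-like ladder
#' @export
setClass("AisSettings",
         representation(nSamples = "numeric", nTemperatures = "numeric",
                        sweeps = "numeric", proposalFrac = "numeric",
                        schedulePower = "numeric"),
         prototype(nSamples = 1000, nTemperatures = 100, sweeps = 1,
                   proposalFrac = 0.05, schedulePower = 3),
         validity = function(object) {
           if (object@nSamples < 1 || object@nTemperatures < 2)
             return("need nSamples >= 1 and nTemperatures >= 2")
           TRUE
         })

#' @rdname AisSettings-class
#' @param nSamples,nTemperatures,sweeps,proposalFrac,schedulePower see slots
#' @return an [AisSettings-class]
#' @export
aisSettings <- function(nSamples = 1000, nTemperatures = 100, sweeps = 1,
                        proposalFrac = 0.05, schedulePower = 3)
  new("AisSettings", nSamples = nSamples, nTemperatures = nTemperatures,
      sweeps = sweeps, proposalFrac = proposalFrac,
      schedulePower = schedulePower)

#' InferenceResult: marginal likelihood and MAP estimate for one model
#'
#' @slot modelId model identifier
#' @slot logMarginal log marginal likelihood in nats
#' @slot logMarginalBits the same in bits (nats / log 2)
#' @slot se Monte-Carlo standard error of `logMarginal`
#' @slot logWeights per-chain log importance weights
#' @slot samples data.frame of final-temperature parameter samples per chain
#' @slot map MAP [ParamSet-class] (argmax of prior x likelihood over every
#'   visited sample)
#' @slot mapLogPosterior unnormalised log posterior at the MAP sample
#' @export
setClass("InferenceResult",
         representation(modelId = "character", logMarginal = "numeric",
                        logMarginalBits = "numeric", se = "numeric",
                        logWeights = "numeric", samples = "data.frame",
                        map = "ParamSet", mapLogPosterior = "numeric"))

#' OutcomeDistribution: distribution of final clockwise counts
#'
#' The large-scale outcome of a trial is the number of individuals travelling
#' clockwise at its end (averaged over a closing window). Over many trials
#' this gives a distribution on `{0, ..., n}` - the object compared between
#' experiment and simulation.
#'
#' @slot n group size
#' @slot proportions numeric vector of length n + 1 over counts 0..n
#' @slot nTrials number of trials behind the distribution
#' @export
setClass("OutcomeDistribution",
         representation(n = "numeric", proportions = "numeric",
                        nTrials = "numeric"),
         validity = function(object) {
           if (length(object@proportions) != object@n + 1)
             return("proportions must have length n + 1")
           if (any(object@proportions < 0)) return("proportions must be >= 0")
           if (abs(sum(object@proportions) - 1) > 1e-12)
             return("proportions must sum to 1")
           if (object@nTrials < 1) return("nTrials must be >= 1")
           TRUE
         })

#' @rdname OutcomeDistribution-class
#' @param n,proportions,nTrials see slots
#' @return an [OutcomeDistribution-class]
#' @export
outcomeDistribution <- function(n, proportions, nTrials)
  new("OutcomeDistribution", n = n, proportions = as.numeric(proportions),
      nTrials = nTrials)

#' FitTestResult: KL divergence and G-test of large-scale fit
#' @slot kl Kullback-Leibler divergence in nats
#' @slot G G statistic (2 m KL)
#' @slot df chi-squared degrees of freedom
#' @slot p upper-tail p-value
#' @export
setClass("FitTestResult",
         representation(kl = "numeric", G = "numeric", df = "numeric",
                        p = "numeric"),
         validity = function(object) {
           if (object@kl < -1e-12) return("kl must be non-negative")
           if (object@p < 0 || object@p > 1) return("p must be in [0, 1]")
           TRUE
         })

#' SimSettings: forward-simulation controls
#'
#' Defaults mirror the experimental protocol: a 1/7.5 s time step and 360 s
#' trials. Per step each agent takes a Gaussian signed step of mean
#' `speedMean * dt` and s.d. `speedSd * sqrt(dt)` along its orientation
#' (negative draws allowed, i.e. occasional backward drift), then turn
#' decisions are drawn from the model's intensity evaluated on the post-move
#' configuration with all orientations frozen at their pre-decision values.
#'
#' @slot nAgents number of agents
#' @slot dt time step in seconds (default 1/7.5)
#' @slot duration trial length in seconds (default 360)
#' @slot speedMean mean angular speed in rad/s (default 0.8)
#' @slot speedSd angular speed s.d. in rad/sqrt(s) (default 0.4)
#' @slot model the generating [ModelSpec-class]
#' @slot params its [ParamSet-class]
#' @slot memoryDialect "trace" (per-neighbour memory, default) or "aggregate"
#' @export
setClass("SimSettings",
         representation(nAgents = "numeric", dt = "numeric", duration = "numeric",
                        speedMean = "numeric", speedSd = "numeric",
                        model = "ModelSpec", params = "ParamSet",
                        memoryDialect = "character"),
         validity = function(object) {
           if (object@nAgents < 1) return("nAgents must be >= 1")
           if (object@dt <= 0) return("dt must be positive")
           if (object@duration < object@dt) return("duration must be >= dt")
           if (!object@memoryDialect %in% c("trace", "aggregate"))
             return("memoryDialect must be 'trace' or 'aggregate'")
           TRUE
         })

#' @rdname SimSettings-class
#' @param nAgents,dt,duration,speedMean,speedSd,model,params,memoryDialect see slots
#' @return a [SimSettings-class]
#' @export
simSettings <- function(nAgents, model, params, dt = 1 / 7.5, duration = 360,
                        speedMean = 0.8, speedSd = 0.4,
                        memoryDialect = "trace") {
  if (is.character(model)) model <- modelSpec(model)
  new("SimSettings", nAgents = nAgents, dt = dt, duration = duration,
      speedMean = speedMean, speedSd = speedSd, model = model,
      params = params, memoryDialect = memoryDialect)
}

#' SimResult: one simulated trial
#' @slot trajectory noise-free positions as a [TrialTrajectory-class]
#' @slot orientation true orientation states as an [OrientationRecord-class]
#' @slot cwCount per-frame number of clockwise-moving agents
#' @export
setClass("SimResult",
         representation(trajectory = "TrialTrajectory",
                        orientation = "OrientationRecord",
                        cwCount = "integer"))

#' RunConfig: configuration of a full analysis run
#'
#' Bundles every knob of the pipeline: what to generate (or read), how to
#' preprocess, which models to fit and with what sampler effort. With the
#' same configuration and seed every stage reproduces its outputs exactly.
#'
#' @slot seed master seed; all stage seeds derive from it
#' @slot frameRate frames per second (default 7.5)
#' @slot trialLength trial length in seconds (default 360)
#' @slot groupSizes group sizes to generate/analyse
#' @slot nTrialsPerSize trials per group size
#' @slot models model ids to fit
#' @slot ais an [AisSettings-class]
#' @slot wMax,rMax prior bounds (see [PriorSpec-class])
#' @slot speedMean,speedSd simulator speed parameters (rad/s)
#' @slot obsMu,obsSigma observation noise of the synthetic tracking data
#'   (rad/frame)
#' @slot generatorModel,generatorParams the data-generating model
#' @slot memoryDialect memory aggregation dialect
#' @export
setClass("RunConfig",
         representation(seed = "numeric", frameRate = "numeric",
                        trialLength = "numeric", groupSizes = "numeric",
                        nTrialsPerSize = "numeric", models = "character",
                        ais = "AisSettings", wMax = "numeric", rMax = "numeric",
                        speedMean = "numeric", speedSd = "numeric",
                        obsMu = "numeric", obsSigma = "numeric",
                        generatorModel = "ModelSpec",
                        generatorParams = "ParamSet",
                        memoryDialect = "character"),
         validity = function(object) {
           if (any(object@groupSizes < 1)) return("group sizes must be >= 1")
           if (object@nTrialsPerSize < 1) return("nTrialsPerSize must be >= 1")
           if (length(object@models) < 1) return("at least one model must be configured")
           if (!all(object@models %in% modelIds()))
             return("unknown model id in 'models'")
           TRUE
         })
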