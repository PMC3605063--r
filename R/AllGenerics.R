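#' @name accessors
#' @title Accessors for ringmotion classes
#' @description Small accessor generics: `trialId`, `nPrawns`, `nFrames`,
#'   `frameRate`, `thetaMatrix`, `stateMatrix`, `eventMatrix`, `modelId`,
#'   `mapParams`, `logMarginal`, `midlineRadius`, `outcomeProportions`.
#' @param x an object
#' @return the corresponding slot value
NULL

#' @rdname accessors
#' @export
setGeneric("trialId", function(x) standardGeneric("trialId"))
#' @rdname accessors
#' @export
setGeneric("nPrawns", function(x) standardGeneric("nPrawns"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("thetaMatrix", function(x) standardGeneric("thetaMatrix"))
#' @rdname accessors
#' @export
setGeneric("stateMatrix", function(x) standardGeneric("stateMatrix"))
#' @rdname accessors
#' @export
setGeneric("eventMatrix", function(x) standardGeneric("eventMatrix"))
#' @rdname accessors
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))
#' @rdname accessors
#' @export
setGeneric("mapParams", function(x) standardGeneric("mapParams"))
#' @rdname accessors
#' @export
setGeneric("logMarginal", function(x) standardGeneric("logMarginal"))
#' @rdname accessors
#' @export
setGeneric("midlineRadius", function(x) standardGeneric("midlineRadius"))
#' @rdname accessors
#' @export
setGeneric("outcomeProportions", function(x) standardGeneric("outcomeProportions"))

#' Down-sample a trajectory by an integer factor
#'
#' Keeps frames `0, factor, 2*factor, ...` (0-based), i.e. removes every
#' second frame when `factor = 2`, and divides the frame rate accordingly.
#'
#' @param x a [TrialTrajectory-class]
#' @param factor integer >= 1
#' @return the down-sampled [TrialTrajectory-class]
#' @examples
#' tr <- trialTrajectory(matrix(seq(0, 1, length.out = 100)), frameRate = 15)
#' downsample(tr, 2)   # 7.5 Hz, 50 frames
#' @export
setGeneric("downsample", function(x, factor) standardGeneric("downsample"))

setMethod("trialId", "TrialTrajectory", function(x) x@trialId)
setMethod("trialId", "OrientationRecord", function(x) x@trialId)
setMethod("nPrawns", "TrialTrajectory", function(x) ncol(x@theta))
setMethod("nPrawns", "OrientationRecord", function(x) ncol(x@state))
setMethod("nFrames", "TrialTrajectory", function(x) nrow(x@theta))
setMethod("nFrames", "OrientationRecord", function(x) nrow(x@state))
setMethod("frameRate", "TrialTrajectory", function(x) x@frameRate)
setMethod("thetaMatrix", "TrialTrajectory", function(x) x@theta)
setMethod("stateMatrix", "OrientationRecord", function(x) x@state)
setMethod("eventMatrix", "OrientationRecord", function(x) x@events)
setMethod("modelId", "ModelSpec", function(x) x@id)
setMethod("modelId", "InferenceResult", function(x) x@modelId)
setMethod("mapParams", "InferenceResult", function(x) x@map)
setMethod("logMarginal", "InferenceResult", function(x) x@logMarginal)
setMethod("midlineRadius", "ArenaSpec",
          function(x) (x@outerDiameter + x@innerDiameter) / 4)
setMethod("outcomeProportions", "OutcomeDistribution", function(x) x@proportions)

setMethod("show", "ArenaSpec", function(object) {
  cat("ArenaSpec: annulus", object@outerDiameter, "mm outer /",
      object@innerDiameter, "mm inner (midline radius",
      midlineRadius(object), "mm)\n")
})

setMethod("show", "TrialTrajectory", function(object) {
  cat("TrialTrajectory '", object@trialId, "': ", nPrawns(object),
      " individual(s), ", nFrames(object), " frames at ", object@frameRate,
      " Hz (", round(nFrames(object) / object@frameRate, 1), " s)\n", sep = "")
})

setMethod("show", "OrientationRecord", function(object) {
  cat("OrientationRecord '", object@trialId, "': ", nPrawns(object),
      " individual(s), ", nFrames(object), " frames, dt = ",
      signif(object@dt, 4), " s, ", sum(object@events),
      " direction change(s)\n", sep = "")
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec ", object@id, ": zone = ", object@zone,
      if (object@usesPositive) ", uses positive neighbours" else "",
      if (object@memory) ", non-Markovian memory" else "", "\n", sep = "")
})

setMethod("show", "ParamSet", function(object) {
  v <- paramVector(object)
  v <- v[!is.na(v)]
  cat("ParamSet:", paste(names(v), signif(v, 4), sep = " = ",
                         collapse = ", "), "\n")
})

setMethod("show", "HmmParams", function(object) {
  cat("HmmParams: pSwitch =", signif(object@pSwitch, 4),
      "mu =", signif(object@mu, 4), "sigma =", signif(object@sigma, 4), "\n")
})

setMethod("show", "InferenceResult", function(object) {
  cat("InferenceResult ", object@modelId, ": log ML = ",
      signif(object@logMarginal, 6), " nats (",
      signif(object@logMarginalBits, 6), " bits), MC se = ",
      signif(object@se, 3), "\n  MAP: ", sep = "")
  show(object@map)
})

setMethod("show", "OutcomeDistribution", function(object) {
  cat("OutcomeDistribution over 0..", object@n, " clockwise (",
      object@nTrials, " trials):\n", sep = "")
  print(setNames(round(object@proportions, 4), 0:object@n))
})

setMethod("show", "FitTestResult", function(object) {
  cat("FitTestResult: KL =", signif(object@kl, 4), "nats, G =",
      signif(object@G, 4), "df =", object@df, "p =", signif(object@p, 4), "\n")
})

#' Parameters of a ParamSet as a named vector
#' @param params a [ParamSet-class]
#' @return named numeric vector (NA entries for unused parameters)
#' @export
paramVector <- function(params)
  c(lambda0 = params@lambda0, wNeg = params@wNeg, wPos = params@wPos,
    R = params@R, K = params@K, alpha = params@alpha)
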