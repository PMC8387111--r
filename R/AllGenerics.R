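#' @rdname NetworkSpec-class
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' @rdname NetworkSpec-class
#' @export
setGeneric("connections", function(x) standardGeneric("connections"))

#' @rdname NetworkSpec-class
#' @export
setGeneric("activations", function(x) standardGeneric("activations"))

#' @rdname SimulationTrace-class
#' @export
setGeneric("xTraces", function(x) standardGeneric("xTraces"))

#' @rdname SimulationTrace-class
#' @export
setGeneric("yTraces", function(x) standardGeneric("yTraces"))

#' @rdname SimulationTrace-class
#' @export
setGeneric("isStable", function(x) standardGeneric("isStable"))

#' @rdname SensorEpochs-class
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname SensorEpochs-class
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))

#' @rdname SensorEpochs-class
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname SensorEpochs-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname TGMatrix-class
#' @export
setGeneric("tgScores", function(x, target = c("angle", "delta"))
  standardGeneric("tgScores"))

#' @rdname TGMatrix-class
#' @export
setGeneric("tgDiagonal", function(x) standardGeneric("tgDiagonal"))

setMethod("nLevels", "NetworkSpec", function(x) x@nLevels)

setMethod("connections", "NetworkSpec", function(x) {
  tab <- .connSlotTable[x@weights != 0, c("src", "dst", "offset"), drop = FALSE]
  tab$weight <- x@weights[x@weights != 0]
  rownames(tab) <- NULL
  tab
})

setMethod("activations", "NetworkSpec", function(x)
  c(x = x@activationX, y = x@activationY))

setMethod("xTraces", "SimulationTrace", function(x) x@values[, 1L, , drop = TRUE])
setMethod("yTraces", "SimulationTrace", function(x) x@values[, 2L, , drop = TRUE])
setMethod("isStable", "SimulationTrace", function(x) x@stable)

setMethod("epochData", "SensorEpochs", function(x) x@data)
setMethod("designTable", "SensorEpochs", function(x) x@design)
setMethod("timePoints", "SensorEpochs", function(x) x@times)
setMethod("samplingRate", "SensorEpochs", function(x) x@sfreq)

setMethod("tgScores", "TGMatrix", function(x, target = c("angle", "delta")) {
  target <- match.arg(target)
  if (target == "angle") x@angle else x@delta
})

setMethod("tgDiagonal", "TGMatrix", function(x) {
  data.frame(time = x@trainTimes,
             angleScore = diag(x@angle),
             deltaR = diag(x@delta))
})

setMethod("show", "NetworkSpec", function(object) {
  cat("NetworkSpec:", object@nLevels, "levels,",
      sum(object@weights != 0), "connection type(s)\n")
  cat("  activations: x =", object@activationX, ", y =", object@activationY, "\n")
  if (any(object@weights != 0)) {
    tab <- connections(object)
    lab <- c(`0` = "recurrent", `1` = "feedforward", `-1` = "feedback")
    for (i in seq_len(nrow(tab)))
      cat(sprintf("  %s -> %s %-11s w = %+.3g\n", tab$src[i], tab$dst[i],
                  lab[as.character(tab$offset[i])], tab$weight[i]))
  }
})

setMethod("show", "StepInput", function(object) {
  cat(sprintf("StepInput: %d samples, amplitude %g on [%d, %d)\n",
              object@nSamples, object@amplitude, object@onStart, object@onEnd))
})

setMethod("show", "SimulationTrace", function(object) {
  d <- dim(object@values)
  cat(sprintf("SimulationTrace: %d levels x 2 roles x %d samples (%s)\n",
              d[1], d[3], if (object@stable) "stable" else "UNSTABLE"))
})

setMethod("show", "SensorEpochs", function(object) {
  d <- dim(object@data)
  cat(sprintf("SensorEpochs: %d stimuli x %d sensors x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@sfreq))
  cat(sprintf("  window %.3f .. %.3f s, locked to %s onset\n",
              min(object@times), max(object@times), object@lockedTo))
})

setMethod("show", "TGMatrix", function(object) {
  cat(sprintf("TGMatrix: %d train x %d test times, %d folds\n",
              length(object@trainTimes), length(object@testTimes),
              object@nFolds))
})
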