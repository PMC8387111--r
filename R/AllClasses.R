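#' @import methods
NULL

.activationKinds <- c("linear", "relu", "satrelu", "satlin")

# The 12 possible connection types of a two-role (observable x / hidden y)
# hierarchy with recurrent (offset 0), feedforward (+1) and feedback (-1)
# connectivity. Slot order is the package-wide convention: offsets grouped
# as recurrent, feedforward, feedback; within each offset src/dst pairs
# x->x, x->y, y->x, y->y.
.connSlotTable <- data.frame(
  slot   = 1:12,
  src    = rep(c("x", "x", "y", "y"), 3),
  dst    = rep(c("x", "y", "x", "y"), 3),
  offset = rep(c(0L, 1L, -1L), each = 4),
  stringsAsFactors = FALSE
)

#' Table of the twelve connection types
#'
#' Each row describes one possible connection type of the hierarchy: a source
#' role (`x` observable, `y` hidden), a target role, and a level offset
#' (0 recurrent, +1 feedforward, -1 feedback). The row order defines the slot
#' indexing used by sign patterns and weight vectors throughout the package.
#'
#' @return A 12-row data.frame with columns `slot`, `src`, `dst`, `offset`.
#' @export
connectionSlots <- function() .connSlotTable

.slotIndex <- function(src, dst, offset) {
  i <- which(.connSlotTable$src == src & .connSlotTable$dst == dst &
               .connSlotTable$offset == offset)
  if (length(i) != 1L)
    stop("no such connection type: ", src, "->", dst, " offset ", offset)
  i
}

#' @rdname NetworkSpec-class
#' @export
setClass("NetworkSpec",
  representation(
    nLevels     = "integer",
    weights     = "numeric",   # length 12, slot order of connectionSlots()
    activationX = "character",
    activationY = "character"
  )
)

setValidity("NetworkSpec", function(object) {
  msg <- character()
  if (length(object@nLevels) != 1L || is.na(object@nLevels) || object@nLevels < 1L)
    msg <- c(msg, "nLevels must be a positive integer")
  if (length(object@weights) != 12L)
    msg <- c(msg, "weights must have exactly 12 entries (one per connection type)")
  if (any(!is.finite(object@weights)) || any(abs(object@weights) > 1))
    msg <- c(msg, "weights must be finite and lie in [-1, 1]")
  if (!(object@activationX %in% .activationKinds))
    msg <- c(msg, "unknown activationX")
  if (!(object@activationY %in% .activationKinds))
    msg <- c(msg, "unknown activationY")
  if (length(msg)) msg else TRUE
})

#' Hierarchical network specification
#'
#' A `NetworkSpec` describes a discrete-time dynamical system: `nLevels`
#' hierarchical levels, each holding one observable unit (`x`) and one hidden
#' unit (`y`), connected by up to twelve connection types (see
#' [connectionSlots()]). A connection type applies identically at every level.
#' Weights lie in `[-1, 1]`; a weight of zero means the connection is absent.
#'
#' @param connections data.frame with columns `src`, `dst` (each `"x"` or
#'   `"y"`), `offset` (-1, 0 or +1) and `weight`, one row per present
#'   connection; at most one row per connection type.
#' @param nLevels number of hierarchical levels (default 10).
#' @param activationX,activationY activation function for observable / hidden
#'   units: one of `"linear"`, `"relu"`, `"satrelu"`, `"satlin"`.
#' @return A `NetworkSpec` object.
#' @examples
#' net <- networkSpec(data.frame(src = "x", dst = "x", offset = 1, weight = 1))
#' nLevels(net)
#' @export
networkSpec <- function(connections = NULL, nLevels = 10L,
                        activationX = "linear", activationY = "linear") {
  w <- numeric(12)
  if (!is.null(connections) && nrow(connections)) {
    idx <- mapply(.slotIndex, connections$src, connections$dst,
                  as.integer(connections$offset))
    if (anyDuplicated(idx))
      stop("at most one connection per (src, dst, offset) type")
    if (any(connections$weight == 0))
      stop("a present connection must have a nonzero weight")
    w[idx] <- connections$weight
  }
  new("NetworkSpec", nLevels = as.integer(nLevels), weights = w,
      activationX = activationX, activationY = activationY)
}

#' @rdname StepInput-class
#' @export
setClass("StepInput",
  representation(
    nSamples  = "integer",
    onStart   = "integer",
    onEnd     = "integer",
    amplitude = "numeric"
  )
)

setValidity("StepInput", function(object) {
  if (object@onStart < 0L || object@onStart >= object@onEnd ||
      object@onEnd > object@nSamples)
    return("need 0 <= onStart < onEnd <= nSamples")
  TRUE
})

#' Step input for network simulation
#'
#' A constant input of the given amplitude applied on sample indices
#' `[onStart, onEnd)` (0-based) of an `nSamples`-long simulation.
#'
#' @param nSamples simulation length in samples (default 120).
#' @param onStart,onEnd input on-window, 0-based sample indices (defaults
#'   30 and 60).
#' @param amplitude input value while on (default 1).
#' @return A `StepInput` object.
#' @export
stepInput <- function(nSamples = 120L, onStart = 30L, onEnd = 60L,
                      amplitude = 1) {
  new("StepInput", nSamples = as.integer(nSamples),
      onStart = as.integer(onStart), onEnd = as.integer(onEnd),
      amplitude = amplitude)
}

#' @rdname SimulationTrace-class
#' @export
setClass("SimulationTrace",
  representation(
    values = "array",    # nLevels x 2 roles (x, y) x nSamples
    stable = "logical"
  )
)

setValidity("SimulationTrace", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L || d[2] != 2L)
    return("values must be an nLevels x 2 x nSamples array")
  TRUE
})

#' @rdname SensorEpochs-class
#' @export
setClass("SensorEpochs",
  representation(
    data     = "array",        # stimuli x sensors x time
    design   = "data.frame",   # one row per stimulus, aligned with dim 1
    times    = "numeric",      # seconds relative to the locking event
    sfreq    = "numeric",
    lockedTo = "character"     # "stimulus" or "sequence"
  )
)

setValidity("SensorEpochs", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L)
    msg <- c(msg, "data must be a stimuli x sensors x time array")
  else {
    if (d[1] != nrow(object@design))
      msg <- c(msg, "design rows must match the first data dimension")
    if (d[3] != length(object@times))
      msg <- c(msg, "times must match the third data dimension")
  }
  if (!all(is.finite(object@data)))
    msg <- c(msg, "epoch data must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname TGMatrix-class
#' @export
setClass("TGMatrix",
  representation(
    angle      = "matrix",   # train-time x test-time angular scores
    delta      = "matrix",   # train-time x test-time Pearson r
    trainTimes = "numeric",
    testTimes  = "numeric",
    nFolds     = "integer",
    seed       = "integer"
  )
)

setValidity("TGMatrix", function(object) {
  if (!all(dim(object@angle) == c(length(object@trainTimes),
                                  length(object@testTimes))))
    return("angle matrix dimensions must match the time axes")
  if (!all(dim(object@delta) == dim(object@angle)))
    return("delta matrix must match the angle matrix shape")
  TRUE
})
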