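#' Monotone activation functions
#'
#' The four unit activation functions of the simulator, all monotone
#' non-decreasing: `linear` is the identity, `relu` is `max(z, 0)`,
#' `satrelu` saturates at `[0, 1]` and `satlin` at `[-1, 1]`.
#'
#' @param kind one of `"linear"`, `"relu"`, `"satrelu"`, `"satlin"`.
#' @param value numeric vector (or array) of pre-activations.
#' @return `value` transformed elementwise.
#' @examples
#' applyActivation("satlin", c(-2, 0.3, 2))
#' @export
applyActivation <- function(kind, value) {
  switch(kind,
    linear  = value,
    relu    = pmax(value, 0),
    satrelu = pmin(pmax(value, 0), 1),
    satlin  = pmin(pmax(value, -1), 1),
    stop("unknown activation kind: ", kind)
  )
}

# Shifted source matrices for one synchronous update.
# state: nLevels x 2 (columns x, y). The external input behaves as a virtual
# level 0 read by the feedforward connections; with inputRoles = "xy" both
# its x and y roles equal the input value, with "x" only the x role does.
.ffSources <- function(xs, ys, inputValue, inputRoles) {
  L <- length(xs)
  list(
    ffX = c(inputValue, xs[-L]),
    ffY = c(if (inputRoles == "xy") inputValue else 0, ys[-L]),
    fbX = c(xs[-1L], 0),
    fbY = c(ys[-1L], 0)
  )
}

#' Advance a network state by one sample
#'
#' Applies the synchronous update rule: each unit's next activity is its
#' activation function applied to the weighted sum of its incoming
#' connections evaluated at the current sample. The external input enters
#' level 1 through the network's feedforward weights as a virtual level-0
#' unit; feedforward out of the top level and feedback out of level 1 are
#' discarded.
#'
#' @param net a [NetworkSpec-class] object.
#' @param state numeric `nLevels x 2` matrix of current activities
#'   (columns `x`, `y`).
#' @param inputValue external input value at the current sample.
#' @param inputRoles `"xy"` (default): the input is read by all four
#'   feedforward connection types (a full virtual level 0); `"x"`: only
#'   feedforward connections with an `x` source carry it.
#' @return The `nLevels x 2` state at the next sample.
#' @export
stepState <- function(net, state, inputValue, inputRoles = c("xy", "x")) {
  inputRoles <- match.arg(inputRoles)
  w <- net@weights
  xs <- state[, 1L]
  ys <- state[, 2L]
  s <- .ffSources(xs, ys, inputValue, inputRoles)
  newX <- applyActivation(net@activationX,
    w[1L] * xs + w[3L] * ys + w[5L] * s$ffX + w[7L] * s$ffY +
      w[9L] * s$fbX + w[11L] * s$fbY)
  newY <- applyActivation(net@activationY,
    w[2L] * xs + w[4L] * ys + w[6L] * s$ffX + w[8L] * s$ffY +
      w[10L] * s$fbX + w[12L] * s$fbY)
  cbind(x = newX, y = newY)
}

.inputSeries <- function(input) {
  u <- numeric(input@nSamples)
  u[(input@onStart + 1L):input@onEnd] <- input@amplitude  # 0-based [on, off)
  u
}

#' Simulate a hierarchical network under a step input
#'
#' Iterates [stepState()] from a zero initial state over the input horizon.
#' A trace containing non-finite values or activities exceeding `1e6` in
#' magnitude is flagged unstable (`isStable()` returns `FALSE`); unstable
#' models are treated as invalid by the architecture search.
#'
#' @inheritParams stepState
#' @param input a [StepInput-class] object.
#' @return A [SimulationTrace-class] object (`nLevels x 2 x nSamples`).
#' @examples
#' net <- networkSpec(data.frame(src = "x", dst = "x", offset = 1, weight = 1))
#' tr <- simulateNetwork(net, stepInput(20, 2, 6))
#' xTraces(tr)[1:3, 1:8]
#' @export
simulateNetwork <- function(net, input = stepInput(),
                            inputRoles = c("xy", "x")) {
  inputRoles <- match.arg(inputRoles)
  L <- net@nLevels
  nT <- input@nSamples
  u <- .inputSeries(input)
  vals <- array(0, dim = c(L, 2L, nT),
                dimnames = list(NULL, c("x", "y"), NULL))
  state <- matrix(0, L, 2L)
  for (t in seq_len(nT - 1L)) {
    state <- stepState(net, state, u[t], inputRoles)
    vals[, , t + 1L] <- state
  }
  stable <- all(is.finite(vals)) && max(abs(vals)) <= 1e6
  new("SimulationTrace", values = vals, stable = stable)
}
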