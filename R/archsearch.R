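.monoTol <- 1e-9

#' Onset, offset and maintenance half-life of a unit response
#'
#' These detectors quantify the phenomenological criteria used to judge
#' whether a simulated hierarchy reproduces the traveling-wave structure of
#' evoked sensor responses.
#'
#' A unit is marked by an *onset* if its maximum value `M`, first reached at
#' sample `tM`, is positive, occurs before the input offset, and the series
#' rises monotonically (tolerance `1e-9`) from the input onset to `tM`. It
#' is marked by an *offset* if its minimum `m`, first reached at `tm`, is
#' negative and the series is non-decreasing from `tm` to the end of the
#' simulation. The maintenance *half-life* is the number of samples after
#' the maximum at which the series first drops to `M / 2`; it is defined
#' only when the series decays monotonically between the maximum and `tm`
#' (strictly, when `strict = TRUE`).
#'
#' `tMl`, the *last* sample attaining the maximum, supports the stricter
#' transient reading used by [validateModel()]: a genuinely transient
#' response leaves its maximum before the input offset, whereas a response
#' that plateaus at its maximum until the input ends does not.
#'
#' All sample indices are 0-based, matching the simulation time axis.
#'
#' @param series numeric vector: one unit's activity over time.
#' @param input the [StepInput-class] used for the simulation.
#' @return `detectOnset()`: list with `hasOnset`, `tM`, `tMl`, `M`;
#'   `detectOffset()`: list with `hasOffset`, `tm`, `m`;
#'   `halfLife()`: integer number of samples, or `NA` if undefined.
#' @examples
#' inp <- stepInput(10, 1, 6)
#' detectOnset(c(0, 0, 1, 2, 3, 3, 2, 1, 0, 0), inp)
#' @export
detectOnset <- function(series, input) {
  stopifnot(all(is.finite(series)))
  M <- max(series)
  tM <- which.max(series) - 1L              # first index attaining the max
  tMl <- max(which(series == M)) - 1L       # last index attaining the max
  rise <- if (tM > input@onStart) {
    all(diff(series[(input@onStart + 1L):(tM + 1L)]) >= -.monoTol)
  } else TRUE
  list(hasOnset = (M > 0) && (tM < input@onEnd) && rise,
       tM = tM, tMl = tMl, M = M)
}

#' @rdname detectOnset
#' @export
detectOffset <- function(series, input) {
  stopifnot(all(is.finite(series)))
  m <- min(series)
  tm <- which.min(series) - 1L
  n <- length(series)
  tail_ok <- if (tm + 1L < n) {
    all(diff(series[(tm + 1L):n]) >= -.monoTol)
  } else TRUE
  list(hasOffset = (m < 0) && tail_ok, tm = tm, m = m)
}

#' @rdname detectOnset
#' @param onset,offset results of [detectOnset()] and [detectOffset()] on
#'   the same series.
#' @param strict require a strictly decreasing decay (every step below the
#'   previous value); with `FALSE` (the default) a non-increasing decay
#'   (tolerance `1e-9`) suffices.
#' @param from measure from the first (`"first"`, default) or last
#'   (`"last"`) attainment of the maximum.
#' @export
halfLife <- function(series, onset, offset, strict = FALSE,
                     from = c("first", "last")) {
  from <- match.arg(from)
  if (!onset$hasOnset || !offset$hasOffset) return(NA_integer_)
  tM <- if (from == "last") onset$tMl else onset$tM
  tm <- offset$tm
  if (tm <= tM) return(NA_integer_)
  d <- diff(series[(tM + 1L):(tm + 1L)])
  if (any(d > .monoTol)) return(NA_integer_)       # rebound: undefined
  if (strict && any(d >= 0)) return(NA_integer_)   # plateau: no decay
  rel <- which(series[(tM + 1L):length(series)] <= onset$M / 2)
  if (!length(rel)) return(NA_integer_)
  as.integer(rel[1L] - 1L)
}

#' Validate a simulated model against the traveling-wave criteria
#'
#' A model is valid when the observable (`x`) unit of *every* level shows an
#' onset, an offset, and a defined maintenance half-life, and the profile of
#' half-lives across levels shows increasing maintenance. Hidden (`y`) units
#' are unconstrained. Unstable traces are invalid.
#'
#' Two readings of the criteria are provided. The default `"transient"`
#' reading — the one under which the architecture search reproduces the
#' published outcome — additionally requires each observable unit to leave
#' its maximum before the input offset, a strictly decreasing decay between
#' the (last-attained) maximum and the offset minimum (a response that
#' plateaus does not "decay toward zero"), and an overall increase of the
#' half-life profile (`h` non-decreasing at every step and strictly larger
#' at the top level than at the bottom). The `"literal"` reading keeps the
#' weakest form of each criterion: first-attainment extrema, non-increasing
#' decay, and a merely non-decreasing half-life profile.
#'
#' @param trace a [SimulationTrace-class].
#' @param input the [StepInput-class] used to produce it.
#' @param criteria `"transient"` (default) or `"literal"`, see Details.
#' @return A list with `valid` (logical) and `levels`, a per-level
#'   data.frame of criterion outcomes (`hasOnset`, `tM`, `tMl`, `M`,
#'   `hasOffset`, `tm`, `m`, `halfLife`).
#' @export
validateModel <- function(trace, input, criteria = c("transient", "literal")) {
  criteria <- match.arg(criteria)
  strict <- criteria == "transient"
  L <- dim(trace@values)[1L]
  if (!trace@stable) {
    lev <- data.frame(level = seq_len(L), hasOnset = FALSE, tM = NA, tMl = NA,
                      M = NA, hasOffset = FALSE, tm = NA, m = NA,
                      halfLife = NA)
    return(list(valid = FALSE, levels = lev, criteria = criteria))
  }
  xs <- trace@values[, 1L, , drop = FALSE]
  rows <- lapply(seq_len(L), function(l) {
    s <- xs[l, 1L, ]
    on <- detectOnset(s, input)
    off <- detectOffset(s, input)
    if (strict)
      on$hasOnset <- on$hasOnset && (on$tMl < input@onEnd)
    th <- halfLife(s, on, off, strict = strict,
                   from = if (strict) "last" else "first")
    data.frame(level = l, hasOnset = on$hasOnset, tM = on$tM, tMl = on$tMl,
               M = on$M, hasOffset = off$hasOffset, tm = off$tm, m = off$m,
               halfLife = th)
  })
  lev <- do.call(rbind, rows)
  hl <- lev$halfLife
  valid <- all(lev$hasOnset) && all(lev$hasOffset) && !anyNA(hl) &&
    all(diff(hl) >= 0)
  if (strict && valid)
    valid <- hl[L] > hl[1L]   # increasing maintenance, not merely constant
  list(valid = valid, levels = lev, criteria = criteria)
}

#' Enumerate connection-sign architectures
#'
#' An architecture is the equivalence class of models sharing the sign
#' (-1, 0, +1) of each of the twelve connection types. There are `3^12 =
#' 531441` architectures in total.
#'
#' @param complexity optional integer (vector): keep only architectures with
#'   this number of nonzero connections.
#' @return Integer matrix with 12 columns, one row per sign pattern.
#' @examples
#' nrow(enumerateArchitectures(complexity = 1))  # 24
#' @export
enumerateArchitectures <- function(complexity = NULL) {
  g <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), 12L),
                             KEEP.OUT.ATTRS = FALSE))
  colnames(g) <- .slotLabels()
  if (!is.null(complexity))
    g <- g[rowSums(g != 0L) %in% complexity, , drop = FALSE]
  g
}

.slotLabels <- function() {
  lab <- c(`0` = "rec", `1` = "ff", `-1` = "fb")
  paste0(.connSlotTable$src, .connSlotTable$dst,
         "_", lab[as.character(.connSlotTable$offset)])
}

#' Closed-form model counts of the architecture grid search
#'
#' `modelCount(k, ...)` is the number of distinct models with exactly `k`
#' present connections: `choose(12, k) * gridSize^k * activationPairs`.
#'
#' @param k number of present connections (may be a vector).
#' @param gridSize number of weight values per connection (21 for the
#'   canonical grid on `[-1, 1]` in steps of 0.05).
#' @param activationPairs number of (x, y) activation combinations (16).
#' @return Numeric count (summed over `1..maxK` in
#'   `cumulativeModelCount()`).
#' @export
modelCount <- function(k, gridSize = 21, activationPairs = 16) {
  choose(12, k) * gridSize^k * activationPairs
}

#' @rdname modelCount
#' @param maxK largest complexity included.
#' @export
cumulativeModelCount <- function(maxK = 4, gridSize = 21,
                                 activationPairs = 16) {
  sum(modelCount(seq_len(maxK), gridSize, activationPairs))
}

# Boolean reachability: can the input drive the x unit of every level?
# Sound pruning only - unreachable x units stay identically zero, so their
# onset criterion (M > 0) can never hold, whatever the weights.
.subsetFeasible <- function(slots, nLevels, inputRoles = "xy") {
  tab <- .connSlotTable[slots, , drop = FALSE]
  reach <- matrix(FALSE, nLevels, 2L)  # columns x, y
  ff <- tab[tab$offset == 1L, , drop = FALSE]
  entry <- if (inputRoles == "xy") ff else ff[ff$src == "x", , drop = FALSE]
  for (d in unique(entry$dst))
    reach[1L, if (d == "x") 1L else 2L] <- TRUE
  if (!any(reach)) return(FALSE)
  repeat {
    new <- reach
    for (r in seq_len(nrow(tab))) {
      srcCol <- if (tab$src[r] == "x") 1L else 2L
      dstCol <- if (tab$dst[r] == "x") 1L else 2L
      off <- tab$offset[r]
      srcLev <- seq_len(nLevels)
      dstLev <- srcLev + off
      keep <- dstLev >= 1L & dstLev <= nLevels
      new[dstLev[keep], dstCol] <- new[dstLev[keep], dstCol] |
        reach[srcLev[keep], srcCol]
    }
    if (identical(new, reach)) break
    reach <- new
  }
  all(reach[, 1L])
}

# Transient-criteria validity for a weight batch via the compiled simulator.
# Returns list(valid, halfLives).
.batchValidity <- function(W, activationX, activationY, nLevels, input,
                           inputRoles = "xy") {
  actIdx <- function(a) match(a, .activationKinds) - 1L
  cc <- .batchSimComponents(W, actIdx(activationX), actIdx(activationY),
                            as.integer(nLevels), input@nSamples,
                            input@onStart, input@onEnd, input@amplitude,
                            if (inputRoles == "xy") 1L else 0L, .monoTol)
  L <- nLevels
  th <- cc$halfLifeL
  levelOK <- cc$M > 0 & cc$tMl < input@onEnd & cc$riseOK &
    cc$m < 0 & cc$tm > cc$tMl & cc$decayStrictL & cc$tailOK & th >= 0
  valid <- rowSums(levelOK) == L & !cc$unstable
  if (L > 1L) {
    hlND <- rowSums(th[, -1L, drop = FALSE] < th[, -L, drop = FALSE]) == 0L
    valid <- valid & hlND & (th[, L] > th[, 1L])
  }
  list(valid = valid, halfLives = th)
}

#' Minimal-complexity architecture search
#'
#' Enumerates models of increasing complexity `k = 1, 2, ...` (number of
#' present connections), evaluating for each `k` every combination of a
#' `k`-subset of the twelve connection types, a nonzero grid weight per
#' present connection, and one of the 16 activation pairs. All models of a
#' complexity level are covered before the search stops at the first level
#' with at least one valid model (transient criteria of [validateModel()]).
#'
#' Two analytic prunes keep the batch simulation tractable without changing
#' the outcome: connection subsets through which the input cannot reach
#' every level's observable unit are skipped (those x units stay identically
#' zero, so the onset criterion must fail), and activation pairs whose x
#' activation is non-negative by construction (`relu`, `satrelu`) are
#' skipped because the offset criterion requires a negative minimum. Pruned
#' models still count toward `modelsCovered`.
#'
#' @param weightGrid nonzero candidate weights in `[-1, 1]`.
#' @param maxK largest complexity to try.
#' @param nLevels hierarchy depth (default 10).
#' @param input simulation input (default: 120 samples, on over `[30, 60)`).
#' @param inputRoles input coupling convention, see [stepState()].
#' @param prune apply the analytic prunes (default `TRUE`; `FALSE` simulates
#'   every model and must give identical results).
#' @param batchSize models simulated per compiled batch.
#' @param verbose print per-complexity progress.
#' @return A list of class `"SearchResult"`: `kMin` (`NA` if none found up
#'   to `maxK`), `found`, `architectures` (sign-pattern matrix, one row per
#'   valid architecture, with an `epiphenomenalX` attribute flagging
#'   architectures whose x units have no outgoing connections), `exemplars`
#'   (one valid [NetworkSpec-class] per architecture), `modelsCovered`,
#'   `modelsSimulated`, and the search parameters.
#' @export
searchMinComplexity <- function(weightGrid = c(-1, -0.75, -0.5, -0.25,
                                               0.25, 0.5, 0.75, 1),
                                maxK = 6L, nLevels = 10L,
                                input = stepInput(),
                                inputRoles = c("xy", "x"), prune = TRUE,
                                batchSize = 16384L, verbose = FALSE) {
  inputRoles <- match.arg(inputRoles)
  stopifnot(all(weightGrid != 0), all(abs(weightGrid) <= 1), maxK <= 12L)
  g <- length(weightGrid)
  actPairs <- expand.grid(x = .activationKinds, y = .activationKinds,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  covered <- 0
  simulated <- 0
  archKeys <- character()
  archSigns <- NULL
  exemplars <- list()
  kMin <- NA_integer_

  for (k in seq_len(maxK)) {
    subsets <- utils::combn(12L, k)
    nSub <- ncol(subsets)
    covered <- covered + nSub * g^k * 16
    feas <- if (prune) {
      apply(subsets, 2L, .subsetFeasible, nLevels = nLevels,
            inputRoles = inputRoles)
    } else rep(TRUE, nSub)
    assignGrid <- as.matrix(expand.grid(rep(list(weightGrid), k),
                                        KEEP.OUT.ATTRS = FALSE))
    nA <- nrow(assignGrid)
    subChunk <- max(1L, batchSize %/% nA)
    for (p in seq_len(nrow(actPairs))) {
      ax <- actPairs$x[p]
      ay <- actPairs$y[p]
      if (prune && ax %in% c("relu", "satrelu")) next
      subIdx <- which(feas)
      for (chunk in split(subIdx, ceiling(seq_along(subIdx) / subChunk))) {
        W <- matrix(0, length(chunk) * nA, 12L)
        row0 <- 0L
        for (s in chunk) {
          rows <- row0 + seq_len(nA)
          W[cbind(rep(rows, each = k), rep(subsets[, s], nA))] <-
            as.vector(t(assignGrid))
          row0 <- row0 + nA
        }
        res <- .batchValidity(W, ax, ay, nLevels, input, inputRoles)
        simulated <- simulated + nrow(W)
        for (h in which(res$valid)) {
          sg <- sign(W[h, ])
          key <- paste(sg, collapse = ",")
          if (!(key %in% archKeys)) {
            archKeys <- c(archKeys, key)
            archSigns <- rbind(archSigns, sg)
            exemplars[[key]] <- new("NetworkSpec",
                                    nLevels = as.integer(nLevels),
                                    weights = W[h, ], activationX = ax,
                                    activationY = ay)
          }
        }
      }
    }
    if (verbose)
      message(sprintf("k = %d: %d valid architecture(s)", k,
                      length(archKeys)))
    if (length(archKeys)) {
      kMin <- k
      break
    }
  }

  if (!is.null(archSigns)) {
    colnames(archSigns) <- .slotLabels()
    rownames(archSigns) <- NULL
    xOut <- .connSlotTable$src == "x"
    attr(archSigns, "epiphenomenalX") <-
      apply(archSigns, 1L, function(sg) all(sg[xOut] == 0))
  }
  structure(list(
    kMin = kMin, found = !is.na(kMin), architectures = archSigns,
    exemplars = unname(exemplars), modelsCovered = covered,
    modelsSimulated = simulated, weightGrid = weightGrid, maxK = maxK,
    nLevels = nLevels, input = input, inputRoles = inputRoles
  ), class = "SearchResult")
}

#' @export
print.SearchResult <- function(x, ...) {
  if (x$found) {
    cat(sprintf("SearchResult: k_min = %d, %d valid architecture(s)\n",
                x$kMin, nrow(x$architectures)))
  } else {
    cat(sprintf("SearchResult: no valid model up to k = %d\n", x$maxK))
  }
  cat(sprintf("  models covered: %.6g (simulated: %.6g)\n",
              x$modelsCovered, x$modelsSimulated))
  invisible(x)
}
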