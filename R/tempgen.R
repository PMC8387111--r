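#' Temporal generalization matrix
#'
#' Trains the per-time-sample decoders of [crossvalDecode()] and scores every
#' decoder trained at time `t` on out-of-fold data from every time `t'`,
#' yielding a train-time by test-time score matrix per target (angular score
#' for the stimulus angle, Pearson r for delta). One fold partition, fixed by
#' `seed`, is shared across all training times, so the matrix diagonal equals
#' the [crossvalDecode()] timecourse.
#'
#' @inheritParams crossvalDecode
#' @return A [TGMatrix-class] object.
#' @export
temporalGeneralization <- function(epochs, K = 5L, seed = 1L) {
  des <- epochs@design
  Y <- targetMatrix(des)
  res <- .cvDecodeCore(epochs@data, Y, attr(Y, "deltaDefined"), des$trial,
                       K, seed, tg = TRUE)
  new("TGMatrix", angle = res$angle, delta = res$deltaR,
      trainTimes = epochs@times, testTimes = epochs@times,
      nFolds = as.integer(K), seed = as.integer(seed))
}

#' Position-resolved decoding of a stimulus sequence
#'
#' Trains one decoder family per sequence position on sequence-locked
#' epochs: the decoders for position `p` predict the features of the `p`-th
#' stimulus of each sequence at every sequence time sample, and are scored
#' against that stimulus' own features. The cumulative score is the
#' elementwise sum across positions (delta contributions start at position 2
#' where delta is defined).
#'
#' @param seqEpochs a sequence-locked [SensorEpochs-class]
#'   (`epochStream(..., lockedTo = "sequence")`).
#' @param positions positions to decode (default 1 to 8).
#' @inheritParams crossvalDecode
#' @return list with `times`, matrices `angle` and `delta`
#'   (`time x position`), and `cumulativeAngle` / `cumulativeDelta` vectors.
#' @export
positionResolvedDecoding <- function(seqEpochs, K = 5L, seed = 1L,
                                     positions = 1:8) {
  if (seqEpochs@lockedTo != "sequence")
    stop("positionResolvedDecoding needs sequence-locked epochs")
  des <- seqEpochs@design
  nT <- dim(seqEpochs@data)[3L]
  angle <- delta <- matrix(NA_real_, nT, length(positions))
  colnames(angle) <- colnames(delta) <- paste0("pos", positions)
  for (j in seq_along(positions)) {
    p <- positions[j]
    aCol <- des[[paste0("alpha", p)]]
    dCol <- des[[paste0("delta", p)]]
    if (is.null(aCol)) stop("position ", p, " missing from the design")
    Yp <- cbind(delta = dCol, sin = sin(aCol), cos = cos(aCol))
    res <- .cvDecodeCore(seqEpochs@data, Yp, !is.na(dCol), des$trial,
                         K, seed, tg = FALSE)
    angle[, j] <- res$angle
    delta[, j] <- res$deltaR
  }
  list(times = seqEpochs@times, angle = angle, delta = delta,
       cumulativeAngle = rowSums(angle),
       cumulativeDelta = rowSums(delta, na.rm = TRUE))
}

#' Diagonal versus reversal decoding comparison
#'
#' For each training time `t`, compares the diagonal score `s(t, t)` with
#' the sign-reversed score of the same decoder tested one stimulus onset
#' asynchrony later, `-s(t, t + soa)`. The returned paired difference
#' `s(t, t) + s(t, t + soa)` is positive when the diagonal decoder
#' outperforms its reversal counterpart; it is the subject-level effect fed
#' to the group statistics.
#'
#' @param tg a [TGMatrix-class].
#' @param soa stimulus onset asynchrony in seconds (default 0.25).
#' @param target `"angle"` or `"delta"`.
#' @return data.frame with columns `time` and `difference` (training times
#'   for which `t + soa` lies inside the matrix).
#' @export
diagonalVsReversal <- function(tg, soa = 0.25, target = c("angle", "delta")) {
  target <- match.arg(target)
  S <- tgScores(tg, target)
  dt <- mean(diff(tg@testTimes))
  k <- as.integer(round(soa / dt))
  nT <- length(tg@trainTimes)
  if (k < 1L || k >= nT)
    stop("SOA lies outside the matrix time axis")
  idx <- seq_len(nT - k)
  data.frame(time = tg@trainTimes[idx],
             difference = S[cbind(idx, idx)] + S[cbind(idx, idx + k)])
}
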