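#' Circular orientation distance
#'
#' Distance between two orientations on the period-pi orientation circle,
#' folded to `[0, pi/2]`.
#'
#' @param a,b orientations in radians, `[0, pi)`.
#' @return Numeric vector of distances.
#' @export
circularDelta <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}

#' Sample a visual-stream experiment design
#'
#' Builds the per-stimulus design table of a rapid serial visual
#' presentation experiment: each trial is an 8-item sequence of oriented
#' Gabor patches flashed every 250 ms, orientations drawn i.i.d. uniform on
#' `[0, pi)`. The full-circle angle is `alpha = 2 * theta` (orientation has
#' period pi) and `delta` is the circular orientation distance to the
#' previous item, undefined at position 1. With the defaults (672 trials)
#' each subject contributes 5376 oriented stimuli.
#'
#' Onset times place each trial in its own rendering block: a 0.25 s
#' pre-roll, eight onsets spaced 250 ms (62/63 samples alternating at
#' 250 Hz), and a silent tail covering the response decay and the
#' inter-trial interval.
#'
#' @param nTrials trials (8-item sequences) per subject; default 672.
#' @param nSubjects number of subjects; default 15.
#' @param seed RNG seed.
#' @param sfreq sampling rate in Hz.
#' @param soa stimulus onset asynchrony in seconds.
#' @return data.frame with columns `subject`, `trial`, `position`,
#'   `theta`, `alpha`, `delta` (`NA` at position 1), `onset` (seconds).
#' @examples
#' d <- sampleDesign(nTrials = 2, nSubjects = 1, seed = 1)
#' head(d)
#' @export
sampleDesign <- function(nTrials = 672L, nSubjects = 15L, seed = NULL,
                         sfreq = 250, soa = 0.25) {
  stopifnot(nTrials >= 1L, nSubjects >= 1L)
  if (!is.null(seed)) set.seed(seed)
  nPos <- 8L
  out <- vector("list", nSubjects)
  for (s in seq_len(nSubjects)) {
    theta <- matrix(runif(nTrials * nPos, 0, pi), nTrials, nPos)
    delta <- cbind(NA_real_,
                   circularDelta(theta[, -1L, drop = FALSE],
                                 theta[, -nPos, drop = FALSE]))
    out[[s]] <- data.frame(
      subject = s,
      trial = rep(seq_len(nTrials), each = nPos),
      position = rep(seq_len(nPos), nTrials),
      theta = as.vector(t(theta)),
      alpha = 2 * as.vector(t(theta)),
      delta = as.vector(t(delta))
    )
  }
  res <- do.call(rbind, out)
  posOffsets <- floor((res$position - 1L) * soa * sfreq + 0.5)
  res$onset <- ((res$trial - 1L) * .trialStride(sfreq) +
                  .trialPreroll(sfreq) + posOffsets) / sfreq
  rownames(res) <- NULL
  res
}

# Samples before the first stimulus of a trial (covers the epoch pre-window).
.trialPreroll <- function(sfreq) as.integer(round(0.25 * sfreq))

# Per-trial block length in samples: pre-roll + 8 onsets spaced 250 ms +
# room for the response tail and the 1.25 s inter-trial interval.
.trialStride <- function(sfreq) {
  .trialPreroll(sfreq) + as.integer(floor(7 * 0.25 * sfreq + 0.5)) +
    as.integer(round(1.25 * sfreq)) + 1L
}

#' Decoding target matrix
#'
#' Assembles the three regression targets in the order (`delta`,
#' `sin(alpha)`, `cos(alpha)`). Rows with undefined delta (position 1) carry
#' `NA` in the delta column and are flagged by the `"deltaDefined"`
#' attribute; they are excluded when fitting the joint spatial filter.
#'
#' @param design a design table from [sampleDesign()] (or any data.frame
#'   with `alpha` and `delta` columns).
#' @return Numeric matrix `stimuli x 3` with attribute `deltaDefined`.
#' @export
targetMatrix <- function(design) {
  Y <- cbind(delta = design$delta, sin = sin(design$alpha),
             cos = cos(design$alpha))
  attr(Y, "deltaDefined") <- !is.na(design$delta)
  Y
}
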