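#' Random sensor projection for a synthetic subject
#'
#' Each subject observes the hierarchy's observable units through a fixed
#' random linear projection `F` (entries i.i.d. standard normal) onto noisy
#' virtual sensors. The source space has one copy of each level's observable
#' unit per stimulus feature dimension (delta, sin alpha, cos alpha), so `F`
#' is `nSensors x (3 * nLevels)`; rows of the source space are ordered
#' feature-major (all levels of the delta copy, then sin, then cos).
#'
#' @param nLevels hierarchy depth of the generating network.
#' @param nSensors number of virtual sensors (default 32).
#' @param noiseSd standard deviation of the i.i.d. Gaussian sensor noise
#'   added to every sample (default 1).
#' @param seed RNG seed; fixes the subject's projection.
#' @return list with elements `F` and `noiseSd`.
#' @export
makeTuning <- function(nLevels, nSensors = 32L, noiseSd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(F = matrix(rnorm(nSensors * 3L * nLevels), nSensors, 3L * nLevels),
       noiseSd = noiseSd)
}

#' Render a synthetic subject's continuous sensor recording
#'
#' For each stimulus, the network's per-level observable impulse profile
#' (input on for the stimulus duration, 58 samples = 233 ms at 250 Hz) is
#' amplitude-modulated by the stimulus' three feature values: `sin(alpha)`,
#' `cos(alpha)` and mean-centered `delta` (the position-1 delta term is set
#' to 0). Responses of successive stimuli superpose additively in source
#' space, are projected through the subject's random tuning `F`, and i.i.d.
#' Gaussian sensor noise is added.
#'
#' @param design design table ([sampleDesign()]) restricted to one subject.
#' @param net generating [NetworkSpec-class]; must be stable.
#' @param tuning subject tuning from [makeTuning()].
#' @param seed RNG seed for the sensor noise.
#' @param sfreq sampling rate (Hz).
#' @param stimSamples stimulus duration in samples (default 58).
#' @param profileSamples length of the rendered impulse profile (default 313
#'   samples = 1.25 s, matching the epoch reach).
#' @param inputRoles input coupling convention, see [stepState()].
#' @return list with `data` (`nSensors x nSamples` matrix), `events` (the
#'   design rows plus a `sample` column of 1-based onset indices), and
#'   `sfreq`.
#' @export
renderSubject <- function(design, net, tuning, seed = NULL, sfreq = 250,
                          stimSamples = 58L, profileSamples = 313L,
                          inputRoles = c("xy", "x")) {
  inputRoles <- match.arg(inputRoles)
  if (length(unique(design$subject)) != 1L)
    stop("design must contain exactly one subject; subset it first")
  tr <- simulateNetwork(net, stepInput(profileSamples, 0L, stimSamples, 1),
                        inputRoles)
  if (!isStable(tr))
    stop("refusing to render from an unstable network")
  L <- nLevels(net)
  xprof <- matrix(xTraces(tr), nrow = L)           # L x profileSamples
  dC <- design$delta - mean(design$delta, na.rm = TRUE)
  dC[is.na(dC)] <- 0                                # position-1 delta term
  feats <- cbind(dC, sin(design$alpha), cos(design$alpha))
  onsetIdx <- as.integer(round(design$onset * sfreq)) + 1L
  nTot <- max(onsetIdx) + profileSamples
  S <- matrix(0, 3L * L, nTot)
  lev <- seq_len(L)
  for (i in seq_along(onsetIdx)) {
    cols <- onsetIdx[i]:(onsetIdx[i] + profileSamples - 1L)
    block <- rbind(xprof * feats[i, 1L], xprof * feats[i, 2L],
                   xprof * feats[i, 3L])
    S[, cols] <- S[, cols] + block
  }
  X <- tuning$F %*% S
  if (tuning$noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    X <- X + matrix(rnorm(length(X), sd = tuning$noiseSd), nrow(X))
  }
  events <- design
  events$sample <- onsetIdx
  list(data = X, events = events, sfreq = sfreq)
}

#' Cut a continuous recording into stimulus- or sequence-locked epochs
#'
#' One epoch per oriented stimulus (time-locked to its onset; no baseline
#' correction), or one epoch per 8-item sequence (time-locked to the onset of
#' its first stimulus, with the per-trial design spread into wide columns
#' `theta1..theta8`, `alpha1..alpha8`, `delta1..delta8`).
#'
#' The window is inclusive of both endpoints at sample resolution: a window
#' of `(-0.25, 1)` s at 250 Hz gives `floor(1.25 * 250) + 1 = 313` samples.
#'
#' @param recording output of [renderSubject()].
#' @param window time window in seconds relative to the locking onset.
#' @param lockedTo `"stimulus"` or `"sequence"`.
#' @return A [SensorEpochs-class] object.
#' @export
epochStream <- function(recording, window = c(-0.25, 1),
                        lockedTo = c("stimulus", "sequence")) {
  lockedTo <- match.arg(lockedTo)
  sfreq <- recording$sfreq
  offsets <- seq(ceiling(window[1L] * sfreq),
                 length.out = floor((window[2L] - window[1L]) * sfreq) + 1L)
  times <- offsets / sfreq
  ev <- recording$events
  if (lockedTo == "sequence") {
    first <- ev[ev$position == 1L, , drop = FALSE]
    wide <- first[, c("subject", "trial", "onset", "sample"), drop = FALSE]
    for (p in 1:8) {
      rows <- ev[ev$position == p, , drop = FALSE]
      rows <- rows[match(wide$trial, rows$trial), , drop = FALSE]
      wide[[paste0("theta", p)]] <- rows$theta
      wide[[paste0("alpha", p)]] <- rows$alpha
      wide[[paste0("delta", p)]] <- rows$delta
    }
    ev <- wide
  }
  nEp <- nrow(ev)
  nSens <- nrow(recording$data)
  nTot <- ncol(recording$data)
  dat <- array(0, dim = c(nEp, nSens, length(offsets)))
  if (nEp) {
    for (i in seq_len(nEp)) {
      cols <- ev$sample[i] + offsets
      if (cols[1L] < 1L || cols[length(cols)] > nTot)
        stop(sprintf(
          "epoch window for event %d (trial %d) exceeds the recording bounds",
          i, ev$trial[i]))
      dat[i, , ] <- recording$data[, cols]
    }
  }
  rownames(ev) <- NULL
  new("SensorEpochs", data = dat, design = ev, times = times, sfreq = sfreq,
      lockedTo = lockedTo)
}

#' Simulate one synthetic subject end to end
#'
#' Convenience wrapper: random tuning, continuous rendering and epoching for
#' one subject of a design.
#'
#' @param design full design table from [sampleDesign()].
#' @param net generating [NetworkSpec-class].
#' @param subject subject id to render.
#' @param seed base seed; the tuning uses `seed` and the sensor noise
#'   `seed + 1`.
#' @param noiseSd sensor noise standard deviation.
#' @param window epoch window (seconds).
#' @param lockedTo `"stimulus"` or `"sequence"`, see [epochStream()].
#' @param ... further arguments passed to [renderSubject()].
#' @return A [SensorEpochs-class] object.
#' @export
simulateSubjectEpochs <- function(design, net, subject = 1L, seed = 1L,
                                  noiseSd = 1, window = c(-0.25, 1),
                                  lockedTo = "stimulus", ...) {
  sub <- design[design$subject == subject, , drop = FALSE]
  tun <- makeTuning(nLevels(net), noiseSd = noiseSd, seed = seed)
  rec <- renderSubject(sub, net, tun, seed = seed + 1L, ...)
  epochStream(rec, window = window, lockedTo = lockedTo)
}
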