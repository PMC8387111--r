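# OLS solve of (X'X) W = X'Y with a pseudo-inverse fallback for
# rank-deficient normal equations (e.g., noiseless low-rank sensor data).
.olsSolve <- function(XtX, XtY) {
  W <- tryCatch(solve(XtX, XtY), error = function(e) NULL)
  if (is.null(W))
    list(W = MASS::ginv(XtX) %*% XtY, pinv = TRUE)
  else
    list(W = W, pinv = FALSE)
}

#' Fit a per-time-sample spatial filter
#'
#' Ordinary least squares from sensors to the stimulus feature targets:
#' `W = (X'X)^-1 X'Y`. Rank-deficient normal equations are solved with the
#' Moore-Penrose pseudo-inverse (with a warning), which yields the least-norm
#' solution.
#'
#' @param X numeric `stimuli x sensors` matrix at one time sample.
#' @param Y numeric `stimuli x targets` matrix (see [targetMatrix()]).
#' @return `sensors x targets` coefficient matrix.
#' @export
fitSpatialFilter <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y))
  fit <- .olsSolve(crossprod(X), crossprod(X, Y))
  if (fit$pinv)
    warning("rank-deficient design; pseudo-inverse solution returned")
  W <- fit$W
  dimnames(W) <- list(colnames(X), colnames(Y))
  W
}

#' Apply a spatial filter to sensor data
#'
#' Computes `Yhat = X W`. The predicted angle `atan2(Yhat_sin, Yhat_cos)` is
#' attached as attribute `"alphaHat"`; by convention `atan2(0, 0)` is 0.
#'
#' @param X `stimuli x sensors` matrix.
#' @param W filter from [fitSpatialFilter()].
#' @return Predicted target matrix with attribute `alphaHat`.
#' @export
predictTargets <- function(X, W) {
  if (ncol(X) != nrow(W)) stop("X and W shapes do not conform")
  Yhat <- X %*% W
  attr(Yhat, "alphaHat") <- atan2(Yhat[, ncol(Yhat) - 1L], Yhat[, ncol(Yhat)])
  Yhat
}

#' Circular decoding scores
#'
#' `angularScore()` is the mean over trials of `pi/2 - |alphaTrue -
#' alphaHat|`, the circular absolute difference being wrapped to `[0, pi]`.
#' Perfect predictions score `pi/2`, maximally wrong ones `-pi/2`, and
#' predictions independent of the truth score 0 on average (chance level).
#' `deltaScore()` is Pearson's correlation between true and predicted
#' orientation changes, `NA` when either side has zero variance.
#'
#' @param alphaTrue,alphaHat angles in radians (full circle).
#' @return A scalar score.
#' @export
angularScore <- function(alphaTrue, alphaHat) {
  if (!length(alphaTrue)) stop("empty input")
  stopifnot(length(alphaTrue) == length(alphaHat))
  d <- abs((alphaTrue - alphaHat + pi) %% (2 * pi) - pi)
  mean(pi / 2 - d)
}

#' @rdname angularScore
#' @param deltaTrue,deltaHat orientation changes (delta-defined rows only).
#' @export
deltaScore <- function(deltaTrue, deltaHat) {
  if (!length(deltaTrue)) stop("empty input")
  if (stats::sd(deltaTrue) == 0 || stats::sd(deltaHat) == 0)
    return(NA_real_)
  stats::cor(deltaTrue, deltaHat)
}

#' Haufe pattern transform
#'
#' Converts a backward (decoding) model into the corresponding forward
#' (encoding) pattern: `P = cov(X) W cov(Yhat)^-1` with empirical
#' covariances. For OLS filters this equals the encoding coefficients
#' `X'Y (Y'Y)^-1` on the training set.
#'
#' @param W fitted spatial filter.
#' @param X training sensor data the filter was fitted on.
#' @param Yhat in-sample predictions `X W`.
#' @return `sensors x targets` pattern matrix.
#' @export
haufePattern <- function(W, X, Yhat) {
  covY <- stats::cov(Yhat)
  inv <- tryCatch(solve(covY), error = function(e) NULL)
  if (is.null(inv)) {
    warning("singular prediction covariance; pseudo-inverse used")
    inv <- MASS::ginv(covY)
  }
  stats::cov(X) %*% W %*% inv
}

#' Grouped cross-validation folds
#'
#' Partitions trials (8-item sequences) into `K` folds so that stimuli of
#' one sequence never appear in both the training and the testing set.
#'
#' @param trials vector of trial identifiers (one per trial, unique).
#' @param K number of folds.
#' @param seed RNG seed for the shuffle.
#' @return Named integer vector mapping trial id to fold.
#' @export
makeFolds <- function(trials, K = 5L, seed = NULL) {
  trials <- unique(trials)
  if (K > length(trials)) stop("K exceeds the number of trials")
  if (!is.null(seed)) set.seed(seed)
  shuffled <- sample(trials)
  fold <- rep(seq_len(K), length.out = length(shuffled))
  stats::setNames(fold[match(trials, shuffled)], trials)
}

# Extract a stimuli x sensors matrix at one time sample without dropping
# dimensions for single-row subsets.
.sliceT <- function(A, rows, t) {
  matrix(A[rows, , t], nrow = length(rows), ncol = dim(A)[2L])
}

# Shared engine for diagonal decoding and temporal generalization.
# Xarr: stimuli x sensors x time; Y: stimuli x 3 (delta, sin, cos);
# dd: delta-defined flags; trials: trial id per stimulus.
# Scores are pooled over out-of-fold predictions from all folds.
.cvDecodeCore <- function(Xarr, Y, dd, trials, K, seed, tg = FALSE) {
  nT <- dim(Xarr)[3L]
  m <- dim(Xarr)[2L]
  foldOf <- makeFolds(unique(trials), K, seed)
  stimFold <- foldOf[match(as.character(trials), names(foldOf))]
  anyDelta <- any(dd)
  fitCols <- if (anyDelta) 1:3 else 2:3
  alphaTrue <- atan2(Y[, 2L], Y[, 3L])
  angleSum <- if (tg) matrix(0, nT, nT) else numeric(nT)
  S1 <- S2 <- S11 <- if (tg) matrix(0, nT, nT) else numeric(nT)
  qTot <- 0
  nD <- 0
  dSum <- 0
  dSum2 <- 0
  usedPinv <- FALSE

  for (f in sort(unique(stimFold))) {
    testRows <- which(stimFold == f)
    trainRows <- which(stimFold != f & (dd | !anyDelta))
    Wstack <- matrix(0, m, length(fitCols) * nT)
    for (t in seq_len(nT)) {
      Xtr <- .sliceT(Xarr, trainRows, t)
      fit <- .olsSolve(crossprod(Xtr),
                       crossprod(Xtr, Y[trainRows, fitCols, drop = FALSE]))
      usedPinv <- usedPinv || fit$pinv
      Wstack[, (t - 1L) * length(fitCols) + seq_along(fitCols)] <- fit$W
    }
    aT <- alphaTrue[testRows]
    dT <- Y[testRows, 1L]
    ddT <- dd[testRows]
    qTot <- qTot + length(testRows)
    nD <- nD + sum(ddT)
    dSum <- dSum + sum(dT[ddT])
    dSum2 <- dSum2 + sum(dT[ddT]^2)
    nc <- length(fitCols)
    for (t2 in seq_len(nT)) {
      P <- .sliceT(Xarr, testRows, t2) %*%
        (if (tg) Wstack else Wstack[, (t2 - 1L) * nc + seq_len(nc),
                                    drop = FALSE])
      # columns grouped per training time as (delta,) sin, cos
      if (anyDelta) {
        sinIdx <- seq(2L, ncol(P), by = nc)
        dhat <- P[, seq(1L, ncol(P), by = nc), drop = FALSE]
      } else {
        sinIdx <- seq(1L, ncol(P), by = nc)
        dhat <- NULL
      }
      sh <- P[, sinIdx, drop = FALSE]
      ch <- P[, sinIdx + 1L, drop = FALSE]
      aH <- atan2(sh, ch)
      contrib <- colSums(pi / 2 - abs((aT - aH + pi) %% (2 * pi) - pi))
      if (tg) {
        angleSum[, t2] <- angleSum[, t2] + contrib
      } else {
        angleSum[t2] <- angleSum[t2] + contrib
      }
      if (anyDelta && sum(ddT)) {
        dh <- dhat[ddT, , drop = FALSE]
        dv <- dT[ddT]
        if (tg) {
          S1[, t2] <- S1[, t2] + colSums(dh)
          S2[, t2] <- S2[, t2] + colSums(dh^2)
          S11[, t2] <- S11[, t2] + colSums(dh * dv)
        } else {
          S1[t2] <- S1[t2] + sum(dh * 1)
          S2[t2] <- S2[t2] + sum(dh^2)
          S11[t2] <- S11[t2] + sum(dh * dv)
        }
      }
    }
  }
  if (usedPinv)
    warning("rank-deficient sensor data in at least one fold; ",
            "pseudo-inverse solutions used")
  angle <- angleSum / qTot
  if (anyDelta && nD > 1) {
    num <- S11 - S1 * dSum / nD
    den <- sqrt(pmax(S2 - S1^2 / nD, 0) * (dSum2 - dSum^2 / nD))
    deltaR <- num / den
    deltaR[!is.finite(deltaR)] <- NA_real_
  } else {
    deltaR <- angle * NA_real_
  }
  list(angle = angle, deltaR = deltaR, seed = seed, K = K)
}

#' Per-time-sample decoding with grouped cross-validation
#'
#' For every time sample, fits the joint spatial filter on the training
#' stimuli of each fold (pooled over sequence positions; rows with undefined
#' delta are excluded from the fit) and scores the pooled out-of-fold
#' predictions: the circular angular score for the stimulus angle and
#' Pearson's r for delta.
#'
#' @param epochs a stimulus-locked [SensorEpochs-class].
#' @param K number of folds (default 5).
#' @param seed RNG seed for the fold partition.
#' @return data.frame with columns `time`, `angleScore`, `deltaR`.
#' @export
crossvalDecode <- function(epochs, K = 5L, seed = 1L) {
  des <- epochs@design
  Y <- targetMatrix(des)
  res <- .cvDecodeCore(epochs@data, Y, attr(Y, "deltaDefined"), des$trial,
                       K, seed, tg = FALSE)
  data.frame(time = epochs@times, angleScore = res$angle,
             deltaR = res$deltaR)
}

#' Cross-validated encoding analysis
#'
#' Fits, per time sample, an OLS regression from the stimulus features to
#' each channel's voltage (`P = (Y'Y)^-1 Y' X`), and reports the Pearson
#' correlation between out-of-fold predicted and actual voltages, pooled
#' over folds, for each channel and time sample.
#'
#' @inheritParams crossvalDecode
#' @return `sensors x time` matrix of correlations (`NA` for zero-variance
#'   channels).
#' @export
encodeCrossval <- function(epochs, K = 5L, seed = 1L) {
  des <- epochs@design
  Y <- targetMatrix(des)
  dd <- attr(Y, "deltaDefined")
  Xarr <- epochs@data
  nT <- dim(Xarr)[3L]
  m <- dim(Xarr)[2L]
  foldOf <- makeFolds(unique(des$trial), K, seed)
  stimFold <- foldOf[match(as.character(des$trial), names(foldOf))]
  S1 <- S2 <- S11 <- T1 <- T2 <- matrix(0, m, nT)
  nTot <- 0
  for (f in sort(unique(stimFold))) {
    testRows <- which(stimFold == f & dd)
    trainRows <- which(stimFold != f & dd)
    nTot <- nTot + length(testRows)
    for (t in seq_len(nT)) {
      Ytr <- Y[trainRows, , drop = FALSE]
      B <- .olsSolve(crossprod(Ytr),
                     crossprod(Ytr, .sliceT(Xarr, trainRows, t)))$W
      Xhat <- Y[testRows, , drop = FALSE] %*% B        # nTest x m
      Xte <- .sliceT(Xarr, testRows, t)
      S1[, t] <- S1[, t] + colSums(Xhat)
      S2[, t] <- S2[, t] + colSums(Xhat^2)
      S11[, t] <- S11[, t] + colSums(Xhat * Xte)
      T1[, t] <- T1[, t] + colSums(Xte)
      T2[, t] <- T2[, t] + colSums(Xte^2)
    }
  }
  num <- S11 - S1 * T1 / nTot
  den <- sqrt(pmax(S2 - S1^2 / nTot, 0) * pmax(T2 - T1^2 / nTot, 0))
  r <- num / den
  r[!is.finite(r)] <- NA_real_
  r
}
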