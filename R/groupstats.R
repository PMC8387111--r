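#' Wilcoxon signed-rank test against chance
#'
#' Two-tailed signed-rank test of subject-level effects against 0, the
#' second-level test used for non-repeated analyses.
#'
#' @param effects numeric vector, one effect size per subject.
#' @return Two-tailed p-value.
#' @export
wilcoxonVsChance <- function(effects) {
  effects <- effects[!is.na(effects)]
  nz <- effects[effects != 0]
  if (length(nz) < 5L)
    stop("need at least 5 non-zero subject effects")
  stats::wilcox.test(nz, mu = 0, alternative = "two.sided")$p.value
}

# Contiguous clusters of suprathreshold points. mask: logical vector (1-D
# time axis) or matrix (2-D grid, 4-connectivity). Returns a list of index
# vectors.
.findClusters <- function(mask) {
  if (is.matrix(mask)) {
    lab <- matrix(0L, nrow(mask), ncol(mask))
    nxt <- 0L
    idx <- which(mask)
    for (i in idx) {
      if (lab[i] != 0L) next
      nxt <- nxt + 1L
      queue <- integer(sum(mask))
      queue[1L] <- i
      qlen <- 1L
      head <- 0L
      lab[i] <- nxt
      nr <- nrow(mask)
      nc <- ncol(mask)
      while (head < qlen) {
        head <- head + 1L
        cur <- queue[head]
        r <- (cur - 1L) %% nr + 1L
        cl <- (cur - 1L) %/% nr + 1L
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          rr <- r + d[1L]
          cc <- cl + d[2L]
          if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
            j <- (cc - 1L) * nr + rr
            if (mask[j] && lab[j] == 0L) {
              lab[j] <- nxt
              qlen <- qlen + 1L
              queue[qlen] <- j
            }
          }
        }
      }
    }
    if (nxt == 0L) return(list())
    split(which(lab != 0L), lab[lab != 0L])
  } else {
    r <- rle(as.vector(mask))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    lapply(keep, function(k) starts[k]:ends[k])
  }
}

#' Cluster-based sign-flip permutation test
#'
#' Nonparametric second-level test for repeated measurements (decoding
#' timecourses, temporal generalization matrices). A one-sample t statistic
#' is computed at every point, thresholded at the two-tailed
#' `alphaCluster` t-quantile, and contiguous suprathreshold points (1-D
#' adjacency along time, or 4-connectivity on a 2-D grid) form clusters
#' whose mass is the sum of t values. The null distribution of the maximum
#' absolute cluster mass is built by randomly flipping the sign of whole
#' subjects; each observed cluster gets
#' `p = (1 + #null >= observed) / (1 + nPerm)`. Positive and negative
#' clusters are formed separately and compared to the common max-|mass|
#' null, making the test two-tailed.
#'
#' @param effects `subjects x points` matrix, or a 3-D
#'   `subjects x rows x cols` array for 2-D grid adjacency.
#' @param adjacency `"time"` (1-D) or `"grid"` (2-D; required for 3-D
#'   input).
#' @param alphaCluster two-tailed cluster-forming alpha (default 0.05).
#' @param nPerm number of random sign flips (>= 100; default 1024).
#' @param seed RNG seed for the sign flips.
#' @return list of class `"ClusterResult"`: `clusters` (index vectors into
#'   the point axis/grid), `mass`, `p`, `sign`, plus `tValues`,
#'   `threshold`, `nPerm`, `seed`.
#' @export
clusterPermutation <- function(effects, adjacency = c("time", "grid"),
                               alphaCluster = 0.05, nPerm = 1024L,
                               seed = 1L) {
  adjacency <- match.arg(adjacency)
  if (nPerm < 100L) stop("nPerm must be at least 100")
  dims <- dim(effects)
  if (length(dims) == 3L) {
    if (adjacency != "grid")
      stop("3-D effects require adjacency = 'grid'")
    gridDim <- dims[2:3]
    X <- matrix(effects, dims[1L])
  } else {
    gridDim <- NULL
    X <- as.matrix(effects)
  }
  n <- nrow(X)
  if (n < 5L) stop("need at least 5 subjects for permutation inference")
  nP <- ncol(X)

  degenerate <- apply(X, 2L, stats::sd) == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance point(s) excluded from testing")
  }
  ssq <- colSums(X^2)
  tOf <- function(meanV) {
    varV <- (ssq - n * meanV^2) / (n - 1)
    tv <- meanV / sqrt(varV / n)
    tv[degenerate | !is.finite(tv)] <- 0
    tv
  }
  thr <- stats::qt(1 - alphaCluster / 2, df = n - 1L)

  maskify <- function(v) if (is.null(gridDim)) v else matrix(v, gridDim[1L])
  clusterMasses <- function(tv) {
    pos <- .findClusters(maskify(tv > thr))
    neg <- .findClusters(maskify(tv < -thr))
    list(pos = pos, neg = neg,
         massPos = vapply(pos, function(ix) sum(tv[ix]), numeric(1)),
         massNeg = vapply(neg, function(ix) sum(tv[ix]), numeric(1)))
  }

  tObs <- tOf(colMeans(X))
  obs <- clusterMasses(tObs)

  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n)
  permMeans <- (signs %*% X) / n
  nullMax <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    tv <- tOf(permMeans[b, ])
    cm <- clusterMasses(tv)
    nullMax[b] <- max(abs(c(cm$massPos, cm$massNeg, 0)))
  }

  clusters <- c(obs$pos, obs$neg)
  mass <- c(obs$massPos, obs$massNeg)
  sgn <- rep(c(1L, -1L), c(length(obs$pos), length(obs$neg)))
  pvals <- vapply(mass, function(m0)
    (1 + sum(nullMax >= abs(m0))) / (1 + nPerm), numeric(1))
  structure(list(clusters = clusters, mass = mass, p = pvals, sign = sgn,
                 tValues = maskify(tObs), threshold = thr, nPerm = nPerm,
                 seed = seed, gridDim = gridDim),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: %d cluster(s), threshold |t| > %.3f, %d permutations\n",
              length(x$clusters), x$threshold, x$nPerm))
  if (length(x$clusters)) {
    for (i in seq_along(x$clusters))
      cat(sprintf("  cluster %d: %d point(s), mass %.2f, p = %.4g\n",
                  i, length(x$clusters[[i]]), x$mass[i], x$p[i]))
  }
  invisible(x)
}

#' Decoding score versus stimulus distance
#'
#' Regresses per-position decoding scores on the stimulus distance (number
#' of intervening items) within each subject and tests the subject-level
#' slopes against 0 with the signed-rank test.
#'
#' @param scores `subjects x positions` matrix of scores (a single subject
#'   may be passed as a vector, in which case no group test is run).
#' @param distances stimulus distances, one per column of `scores`.
#' @return list with `slopes` (per subject), `meanSlope`, and `p` (`NA` for
#'   a single subject).
#' @export
scoreVsDistanceSlope <- function(scores, distances) {
  if (is.vector(scores)) scores <- matrix(scores, nrow = 1L)
  if (length(distances) != ncol(scores))
    stop("one distance per score column required")
  if (length(unique(distances)) < 2L) stop("distances are constant")
  if (length(distances) < 3L) stop("need at least 3 positions")
  slopes <- apply(scores, 1L, function(y) {
    ok <- !is.na(y)
    stats::coef(stats::lm(y[ok] ~ distances[ok]))[[2L]]
  })
  p <- if (length(slopes) >= 5L) wilcoxonVsChance(slopes) else NA_real_
  list(slopes = slopes, meanSlope = mean(slopes), p = p)
}
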