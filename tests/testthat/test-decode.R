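test_that("spatial filters solve the least-squares problem", {
  X <- diag(2)
  Y <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(unname(fitSpatialFilter(X, Y)), Y)

  set.seed(1)
  X <- matrix(rnorm(200), 50, 4)
  Y <- matrix(rnorm(150), 50, 3)
  expect_equal(unname(fitSpatialFilter(X, Y)), oracleOLS(X, Y),
               tolerance = 1e-10)

  # an all-zero target column yields the zero filter column
  Y0 <- Y
  Y0[, 2] <- 0
  expect_equal(unname(fitSpatialFilter(X, Y0)[, 2]), rep(0, 4))

  # rank-deficient sensors fall back to the pseudo-inverse with a warning
  Xr <- cbind(X, X[, 1])
  expect_warning(fitSpatialFilter(Xr, Y), "pseudo-inverse")
})

test_that("predictions are the matrix product with an atan2 angle", {
  set.seed(2)
  X <- matrix(rnorm(120), 30, 4)
  Y <- matrix(rnorm(90), 30, 3)
  W <- fitSpatialFilter(X, Y)
  P <- predictTargets(X, W)
  H <- X %*% solve(crossprod(X)) %*% crossprod(X, Y)  # hat-matrix oracle
  expect_equal(unname(P[, ]), unname(H), tolerance = 1e-10)
  expect_equal(attr(P, "alphaHat"), atan2(P[, 2], P[, 3]))
  # zero filter: predictions zero, angle falls back to 0
  P0 <- predictTargets(X, matrix(0, 4, 3))
  expect_true(all(P0 == 0))
  expect_true(all(attr(P0, "alphaHat") == 0))
  expect_error(predictTargets(X, matrix(0, 5, 3)), "conform")
})

test_that("a single sensor carrying the angle decodes it exactly", {
  alpha <- runif(50, -pi, pi)
  X <- cbind(sin(alpha), cos(alpha))
  W <- rbind(c(0, 1, 0), c(0, 0, 1))
  aHat <- attr(predictTargets(X, W), "alphaHat")
  expect_equal(aHat, alpha, tolerance = 1e-12)
})

test_that("the angular score has the documented extremes and chance level", {
  a <- runif(500, 0, 2 * pi)
  expect_equal(angularScore(a, a), pi / 2)
  expect_equal(angularScore(a, a + pi), -pi / 2)
  expect_error(angularScore(numeric(0), numeric(0)), "empty")
  # invariance to a common circular shift
  b <- runif(500, 0, 2 * pi)
  expect_equal(angularScore(a, b), angularScore(a + 1.3, b + 1.3))
  # Monte-Carlo chance level
  set.seed(4)
  n <- 1e5
  sc <- angularScore(runif(n, 0, 2 * pi), runif(n, 0, 2 * pi))
  sem <- pi / sqrt(12 * n)
  expect_lt(abs(sc), 3 * sem)
})

test_that("the delta score is a Pearson correlation with missing-value rules", {
  d <- runif(40, 0, pi / 2)
  expect_equal(deltaScore(d, d), 1)
  expect_equal(deltaScore(d, -d + 2), -1)
  pairs <- cbind(c(0.11, 0.52, 0.34, 1.20, 0.75, 0.98),
                 c(0.20, 0.61, 0.30, 1.10, 0.80, 1.02))
  num <- sum((pairs[, 1] - mean(pairs[, 1])) * (pairs[, 2] - mean(pairs[, 2])))
  den <- sqrt(sum((pairs[, 1] - mean(pairs[, 1]))^2) *
                sum((pairs[, 2] - mean(pairs[, 2]))^2))
  expect_equal(deltaScore(pairs[, 1], pairs[, 2]), num / den)
  expect_true(is.na(deltaScore(d, rep(1, 40))))
})

test_that("Haufe patterns equal the encoding coefficients for exact fits", {
  set.seed(6)
  X <- matrix(rnorm(500), 100, 5)
  X <- scale(X, scale = FALSE)
  B <- matrix(rnorm(15), 5, 3)
  Y <- X %*% B                      # exactly decodable targets
  W <- fitSpatialFilter(X, Y)
  P <- haufePattern(W, X, X %*% W)
  expect_equal(unname(P), unname(oracleEncoding(X, Y)), tolerance = 1e-8)
  # whitened sensors with identity prediction covariance: P equals W
  Q <- qr.Q(qr(scale(matrix(rnorm(400), 100, 4), scale = FALSE)))
  Xw <- sqrt(99) * Q
  Ww <- diag(4)[, 1:3]
  expect_equal(unname(haufePattern(Ww, Xw, Xw %*% Ww)), Ww,
               tolerance = 1e-10)
})

test_that("grouped folds partition trials without leakage", {
  f <- makeFolds(1:23, K = 5, seed = 1)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(length(f), 23L)
  expect_true(all(table(f) >= 4))
  expect_error(makeFolds(1:3, K = 5), "exceeds")
  # same seed, same partition
  expect_identical(f, makeFolds(1:23, K = 5, seed = 1))

  # duplicating a trial's epochs under its own id must not inflate scores
  ep <- smallEpochs(nTrials = 16, seed = 19, noiseSd = 2)
  sc <- crossvalDecode(ep, K = 4, seed = 5)
  dat <- epochData(ep)
  des <- designTable(ep)
  dup <- new("SensorEpochs",
             data = abind_rows(dat, dat), design = rbind(des, des),
             times = timePoints(ep), sfreq = samplingRate(ep),
             lockedTo = "stimulus")
  scDup <- crossvalDecode(dup, K = 4, seed = 5)
  expect_lt(max(scDup$angleScore) - max(sc$angleScore), 0.15)
})

test_that("label shuffling drives decoding to chance", {
  ep <- smallEpochs(nTrials = 20, seed = 23, noiseSd = 1)
  des <- designTable(ep)
  set.seed(7)
  perm <- sample(nrow(des))
  shuf <- new("SensorEpochs", data = epochData(ep),
              design = transform(des, theta = theta[perm],
                                 alpha = alpha[perm], delta = delta[perm]),
              times = timePoints(ep), sfreq = samplingRate(ep),
              lockedTo = "stimulus")
  sc <- crossvalDecode(shuf, K = 5, seed = 3)
  sem <- (pi / sqrt(12)) / sqrt(nrow(des))
  expect_true(all(abs(sc$angleScore) < 4 * sem))
})

test_that("decoding improves monotonically as sensor noise falls", {
  peaks <- vapply(c(4, 1, 0), function(ns) {
    ep <- suppressWarnings(smallEpochs(nTrials = 20, seed = 29, noiseSd = ns))
    max(suppressWarnings(crossvalDecode(ep, K = 5, seed = 3))$angleScore)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("cross-validated encoding recovers feature-driven channels", {
  set.seed(8)
  n <- 200
  trials <- rep(1:25, each = 8)
  alpha <- runif(n, 0, 2 * pi)
  delta <- c(NA, runif(n - 1, 0, pi / 2))
  des <- data.frame(subject = 1, trial = trials, position = rep(1:8, 25),
                    theta = alpha / 2, alpha = alpha, delta = delta)
  des$delta[des$position == 1] <- NA
  X <- array(rnorm(n * 3 * 2), c(n, 3, 2))
  X[, 1, 1] <- sin(alpha)                 # channel 1 codes the angle
  X[, 2, 1] <- 0.05 * rnorm(n)            # channel 2 is noise
  ep <- new("SensorEpochs", data = X, design = des, times = c(0, 0.004),
            sfreq = 250, lockedTo = "stimulus")
  r <- encodeCrossval(ep, K = 5, seed = 2)
  expect_gt(r[1, 1], 0.95)
  expect_lt(abs(r[2, 1]), 3 / sqrt(n))
})

test_that("encoder coefficients match the decoder's Haufe patterns", {
  set.seed(9)
  X <- scale(matrix(rnorm(600), 120, 5), scale = FALSE)
  B <- matrix(rnorm(15), 5, 3)
  Y <- X %*% B
  W <- fitSpatialFilter(X, Y)
  P <- haufePattern(W, X, X %*% W)
  enc <- t(oracleOLS(Y, X))               # (Y'Y)^-1 Y'X, transposed
  expect_equal(unname(P), unname(enc), tolerance = 1e-8)
})
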