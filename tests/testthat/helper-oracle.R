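# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: the simulator is a plain triple
# loop over the connection table, and the regression oracles are explicit
# matrix formulas.

oracleSimulate <- function(net, input, inputRoles = "xy") {
  conns <- connections(net)
  L <- nLevels(net)
  acts <- activations(net)
  f <- function(kind, z) {
    switch(kind,
           linear = z,
           relu = max(z, 0),
           satrelu = min(max(z, 0), 1),
           satlin = min(max(z, -1), 1))
  }
  nT <- input@nSamples
  x <- matrix(0, L, nT)
  y <- matrix(0, L, nT)
  for (t in 2:nT) {
    u <- if ((t - 2) >= input@onStart && (t - 2) < input@onEnd)
      input@amplitude else 0
    for (l in seq_len(L)) {
      zx <- 0
      zy <- 0
      for (r in seq_len(nrow(conns))) {
        srcLev <- l - conns$offset[r]
        val <- if (srcLev == 0) {
          if (conns$src[r] == "x" || inputRoles == "xy") u else 0
        } else if (srcLev >= 1 && srcLev <= L) {
          if (conns$src[r] == "x") x[srcLev, t - 1] else y[srcLev, t - 1]
        } else 0
        contrib <- conns$weight[r] * val
        if (conns$dst[r] == "x") zx <- zx + contrib else zy <- zy + contrib
      }
      x[l, t] <- f(acts[["x"]], zx)
      y[l, t] <- f(acts[["y"]], zy)
    }
  }
  list(x = x, y = y)
}

# explicit normal-equations OLS
oracleOLS <- function(X, Y) solve(t(X) %*% X) %*% t(X) %*% Y

# encoding coefficients (column-centered closed form)
oracleEncoding <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  t(Xc) %*% Yc %*% solve(t(Yc) %*% Yc)
}

randomStableNet <- function(nLevels = 3L, seed = 1, density = 0.4,
                            scale = 0.35,
                            activationX = "linear", activationY = "linear") {
  set.seed(seed)
  w <- round(runif(12, -1, 1), 2) * rbinom(12, 1, density) * scale
  new("NetworkSpec", nLevels = as.integer(nLevels), weights = w,
      activationX = activationX, activationY = activationY)
}

smallEpochs <- function(nTrials = 24, seed = 7, noiseSd = 1,
                        window = c(-0.1, 0.6), net = updatingHierarchy(),
                        lockedTo = "stimulus") {
  d <- sampleDesign(nTrials = nTrials, nSubjects = 1, seed = seed)
  simulateSubjectEpochs(d, net, 1, seed = seed + 100, noiseSd = noiseSd,
                        window = window, lockedTo = lockedTo)
}

# stack two stimuli x sensors x time arrays along the first axis
abind_rows <- function(a, b) {
  out <- array(0, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}
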