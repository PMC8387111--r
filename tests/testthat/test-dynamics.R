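test_that("activation functions implement the four monotone maps", {
  expect_equal(applyActivation("linear", 0.3), 0.3)
  expect_equal(applyActivation("relu", -0.5), 0)
  expect_equal(applyActivation("satlin", -2), -1)
  expect_equal(applyActivation("satrelu", c(-1, 0.4, 3)), c(0, 0.4, 1))
  expect_error(applyActivation("tanh", 1), "unknown activation")
  # monotone non-decreasing on a grid
  z <- seq(-3, 3, by = 0.1)
  for (k in c("linear", "relu", "satrelu", "satlin"))
    expect_true(all(diff(applyActivation(k, z)) >= 0))
})

test_that("stepState applies the synchronous update rule", {
  empty <- networkSpec(NULL, nLevels = 3)
  s0 <- matrix(1, 3, 2)
  expect_equal(unname(stepState(empty, s0, 5)), matrix(0, 3, 2))

  ff <- networkSpec(data.frame(src = "x", dst = "x", offset = 1, weight = 1),
                    nLevels = 3)
  nxt <- stepState(ff, matrix(0, 3, 2), 1)
  expect_equal(unname(nxt[, 1]), c(1, 0, 0))
  expect_equal(unname(nxt[, 2]), c(0, 0, 0))

  loop <- networkSpec(data.frame(src = c("x", "y"), dst = c("y", "x"),
                                 offset = c(0, 0), weight = c(1, -1)),
                      nLevels = 1)
  st <- matrix(c(1, 0), 1, 2)
  nxt <- stepState(loop, st, 0)
  expect_equal(unname(nxt), matrix(c(0, 1), 1, 2))
})

test_that("a feedforward chain is a pure delay line", {
  net <- feedforwardChain(5)
  inp <- stepInput(30, 3, 9)
  x <- xTraces(simulateNetwork(net, inp))
  u <- c(rep(0, 3), rep(1, 6), rep(0, 21))
  for (l in 1:5) {
    shifted <- c(rep(0, l), u)[1:30]
    expect_equal(unname(x[l, ]), shifted)
  }
  expect_true(isStable(simulateNetwork(net, inp)))
})

test_that("the empty network produces an all-zero stable trace", {
  tr <- simulateNetwork(networkSpec(NULL), stepInput())
  expect_true(all(tr@values == 0))
  expect_true(isStable(tr))
})

test_that("unbounded linear recurrence is flagged unstable", {
  net <- networkSpec(data.frame(src = c("x", "x"), dst = c("x", "x"),
                                offset = c(1, 0), weight = c(1, 1)))
  tr <- simulateNetwork(net, stepInput())
  expect_false(isStable(tr))
  expect_error(
    renderSubject(sampleDesign(2, 1, seed = 1), net,
                  makeTuning(10, seed = 1)),
    "unstable")
})

test_that("simulation agrees exactly with an independent scalar oracle", {
  for (seed in 1:12) {
    net <- randomStableNet(nLevels = 2L, seed = seed, scale = 1,
                           activationX = sample(c("linear", "satlin"), 1),
                           activationY = sample(c("linear", "relu",
                                                  "satrelu", "satlin"), 1))
    inp <- stepInput(50, 5, 20)
    for (roles in c("xy", "x")) {
      tr <- simulateNetwork(net, inp, inputRoles = roles)
      ref <- oracleSimulate(net, inp, inputRoles = roles)
      expect_identical(unname(xTraces(tr)), ref$x)
      expect_identical(unname(yTraces(tr)), ref$y)
    }
  }
})

test_that("compiled batch simulation matches the scalar path exactly", {
  inp <- stepInput()
  kinds <- c("linear", "relu", "satrelu", "satlin")
  set.seed(42)
  for (i in 1:20) {
    w <- round(runif(12, -1, 1), 2) * rbinom(12, 1, 0.35)
    ax <- sample(c("linear", "satlin"), 1)
    ay <- sample(kinds, 1)
    net <- new("NetworkSpec", nLevels = 10L, weights = w,
               activationX = ax, activationY = ay)
    tr <- simulateNetwork(net, inp)
    v1 <- validateModel(tr, inp)$valid && isStable(tr)
    v2 <- streamdyn:::.batchValidity(matrix(w, 1), ax, ay, 10L, inp)$valid
    expect_identical(v1, v2)
  }
})

test_that("linear dynamics obey superposition and time invariance", {
  net <- randomStableNet(nLevels = 4L, seed = 3, density = 0.6)
  a <- stepInput(80, 10, 25, amplitude = 1)
  b <- stepInput(80, 10, 25, amplitude = 0.6)
  ab <- stepInput(80, 10, 25, amplitude = 1.6)
  expect_equal(simulateNetwork(net, a)@values + simulateNetwork(net, b)@values,
               simulateNetwork(net, ab)@values, tolerance = 1e-12)
  # shifting the input shifts the trace
  sh <- 7L
  t1 <- simulateNetwork(net, stepInput(80, 10, 25))@values
  t2 <- simulateNetwork(net, stepInput(80, 10 + sh, 25 + sh))@values
  expect_equal(t2[, , (1 + sh):80], t1[, , 1:(80 - sh)], tolerance = 1e-12)
})

test_that("saturating activations bound every activity", {
  net <- randomStableNet(nLevels = 4L, seed = 9, density = 0.8, scale = 1,
                         activationX = "satlin", activationY = "satlin")
  v <- simulateNetwork(net, stepInput())@values
  expect_true(all(v >= -1 & v <= 1))
  net2 <- randomStableNet(nLevels = 4L, seed = 9, density = 0.8, scale = 1,
                          activationX = "satrelu", activationY = "satrelu")
  v2 <- simulateNetwork(net2, stepInput())@values
  expect_true(all(v2 >= 0 & v2 <= 1))
})

test_that("network specs round-trip through JSON", {
  net <- updatingHierarchy()
  path <- tempfile(fileext = ".json")
  writeNetworkSpec(net, path)
  back <- readNetworkSpec(path)
  expect_equal(back@weights, net@weights)
  expect_equal(nLevels(back), nLevels(net))
  expect_equal(activations(back), activations(net))
  expect_error(readNetworkSpec(tempfile()), "not found")
})

test_that("step input validates its window", {
  expect_error(stepInput(10, 5, 5), "onStart < onEnd")
  expect_error(stepInput(10, 5, 12), "onStart < onEnd")
  expect_silent(stepInput(10, 0, 10))
})
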