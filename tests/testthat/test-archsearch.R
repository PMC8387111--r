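test_that("onset detection follows the rise-to-positive-maximum rule", {
  inp <- stepInput(8, 0, 6)
  on <- detectOnset(c(0, 1, 2, 3, 3, 3, 3, 3), inp)
  expect_true(on$hasOnset)
  expect_equal(on$tM, 3)
  expect_equal(on$M, 3)
  expect_equal(on$tMl, 7)   # plateau: last attainment at the end

  expect_false(detectOnset(rep(0, 8), inp)$hasOnset)       # M not > 0
  expect_false(detectOnset(c(0, 2, 1, 3, 2, 0, 0, 0),
                           inp)$hasOnset)                  # non-monotone rise
  # maximum after input offset
  late <- detectOnset(c(0, 0, 0, 0, 0, 0, 1, 2), inp)
  expect_false(late$hasOnset)
})

test_that("offset detection requires a negative minimum with monotone recovery", {
  inp <- stepInput(8, 0, 4)
  off <- detectOffset(c(0, 1, 0, -2, -1, -0.5, -0.1, -0.05), inp)
  expect_true(off$hasOffset)
  expect_equal(off$tm, 3)
  expect_false(detectOffset(c(0, 1, 2, 2, 1, 0.5, 0.2, 0), inp)$hasOffset)
  expect_false(detectOffset(c(0, 1, -1, 0.5, -0.8, -0.1, 0, 0),
                            inp)$hasOffset)                # oscillating tail
})

test_that("half-life is the first crossing of half the maximum", {
  inp <- stepInput(10, 0, 6)
  s <- c(0, 2, 3, 4, 3, 2, 1, 0.5, -1, -0.5)
  on <- detectOnset(s, inp)
  off <- detectOffset(s, inp)
  expect_equal(halfLife(s, on, off), 2L)    # value 2 = M/2 two samples later

  s2 <- c(0, 4, 0, 0, 0, 0, 0, 0, -1, -0.5)
  expect_equal(halfLife(s2, detectOnset(s2, inp), detectOffset(s2, inp)), 1L)

  s3 <- c(0, 2, 3, 4, 3, 3.5, 1, 0.5, -1, -0.5)  # rebound during decay
  expect_true(is.na(halfLife(s3, detectOnset(s3, inp), detectOffset(s3, inp))))

  # strict mode rejects a plateau inside the decay
  s4 <- c(0, 2, 4, 3, 3, 2, 1, 0.5, -1, -0.5)
  expect_equal(halfLife(s4, detectOnset(s4, inp), detectOffset(s4, inp)), 3L)
  expect_true(is.na(halfLife(s4, detectOnset(s4, inp), detectOffset(s4, inp),
                             strict = TRUE)))
})

test_that("model validation accepts the discovered hierarchy and rejects degenerate models", {
  inp <- stepInput()
  expect_false(validateModel(simulateNetwork(networkSpec(NULL), inp),
                             inp)$valid)
  # pure feedforward chain: onsets everywhere under the literal reading, but
  # the minimum never goes negative, so it fails the offset criterion
  chTr <- simulateNetwork(feedforwardChain(), inp)
  ch <- validateModel(chTr, inp, criteria = "literal")
  expect_false(ch$valid)
  expect_true(all(ch$levels$hasOnset[1:5]))
  expect_false(any(ch$levels$hasOffset))
  expect_false(validateModel(chTr, inp)$valid)
  # the updating hierarchy passes, with increasing maintenance
  uh <- validateModel(simulateNetwork(updatingHierarchy(), inp), inp)
  expect_true(uh$valid)
  expect_true(all(diff(uh$levels$halfLife) >= 0))
  expect_gt(uh$levels$halfLife[10], uh$levels$halfLife[1])
  # unstable trace is invalid
  bad <- networkSpec(data.frame(src = c("x", "x"), dst = c("x", "x"),
                                offset = c(1, 0), weight = c(1, 1)))
  expect_false(validateModel(simulateNetwork(bad, inp), inp)$valid)
})

test_that("architecture enumeration counts sign patterns", {
  expect_equal(nrow(enumerateArchitectures(complexity = 0)), 1L)
  expect_equal(nrow(enumerateArchitectures(complexity = 1)), 24L)
  expect_equal(nrow(enumerateArchitectures(complexity = 2)),
               choose(12, 2) * 4L)
  a1 <- enumerateArchitectures(complexity = 1)
  expect_true(all(rowSums(a1 != 0) == 1))
})

test_that("model-count arithmetic matches the enumeration counter", {
  expect_equal(modelCount(1, gridSize = 2), 12 * 2 * 16)
  sr <- searchMinComplexity(weightGrid = c(-0.5, 0.5), maxK = 2L,
                            prune = FALSE)
  expect_equal(sr$modelsCovered, modelCount(1, 2) + modelCount(2, 2))
  expect_equal(sr$modelsSimulated, sr$modelsCovered)
})

test_that("pruning does not change the search outcome", {
  g <- c(-0.5, 0.5)
  a <- searchMinComplexity(weightGrid = g, maxK = 2L, prune = TRUE)
  b <- searchMinComplexity(weightGrid = g, maxK = 2L, prune = FALSE)
  expect_identical(a$kMin, b$kMin)
  expect_identical(a$found, b$found)
  expect_identical(a$architectures, b$architectures)
  expect_equal(a$modelsCovered, b$modelsCovered)
  expect_lt(a$modelsSimulated, b$modelsSimulated)
})

test_that("no single connection yields a valid model", {
  sr <- searchMinComplexity(weightGrid = c(-1, -0.5, 0.5, 1), maxK = 1L)
  expect_false(sr$found)
  expect_true(is.na(sr$kMin))
})

test_that("search results are deterministic and sign-consistent", {
  g <- c(-0.5, 0.5)
  a <- searchMinComplexity(weightGrid = g, maxK = 2L)
  b <- searchMinComplexity(weightGrid = g, maxK = 2L)
  expect_identical(a$architectures, b$architectures)
  expect_identical(a$modelsSimulated, b$modelsSimulated)
})

test_that("valid exemplars match their architecture sign pattern", {
  sr <- searchMinComplexity(weightGrid = c(-0.5, -0.25, 0.25, 0.5),
                            maxK = 4L)
  expect_true(sr$found)
  expect_equal(sr$kMin, 4L)
  for (i in seq_len(nrow(sr$architectures))) {
    ex <- sr$exemplars[[i]]
    expect_identical(unname(sign(ex@weights)),
                     as.numeric(sr$architectures[i, ]))
    inp <- stepInput()
    expect_true(validateModel(simulateNetwork(ex, inp), inp)$valid)
  }
})
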