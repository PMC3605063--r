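test_that("angular separation is the unsigned ring distance", {
  expect_equal(angularSeparation(1.0, 1.0), 0)
  expect_equal(angularSeparation(0.0, pi), pi)
  expect_equal(angularSeparation(0.1, 6.2), 2 * pi - 6.1, tolerance = 1e-12)
  ## symmetry
  a <- runif(20, 0, 2 * pi); b <- runif(20, 0, 2 * pi)
  expect_equal(angularSeparation(a, b), angularSeparation(b, a))
})

test_that("zone membership follows the symmetric/forward geometry", {
  ## symmetric zone of total width R: half-width R/2 each side, inclusive
  expect_true(inZone(0, 1L, 0.05, "symmetric", 0.2))
  expect_true(inZone(0, 1L, 0.1, "symmetric", 0.2))     # boundary inclusive
  expect_false(inZone(0, 1L, 0.11, "symmetric", 0.2))
  expect_true(inZone(0, 1L, 0, "symmetric", 0.2))       # coincident counts
  ## forward zone: (0, R] ahead of the heading only
  expect_false(inZone(0, 1L, -0.1, "forward", 0.2))     # 0.1 behind
  expect_true(inZone(0, 1L, 0.1, "forward", 0.2))
  expect_false(inZone(0, 1L, 0, "forward", 0.2))        # coincident excluded
  expect_true(inZone(0, -1L, -0.1, "forward", 0.2))     # CW heading reversed
  ## wrap-around: ACW focal at 6.2, other at 0.1 is 0.1832 rad ahead
  expect_true(inZone(6.2, 1L, 0.1, "forward", 0.2))
  expect_false(inZone(6.2, 1L, 0.1, "forward", 0.15))
  expect_error(inZone(0, 1L, 0.1, "global", 0.2), "symmetric")
})

test_that("neighbour counting covers global, topological and spatial zones", {
  ## 6 individuals, global: CW focal with 3 other CW and 2 ACW -> (2, 3)
  th <- seq(0, 2 * pi, length.out = 7)[1:6]
  or <- c(-1L, -1L, -1L, -1L, 1L, 1L)
  expect_equal(neighbourCounts(th, or, 1, "global"),
               c(nNeg = 2L, nPos = 3L))
  ## nearest-K with K = N - 1 equals global
  for (i in 1:6)
    expect_equal(neighbourCounts(th, or, i, "nearest", K = 5),
                 neighbourCounts(th, or, i, "global"))
  expect_error(neighbourCounts(th, or, 1, "nearest", K = 6), "K < N")
  ## symmetric zone geometry: one opposite individual at separation 0.09
  th2 <- c(0, 0.09, 0.15, -0.15, 0.5, 3)
  or2 <- c(1L, -1L, 1L, 1L, -1L, -1L)
  expect_equal(neighbourCounts(th2, or2, 1, "symmetric", R = 0.2),
               c(nNeg = 1L, nPos = 0L))
})

test_that("Markovian intensities match their closed forms", {
  expect_equal(intensityMarkov("MF", paramSet("MF", lambda0 = -7.5,
                                              wNeg = 0.76), c(5, 0)), -3.7)
  expect_equal(intensityMarkov("S3",
                               paramSet("S3", lambda0 = -7.5, wNeg = 1.72,
                                        wPos = 0.23, R = 0.2), c(1, 2)),
               -5.32)
  ## zero neighbours always gives the baseline
  for (id in c("Null", "MF", "T", "S1", "S4")) {
    ps <- presetParams(id)
    expect_equal(intensityMarkov(id, ps, c(0, 0)), -7.5)
  }
  expect_error(intensityMarkov("D3", presetParams("D3"), c(0, 0)),
               "memoryless")
})

test_that("memory traces decay geometrically after zone exit and reset on turns", {
  m <- modelSpec("D1")
  ps <- paramSet("D1", lambda0 = -7.5, wNeg = 1, R = 0.2, alpha = 0.92)
  mem <- emptyMemory(2, -7.5)
  ## neighbour in zone for one step, then gone: -6.5, -6.58, -6.6536, ...
  s1 <- intensityMemoryStep(m, ps, mem, negIn = 2L, posIn = integer(0))
  expect_equal(s1$lambda, -6.5)
  s2 <- intensityMemoryStep(m, ps, s1$mem, integer(0), integer(0))
  expect_equal(s2$lambda, -7.5 + 0.92)
  s3 <- intensityMemoryStep(m, ps, s2$mem, integer(0), integer(0))
  expect_equal(s3$lambda, -7.5 + 0.92^2)
  ## a turn erases accumulated memory
  s4 <- intensityMemoryStep(m, ps, s3$mem, integer(0), integer(0),
                            turned = TRUE)
  expect_equal(s4$lambda, -7.5)
  ## but currently in-zone neighbours still act at full weight after a turn
  s5 <- intensityMemoryStep(m, ps, s3$mem, negIn = 2L, posIn = integer(0),
                            turned = TRUE)
  expect_equal(s5$lambda, -6.5)
})

test_that("both memory dialects reduce exactly to the Markov model at alpha = 0", {
  set.seed(61)
  for (pair in list(c("D1", "S1"), c("D2", "S2"), c("D3", "S3"),
                    c("D4", "S4"))) {
    dm <- modelSpec(pair[1]); sm <- modelSpec(pair[2])
    base <- paramVector(presetParams(pair[2]))
    args <- as.list(base[!is.na(base)])
    dps <- do.call(paramSet, c(list(model = dm), args, alpha = 0))
    sps <- do.call(paramSet, c(list(model = sm), args))
    for (rep in 1:30) {
      N <- 5
      mems <- list(trace = emptyMemory(N, -7.5), aggregate = emptyMemory(N, -7.5))
      th <- runif(N, 0, 2 * pi); or <- sample(c(-1L, 1L), N, TRUE)
      for (step in 1:4) {
        th <- wrapAngle(th + rnorm(N, 0, 0.3))
        others <- 2:N
        inz <- others[inZone(th[1], or[1], th[others], dm@zone, dps@R)]
        negIn <- inz[or[inz] != or[1]]; posIn <- inz[or[inz] == or[1]]
        turned <- runif(1) < 0.3
        lamS <- intensityMarkov(sm, sps,
                                c(length(negIn), length(posIn)))
        for (dl in c("trace", "aggregate")) {
          r <- intensityMemoryStep(dm, dps, mems[[dl]], negIn, posIn,
                                   turned = turned, dialect = dl)
          mems[[dl]] <- r$mem
          expect_equal(r$lambda, lamS, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("the logistic link behaves as a probability map", {
  expect_equal(turnProbability(0), 0.5)
  expect_equal(turnProbability(-7.5), 1 / (1 + exp(7.5)), tolerance = 1e-12)
  lam <- seq(-10, 10, length.out = 41)
  expect_equal(turnProbability(lam) + turnProbability(-lam), rep(1, 41))
  expect_true(all(diff(turnProbability(lam)) > 0))
})

test_that("adding a negative neighbour never decreases the turn probability", {
  for (id in c("MF", "T", "S1", "S3")) {
    ps <- presetParams(id)
    for (n in 0:4) {
      l1 <- intensityMarkov(id, ps, c(n, 1))
      l2 <- intensityMarkov(id, ps, c(n + 1, 1))
      expect_gte(turnProbability(l2), turnProbability(l1))
    }
  }
})

test_that("intensities are invariant under rigid rotation of all positions", {
  set.seed(77)
  th <- runif(6, 0, 2 * pi); or <- sample(c(-1L, 1L), 6, TRUE)
  for (rot in c(0.5, 2.1, 5.9)) {
    th2 <- wrapAngle(th + rot)
    for (id in c("MF", "T", "S1", "S2", "S3", "S4")) {
      ps <- presetParams(id)
      for (i in 1:6)
        expect_equal(
          intensityMarkov(id, ps, neighbourCounts(th, or, i, modelSpec(id)@zone,
                                                  R = ps@R, K = ps@K)),
          intensityMarkov(id, ps, neighbourCounts(th2, or, i, modelSpec(id)@zone,
                                                  R = ps@R, K = ps@K)))
    }
  }
})

test_that("parameter sets enforce each model's parameter usage", {
  expect_error(paramSet("MF", lambda0 = -7.5), "requires parameter 'wNeg'")
  expect_error(paramSet("MF", lambda0 = -7.5, wNeg = 0.7, R = 0.2),
               "does not use")
  expect_error(paramSet("MF", lambda0 = -7.5, wNeg = -1), "wNeg")
  expect_error(paramSet("D1", lambda0 = -7.5, wNeg = 1, R = 0.2, alpha = 1),
               "alpha")
  ## the model table pins zone structure and flags
  d3 <- modelSpec("D3")
  expect_equal(d3@zone, "symmetric")
  expect_true(d3@usesPositive && d3@memory)
  expect_equal(modelParams("T"), c("lambda0", "wNeg", "K"))
  expect_length(modelIds(), 11)
})
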