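test_that("null-model likelihood matches its closed form", {
  p0 <- 1 / (1 + exp(7.5))
  ## one individual, 2 decision steps, no change
  rec <- orientationRecord(matrix(c(1L, 1L, 1L), ncol = 1), dt = 1 / 7.5)
  tr <- trialTrajectory(matrix(c(0, 0.1, 0.2), ncol = 1), frameRate = 7.5)
  ll <- logLikelihood(rec, tr, "Null", paramSet("Null", lambda0 = -7.5))
  expect_equal(as.numeric(ll), 2 * log(1 - p0), tolerance = 1e-12)
  ## one change in one step: log p = lambda - log(1 + e^lambda)
  rec2 <- orientationRecord(matrix(c(1L, -1L), ncol = 1), dt = 1 / 7.5)
  tr2 <- trialTrajectory(matrix(c(0, 0.1), ncol = 1), frameRate = 7.5)
  ll2 <- logLikelihood(rec2, tr2, "Null", paramSet("Null", lambda0 = -7.5))
  expect_equal(as.numeric(ll2), -7.5 - log(1 + exp(-7.5)), tolerance = 1e-12)
  expect_equal(as.numeric(ll2), log(p0), tolerance = 1e-12)
})

test_that("the total likelihood is invariant to trial order", {
  d <- simPair("MF", presetParams("MF"), 4, seed = 21, duration = 60)
  ps <- presetParams("MF")
  ll <- logLikelihood(d$recs, d$trs, "MF", ps)
  perm <- c(3, 1, 4, 2)
  expect_equal(as.numeric(logLikelihood(d$recs[perm], d$trs[perm], "MF", ps)),
               as.numeric(ll))
})

test_that("the compiled likelihood agrees with the plain-R intensity chain", {
  ## dual-route check on every model, small randomised configurations
  for (id in modelIds()) {
    cfg <- randomConfig(12, 4, seed = 500 + match(id, modelIds()))
    base <- paramVector(presetParams(id))
    args <- as.list(base[!is.na(base)])
    if ("K" %in% names(args)) args$K <- 2   # N = 4 here
    ps <- do.call(paramSet, c(list(model = id), args))
    for (dl in c("trace", "aggregate")) {
      if (!modelSpec(id)@memory && dl == "aggregate") next
      expect_equal(as.numeric(logLikelihood(cfg$rec, cfg$tr, id, ps,
                                            dialect = dl)),
                   referenceLogLik(cfg$rec, cfg$tr, id, ps, dialect = dl),
                   tolerance = 1e-10, label = paste(id, dl))
    }
  }
})

test_that("sufficient-statistic evaluation equals the generic kernel", {
  d <- simPair("MF", presetParams("MF"), 3, seed = 31, duration = 120)
  ## mean-field
  tab <- ringmotion:::.countTable(d$recs, d$trs, "global")
  for (w in c(0, 0.4, 0.76, 2)) {
    ps <- paramSet("MF", lambda0 = -7.5, wNeg = w)
    expect_equal(ringmotion:::.loglikFromTable(tab, -7.5, w),
                 as.numeric(logLikelihood(d$recs, d$trs, "MF", ps)),
                 tolerance = 1e-9)
  }
  ## topological, every K
  for (K in 1:5) {
    tabK <- ringmotion:::.countTable(d$recs, d$trs, "nearest", K)
    ps <- paramSet("T", lambda0 = -7.5, wNeg = 0.77, K = K)
    expect_equal(ringmotion:::.loglikFromTable(tabK, -7.5, 0.77),
                 as.numeric(logLikelihood(d$recs, d$trs, "T", ps)),
                 tolerance = 1e-9)
  }
})

test_that("no clamping occurs on simulator-generated data at matched dialects", {
  d <- simPair("D3", presetParams("D3"), 3, seed = 41, duration = 120)
  ll <- logLikelihood(d$recs, d$trs, "D3", presetParams("D3"))
  expect_equal(attr(ll, "clamped"), 0L)
})

test_that("the baseline estimate is the logit of the pooled change rate", {
  ## a change rate of 1/(1 + e^7.5) maps back to lambda0 = -7.5
  expect_equal(qlogis(1 / (1 + exp(7.5))), -7.5, tolerance = 1e-12)
  ## a record engineered to a known rate: 3 events in 19 steps
  st <- rep(1L, 20)
  for (k in c(5, 11, 16)) st[k:20] <- -st[k]
  rec <- orientationRecord(matrix(st, ncol = 1), dt = 1 / 7.5)
  expect_equal(estimateBaseline(rec), qlogis(3 / 19), tolerance = 1e-12)
  ## the general identity holds for any observed rate
  rec5 <- orientationRecord(matrix(rep(c(1L, 1L, -1L, -1L), 6), ncol = 1),
                            dt = 0.1)
  r5 <- sum(eventMatrix(rec5)) / length(eventMatrix(rec5))
  expect_equal(estimateBaseline(rec5), qlogis(r5), tolerance = 1e-12)
  ## doubling the data leaves the estimate unchanged
  expect_equal(estimateBaseline(list(rec, rec)), estimateBaseline(rec))
  ## no events -> informative error
  con <- orientationRecord(matrix(1L, 50, 1), dt = 0.1)
  expect_error(estimateBaseline(con), "no direction changes")
})

test_that("log priors integrate the declared supports", {
  pr <- priorSpec(-7.5, nAgents = 6, wMax = 5, rMax = 0.5)
  ## uniform density on wNeg
  expect_equal(logPrior(paramSet("MF", lambda0 = -7.5, wNeg = 2.5), pr, "MF"),
               -log(5))
  ## out-of-support R
  expect_equal(logPrior(paramSet("S1", lambda0 = -7.5, wNeg = 1, R = 0.7),
                        pr, "S1"), -Inf)
  ## discrete uniform over K in 1..5, on top of the wNeg density
  for (K in 1:5)
    expect_equal(logPrior(paramSet("T", lambda0 = -7.5, wNeg = 1, K = K),
                          pr, "T"), -log(5) - log(5))
  ## mismatched pinned baseline
  expect_equal(logPrior(paramSet("MF", lambda0 = -7, wNeg = 1), pr, "MF"),
               -Inf)
  ## D3: wNeg uniform, wPos uniform on [-wMax, wMax], R uniform, alpha unit
  expect_equal(logPrior(presetParams("D3"), pr, "D3"),
               -log(5) - log(10) - log(0.5))
})
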