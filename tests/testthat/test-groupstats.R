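test_that("polarisation and its binomial expectation match closed forms", {
  expect_equal(polarisation(6, 6), 1)
  expect_equal(polarisation(3, 6), 0)
  expect_equal(polarisation(4, 6), 1 / 3)
  expect_error(polarisation(7, 6), "c <= n")
  expect_equal(expectedRandomPolarisation(1), 1)
  expect_equal(expectedRandomPolarisation(2), 0.5)
  expect_equal(expectedRandomPolarisation(6), 0.3125)
  ## enumeration oracle for a larger group
  n <- 9
  x <- 0:n
  expect_equal(expectedRandomPolarisation(n),
               sum(choose(n, x) / 2^n * abs(2 * x - n) / n))
})

test_that("excess polarisation subtracts the random expectation", {
  ## all trials fully aligned always, n = 6 -> constant 1 - 0.3125
  aligned <- orientationRecord(matrix(-1L, 30, 6), dt = 0.1)
  ep <- excessPolarisationSeries(list(aligned, aligned))
  expect_equal(ep, rep(0.6875, 30))
  ## single individual -> identically 0
  one <- orientationRecord(matrix(1L, 30, 1), dt = 0.1)
  expect_equal(excessPolarisationSeries(one), rep(0, 30))
  ## i.i.d. fair orientations at every frame -> near zero everywhere
  set.seed(88)
  recs <- lapply(1:2000, function(i)
    orientationRecord(matrix(sample(c(-1L, 1L), 12, TRUE), 2, 6), dt = 0.1))
  expect_lt(max(abs(excessPolarisationSeries(recs))), 0.03)
})

test_that("final outcomes average the closing window and round half up", {
  ## constant C = 6 puts all mass on category 6
  all6 <- orientationRecord(matrix(-1L, 150, 6), dt = 0.1)
  od <- finalOutcomeDistribution(list(all6), window = 10)
  expect_equal(outcomeProportions(od), c(0, 0, 0, 0, 0, 0, 1))
  ## C alternating 5, 6 over the window: mean 5.5 rounds up to 6
  st <- matrix(-1L, 151, 6)
  st[seq(1, 151, by = 2), 6] <- 1L   # individual 6 flips every frame
  alt <- orientationRecord(st, dt = 0.1)
  odAlt <- finalOutcomeDistribution(list(alt), window = 10)
  expect_equal(which(outcomeProportions(odAlt) == 1) - 1, 6)
  ## short trials are rejected
  expect_error(finalOutcomeDistribution(
    list(orientationRecord(matrix(1L, 10, 2), dt = 0.1)), window = 10),
    "shorter")
})

test_that("KL divergence matches direct evaluation and Gibbs' inequality", {
  two <- function(p, m = 100) outcomeDistribution(1, p, m)
  expect_equal(klDivergence(two(c(0.5, 0.5)), two(c(0.5, 0.5))), 0)
  expect_equal(klDivergence(two(c(0.5, 0.5)), two(c(0.25, 0.75))),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  set.seed(17)
  for (rep in 1:200) {
    p <- rexp(7); p <- p / sum(p)
    q <- rexp(7); q <- q / sum(q)
    expect_gte(klDivergence(outcomeDistribution(6, p, 50),
                            outcomeDistribution(6, q, 50)), 0)
  }
  ## zero simulated mass is smoothed, keeping the divergence finite
  p <- outcomeDistribution(2, c(0.5, 0.25, 0.25), 40)
  q <- outcomeDistribution(2, c(1, 0, 0), 200)
  expect_true(is.finite(klDivergence(p, q)))
})

test_that("the G-test scales the divergence and uses an n-df chi-squared tail", {
  two <- function(p, m) outcomeDistribution(1, p, m)
  ## identical distributions: G = 0, p = 1
  g0 <- gTest(two(c(0.3, 0.7), 25), two(c(0.3, 0.7), 1000))
  expect_equal(g0@G, 0)
  expect_equal(g0@p, 1)
  ## m = 10, KL = 0.1438 nats, 2 categories -> G = 2.877, p = 0.0899
  g <- gTest(two(c(0.5, 0.5), 10), two(c(0.25, 0.75), 1000))
  expect_equal(g@G, 20 * (0.5 * log(2) + 0.5 * log(2 / 3)), tolerance = 1e-12)
  expect_equal(g@G, 2.877, tolerance = 1e-3)
  expect_equal(g@df, 1)
  expect_equal(g@p, pchisq(2.877, 1, lower.tail = FALSE), tolerance = 1e-3)
  expect_equal(round(g@p, 4), 0.0899, tolerance = 2e-4)
})

test_that("steps without an opposite-facing individual are excluded from the curve", {
  ## two individuals, same orientation throughout: no curve at all
  rec <- orientationRecord(matrix(1L, 20, 2), dt = 0.1)
  tr <- trialTrajectory(matrix(runif(40, 0, 2 * pi), 20, 2), frameRate = 10)
  expect_warning(curve <- turnFrequencyVsNearestOpponent(rec, tr),
                 "no opposite-facing")
  expect_equal(nrow(curve), 0)
  ## mixed orientations: pooled counts equal the number of (step, focal)
  ## pairs that see at least one opponent
  st <- cbind(rep(1L, 20), rep(-1L, 20), c(rep(1L, 10), rep(-1L, 10)))
  rec2 <- orientationRecord(st, dt = 0.1)
  tr2 <- trialTrajectory(matrix(runif(60, 0, 2 * pi), 20, 3), frameRate = 10)
  curve2 <- turnFrequencyVsNearestOpponent(rec2, tr2)
  expect_equal(sum(curve2$count), 19 * 3)  # every focal always has an opponent
})

test_that("validateModel with one set reports that set's G-test", {
  d <- simPair("Null", paramSet("Null", lambda0 = -7.5), 30, seed = 19,
               duration = 60)
  od <- finalOutcomeDistribution(d$recs)
  v <- validateModel(od, "Null", paramSet("Null", lambda0 = -7.5),
                     duration = 60, nSets = 1, setSize = 40, seed = 4)
  expect_length(v$tests, 1)
  expect_equal(v$medianP, v$p[1])
  expect_identical(v$consistent, unname(v$medianP > 0.05))
})

test_that("validation separates matched from badly mismatched models", {
  ## the experimental distribution concentrated at C = n is inconsistent
  ## with null simulations
  odExtreme <- outcomeDistribution(6, c(0, 0, 0, 0, 0, 0, 1), 50)
  v <- validateModel(odExtreme, "Null", paramSet("Null", lambda0 = -7.5),
                     duration = 60, nSets = 3, setSize = 50, seed = 8)
  expect_lt(v$medianP, 1e-6)
  expect_false(v$consistent)
})
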