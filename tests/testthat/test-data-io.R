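test_that("trajectory CSV reading wraps angles, densifies ids and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(trial_id = "a", time_s = c(0, 1 / 7.5),
                   prawn_id = 3, theta_rad = c(0.0, 0.1))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  trs <- readTrajectories(path)
  expect_length(trs, 1)
  expect_equal(nFrames(trs[[1]]), 2)
  expect_equal(nPrawns(trs[[1]]), 1)
  expect_equal(frameRate(trs[[1]]), 7.5, tolerance = 1e-9)

  ## angles outside [0, 2*pi) are wrapped: 6.38 -> 6.38 - 2*pi
  df$theta_rad <- c(6.38, 0.1)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  trs <- readTrajectories(path)
  expect_equal(thetaMatrix(trs[[1]])[1, 1], 6.38 - 2 * pi, tolerance = 1e-12)

  ## write -> read round trip
  out <- withr::local_tempfile(fileext = ".csv")
  writeTrajectories(trs, out)
  back <- readTrajectories(out)
  expect_equal(thetaMatrix(back[[1]]), thetaMatrix(trs[[1]]),
               ignore_attr = TRUE)
})

test_that("malformed trajectory files are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  ## missing column
  write.csv(data.frame(trial_id = "a", time_s = 0, prawn_id = 0), path,
            row.names = FALSE)
  expect_error(readTrajectories(path), "missing column")
  ## a prawn present at t = 0 only
  write.csv(data.frame(trial_id = "a", time_s = c(0, 1, 0),
                       prawn_id = c(0, 0, 1), theta_rad = c(0, 0.1, 0.2)),
            path, row.names = FALSE)
  expect_error(readTrajectories(path), "missing cell.*trial 'a'.*time 1")
  ## non-uniform spacing beyond tolerance
  write.csv(data.frame(trial_id = "a", time_s = c(0, 1, 2.5),
                       prawn_id = 0, theta_rad = c(0, 0.1, 0.2)),
            path, row.names = FALSE)
  expect_error(readTrajectories(path), "non-uniform")
})

test_that("downsampling keeps even-index frames and composes multiplicatively", {
  tr <- trialTrajectory(matrix(seq(0, 3, length.out = 100), ncol = 1),
                        frameRate = 15, trialId = "x")
  d2 <- downsample(tr, 2)
  expect_equal(frameRate(d2), 7.5)
  expect_equal(nFrames(d2), 50)
  expect_equal(thetaMatrix(d2)[, 1], thetaMatrix(tr)[seq(1, 100, 2), 1])
  ## identity at factor 1
  expect_equal(downsample(tr, 1), tr)
  ## T = 10, factor 3 keeps 0-based frames {0, 3, 6, 9}
  t10 <- trialTrajectory(matrix(seq_len(10) / 10, ncol = 1), frameRate = 15)
  d3 <- downsample(t10, 3)
  expect_equal(nFrames(d3), 4)
  expect_equal(thetaMatrix(d3)[, 1], thetaMatrix(t10)[c(1, 4, 7, 10), 1])
  ## composition: down(down(x, a), b) == down(x, a * b)
  tr2 <- trialTrajectory(matrix(runif(120, 0, 2 * pi), ncol = 2),
                         frameRate = 30)
  expect_equal(thetaMatrix(downsample(downsample(tr2, 2), 3)),
               thetaMatrix(downsample(tr2, 6)))
  expect_error(downsample(tr, 0), "factor")
})

test_that("orientation CSV serialisation is a bit-exact round trip", {
  rec <- orientationRecord(matrix(c(1L, 1L, -1L, -1L, 1L, 1L,
                                    -1L, 1L, 1L, -1L, -1L, -1L), ncol = 2),
                           dt = 1 / 7.5, trialId = "t1")
  path <- withr::local_tempfile(fileext = ".csv")
  writeOrientations(rec, path)
  back <- readOrientations(path)
  expect_length(back, 1)
  expect_identical(stateMatrix(back[[1]]), stateMatrix(rec))
  expect_identical(eventMatrix(back[[1]]), eventMatrix(rec))
  expect_equal(back[[1]]@dt, rec@dt, tolerance = 1e-9)

  ## empty list gives a header-only file
  writeOrientations(list(), path)
  expect_equal(nrow(read.csv(path)), 0)

  ## unknown state labels rejected
  writeLines(c("trial_id,time_s,prawn_id,state,event",
               "a,0,0,UP,0", "a,0.5,0,CW,0"), path)
  expect_error(readOrientations(path), "state")
})

test_that("angle wrapping is idempotent and displacement wrapping is signed", {
  x <- c(-10, -pi, 0, 0.1, 2 * pi, 6.38, 100)
  expect_equal(wrapAngle(wrapAngle(x)), wrapAngle(x))
  expect_true(all(wrapAngle(x) >= 0 & wrapAngle(x) < 2 * pi))
  ## displacement examples: forward step, wrap-around step, no movement
  tr <- trialTrajectory(matrix(c(0.10, 0.15, 0.05, 6.25, 1, 1), nrow = 2),
                        frameRate = 7.5)
  d <- displacements(tr)
  expect_equal(d[1, 1], 0.05, tolerance = 1e-12)
  expect_equal(d[1, 2], (6.25 - 0.05 + pi) %% (2 * pi) - pi,
               tolerance = 1e-12)
  expect_lt(d[1, 2], 0)    # shorter way round is backwards
  expect_equal(d[1, 3], 0)
})

test_that("orientation events are exactly the finite difference of states", {
  st <- matrix(sample(c(-1L, 1L), 60, replace = TRUE), ncol = 3)
  rec <- orientationRecord(st, dt = 0.1)
  expect_identical(eventMatrix(rec),
                   (st[-1, ] != st[-nrow(st), ]) * 1L)
  ## and the class rejects hand-tampered events
  bad <- rec
  bad@events[1, 1] <- 1L - bad@events[1, 1]
  expect_error(validObject(bad), "finite difference")
})
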