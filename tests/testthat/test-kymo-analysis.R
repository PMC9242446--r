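# Kymograph procedures on constructed and generated fixtures.

test_that("movie collapse integrates 11 pixels across the DNA axis", {
  movie <- array(1, c(4, 20, 30))
  movie[2, 10, 5] <- 100
  k <- collapseToKymograph(movie, axisRow = 10)
  expect_equal(dim(channel(k, "DNA")), c(4, 30))
  expect_equal(channel(k, "DNA")[1, 1], 11)       # 11-pixel band of ones
  expect_equal(channel(k, "DNA")[2, 5], 110)      # 10 ones + the spike
})

test_that("preprocessing removes background and keeps point emitters", {
  const <- kymograph(list(ParB = matrix(7, 40, 50)))
  out <- preprocessKymograph(const)
  expect_true(all(channel(out, "ParB") == 0))
  spot <- matrix(5, 60, 50)
  spot[25:27, 24:26] <- spot[25:27, 24:26] + c(40, 80, 40)
  k <- kymograph(list(ParB = spot))
  filtered <- channel(preprocessKymograph(k), "ParB")
  peak <- which(filtered == max(filtered), arr.ind = TRUE)[1, ]
  expect_lte(abs(peak[["row"]] - 26), 1)
  expect_lte(abs(peak[["col"]] - 25), 1)
  # approximate idempotence of the tophat on a background-free sparse image
  th1 <- channel(preprocessKymograph(k, medianRadius = 0), "ParB")
  th2 <- channel(preprocessKymograph(kymograph(list(ParB = th1)),
                                     medianRadius = 0), "ParB")
  expect_lt(max(abs(th2 - th1)), 0.05 * max(th1))
  expect_error(preprocessKymograph(kymograph(list(P = matrix(1, 4, 4)))),
               "smaller than")
})

test_that("relative loading position follows the end-normalized formula", {
  tr <- spotTrace(1:20, rep(30, 20))
  expect_equal(relativeLoadingPosition(tr, 10, 50), 0.5)
  trEnd <- spotTrace(1:20, rep(50, 20))
  expect_equal(relativeLoadingPosition(trEnd, 10, 50), 0)
  # only the first full second enters the average
  trMove <- spotTrace(1:30, c(rep(30, 10), rep(46, 20)))
  expect_equal(relativeLoadingPosition(trMove, 10, 50, 0.1), 0.5)
  short <- spotTrace(1:5, rep(30, 5))
  expect_error(relativeLoadingPosition(short, 10, 50, 0.1), "one second")
  expect_error(relativeLoadingPosition(tr, 50, 10), "exceed")
})

test_that("residence times convert trace spans to seconds", {
  tr <- spotTrace(1:760, rep(20, 760))
  dw <- residenceTimes(list(tr), 0.1)
  expect_equal(dwellTimes(dw), 76)
  expect_equal(frameTime(dw), 0.1)
  empty <- residenceTimes(list(), 0.1)
  expect_length(dwellTimes(empty), 0)
})

test_that("tracker recovers a noiseless scripted trace to sub-pixel RMS", {
  set.seed(15)
  path <- 30 + cumsum(rnorm(400, 0, 0.6))
  path <- 8 + abs((path - 8) %% 88 - 44)   # reflect into [8, 52]
  k <- spotKymograph(path)
  tr <- trackKymograph(k, threshold = 10)
  expect_length(tr, 1)
  expect_equal(length(traceFrames(tr[[1]])), 400)
  rms <- sqrt(mean((tracePositions(tr[[1]]) - path)^2))
  expect_lt(rms, 0.25)
})

test_that("recruitment detection needs both the step and the split", {
  k <- kymograph(list(ParB = matrix(0, 500, 60)))   # calibration carrier
  # recruiter with an intensity doubling at frame 200, split at frame 280
  intens <- c(rep(100, 199), rep(205, 101), rep(100, 200))
  a <- spotTrace(1:500, rep(20, 500), intens)
  b <- spotTrace(280:420, rep(21, 141), rep(100, 141))
  ev <- detectRecruitment(list(a, b), k)
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$frame - 200), 3)
  expect_lt(abs(ev$positionPx - 20) * 110, 300)
  # crossing traces without any intensity increase: no event
  c1 <- spotTrace(1:300, seq(10, 40, length.out = 300), rep(100, 300))
  c2 <- spotTrace(50:300, seq(40, 10, length.out = 251), rep(100, 251))
  expect_equal(nrow(detectRecruitment(list(c1, c2), k)), 0)
})

test_that("scripted recruitment on a rendered movie is found within 3 frames", {
  sc <- data.frame(tStart = c(5, 30), posFrac = c(NA, NA),
                   dwell = c(80, 40), D = c(0.02, 0.02),
                   recruitFrom = c(NA, 1), conjunct = c(NA, 8))
  out <- renderKymograph(sceneSpec(script = sc, nFrames = 1000, seed = 4))
  tr <- trackKymograph(out$kymo, maxLinkNm = 450, maxGap = 4)
  ev <- detectRecruitment(tr, out$kymo)
  truth <- out$truth$events
  expect_gt(nrow(ev), 0)
  hit <- which.min(abs(ev$frame - truth$frame[1]))
  expect_lte(abs(ev$frame[hit] - truth$frame[1]), 3)
  truthPx <- truth$posNm[1] / 110 + out$truth$xStartPx
  expect_lt(abs(ev$positionPx[hit] - truthPx) * 110, 300)
})

test_that("roadblock localization is robust, tie-broken and guarded", {
  set.seed(16)
  prof <- matrix(rnorm(400 * 80, 10, 2), 400, 80)
  prof <- prof + outer(rep(1, 400), 10 * exp(-(seq_len(80) - 40)^2 / 8))
  k <- kymograph(list(roadblock = pmax(prof, 0)))
  expect_lt(abs(locateRoadblock(k) - 40), 1)
  twin <- matrix(1, 30, 40)
  twin[, 12] <- twin[, 30] <- 5
  kTwin <- kymograph(list(roadblock = twin))
  expect_warning(pos <- locateRoadblock(kTwin), "tie")
  expect_lt(pos, 20)
  flat <- kymograph(list(roadblock = matrix(3, 30, 40)))
  expect_error(locateRoadblock(flat), "flat")
  expect_error(locateRoadblock(kymograph(list(roadblock = matrix(1, 5, 5)))),
               "positions")
})

test_that("arm intensities separate blocked and bypass scenarios", {
  zero <- kymograph(list(ParB = matrix(0, 400, 60)))
  ai0 <- armIntensities(zero, 40, 150, parsPx = 20)
  expect_true(all(ai0$parS == 0) && all(ai0$far == 0))
  expect_error(armIntensities(zero, 40, 50, parsPx = 20), "pre-binding")

  d <- withr::local_tempdir()
  makeFixtureSuite(d, seed = 1)
  kb <- readKymographTiff(file.path(d, "blocked.yaml"))
  tb <- jsonlite::read_json(file.path(d, "blocked_truth.json"))
  aiB <- armIntensities(kb, locateRoadblock(kb), 150, parsPx = tb$parsPx)
  # far side carries no signal: flat at ~0 relative to the parS side
  expect_lt(abs(mean(aiB$far)), 0.05 * mean(aiB$parS))
  kp <- readKymographTiff(file.path(d, "bypass.yaml"))
  tp <- jsonlite::read_json(file.path(d, "bypass_truth.json"))
  aiP <- armIntensities(kp, locateRoadblock(kp), 150, parsPx = tp$parsPx)
  # bypass: the far side shows a discrete step well above the blocked level
  expect_gt(quantile(aiP$far, 0.9), 20 * max(1, abs(mean(aiB$far))))
})

test_that("profile decomposition selects one or two Gaussian components", {
  x <- seq_len(60)
  one <- recruitmentProfileComponents(exp(-(x - 25)^2 / 8))
  expect_equal(one$nComponents, 1)
  expect_lt(abs(one$means - 25), 0.5)
  two <- recruitmentProfileComponents(exp(-(x - 25)^2 / 8) +
                                      exp(-(x - 35)^2 / 8))
  expect_equal(two$nComponents, 2)
  expect_equal(sort(two$means), c(25, 35), tolerance = 0.02)
  sym <- recruitmentProfileComponents(exp(-(x - 24)^2 / 8) +
                                      exp(-(x - 36)^2 / 8))
  expect_lt(abs(mean(sym$means) - 30), 0.5)
  expect_error(recruitmentProfileComponents(rep(1, 40)), "degenerate")
  expect_error(recruitmentProfileComponents(1:5), "at least 10")
})
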