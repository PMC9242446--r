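# Synthetic-kymograph generator: determinism, ground truth, photophysics.

test_that("rendering is deterministic under a fixed seed", {
  spec <- sceneSpec(nMolecules = 3, seed = 12, nFrames = 400)
  a <- renderKymograph(spec)
  b <- renderKymograph(spec)
  expect_identical(a$kymo@channels, b$kymo@channels)
  expect_identical(a$truth$dwells, b$truth$dwells)
  spec2 <- sceneSpec(nMolecules = 3, seed = 13, nFrames = 400)
  expect_false(identical(renderKymograph(spec2)$kymo@channels,
                         a$kymo@channels))
})

test_that("ground-truth positions match the rendered intensity", {
  sc <- data.frame(tStart = 2, posFrac = 0.5, dwell = 25, D = 0.01,
                   recruitFrom = NA)
  out <- renderKymograph(sceneSpec(script = sc, nFrames = 300, seed = 3,
                                   peakPhotons = 3000, background = 1,
                                   readNoise = 0))
  tr <- trackKymograph(out$kymo, maxLinkNm = 450)
  expect_length(tr, 1)
  truth <- out$truth$traces[[1]]
  common <- intersect(traceFrames(tr[[1]]), truth$frame)
  dev <- tracePositions(tr[[1]])[match(common, traceFrames(tr[[1]]))] -
    truth$posPx[match(common, truth$frame)]
  expect_lt(sqrt(mean(dev^2)), 0.25)
})

test_that("stochastic-mode dwells follow the delayed-release law", {
  spec <- sceneSpec(nMolecules = 500, seed = 31)
  set.seed(spec@seed)
  sim <- ParBspread:::.simulateSceneTraces(spec)
  dw <- dwellSample(sim$dwells, frameTime = 0.1)
  f <- fitDwellModel(dw, "delayed", kBlFixed = 1.75e-4, seed = 1)
  ci <- confint68(f)
  expect_lt(abs(rates(f)@kCtp - 0.025), 3 * (ci[1, 2] - ci[1, 1]) / 2)
  expect_lt(abs(rates(f)@kOff - 0.06), 3 * (ci[2, 2] - ci[2, 1]) / 2)
})

test_that("fixture suite is deterministic, hashed and readable", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- makeFixtureSuite(d1, seed = 5)
  f2 <- makeFixtureSuite(d2, seed = 5)
  h <- function(fs) vapply(fs, function(f)
    digest::digest(f, algo = "sha256", file = TRUE), "")
  # identical seeds give byte-identical TIFF/CSV/XYZ payloads
  payload1 <- grep("manifest", f1, invert = TRUE, value = TRUE)
  payload2 <- grep("manifest", f2, invert = TRUE, value = TRUE)
  expect_identical(unname(h(payload1)), unname(h(payload2)))
  # the manifest lists every payload file with its correct digest
  man <- jsonlite::read_json(file.path(d1, "manifest.json"),
                             simplifyVector = TRUE)
  expect_setequal(man$files$file, basename(payload1))
  idx <- match(basename(payload1), man$files$file)
  expect_identical(man$files$sha256[idx], unname(h(payload1)))
  # fixtures load back through the package readers without warnings
  expect_no_warning(kb <- readKymographTiff(file.path(d1, "blocked.yaml")))
  expect_s4_class(kb, "Kymograph")
  expect_no_warning(readDwellCsv(file.path(d1, "dwells.csv")))
  expect_no_warning(hp <- readXyz(file.path(d1, "hairpin.xyz")))
  expect_equal(dim(hp$trajectory)[2], 3)
})

test_that("roadblock scenes keep the far arm dark unless scripted", {
  d <- withr::local_tempdir()
  makeFixtureSuite(d, seed = 2)
  kb <- readKymographTiff(file.path(d, "blocked.yaml"))
  tb <- jsonlite::read_json(file.path(d, "blocked_truth.json"))
  rb <- locateRoadblock(kb)
  expect_lt(abs(rb - tb$roadblockPx), 1.5)
  ai <- armIntensities(kb, rb, 150, parsPx = tb$parsPx)
  fit <- lm(far ~ f, data.frame(far = ai$far, f = seq_along(ai$far)))
  # far-side slope is negligible against the parS-side signal scale
  expect_lt(abs(coef(fit)[2]) * length(ai$far), 0.05 * mean(ai$parS))
})
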