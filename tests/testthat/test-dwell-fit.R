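# Maximum-likelihood machinery: likelihood identities, recovery, BIC,
# bootstrap.

test_that("negative log-likelihood has the defining identities", {
  r <- kineticRates(0.025, 0.06, 0)
  s1 <- dwellSample(10)
  expect_equal(negLogLikelihood(s1, r, "delayed"),
               -log(pdfApparentDwell(10, r, "delayed")))
  s <- sampleApparentDwells(r, "delayed", 500, seed = 3)
  twice <- dwellSample(rep(dwellTimes(s), 2))
  expect_equal(negLogLikelihood(twice, r, "delayed"),
               2 * negLogLikelihood(s, r, "delayed"))
  # likelihood concentrates at the true rates on a large sample
  big <- sampleApparentDwells(r, "delayed", 1e4, seed = 4)
  rPert <- kineticRates(0.025 * 1.5, 0.06, 0)
  expect_lt(negLogLikelihood(big, r, "delayed"),
            negLogLikelihood(big, rPert, "delayed"))
  expect_error(negLogLikelihood(dwellSample(c(3, 5)), r, "delayed",
                                minDwell = 4), "record 1")
})

test_that("fits recover generating rates for both models", {
  r <- kineticRates(0.025, 0.06, 1.75e-4)
  # median z-score over a few replicates guards against the long tail of
  # the weakly identified (kCtp, kOff) likelihood ridge
  z <- sapply(1:5, function(i) {
    s <- sampleApparentDwells(r, "delayed", 332, seed = 40 + i)
    f <- fitDwellModel(s, "delayed", kBlFixed = 1.75e-4, seed = i)
    ci <- confint68(f)
    sds <- (ci[, 2] - ci[, 1]) / 2
    abs(c(rates(f)@kCtp - 0.025, rates(f)@kOff - 0.06)) / sds
  })
  expect_lte(median(z[1, ]), 3)
  expect_lte(median(z[2, ]), 3)
  ri <- kineticRates(0.02, Inf, 0)
  si <- sampleApparentDwells(ri, "immediate", 500, seed = 50)
  fi <- fitDwellModel(si, "immediate", kBlFixed = 0, seed = 1)
  ci <- confint68(fi)
  expect_lt(abs(rates(fi)@kCtp - 0.02), 3 * (ci[1, 2] - ci[1, 1]) / 2)
  expect_true(isConverged(fi))
})

test_that("degenerate all-equal data do not crash the fit", {
  s <- dwellSample(rep(12, 40))
  f <- fitDwellModel(s, "delayed", kBlFixed = 0, seed = 1)
  expect_s4_class(f, "FitResult")
  expect_true(is.logical(isConverged(f)))
})

test_that("kBl = 0 reproduces the uncensored likelihood", {
  r0 <- kineticRates(0.022, 0.025, 0)
  s <- sampleApparentDwells(r0, "delayed", 400, seed = 6)
  uncensored <- -sum(log(pdfTotalDwell(dwellTimes(s), r0, "delayed")))
  expect_equal(negLogLikelihood(s, r0, "delayed"), uncensored)
})

test_that("BIC comparison prefers the right model and validates inputs", {
  r <- kineticRates(0.025, 0.06, 1.75e-4)
  s <- sampleApparentDwells(r, "delayed", 1000, seed = 60)
  fd <- fitDwellModel(s, "delayed", 1.75e-4, seed = 1)
  fi <- fitDwellModel(s, "immediate", 1.75e-4, seed = 1)
  cmp <- compareModelsBic(list(fd, fi))
  expect_identical(cmp$model, "delayed")
  expect_true(all(cmp$deltaBic >= 0))
  expect_equal(bic(fd), 2 * log(1000) - 2 * logLik(fd))
  # identical fits duplicated: tie-break to fewer parameters
  tie <- compareModelsBic(list(fd, fd, fi, fi))
  expect_true(tie$model %in% c("delayed", "immediate"))
  dup <- compareModelsBic(list(fi, fi))
  expect_identical(dup$model, "immediate")
  sOther <- sampleApparentDwells(r, "delayed", 999, seed = 61)
  fOther <- fitDwellModel(sOther, "immediate", 1.75e-4, seed = 1)
  expect_error(compareModelsBic(list(fd, fOther)), "different size")
})

test_that("bootstrap mean and SEM follow their formulas", {
  const <- dwellSample(rep(5, 30))
  b <- bootstrapMean(const, nIter = 200, seed = 1)
  expect_equal(b$sem, 0)
  expect_equal(b$bootSd, 0)
  tri <- dwellSample(c(1, 2, 3))
  expect_equal(bootstrapMean(tri, nIter = 100, seed = 1)$sem,
               sd(c(1, 2, 3)) / sqrt(3))
  r <- kineticRates(0.025, 0.06, 0)
  s <- sampleApparentDwells(r, "delayed", 332, seed = 70)
  b2 <- bootstrapMean(s, nIter = 2000, seed = 2)
  expect_lt(abs(b2$mean - 76.6667), 3 * b2$sem)
  expect_error(bootstrapMean(s, nIter = 0), "nIter")
})
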