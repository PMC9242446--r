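# Residence-time model: closed forms against quadrature and Monte-Carlo
# oracles.

test_that("hydrolysis-time density is a normalized max-of-two-exponentials", {
  expect_equal(pdfHydrolysisTime(0, 0.025), 0)
  expect_equal(pdfHydrolysisTime(0, 1), 0)
  norm <- integrate(pdfHydrolysisTime, 0, Inf, kCtp = 0.025,
                    rel.tol = 1e-10)$value
  expect_equal(norm, 1, tolerance = 1e-6)
  m <- integrate(function(t) t * pdfHydrolysisTime(t, 0.025), 0, Inf,
                 rel.tol = 1e-10)$value
  expect_equal(m, 3 / (2 * 0.025), tolerance = 1e-6)   # 60 s
  # Monte-Carlo max of two exponential draws
  set.seed(5)
  mc <- mean(pmax(rexp(2e5, 0.025), rexp(2e5, 0.025)))
  expect_lt(abs(mc - 60), 3 * 60 / sqrt(2e5) * 0.75)   # 3 SEM (sd ~ 0.745 mu)
  expect_error(pdfHydrolysisTime(-1, 0.025), "finite")
  expect_error(pdfHydrolysisTime(1, 0), "kCtp")
})

test_that("delayed closed form matches the quadrature convolution oracle", {
  grid <- seq(0, 400, by = 2)
  for (p in c(list(c(kCtp = 0.025, kOff = 0.06)), randomRatePairs(5))) {
    r <- kineticRates(p[["kCtp"]], p[["kOff"]])
    dev <- max(abs(pdfTotalDwell(grid, r, "delayed") -
                   convolvedDelayedPdf(grid, p[["kCtp"]], p[["kOff"]])))
    expect_lt(dev, 1e-8)
  }
})

test_that("dwell densities are normalized with the documented means", {
  r <- kineticRates(0.025, 0.06)
  expect_equal(integrate(pdfTotalDwell, 0, Inf, rates = r,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-6)
  m <- integrate(function(t) t * pdfTotalDwell(t, r, "delayed"), 0, Inf,
                 rel.tol = 1e-10)$value
  expect_equal(m, 3 / (2 * 0.025) + 1 / 0.06, tolerance = 1e-6)  # 76.7 s
  expect_equal(meanTotalDwell(r, "delayed"), 76.6667, tolerance = 1e-4)
  # immediate model is the kOff -> Inf limit
  rBig <- kineticRates(0.025, 5e4)
  t <- seq(0, 300, by = 1)
  expect_equal(pdfTotalDwell(t, rBig, "delayed"),
               pdfTotalDwell(t, r, "immediate"), tolerance = 1e-3)
  # censored density is normalized at a second rate set
  r2 <- kineticRates(0.022, 0.025, 1.75e-4)
  expect_equal(integrate(pdfApparentDwell, 0, Inf, rates = r2,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-6)
})

test_that("survival functions agree with integrated densities", {
  r <- kineticRates(0.025, 0.06)
  for (model in c("delayed", "immediate")) {
    expect_equal(survivalTotalDwell(0, r, model), 1)
    tail <- integrate(pdfTotalDwell, 50, Inf, rates = r, model = model,
                      rel.tol = 1e-12)$value
    expect_lt(abs(survivalTotalDwell(50, r, model) - tail), 1e-8)
    s <- survivalTotalDwell(seq(0, 500, by = 5), r, model)
    expect_true(all(diff(s) <= 0))
  }
  # generative check of the survival at T = 100 s
  set.seed(11)
  n <- 1e5
  tot <- pmax(rexp(n, 0.025), rexp(n, 0.025)) + rexp(n, 0.06)
  p <- survivalTotalDwell(100, r, "delayed")
  expect_lt(abs(mean(tot > 100) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("censored density matches its sampler and reduces at kBl = 0", {
  r0 <- kineticRates(0.025, 0.06, 0)
  t <- seq(0, 400, by = 2)
  expect_identical(pdfApparentDwell(t, r0, "delayed"),
                   pdfTotalDwell(t, r0, "delayed"))
  r <- kineticRates(0.025, 0.06, 1.75e-4)
  s <- sampleApparentDwells(r, "delayed", 1e5, seed = 21)
  ks <- ks.test(dwellTimes(s),
                function(q) 1 - survivalApparentDwell(q, r, "delayed"))
  expect_gt(ks$p.value, 0.01)
  # survival consistency: numerical derivative of the survival = -density
  h <- 1e-5
  mid <- c(5, 20, 80, 200)
  dS <- (survivalApparentDwell(mid + h, r, "delayed") -
         survivalApparentDwell(mid - h, r, "delayed")) / (2 * h)
  expect_equal(-dS, pdfApparentDwell(mid, r, "delayed"), tolerance = 1e-5)
})

test_that("sampler is reproducible and honours limiting regimes", {
  r <- kineticRates(0.025, 0.06, 0)
  s1 <- sampleApparentDwells(r, "delayed", 1e5, seed = 7)
  s2 <- sampleApparentDwells(r, "delayed", 1e5, seed = 7)
  expect_identical(dwellTimes(s1), dwellTimes(s2))
  m <- mean(dwellTimes(s1))
  sem <- sd(dwellTimes(s1)) / sqrt(1e5)
  expect_lt(abs(m - 76.6667), 3 * sem)
  # censoring-dominated limit
  rFast <- kineticRates(0.025, 0.06, 5)
  sf <- sampleApparentDwells(rFast, "delayed", 2e4, seed = 8)
  expect_equal(mean(dwellTimes(sf)), 1 / 5, tolerance = 0.05)
  expect_error(sampleApparentDwells(r, "delayed", 0), "n must be")
})

test_that("degenerate rate coincidences are regularized, not NaN", {
  for (b in c(0.025, 0.05)) {   # kOff = kCtp and kOff = 2 kCtp
    rEq <- kineticRates(0.025, b)
    rNear <- kineticRates(0.025, b * (1 + 1e-4))
    v1 <- pdfTotalDwell(c(10, 60, 150), rEq, "delayed")
    v2 <- pdfTotalDwell(c(10, 60, 150), rNear, "delayed")
    expect_true(all(is.finite(v1)))
    expect_equal(v1, v2, tolerance = 1e-3)
  }
  expect_error(pdfTotalDwell(1, kineticRates(0.025, 0.06), "nonsense"))
})
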