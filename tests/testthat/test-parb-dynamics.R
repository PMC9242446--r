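# ParB lattice layer: diffusion rules, trans eligibility, recruitment,
# coupled simulation and bypass statistics.

test_that("free lattice walker moves at the configured frequency", {
  set.seed(1)
  st <- parbLattice(41, occupied = 21)
  n <- 2e4
  moved <- 0L
  pos <- 21L
  for (i in seq_len(n)) {
    st <- diffusionUpdate(st, boundary = "periodic")
    np <- which(st@occupancy)
    if (np != pos) moved <- moved + 1L
    pos <- np
  }
  p <- moved / n
  expect_lt(abs(p - 0.125), 3 * sqrt(0.125 * 0.875 / n))
})

test_that("blocked moves are rejected without disturbing occupancy", {
  # walker boxed in by roadblock and lattice edge never moves
  set.seed(2)
  st <- parbLattice(3, occupied = 2, roadblock = 1)
  for (i in 1:100) st <- diffusionUpdate(st, moveProb = 1)
  expect_identical(which(st@occupancy), 2L)
  # two adjacent walkers on a two-bead lattice cannot swap
  st2 <- parbLattice(2, occupied = c(1, 2))
  for (i in 1:50) st2 <- diffusionUpdate(st2, moveProb = 1)
  expect_identical(which(st2@occupancy), c(1L, 2L))
})

test_that("blocked walk matches the reflecting-boundary transition oracle", {
  nB <- 7; rb <- 7L; start <- 4L
  P <- latticeTransitionMatrix(nB, rb)
  steps <- 25
  target <- drop((diag(nB)[start, ] %*%
                    Reduce(`%*%`, rep(list(P), steps))))
  set.seed(3)
  nChains <- 600
  finals <- vapply(seq_len(nChains), function(i) {
    st <- parbLattice(nB, occupied = start, roadblock = rb)
    for (s in seq_len(steps)) st <- diffusionUpdate(st)
    which(st@occupancy)
  }, 0L)
  emp <- tabulate(finals, nB) / nChains
  expect_equal(emp[rb], 0)
  expect_lt(max(abs(emp - target)), 4 * sqrt(max(target) / nChains))
})

test_that("in-trans eligibility follows the cutoff and 1D exclusion rules", {
  hp <- ParBspread:::.hairpinCoords(100, gap = 1)
  st <- parbLattice(100, occupied = 25)
  elig <- eligibleTransNeighbors(st, hp, 25)
  expect_true(length(elig) >= 1)
  expect_true(all(abs(elig - 25) > 2))
  d <- sqrt(rowSums((hp[elig, , drop = FALSE] -
                     matrix(hp[25, ], length(elig), 3, byrow = TRUE))^2))
  expect_true(all(d <= 2))
  # straight stretched chain: second-nearest neighbours are within the
  # cutoff but excluded in 1D, so the list is empty
  straight <- cbind((0:99) * 0.97, 0, 0)
  st2 <- parbLattice(100, occupied = 50)
  expect_length(eligibleTransNeighbors(st2, straight, 50), 0)
  # occupied and roadblock beads are never eligible
  st3 <- parbLattice(100, occupied = c(25, 75), roadblock = 76)
  expect_false(any(c(75, 76) %in% eligibleTransNeighbors(st3, hp, 25)))
  expect_error(eligibleTransNeighbors(st2, straight, 51), "no ParB")
})

test_that("recruitment attempts load cis/trans targets or log failures", {
  straight <- cbind((0:99) * 0.97, 0, 0)
  set.seed(4)
  st <- parbLattice(100, occupied = 50)
  resCis <- attemptRecruitment(st, straight, 50, pCis = 1)
  expect_identical(resCis$event$type, "cis")
  expect_true(resCis$event$dst %in% c(49, 51))
  expect_equal(sum(resCis$state@occupancy), 2)

  resFail <- attemptRecruitment(st, straight, 50, pCis = 0)
  expect_identical(resFail$event$type, "failed")
  expect_identical(resFail$state@occupancy, st@occupancy)

  # hairpin with the roadblock between the strands: a trans event lands on
  # the far segment, i.e. beyond the roadblock index
  hp <- ParBspread:::.hairpinCoords(100, gap = 1)
  st2 <- parbLattice(100, occupied = 25, roadblock = 60)
  set.seed(5)
  resTrans <- attemptRecruitment(st2, hp, 25, pCis = 0)
  expect_identical(resTrans$event$type, "trans")
  expect_gt(resTrans$event$dst, 60)
})

test_that("pure in-cis spreading stays contiguous around parS", {
  pp <- polymerParams(nBeads = 60, extension = 0.5, withRoadblock = FALSE,
                      softSteps = 5000)
  bp <- parbParams(updateIntervalTauB = 10, recruitRate = 2e-2, pCis = 1,
                   nUpdates = 300, sampleEvery = 50)
  rec <- runCoupledSimulation(pp, bp, seed = 9, eqTauB = 20)
  expect_gt(rec@nParB, 3)
  occ <- occupancyMatrix(rec)
  final <- which(occ[nrow(occ), ] == 1)
  expect_identical(final, seq(min(final), max(final)))
  ev <- simEvents(rec)
  expect_identical(sum(ev$type %in% c("load", "cis", "trans")), rec@nParB)
  expect_identical(ev$type[1], "load")
  expect_identical(ev$dst[1], pp@parsIndex)
})

test_that("bypass requires trans recruitment and slack DNA", {
  # recruitment is made frequent here so the short desk-scale runs sample
  # trans events at all; defaults keep the physical rate
  runBatch <- function(ext, pCis, n = 6, seed0 = 100) {
    pp <- polymerParams(nBeads = 100, extension = ext, softSteps = 5000)
    bp <- parbParams(updateIntervalTauB = 10, recruitRate = 5e-3,
                     pCis = pCis, nUpdates = 500, sampleEvery = 50)
    vapply(seq_len(n), function(r) {
      rec <- runCoupledSimulation(pp, bp, seed = seed0 + r, eqTauB = 200)
      occ <- occupancyMatrix(rec)
      rbCol <- pp@roadblockIndex
      expect_true(all(occ[, rbCol] == 0))     # roadblock inviolable
      expect_lte(max(occ), 1)                 # occupancy exclusive
      hasBypass(rec)
    }, TRUE)
  }
  lo <- runBatch(0.15, pCis = 0.1)
  hi <- runBatch(0.75, pCis = 0.1, seed0 = 300)
  cisOnly <- runBatch(0.15, pCis = 1, seed0 = 500)
  expect_gt(mean(lo), 0)                 # slack DNA: bypass happens
  expect_equal(mean(hi), 0)              # taut DNA: it does not
  expect_gte(mean(lo), mean(hi))         # non-increasing in extension
  expect_equal(mean(cisOnly), 0)         # without trans, never
})

test_that("bypass fraction reports Wilson intervals and guards input", {
  bf <- bypassFraction(c(rep(TRUE, 8), rep(FALSE, 2)))
  expect_equal(bf$fraction, 0.8)
  expect_true(bf$lower < 0.8 && bf$upper > 0.8)
  z <- bypassFraction(rep(FALSE, 12))
  expect_equal(z$fraction, 0)
  expect_equal(z$lower, 0)
  expect_error(bypassFraction(logical()), "no simulation")
})

test_that("looping-integral bypass estimates decay with extension", {
  x <- seq(0.3, 0.8, by = 0.1)
  tb <- theoreticalBypass(x)
  expect_true(all(diff(tb) < 0))
  expect_lt(theoreticalBypass(0.99) / tb[1], 1e-4)   # straight chain: no loops
  # empirical contact-counting route: slack chain loops, taut chain does not
  p <- polymerParams(nBeads = 100, extension = 0.12, withRoadblock = FALSE,
                     softSteps = 5000)
  trajLo <- runLangevin(p, 1.5e6, 1e4, seed = 8)$trajectory
  lo <- theoreticalBypass(method = "empirical",
                          trajectory = trajLo[, , 30:150])
  p2 <- polymerParams(nBeads = 100, extension = 0.75, withRoadblock = FALSE,
                      softSteps = 2000)
  hi <- theoreticalBypass(method = "empirical",
                          trajectory = runLangevin(p2, 5e5, 1e4,
                                                   seed = 8)$trajectory)
  expect_gt(lo, 0)
  expect_gt(lo, hi)
})
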