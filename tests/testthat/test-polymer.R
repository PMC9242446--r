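# Bead-spring tether: potentials, engine equilibrium behaviour, WLC map.

test_that("pair potentials evaluate to their closed-form landmarks", {
  expect_equal(ljPairEnergy(2^(1 / 6)), 0, tolerance = 1e-12)
  expect_equal(ljPairEnergy(1), 1)
  expect_equal(ljPairEnergy(1.2), 0)
  expect_error(ljPairEnergy(0), "overflow")

  expect_equal(feneBondEnergy(0), 0)
  expect_equal(feneBondEnergy(0.75), -0.5 * 30 * 1.5^2 * log(0.75))
  expect_gt(feneBondEnergy(0.999 * 1.5), 100)
  expect_error(feneBondEnergy(1.5), "overstretch")

  expect_equal(bendingEnergy(0), 0)
  expect_equal(bendingEnergy(pi / 2), 10)
  expect_equal(bendingEnergy(pi), 20)
  expect_error(bendingEnergy(4), "theta")

  b0 <- equilibriumBondLength()
  expect_gt(b0, 0.9)
  expect_lt(b0, 1.0)
})

test_that("engine energies agree with the closed-form potentials", {
  set.seed(31)
  n <- 15
  coords <- cbind(cumsum(runif(n, 0.85, 1.05)), rnorm(n, 0, 0.3),
                  rnorm(n, 0, 0.3))
  p <- polymerParams(nBeads = n, extension = 0.5)
  e <- chainEnergy(coords, p)
  b <- sqrt(rowSums(diff(coords)^2))
  expect_equal(e$fene, sum(feneBondEnergy(b)), tolerance = 1e-10)
  d <- as.matrix(dist(coords))
  wca <- sum(ljPairEnergy(d[upper.tri(d)]))
  expect_equal(e$wca, wca, tolerance = 1e-10)
  v <- diff(coords)
  cosang <- rowSums(v[-1, ] * v[-(n - 1), ]) /
    (sqrt(rowSums(v[-1, ]^2)) * sqrt(rowSums(v[-(n - 1), ]^2)))
  expect_equal(e$bend, sum(bendingEnergy(acos(pmin(1, cosang)))),
               tolerance = 1e-8)
})

test_that("relaxed straight chain is in force equilibrium at T = 0", {
  p <- polymerParams(nBeads = 30, extension = 0.9, temperature = 0,
                     softSteps = 0)
  st <- straightChainState(30)
  out <- runLangevin(p, 2e4, 2e4, seed = 1, state = st)
  expect_lt(max(abs(out$state@coords - st@coords)), 1e-6)
})

test_that("thermal chain equilibrates with sane bond statistics", {
  p <- polymerParams(nBeads = 60, extension = 0.5, withRoadblock = FALSE,
                     softSteps = 5000)
  out <- runLangevin(p, 3e5, 3e3, seed = 13)
  traj <- out$trajectory[, , 40:100]      # discard early frames
  bonds <- apply(traj, 3, function(m) sqrt(rowSums(diff(m)^2)))
  b0 <- equilibriumBondLength()
  expect_lt(abs(mean(bonds) - b0), 0.05)
  expect_lt(max(bonds), 1.5)              # no bond ever reaches R0
  # anchored ends are immobile, end-to-end exactly constant
  ee <- apply(out$trajectory, 3, function(m)
    sqrt(sum((m[60, ] - m[1, ])^2)))
  expect_equal(max(ee) - min(ee), 0)
  expect_equal(out$state@coords[1, ], c(0, 0, 0))
})

test_that("interior-bead MSD is linear at short times (overdamped oracle)", {
  p <- polymerParams(nBeads = 20, extension = 0.5, dt = 2e-4,
                     integrator = "euler", softSteps = 5000)
  out <- runLangevin(p, 4e3, 1, seed = 2)
  tr <- out$trajectory
  msd <- sapply(1:3, function(k) {
    i <- seq(1, dim(tr)[3] - k, by = 40)
    mean((tr[5:16, , i + k] - tr[5:16, , i])^2) * 3
  })
  # MSD ~ 6 D t with D = kT/gamma before spring confinement sets in
  expect_equal(msd / (6 * 2e-4 * (1:3)), rep(1, 3), tolerance = 0.15)
})

test_that("instability aborts with a step index instead of corrupting", {
  p <- polymerParams(nBeads = 20, extension = 0.5, dt = 1e-3,
                     integrator = "euler", softSteps = 0)
  st <- straightChainState(20)
  expect_warning(
    expect_error(runLangevin(p, 5e3, 1e3, seed = 1, state = st),
                 "instability .* step"),
    "unstable")
})

test_that("Marko-Siggia force map reproduces the WLC landmarks", {
  expect_equal(wlcForceFromExtension(0), 0)
  expect_equal(round(wlcForceFromExtension(0.65, 50, 4.11), 2), 0.20)
  x <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(wlcForceFromExtension(x)) > 0))
  expect_error(wlcForceFromExtension(1), "x must be")
})

test_that("unit map stores both printed and recomputed diffusion constants", {
  um <- unitMap()
  expect_equal(um$sigmaNm, 5.5)
  expect_equal(um$dLatticePrinted, 0.062)
  expect_equal(um$dLatticeRecomputed, 0.059, tolerance = 0.01)
  expect_equal(um$nmFromSigma(2), 11)
})
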