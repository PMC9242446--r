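# Coarse-grained DNA tether: closed-form potentials, unit mapping,
# configuration building, and the Langevin driver around the C++ engine.

#' Pair potentials of the bead-spring DNA model
#'
#' `ljPairEnergy` is the shifted and truncated Lennard-Jones (WCA) excluded
#' volume, `4 eps [(sigma/r)^12 - (sigma/r)^6 + 1/4]` for
#' `r <= 2^(1/6) sigma`, 0 beyond; `feneBondEnergy` is the finitely
#' extensible bond `-0.5 k R0^2 log(1 - (r/R0)^2)` (diverges as r -> R0);
#' `bendingEnergy` is the three-bead bending term `kTheta (1 - cos theta)`.
#' All energies are in units of the thermal energy eps = kBT, distances in
#' bead diameters sigma.
#'
#' @param r pair or bond distance (sigma units), vectorized.
#' @param sigma bead diameter (default 1).
#' @param eps energy unit (default 1).
#' @return energy values.
#' @examples
#' ljPairEnergy(1)            # eps
#' ljPairEnergy(2^(1/6))      # 0 at the cutoff
#' feneBondEnergy(0.5 * 1.5)  # -0.5*30*1.5^2*log(0.75)
#' @export
ljPairEnergy <- function(r, sigma = 1, eps = 1) {
  if (any(r <= 0)) stop("r must be > 0 (overflow guard)", call. = FALSE)
  s6 <- (sigma / r)^6
  ifelse(r <= 2^(1 / 6) * sigma, 4 * eps * (s6^2 - s6 + 0.25), 0)
}

#' @param k FENE spring constant (default 30 eps/sigma^2).
#' @param r0 maximum bond extension R0 (default 1.5 sigma).
#' @rdname ljPairEnergy
#' @export
feneBondEnergy <- function(r, k = 30, r0 = 1.5) {
  if (any(r < 0)) stop("r must be >= 0", call. = FALSE)
  if (any(r >= r0)) stop("bond overstretch: r >= R0", call. = FALSE)
  -0.5 * k * r0^2 * log(1 - (r / r0)^2)
}

#' @param theta bond angle in radians, 0 for a straight chain, in `[0, pi]`.
#' @param kTheta bending stiffness in kBT (default 10).
#' @rdname ljPairEnergy
#' @export
bendingEnergy <- function(theta, kTheta = 10) {
  if (any(theta < 0 | theta > pi)) stop("theta must be in [0, pi]",
                                        call. = FALSE)
  kTheta * (1 - cos(theta))
}

#' Equilibrium bond length of the combined FENE + WCA bond
#'
#' Numerical minimum of `feneBondEnergy(r) + ljPairEnergy(r)`; about
#' 0.97 sigma for the default parameters.
#'
#' @inheritParams ljPairEnergy
#' @inheritParams feneBondEnergy
#' @return scalar bond length (sigma units).
#' @export
equilibriumBondLength <- function(k = 30, r0 = 1.5, sigma = 1, eps = 1) {
  optimize(function(r) feneBondEnergy(r, k, r0) +
             ljPairEnergy(r, sigma, eps),
           interval = c(0.6 * sigma, min(2^(1 / 6) * sigma, 0.999 * r0)))$minimum
}

#' Worm-like-chain force from relative extension
#'
#' Marko-Siggia interpolation
#' `F = (kT / Lp) [1 / (4 (1 - x)^2) - 1/4 + x]`.
#'
#' @param x relative extension in `[0, 1)`.
#' @param persistenceNm DNA persistence length in nm (default 50).
#' @param kTPnNm thermal energy in pN nm (default 4.11 at room temperature).
#' @return stretching force in pN.
#' @examples
#' wlcForceFromExtension(0.65)  # 0.20 pN
#' @export
wlcForceFromExtension <- function(x, persistenceNm = 50, kTPnNm = 4.11) {
  if (any(x < 0 | x >= 1)) stop("x must be in [0, 1)", call. = FALSE)
  (kTPnNm / persistenceNm) * (1 / (4 * (1 - x)^2) - 0.25 + x)
}

#' Unit map between reduced simulation units and physical units
#'
#' One bead is sigma = 5.5 nm = 16 bp. The printed time conversion of the
#' source simulations states 1 s = 2.8e8 dt inside the identity
#' `0.05 um^2/s = 0.062 sigma^2 / 1e4 dt`; independent recomputation of
#' that identity gives 0.059 sigma^2/1e4 dt. Both constants are kept, the
#' printed one is the default.
#'
#' @return list of conversion constants and helper closures.
#' @export
unitMap <- function() {
  sigmaNm <- 5.5
  dtPerSecond <- 2.8e8
  um <- list(
    sigmaNm = sigmaNm,
    bpPerBead = 16,
    kTPnNm = 4.11,
    dtPerSecond = dtPerSecond,
    # lattice diffusion in sigma^2 per 1e4 dt for D = 0.05 um^2/s:
    dLatticePrinted = 0.062,
    dLatticeRecomputed = 0.05 * 1e6 / sigmaNm^2 * 1e4 / dtPerSecond,
    nmFromSigma = function(x) x * sigmaNm,
    sigmaFromNm = function(x) x / sigmaNm,
    secondsFromDt = function(n) n / dtPerSecond
  )
  um
}

.chainRoles <- function(params) {
  roles <- rep("plain", params@nBeads)
  roles[params@parsIndex] <- "parS"
  if (!is.na(params@roadblockIndex)) roles[params@roadblockIndex] <- "roadblock"
  roles
}

# C++ engine parameter list
.enginePar <- function(params, overdamped = NULL, softSteps = NULL) {
  list(dt = params@dt, kT = params@temperature, gamma = params@gamma,
       eps = 1, sigma = 1, feneK = params@feneK, feneR0 = params@feneR0,
       kTheta = params@kTheta, anchored = TRUE,
       overdamped = if (is.null(overdamped)) params@integrator == "euler"
                    else overdamped,
       softSteps = if (is.null(softSteps)) params@softSteps else softSteps)
}

#' Build an initial tether configuration
#'
#' Constructs a chain with all bonds at the equilibrium bond length whose
#' anchors sit `extension * (N - 1) * b0` apart along x: the per-bond
#' x-advance is fixed at `extension * b0` and the transverse slack is laid
#' out as a smooth random walk, bridge-corrected so both ends lie on the
#' axis. The configuration is not equilibrated; [runLangevin()] applies a
#' short capped-gradient relaxation before dynamics.
#'
#' @param params a [PolymerParams-class].
#' @param seed integer seed.
#' @return a [PolymerState-class] with anchors at beads 1 and N.
#' @export
initialChainState <- function(params, seed = 1) {
  set.seed(seed)
  n <- params@nBeads
  b0 <- equilibriumBondLength(params@feneK, params@feneR0)
  dx <- params@extension * b0
  tt <- b0 * sqrt(1 - params@extension^2)
  phi <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n - 2, 0, 0.45)))
  y <- c(0, cumsum(tt * cos(phi)))
  z <- c(0, cumsum(tt * sin(phi)))
  i <- seq_len(n) - 1
  y <- y - i / (n - 1) * y[n]
  z <- z - i / (n - 1) * z[n]
  coords <- cbind(x = i * dx, y = y, z = z)
  new("PolymerState", coords = unname(coords), roles = .chainRoles(params),
      anchors = c(1L, n), time = 0)
}

#' Run Langevin dynamics of the tethered chain
#'
#' Evolves the bead-spring chain with frozen terminal beads using the
#' compiled engine (BAOAB Langevin by default). Fails loudly with the step
#' index if a bond overstretches.
#'
#' @param params a [PolymerParams-class].
#' @param nSteps number of integration steps (time `nSteps * dt` tau_B).
#' @param stride sampling stride in steps (a frame every `stride` steps).
#' @param seed integer seed for the engine RNG (and configuration builder
#'   when `state` is NULL).
#' @param state optional starting [PolymerState-class]; default builds one
#'   with [initialChainState()].
#' @return list with `trajectory` (nBeads x 3 x nFrames array, sigma
#'   units), `state` (final [PolymerState-class]) and `params`.
#' @examples
#' p <- polymerParams(nBeads = 50, extension = 0.5, softSteps = 2000)
#' out <- runLangevin(p, nSteps = 2e4, stride = 2e3, seed = 1)
#' dim(out$trajectory)
#' @export
runLangevin <- function(params, nSteps, stride = max(1, nSteps %/% 100),
                        seed = 1, state = NULL) {
  if (params@integrator == "euler" && params@dt > 5e-4)
    warning("overdamped Euler is unstable for the stiff FENE/WCA bonds ",
            "above dt ~ 5e-4 tau_B; use the BAOAB integrator or reduce dt")
  if (is.null(state)) state <- initialChainState(params, seed)
  soft <- if (identical(state@time, 0)) params@softSteps else 0
  res <- cpp_run_bd(state@coords, .enginePar(params, softSteps = soft),
                    nSteps, stride, as.integer(seed))
  if (!isTRUE(res$ok))
    stop("polymer instability (bond overstretch) at step ", res$failStep,
         call. = FALSE)
  final <- new("PolymerState", coords = res$coords,
               roles = state@roles, anchors = state@anchors,
               time = state@time + nSteps * params@dt)
  list(trajectory = res$traj, state = final, params = params)
}

#' Energy decomposition of a chain configuration
#'
#' Total FENE, excluded-volume and bending energies of a configuration,
#' computed by the engine; useful for cross-checking against the
#' closed-form potentials.
#'
#' @param state a [PolymerState-class] (or nBeads x 3 matrix).
#' @param params a [PolymerParams-class].
#' @return list with `fene`, `wca`, `bend` (units of kBT).
#' @export
chainEnergy <- function(state, params) {
  coords <- if (is(state, "PolymerState")) state@coords else state
  cpp_chain_energy(coords, .enginePar(params))
}

#' Persistence length from bond-direction correlations
#'
#' Estimates `<cos theta(s)> = exp(-s / Lp)` from sampled frames of a free
#' (or anchored) chain and returns the decay length in beads from a
#' log-linear fit over separations `1..maxS`.
#'
#' @param trajectory nBeads x 3 x nFrames array as returned by
#'   [runLangevin()].
#' @param maxS largest bond separation used in the fit (default 12).
#' @param trim number of bonds dropped at each chain end (anchored ends
#'   perturb local statistics; default 2).
#' @return persistence length in beads.
#' @export
persistenceLengthBeads <- function(trajectory, maxS = 12, trim = 2) {
  nFrames <- dim(trajectory)[3]
  corSum <- numeric(maxS)
  corN <- numeric(maxS)
  for (f in seq_len(nFrames)) {
    xyz <- trajectory[, , f]
    b <- diff(xyz)
    b <- b / sqrt(rowSums(b^2))
    nb <- nrow(b)
    keep <- seq.int(1 + trim, nb - trim)
    for (s in seq_len(maxS)) {
      i <- keep[keep + s <= nb - trim]
      if (!length(i)) next
      corSum[s] <- corSum[s] + sum(rowSums(b[i, , drop = FALSE] *
                                           b[i + s, , drop = FALSE]))
      corN[s] <- corN[s] + length(i)
    }
  }
  cc <- corSum / corN
  s <- seq_len(maxS)
  ok <- is.finite(cc) & cc > 0.05
  fit <- lm(log(cc[ok]) ~ 0 + s[ok])
  -1 / unname(coef(fit)[1])
}
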