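# Lattice model of ParB on the polymer: blocked 1D diffusion, in-cis /
# in-trans recruitment, coupled simulation driver, bypass statistics and the
# looping-integral bypass estimate.

#' Lattice occupancy state of ParB on the chain
#'
#' @slot occupancy logical vector, one entry per bead.
#' @slot roadblock integer(1), blocked bead index (NA for none).
#' @export
setClass("ParBLattice",
  representation(occupancy = "logical", roadblock = "integer"))

setValidity("ParBLattice", function(object) {
  msg <- character()
  if (!is.na(object@roadblock)) {
    if (object@roadblock < 1 || object@roadblock > length(object@occupancy))
      msg <- c(msg, "roadblock index out of range")
    else if (object@occupancy[object@roadblock])
      msg <- c(msg, "the roadblock bead can never be occupied")
  }
  if (length(msg)) msg else TRUE
})

#' @param nBeads lattice size.
#' @param occupied integer indices of initially loaded ParB.
#' @param roadblock blocked bead index or NA.
#' @return A `ParBLattice`.
#' @rdname ParBLattice-class
#' @export
parbLattice <- function(nBeads, occupied = integer(), roadblock = NA) {
  occ <- rep(FALSE, nBeads)
  occ[occupied] <- TRUE
  new("ParBLattice", occupancy = occ, roadblock = as.integer(roadblock))
}

#' One diffusion update of all loaded ParB
#'
#' Each loaded ParB independently attempts a +-1 hop with total probability
#' `moveProb` (direction 50/50). A move is rejected - the ParB stays put -
#' if the target bead is occupied by another ParB, is the roadblock, or
#' lies off the lattice (`boundary = "blocked"`); with
#' `boundary = "periodic"` the lattice wraps around.
#'
#' Uses R's RNG; seed with [set.seed()] for reproducibility.
#'
#' @param state a [ParBLattice-class].
#' @param moveProb total hop probability per ParB per update (default
#'   0.125, the lattice equivalent of D = 0.05 um^2/s at the update
#'   cadence of the coupled model).
#' @param boundary "blocked" (tether ends) or "periodic".
#' @return the updated [ParBLattice-class].
#' @export
diffusionUpdate <- function(state, moveProb = 0.125,
                            boundary = c("blocked", "periodic")) {
  boundary <- match.arg(boundary)
  occ <- state@occupancy
  n <- length(occ)
  for (i in which(occ)) {
    if (runif(1) >= moveProb) next
    j <- i + if (runif(1) < 0.5) -1L else 1L
    if (boundary == "periodic") j <- ((j - 1L) %% n) + 1L
    if (j < 1 || j > n) next                       # off-lattice: rejected
    if (occ[j] || identical(j, state@roadblock)) next  # blocked: rejected
    occ[i] <- FALSE
    occ[j] <- TRUE
  }
  initialize(state, occupancy = occ)
}

#' Eligible in-trans recruitment targets
#'
#' Beads that are (i) within the Euclidean cutoff of the recruiting ParB
#' (11 nm = 2 sigma, about the size of two ParB dimers), (ii) farther than
#' the `exclusion`-th nearest neighbour along the chain (default 2, so
#' first- and second-nearest neighbours are excluded as effectively
#' in-cis), (iii) unoccupied and (iv) not the roadblock bead.
#'
#' @param state a [ParBLattice-class].
#' @param coords nBeads x 3 coordinate matrix (sigma units).
#' @param i bead index of the recruiting (loaded) ParB.
#' @param cutoffSigma Euclidean cutoff in sigma (default 2 = 11 nm).
#' @param exclusion 1D exclusion range (default 2).
#' @return integer vector of eligible bead indices (possibly empty).
#' @export
eligibleTransNeighbors <- function(state, coords, i, cutoffSigma = 2,
                                   exclusion = 2) {
  if (!state@occupancy[i]) stop("no ParB loaded at bead ", i, call. = FALSE)
  d2 <- rowSums((coords - matrix(coords[i, ], nrow(coords), 3,
                                 byrow = TRUE))^2)
  j <- which(d2 <= cutoffSigma^2 & abs(seq_len(nrow(coords)) - i) > exclusion &
             !state@occupancy)
  if (!is.na(state@roadblock)) j <- setdiff(j, state@roadblock)
  j
}

#' One recruitment attempt by a loaded ParB
#'
#' With probability `pCis` the attempt is in cis: one of the two adjacent
#' beads is picked at random and loaded if free and not the roadblock,
#' otherwise the attempt fails. With probability `1 - pCis` it is in
#' trans: a uniform pick from [eligibleTransNeighbors()]; an empty list is
#' a logged failure.
#'
#' @param state a [ParBLattice-class].
#' @param coords nBeads x 3 coordinates (sigma units).
#' @param recruiter bead index of the recruiting ParB.
#' @param pCis in-cis probability.
#' @inheritParams eligibleTransNeighbors
#' @return list with `state` (updated) and `event` (data.frame with
#'   `type` = "cis"/"trans"/"failed", `src`, `dst`).
#' @export
attemptRecruitment <- function(state, coords, recruiter, pCis,
                               cutoffSigma = 2, exclusion = 2) {
  if (!state@occupancy[recruiter])
    stop("no ParB loaded at bead ", recruiter, call. = FALSE)
  n <- length(state@occupancy)
  if (runif(1) < pCis) {
    j <- recruiter + if (runif(1) < 0.5) -1L else 1L
    ok <- j >= 1 && j <= n && !state@occupancy[j] &&
      !identical(j, state@roadblock)
    if (ok) {
      state@occupancy[j] <- TRUE
      return(list(state = state,
                  event = data.frame(type = "cis", src = recruiter,
                                     dst = j)))
    }
    return(list(state = state,
                event = data.frame(type = "failed", src = recruiter,
                                   dst = NA_integer_)))
  }
  elig <- eligibleTransNeighbors(state, coords, recruiter, cutoffSigma,
                                 exclusion)
  if (!length(elig))
    return(list(state = state,
                event = data.frame(type = "failed", src = recruiter,
                                   dst = NA_integer_)))
  j <- if (length(elig) == 1) elig else sample(elig, 1)
  state@occupancy[j] <- TRUE
  list(state = state,
       event = data.frame(type = "trans", src = recruiter, dst = j))
}

#' Coupled polymer-ParB simulation
#'
#' Interleaves Langevin dynamics of the tether with lattice updates of the
#' ParB layer: every `updateIntervalTauB` of polymer time each loaded ParB
#' attempts one diffusion hop (total probability `moveProb`) and, with the
#' per-update recruitment probability `recruitRate * updateIntervalTauB`,
#' one in-cis / in-trans recruitment. A single ParB is loaded at the parS
#' bead at t = 0. The bypass flag is sticky: it is set as soon as any ParB
#' occupies a bead strictly beyond the roadblock.
#'
#' @param polyParams a [PolymerParams-class].
#' @param parb a [ParBParams-class].
#' @param seed integer seed (drives both the thermal noise and the lattice
#'   RNG of the compiled engine).
#' @param eqTauB polymer equilibration time before the ParB load (tau_B).
#' @return a [SimRecord-class].
#' @examples
#' rec <- runCoupledSimulation(
#'   polymerParams(nBeads = 60, extension = 0.5, softSteps = 2000),
#'   parbParams(nUpdates = 50), seed = 1)
#' hasBypass(rec)
#' @export
runCoupledSimulation <- function(polyParams, parb = parbParams(), seed = 1,
                                 eqTauB = 100) {
  state <- initialChainState(polyParams, seed)
  sigmaNm <- unitMap()$sigmaNm
  pl <- list(
    updateEvery = round(parb@updateIntervalTauB / polyParams@dt),
    nUpdates = parb@nUpdates,
    eqSteps = round(eqTauB / polyParams@dt),
    moveProb = parb@moveProb,
    recruitProb = parb@recruitRate * parb@updateIntervalTauB,
    pCis = parb@pCis,
    transCutoff = parb@transCutoffNm / sigmaNm,
    transExcl = parb@transExclusion,
    parsIndex = polyParams@parsIndex - 1L,
    rbIndex = if (is.na(polyParams@roadblockIndex)) -1L
              else polyParams@roadblockIndex - 1L,
    sampleEvery = parb@sampleEvery)
  res <- cpp_run_coupled(state@coords, .enginePar(polyParams), pl,
                         as.integer(seed))
  if (!isTRUE(res$ok))
    stop("polymer instability (bond overstretch) at step ", res$failStep,
         call. = FALSE)
  types <- c("load", "cis", "trans", "failed")[res$eventType + 1L]
  events <- data.frame(time = res$eventTime, type = types,
                       src = res$eventSrc + 1L, dst = res$eventDst + 1L)
  new("SimRecord", occupancy = res$occupancy, events = events,
      bypass = res$bypass, nParB = res$nParB,
      params = list(polymer = polyParams, parb = parb, seed = seed,
                    moveAttempts = res$moveAttempts,
                    moveAccepted = res$moveAccepted))
}

#' Wilson score interval for a binomial proportion
#' @noRd
.wilson <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Fraction of simulations with roadblock bypass
#'
#' Share of simulation records whose sticky bypass flag is set, with a
#' Wilson 95\% confidence interval.
#'
#' @param records list of [SimRecord-class] objects, or a logical vector of
#'   bypass flags.
#' @return list with `fraction`, `lower`, `upper`, `n`.
#' @export
bypassFraction <- function(records) {
  flags <- if (is.logical(records)) records
           else vapply(records, hasBypass, TRUE)
  if (!length(flags)) stop("no simulation records", call. = FALSE)
  ci <- .wilson(sum(flags), length(flags))
  list(fraction = mean(flags), lower = unname(ci[1]),
       upper = unname(ci[2]), n = length(flags))
}

# Loop-closure density (J factor) of a semiflexible loop of ell = L/Lp
# persistence lengths: Shimada-Yamakawa approximation for short loops,
# Gaussian closure for long loops (the two are crossed over at their
# minimum since the SY form diverges for large ell).
.loopJ <- function(ell) {
  sy <- 112.04 * ell^-5 * exp(0.246 * ell - 14.055 / ell)
  ga <- (3 / (4 * pi * ell))^1.5
  pmin(sy, ga)
}

#' Relative roadblock-bypass probability from the looping integral
#'
#' The probability that in-trans recruitment bridges the roadblock is
#' proportional to the integral of the loop-closure probability over loop
#' lengths above the 1D exclusion range. Two routes are provided:
#' `"closed-form"` combines a Shimada-Yamakawa / Gaussian loop-closure
#' factor with a tension penalty `exp(-F(x) * x * s * b0)` for pulling a
#' loop of contour `s` beads out of a tether held at relative extension
#' `x` (force from [wlcForceFromExtension()] in reduced units);
#' `"empirical"` counts contacts (pair distance below `contactSigma`) as a
#' function of 1D separation in a sampled trajectory and integrates that
#' contact probability. Both are normalized only relatively: use them for
#' curve shapes, not absolute rates. Both are approximations; the
#' integration measure of the looping integral is not fully constrained by
#' the model definition.
#'
#' @param extension relative extension(s) in (0,1) (closed-form route).
#' @param method "closed-form" or "empirical".
#' @param trajectory nBeads x 3 x nFrames array (empirical route).
#' @param exclusion 1D exclusion (loops shorter than this are in-cis-like;
#'   default 2).
#' @param lpBeads persistence length in beads (default 10).
#' @param nBeads chain length used to bound the loop integral (closed-form
#'   route; default 300).
#' @param contactSigma contact distance in sigma (default 2, the trans
#'   cutoff).
#' @return numeric vector (closed-form: one value per extension) or scalar
#'   (empirical), in arbitrary units.
#' @export
theoreticalBypass <- function(extension = NULL,
                              method = c("closed-form", "empirical"),
                              trajectory = NULL, exclusion = 2,
                              lpBeads = 10, nBeads = 300,
                              contactSigma = 2) {
  method <- match.arg(method)
  if (method == "closed-form") {
    if (is.null(extension)) stop("extension required", call. = FALSE)
    if (any(extension <= 0 | extension >= 1))
      stop("extension must be in (0,1)", call. = FALSE)
    b0 <- equilibriumBondLength()
    s <- seq(exclusion + 1, floor(nBeads / 2))
    vapply(extension, function(x) {
      f <- wlcForceFromExtension(x, persistenceNm = lpBeads, kTPnNm = 1)
      sum(.loopJ(s * b0 / lpBeads) * exp(-f * x * s * b0))
    }, 0)
  } else {
    if (is.null(trajectory)) stop("trajectory required", call. = FALSE)
    n <- dim(trajectory)[1]
    nFrames <- dim(trajectory)[3]
    smax <- n - 1
    hits <- numeric(smax)
    tries <- numeric(smax)
    for (f in seq_len(nFrames)) {
      xyz <- trajectory[, , f]
      d <- as.matrix(dist(xyz)) < contactSigma
      for (s in seq.int(exclusion + 1, smax)) {
        idx <- cbind(seq_len(n - s), seq_len(n - s) + s)
        hits[s] <- hits[s] + sum(d[idx])
        tries[s] <- tries[s] + (n - s)
      }
    }
    pl <- hits / pmax(tries, 1)
    sum(pl[seq.int(exclusion + 1, smax)])
  }
}
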