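# S4 classes for the central data objects, with validity methods and
# constructors. Accessors live in accessors.R, show methods in show-methods.R.

#' Rate triple governing ParB residence times
#'
#' Holds the three rate constants of the residence-time model: `kCtp`, the
#' CTP hydrolysis rate per monomer (1/s); `kOff`, the release rate of the
#' ParB clamp after both CTPs are hydrolysed (1/s; `Inf` encodes the
#' immediate-release convention); and `kBl`, the photobleaching rate of the
#' fluorophore (1/s, 0 for a non-bleaching dye).
#'
#' @slot kCtp numeric(1), hydrolysis rate per monomer, > 0.
#' @slot kOff numeric(1), post-hydrolysis release rate, > 0 (may be `Inf`).
#' @slot kBl numeric(1), photobleaching rate, >= 0.
#' @export
setClass("KineticRates",
  representation(kCtp = "numeric", kOff = "numeric", kBl = "numeric"),
  prototype(kCtp = 0.025, kOff = 0.06, kBl = 0))

setValidity("KineticRates", function(object) {
  msg <- character()
  if (length(object@kCtp) != 1 || !is.finite(object@kCtp) || object@kCtp <= 0)
    msg <- c(msg, "kCtp must be a single finite positive number")
  if (length(object@kOff) != 1 || is.na(object@kOff) || object@kOff <= 0)
    msg <- c(msg, "kOff must be a single positive number (Inf allowed)")
  if (length(object@kBl) != 1 || !is.finite(object@kBl) || object@kBl < 0)
    msg <- c(msg, "kBl must be a single finite non-negative number")
  if (length(msg)) msg else TRUE
})

#' @param kCtp,kOff,kBl see slot descriptions.
#' @return A `KineticRates` object.
#' @examples
#' kineticRates(0.025, 0.06, 1.75e-4)
#' @rdname KineticRates-class
#' @export
kineticRates <- function(kCtp, kOff = Inf, kBl = 0) {
  new("KineticRates", kCtp = as.numeric(kCtp), kOff = as.numeric(kOff),
      kBl = as.numeric(kBl))
}

#' Sample of apparent single-molecule dwell times
#'
#' Apparent dwell times T' (seconds) of individual fluorescently labeled
#' ParB molecules, i.e. the minimum of the true residence time and the
#' photobleaching time. When extracted from kymographs the times are
#' multiples of the frame time.
#'
#' @slot times numeric vector of dwell times in seconds, all > 0.
#' @slot label character(1), dye / condition label.
#' @slot frameTime numeric(1), seconds per frame (NA when not frame-derived).
#' @export
setClass("DwellSample",
  representation(times = "numeric", label = "character",
                 frameTime = "numeric"),
  prototype(times = numeric(), label = "", frameTime = NA_real_))

setValidity("DwellSample", function(object) {
  msg <- character()
  if (any(!is.finite(object@times)) || any(object@times <= 0))
    msg <- c(msg, "all dwell times must be finite and > 0")
  if (length(object@label) != 1) msg <- c(msg, "label must be length 1")
  if (length(object@frameTime) != 1 ||
      (!is.na(object@frameTime) && object@frameTime <= 0))
    msg <- c(msg, "frameTime must be a single positive number or NA")
  if (length(msg)) msg else TRUE
})

#' @param times,label,frameTime see slot descriptions.
#' @return A `DwellSample`.
#' @rdname DwellSample-class
#' @export
dwellSample <- function(times, label = "", frameTime = NA_real_) {
  new("DwellSample", times = as.numeric(times), label = label,
      frameTime = as.numeric(frameTime))
}

#' Result of a maximum-likelihood dwell-time fit
#'
#' @slot model character(1), "immediate" or "delayed".
#' @slot rates fitted [KineticRates-class] (kBl is the fixed input value).
#' @slot ci numeric matrix with columns `lower`/`upper` and one row per free
#'   rate; 68\% intervals (point estimate +/- one standard deviation from the
#'   inverse observed information).
#' @slot logLik numeric(1), maximized log-likelihood.
#' @slot bic numeric(1), `nu * log(n) - 2 * logLik`.
#' @slot n integer(1), number of dwell times fitted.
#' @slot nu integer(1), number of free parameters (1 immediate, 2 delayed).
#' @slot converged logical(1).
#' @slot details list: optimizer diagnostics (starts, values, messages).
#' @export
setClass("FitResult",
  representation(model = "character", rates = "KineticRates", ci = "matrix",
                 logLik = "numeric", bic = "numeric", n = "integer",
                 nu = "integer", converged = "logical", details = "list"))

setValidity("FitResult", function(object) {
  msg <- character()
  if (!object@model %in% c("immediate", "delayed"))
    msg <- c(msg, "model must be 'immediate' or 'delayed'")
  expected <- if (object@model == "immediate") 1L else 2L
  if (object@nu != expected)
    msg <- c(msg, sprintf("nu must be %d for the %s model", expected,
                          object@model))
  if (is.finite(object@bic) && is.finite(object@logLik) &&
      abs(object@bic - (object@nu * log(object@n) - 2 * object@logLik)) >
        1e-6 * max(1, abs(object@bic)))
    msg <- c(msg, "bic is inconsistent with nu * log(n) - 2 * logLik")
  if (length(msg)) msg else TRUE
})

#' Parameters of the coarse-grained DNA tether
#'
#' Reduced-unit parameters of the bead-spring chain: bead diameter
#' sigma = 1 (5.5 nm = 16 bp of DNA), thermal energy epsilon = kBT = 1,
#' friction gamma = 1, so the Brownian time tau_B = 1 and the integration
#' step `dt` is expressed in tau_B.
#'
#' @slot nBeads integer(1), number of beads (desk-scale default 300; the
#'   full-scale chain uses 1400).
#' @slot extension numeric(1) in (0,1), anchored end-to-end distance as a
#'   fraction of the contour length.
#' @slot parsIndex integer(1), 1-based bead index of the parS site (middle).
#' @slot roadblockIndex integer(1), 1-based bead index of the roadblock
#'   (two-thirds of the chain), or NA for no roadblock.
#' @slot kTheta numeric(1), bending stiffness in kBT (default 10, giving a
#'   persistence length of about 10 beads, ~55 nm).
#' @slot feneK,feneR0 FENE bond spring constant (30 eps/sigma^2) and maximum
#'   bond length (1.5 sigma).
#' @slot dt numeric(1), integration step in tau_B (default 0.01).
#' @slot temperature numeric(1), kBT in reduced units (default 1; 0 disables
#'   noise).
#' @slot gamma numeric(1), friction coefficient (default 1).
#' @slot integrator character(1), "baoab" (inertial Langevin, default) or
#'   "euler" (overdamped Euler-Maruyama, for small-dt checks).
#' @slot softSteps numeric(1), capped steepest-descent pre-relaxation steps
#'   applied to freshly built configurations.
#' @export
setClass("PolymerParams",
  representation(nBeads = "integer", extension = "numeric",
                 parsIndex = "integer", roadblockIndex = "integer",
                 kTheta = "numeric", feneK = "numeric", feneR0 = "numeric",
                 dt = "numeric", temperature = "numeric", gamma = "numeric",
                 integrator = "character", softSteps = "numeric"))

setValidity("PolymerParams", function(object) {
  msg <- character()
  if (object@nBeads < 4) msg <- c(msg, "nBeads must be >= 4")
  if (!(object@extension > 0 && object@extension < 1))
    msg <- c(msg, "extension must lie strictly between 0 and 1")
  if (object@parsIndex < 1 || object@parsIndex > object@nBeads)
    msg <- c(msg, "parsIndex out of range")
  if (!is.na(object@roadblockIndex) &&
      (object@roadblockIndex < 1 || object@roadblockIndex > object@nBeads))
    msg <- c(msg, "roadblockIndex out of range")
  if (object@kTheta < 0) msg <- c(msg, "kTheta must be >= 0")
  if (object@feneR0 <= 1) msg <- c(msg, "feneR0 must exceed sigma = 1")
  if (object@dt <= 0 || object@dt > 0.01 + 1e-12)
    msg <- c(msg, "dt must be positive and <= 0.01 tau_B")
  if (!object@integrator %in% c("baoab", "euler"))
    msg <- c(msg, "integrator must be 'baoab' or 'euler'")
  if (length(msg)) msg else TRUE
})

#' @param nBeads,extension,kTheta,feneK,feneR0,dt,temperature,gamma,integrator,softSteps
#'   see slot descriptions.
#' @param parsFrac,roadblockFrac relative positions of the parS bead and of
#'   the roadblock bead along the chain (defaults 1/2 and 2/3).
#' @param withRoadblock logical; set `FALSE` for a roadblock-free chain.
#' @return A `PolymerParams` object.
#' @examples
#' polymerParams(nBeads = 100, extension = 0.35)
#' @rdname PolymerParams-class
#' @export
polymerParams <- function(nBeads = 300, extension = 0.75, parsFrac = 0.5,
                          roadblockFrac = 2 / 3, withRoadblock = TRUE,
                          kTheta = 10, feneK = 30, feneR0 = 1.5, dt = 0.01,
                          temperature = 1, gamma = 1,
                          integrator = c("baoab", "euler"),
                          softSteps = 2e4) {
  nBeads <- as.integer(nBeads)
  new("PolymerParams", nBeads = nBeads, extension = extension,
      parsIndex = as.integer(round(parsFrac * (nBeads - 1)) + 1L),
      roadblockIndex = if (withRoadblock)
        as.integer(round(roadblockFrac * (nBeads - 1)) + 1L) else NA_integer_,
      kTheta = kTheta, feneK = feneK, feneR0 = feneR0, dt = dt,
      temperature = temperature, gamma = gamma,
      integrator = match.arg(integrator), softSteps = softSteps)
}

#' Instantaneous state of the polymer chain
#'
#' @slot coords numeric matrix (nBeads x 3) of bead coordinates in sigma.
#' @slot roles character vector: "plain", "parS" or "roadblock" per bead.
#' @slot anchors integer(2), indices of the frozen terminal beads.
#' @slot time numeric(1), elapsed simulation time in tau_B.
#' @export
setClass("PolymerState",
  representation(coords = "matrix", roles = "character",
                 anchors = "integer", time = "numeric"))

setValidity("PolymerState", function(object) {
  msg <- character()
  if (ncol(object@coords) != 3) msg <- c(msg, "coords must be N x 3")
  if (any(!is.finite(object@coords))) msg <- c(msg, "coords contain NaN/Inf")
  if (length(object@roles) != nrow(object@coords))
    msg <- c(msg, "roles length must equal bead count")
  if (!all(object@roles %in% c("plain", "parS", "roadblock")))
    msg <- c(msg, "roles must be 'plain', 'parS' or 'roadblock'")
  if (length(msg)) msg else TRUE
})

#' Parameters of the ParB lattice layer
#'
#' @slot updateIntervalTauB numeric(1): polymer time between ParB updates
#'   (100 tau_B, i.e. 1e4 integration steps at dt = 0.01).
#' @slot moveProb numeric(1): total probability that a ParB attempts a hop
#'   per update (0.125; direction chosen 50/50).
#' @slot recruitRate numeric(1): recruitment rate per loaded ParB in 1/tau_B
#'   (1e-6, i.e. probability 1e-4 per update).
#' @slot pCis numeric(1): probability that a recruitment event is in cis
#'   (p_trans = 1 - pCis).
#' @slot transCutoffNm numeric(1): Euclidean cutoff for in-trans partners
#'   (11 nm, about the size of two ParB dimers).
#' @slot transExclusion integer(1): 1D exclusion for trans partners (2:
#'   first- and second-nearest neighbours are never in-trans targets).
#' @slot nUpdates numeric(1): number of ParB updates per run.
#' @slot sampleEvery numeric(1): occupancy sampling cadence in updates.
#' @slot releaseRate numeric(1): optional ParB unloading rate per update
#'   (default 0; the coupled model has no release).
#' @export
setClass("ParBParams",
  representation(updateIntervalTauB = "numeric", moveProb = "numeric",
                 recruitRate = "numeric", pCis = "numeric",
                 transCutoffNm = "numeric", transExclusion = "integer",
                 nUpdates = "numeric", sampleEvery = "numeric",
                 releaseRate = "numeric"))

setValidity("ParBParams", function(object) {
  msg <- character()
  if (object@moveProb < 0 || object@moveProb > 1)
    msg <- c(msg, "moveProb must be in [0, 1]")
  if (object@pCis < 0 || object@pCis > 1)
    msg <- c(msg, "pCis must be in [0, 1]")
  if (object@transCutoffNm <= 0) msg <- c(msg, "transCutoffNm must be > 0")
  if (object@recruitRate < 0) msg <- c(msg, "recruitRate must be >= 0")
  if (object@nUpdates < 1) msg <- c(msg, "nUpdates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param updateIntervalTauB,moveProb,recruitRate,pCis,transCutoffNm,transExclusion,nUpdates,sampleEvery,releaseRate
#'   see slot descriptions.
#' @return A `ParBParams` object.
#' @rdname ParBParams-class
#' @export
parbParams <- function(updateIntervalTauB = 100, moveProb = 0.125,
                       recruitRate = 1e-6, pCis = 0.1, transCutoffNm = 11,
                       transExclusion = 2L, nUpdates = 1000,
                       sampleEvery = 10, releaseRate = 0) {
  new("ParBParams", updateIntervalTauB = updateIntervalTauB,
      moveProb = moveProb, recruitRate = recruitRate, pCis = pCis,
      transCutoffNm = transCutoffNm,
      transExclusion = as.integer(transExclusion),
      nUpdates = nUpdates, sampleEvery = sampleEvery,
      releaseRate = releaseRate)
}

#' Record of one coupled polymer-ParB simulation
#'
#' @slot occupancy integer matrix (sampled time x lattice index), 0/1 ParB
#'   occupancy of the beads.
#' @slot events data.frame with columns `time` (updates), `type` ("load",
#'   "cis", "trans", "failed"), `src`, `dst` (1-based bead indices).
#' @slot bypass logical(1): TRUE if any ParB was ever strictly beyond the
#'   roadblock (sticky).
#' @slot nParB integer(1): final number of loaded ParB.
#' @slot params list echoing the polymer and ParB parameters and the seed.
#' @export
setClass("SimRecord",
  representation(occupancy = "matrix", events = "data.frame",
                 bypass = "logical", nParB = "integer", params = "list"))

setValidity("SimRecord", function(object) {
  msg <- character()
  if (any(object@occupancy < 0 | object@occupancy > 1))
    msg <- c(msg, "occupancy must be 0/1")
  if (any(rowSums(object@occupancy) !=
          rowSums(object@occupancy > 0)))
    msg <- c(msg, "at most one ParB per bead per sampled time")
  if (length(msg)) msg else TRUE
})

#' Calibrated multi-channel kymograph
#'
#' A time x position intensity raster per channel, with physical calibration.
#' Channels are co-registered: all matrices share the same dimensions
#' (frames x pixels).
#'
#' @slot channels named list of numeric matrices (frames x pixels); typical
#'   names are "DNA", "ParB", "roadblock".
#' @slot nmPerPixel numeric(1), > 0.
#' @slot secPerFrame numeric(1), > 0.
#' @export
setClass("Kymograph",
  representation(channels = "list", nmPerPixel = "numeric",
                 secPerFrame = "numeric"))

setValidity("Kymograph", function(object) {
  msg <- character()
  if (!length(object@channels)) msg <- c(msg, "at least one channel required")
  dims <- lapply(object@channels, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) > 1)
    msg <- c(msg, "all channels must share the same frames x pixels shape")
  if (any(vapply(object@channels, function(m) any(!is.finite(m)), TRUE)))
    msg <- c(msg, "intensities must be finite")
  if (any(vapply(object@channels, function(m) any(m < 0), TRUE)))
    msg <- c(msg, "intensities must be non-negative")
  if (object@nmPerPixel <= 0 || object@secPerFrame <= 0)
    msg <- c(msg, "calibration must be positive")
  if (length(msg)) msg else TRUE
})

#' @param channels,nmPerPixel,secPerFrame see slot descriptions.
#' @return A `Kymograph`.
#' @rdname Kymograph-class
#' @export
kymograph <- function(channels, nmPerPixel = 110, secPerFrame = 0.1) {
  new("Kymograph", channels = channels, nmPerPixel = nmPerPixel,
      secPerFrame = secPerFrame)
}

#' Single-particle trace on a kymograph
#'
#' @slot frames integer vector, strictly increasing 1-based frame numbers.
#' @slot positions numeric vector, sub-pixel positions (pixels) per frame.
#' @slot intensity numeric vector, spot intensity per frame.
#' @export
setClass("Trace",
  representation(frames = "integer", positions = "numeric",
                 intensity = "numeric"))

setValidity("Trace", function(object) {
  msg <- character()
  if (length(object@frames) == 0) msg <- c(msg, "empty trace")
  if (any(diff(object@frames) <= 0))
    msg <- c(msg, "frames must be strictly increasing")
  if (length(object@positions) != length(object@frames) ||
      length(object@intensity) != length(object@frames))
    msg <- c(msg, "positions/intensity must match frames in length")
  if (length(msg)) msg else TRUE
})

#' @param frames,positions,intensity see slot descriptions.
#' @return A `Trace`.
#' @rdname Trace-class
#' @export
spotTrace <- function(frames, positions,
                      intensity = rep(NA_real_, length(frames))) {
  new("Trace", frames = as.integer(frames), positions = as.numeric(positions),
      intensity = as.numeric(intensity))
}

#' Parameters of the accidental-colocalization null model
#'
#' @slot D numeric(1), 1D diffusion constant in um^2/s (0.066).
#' @slot meanResidence,sdResidence normal residence-time law in seconds
#'   (mean 76, sd 50), truncated at one frame.
#' @slot meanMolecules,sdMolecules normal law for the number of parS-loaded
#'   and of nonspecifically bound molecules per kymograph (mean 4, sd 1),
#'   rounded and floored at 0.
#' @slot nFrames numeric(1), kymograph length in frames (7500 = 1500 s).
#' @slot secPerFrame numeric(1), seconds per frame (0.2).
#' @slot parsFrac numeric(1), relative parS position (0.5).
#' @slot radiusNm,windowFrames colocalization criterion: closer than 300 nm
#'   within three frames.
#' @slot contourKb,extension DNA contour length (42 kb) and relative tether
#'   extension (0.65) fixing the visible DNA length.
#' @slot nScenarios numeric(1), number of simulated kymographs (1000).
#' @export
setClass("NullParams",
  representation(D = "numeric", meanResidence = "numeric",
                 sdResidence = "numeric", meanMolecules = "numeric",
                 sdMolecules = "numeric", nFrames = "numeric",
                 secPerFrame = "numeric", parsFrac = "numeric",
                 radiusNm = "numeric", windowFrames = "numeric",
                 contourKb = "numeric", extension = "numeric",
                 nScenarios = "numeric"))

setValidity("NullParams", function(object) {
  msg <- character()
  if (object@D <= 0) msg <- c(msg, "D must be > 0")
  if (object@radiusNm <= 0) msg <- c(msg, "radiusNm must be > 0")
  if (object@meanResidence <= 0 || object@sdResidence < 0)
    msg <- c(msg, "residence-time law must be positive")
  if (object@nScenarios < 1) msg <- c(msg, "nScenarios must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param D,meanResidence,sdResidence,meanMolecules,sdMolecules,nFrames,secPerFrame,parsFrac,radiusNm,windowFrames,contourKb,extension,nScenarios
#'   see slot descriptions.
#' @return A `NullParams` object.
#' @rdname NullParams-class
#' @export
nullParams <- function(D = 0.066, meanResidence = 76, sdResidence = 50,
                       meanMolecules = 4, sdMolecules = 1, nFrames = 7500,
                       secPerFrame = 0.2, parsFrac = 0.5, radiusNm = 300,
                       windowFrames = 3, contourKb = 42, extension = 0.65,
                       nScenarios = 1000) {
  new("NullParams", D = D, meanResidence = meanResidence,
      sdResidence = sdResidence, meanMolecules = meanMolecules,
      sdMolecules = sdMolecules, nFrames = nFrames,
      secPerFrame = secPerFrame, parsFrac = parsFrac, radiusNm = radiusNm,
      windowFrames = windowFrames, contourKb = contourKb,
      extension = extension, nScenarios = nScenarios)
}

#' Scene description for the synthetic-kymograph generator
#'
#' Either a scripted scene (explicit molecule arrivals, dwells and
#' recruitment events in `script`) or a stochastic one (molecules load at
#' parS under the delayed-release dwell law with 1D diffusion).
#'
#' @slot dnaKb numeric(1), DNA length in kb (42).
#' @slot extension numeric(1), relative tether extension (0.65).
#' @slot parsFrac numeric(1), relative parS position (0.5).
#' @slot roadblockFrac numeric(1), relative roadblock position (2/3) or NA.
#' @slot script data.frame or NULL; columns `tStart` (s), `posFrac` (relative
#'   loading position, NA = parS), `dwell` (s), `D` (um^2/s, NA = spec
#'   default), `recruitFrom` (integer id of the recruiting molecule or NA),
#'   one row per molecule. Rows with `recruitFrom` set appear at the
#'   recruiter's current position.
#' @slot nMolecules numeric(1), stochastic mode: number of sequentially
#'   loaded molecules.
#' @slot rates [KineticRates-class] used in stochastic mode.
#' @slot D numeric(1), 1D diffusion constant in um^2/s (0.066).
#' @slot peakPhotons,background,readNoise photophysics: expected photons in
#'   the brightest pixel of a spot, background photons per pixel, and
#'   Gaussian read noise (counts).
#' @slot psfFwhmNm numeric(1), point-spread-function FWHM (300 nm).
#' @slot nmPerPixel,secPerFrame calibration (110 nm, 0.1 s).
#' @slot nFrames numeric(1), movie length (frames); NA = auto from content.
#' @slot seed numeric(1), RNG seed for reproducible rendering.
#' @export
setClass("SceneSpec",
  representation(dnaKb = "numeric", extension = "numeric",
                 parsFrac = "numeric", roadblockFrac = "numeric",
                 script = "ANY", nMolecules = "numeric",
                 rates = "KineticRates", D = "numeric",
                 peakPhotons = "numeric", background = "numeric",
                 readNoise = "numeric", psfFwhmNm = "numeric",
                 nmPerPixel = "numeric", secPerFrame = "numeric",
                 nFrames = "numeric", seed = "numeric"))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (!(object@parsFrac > 0 && object@parsFrac < 1))
    msg <- c(msg, "parsFrac must be in (0,1)")
  if (!is.na(object@roadblockFrac) &&
      !(object@roadblockFrac > 0 && object@roadblockFrac < 1))
    msg <- c(msg, "roadblockFrac must be in (0,1) or NA")
  if (!is.null(object@script)) {
    if (!is.data.frame(object@script))
      msg <- c(msg, "script must be a data.frame or NULL")
    else if (is.unsorted(object@script$tStart))
      msg <- c(msg, "scripted events must be time-ordered")
  }
  if (length(msg)) msg else TRUE
})

#' @param dnaKb,extension,parsFrac,roadblockFrac,script,nMolecules,rates,D,peakPhotons,background,readNoise,psfFwhmNm,nmPerPixel,secPerFrame,nFrames,seed
#'   see slot descriptions.
#' @return A `SceneSpec` object.
#' @rdname SceneSpec-class
#' @export
sceneSpec <- function(dnaKb = 42, extension = 0.65, parsFrac = 0.5,
                      roadblockFrac = NA_real_, script = NULL,
                      nMolecules = 20,
                      rates = kineticRates(0.025, 0.06, 1.75e-4),
                      D = 0.066, peakPhotons = 150, background = 10,
                      readNoise = 2, psfFwhmNm = 300, nmPerPixel = 110,
                      secPerFrame = 0.1, nFrames = NA_real_, seed = 1) {
  new("SceneSpec", dnaKb = dnaKb, extension = extension,
      parsFrac = parsFrac, roadblockFrac = roadblockFrac, script = script,
      nMolecules = nMolecules, rates = rates, D = D,
      peakPhotons = peakPhotons, background = background,
      readNoise = readNoise, psfFwhmNm = psfFwhmNm,
      nmPerPixel = nmPerPixel, secPerFrame = secPerFrame,
      nFrames = nFrames, seed = seed)
}
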