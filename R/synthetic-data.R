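# Synthetic-kymograph generator: renders two/three-channel kymographs of a
# doubly tethered DNA with a central parS, diffusing ParB traces under the
# delayed-release dwell law (or a deterministic script), optional roadblock
# channel, realistic photophysics, and machine-readable ground truth.

# --- trace simulation --------------------------------------------------------

# 1D Brownian path in nm reflected into [lo, hi]
.diffusePath <- function(nFrames, x0, D, dtSec, hi, lo = 0) {
  if (nFrames < 1) return(numeric())
  if (D <= 0) return(rep(x0, nFrames))
  x <- x0 + c(0, cumsum(rnorm(nFrames - 1, 0, sqrt(2 * D * 1e6 * dtSec))))
  w <- hi - lo
  x <- (x - lo) %% (2 * w)
  lo + ifelse(x > w, 2 * w - x, x)
}

# Simulate molecule trajectories for a scene. Returns a list of per-molecule
# data.frames (frame, posNm) plus ground-truth dwells and events.
.simulateSceneTraces <- function(spec) {
  L <- spec@dnaKb * 1e3 * 0.34 * spec@extension   # visible tether length, nm
  dtS <- spec@secPerFrame
  parsNm <- spec@parsFrac * L
  rbNm <- if (is.na(spec@roadblockFrac)) NA_real_ else spec@roadblockFrac * L
  # a roadblock blocks 1D sliding: each molecule stays on its initial side
  sideBounds <- function(x0) {
    if (is.na(rbNm)) c(0, L)
    else if (x0 <= rbNm) c(0, rbNm) else c(rbNm, L)
  }
  traces <- list()
  events <- data.frame(type = character(), frame = integer(),
                       posNm = numeric(), recruiter = integer(),
                       recruit = integer())
  if (!is.null(spec@script)) {
    sc <- spec@script
    for (i in seq_len(nrow(sc))) {
      startF <- as.integer(round(sc$tStart[i] / dtS)) + 1L
      nF <- max(1L, as.integer(round(sc$dwell[i] / dtS)))
      D <- if (!is.null(sc$D) && !is.na(sc$D[i])) sc$D[i] else spec@D
      if (!is.null(sc$recruitFrom) && !is.na(sc$recruitFrom[i])) {
        # recruited molecule: appears at the recruiter's position, rides
        # along for a conjunct phase, then splits off and diffuses freely
        rec <- traces[[sc$recruitFrom[i]]]
        at <- which(rec$frame == startF)
        if (!length(at))
          stop("scripted recruitment outside the recruiter's lifetime",
               call. = FALSE)
        cf <- if (!is.null(sc$conjunct) && !is.na(sc$conjunct[i]))
          as.integer(round(sc$conjunct[i] / dtS)) else as.integer(round(8 / dtS))
        cf <- min(cf, nrow(rec) - at + 1L, nF)
        shared <- rec$posNm[at:(at + cf - 1L)]
        bnd <- sideBounds(shared[cf])
        free <- .diffusePath(nF - cf + 1L, shared[cf], D, dtS, bnd[2], bnd[1])
        pos <- c(shared, free[-1])
        events <- rbind(events, data.frame(
          type = "recruitment", frame = startF, posNm = shared[1],
          recruiter = sc$recruitFrom[i], recruit = i))
        traces[[i]] <- data.frame(
          frame = seq.int(startF, startF + nF - 1L), posNm = pos)
        next
      }
      x0 <- if (is.na(sc$posFrac[i])) parsNm else sc$posFrac[i] * L
      bnd <- sideBounds(x0)
      traces[[i]] <- data.frame(
        frame = seq.int(startF, startF + nF - 1L),
        posNm = .diffusePath(nF, x0, D, dtS, bnd[2], bnd[1]))
    }
    dwells <- vapply(seq_len(nrow(sc)), function(i)
      nrow(traces[[i]]) * dtS, 0)
  } else {
    # stochastic mode: molecules load sequentially at parS, dwell under the
    # delayed-release law censored by bleaching, diffuse with constant D
    dwells <- numeric(spec@nMolecules)
    nextF <- 26L
    for (i in seq_len(spec@nMolecules)) {
      dw <- dwellTimes(sampleApparentDwells(spec@rates, "delayed", 1))
      nF <- max(1L, as.integer(round(dw / dtS)))
      dwells[i] <- nF * dtS
      bnd <- sideBounds(parsNm)
      traces[[i]] <- data.frame(
        frame = seq.int(nextF, nextF + nF - 1L),
        posNm = .diffusePath(nF, parsNm, spec@D, dtS, bnd[2], bnd[1]))
      nextF <- nextF + nF + 25L
    }
  }
  nFrames <- if (is.na(spec@nFrames))
    max(vapply(traces, function(tr) max(tr$frame), 0)) + 25 else spec@nFrames
  traces <- lapply(traces, function(tr) tr[tr$frame <= nFrames, ,
                                           drop = FALSE])
  list(traces = traces, dwells = dwells, events = events,
       nFrames = as.integer(nFrames), lengthNm = L, parsNm = parsNm)
}

# --- rendering ---------------------------------------------------------------

# add Gaussian spots (centers px, one per row index) into a raster
.addSpots <- function(mat, rows, centersPx, amplitude, sigmaPx) {
  npx <- ncol(mat)
  for (k in -4:4) {
    px <- round(centersPx) + k
    ok <- px >= 1 & px <= npx
    if (!any(ok)) next
    contrib <- amplitude * exp(-(px[ok] - centersPx[ok])^2 / (2 * sigmaPx^2))
    idx <- cbind(rows[ok], px[ok])
    mat[idx] <- mat[idx] + contrib
  }
  mat
}

#' Render a synthetic kymograph with ground truth
#'
#' Produces a DNA channel (tether profile with an AR(1) intensity wiggle
#' whose amplitude shrinks with extension), a ParB channel (Gaussian
#' point-spread function of 300 nm FWHM along the simulated traces,
#' Poisson shot noise plus Gaussian read noise), and - when
#' `roadblockFrac` is set - a roadblock channel with a static emitter.
#' Ground truth (per-frame positions, dwell times, scripted recruitment
#' events, calibration landmarks) is returned alongside.
#'
#' @param spec a [SceneSpec-class].
#' @return list with `kymo` (a [Kymograph-class]) and `truth` (list:
#'   `traces` - data.frames with `frame`, `posNm`, `posPx`; `dwells` -
#'   seconds; `events`; `xStartPx`, `xEndPx`, `parsPx`, `roadblockPx`,
#'   `nFrames`).
#' @examples
#' out <- renderKymograph(sceneSpec(nMolecules = 2, seed = 1))
#' out$kymo
#' @export
renderKymograph <- function(spec) {
  set.seed(spec@seed)
  sim <- .simulateSceneTraces(spec)
  pad <- 7
  npx <- ceiling(sim$lengthNm / spec@nmPerPixel) + 2 * pad
  nF <- sim$nFrames
  toPx <- function(nm) pad + nm / spec@nmPerPixel
  sigmaPx <- spec@psfFwhmNm / 2.355 / spec@nmPerPixel

  # DNA channel: uniform tether + low-frequency AR(1) wiggle
  dnaPx <- which(seq_len(npx) >= toPx(0) & seq_len(npx) <= toPx(sim$lengthNm))
  dna <- matrix(spec@background, nF, npx)
  wiggleAmp <- 0.25 * (1 - spec@extension)
  ar <- numeric(nF)
  for (f in 2:max(nF, 2)) ar[f] <- 0.95 * ar[f - 1] + rnorm(1, 0, 0.1)
  base <- 4 * spec@background
  dna[, dnaPx] <- dna[, dnaPx] + base * (1 + wiggleAmp * ar)
  dna <- matrix(rpois(length(dna), dna), nF, npx) +
    matrix(rnorm(length(dna), 0, spec@readNoise), nF, npx)

  # ParB channel
  parb <- matrix(spec@background, nF, npx)
  amp <- spec@peakPhotons
  for (tr in sim$traces)
    parb <- .addSpots(parb, tr$frame, toPx(tr$posNm), amp, sigmaPx)
  parb <- matrix(rpois(length(parb), parb), nF, npx) +
    matrix(rnorm(length(parb), 0, spec@readNoise), nF, npx)

  channels <- list(DNA = pmax(dna, 0), ParB = pmax(parb, 0))
  roadblockPx <- NA_real_
  if (!is.na(spec@roadblockFrac)) {
    roadblockPx <- toPx(spec@roadblockFrac * sim$lengthNm)
    rb <- matrix(spec@background, nF, npx)
    rb <- .addSpots(rb, seq_len(nF), rep(roadblockPx, nF), amp, sigmaPx)
    rb <- matrix(rpois(length(rb), rb), nF, npx) +
      matrix(rnorm(length(rb), 0, spec@readNoise), nF, npx)
    channels$roadblock <- pmax(rb, 0)
  }

  truth <- list(
    traces = lapply(sim$traces, function(tr)
      cbind(tr, posPx = toPx(tr$posNm))),
    dwells = sim$dwells, events = sim$events,
    xStartPx = toPx(0), xEndPx = toPx(sim$lengthNm),
    parsPx = toPx(sim$parsNm), roadblockPx = roadblockPx,
    nFrames = nF)
  list(kymo = kymograph(channels, spec@nmPerPixel, spec@secPerFrame),
       truth = truth)
}

# --- fixture suite -----------------------------------------------------------

# deterministic hairpin conformation: two antiparallel strands joined by a
# turn, so beads on opposite strands are 3D-proximal but 1D-distant
.hairpinCoords <- function(n = 100, gap = 1) {
  half <- n %/% 2
  up <- cbind(seq_len(half) * 0.97, 0, 0)
  turn <- cbind(half * 0.97 + 0.5, gap / 2, 0)
  down <- cbind(rev(seq_len(n - half - 1)) * 0.97, gap, 0)
  rbind(up, turn, down)
}

#' Write a deterministic suite of small fixtures
#'
#' Generates, under `outDir`: a hairpin polymer conformation (XYZ), a
#' blocked-diffusion kymograph (roadblock, no bypass), a bypass kymograph
#' (scripted in-trans recruitment across the roadblock), a dwell-time CSV
#' with sidecar, and a JSON manifest listing every file with its SHA-256
#' digest. Output is byte-identical for identical seeds.
#'
#' @param outDir output directory (created).
#' @param seed integer seed.
#' @return invisible list of written paths (manifest last).
#' @export
makeFixtureSuite <- function(outDir, seed = 1) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  files <- character()

  hp <- .hairpinCoords()
  traj <- array(hp, c(nrow(hp), 3, 1))
  p <- file.path(outDir, "hairpin.xyz")
  writeXyz(traj, rep("plain", nrow(hp)), p)
  files <- c(files, p)

  blocked <- renderKymograph(sceneSpec(
    roadblockFrac = 2 / 3,
    script = data.frame(tStart = 15, posFrac = 0.5, dwell = 60, D = 0.02,
                        recruitFrom = NA),
    nFrames = 900, seed = seed))
  files <- c(files, .writeKymoFixture(blocked, outDir, "blocked"))

  bypass <- renderKymograph(sceneSpec(
    roadblockFrac = 2 / 3,
    script = data.frame(tStart = c(15, 40),
                        posFrac = c(0.5, 0.8),
                        dwell = c(60, 45), D = c(0.02, 0.02),
                        recruitFrom = c(NA, NA)),
    nFrames = 900, seed = seed + 1))
  files <- c(files, .writeKymoFixture(bypass, outDir, "bypass"))

  dw <- sampleApparentDwells(kineticRates(0.025, 0.06, 1.75e-4), "delayed",
                             200, seed = seed, label = "synthetic-alexa647",
                             frameTime = 0.1)
  p <- file.path(outDir, "dwells.csv")
  writeDwellCsv(dw, p, rates = kineticRates(0.025, 0.06, 1.75e-4),
                seed = seed, model = "delayed")
  files <- c(files, p, paste0(p, ".json"))

  manifest <- file.path(outDir, "manifest.json")
  entries <- lapply(unname(files), function(f) list(
    file = basename(f),
    sha256 = digest::digest(f, algo = "sha256", file = TRUE)))
  jsonlite::write_json(list(seed = seed, files = entries), manifest,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, manifest))
}

.writeKymoFixture <- function(rendered, outDir, base) {
  mp <- writeKymographTiff(rendered$kymo, outDir, base)
  tp <- file.path(outDir, paste0(base, "_truth.json"))
  tr <- rendered$truth
  tr$traces <- lapply(tr$traces, function(d) as.list(d))
  jsonlite::write_json(tr, tp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  man <- yaml::read_yaml(mp)
  c(vapply(man$channels, function(f) file.path(outDir, f), ""), mp, tp)
}
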