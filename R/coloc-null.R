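# Monte-Carlo null model of accidental colocalization between parS-loaded
# and nonspecifically bound ParB molecules on a DNA tether.

# Simulate one reflected 1D Brownian trajectory on [0, L] nm.
.brown1D <- function(nFrames, x0, D, dtSec, L) {
  if (nFrames < 1) return(numeric())
  sdStep <- sqrt(2 * D * 1e6 * dtSec)   # D um^2/s -> nm^2/s
  x <- x0 + c(0, cumsum(rnorm(nFrames - 1, 0, sdStep)))
  # reflect into [0, L]
  x <- x %% (2 * L)
  ifelse(x > L, 2 * L - x, x)
}

#' Simulate the accidental-colocalization null model
#'
#' For each of `nScenarios` kymographs, parS-loaded molecules (count ~
#' round(Normal(meanMolecules, sdMolecules)), min 0) bind at the parS
#' position at uniform start frames and diffuse with constant `D`;
#' nonspecifically bound molecules (same count law) bind at uniform
#' positions and uniform start frames. Residence times are drawn from
#' Normal(meanResidence, sdResidence) truncated at one frame. A parS-loaded
#' molecule scores an accidental colocalization when a nonspecific molecule
#' \emph{appears} within `radiusNm` of it within `windowFrames` frames of
#' the nonspecific molecule's binding - the observable signature by which
#' recruitment is identified on a kymograph.
#'
#' @param params a [NullParams-class].
#' @param seed integer RNG seed.
#' @param perKymograph if TRUE additionally report the fraction of
#'   kymographs (rather than of loaded molecules) with at least one
#'   accidental colocalization.
#' @param nonspecificCount optional fixed number of nonspecifically bound
#'   molecules per kymograph (overrides the count law; 0 gives the
#'   no-nonspecific control).
#' @return list with `fraction` (per loaded molecule), Wilson 95\% `lower`
#'   and `upper`, `nLoaded`, and if requested `fractionPerKymograph`.
#' @examples
#' simulateColocNull(nullParams(nScenarios = 50), seed = 1)$fraction
#' @export
simulateColocNull <- function(params, seed = 1, perKymograph = FALSE,
                              nonspecificCount = NULL) {
  set.seed(seed)
  L <- params@contourKb * 1e3 * 0.34 * params@extension   # nm
  parsX <- params@parsFrac * L
  nF <- params@nFrames
  dtS <- params@secPerFrame
  drawCount <- function()
    max(0L, as.integer(round(rnorm(1, params@meanMolecules,
                                   params@sdMolecules))))
  drawDwellFrames <- function(k)
    pmax(1, round(rnorm(k, params@meanResidence, params@sdResidence) / dtS))

  hits <- 0L; loaded <- 0L; kymoHits <- 0L
  for (sc in seq_len(params@nScenarios)) {
    nLoad <- drawCount()
    nNs <- if (is.null(nonspecificCount)) drawCount()
           else as.integer(nonspecificCount)
    if (nLoad == 0L) next
    loaded <- loaded + nLoad
    if (nNs == 0L) next
    loadStart <- sample.int(nF, nLoad, replace = TRUE)
    loadDur <- drawDwellFrames(nLoad)
    loadTraj <- lapply(seq_len(nLoad), function(i) {
      len <- min(loadDur[i], nF - loadStart[i] + 1)
      .brown1D(len, parsX, params@D, dtS, L)
    })
    nsStart <- sample.int(nF, nNs, replace = TRUE)
    nsPos <- runif(nNs, 0, L)
    scHit <- FALSE
    for (i in seq_len(nLoad)) {
      tr <- loadTraj[[i]]
      if (!length(tr)) next
      t0 <- loadStart[i]
      t1 <- t0 + length(tr) - 1L
      for (j in seq_len(nNs)) {
        # frames of the loaded trace within the appearance window of ns j
        w <- max(t0, nsStart[j] - params@windowFrames):
             min(t1, nsStart[j] + params@windowFrames)
        if (w[1] > w[length(w)]) next
        if (any(abs(tr[w - t0 + 1L] - nsPos[j]) <= params@radiusNm)) {
          hits <- hits + 1L
          scHit <- TRUE
          break
        }
      }
    }
    if (scHit) kymoHits <- kymoHits + 1L
  }
  ci <- .wilson(hits, max(loaded, 1L))
  out <- list(fraction = hits / max(loaded, 1L),
              lower = unname(ci[1]), upper = unname(ci[2]),
              nLoaded = loaded)
  if (perKymograph)
    out$fractionPerKymograph <- kymoHits / params@nScenarios
  out
}
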