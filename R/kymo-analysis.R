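# Kymograph-level procedures: preprocessing, trace tracking, loading
# positions, residence times, recruitment detection, roadblock localization,
# arm intensities and recruitment-profile decomposition.
#
# Coordinate conventions: pixels and frames are 1-based; sub-pixel positions
# are continuous in pixel units; relative loading positions follow
# (xEnd - x) / (xEnd - xStart) so that a molecule at the xEnd pixel maps
# to 0.

#' Collapse a 2D movie to a kymograph
#'
#' Integrates the total fluorescence of `2 * halfWidth + 1` pixels across
#' the DNA axis (11 pixels by default) for each time point and stacks the
#' profiles into a kymograph.
#'
#' @param movie numeric array `[frames, rows, cols]` with the DNA lying
#'   along the column direction.
#' @param axisRow row index of the DNA axis.
#' @param halfWidth half-width of the integration band (default 5).
#' @param nmPerPixel,secPerFrame calibration of the returned kymograph.
#' @param name channel name of the result.
#' @return a single-channel [Kymograph-class].
#' @export
collapseToKymograph <- function(movie, axisRow, halfWidth = 5,
                                nmPerPixel = 110, secPerFrame = 0.1,
                                name = "DNA") {
  rows <- max(1, axisRow - halfWidth):min(dim(movie)[2], axisRow + halfWidth)
  raster <- apply(movie[, rows, , drop = FALSE], c(1, 3), sum)
  kymograph(setNames(list(raster), name), nmPerPixel, secPerFrame)
}

#' Preprocess a kymograph
#'
#' Median-filters each channel (square window of radius `medianRadius`)
#' and subtracts the background with a grayscale white-tophat operation
#' (box structuring element of half-width `tophatHalfWidth`). A constant
#' raster maps to zero.
#'
#' @param k a [Kymograph-class].
#' @param medianRadius median filter radius in pixels (window
#'   `2 * r + 1`); 0 disables. The default 1 is matched to
#'   diffraction-limited spots that span only ~3 pixels on a kymograph.
#' @param tophatHalfWidth half-width of the tophat structuring element
#'   (default 7, i.e. a 15 x 15 box).
#' @return the filtered [Kymograph-class].
#' @export
preprocessKymograph <- function(k, medianRadius = 1, tophatHalfWidth = 7) {
  d <- dim(k@channels[[1]])
  win <- 2 * max(medianRadius, tophatHalfWidth) + 1
  if (any(d < win))
    stop("raster (", d[1], " x ", d[2], ") smaller than filter window ",
         win, call. = FALSE)
  filt <- function(m) {
    hi <- max(m)
    if (hi <= 0) return(m * 0)
    mm <- m / hi
    if (medianRadius > 0)
      mm <- EBImage::medianFilter(mm, medianRadius)
    kern <- EBImage::makeBrush(2 * tophatHalfWidth + 1, shape = "box")
    mm <- EBImage::whiteTopHat(mm, kern)
    pmax(mm, 0) * hi
  }
  initialize(k, channels = lapply(k@channels, filt))
}

#' Relative loading position of a trace
#'
#' Mean pixel position of the trace over its first full second, expressed
#' relative to the DNA ends:
#' `(xEnd - mean(x_firstSecond)) / (xEnd - xStart)`. A molecule loading at
#' the `xEnd` pixel maps to 0, one at `xStart` to 1.
#'
#' @param tr a [Trace-class].
#' @param xStart,xEnd DNA end positions in pixels, `xEnd > xStart`.
#' @param secPerFrame seconds per frame.
#' @return relative position in `[0, 1]`.
#' @export
relativeLoadingPosition <- function(tr, xStart, xEnd, secPerFrame = 0.1) {
  if (xEnd <= xStart) stop("xEnd must exceed xStart", call. = FALSE)
  nSec <- ceiling(1 / secPerFrame)
  if (traceDuration(tr, secPerFrame) < 1)
    stop("trace shorter than one second", call. = FALSE)
  first <- tr@frames <= tr@frames[1] + nSec - 1
  xm <- mean(tr@positions[first])
  (xEnd - xm) / (xEnd - xStart)
}

#' Residence times of a set of traces
#'
#' Dwell time of each trace in seconds
#' (`(end - start + 1) * secPerFrame`); the result feeds directly into
#' [fitDwellModel()].
#'
#' @param traces list of [Trace-class] objects (may be empty).
#' @param secPerFrame seconds per frame.
#' @param label dye / condition label for the sample.
#' @return a [DwellSample-class].
#' @export
residenceTimes <- function(traces, secPerFrame = 0.1, label = "") {
  t <- vapply(traces, traceDuration, 0, secPerFrame = secPerFrame)
  dwellSample(t, label = label, frameTime = secPerFrame)
}

# per-frame peak detection: local maxima above threshold, sub-pixel by
# intensity centroid over +-2 px, intensity = sum of the 3 central pixels
.framePeaks <- function(v, threshold, minSepPx = 3) {
  n <- length(v)
  isMax <- v > threshold &
    v >= c(-Inf, v[-n]) & v >= c(v[-1], -Inf)
  idx <- which(isMax)
  if (length(idx) > 1) {            # enforce minimal separation, keep brighter
    keep <- logical(length(idx))
    ord <- order(v[idx], decreasing = TRUE)
    taken <- rep(FALSE, n)
    for (o in ord) {
      i <- idx[o]
      lo <- max(1, i - minSepPx); hi <- min(n, i + minSepPx)
      if (!any(taken[lo:hi])) { keep[o] <- TRUE; taken[i] <- TRUE }
    }
    idx <- sort(idx[keep])
  }
  if (!length(idx))
    return(data.frame(pos = numeric(), intensity = numeric()))
  pos <- vapply(idx, function(i) {
    w <- max(1, i - 2):min(n, i + 2)
    ww <- pmax(v[w] - threshold, 0)
    if (sum(ww) <= 0) i else sum(w * ww) / sum(ww)
  }, 0)
  intensity <- vapply(idx, function(i) {
    w <- max(1, i - 1):min(n, i + 1)
    sum(v[w])
  }, 0)
  data.frame(pos = pos, intensity = intensity)
}

#' Track single-particle traces on a kymograph
#'
#' Frame-by-frame peak detection (local maxima above a robust threshold,
#' sub-pixel centroid refinement) followed by nearest-neighbour linking
#' within `maxLinkNm` (default 300 nm, the diffraction limit), tolerating
#' up to `maxGap` missed frames. Linking is greedy by distance, which is
#' sufficient in the sparse regime of a few molecules per tether.
#'
#' @param k a [Kymograph-class].
#' @param channelName channel to track (default "ParB").
#' @param threshold absolute intensity threshold; default
#'   `median + 5 * mad` of the raster.
#' @param maxLinkNm maximum per-link displacement in nm.
#' @param maxGap maximum number of consecutive missed frames within a
#'   trace.
#' @param minFrames minimum number of detected frames per reported trace.
#' @return list of [Trace-class] objects ordered by start frame.
#' @export
trackKymograph <- function(k, channelName = "ParB", threshold = NULL,
                           maxLinkNm = 300, maxGap = 2, minFrames = 3) {
  m <- channel(k, channelName)
  if (is.null(threshold))
    threshold <- median(m) + 5 * mad(m)
  maxLinkPx <- maxLinkNm / k@nmPerPixel
  active <- list()   # each: frames, pos, int, lastFrame, lastPos
  done <- list()
  for (f in seq_len(nrow(m))) {
    pk <- .framePeaks(m[f, ], threshold)
    assigned <- rep(FALSE, nrow(pk))
    if (length(active) && nrow(pk)) {
      lastPos <- vapply(active, function(a) a$lastPos, 0)
      # diffusive gating: the allowed displacement grows with the square
      # root of the elapsed frames when bridging detection gaps
      gate <- maxLinkPx *
        sqrt(f - vapply(active, function(a) a$lastFrame, 0))
      dmat <- abs(outer(lastPos, pk$pos, "-"))
      dmat[dmat > gate] <- NA
      repeat {
        if (all(is.na(dmat))) break
        mi <- arrayInd(which.min(dmat), dim(dmat))
        a <- mi[1]; p <- mi[2]
        tr <- active[[a]]
        tr$frames <- c(tr$frames, f)
        tr$pos <- c(tr$pos, pk$pos[p])
        tr$int <- c(tr$int, pk$intensity[p])
        tr$lastFrame <- f; tr$lastPos <- pk$pos[p]
        active[[a]] <- tr
        assigned[p] <- TRUE
        dmat[a, ] <- NA; dmat[, p] <- NA
      }
    }
    for (p in which(!assigned)) {
      active[[length(active) + 1]] <-
        list(frames = f, pos = pk$pos[p], int = pk$intensity[p],
             lastFrame = f, lastPos = pk$pos[p])
    }
    if (length(active)) {
      expired <- vapply(active, function(a) f - a$lastFrame > maxGap, TRUE)
      done <- c(done, active[expired])
      active <- active[!expired]
    }
  }
  done <- c(done, active)
  done <- Filter(function(a) length(a$frames) >= minFrames, done)
  done <- done[order(vapply(done, function(a) a$frames[1], 0))]
  lapply(done, function(a) spotTrace(a$frames, a$pos, a$int))
}

# windowed means of a series: mean over [i, i+w-1]
.forwardMean <- function(x, w) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  i <- seq_len(n - w + 1)
  (cs[i + w] - cs[i]) / w
}

#' Detect ParB-ParB recruitment events
#'
#' A recruitment event on a kymograph is (i) a step increase (factor
#' `stepFactor`, default 1.5) of a trace's integrated spot intensity
#' (3 surrounding pixels, compared over `intWindow`-frame windows before
#' and after the step), followed by (ii) the appearance of a new trace
#' that starts within `radiusNm` / `windowFrames` of the stepped trace
#' (the split of the conjunct pair).
#'
#' @param traces list of [Trace-class] from [trackKymograph()].
#' @param k the [Kymograph-class] the traces came from (calibration).
#' @param radiusNm,windowFrames colocalization criterion for the split
#'   (defaults 300 nm, 3 frames).
#' @param stepFactor minimum intensity step ratio (default 1.5, below the
#'   ~2x expected for a second labeled dimer).
#' @param intWindow frames per intensity window (default 20).
#' @param maxConjunctFrames maximum frames between the intensity step and
#'   the split (default 300).
#' @return data.frame with one row per event: `frame` (step time),
#'   `positionPx`, `recruiter`, `recruit` (trace indices).
#' @export
detectRecruitment <- function(traces, k, radiusNm = 300, windowFrames = 3,
                              stepFactor = 1.5, intWindow = 20,
                              maxConjunctFrames = 300) {
  radiusPx <- radiusNm / k@nmPerPixel
  events <- data.frame(frame = integer(), positionPx = numeric(),
                       recruiter = integer(), recruit = integer())
  if (length(traces) < 2) return(events)
  for (ai in seq_along(traces)) {
    a <- traces[[ai]]
    nA <- length(a@frames)
    if (nA < 2 * intWindow) next
    intens <- a@intensity
    # step time candidates: ratio of forward to backward window means
    fwd <- .forwardMean(intens, intWindow)
    idx <- seq.int(intWindow + 1, nA - intWindow + 1)
    ratio <- fwd[idx] / fwd[idx - intWindow]
    for (bi in seq_along(traces)) {
      if (bi == ai) next
      b <- traces[[bi]]
      sB <- b@frames[1]
      if (sB <= a@frames[1] || sB > a@frames[nA]) next
      # colocalization of the new trace with a at its appearance
      near <- which(abs(a@frames - sB) <= windowFrames)
      if (!length(near)) next
      if (min(abs(a@positions[near] - b@positions[1])) > radiusPx) next
      # look for the intensity step in the conjunct window before the split
      stepWin <- which(a@frames[idx] >= sB - maxConjunctFrames &
                       a@frames[idx] <= sB)
      if (!length(stepWin)) next
      best <- stepWin[which.max(ratio[stepWin])]
      if (is.na(ratio[best]) || ratio[best] < stepFactor) next
      events <- rbind(events, data.frame(
        frame = a@frames[idx[best]],
        positionPx = a@positions[idx[best]],
        recruiter = ai, recruit = bi))
    }
  }
  events
}

#' Locate the roadblock on its kymograph channel
#'
#' Position of the maximum of the time-averaged roadblock channel after
#' Savitzky-Golay smoothing (window 11, order 1), refined to sub-pixel
#' precision by a parabolic fit through the maximum and its neighbours.
#' Ties break deterministically to the lower index with a warning; a flat
#' channel is an error.
#'
#' @param k a [Kymograph-class].
#' @param channelName channel to use (default "roadblock").
#' @param sgWindow,sgOrder Savitzky-Golay filter length and order.
#' @return sub-pixel position (pixels, 1-based).
#' @export
locateRoadblock <- function(k, channelName = "roadblock", sgWindow = 11,
                            sgOrder = 1) {
  m <- channel(k, channelName)
  if (ncol(m) < sgWindow)
    stop("need at least ", sgWindow, " positions", call. = FALSE)
  prof <- colMeans(m)
  if (diff(range(prof)) <= 1e-12 * max(abs(prof), 1))
    stop("flat roadblock channel: no roadblock found", call. = FALSE)
  sm <- signal::sgolayfilt(prof, p = sgOrder, n = sgWindow)
  top <- which(sm == max(sm))
  if (length(top) > 1)
    warning("tied roadblock maxima; taking the lower index")
  i <- top[1]
  if (i <= 1 || i >= length(sm)) return(as.numeric(i))
  denom <- sm[i - 1] - 2 * sm[i] + sm[i + 1]
  if (denom >= 0) return(as.numeric(i))
  i + 0.5 * (sm[i - 1] - sm[i + 1]) / denom
}

#' parS-side and far-side arm intensities around a roadblock
#'
#' Background (the per-pixel mean over `preFrames` frames before the first
#' ParB binding) is subtracted; a window of `excludePx` pixels on either
#' side of the roadblock is discarded (fluorescence leakage); the summed
#' arm intensities are median-filtered over time (kernel `medianKernel`
#' frames).
#'
#' @param k a [Kymograph-class].
#' @param roadblockPx roadblock position (pixels).
#' @param firstBindingFrame frame of the first ParB binding; must exceed
#'   `preFrames`.
#' @param parsPx parS position in pixels (decides which arm is which).
#' @param channelName ParB channel name.
#' @param excludePx half-width of the exclusion window (default 5).
#' @param medianKernel temporal median kernel in frames (default 21).
#' @param preFrames background frames (default 100).
#' @return list with numeric series `parS` and `far` (one value per frame
#'   from `firstBindingFrame` on) and `frames`.
#' @export
armIntensities <- function(k, roadblockPx, firstBindingFrame, parsPx,
                           channelName = "ParB", excludePx = 5,
                           medianKernel = 21, preFrames = 100) {
  m <- channel(k, channelName)
  if (firstBindingFrame <= preFrames)
    stop("need at least ", preFrames, " pre-binding frames", call. = FALSE)
  bg <- colMeans(m[seq.int(firstBindingFrame - preFrames,
                           firstBindingFrame - 1), , drop = FALSE])
  frames <- seq.int(firstBindingFrame, nrow(m))
  sub <- sweep(m[frames, , drop = FALSE], 2, bg)
  px <- seq_len(ncol(m))
  left <- px < roadblockPx - excludePx
  right <- px > roadblockPx + excludePx
  if (parsPx > roadblockPx) { tmp <- left; left <- right; right <- tmp }
  smooth <- function(v) {
    if (length(v) >= medianKernel) runmed(v, medianKernel) else v
  }
  list(parS = smooth(rowSums(sub[, left, drop = FALSE])),
       far = smooth(rowSums(sub[, right, drop = FALSE])),
       frames = frames)
}

#' Decompose a recruitment intensity profile into 1 or 2 peaks
#'
#' Fits Gaussian mixture models with one and two components to the
#' intensity-weighted position distribution of a (time-averaged) profile
#' and selects the component count by BIC.
#'
#' @param profile numeric intensity profile (length >= 10, non-degenerate).
#' @param pseudoN number of pseudo-observations used to represent the
#'   profile (default 2000).
#' @return list with `nComponents`, `means` (pixels), `sds`,
#'   `proportions`.
#' @export
recruitmentProfileComponents <- function(profile, pseudoN = 2000) {
  if (length(profile) < 10)
    stop("profile must have at least 10 positions", call. = FALSE)
  w <- pmax(profile - min(profile), 0)
  if (!any(is.finite(w)) || sum(w) <= 0 || diff(range(profile)) <= 0)
    stop("degenerate profile", call. = FALSE)
  counts <- round(w / sum(w) * pseudoN)
  xs <- rep(seq_along(profile), counts)
  # deterministic sub-pixel jitter spreads the pseudo-sample inside pixels
  off <- unlist(lapply(counts[counts > 0], function(k)
    (seq_len(k) - 0.5) / k - 0.5))
  xs <- xs + off
  fit <- Mclust(xs, G = 1:2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed", call. = FALSE)
  g <- fit$G
  list(nComponents = g,
       means = unname(fit$parameters$mean),
       sds = sqrt(unname(fit$parameters$variance$sigmasq)),
       proportions = unname(fit$parameters$pro))
}
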