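# Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for ParBspread classes
#' @description Small accessor generics so user code never touches slots.
#' @param object a ParBspread S4 object.
#' @param name channel name.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("dwellTimes", function(object) standardGeneric("dwellTimes"))
#' @rdname accessors
#' @export
setMethod("dwellTimes", "DwellSample", function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("frameTime", function(object) standardGeneric("frameTime"))
#' @rdname accessors
#' @export
setMethod("frameTime", "DwellSample", function(object) object@frameTime)

#' @rdname accessors
#' @export
setGeneric("rates", function(object) standardGeneric("rates"))
#' @rdname accessors
#' @export
setMethod("rates", "FitResult", function(object) object@rates)

#' @rdname accessors
#' @export
setGeneric("bic", function(object) standardGeneric("bic"))
#' @rdname accessors
#' @export
setMethod("bic", "FitResult", function(object) object@bic)

#' @rdname accessors
#' @export
setGeneric("confint68", function(object) standardGeneric("confint68"))
#' @rdname accessors
#' @export
setMethod("confint68", "FitResult", function(object) object@ci)

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setMethod("isConverged", "FitResult", function(object) object@converged)

#' @rdname accessors
#' @export
setMethod("logLik", "FitResult", function(object) object@logLik)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "Kymograph",
          function(object) names(object@channels))

#' @rdname accessors
#' @export
setGeneric("channel", function(object, name) standardGeneric("channel"))
#' @rdname accessors
#' @export
setMethod("channel", "Kymograph", function(object, name) {
  if (!name %in% names(object@channels))
    stop("no channel '", name, "' in kymograph", call. = FALSE)
  object@channels[[name]]
})

#' @rdname accessors
#' @export
setGeneric("nmPerPixel", function(object) standardGeneric("nmPerPixel"))
#' @rdname accessors
#' @export
setMethod("nmPerPixel", "Kymograph", function(object) object@nmPerPixel)

#' @rdname accessors
#' @export
setGeneric("secPerFrame", function(object) standardGeneric("secPerFrame"))
#' @rdname accessors
#' @export
setMethod("secPerFrame", "Kymograph", function(object) object@secPerFrame)

#' @rdname accessors
#' @export
setGeneric("occupancyMatrix",
           function(object) standardGeneric("occupancyMatrix"))
#' @rdname accessors
#' @export
setMethod("occupancyMatrix", "SimRecord", function(object) object@occupancy)

#' @rdname accessors
#' @export
setGeneric("simEvents", function(object) standardGeneric("simEvents"))
#' @rdname accessors
#' @export
setMethod("simEvents", "SimRecord", function(object) object@events)

#' @rdname accessors
#' @export
setGeneric("hasBypass", function(object) standardGeneric("hasBypass"))
#' @rdname accessors
#' @export
setMethod("hasBypass", "SimRecord", function(object) object@bypass)

#' @rdname accessors
#' @export
setGeneric("beadCoords", function(object) standardGeneric("beadCoords"))
#' @rdname accessors
#' @export
setMethod("beadCoords", "PolymerState", function(object) object@coords)

#' @rdname accessors
#' @export
setGeneric("beadRoles", function(object) standardGeneric("beadRoles"))
#' @rdname accessors
#' @export
setMethod("beadRoles", "PolymerState", function(object) object@roles)

#' @rdname accessors
#' @export
setGeneric("traceFrames", function(object) standardGeneric("traceFrames"))
#' @rdname accessors
#' @export
setMethod("traceFrames", "Trace", function(object) object@frames)

#' @rdname accessors
#' @export
setGeneric("tracePositions",
           function(object) standardGeneric("tracePositions"))
#' @rdname accessors
#' @export
setMethod("tracePositions", "Trace", function(object) object@positions)

#' Trace duration in seconds
#'
#' Duration is `(end - start + 1) * secPerFrame`, i.e. a one-frame trace
#' lasts one frame time.
#'
#' @param object a [Trace-class].
#' @param secPerFrame seconds per frame.
#' @return numeric(1), seconds.
#' @export
setGeneric("traceDuration",
           function(object, secPerFrame) standardGeneric("traceDuration"))
#' @rdname traceDuration
#' @export
setMethod("traceDuration", "Trace", function(object, secPerFrame) {
  (object@frames[length(object@frames)] - object@frames[1] + 1) * secPerFrame
})

setMethod("length", "DwellSample", function(x) length(x@times))

setMethod("show", "KineticRates", function(object) {
  cat("KineticRates: kCtp =", object@kCtp, "1/s, kOff =", object@kOff,
      "1/s, kBl =", object@kBl, "1/s\n")
})

setMethod("show", "DwellSample", function(object) {
  cat(sprintf("DwellSample '%s': n = %d, mean = %.1f s%s\n",
              object@label, length(object@times),
              if (length(object@times)) mean(object@times) else NA,
              if (is.na(object@frameTime)) ""
              else sprintf(", frame time %.3g s", object@frameTime)))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (%s model, n = %d, converged: %s)\n",
              object@model, object@n, object@converged))
  est <- c(kCtp = object@rates@kCtp,
           if (object@model == "delayed") c(kOff = object@rates@kOff))
  for (nm in names(est)) {
    ci <- object@ci[nm, ]
    cat(sprintf("  %-5s = %.4g 1/s  (68%% CI %.4g - %.4g)\n",
                nm, est[[nm]], ci[1], ci[2]))
  }
  cat(sprintf("  kBl fixed at %.3g 1/s\n", object@rates@kBl))
  cat(sprintf("  logLik = %.3f, BIC = %.3f\n", object@logLik, object@bic))
})

setMethod("show", "Kymograph", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf(
    "Kymograph: %d frames x %d pixels, channels [%s], %g nm/px, %g s/frame\n",
    d[1], d[2], paste(names(object@channels), collapse = ", "),
    object@nmPerPixel, object@secPerFrame))
})

setMethod("show", "SimRecord", function(object) {
  cat(sprintf(
    "SimRecord: %d sampled frames x %d beads, %d ParB, %d events, bypass: %s\n",
    nrow(object@occupancy), ncol(object@occupancy), object@nParB,
    nrow(object@events), object@bypass))
})

setMethod("show", "PolymerState", function(object) {
  cat(sprintf("PolymerState: %d beads at t = %.4g tau_B\n",
              nrow(object@coords), object@time))
})

setMethod("show", "Trace", function(object) {
  cat(sprintf("Trace: frames %d-%d (%d points)\n", object@frames[1],
              object@frames[length(object@frames)], length(object@frames)))
})
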