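# Residence-time model: two CTPs hydrolyse independently at rate kCtp, the
# clamp then releases either immediately or after an exponential delay at
# rate kOff, and observation is censored by exponential photobleaching at
# rate kBl. All densities are in 1/s, all times in s.

# Degenerate rate coincidences kOff == kCtp or kOff == 2 kCtp make the
# delayed closed form 0/0; they are handled by a relative epsilon
# perturbation of kOff (tolerance 1e-9 relative, nudge 1e-6 relative).
.regularizeRates <- function(kCtp, kOff) {
  if (!is.finite(kOff)) return(kOff)
  for (bad in c(kCtp, 2 * kCtp)) {
    if (abs(kOff - bad) < 1e-9 * bad) kOff <- bad * (1 + 1e-6)
  }
  kOff
}

.checkModel <- function(model) {
  if (!is.character(model) || length(model) != 1 ||
      !model %in% c("immediate", "delayed"))
    stop("model must be \"immediate\" or \"delayed\"", call. = FALSE)
  model
}

.checkTimes <- function(t) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("times must be finite and >= 0", call. = FALSE)
  t
}

#' Density of the two-CTP hydrolysis time
#'
#' The time until both CTP molecules of a ParB dimer are hydrolysed is the
#' maximum of two independent exponential times with rate `kCtp`, with
#' density `2 kCtp exp(-kCtp t) (1 - exp(-kCtp t))`. Its mean is
#' `3 / (2 kCtp)`.
#'
#' @param t time(s) in seconds, >= 0 (vectorized).
#' @param kCtp hydrolysis rate per monomer (1/s), > 0.
#' @return density values (1/s).
#' @examples
#' integrate(pdfHydrolysisTime, 0, Inf, kCtp = 0.025)  # 1
#' @export
pdfHydrolysisTime <- function(t, kCtp) {
  if (!is.finite(kCtp) || kCtp <= 0) stop("kCtp must be > 0", call. = FALSE)
  .checkTimes(t)
  2 * kCtp * exp(-kCtp * t) * (1 - exp(-kCtp * t))
}

#' Density of the total ParB dwell time
#'
#' Under the immediate-release model the dwell time is the hydrolysis time
#' itself ([pdfHydrolysisTime()]). Under the delayed-release model an
#' exponential release time with rate `kOff` is added, and the density is
#' the convolution
#' \deqn{P(T) = 2 k_{CTP} k_{off} e^{-k_{off}T}
#'  [(k_{CTP}-k_{off})^{-1}(1-e^{-(k_{CTP}-k_{off})T}) -
#'   (2k_{CTP}-k_{off})^{-1}(1-e^{-(2k_{CTP}-k_{off})T})].}
#' The mean is `3/(2 kCtp) + 1/kOff`.
#'
#' @param t time(s) in seconds, >= 0 (vectorized).
#' @param rates a [KineticRates-class] object (`kBl` is ignored here).
#' @param model "immediate" or "delayed".
#' @return density values (1/s).
#' @examples
#' r <- kineticRates(0.025, 0.06)
#' integrate(pdfTotalDwell, 0, Inf, rates = r, model = "delayed")  # 1
#' @export
pdfTotalDwell <- function(t, rates, model = c("delayed", "immediate")) {
  model <- .checkModel(match.arg(model))
  .checkTimes(t)
  a <- rates@kCtp
  if (model == "immediate" || !is.finite(rates@kOff))
    return(pdfHydrolysisTime(t, a))
  b <- .regularizeRates(a, rates@kOff)
  # expanded form of the convolution result (numerically stable at large t;
  # algebraically identical to the factored closed form)
  2 * a * b * ((exp(-b * t) - exp(-a * t)) / (a - b) -
               (exp(-b * t) - exp(-2 * a * t)) / (2 * a - b))
}

#' Survival function of the total dwell time
#'
#' `P(T > t)` for the model of [pdfTotalDwell()]. The printed closed form of
#' the censoring survival in the source material is unreliable; this
#' implementation integrates the dwell density analytically term by term:
#' for the delayed model
#' \deqn{S(T) = \frac{2a^2 e^{-bT}}{(a-b)(2a-b)} - \frac{2b e^{-aT}}{a-b}
#'       + \frac{b e^{-2aT}}{2a-b}}
#' with `a = kCtp`, `b = kOff`; for the immediate model
#' `S(T) = 2 exp(-aT) - exp(-2aT)`.
#'
#' @inheritParams pdfTotalDwell
#' @return survival probabilities in `[0, 1]`, monotone non-increasing.
#' @export
survivalTotalDwell <- function(t, rates, model = c("delayed", "immediate")) {
  model <- .checkModel(match.arg(model))
  .checkTimes(t)
  a <- rates@kCtp
  if (model == "immediate" || !is.finite(rates@kOff))
    return(2 * exp(-a * t) - exp(-2 * a * t))
  b <- .regularizeRates(a, rates@kOff)
  2 * a^2 * exp(-b * t) / ((a - b) * (2 * a - b)) -
    2 * b * exp(-a * t) / (a - b) +
    b * exp(-2 * a * t) / (2 * a - b)
}

#' Density of the apparent (bleaching-censored) dwell time
#'
#' The apparent dwell time is `T' = min(T, t_bl)` with exponential bleaching
#' time `t_bl` at rate `kBl`:
#' `P(T') = P(T = T') exp(-kBl T') + kBl exp(-kBl T') P(T > T')`.
#' With `kBl = 0` this reduces to [pdfTotalDwell()].
#'
#' @inheritParams pdfTotalDwell
#' @return density values (1/s).
#' @export
pdfApparentDwell <- function(t, rates, model = c("delayed", "immediate")) {
  model <- .checkModel(match.arg(model))
  kBl <- rates@kBl
  if (kBl == 0) return(pdfTotalDwell(t, rates, model))
  exp(-kBl * t) *
    (pdfTotalDwell(t, rates, model) +
     kBl * survivalTotalDwell(t, rates, model))
}

#' Survival function of the apparent dwell time
#'
#' `P(T' > t) = P(T > t) P(t_bl > t)`; used for left truncation of fits.
#'
#' @inheritParams pdfTotalDwell
#' @return survival probabilities.
#' @export
survivalApparentDwell <- function(t, rates,
                                  model = c("delayed", "immediate")) {
  model <- .checkModel(match.arg(model))
  exp(-rates@kBl * t) * survivalTotalDwell(t, rates, model)
}

#' Mean dwell times of the kinetic model
#'
#' `meanTotalDwell` returns `3/(2 kCtp)` (+ `1/kOff` for the delayed
#' model); `postHydrolysisDwell` returns the mean residence after CTP
#' hydrolysis, `1/kOff`.
#'
#' @param rates a [KineticRates-class].
#' @param model "immediate" or "delayed".
#' @return mean time in seconds.
#' @examples
#' meanTotalDwell(kineticRates(0.025, 0.06), "delayed")  # 76.7 s
#' postHydrolysisDwell(kineticRates(0.025, 0.06))        # 16.7 s
#' @export
meanTotalDwell <- function(rates, model = c("delayed", "immediate")) {
  model <- .checkModel(match.arg(model))
  m <- 1.5 / rates@kCtp
  if (model == "delayed" && is.finite(rates@kOff)) m <- m + 1 / rates@kOff
  m
}

#' @rdname meanTotalDwell
#' @export
postHydrolysisDwell <- function(rates) 1 / rates@kOff

#' Draw apparent dwell times from the generative model
#'
#' Generative twin of [pdfApparentDwell()]: draws the hydrolysis time as the
#' maximum of two exponentials, adds an exponential release delay (delayed
#' model only) and censors with an exponential bleaching time.
#'
#' @param rates a [KineticRates-class].
#' @param model "immediate" or "delayed".
#' @param n number of molecules, >= 1.
#' @param seed integer RNG seed (uses R's RNG reproducibly).
#' @param label,frameTime stored in the returned [DwellSample-class].
#' @return a [DwellSample-class] of length `n`.
#' @examples
#' s <- sampleApparentDwells(kineticRates(0.025, 0.06), "delayed", 1000, 1)
#' mean(dwellTimes(s))
#' @export
sampleApparentDwells <- function(rates, model = c("delayed", "immediate"),
                                 n, seed = NULL, label = "",
                                 frameTime = NA_real_) {
  model <- .checkModel(match.arg(model))
  if (length(n) != 1 || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  tCtp <- pmax(rexp(n, rates@kCtp), rexp(n, rates@kCtp))
  tot <- if (model == "delayed" && is.finite(rates@kOff))
    tCtp + rexp(n, rates@kOff) else tCtp
  if (rates@kBl > 0) tot <- pmin(tot, rexp(n, rates@kBl))
  dwellSample(tot, label = label, frameTime = frameTime)
}
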