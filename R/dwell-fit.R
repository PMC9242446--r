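# Maximum-likelihood fitting of apparent dwell times with fixed bleaching
# rate, 68% confidence intervals from the observed information, BIC model
# comparison and bootstrap summaries.

.freeParams <- function(model) {
  if (model == "immediate") "kCtp" else c("kCtp", "kOff")
}

.ratesFromPar <- function(par, model, kBl) {
  if (model == "immediate")
    kineticRates(par[["kCtp"]], Inf, kBl)
  else
    kineticRates(par[["kCtp"]], par[["kOff"]], kBl)
}

#' Negative log-likelihood of a dwell sample
#'
#' `-sum(log P(T' = t_i))` under the censored dwell model. With a left
#' truncation bound `minDwell > 0` the density is conditioned on
#' `T' >= minDwell` (dwells below the bound are rejected with an error).
#'
#' @param data a [DwellSample-class]; all dwell times must be > 0.
#' @param rates a [KineticRates-class] (kBl participates).
#' @param model "immediate" or "delayed".
#' @param minDwell optional left-truncation bound in seconds (default 0,
#'   i.e. off).
#' @return scalar negative log-likelihood.
#' @export
negLogLikelihood <- function(data, rates, model = c("delayed", "immediate"),
                             minDwell = 0) {
  model <- match.arg(model)
  t <- dwellTimes(data)
  bad <- which(!is.finite(t) | t <= 0)
  if (length(bad))
    stop("non-positive dwell time at record ", bad[1], call. = FALSE)
  if (minDwell > 0) {
    below <- which(t < minDwell)
    if (length(below))
      stop("dwell time below truncation bound at record ", below[1],
           call. = FALSE)
  }
  ll <- sum(log(pdfApparentDwell(t, rates, model)))
  if (minDwell > 0)
    ll <- ll - length(t) * log(survivalApparentDwell(minDwell, rates, model))
  -ll
}

# observed information by central finite differences on the rate scale,
# relative step 1e-4
.fdHessian <- function(fn, par, rel = 1e-4) {
  k <- length(par)
  h <- pmax(abs(par), 1e-12) * rel
  H <- matrix(NA_real_, k, k, dimnames = list(names(par), names(par)))
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        pp <- pm <- par
        pp[i] <- par[i] + h[i]; pm[i] <- par[i] - h[i]
        H[i, i] <- (fn(pp) - 2 * fn(par) + fn(pm)) / h[i]^2
      } else {
        ppp <- ppm <- pmp <- pmm <- par
        ppp[c(i, j)] <- par[c(i, j)] + h[c(i, j)]
        pmm[c(i, j)] <- par[c(i, j)] - h[c(i, j)]
        ppm[i] <- par[i] + h[i]; ppm[j] <- par[j] - h[j]
        pmp[i] <- par[i] - h[i]; pmp[j] <- par[j] + h[j]
        H[i, j] <- H[j, i] <-
          (fn(ppp) - fn(ppm) - fn(pmp) + fn(pmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Fit the dwell-time model by maximum likelihood
#'
#' Maximizes the likelihood of [pdfApparentDwell()] over the free rates
#' (`kCtp` for the immediate model, `kCtp` and `kOff` for the delayed
#' model) with the bleaching rate fixed at `kBlFixed`. Optimization runs on
#' the log-rate scale (BFGS, positivity by construction) from a
#' method-of-moments start plus jittered restarts. 68\% confidence
#' intervals are the point estimate +/- one standard deviation from the
#' inverse observed information (central finite differences, relative step
#' 1e-4).
#'
#' @param data a [DwellSample-class] with at least 10 dwells.
#' @param model "immediate" or "delayed".
#' @param kBlFixed fixed photobleaching rate (1/s), >= 0.
#' @param minDwell optional left-truncation bound (s), default 0 (off).
#' @param nStarts number of jittered optimizer starts (default 3).
#' @param seed optional seed for the start jitter.
#' @return a [FitResult-class]. Non-convergence is reported through the
#'   `converged` flag and `details`, never silently.
#' @examples
#' s <- sampleApparentDwells(kineticRates(0.025, 0.06, 1.75e-4),
#'                           "delayed", 332, seed = 7)
#' fitDwellModel(s, "delayed", kBlFixed = 1.75e-4)
#' @export
fitDwellModel <- function(data, model = c("delayed", "immediate"),
                          kBlFixed = 0, minDwell = 0, nStarts = 3,
                          seed = NULL) {
  model <- match.arg(model)
  t <- dwellTimes(data)
  if (length(t) < 10) stop("need at least 10 dwell times", call. = FALSE)
  if (kBlFixed < 0) stop("kBlFixed must be >= 0", call. = FALSE)
  free <- .freeParams(model)

  nll <- function(par) {  # par on the rate scale, named
    v <- try({
      r <- .ratesFromPar(as.list(par), model, kBlFixed)
      negLogLikelihood(data, r, model, minDwell)
    }, silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) 1e10 else v
  }
  nllLog <- function(lp) nll(setNames(exp(lp), free))

  # method-of-moments start: immediate-model mean is 1.5/kCtp; delayed seed
  # puts kOff at twice kCtp
  m <- mean(t)
  start <- if (model == "immediate") c(kCtp = 1.5 / m)
           else c(kCtp = 2 / m, kOff = 4 / m)
  if (!is.null(seed)) set.seed(seed)
  starts <- c(list(log(start)), lapply(seq_len(max(0, nStarts - 1)),
    function(i) log(start) + runif(length(start), -0.7, 0.7)))

  fits <- lapply(starts, function(s0)
    tryCatch(optim(s0, nllLog, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
             error = function(e) list(value = Inf, convergence = 99L,
                                      message = conditionMessage(e))))
  vals <- vapply(fits, function(f) f$value, 0)
  best <- fits[[which.min(vals)]]
  est <- setNames(exp(best$par), free)
  converged <- is.finite(best$value) && best$convergence == 0L

  # observed information on the rate scale
  H <- .fdHessian(nll, est)
  sds <- rep(NA_real_, length(free))
  covOk <- FALSE
  V <- try(solve(H), silent = TRUE)
  if (!inherits(V, "try-error") && all(is.finite(diag(V))) &&
      all(diag(V) > 0)) {
    sds <- sqrt(diag(V))
    covOk <- TRUE
  }
  converged <- converged && covOk
  ci <- cbind(lower = est - sds, upper = est + sds)
  rownames(ci) <- free

  ll <- -best$value
  n <- length(t)
  nu <- length(free)
  new("FitResult", model = model,
      rates = .ratesFromPar(as.list(est), model, kBlFixed),
      ci = ci, logLik = ll, bic = nu * log(n) - 2 * ll,
      n = as.integer(n), nu = as.integer(nu), converged = converged,
      details = list(startValues = vals, optim = best[c("convergence",
                     "counts")], hessianOk = covOk, minDwell = minDwell))
}

#' Compare fitted models by BIC
#'
#' Returns the model with the lowest `BIC = nu log N - 2 logL`; ties break
#' towards fewer parameters. All fits must be on samples of identical size.
#'
#' @param fits list of [FitResult-class] objects (>= 2) fitted to the same
#'   data.
#' @return list with `model` (preferred tag), `bic` (named vector) and
#'   `deltaBic` (BIC differences to the best).
#' @export
compareModelsBic <- function(fits) {
  if (length(fits) < 2) stop("need at least two fits", call. = FALSE)
  ns <- vapply(fits, function(f) f@n, 0L)
  if (length(unique(ns)) != 1)
    stop("fits were computed on samples of different size", call. = FALSE)
  bics <- vapply(fits, function(f) f@bic, 0)
  nus <- vapply(fits, function(f) f@nu, 0L)
  names(bics) <- vapply(fits, function(f) f@model, "")
  ord <- order(bics, nus)   # ties: fewer parameters first
  list(model = names(bics)[ord[1]], bic = bics,
       deltaBic = bics - bics[ord[1]])
}

#' Bootstrap mean of a dwell sample
#'
#' Resamples the dwell times with replacement `nIter` times (default 5000)
#' and reports the bootstrap mean and spread, together with the plug-in
#' standard error of the mean `SEM = SD / sqrt(n)`.
#'
#' @param data a [DwellSample-class] with n >= 2.
#' @param nIter bootstrap iterations, > 0.
#' @param seed optional RNG seed.
#' @return list with `mean`, `bootSd` (sd of bootstrap means) and `sem`.
#' @export
bootstrapMean <- function(data, nIter = 5000, seed = NULL) {
  t <- dwellTimes(data)
  if (length(t) < 2) stop("need at least two dwell times", call. = FALSE)
  if (nIter <= 0) stop("nIter must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(t)
  bm <- vapply(seq_len(nIter), function(i) mean(t[sample.int(n, n,
                                                 replace = TRUE)]), 0)
  list(mean = mean(bm), bootSd = sd(bm), sem = sd(t) / sqrt(n))
}
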