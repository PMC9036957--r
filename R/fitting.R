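#' Control parameters for FROC fitting
#'
#' Bounds, initial values and stage switches for [fitFroc()].  Defaults:
#' D in [0.01, 3] \eqn{\times 10^{-3}} mm\eqn{^2}/s, beta in (0.3, 1],
#' mu in [1, 20] \eqn{\mu}m, S0 in (0, 2 max(signal)]; initial beta 0.8 and
#' mu 8 \eqn{\mu}m; low-b segment b <= 200 s/mm\eqn{^2}; joint refinement on.
#'
#' The mu initializer doubles as the anchor of the spatial scale: when b is
#' varied only through the gradient amplitude, D and mu enter the decay only
#' through the product \eqn{D \mu^{2(\beta - 1)}}, so the data alone cannot
#' separate them (see the methods vignette).  The main nonlinear stage
#' therefore fits the identifiable pair (D, beta) with mu held at
#' \code{muInit}; the joint refinement then lets mu move only as far as the
#' data constrain it.
#'
#' @param dBounds,betaBounds,muBounds length-2 numeric bounds.
#' @param betaInit,muInit starting values for the nonlinear stages.
#' @param lowBMax upper edge of the low-b segment used for the log-linear
#'   (S0, D) stage, s/mm\eqn{^2}.
#' @param refine logical; run the joint bounded refinement of all four
#'   parameters after the staged fit.
#' @param nodata sentinel written outside the mask by [fitMap()].
#' @param maxIter iteration cap per optimizer stage.
#' @return A list of class \code{frocFitControl}.
#' @export
frocFitControl <- function(dBounds = c(0.01, 3.0), betaBounds = c(0.3, 1.0),
                           muBounds = c(1, 20), betaInit = 0.8, muInit = 8,
                           lowBMax = 200, refine = TRUE, nodata = NA_real_,
                           maxIter = 200L) {
  stopifnot(length(dBounds) == 2L, length(betaBounds) == 2L,
            length(muBounds) == 2L, dBounds[1] > 0, betaBounds[1] > 0,
            betaBounds[2] <= 1, muBounds[1] > 0, lowBMax > 0)
  structure(list(dBounds = dBounds, betaBounds = betaBounds,
                 muBounds = muBounds, betaInit = betaInit, muInit = muInit,
                 lowBMax = lowBMax, refine = refine, nodata = nodata,
                 maxIter = as.integer(maxIter)),
            class = "frocFitControl")
}

clip <- function(x, bounds) pmin(pmax(x, bounds[1]), bounds[2])

#' Two-point ADC estimate
#'
#' Conventional mono-exponential apparent diffusion coefficient from the
#' b = 0 and b = 1000 s/mm\eqn{^2} images:
#' \eqn{ADC = \ln(S(0)/S(1000)) / 1000}, reported in \eqn{\times 10^{-3}}
#' mm\eqn{^2}/s.
#'
#' @param signal numeric decay signal aligned with \code{bValues(scheme)}.
#' @param scheme an [AcquisitionScheme-class] containing b = 0 and b = 1000.
#' @return An [AdcFit-class].  A signal that rises between the two points
#'   yields a negative ADC and \code{flagged = TRUE}.
#' @export
fitAdcTwoPoint <- function(signal, scheme) {
  stopifnot(is(scheme, "AcquisitionScheme"))
  b <- scheme@bValues
  if (length(signal) != length(b)) {
    stop("signal length does not match the scheme")
  }
  i0 <- match(0, b)
  i1 <- match(1000, b)
  if (is.na(i1)) stop("scheme must contain b = 1000 s/mm^2 for the two-point ADC")
  s0 <- signal[i0]
  s1 <- signal[i1]
  if (!is.finite(s0) || !is.finite(s1) || s0 <= 0 || s1 <= 0) {
    stop("two-point ADC needs positive signals at b = 0 and b = 1000")
  }
  adc <- log(s0 / s1) # /1000 s/mm^2 then x1e3 into Table units: identity
  new("AdcFit", adc = adc, s0 = s0, flagged = adc < 0)
}

## Residuals of the FROC model for the optimizer; p is the active subset of
## c(s0, d, beta, mu), fixed carries the rest.  When mu is active, a weak
## quadratic anchor on log(mu) is appended: with b varied only through the
## gradient amplitude the (D, mu) direction at constant D mu^(2 beta - 2) is
## exactly flat, and the anchor pins the otherwise arbitrary ridge position
## at muAnchor without perturbing identifiable parameters.
frocResiduals <- function(p, active, fixed, b, signal, deltaSmall, deltaBig,
                          muAnchor = NULL, anchorWeight = 0) {
  fixed[active] <- p
  r <- fixed[["s0"]] * exp(-frocExponent(b, fixed[["d"]], fixed[["beta"]],
                                         fixed[["mu"]], deltaSmall,
                                         deltaBig)) - signal
  if (!is.null(muAnchor) && anchorWeight > 0) {
    r <- c(r, anchorWeight * (log(fixed[["mu"]]) - log(muAnchor)))
  }
  r
}

#' Fit the FROC model to one decay signal
#'
#' Staged bounded nonlinear least squares:
#' \enumerate{
#'   \item \emph{Low-b stage}: log-linear regression of \eqn{\ln S} on b over
#'     the segment b <= \code{lowBMax} gives starting values for \eqn{S_0}
#'     and D (the latter kept as \code{stageD}).
#'   \item \emph{Main stage}: bounded Levenberg--Marquardt over the
#'     identifiable pair (D, beta) across all b-values, with mu anchored at
#'     \code{muInit} and \eqn{S_0} at its stage-1 value.
#'   \item \emph{Refinement} (optional, default on): one joint bounded pass
#'     over (\eqn{S_0}, D, beta, mu).
#' }
#' The optimizer never raises on stalls: \code{converged = FALSE} is
#' returned with the best point found.  The procedure is fully
#' deterministic.
#'
#' @param signal positive numeric decay signal aligned with the scheme.
#' @param scheme an [AcquisitionScheme-class] with gradient timing; needs at
#'   least 6 b-values including b = 0, at least 4 distinct nonzero b-values
#'   and at least two b >= 500 s/mm\eqn{^2} (the non-Gaussian regime).
#' @param control a [frocFitControl()] list.
#' @return A [FrocFit-class].
#' @examples
#' sc <- cervicalProtocol()
#' fitFroc(frocSignal(frocParams(1000, 0.82, 0.73, 8.27), sc), sc)
#' @export
fitFroc <- function(signal, scheme, control = frocFitControl()) {
  stopifnot(is(scheme, "AcquisitionScheme"))
  if (is.na(scheme@deltaSmall)) {
    stop("FROC fitting needs the gradient timing of the scheme")
  }
  b <- scheme@bValues
  if (length(signal) != length(b)) stop("signal length does not match the scheme")
  if (all(signal == 0)) stop("all-zero signal cannot be fitted")
  if (length(b) < 6L || b[1L] != 0) {
    stop("FROC fitting needs at least 6 b-values including b = 0")
  }
  if (length(unique(b[b > 0])) < 4L) {
    stop("FROC fitting needs at least 4 distinct nonzero b-values")
  }
  if (sum(b >= 500) < 2L) {
    stop("FROC fitting needs at least two b-values >= 500 s/mm^2")
  }
  if (any(!is.finite(signal)) || any(signal <= 0)) {
    stop("signals must be positive and finite")
  }
  ds <- scheme@deltaSmall
  db <- scheme@deltaBig
  ctl <- control

  ## stage 1: log-linear low-b fit
  low <- b <= ctl$lowBMax
  if (sum(low) < 2L) low <- seq_len(min(3L, length(b)))
  co <- stats::coef(stats::lm(log(signal[low]) ~ b[low]))
  s0Bounds <- c(.Machine$double.eps, 2 * max(signal))
  s0Hat <- clip(exp(co[[1L]]), s0Bounds)
  stageD <- unname(-co[[2L]] * 1e3) # slope in mm^2/s per (s/mm^2) -> x1e-3 units
  dHat <- clip(stageD, ctl$dBounds)

  par0 <- c(s0 = unname(s0Hat), d = unname(dHat), beta = ctl$betaInit,
            mu = ctl$muInit)
  lower <- c(s0 = s0Bounds[1], d = ctl$dBounds[1], beta = ctl$betaBounds[1],
             mu = ctl$muBounds[1])
  upper <- c(s0 = s0Bounds[2], d = ctl$dBounds[2], beta = ctl$betaBounds[2],
             mu = ctl$muBounds[2])

  anchorW <- 1e-3 * max(signal)
  runStage <- function(active, start) {
    withMu <- "mu" %in% active
    fit <- minpack.lm::nls.lm(
      par = start[active],
      lower = lower[active], upper = upper[active],
      fn = frocResiduals, active = active, fixed = start,
      b = b, signal = signal, deltaSmall = ds, deltaBig = db,
      muAnchor = if (withMu) ctl$muInit else NULL,
      anchorWeight = if (withMu) anchorW else 0,
      control = minpack.lm::nls.lm.control(maxiter = ctl$maxIter))
    start[active] <- pmin(pmax(unlist(fit$par), lower[active]), upper[active])
    rss <- sum(frocResiduals(start[active], active, start, b, signal, ds, db)^2)
    list(par = start, info = fit$info, niter = fit$niter, rss = rss)
  }

  ## stage 2: identifiable pair (D, beta), mu anchored
  st2 <- runStage(c("d", "beta"), par0)
  nIter <- st2$niter
  res <- st2

  ## stage 3: joint bounded refinement
  if (isTRUE(ctl$refine)) {
    st3 <- runStage(c("s0", "d", "beta", "mu"), st2$par)
    nIter <- nIter + st3$niter
    if (st3$rss <= st2$rss) res <- st3
  }

  conv <- res$info %in% 1:3
  p <- res$par
  new("FrocFit",
      params = frocParams(p[["s0"]], p[["d"]], p[["beta"]], p[["mu"]]),
      rss = res$rss, converged = conv, nIter = as.integer(nIter),
      stageD = stageD)
}

#' Voxelwise parameter mapping
#'
#' Runs [fitAdcTwoPoint()] and [fitFroc()] on every voxel of a 4D DWI volume
#' inside a 3D mask, assembling co-registered ADC, D, beta and mu maps.
#' Voxels outside the mask carry the \code{nodata} sentinel; voxels whose
#' fit fails or does not converge are flagged in the convergence map and the
#' per-map count of such voxels is reported via \code{message()}.
#'
#' @param volume 4D numeric array; 4th dimension aligned with the scheme.
#' @param mask 3D array (logical or 0/1) matching the spatial dimensions.
#' @param scheme an [AcquisitionScheme-class].
#' @param control a [frocFitControl()] list.
#' @return A [ParameterMapSet-class].
#' @export
fitMap <- function(volume, mask, scheme, control = frocFitControl()) {
  stopifnot(is(scheme, "AcquisitionScheme"))
  dv <- dim(volume)
  if (length(dv) != 4L || dv[4L] != length(scheme@bValues)) {
    stop("volume must be 4D with 4th dimension matching the scheme")
  }
  dm <- dim(mask)
  if (length(dm) != 3L || !all(dm == dv[1:3])) {
    stop("mask shape does not match the volume's spatial dimensions")
  }
  maskL <- array(as.logical(mask), dim = dm)
  nod <- control$nodata
  shape3 <- dv[1:3]
  adc <- d <- beta <- mu <- array(nod, dim = shape3)
  conv <- array(FALSE, dim = shape3)
  idx <- which(maskL)
  if (!length(idx)) {
    warning("empty mask: no voxels fitted")
  }
  nvb <- prod(shape3)
  nFail <- 0L
  for (i in idx) {
    sig <- volume[i + (seq_len(dv[4L]) - 1L) * nvb]
    ok <- tryCatch({
      af <- fitAdcTwoPoint(sig, scheme)
      ff <- fitFroc(sig, scheme, control)
      adc[i] <- af@adc
      d[i] <- ff@params@d
      beta[i] <- ff@params@beta
      mu[i] <- ff@params@mu
      ff@converged
    }, error = function(e) FALSE)
    conv[i] <- ok
    if (!ok) nFail <- nFail + 1L
  }
  message(sprintf("fitMap: %d voxels fitted, %d non-converged or failed",
                  length(idx), nFail))
  new("ParameterMapSet", adc = adc, d = d, beta = beta, mu = mu,
      mask = maskL, converged = conv, nodata = nod)
}

setMethod("show", "ParameterMapSet", function(object) {
  dm <- dim(object@adc)
  cat(sprintf("ParameterMapSet %dx%dx%d; %d masked voxels (%d converged)\n",
              dm[1], dm[2], dm[3], sum(object@mask), sum(object@converged)))
  invisible(NULL)
})

#' Extract one parameter map
#'
#' @param maps a [ParameterMapSet-class].
#' @param which one of "adc", "d", "beta", "mu".
#' @return The 3D array of that parameter.
#' @export
parameterMap <- function(maps, which = c("adc", "d", "beta", "mu")) {
  which <- match.arg(which)
  slot(maps, which)
}
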