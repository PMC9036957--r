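#' Construct an acquisition scheme
#'
#' @param bValues numeric vector of b-values in s/mm\eqn{^2}; must start at 0
#'   and be strictly increasing.
#' @param deltaSmall gradient pulse duration \eqn{\delta} in ms, or NA when
#'   the timing is unknown (the mono-exponential model does not need it).
#' @param deltaBig gradient separation \eqn{\Delta} in ms, or NA.
#' @param gamma gyromagnetic ratio, rad s\eqn{^{-1}} T\eqn{^{-1}}.
#' @return An [AcquisitionScheme-class] object.
#' @examples
#' acquisitionScheme(c(0, 500, 1000), deltaSmall = 20, deltaBig = 40)
#' @export
acquisitionScheme <- function(bValues, deltaSmall = NA_real_,
                              deltaBig = NA_real_, gamma = protonGamma) {
  new("AcquisitionScheme", bValues = as.numeric(bValues),
      deltaSmall = as.numeric(deltaSmall), deltaBig = as.numeric(deltaBig),
      gamma = as.numeric(gamma))
}

#' The nine-b-value cervical DWI protocol
#'
#' The multi-b-value EPI-DWI protocol used throughout the package's worked
#' examples: b = 0, 20, 40, 80, 160, 200, 500, 1000 and 2000 s/mm\eqn{^2}.
#' The gradient timing is not part of the published protocol; the defaults
#' \eqn{\delta} = 20 ms, \eqn{\Delta} = 40 ms are stated assumptions,
#' typical of a 3T spin-echo EPI diffusion preparation, and can be
#' overridden.
#'
#' @inheritParams acquisitionScheme
#' @return An [AcquisitionScheme-class].
#' @export
cervicalProtocol <- function(deltaSmall = 20, deltaBig = 40,
                             gamma = protonGamma) {
  acquisitionScheme(c(0, 20, 40, 80, 160, 200, 500, 1000, 2000),
                    deltaSmall = deltaSmall, deltaBig = deltaBig,
                    gamma = gamma)
}

#' @describeIn acquisitionScheme b-values accessor.
#' @param x an AcquisitionScheme.
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))

#' @rdname acquisitionScheme
#' @export
setMethod("bValues", "AcquisitionScheme", function(x) x@bValues)

#' @describeIn acquisitionScheme gradient timing accessor; returns
#'   c(deltaSmall, deltaBig) in ms.
#' @export
setGeneric("gradientTiming", function(x) standardGeneric("gradientTiming"))

#' @rdname acquisitionScheme
#' @export
setMethod("gradientTiming", "AcquisitionScheme", function(x) {
  c(deltaSmall = x@deltaSmall, deltaBig = x@deltaBig)
})

setMethod("show", "AcquisitionScheme", function(object) {
  cat("AcquisitionScheme with", length(object@bValues), "b-values (s/mm^2):\n ",
      paste(object@bValues, collapse = ", "), "\n")
  if (!is.na(object@deltaSmall)) {
    cat("  delta =", object@deltaSmall, "ms, Delta =", object@deltaBig, "ms\n")
  } else {
    cat("  gradient timing: not specified\n")
  }
  invisible(NULL)
})

#' Construct a FROC parameter set
#'
#' @param s0 signal at b = 0 (arbitrary units), positive.
#' @param d anomalous diffusion coefficient, \eqn{\times 10^{-3}}
#'   mm\eqn{^2}/s, positive.
#' @param beta heterogeneity exponent in (0, 1].
#' @param mu spatial parameter, \eqn{\mu}m, positive.
#' @return A [FrocParams-class].
#' @export
frocParams <- function(s0, d, beta, mu) {
  new("FrocParams", s0 = as.numeric(s0), d = as.numeric(d),
      beta = as.numeric(beta), mu = as.numeric(mu))
}

setMethod("show", "FrocFit", function(object) {
  p <- object@params
  cat(sprintf(
    "FrocFit: S0 = %.4g, D = %.4g x1e-3 mm^2/s, beta = %.4g, mu = %.4g um\n",
    p@s0, p@d, p@beta, p@mu))
  cat(sprintf("  rss = %.4g, converged = %s, iterations = %d, stage D = %.4g\n",
              object@rss, object@converged, object@nIter, object@stageD))
  invisible(NULL)
})

## Decay exponent of the FROC model, fully vectorized over voxels x b-values.
## Units: b in s/mm^2, d in 1e-3 mm^2/s, mu in um, timing in ms; evaluation in
## a consistent (mm, s) system.  With b varied through the gradient amplitude
## at fixed timing, (gamma G delta)^(2 beta) = [b / (Delta - delta/3)]^beta,
## so the exponent collapses to  d' mu'^(2(beta-1)) K(beta) b^beta  with
## K(beta) = (Delta - delta/3)^(-beta) (Delta - (2 beta - 1)/(2 beta + 1) delta).
frocExponent <- function(b, d, beta, mu, deltaSmall, deltaBig) {
  dS <- deltaSmall * 1e-3 # s
  dB <- deltaBig * 1e-3
  dMm <- d * 1e-3    # mm^2/s
  muMm <- mu * 1e-3  # mm
  tdiff <- dB - dS / 3
  tau <- dB - (2 * beta - 1) / (2 * beta + 1) * dS
  pref <- dMm * muMm^(2 * (beta - 1)) * tdiff^(-beta) * tau
  bPow <- ifelse(b == 0, 0, exp(beta * log(ifelse(b == 0, 1, b))))
  pref * bPow
}

#' FROC forward signal model
#'
#' Evaluates the fractional-order-calculus diffusion signal
#' \deqn{S(b) = S_0 \exp\!\Big[-D\,\mu^{2(\beta-1)}\,(\gamma G_d
#'   \delta)^{2\beta}\Big(\Delta - \frac{2\beta-1}{2\beta+1}\,\delta\Big)\Big]}
#' at each b-value of the scheme.  The gradient amplitude \eqn{G_d} is
#' eliminated through the Stejskal--Tanner relation
#' \eqn{b = (\gamma G_d \delta)^2 (\Delta - \delta/3)}, i.e.
#' \eqn{(\gamma G_d \delta)^{2\beta} = [b/(\Delta - \delta/3)]^{\beta}},
#' so only \code{(b, delta, Delta)} are needed.  At \eqn{\beta = 1} the
#' timing factors cancel and the model reduces exactly to
#' \eqn{S_0 e^{-bD}}.
#'
#' @param params a [FrocParams-class].
#' @param scheme an [AcquisitionScheme-class] with gradient timing set.
#' @return Numeric vector of signal intensities aligned with
#'   \code{bValues(scheme)}.
#' @examples
#' sc <- cervicalProtocol()
#' frocSignal(frocParams(1000, 0.77, 0.67, 8.19), sc)
#' @export
frocSignal <- function(params, scheme) {
  stopifnot(is(params, "FrocParams"), is(scheme, "AcquisitionScheme"))
  validObject(params)
  validObject(scheme)
  if (is.na(scheme@deltaSmall) || is.na(scheme@deltaBig)) {
    stop("the FROC model needs the gradient timing (delta, Delta) of the scheme")
  }
  b <- scheme@bValues
  params@s0 * exp(-frocExponent(b, params@d, params@beta, params@mu,
                                scheme@deltaSmall, scheme@deltaBig))
}

#' Mono-exponential (Gaussian) signal model
#'
#' \eqn{S(b) = S_0 e^{-b \cdot ADC}} at each b-value of the scheme.
#'
#' @param s0 positive signal at b = 0.
#' @param adc apparent diffusion coefficient, \eqn{\times 10^{-3}}
#'   mm\eqn{^2}/s, positive.
#' @param scheme an [AcquisitionScheme-class].
#' @return Numeric vector aligned with \code{bValues(scheme)}.
#' @export
monoSignal <- function(s0, adc, scheme) {
  stopifnot(is(scheme, "AcquisitionScheme"))
  if (!is.numeric(s0) || length(s0) != 1L || s0 <= 0) {
    stop("s0 must be a positive scalar")
  }
  if (!is.numeric(adc) || length(adc) != 1L || adc <= 0) {
    stop("adc must be a positive scalar")
  }
  s0 * exp(-scheme@bValues * adc * 1e-3)
}

#' b-value of a pulsed-gradient experiment
#'
#' Standard Stejskal--Tanner relation \eqn{b = (\gamma G_d \delta)^2
#' (\Delta - \delta/3)}, returned in s/mm\eqn{^2}.
#'
#' @param gamma gyromagnetic ratio, rad s\eqn{^{-1}} T\eqn{^{-1}}.
#' @param gD diffusion gradient amplitude, T/m.
#' @param deltaSmall gradient pulse duration \eqn{\delta}, ms.
#' @param deltaBig gradient separation \eqn{\Delta}, ms.
#' @return b-value in s/mm\eqn{^2}.
#' @examples
#' bFromGradient(protonGamma, 30e-3, 20, 40) # ~859 s/mm^2
#' @export
bFromGradient <- function(gamma = protonGamma, gD, deltaSmall, deltaBig) {
  if (any(c(gamma, deltaSmall, deltaBig) <= 0) || gD < 0) {
    stop("gamma, delta and Delta must be positive; gD non-negative")
  }
  if (deltaBig <= deltaSmall) stop("need Delta > delta")
  dS <- deltaSmall * 1e-3
  dB <- deltaBig * 1e-3
  b <- (gamma * gD * dS)^2 * (dB - dS / 3) / 1e6 # s/m^2 -> s/mm^2
  if (b > 1e5) {
    stop("computed b exceeds 1e5 s/mm^2; check input units (gD in T/m, timing in ms)")
  }
  b
}
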