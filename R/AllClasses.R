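#' @import methods
NULL

#' Gyromagnetic ratio of the proton
#'
#' \eqn{\gamma} for \eqn{^1}H in rad s\eqn{^{-1}} T\eqn{^{-1}}, used to relate
#' the diffusion gradient amplitude to the b-value through the
#' Stejskal--Tanner relation \eqn{b = (\gamma G_d \delta)^2 (\Delta -
#' \delta/3)}.  Overridable wherever a \code{gamma} argument is accepted.
#'
#' @export
protonGamma <- 2.6753e8

#' Diffusion acquisition scheme
#'
#' Encodes the diffusion weighting of a multi-b-value DWI series: the
#' b-values (s/mm\eqn{^2}) and, when known, the gradient pulse duration
#' \eqn{\delta} and separation \eqn{\Delta} (ms) of the pulsed-gradient
#' spin-echo preparation.  The gradient amplitude itself is never stored; it
#' is eliminated analytically through the Stejskal--Tanner relation, so an
#' acquisition is fully described by \code{(b, delta, Delta)}.
#'
#' @slot bValues numeric, non-negative and strictly increasing, first element 0.
#' @slot deltaSmall gradient pulse duration \eqn{\delta} in ms (NA if unknown).
#' @slot deltaBig gradient separation \eqn{\Delta} in ms (NA if unknown).
#' @slot gamma gyromagnetic ratio in rad s\eqn{^{-1}} T\eqn{^{-1}}.
#'
#' @seealso [acquisitionScheme()], [cervicalProtocol()]
#' @export
setClass("AcquisitionScheme",
  representation(
    bValues = "numeric",
    deltaSmall = "numeric",
    deltaBig = "numeric",
    gamma = "numeric"
  )
)

setValidity("AcquisitionScheme", function(object) {
  b <- object@bValues
  msg <- character()
  if (length(b) < 2L) msg <- c(msg, "need at least two b-values")
  if (anyNA(b) || any(b < 0)) msg <- c(msg, "b-values must be non-negative")
  if (length(b) && b[1L] != 0) msg <- c(msg, "first b-value must be 0")
  if (is.unsorted(b, strictly = TRUE)) {
    msg <- c(msg, "b-values must be strictly increasing")
  }
  ds <- object@deltaSmall
  db <- object@deltaBig
  if (length(ds) != 1L || length(db) != 1L) {
    msg <- c(msg, "delta and Delta must be scalars (possibly NA)")
  } else if (!is.na(ds) || !is.na(db)) {
    if (is.na(ds) || is.na(db)) {
      msg <- c(msg, "provide both delta and Delta or neither")
    } else if (!(db > ds && ds > 0)) {
      msg <- c(msg, "need Delta > delta > 0")
    }
  }
  if (length(object@gamma) != 1L || !is.finite(object@gamma) ||
      object@gamma <= 0) {
    msg <- c(msg, "gamma must be a positive scalar")
  }
  if (length(msg)) msg else TRUE
})

#' FROC model parameters
#'
#' Parameter set of the fractional-order-calculus diffusion signal model:
#' signal without weighting \eqn{S_0}, anomalous diffusion coefficient
#' \eqn{D} (reported in \eqn{\times 10^{-3}} mm\eqn{^2}/s), intravoxel
#' heterogeneity exponent \eqn{\beta \in (0, 1]} (\eqn{\beta = 1} recovers
#' Gaussian diffusion) and spatial scale \eqn{\mu} (\eqn{\mu}m).
#'
#' @slot s0 positive scalar, arbitrary signal units.
#' @slot d anomalous diffusion coefficient, \eqn{\times 10^{-3}} mm\eqn{^2}/s.
#' @slot beta heterogeneity exponent in (0, 1].
#' @slot mu spatial parameter, \eqn{\mu}m.
#' @export
setClass("FrocParams",
  representation(s0 = "numeric", d = "numeric", beta = "numeric",
                 mu = "numeric")
)

setValidity("FrocParams", function(object) {
  v <- c(s0 = object@s0, d = object@d, beta = object@beta, mu = object@mu)
  if (length(v) != 4L || anyNA(v)) return("all four parameters must be scalars")
  msg <- character()
  if (object@s0 <= 0) msg <- c(msg, "s0 must be positive")
  if (object@d <= 0) msg <- c(msg, "d must be positive")
  if (object@beta <= 0 || object@beta > 1) msg <- c(msg, "beta must lie in (0, 1]")
  if (object@mu <= 0) msg <- c(msg, "mu must be positive")
  if (length(msg)) msg else TRUE
})

#' Result of a FROC model fit
#'
#' @slot params fitted [FrocParams-class].
#' @slot rss residual sum of squares (signal units squared).
#' @slot converged logical success flag; when FALSE the parameters carry the
#'   best point found rather than an error.
#' @slot nIter total optimizer iterations across stages.
#' @slot stageD the mono-exponential D estimate from the low-b stage,
#'   \eqn{\times 10^{-3}} mm\eqn{^2}/s, kept as a diagnostic.
#' @export
setClass("FrocFit",
  representation(params = "FrocParams", rss = "numeric",
                 converged = "logical", nIter = "integer", stageD = "numeric")
)

setValidity("FrocFit", function(object) {
  if (length(object@rss) != 1L || is.na(object@rss) || object@rss < 0) {
    return("rss must be a non-negative scalar")
  }
  TRUE
})

#' Result of a two-point ADC fit
#'
#' @slot adc apparent diffusion coefficient, \eqn{\times 10^{-3}} mm\eqn{^2}/s.
#'   Negative values are permitted only for inputs whose signal rises with b;
#'   such fits are flagged.
#' @slot s0 signal at b = 0 used for the estimate.
#' @slot flagged logical; TRUE when the input violated monotonicity.
#' @export
setClass("AdcFit",
  representation(adc = "numeric", s0 = "numeric", flagged = "logical")
)

#' Co-registered diffusion parameter maps
#'
#' Holds the four 3D parameter maps produced by voxelwise fitting (ADC, D,
#' beta, mu, in the units used throughout: \eqn{\times 10^{-3}} mm\eqn{^2}/s
#' for ADC and D, unitless beta, \eqn{\mu}m for mu), the fitted mask, a
#' per-voxel convergence map, and the sentinel used outside the mask.
#'
#' @slot adc,d,beta,mu 3D numeric arrays of one common shape.
#' @slot mask 3D logical array; TRUE where a fit was attempted.
#' @slot converged 3D logical array; TRUE where the FROC fit converged.
#' @slot nodata sentinel value carried by voxels outside the mask.
#' @export
setClass("ParameterMapSet",
  representation(adc = "array", d = "array", beta = "array", mu = "array",
                 mask = "array", converged = "array", nodata = "numeric")
)

setValidity("ParameterMapSet", function(object) {
  dims <- lapply(list(object@adc, object@d, object@beta, object@mu,
                      object@mask, object@converged), dim)
  if (any(vapply(dims, length, 1L) != 3L)) {
    return("all maps must be 3D arrays")
  }
  if (!all(vapply(dims, identical, TRUE, y = dims[[1L]]))) {
    return("all maps must share one shape")
  }
  if (length(object@nodata) != 1L) return("nodata must be a scalar")
  TRUE
})

#' ROC analysis result
#'
#' Empirical ROC of a continuous score against a binary gold standard, with
#' the Mann--Whitney AUC, a Hanley--McNeil 95\% confidence interval, and the
#' Youden-index operating point (cutoff, sensitivity, specificity, accuracy).
#' Scores and labels are retained so that paired curve comparisons
#' ([compareAuc()]) and paired classification comparisons ([mcnemarTest()])
#' can be run afterwards.
#'
#' @slot auc area under the curve (orientation chosen so auc >= 0.5).
#' @slot ciLow,ciHigh 95\% confidence bounds, clipped to [0, 1].
#' @slot cutoff Youden-optimal threshold on the original score scale.
#' @slot sensitivity,specificity,accuracy operating characteristics at the
#'   cutoff, on the same cohort.
#' @slot direction "gt" if larger scores indicate the positive class at the
#'   chosen orientation, "lt" otherwise.
#' @slot scores,labels the per-subject inputs (labels as logical: TRUE =
#'   positive class).
#' @slot positiveLabel the class treated as positive.
#' @export
setClass("RocResult",
  representation(auc = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 cutoff = "numeric", sensitivity = "numeric",
                 specificity = "numeric", accuracy = "numeric",
                 direction = "character", scores = "numeric",
                 labels = "logical", positiveLabel = "character")
)

setValidity("RocResult", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must lie in [0, 1]")
  if (object@ciLow > object@auc || object@ciHigh < object@auc) {
    msg <- c(msg, "confidence interval must contain the auc")
  }
  ok01 <- function(x) x >= 0 && x <= 1
  if (!all(vapply(list(object@sensitivity, object@specificity,
                       object@accuracy), ok01, TRUE))) {
    msg <- c(msg, "operating characteristics must lie in [0, 1]")
  }
  if (!object@direction %in% c("gt", "lt")) {
    msg <- c(msg, "direction must be 'gt' or 'lt'")
  }
  if (length(object@scores) != length(object@labels)) {
    msg <- c(msg, "scores and labels must have equal length")
  }
  if (length(msg)) msg else TRUE
})

#' Logistic combination of diffusion parameters
#'
#' @slot features names of the combined parameters.
#' @slot coefficients intercept and slopes of the logistic model.
#' @slot scores per-subject combined score (the linear predictor).
#' @slot roc [RocResult-class] of the combined score.
#' @slot separated TRUE when the fit showed (quasi-)complete separation; the
#'   score from the final iterate is still usable for ranking.
#' @export
setClass("CombinedModel",
  representation(features = "character", coefficients = "numeric",
                 scores = "numeric", roc = "RocResult", separated = "logical")
)
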