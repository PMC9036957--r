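## Run expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Truncated-normal draws by rejection; bounds keep parameters physical.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Specification of one synthetic patient group
#'
#' Mean and SD of the four VOI-mean diffusion parameters for one group, in
#' the units used throughout (ADC and D in \eqn{\times 10^{-3}}
#' mm\eqn{^2}/s, beta unitless, mu in \eqn{\mu}m).  Subjects are drawn from
#' independent truncated normal distributions; beta is truncated to
#' (0.3, 1] and D, mu, ADC to physically sensible ranges.
#'
#' @param label group name.
#' @param n number of subjects, >= 1.
#' @param meanAdc,sdAdc,meanBeta,sdBeta,meanD,sdD,meanMu,sdMu distribution
#'   parameters; all SDs >= 0.
#' @return A list of class \code{GroupSpec}.
#' @export
groupSpec <- function(label, n, meanAdc, sdAdc, meanBeta, sdBeta,
                      meanD, sdD, meanMu, sdMu) {
  sds <- c(sdAdc, sdBeta, sdD, sdMu)
  if (any(sds < 0)) stop("group SDs must be non-negative")
  if (n < 1) stop("group size must be >= 1")
  structure(list(label = as.character(label), n = as.integer(n),
                 meanAdc = meanAdc, sdAdc = sdAdc,
                 meanBeta = meanBeta, sdBeta = sdBeta,
                 meanD = meanD, sdD = sdD,
                 meanMu = meanMu, sdMu = sdMu),
            class = "GroupSpec")
}

#' Built-in cohort presets
#'
#' Default group specifications emulating a 60-patient cervical carcinoma
#' cohort: the \code{"subtype"} preset contrasts squamous cell carcinoma
#' (SCC, n = 47) with adenocarcinoma (ACA, n = 13); the \code{"grade"}
#' preset contrasts low-grade (n = 28) with high-grade (n = 32) tumours.
#' Parameter means and SDs follow the published per-group VOI statistics of
#' that cohort.
#'
#' @param which "subtype" or "grade".
#' @param nScale positive multiplier applied to both group sizes (useful for
#'   large-sample checks).
#' @return List of two [groupSpec()] objects.
#' @export
cohortPreset <- function(which = c("subtype", "grade"), nScale = 1) {
  which <- match.arg(which)
  stopifnot(nScale > 0)
  s <- function(n) max(1L, as.integer(round(n * nScale)))
  if (which == "subtype") {
    list(
      groupSpec("SCC", s(47), meanAdc = 0.92, sdAdc = 0.17,
                meanBeta = 0.67, sdBeta = 0.05, meanD = 0.77, sdD = 0.12,
                meanMu = 8.19, sdMu = 0.80),
      groupSpec("ACA", s(13), meanAdc = 1.00, sdAdc = 0.27,
                meanBeta = 0.71, sdBeta = 0.08, meanD = 0.80, sdD = 0.20,
                meanMu = 8.40, sdMu = 0.31)
    )
  } else {
    list(
      groupSpec("low", s(28), meanAdc = 0.98, sdAdc = 0.19,
                meanBeta = 0.73, sdBeta = 0.06, meanD = 0.82, sdD = 0.13,
                meanMu = 8.27, sdMu = 0.93),
      groupSpec("high", s(32), meanAdc = 0.90, sdAdc = 0.20,
                meanBeta = 0.68, sdBeta = 0.08, meanD = 0.74, sdD = 0.14,
                meanMu = 8.26, sdMu = 0.36)
    )
  }
}

#' Sample a synthetic cohort of VOI-mean parameters
#'
#' Draws, for every subject, the four VOI-mean parameters from independent
#' truncated normal distributions defined by the group specifications.  The
#' group label is the ground truth carried into the downstream statistics.
#'
#' @param specs list of [groupSpec()] objects.
#' @param seed integer seed; sampling is fully reproducible.
#' @return data.frame with columns subject_id, group, mean_adc, mean_beta,
#'   mean_d, mean_mu.
#' @examples
#' head(sampleCohort(cohortPreset("subtype"), seed = 1))
#' @export
sampleCohort <- function(specs, seed) {
  if (!length(specs)) stop("need at least one group specification")
  if (missing(seed)) stop("a seed is required for cohort sampling")
  withSeed(seed, {
    rows <- lapply(specs, function(g) {
      stopifnot(inherits(g, "GroupSpec"))
      data.frame(
        group = rep(g$label, g$n),
        mean_adc = rtruncnorm(g$n, g$meanAdc, g$sdAdc, 0.05, 5),
        mean_beta = rtruncnorm(g$n, g$meanBeta, g$sdBeta, 0.3, 1.0),
        mean_d = rtruncnorm(g$n, g$meanD, g$sdD, 0.01, 3.0),
        mean_mu = rtruncnorm(g$n, g$meanMu, g$sdMu, 1, 20),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(out))), out)
    out$subject_id <- as.character(out$subject_id)
    out
  })
}

#' Ground truth for an image-level phantom
#'
#' Builds the voxelwise truth maps for [makePhantom()]: a 3D grid with a
#' central ellipsoidal lesion carrying the lesion parameters and a
#' surrounding background tissue.  The default 20 x 20 x 5 grid keeps
#' end-to-end fitting tests at minute scale.
#'
#' @param shape integer length-3 grid size.
#' @param lesion named numeric vector or list with adc, d, beta, mu for the
#'   lesion voxels.
#' @param background same for background voxels.
#' @param s0 b = 0 signal, uniform across the volume.
#' @param snr ratio of the b = 0 signal to the Rician noise sigma; Inf
#'   disables noise.
#' @return List of class \code{PhantomTruth}: arrays adc, d, beta, mu, the
#'   logical lesion \code{mask}, \code{s0} and \code{snr}.
#' @export
phantomTruth <- function(shape = c(20, 20, 5),
                         lesion = c(adc = 0.90, d = 0.74, beta = 0.68,
                                    mu = 8.26),
                         background = c(adc = 1.60, d = 1.40, beta = 0.90,
                                        mu = 8.0),
                         s0 = 1000, snr = 50) {
  stopifnot(length(shape) == 3L, snr > 0, s0 > 0)
  lesion <- as.list(lesion)
  background <- as.list(background)
  ctr <- (shape + 1) / 2
  rad <- pmax(shape / 3, 1)
  g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                   k = seq_len(shape[3]))
  inside <- ((g$i - ctr[1]) / rad[1])^2 + ((g$j - ctr[2]) / rad[2])^2 +
    ((g$k - ctr[3]) / rad[3])^2 <= 1
  mask <- array(inside, dim = shape)
  mk <- function(p) array(ifelse(inside, lesion[[p]], background[[p]]),
                          dim = shape)
  structure(list(adc = mk("adc"), d = mk("d"), beta = mk("beta"),
                 mu = mk("mu"), mask = mask, s0 = s0, snr = snr),
            class = "PhantomTruth")
}

#' Apply Rician noise to a magnitude signal
#'
#' Magnitude-MRI noise model: \eqn{M = \sqrt{(S + n_1)^2 + n_2^2}} with
#' \eqn{n_1, n_2} independent zero-mean Gaussians of SD \code{sigma}.
#' \code{sigma = 0} is the identity.  Useful closed-form moments:
#' \eqn{E[M^2] = S^2 + 2\sigma^2}, and at S = 0 the output is Rayleigh with
#' mean \eqn{\sigma\sqrt{\pi/2}}.
#'
#' @param signal numeric vector or array of noiseless magnitudes.
#' @param sigma noise SD, >= 0.
#' @param seed optional integer seed for reproducibility.
#' @return Noisy magnitudes, same shape as \code{signal}.
#' @export
ricianNoise <- function(signal, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(signal)
  draw <- function() {
    n <- length(signal)
    out <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 +
                  stats::rnorm(n, 0, sigma)^2)
    if (!is.null(dim(signal))) dim(out) <- dim(signal)
    out
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' Generate a 4D DWI phantom from voxelwise truth
#'
#' Evaluates the FROC forward model at every voxel of a [phantomTruth()]
#' object over the scheme's b-values, then applies Rician noise at
#' \eqn{\sigma = S_0 / \mathrm{snr}} (no noise when \code{snr} is Inf).
#'
#' @param truth a \code{PhantomTruth}.
#' @param scheme an [AcquisitionScheme-class] with gradient timing.
#' @param seed integer seed for the noise (ignored when snr is Inf).
#' @return 4D array: spatial grid x b-values.
#' @export
makePhantom <- function(truth, scheme, seed = 1L) {
  stopifnot(inherits(truth, "PhantomTruth"), is(scheme, "AcquisitionScheme"))
  if (is.na(scheme@deltaSmall)) {
    stop("phantom generation needs the gradient timing of the scheme")
  }
  shape <- dim(truth$adc)
  b <- scheme@bValues
  nb <- length(b)
  nv <- prod(shape)
  dV <- as.numeric(truth$d)
  betaV <- as.numeric(truth$beta)
  muV <- as.numeric(truth$mu)
  ## voxel x b matrix of decay exponents; prefactor is per-voxel, b^beta mixes
  dS <- scheme@deltaSmall * 1e-3
  dB <- scheme@deltaBig * 1e-3
  tdiff <- dB - dS / 3
  tau <- dB - (2 * betaV - 1) / (2 * betaV + 1) * dS
  pref <- dV * 1e-3 * (muV * 1e-3)^(2 * (betaV - 1)) * tdiff^(-betaV) * tau
  logb <- ifelse(b == 0, 0, log(b))
  bPow <- exp(outer(betaV, logb)) # nv x nb
  bPow[, b == 0] <- 0
  sig <- truth$s0 * exp(-pref * bPow)
  vol <- array(sig, dim = c(shape, nb))
  if (is.finite(truth$snr)) {
    vol <- ricianNoise(vol, sigma = truth$s0 / truth$snr, seed = seed)
  }
  vol
}
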