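#' Mann-Whitney U test for two independent groups
#'
#' Two-sided rank-sum comparison.  When both groups have at most
#' \code{exactMax} observations and there are no ties, the exact null
#' distribution is used; otherwise the normal approximation with tie
#' correction (and no continuity correction, matching the asymptotic output
#' of mainstream clinical statistics software).
#'
#' @param valuesA,valuesB numeric vectors, each with >= 2 observations.
#' @param exactMax switch point between exact and approximate p-values.
#' @return A list of class \code{ComparisonResult}: \code{u} (U statistic of
#'   group A), \code{p}, \code{exact} flag, and per-group descriptives
#'   (mean, sd, median, range).
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
mannWhitney <- function(valuesA, valuesB, exactMax = 8L) {
  if (length(valuesA) < 2L || length(valuesB) < 2L) {
    stop("each group needs at least 2 observations")
  }
  ties <- anyDuplicated(c(valuesA, valuesB)) > 0L
  exact <- !ties && length(valuesA) <= exactMax && length(valuesB) <= exactMax
  wt <- suppressWarnings(
    stats::wilcox.test(valuesA, valuesB, exact = exact, correct = FALSE))
  desc <- function(x) {
    c(mean = mean(x), sd = stats::sd(x), median = stats::median(x),
      range = diff(range(x)))
  }
  structure(list(u = unname(wt$statistic), p = wt$p.value, exact = exact,
                 groupA = desc(valuesA), groupB = desc(valuesB)),
            class = "ComparisonResult")
}

#' Bonferroni correction
#'
#' \eqn{p_{adj} = \min(1, m \cdot p)} per value.  \code{m} defaults to 4,
#' the number of diffusion parameters compared per analysis (ADC, beta, D,
#' mu).
#'
#' @param p numeric p-values in [0, 1].
#' @param m number of tests.
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p, m = 4L) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pmin(1, m * p)
}

## Mann-Whitney AUC with 0.5 credit for ties: wilcox statistic / (nP * nN).
aucMW <- function(scores, pos) {
  nP <- sum(pos)
  nN <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

## Hanley-McNeil standard error of an empirical AUC.
hanleyMcNeilSE <- function(auc, nPos, nNeg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (nPos - 1) * (q1 - auc^2) +
          (nNeg - 1) * (q2 - auc^2)) / (nPos * nNeg))
}

#' ROC analysis with Youden-index operating point
#'
#' Empirical ROC of a continuous score against a binary gold standard.  The
#' AUC is the Mann--Whitney (trapezoidal) estimator; its 95\% confidence
#' interval uses the Hanley--McNeil standard error with a normal
#' approximation, clipped to [0, 1].  The score orientation is chosen so
#' that AUC >= 0.5 and recorded in \code{direction}: "gt" means larger
#' scores indicate the positive class (rule: score >= cutoff is positive),
#' "lt" the opposite (score <= cutoff is positive).  The Youden cutoff is
#' the observed score value maximizing sensitivity + specificity - 1, the
#' lowest qualifying value on ties.
#'
#' @param scores finite numeric scores.
#' @param labels vector of class labels, two classes present.
#' @param positiveLabel the label treated as positive (default: the label of
#'   the class the oriented score increases with is still reported as
#'   \code{positiveLabel}; sensitivity is defined on this class).
#' @return A [RocResult-class].
#' @examples
#' rocAnalysis(c(1, 2, 3, 4), c("a", "a", "b", "b"), positiveLabel = "b")
#' @export
rocAnalysis <- function(scores, labels, positiveLabel) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (missing(positiveLabel)) positiveLabel <- as.character(sort(unique(labels))[1L])
  pos <- labels == positiveLabel
  if (!any(pos) || all(pos)) stop("both classes must be present")
  auc0 <- aucMW(scores, pos)
  direction <- if (auc0 >= 0.5) "gt" else "lt"
  auc <- max(auc0, 1 - auc0)
  nP <- sum(pos)
  nN <- sum(!pos)
  se <- hanleyMcNeilSE(auc, nP, nN)
  ci <- clip(auc + c(-1, 1) * stats::qnorm(0.975) * se, c(0, 1))
  yj <- youdenScan(scores, pos, direction)
  new("RocResult", auc = auc, ciLow = min(ci[1], auc), ciHigh = max(ci[2], auc),
      cutoff = yj$cutoff, sensitivity = yj$sensitivity,
      specificity = yj$specificity, accuracy = yj$accuracy,
      direction = direction, scores = as.numeric(scores),
      labels = as.logical(pos), positiveLabel = as.character(positiveLabel))
}

## Exhaustive scan over observed thresholds; lowest cutoff wins ties.
youdenScan <- function(scores, pos, direction) {
  cuts <- sort(unique(scores))
  best <- NULL
  for (ct in cuts) {
    pred <- if (direction == "gt") scores >= ct else scores <= ct
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(cutoff = ct, sensitivity = sens, specificity = spec,
                   accuracy = mean(pred == pos), j = j)
    }
  }
  best
}

#' @describeIn rocAnalysis recompute the Youden operating point of a fitted
#'   ROC; returns a list (cutoff, sensitivity, specificity, accuracy).
#' @param roc a [RocResult-class].
#' @export
youdenCutoff <- function(roc) {
  stopifnot(is(roc, "RocResult"))
  out <- youdenScan(roc@scores, roc@labels, roc@direction)
  out[c("cutoff", "sensitivity", "specificity", "accuracy")]
}

#' @describeIn rocAnalysis per-subject predicted-correct indicators at the
#'   Youden cutoff (input to [mcnemarTest()]).
#' @export
rocCorrect <- function(roc) {
  stopifnot(is(roc, "RocResult"))
  pred <- if (roc@direction == "gt") roc@scores >= roc@cutoff
          else roc@scores <= roc@cutoff
  pred == roc@labels
}

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUC = %.3f (95%% CI %.3f-%.3f)\n",
              object@auc, object@ciLow, object@ciHigh))
  cat(sprintf(
    "  Youden cutoff = %.4g (%s): sens %.1f%%, spec %.1f%%, acc %.1f%%\n",
    object@cutoff, if (object@direction == "gt") ">=" else "<=",
    100 * object@sensitivity, 100 * object@specificity,
    100 * object@accuracy))
  invisible(NULL)
})

#' Accessors for ROC results
#'
#' @param x a [RocResult-class].
#' @return \code{auc}: the AUC; \code{aucCI}: c(low, high).
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname auc
#' @export
setMethod("auc", "RocResult", function(x) x@auc)

#' @rdname auc
#' @export
setGeneric("aucCI", function(x) standardGeneric("aucCI"))

#' @rdname auc
#' @export
setMethod("aucCI", "RocResult", function(x) c(low = x@ciLow, high = x@ciHigh))

#' Logistic combination of diffusion parameters
#'
#' Unpenalized maximum-likelihood logistic regression of a binary outcome on
#' the requested features; the per-subject combined score is the linear
#' predictor, whose ROC (invariant to any monotone transform of the score)
#' is computed as in [rocAnalysis()].  (Quasi-)complete separation is
#' flagged, not raised: the score from the final iterate still ranks
#' subjects.
#'
#' @param cohort cohort data.frame (see [readCohortTable()]).
#' @param features character vector of cohort column names, e.g.
#'   \code{c("mean_d", "mean_beta", "mean_mu")}.
#' @param outcome name of the group-label column.
#' @param positiveLabel level of \code{outcome} treated as positive.
#' @return A [CombinedModel-class].
#' @export
logisticCombine <- function(cohort, features, outcome, positiveLabel) {
  stopifnot(length(features) >= 1L, all(features %in% names(cohort)),
            outcome %in% names(cohort))
  y <- cohort[[outcome]] == positiveLabel
  if (!any(y) || all(y)) stop("outcome must contain both classes")
  dat <- cohort[, features, drop = FALSE]
  dat$.y <- as.integer(y)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  score <- as.numeric(stats::predict(fit, type = "link"))
  roc <- rocAnalysis(score, cohort[[outcome]], positiveLabel = positiveLabel)
  new("CombinedModel", features = features,
      coefficients = stats::coef(fit), scores = score, roc = roc,
      separated = sep)
}

setMethod("show", "CombinedModel", function(object) {
  cat("CombinedModel:", paste(object@features, collapse = " + "),
      if (object@separated) "(separation flagged)" else "", "\n")
  show(object@roc)
  invisible(NULL)
})

## Correlation between two empirical AUC estimators on the same subjects,
## from the DeLong placement components.  This is the quantity the classical
## paired-AUC correlation table approximates under a binormal model.
pairedAucCor <- function(s1, s2, pos) {
  v10 <- function(s) {
    vapply(s[pos], function(x) mean((x > s[!pos]) + 0.5 * (x == s[!pos])), 0)
  }
  v01 <- function(s) {
    vapply(s[!pos], function(y) mean((s[pos] > y) + 0.5 * (s[pos] == y)), 0)
  }
  a10 <- v10(s1); b10 <- v10(s2)
  a01 <- v01(s1); b01 <- v01(s2)
  nP <- sum(pos); nN <- sum(!pos)
  cv <- stats::cov(a10, b10) / nP + stats::cov(a01, b01) / nN
  v1 <- stats::var(a10) / nP + stats::var(a01) / nN
  v2 <- stats::var(b10) / nP + stats::var(b01) / nN
  if (v1 <= 0 || v2 <= 0) return(0)
  max(-1, min(1, cv / sqrt(v1 * v2)))
}

#' Hanley-McNeil comparison of two AUCs
#'
#' z-test \eqn{z = (A_1 - A_2)/\sqrt{SE_1^2 + SE_2^2 - 2 r\, SE_1 SE_2}}
#' with the Hanley--McNeil standard errors (\eqn{Q_1 = A/(2-A)},
#' \eqn{Q_2 = 2A^2/(1+A)}).  For paired curves (both scores on the same
#' subjects) the correlation r between the two AUC estimators is computed
#' from the data via DeLong placement components; unpaired curves use
#' r = 0.
#'
#' @param rocA,rocB [RocResult-class] objects.
#' @param paired logical; TRUE when both scores come from the same subjects
#'   (labels must agree subject by subject).
#' @return List with \code{z}, \code{p} (two-sided), \code{r}, and the two
#'   AUCs.
#' @export
compareAuc <- function(rocA, rocB, paired = TRUE) {
  stopifnot(is(rocA, "RocResult"), is(rocB, "RocResult"))
  nP1 <- sum(rocA@labels); nN1 <- sum(!rocA@labels)
  se1 <- hanleyMcNeilSE(rocA@auc, nP1, nN1)
  se2 <- hanleyMcNeilSE(rocB@auc, sum(rocB@labels), sum(!rocB@labels))
  if (paired) {
    if (length(rocA@labels) != length(rocB@labels) ||
        any(rocA@labels != rocB@labels)) {
      stop("paired comparison requires identical subjects and labels")
    }
    sA <- if (rocA@direction == "gt") rocA@scores else -rocA@scores
    sB <- if (rocB@direction == "gt") rocB@scores else -rocB@scores
    r <- pairedAucCor(sA, sB, rocA@labels)
  } else {
    r <- 0
  }
  denom <- sqrt(max(se1^2 + se2^2 - 2 * r * se1 * se2, 0))
  dA <- rocA@auc - rocB@auc
  z <- if (dA == 0) 0 else if (denom == 0) sign(dA) * Inf else dA / denom
  list(z = z, p = 2 * stats::pnorm(-abs(z)), r = r,
       aucA = rocA@auc, aucB = rocB@auc)
}

#' McNemar test on paired correct-classification indicators
#'
#' Builds the 2x2 discordance table between two classifiers evaluated on the
#' same subjects.  With at most 25 discordant pairs the exact two-sided
#' binomial test on the discordant pairs is used; beyond that, the
#' chi-square statistic with continuity correction
#' \eqn{(|b - c| - 1)^2/(b + c)}.  Zero discordant pairs give p = 1.
#'
#' @param correctA,correctB logical (or 0/1) vectors of equal length: was
#'   each subject classified correctly by classifier A resp. B?
#' @param exactMax discordant-pair count at or below which the exact test is
#'   used.
#' @return List with \code{p}, discordant counts \code{b} (A right, B
#'   wrong) and \code{c}, the \code{method} used, and \code{statistic} (the
#'   chi-square value, NA on the exact path).
#' @export
mcnemarTest <- function(correctA, correctB, exactMax = 25L) {
  if (length(correctA) != length(correctB)) {
    stop("paired indicators must have equal length")
  }
  a <- as.logical(correctA)
  b <- as.logical(correctB)
  if (anyNA(a) || anyNA(b)) stop("indicators must be binary without NA")
  nb <- sum(a & !b)
  nc <- sum(!a & b)
  nd <- nb + nc
  if (nd == 0L) {
    return(list(p = 1, b = nb, c = nc, method = "degenerate",
                statistic = NA_real_,
                note = "no discordant pairs"))
  }
  if (nd <= exactMax) {
    p <- stats::binom.test(nb, nd, p = 0.5)$p.value
    list(p = p, b = nb, c = nc, method = "exact binomial",
         statistic = NA_real_)
  } else {
    stat <- (abs(nb - nc) - 1)^2 / nd
    list(p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         b = nb, c = nc, method = "chi-square with continuity correction",
         statistic = stat)
  }
}

#' Group comparison of all four diffusion parameters
#'
#' Runs [mannWhitney()] on mean ADC, beta, D and mu between the two levels
#' of a grouping column, with Bonferroni adjustment across the four tests,
#' and tabulates per-group descriptives (mean, SD, median, range).
#'
#' @param cohort cohort data.frame.
#' @param by name of the two-level grouping column.
#' @param params parameter columns to compare.
#' @return data.frame, one row per parameter: U, raw and Bonferroni p, and
#'   mean/sd/median/range per group.
#' @export
compareGroups <- function(cohort, by,
                          params = c("mean_adc", "mean_beta", "mean_d",
                                     "mean_mu")) {
  lev <- unique(cohort[[by]])
  if (length(lev) != 2L) stop("grouping column must have exactly two levels")
  rows <- lapply(params, function(pn) {
    cr <- mannWhitney(cohort[[pn]][cohort[[by]] == lev[1L]],
                      cohort[[pn]][cohort[[by]] == lev[2L]])
    data.frame(parameter = pn, u = cr$u, p_raw = cr$p,
               mean_1 = cr$groupA[["mean"]], sd_1 = cr$groupA[["sd"]],
               median_1 = cr$groupA[["median"]], range_1 = cr$groupA[["range"]],
               mean_2 = cr$groupB[["mean"]], sd_2 = cr$groupB[["sd"]],
               median_2 = cr$groupB[["median"]], range_2 = cr$groupB[["range"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni(out$p_raw, m = length(params))
  attr(out, "groups") <- as.character(lev)
  out
}

#' Plot an ROC curve
#'
#' Base-graphics empirical ROC curve with the Youden operating point marked.
#'
#' @param roc a [RocResult-class].
#' @param add logical; add to an existing plot.
#' @param col line colour.
#' @param ... further arguments to [graphics::lines()].
#' @return Invisibly, a data.frame of (fpr, tpr) pairs.
#' @export
plotRoc <- function(roc, add = FALSE, col = "black", ...) {
  stopifnot(is(roc, "RocResult"))
  s <- if (roc@direction == "gt") roc@scores else -roc@scores
  cuts <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  tpr <- vapply(cuts, function(ct) mean(s[roc@labels] >= ct), 0)
  fpr <- vapply(cuts, function(ct) mean(s[!roc@labels] >= ct), 0)
  if (!add) {
    graphics::plot(fpr, tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "1 - specificity", ylab = "sensitivity", col = col,
                   ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  } else {
    graphics::lines(fpr, tpr, col = col, ...)
  }
  graphics::points(1 - roc@specificity, roc@sensitivity, pch = 19, col = col)
  invisible(data.frame(fpr = fpr, tpr = tpr))
}
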