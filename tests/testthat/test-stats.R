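test_that("Mann-Whitney exact p equals full enumeration for small groups", {
  cases <- list(
    list(a = c(1, 2, 3), b = c(4, 5, 6)),
    list(a = c(1, 4, 6), b = c(2, 3, 5)),
    list(a = c(10, 12, 13, 19), b = c(11, 14, 15, 16, 17)),
    list(a = c(0.1, 0.9), b = c(0.2, 0.4, 0.6))
  )
  for (cs in cases) {
    got <- mannWhitney(cs$a, cs$b)
    expect_true(got$exact)
    expect_equal(got$p, oracleMannWhitneyP(cs$a, cs$b), tolerance = 1e-12)
  }
  r <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)
})

test_that("identical groups give p = 1 and ties fall back to the
           tie-corrected normal approximation", {
  same <- mannWhitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_false(same$exact)
  expect_equal(same$p, 1)
  big <- mannWhitney(rnorm(30), rnorm(30))
  expect_false(big$exact)
  expect_error(mannWhitney(1, c(1, 2)), "at least 2")
})

test_that("Mann-Whitney holds its nominal type-I error under the null", {
  set.seed(123)
  rej <- mean(replicate(1000, {
    mannWhitney(rnorm(25), rnorm(25))$p < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("Bonferroni correction multiplies, caps at 1 and never decreases", {
  expect_equal(bonferroni(0.01, 4), 0.04)
  expect_equal(bonferroni(0.5, 4), 1.0)
  expect_equal(bonferroni(0.009, 4), 0.036)
  p <- runif(20)
  expect_true(all(bonferroni(p, 4) >= p))
  expect_true(all(bonferroni(p, 4) <= 1))
  expect_error(bonferroni(1.2), "0, 1")
})

test_that("AUC equals the brute-force concordant-pair fraction", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(6:60, 1)
    labels <- sample(c("neg", "pos"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), sample(c(1, 2, 8), 1)) # some runs with ties
    r <- rocAnalysis(scores, labels, positiveLabel = "pos")
    bf <- oracleAuc(scores, labels == "pos")
    expect_equal(r@auc, max(bf, 1 - bf), tolerance = 1e-12)
  }
  r <- rocAnalysis(c(1, 2, 3, 4), c(0, 0, 1, 1), positiveLabel = "1")
  expect_equal(r@auc, 1)
  expect_equal(r@sensitivity, 1)
  expect_equal(r@specificity, 1)
})

test_that("AUC averages to one half for uninformative scores", {
  set.seed(42)
  labels <- rep(c("a", "b"), each = 40)
  reps <- replicate(300, {
    scores <- rnorm(80)
    bf <- oracleAuc(scores, labels == "b")
    r <- rocAnalysis(scores, labels, "b")
    c(unoriented = bf, diff = r@auc - max(bf, 1 - bf))
  })
  expect_lt(abs(mean(reps["unoriented", ]) - 0.5), 0.02)
  expect_lt(max(abs(reps["diff", ])), 1e-12)
})

test_that("AUC is invariant to strictly increasing score transforms", {
  set.seed(5)
  scores <- rnorm(50)
  labels <- sample(c("x", "y"), 50, replace = TRUE)
  r1 <- rocAnalysis(scores, labels, "y")
  r2 <- rocAnalysis(exp(2 * scores) + 7, labels, "y")
  expect_equal(r1@auc, r2@auc, tolerance = 1e-12)
  expect_equal(r1@sensitivity, r2@sensitivity)
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- rnorm(60)
  labels <- sample(0:1, 60, replace = TRUE)
  r <- rocAnalysis(scores, labels, positiveLabel = "1")
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(labels, scores, direction = "<", quiet = TRUE))))
  expect_equal(r@auc, max(ref, 1 - ref), tolerance = 1e-12)
})

test_that("Youden cutoff equals the exhaustive threshold scan", {
  scores <- c(1, 2, 3, 4, 5)
  labels <- c(0, 0, 1, 0, 1)
  r <- rocAnalysis(scores, labels, positiveLabel = "1")
  sc <- oracleYouden(scores, labels == 1)
  y <- youdenCutoff(r)
  expect_equal(y$cutoff, sc$cutoff)
  expect_equal(y$sensitivity, sc$sens)
  expect_equal(y$specificity, sc$spec)
  set.seed(10)
  for (i in 1:20) {
    s <- round(rnorm(40), 1)
    l <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    if (length(unique(l)) < 2) next
    r <- rocAnalysis(s, l, positiveLabel = "TRUE")
    if (r@direction != "gt") next
    sc <- oracleYouden(s, l)
    expect_equal(r@sensitivity + r@specificity,
                 sc$sens + sc$spec, tolerance = 1e-12)
    expect_equal(r@cutoff, sc$cutoff) # lowest qualifying cutoff on ties
  }
})

test_that("logistic combination reduces to the single-feature ROC and
           handles collinearity and separation", {
  co <- sampleCohort(cohortPreset("grade"), seed = 6)
  single <- logisticCombine(co, "mean_d", "group", "high")
  direct <- rocAnalysis(co$mean_d, co$group, "high")
  expect_equal(single@roc@auc, direct@auc, tolerance = 1e-12)

  co$dup <- co$mean_d
  dup <- suppressWarnings(logisticCombine(co, c("mean_d", "dup"), "group",
                                          "high"))
  expect_equal(dup@roc@auc, direct@auc, tolerance = 1e-12)

  sep <- data.frame(group = rep(c("low", "high"), each = 10),
                    mean_d = c(rnorm(10, 0), rnorm(10, 30)))
  m <- logisticCombine(sep, "mean_d", "group", "high")
  expect_true(m@separated)
  expect_equal(m@roc@auc, 1)
})

test_that("well-separated three-parameter combination reaches AUC 1", {
  specs <- list(
    groupSpec("low", 20, 1.4, 0.01, 0.95, 0.005, 1.4, 0.01, 12, 0.05),
    groupSpec("high", 20, 0.6, 0.01, 0.55, 0.005, 0.5, 0.01, 5, 0.05))
  co <- sampleCohort(specs, seed = 12)
  cm <- suppressWarnings(
    logisticCombine(co, c("mean_d", "mean_beta", "mean_mu"), "group", "high"))
  expect_equal(cm@roc@auc, 1)
})

test_that("Hanley-McNeil comparison has its closed-form SE and null behaviour", {
  # at A = 0.5 with equal class sizes n, SE^2 = [0.25 + (n - 1)/6]/n^2
  n <- 20
  expect_equal(frocdwi:::hanleyMcNeilSE(0.5, n, n)^2,
               (0.25 + (n - 1) / 6) / n^2, tolerance = 1e-12)

  set.seed(13)
  scores <- rnorm(40)
  labels <- rep(c("a", "b"), 20)
  r1 <- rocAnalysis(scores, labels, "b")
  same <- compareAuc(r1, r1, paired = TRUE)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  r2 <- rocAnalysis(rnorm(40), labels, "b")
  un <- compareAuc(r1, r2, paired = FALSE)
  seExp <- sqrt(frocdwi:::hanleyMcNeilSE(r1@auc, 20, 20)^2 +
                  frocdwi:::hanleyMcNeilSE(r2@auc, 20, 20)^2)
  expect_equal(un$z, (r1@auc - r2@auc) / seExp, tolerance = 1e-12)
  expect_equal(un$r, 0)
})

test_that("paired AUC comparison detects a real gap more often than the null", {
  set.seed(14)
  rej <- function(gap) {
    mean(replicate(120, {
      x <- rnorm(60)
      labels <- rep(c("a", "b"), 30)
      strong <- x + (labels == "b") * gap
      weak <- rnorm(60) + (labels == "b") * 0.1
      compareAuc(rocAnalysis(strong, labels, "b"),
                 rocAnalysis(weak, labels, "b"), paired = TRUE)$p < 0.05
    }))
  }
  expect_gt(rej(1.2), rej(0))
})

test_that("McNemar test matches its closed forms", {
  expect_equal(mcnemarTest(c(1, 1, 0, 0), c(1, 1, 0, 0))$p, 1)
  # discordant b = 1, c = 5: exact two-sided binomial
  a <- c(rep(TRUE, 1), rep(FALSE, 5), TRUE, FALSE)
  b <- c(rep(FALSE, 1), rep(TRUE, 5), TRUE, FALSE)
  got <- mcnemarTest(a, b)
  expect_equal(got$method, "exact binomial")
  expect_equal(got$p, 0.21875, tolerance = 1e-12)
  # discordant b = 10, c = 30: continuity-corrected chi-square
  a2 <- c(rep(TRUE, 10), rep(FALSE, 30), rep(TRUE, 5))
  b2 <- c(rep(FALSE, 10), rep(TRUE, 30), rep(TRUE, 5))
  got2 <- mcnemarTest(a2, b2)
  expect_equal(got2$statistic, (abs(10 - 30) - 1)^2 / 40, tolerance = 1e-12)
  expect_equal(got2$p, pchisq(9.025, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(mcnemarTest(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("group comparison table carries descriptives and adjusted p-values", {
  co <- sampleCohort(cohortPreset("grade"), seed = 15)
  tab <- compareGroups(co, "group")
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$p_bonferroni >= tab$p_raw))
  expect_true(all(tab$p_bonferroni <= 1))
  lowBeta <- co$mean_beta[co$group == "low"]
  expect_equal(tab$mean_1[tab$parameter == "mean_beta"], mean(lowBeta))
  expect_equal(tab$range_1[tab$parameter == "mean_beta"], diff(range(lowBeta)))
})
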