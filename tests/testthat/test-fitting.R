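test_that("two-point ADC is exact on mono-exponential input", {
  for (adc in c(0.90, 0.92, 1.3)) {
    f <- fitAdcTwoPoint(monoSignal(800, adc, protocol), protocol)
    expect_equal(f@adc, adc, tolerance = 1e-10)
    expect_false(f@flagged)
  }
  flat <- rep(500, length(bValues(protocol)))
  expect_equal(fitAdcTwoPoint(flat, protocol)@adc, 0)
  rising <- rev(monoSignal(800, 1, protocol))
  expect_true(fitAdcTwoPoint(rising, protocol)@flagged)
  sc <- acquisitionScheme(c(0, 200, 500), deltaSmall = 20, deltaBig = 40)
  expect_error(fitAdcTwoPoint(c(1, 1, 1), sc), "b = 1000")
})

test_that("noiseless inversion recovers beta exactly and the identifiable
           decay scale within 0.1%", {
  for (row in publishedGroupRows) {
    sig <- frocSignal(frocParams(1000, row$d, row$beta, row$mu), protocol)
    fit <- fitFroc(sig, protocol)
    p <- fit@params
    expect_lt(abs(p@beta - row$beta) / row$beta, 1e-3)
    # the data determine D * mu^(2 beta - 2), not D and mu separately
    scaleHat <- p@d * (p@mu * 1e-3)^(2 * (p@beta - 1))
    scaleTrue <- row$d * (row$mu * 1e-3)^(2 * (row$beta - 1))
    expect_lt(abs(scaleHat - scaleTrue) / scaleTrue, 1e-3)
    expect_lt(fit@rss, 1e-12)
    expect_true(fit@converged)
  }
})

test_that("with mu constrained by its anchor, D lands within the documented
           few-percent band of the generating value", {
  for (row in publishedGroupRows) {
    sig <- frocSignal(frocParams(1000, row$d, row$beta, row$mu), protocol)
    p <- fitFroc(sig, protocol)@params
    expect_lt(abs(p@d - row$d) / row$d, 0.05)
    expect_lt(abs(p@mu - row$mu) / row$mu, 0.08)
  }
})

test_that("a mono-exponential input drives beta to its Gaussian limit", {
  fit <- fitFroc(monoSignal(1000, 1.0, protocol), protocol)
  expect_gte(fit@params@beta, 0.99)
})

test_that("fitting the same noisy signal twice is bitwise identical", {
  sig <- ricianNoise(frocSignal(frocParams(1000, 0.8, 0.7, 8.3), protocol),
                     sigma = 20, seed = 42)
  f1 <- fitFroc(sig, protocol)
  f2 <- fitFroc(sig, protocol)
  expect_identical(f1@params@d, f2@params@d)
  expect_identical(f1@params@beta, f2@params@beta)
  expect_identical(f1@params@mu, f2@params@mu)
  expect_identical(f1@rss, f2@rss)
})

test_that("degenerate and malformed fit inputs raise configuration errors", {
  expect_error(fitFroc(rep(0, 9), protocol), "all-zero")
  few <- acquisitionScheme(c(0, 500, 1000, 2000), deltaSmall = 20,
                           deltaBig = 40)
  expect_error(fitFroc(c(1000, 700, 500, 300), few), "at least 6")
  lowOnly <- acquisitionScheme(c(0, 20, 40, 80, 160, 200), deltaSmall = 20,
                               deltaBig = 40)
  expect_error(fitFroc(1000 * exp(-0.001 * bValues(lowOnly)), lowOnly),
               ">= 500")
  expect_error(fitFroc(c(rep(1000, 8), -5), protocol), "positive")
})

test_that("fit RSS never exceeds the exhaustive grid-search optimum", {
  set.seed(3)
  for (i in 1:5) {
    d <- runif(1, 0.5, 1.2)
    be <- runif(1, 0.55, 0.95)
    mu <- runif(1, 5, 11)
    sig <- frocSignal(frocParams(1000, d, be, mu), protocol)
    if (i > 2) sig <- ricianNoise(sig, sigma = 10, seed = i)
    fit <- fitFroc(sig, protocol)
    expect_lte(fit@rss,
               oracleGridRss(sig, fit@params@s0, protocol) + 1e-9)
  }
})

test_that("voxelwise maps agree with scalar fits and flag failures", {
  sig <- frocSignal(frocParams(1000, 0.82, 0.73, 8.27), protocol)
  vol <- array(rep(sig, each = 1), dim = c(1, 1, 1, length(sig)))
  mask <- array(TRUE, dim = c(1, 1, 1))
  maps <- suppressMessages(fitMap(vol, mask, protocol))
  ff <- fitFroc(sig, protocol)
  af <- fitAdcTwoPoint(sig, protocol)
  expect_equal(parameterMap(maps, "beta")[1, 1, 1], ff@params@beta)
  expect_equal(parameterMap(maps, "d")[1, 1, 1], ff@params@d)
  expect_equal(parameterMap(maps, "adc")[1, 1, 1], af@adc)

  empty <- array(FALSE, dim = c(1, 1, 1))
  expect_warning(suppressMessages(fitMap(vol, empty, protocol)), "empty mask")

  expect_error(suppressMessages(
    fitMap(vol, array(TRUE, dim = c(2, 1, 1)), protocol)), "mask shape")
  expect_error(suppressMessages(
    fitMap(vol[, , , 1:3, drop = FALSE], mask, protocol)), "4th dimension")
})

test_that("small-phantom voxelwise fitting recovers the median beta", {
  truth <- phantomTruth(shape = c(10, 10, 3),
                        lesion = c(adc = 0.90, d = 0.74, beta = 0.68,
                                   mu = 8.26),
                        snr = 50)
  vol <- makePhantom(truth, protocol, seed = 9)
  maps <- suppressMessages(fitMap(vol, truth$mask, protocol))
  sel <- truth$mask & maps@converged
  expect_lt(abs(median(parameterMap(maps, "beta")[sel]) - 0.68), 0.03)
})
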