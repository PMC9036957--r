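test_that("b = 0 returns S0 and the decay is strictly monotone in b", {
  for (row in publishedGroupRows) {
    s <- frocSignal(frocParams(1000, row$d, row$beta, row$mu), protocol)
    expect_identical(s[1], 1000)
    expect_true(all(diff(s) < 0))
  }
  expect_identical(monoSignal(750, 0.92, protocol)[1], 750)
})

test_that("FROC signal matches an independently written evaluation", {
  b <- bValues(protocol)
  for (row in publishedGroupRows) {
    got <- frocSignal(frocParams(1000, row$d, row$beta, row$mu), protocol)
    want <- oracleFrocSignal(1000, row$d, row$beta, row$mu, b, 20, 40)
    expect_equal(got, want, tolerance = 1e-14)
  }
  # frozen value from a 40-digit arbitrary-precision evaluation of the same
  # formula (S0 = 1000, D = 0.77, beta = 0.67, mu = 8.19, b = 1000)
  got <- frocSignal(frocParams(1000, 0.77, 0.67, 8.19), protocol)
  expect_equal(got[bValues(protocol) == 1000], 506.46662669899786,
               tolerance = 1e-13)
  expect_equal(got[bValues(protocol) == 2000], 338.78082184438851,
               tolerance = 1e-13)
})

test_that("mono-exponential signal has its analytic values", {
  sc <- protocol
  expect_equal(monoSignal(500, 1.0, sc)[bValues(sc) == 1000], 500 / exp(1),
               tolerance = 1e-15)
  expect_equal(monoSignal(1000, 0.92, sc), 1000 * exp(-bValues(sc) * 0.92e-3),
               tolerance = 1e-15)
})

test_that("beta = 1 reduces the FROC model exactly to the mono-exponential", {
  for (mu in c(1, 5, 8.2, 20)) {
    s <- frocSignal(frocParams(1000, 0.9, 1, mu), protocol)
    m <- monoSignal(1000, 0.9, protocol)
    expect_lt(max(abs(s - m)), 1e-12 * 1000)
  }
  # mu is irrelevant at beta = 1 to machine precision
  s1 <- frocSignal(frocParams(1000, 0.9, 1, 2), protocol)
  s2 <- frocSignal(frocParams(1000, 0.9, 1, 19), protocol)
  expect_identical(s1, s2)
})

test_that("signal is scale-equivariant in S0", {
  base <- frocSignal(frocParams(1, 0.77, 0.67, 8.19), protocol)
  expect_equal(frocSignal(frocParams(1234, 0.77, 0.67, 8.19), protocol),
               1234 * base, tolerance = 1e-15)
})

test_that("Stejskal-Tanner b-value matches a hand unit-tracked computation", {
  # gamma = 2.6753e8 rad/s/T, G = 30 mT/m, delta = 20 ms, Delta = 40 ms:
  # (gamma G delta)^2 = (2.6753e8 * 0.03 * 0.02)^2 = 160518^2 per m^2;
  # times (0.04 - 0.02/3) s = 858.8676108 s/mm^2.
  expect_equal(bFromGradient(protonGamma, 30e-3, 20, 40), 858.8676108,
               tolerance = 1e-9)
  expect_identical(bFromGradient(protonGamma, 0, 20, 40), 0)
  # round trip through the inverse relation
  gD <- sqrt(1000 * 1e6 / (0.04 - 0.02 / 3)) / (protonGamma * 0.02)
  expect_equal(bFromGradient(protonGamma, gD, 20, 40), 1000,
               tolerance = 1e-9)
  expect_error(bFromGradient(protonGamma, 30, 20, 40), "units")
})

test_that("scheme and parameter validity is enforced", {
  expect_error(acquisitionScheme(c(0, 500, 500)), "increasing")
  expect_error(acquisitionScheme(c(20, 500)), "first")
  expect_error(acquisitionScheme(c(0, 500), deltaSmall = 40, deltaBig = 20),
               "Delta > delta")
  expect_error(frocParams(1000, 0.8, 1.2, 8), "beta")
  expect_error(frocParams(-1, 0.8, 0.7, 8), "s0")
  expect_error(monoSignal(1000, -0.5, protocol), "adc")
  noTiming <- acquisitionScheme(bValues(protocol))
  expect_error(frocSignal(frocParams(1000, 0.8, 0.7, 8), noTiming), "timing")
})
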