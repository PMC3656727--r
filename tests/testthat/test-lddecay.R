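test_that("expected r2 is strictly decreasing in C and has the right limits", {
  for (n in c(8, 24, 97)) {
    C <- c(0, 10^seq(-4, 4, length.out = 200))
    v <- expectedR2(C, n)
    expect_true(all(diff(v) < 0))
    # large-C asymptote is the 1/n sampling floor
    expect_equal(expectedR2(1e9, n), 1 / n, tolerance = 1e-4)
  }
  # large-n, C -> 0 limit is 10/22
  expect_equal(expectedR2(0, 1e9), 10 / 22, tolerance = 1e-6)
  expect_error(expectedR2(-1, 10))
})

test_that("noiseless Hill-Weir data recover the generating rate to 1e-6", {
  n <- 48
  for (rho_bp in c(2e-4, 5e-3, 0.08)) {
    d <- seq(10, 2500, by = 30)
    pairs <- data.frame(distance_bp = d, r2 = expectedR2(rho_bp * d, n))
    fit <- fitHillWeir(pairs, n = n)
    expect_equal(fit@param, rho_bp, tolerance = 1e-6)
    expect_true(fit@rss < 1e-10)
    expect_false(fit@illConditioned)
  }
})

test_that("the sample size enters the fit via haplotype counts when omitted", {
  d <- seq(10, 1000, by = 25)
  pairs <- data.frame(
    distance_bp = d, r2 = expectedR2(0.01 * d, 20),
    n11 = 8, n12 = 4, n21 = 4, n22 = 4
  )
  fit <- fitHillWeir(pairs)
  expect_identical(fit@n, 20)
  expect_error(
    fitHillWeir(data.frame(distance_bp = d, r2 = d * 0 + 0.1)),
    "supply n"
  )
})

test_that("degenerate decay inputs error or warn", {
  expect_error(fitHillWeir(data.frame(distance_bp = 1:3, r2 = 0.1), n = 10),
    "at least 5")
  expect_error(
    fitHillWeir(data.frame(distance_bp = c(0, 1:5), r2 = 0.1), n = 10),
    "positive"
  )
  expect_warning(
    fitHillWeir(data.frame(distance_bp = rep(7, 6), r2 = runif(6)), n = 10),
    "ill-conditioned"
  )
})

test_that("recombination fraction mappings behave at small and large distances", {
  expect_equal(recombinationFraction(1e6, mapScale = 1), 0.01)
  expect_identical(recombinationFraction(1e12, mapScale = 1), 0.5)
  # Haldane and linear agree to first order at kb scales
  d <- 5000
  expect_equal(
    recombinationFraction(d, 1, "haldane"),
    recombinationFraction(d, 1, "linear"),
    tolerance = 1e-4
  )
  expect_true(recombinationFraction(1e8, 1, "haldane") <
    recombinationFraction(1e8, 1, "linear"))
})

test_that("noiseless D' data recover the generation count to 1e-6", {
  for (t_true in c(50, 5000, 2e5)) {
    d <- seq(50, 5000, by = 50)
    r <- recombinationFraction(d, mapScale = 1)
    pairs <- data.frame(distance_bp = d, dprime = (1 - r)^t_true)
    fit <- fitDprimeDecay(pairs, mapScale = 1)
    expect_equal(fit@param, t_true, tolerance = 1e-6)
  }
  # complete disequilibrium everywhere -> t = 0 exactly
  flat <- fitDprimeDecay(data.frame(distance_bp = seq(50, 500, 50), dprime = 1))
  expect_identical(flat@param, 0)
})

test_that("the assumed map scale rescales fitted generations inversely", {
  d <- seq(50, 5000, by = 50)
  r <- recombinationFraction(d, mapScale = 1)
  pairs <- data.frame(distance_bp = d, dprime = (1 - r)^2000)
  t1 <- fitDprimeDecay(pairs, mapScale = 1)@param
  t10 <- fitDprimeDecay(pairs, mapScale = 10)@param
  expect_equal(t1 / t10, 10, tolerance = 1e-3)
})

test_that("predictDecay matches the fitted-model formulas", {
  d <- seq(10, 500, by = 10)
  pairs <- data.frame(distance_bp = d, r2 = expectedR2(0.02 * d, 30))
  fit <- fitHillWeir(pairs, n = 30)
  expect_equal(predictDecay(fit, c(7, 312)),
    expectedR2(fit@param * c(7, 312), 30),
    tolerance = 1e-12)
})

test_that("crossing distance honors its boundary conventions", {
  d <- seq(10, 2500, by = 30)
  fit <- fitHillWeir(
    data.frame(distance_bp = d, r2 = expectedR2(0.01 * d, 48)),
    n = 48
  )
  cr <- crossingDistance(fit, threshold = 0.2)
  expect_identical(cr$status, "ok")
  expect_true(predictDecay(fit, cr$bp) < 0.2)
  expect_true(predictDecay(fit, cr$bp - 1) >= 0.2)
  # already below the threshold at the origin
  below <- crossingDistance(fit, threshold = 0.9)
  expect_identical(below$bp, 0)
  expect_identical(below$status, "below_at_origin")
  # a curve that never reaches the threshold inside the search range
  never <- fitDprimeDecay(
    data.frame(distance_bp = seq(50, 500, 50), dprime = 1)
  )
  nr <- crossingDistance(never, threshold = 0.2, dMax = 1e6)
  expect_identical(nr$bp, Inf)
  expect_identical(nr$status, "never_reached")
})

test_that("fits accept an LDPairSet directly", {
  aln <- LocusAlignment("ld", c(
    s1 = "CAGA", s2 = "CAGA", s3 = "CAGC", s4 = "GTTC", s5 = "GTTC",
    s6 = "GTGA", s7 = "CATC", s8 = "CAGA"
  ))
  ld <- buildLdPairs(aln)
  expect_identical(nrow(ldPairs(ld)), 6L)
  fit <- fitHillWeir(ld)
  expect_s4_class(fit, "DecayFit")
  expect_true(fit@param >= 0)
})
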