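test_that("canonical configuration codes are invariant under the 8 symmetries", {
  canonicalConfigCode <- haploLD:::canonicalConfigCode
  set.seed(2)
  n <- 12L
  for (i in 1:100) {
    cfg <- as.vector(stats::rmultinom(1, n, runif(4, 0.1, 1)))
    a <- cfg[1]; b <- cfg[2]; c <- cfg[3]; d <- cfg[4]
    variants <- rbind(
      c(a, b, c, d), c(c, d, a, b), c(b, a, d, c), c(d, c, b, a),
      c(a, c, b, d), c(b, d, a, c), c(c, a, d, b), c(d, b, c, a)
    )
    codes <- canonicalConfigCode(variants, n)
    expect_identical(length(unique(codes)), 1L)
    expect_type(codes, "integer")
  }
})

test_that("projection to the table sample size preserves totals and support", {
  pr <- haploLD:::.projectConfig
  expect_identical(pr(c(3L, 2L, 1L, 2L), 8L), c(3L, 2L, 1L, 2L))
  set.seed(4)
  for (i in 1:200) {
    n <- sample(8:40, 1)
    m <- sample(4:(n - 1), 1)
    counts <- as.vector(stats::rmultinom(1, m, runif(4, 0.05, 1)))
    out <- pr(counts, n)
    expect_identical(sum(out), n)
    expect_true(all(out[counts > 0] >= 1L))
    expect_true(all(out[counts == 0] == 0L))
    # method-of-moments direction: scaled counts within 1 of counts*n/m
    expect_true(all(abs(out - counts * n / m) <= 1 + 1e-9))
  }
})

test_that("lookup construction is deterministic and normalized", {
  lk1 <- buildLookup(8, rhoGrid = c(0, 25, 50), nSims = 300L, seed = 5L)
  lk2 <- buildLookup(8, rhoGrid = c(0, 25, 50), nSims = 300L, seed = 5L)
  expect_identical(lk1@logLik, lk2@logLik)
  expect_identical(lk1@configCode, lk2@configCode)
  # smoothed probabilities over ALL configurations sum to
  # (observed draws + observed configs) / (nDraws + 1) <= ~1; the tabulated
  # (observed) configurations alone account for nearly all mass
  for (g in seq_along(lk1@rhoGrid)) {
    mass <- sum(exp(lk1@logLik[, g]))
    expect_true(mass <= 1 + length(lk1@configCode) / (lk1@nDraws + 1))
    expect_true(mass > 0.99)
  }
  # a different seed gives a different table
  lk3 <- buildLookup(8, rhoGrid = c(0, 25, 50), nSims = 300L, seed = 6L)
  expect_false(identical(lk1@logLik, lk3@logLik))
})

test_that("lookup tables round-trip exactly through the text dialect", {
  lk <- buildLookup(6, rhoGrid = c(0, 50, 100), nSims = 200L, seed = 3L)
  tmp <- tempfile(fileext = ".txt")
  writeLookupTable(lk, tmp)
  back <- readLookupTable(tmp)
  expect_identical(back@n, lk@n)
  expect_identical(back@rhoGrid, lk@rhoGrid)
  expect_identical(back@configCode, lk@configCode)
  expect_equal(back@logLik, lk@logLik, tolerance = 1e-15)
  expect_identical(back@nDraws, lk@nDraws)
})

test_that("lookup parse failures report the offending line", {
  lk <- buildLookup(6, rhoGrid = c(0, 50, 100), nSims = 200L, seed = 3L)
  tmp <- tempfile()
  writeLookupTable(lk, tmp)
  lines <- readLines(tmp)
  # truncate the configuration block
  writeLines(lines[1:8], tmp)
  expect_error(readLookupTable(tmp), "truncated")
  # corrupt a header line
  lines2 <- lines
  lines2[2] <- "n not_a_number"
  writeLines(lines2, tmp)
  expect_error(readLookupTable(tmp), "line 2")
  # corrupt a configuration row
  lines3 <- lines
  lines3[9] <- sub(":", "", lines3[9], fixed = TRUE)
  writeLines(lines3, tmp)
  expect_error(readLookupTable(tmp), "line 9")
  # wrong magic
  lines4 <- lines
  lines4[1] <- "something else"
  writeLines(lines4, tmp)
  expect_error(readLookupTable(tmp), "line 1")
})

test_that("a theta disagreement warns and the header wins", {
  lk <- buildLookup(6, thetaPerSite = 0.002, rhoGrid = c(0, 100),
    nSims = 200L, seed = 3L)
  tmp <- tempfile()
  writeLookupTable(lk, tmp)
  expect_warning(back <- readLookupTable(tmp, thetaPerSite = 0.001),
    "header wins")
  expect_identical(back@thetaPerSite, 0.002)
})

test_that("estimateRho validates inputs and handles sparse loci gracefully", {
  lk <- cachedLookup(16)
  big <- LocusAlignment("big", setNames(
    rep("ACGT", 20), paste0("s", 1:20)
  ))
  sites_big <- classifySites(big, "pairwise_available")
  expect_error(estimateRho(big, sites_big, lk), "rebuild the table")
  mono <- LocusAlignment("mono", setNames(rep("AAAA", 8), paste0("s", 1:8)))
  sm <- classifySites(mono, "pairwise_available")
  out <- estimateRho(mono, sm, lk)
  expect_false(out$computed)
  expect_true(is.na(out$rho_per_kb))
  expect_identical(out$n_pairs_used, 0L)
})

test_that("estimates on fixed data are bit-reproducible and profile-shaped", {
  set.seed(21)
  truth <- SimTruth("r", thetaPerSite = 0.01, rhoPerSite = 0.02,
    locusLength = 1500L, samplesPerPopulation = 16L, seed = 77L)
  sim <- simulateLocus(truth)
  sites <- classifySites(sim$alignment, "pairwise_available")
  lk <- cachedLookup(16)
  e1 <- estimateRho(sim$alignment, sites, lk)
  e2 <- estimateRho(sim$alignment, sites, lk)
  expect_identical(e1$rho_per_kb, e2$rho_per_kb)
  expect_identical(e1$profile, e2$profile)
  expect_true(e1$computed)
  expect_identical(nrow(e1$profile), 101L)
  expect_equal(
    max(e1$profile$log_composite_likelihood),
    e1$profile$log_composite_likelihood[
      match(e1$rho_per_kb, e1$profile$rho_per_kb)
    ],
    tolerance = 1e-12
  )
  expect_equal(e1$rho_locus, e1$rho_per_site * 1500, tolerance = 1e-12)
})

test_that("recombining loci score higher rates than non-recombining ones", {
  lk <- cachedLookup(16)
  est_at <- function(rho_site, seeds) {
    vapply(seeds, function(s) {
      truth <- SimTruth("r", thetaPerSite = 0.012, rhoPerSite = rho_site,
        locusLength = 1200L, samplesPerPopulation = 16L, seed = s)
      sim <- simulateLocus(truth)
      sites <- classifySites(sim$alignment, "pairwise_available")
      e <- estimateRho(sim$alignment, sites, lk)
      if (isTRUE(e$computed)) e$rho_per_kb else NA_real_
    }, 1)
  }
  low <- est_at(0, 101:106)
  high <- est_at(0.05, 201:206)
  expect_true(mean(high, na.rm = TRUE) > mean(low, na.rm = TRUE))
})

test_that("rho/theta handles undefined quotients", {
  est <- list(computed = TRUE, rho_per_site = 0.004)
  expect_equal(rhoOverTheta(est, 0.002)$rho_over_theta, 2, tolerance = 1e-12)
  expect_false(rhoOverTheta(est, 0)$defined)
  expect_false(rhoOverTheta(list(computed = FALSE, rho_per_site = NA_real_),
    0.002)$defined)
  row <- data.frame(theta_w = 0.008)
  expect_equal(rhoOverTheta(0.004, row)$rho_over_theta, 0.5, tolerance = 1e-12)
})
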