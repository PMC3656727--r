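test_that("theta = 0 gives identical sequences and no segregating sites", {
  truth <- SimTruth("z", thetaPerSite = 0, locusLength = 300L,
    samplesPerPopulation = 10L, seed = 2L)
  sim <- simulateLocus(truth)
  seqs <- as.character(sequences(sim$alignment))
  expect_identical(length(unique(seqs)), 1L)
  expect_identical(nrow(sim$siteTruth), 0L)
})

test_that("a fixed seed reproduces the locus exactly", {
  truth <- SimTruth("d", thetaPerSite = 0.01, rhoPerSite = 0.005,
    locusLength = 800L, samplesPerPopulation = c(6L, 6L),
    migrationRate = 5, readJitter = 0.2,
    maskLayout = IRanges::IRanges(start = c(1L, 600L), end = c(200L, 800L)),
    seed = 33L)
  s1 <- simulateLocus(truth)
  s2 <- simulateLocus(truth)
  expect_identical(as.character(sequences(s1$alignment)),
    as.character(sequences(s2$alignment)))
  expect_identical(s1$siteTruth, s2$siteTruth)
})

test_that("contradictory structure parameters are refused", {
  expect_error(
    simulateAncestry(8, 1, samplesPerPopulation = c(4L, 4L),
      migrationRate = 0),
    "common"
  )
})

test_that("without recombination every locus passes the four-gamete test", {
  set.seed(14)
  for (rep in 1:10) {
    truth <- SimTruth("fg", thetaPerSite = 0.02, rhoPerSite = 0,
      locusLength = 500L, samplesPerPopulation = 12L,
      seed = sample.int(1e6, 1))
    sim <- simulateLocus(truth)
    sites <- classifySites(sim$alignment, "complete_deletion")
    am <- alleleMatrix(sim$alignment, sites)
    k <- ncol(am)
    if (k < 2) next
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        gam <- unique(paste(am[, i], am[, j]))
        expect_true(length(gam) <= 3)
      }
    }
  }
})

test_that("mutation counts and site frequencies track the coalescent expectations", {
  set.seed(91)
  n <- 20
  theta <- 6
  reps <- 300
  S <- replicate(reps, length(simulateAncestry(n, theta)$carriers))
  a1 <- sum(1 / seq_len(n - 1))
  expect_true(abs(mean(S) - theta * a1) / (theta * a1) < 0.08)
})

test_that("summary statistics agree in distribution with an independent simulator", {
  oracle <- oracleCoalescentReplicates()
  set.seed(515)
  reps <- 300
  n <- 50
  cs <- tajimaConstants(n)
  stats <- t(replicate(reps, {
    muts <- simulateAncestry(n, 10)
    S <- length(muts$carriers)
    k <- vapply(muts$carriers, length, 1L)
    pit <- sum(2 * k * (n - k) / (n * (n - 1)))
    d <- if (S > 0) {
      (pit - S / cs$a1) / sqrt(cs$e1 * S + cs$e2 * S * (S - 1))
    } else {
      NA_real_
    }
    c(S = S, pi_total = pit, d = d)
  }))
  expect_true(
    suppressWarnings(stats::ks.test(stats[, "S"], oracle$s)$p.value) > 0.01
  )
  expect_true(
    stats::ks.test(stats[, "pi_total"], oracle$pi_total)$p.value > 0.01
  )
  d_ours <- stats[, "d"][!is.na(stats[, "d"])]
  expect_true(stats::ks.test(d_ours, oracle$d[!is.na(oracle$d)])$p.value > 0.01)
})

test_that("masking writes N outside sequenced windows, jitter shortens reads", {
  truth <- SimTruth("mask", thetaPerSite = 0.01, locusLength = 1000L,
    samplesPerPopulation = 8L, readJitter = 0,
    maskLayout = endMaskLayout(1000L, 300L), seed = 5L)
  alignmentMatrix <- haploLD:::alignmentMatrix
  sim <- simulateLocus(truth)
  m <- alignmentMatrix(sim$alignment)
  # windows: [1, 150] and [851, 1000]
  expect_true(all(m[, 151:850] == "N"))
  expect_true(all(m[, 1:150] != "N"))
  expect_true(all(m[, 851:1000] != "N"))
  # with jitter, individual read ends vary
  truth_j <- SimTruth("maskj", thetaPerSite = 0.01, locusLength = 1000L,
    samplesPerPopulation = 8L, readJitter = 0.5,
    maskLayout = endMaskLayout(1000L, 300L), seed = 5L)
  mj <- alignmentMatrix(simulateLocus(truth_j)$alignment)
  read_len <- rowSums(mj[, 1:150] != "N")
  expect_true(length(unique(read_len)) > 1)
  # odd window is cut from the right: starts always called
  expect_true(all(mj[, 1] != "N"))
  # even window is cut from the left: its end always called
  expect_true(all(mj[, 1000] != "N"))
})

test_that("end mask layout splits the sequenced total across both amplicon ends", {
  w <- endMaskLayout(4681L, 457L)
  expect_identical(length(w), 2L)
  expect_identical(sum(IRanges::width(w)), 457L)
  expect_identical(IRanges::start(w)[1], 1L)
  expect_identical(IRanges::end(w)[2], 4681L)
  # degenerate: fully sequenced amplicon -> single window
  w2 <- endMaskLayout(100L, 100L)
  expect_identical(length(w2), 1L)
})

test_that("the default study has the expected shape and is seed-reproducible", {
  cfg <- studyConfig(seed = 77L)
  expect_identical(cfg$nLoci, 11L)
  expect_identical(sum(cfg$populationSizes), 128L)
  expect_identical(sort(unique(cfg$populationSizes)), c(8L, 24L))
  study <- simulateStudy(cfg)
  expect_length(study$alignments, 11L)
  expect_identical(nrow(assignments(study$popmap)), 128L)
  expect_true(all(vapply(study$alignments, nSequences, 1L) == 128L))
  # amplicon lengths match the configuration
  expect_identical(
    unname(vapply(study$alignments, ampliconLength, 1L)),
    cfg$ampliconLengths
  )
  # byte-identical outputs under the same seed
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  writeSimResult(study, d1)
  writeSimResult(simulateStudy(studyConfig(seed = 77L)), d2)
  f1 <- list.files(d1)
  expect_identical(sort(f1), sort(list.files(d2)))
  expect_identical(length(list.files(d1, "\\.fasta$")), 11L)
  for (f in f1) {
    expect_identical(
      unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f)))
    )
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("study configurations round-trip through the key-value file", {
  cfg <- studyConfig(scenario = "gradient", seed = 5L)
  tmp <- file.path(tempdir(), "cfg_roundtrip")
  dir.create(tmp, showWarnings = FALSE)
  writeLines(vapply(names(cfg), function(k) {
    paste(k, paste(cfg[[k]], collapse = ","), sep = "=")
  }, ""), file.path(tmp, "config.txt"))
  back <- readStudyConfig(file.path(tmp, "config.txt"))
  expect_identical(back$scenario, "gradient")
  expect_identical(back$populationSizes, cfg$populationSizes)
  expect_equal(back$growthRate, cfg$growthRate, tolerance = 1e-12)
  expect_identical(back$migrationRate, 0)
  # malformed line reports its number
  writeLines(c("a=1", "oops"), file.path(tmp, "config.txt"))
  expect_error(readStudyConfig(file.path(tmp, "config.txt")), "line 2")
  unlink(tmp, recursive = TRUE)
})

test_that("the gradient scenario produces a latitudinal cline in growth rates", {
  cfg <- studyConfig(scenario = "gradient")
  expect_length(cfg$growthRate, 10L)
  expect_true(all(diff(cfg$growthRate) < 0))
  expect_identical(cfg$migrationRate, 0)
  expect_identical(studyConfig(scenario = "panmictic")$migrationRate, 50)
})
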