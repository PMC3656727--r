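test_that("Watterson's theta matches the closed form", {
  expect_identical(wattersonTheta(3, 2, 100), 0.03) # a1 = 1
  expect_equal(wattersonTheta(10, 5, 1000), 10 / (sum(1 / 1:4) * 1000))
  expect_identical(wattersonTheta(0, 10, 50), 0)
  expect_error(wattersonTheta(1, 1, 100), "at least 2")
})

test_that("Tajima constants reproduce hand-computed values at n = 6", {
  cs <- tajimaConstants(6)
  expect_equal(cs$a1, tinyOracle$a1, tolerance = 1e-12)
  expect_equal(cs$a2, sum(1 / (1:5)^2), tolerance = 1e-12)
  expect_equal(cs$b1, 7 / 15, tolerance = 1e-12)
  expect_equal(cs$b2, 2 * 45 / (9 * 6 * 5), tolerance = 1e-12)
})

test_that("diversity, theta and D on the tiny alignment match frozen oracle values", {
  aln <- tinyAlignment()
  sites <- classifySites(aln, "complete_deletion")
  div <- nucleotideDiversity(sites)
  expect_identical(div$S, tinyOracle$S)
  expect_identical(div$L, 10L)
  expect_equal(div$pi_total, tinyOracle$pi_total, tolerance = 1e-12)
  expect_equal(
    wattersonTheta(div$S, 6, div$L) * div$L,
    tinyOracle$theta_locus,
    tolerance = 1e-12
  )
  td <- tajimasD(div$S, 6, div$pi_total)
  expect_equal(td$d, tinyOracle$d, tolerance = 1e-10)
  expect_equal(td$p_value, tinyOracle$d_beta_p, tolerance = 1e-9)
  expect_false(td$significant)
})

test_that("nucleotideDiversity equals the brute-force pair average", {
  aln <- tinyAlignment()
  sites <- classifySites(aln, "complete_deletion")
  div <- nucleotideDiversity(sites)
  brute <- oraclePi(as.character(sequences(aln)))
  expect_equal(div$pi_total, brute$pi_total, tolerance = 1e-12)
  expect_identical(div$L, brute$L)
  # and against the in-package reference implementation
  pd <- pairwiseDifferences(aln, sites)
  expect_equal(div$pi_total, pd$pi_total, tolerance = 1e-12)
})

test_that("brute-force agreement holds on random fully-called alignments", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(4:10, 1)
    L <- sample(8:30, 1)
    # at most two bases per column, so no column is excluded as
    # multiallelic and the brute-force average is directly comparable
    m <- vapply(seq_len(L), function(j) {
      pair <- sample(c("A", "C", "G", "T"), 2)
      sample(pair, n, replace = TRUE, prob = c(0.8, 0.2))
    }, character(n))
    seqs <- apply(m, 1, paste0, collapse = "")
    names(seqs) <- paste0("s", seq_len(n))
    aln <- LocusAlignment("rand", seqs)
    div <- nucleotideDiversity(classifySites(aln, "complete_deletion"))
    brute <- oraclePi(seqs)
    expect_equal(div$pi_total, brute$pi_total, tolerance = 1e-12)
    expect_identical(div$L, brute$L)
  }
})

test_that("D is 0 when the two theta estimators agree, NA with no variation", {
  cs <- tajimaConstants(10)
  expect_equal(tajimasD(5, 10, 5 / cs$a1)$d, 0, tolerance = 1e-12)
  td0 <- tajimasD(0, 10, 0)
  expect_true(is.na(td0$d))
  expect_true(is.na(td0$p_value))
  expect_false(td0$significant)
  expect_warning(tajimasD(2, 3, 1), "unstable")
})

test_that("beta p-value is symmetric-ish, bounded, and extreme at the bounds", {
  p0 <- tajimaBetaPvalue(0, 20)
  expect_true(p0 > 0.5 && p0 <= 1)
  expect_true(tajimaBetaPvalue(-2, 20) < tajimaBetaPvalue(-1, 20))
  expect_identical(tajimaBetaPvalue(-10, 20), .Machine$double.eps)
  expect_identical(tajimaBetaPvalue(10, 20), .Machine$double.eps)
  expect_true(is.na(tajimaBetaPvalue(NA_real_, 20)))
})

test_that("simulated p-value is deterministic and in (0, 1]", {
  p1 <- tajimaSimulatedPvalue(-1.5, 10, 5, reps = 80, seed = 7)
  p2 <- tajimaSimulatedPvalue(-1.5, 10, 5, reps = 80, seed = 7)
  expect_identical(p1, p2)
  expect_true(p1 > 0 && p1 <= 1)
  # D = 0 is never extreme: p should be large
  expect_true(tajimaSimulatedPvalue(0, 10, 5, reps = 80, seed = 7) > 0.5)
})

test_that("haplotype statistics match the frozen oracle", {
  aln <- tinyAlignment()
  sites <- classifySites(aln, "complete_deletion")
  hap <- haplotypeStats(aln, sites)
  expect_identical(hap$H, tinyOracle$H)
  expect_equal(hap$Hd, tinyOracle$Hd, tolerance = 1e-12)
  expect_identical(hap$n_used, 6L)
  expect_identical(hap$n_excluded, 0L)
})

test_that("sequences missing at a segregating site are excluded from haplotypes", {
  aln <- LocusAlignment("x", c(
    a = "AAC", b = "AAC", c = "ATC", d = "ANC"
  ))
  sites <- classifySites(aln, "pairwise_available")
  hap <- haplotypeStats(aln, sites)
  expect_identical(hap$n_excluded, 1L)
  expect_identical(hap$n_used, 3L)
  expect_identical(hap$H, 2L)
})

test_that("summarizeLocus assembles the component statistics coherently", {
  aln <- tinyAlignment()
  row <- summarizeLocus(aln)
  expect_identical(row$S, 4L)
  expect_identical(row$singletons, 2L)
  expect_identical(row$H, 4L)
  expect_equal(row$tajimas_d, tinyOracle$d, tolerance = 1e-10)
  expect_equal(row$pi, tinyOracle$pi_total / 10, tolerance = 1e-12)
  expect_true(row$computed)
})

test_that("population scope recomputes within subsets and flags tiny populations", {
  aln <- tinyAlignment()
  pm <- PopulationMap(
    data.frame(
      individual_id = paste0("s", 1:6),
      population_id = c("A", "A", "A", "A", "A", "B")
    ),
    data.frame(
      population_id = c("A", "B"), name = c("A", "B"),
      latitude = c(60, 65), longitude = c(10, 20), n_sampled = c(5L, 1L)
    )
  )
  tab <- summarizeLoci(list(aln), pm, scope = "population")
  expect_identical(nrow(tab), 2L)
  a_row <- tab[tab$population_id == "A", ]
  b_row <- tab[tab$population_id == "B", ]
  expect_true(a_row$computed)
  expect_false(b_row$computed)
  expect_true(is.na(b_row$tajimas_d))
  # within A, site 5 (T only in s5? no - s6 excluded) is reclassified
  sub <- subsetAlignment(aln, paste0("s", 1:5))
  expect_identical(a_row$S, nucleotideDiversity(
    classifySites(sub, "complete_deletion")
  )$S)
})
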