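test_that("r2 and D' match frozen oracle values and the documented example", {
  ex <- ldPairStats(6, 2, 2, 6)
  expect_equal(ex$r2, 0.25, tolerance = 1e-12)
  expect_equal(ex$dprime, 0.5, tolerance = 1e-12)
  got <- ldPairStats(10, 2, 3, 9)
  expect_equal(got$r2, frozenLd$r2, tolerance = 1e-12)
  expect_equal(got$dprime, frozenLd$dprime, tolerance = 1e-12)
  expect_error(ldPairStats(5, 5, 0, 0), "monomorphic")
})

test_that("r2 and D' agree with the independent definition-based oracle", {
  set.seed(3)
  for (i in 1:200) {
    tab <- as.vector(stats::rmultinom(1, sample(8:40, 1), runif(4, 0.05, 1)))
    if ((tab[1] + tab[2]) %in% c(0, sum(tab))) next
    if ((tab[1] + tab[3]) %in% c(0, sum(tab))) next
    got <- ldPairStats(tab[1], tab[2], tab[3], tab[4])
    ref <- oracleLd(tab[1], tab[2], tab[3], tab[4])
    expect_equal(got$r2, ref$r2, tolerance = 1e-12)
    expect_equal(got$dprime, ref$dprime, tolerance = 1e-12)
  }
})

test_that("exact test matches frozen two-sided reference p-values", {
  for (f in frozenFisher) {
    expect_equal(
      ldExactTest(f$tab[1], f$tab[2], f$tab[3], f$tab[4]),
      f$p,
      tolerance = 1e-12
    )
  }
  # documented example: 2 / choose(10, 5)
  expect_equal(ldExactTest(5, 0, 0, 5), 2 / choose(10, 5), tolerance = 1e-12)
  # degenerate margins
  expect_identical(ldExactTest(0, 0, 3, 4), 1)
  expect_identical(ldExactTest(3, 4, 0, 0), 1)
})

test_that("exact test equals enumeration on random tables", {
  set.seed(5)
  for (i in 1:300) {
    tab <- as.vector(stats::rmultinom(1, sample(4:30, 1), runif(4)))
    expect_equal(
      ldExactTest(tab[1], tab[2], tab[3], tab[4]),
      oracleFisherP(tab[1], tab[2], tab[3], tab[4]),
      tolerance = 1e-12
    )
  }
})

test_that("r2, D' and p are invariant under allele relabeling and site swap", {
  set.seed(8)
  for (i in 1:300) {
    t0 <- as.vector(stats::rmultinom(1, sample(8:40, 1), runif(4, 0.05, 1)))
    n11 <- t0[1]; n12 <- t0[2]; n21 <- t0[3]; n22 <- t0[4]
    if ((n11 + n12) %in% c(0, sum(t0)) || (n11 + n21) %in% c(0, sum(t0))) next
    base <- ldPairStats(n11, n12, n21, n22)
    basep <- ldExactTest(n11, n12, n21, n22)
    variants <- list(
      c(n12, n11, n22, n21), # relabel site 2
      c(n21, n22, n11, n12), # relabel site 1
      c(n22, n21, n12, n11), # relabel both
      c(n11, n21, n12, n22) # swap sites
    )
    for (v in variants) {
      alt <- ldPairStats(v[1], v[2], v[3], v[4])
      expect_equal(alt$r2, base$r2, tolerance = 1e-12)
      expect_equal(alt$dprime, base$dprime, tolerance = 1e-12)
      expect_equal(ldExactTest(v[1], v[2], v[3], v[4]), basep,
        tolerance = 1e-12)
    }
  }
})

# An alignment with two perfectly linked informative sites, one unlinked
# informative site, and one singleton (never paired).
.ldAln <- function() {
  LocusAlignment("ld", c(
    s1 = "ACAAG", s2 = "ACAAG", s3 = "ACAAT", s4 = "AGATT",
    s5 = "AGATG", s6 = "AGATT", s7 = "TCAAG", s8 = "ACAAG"
  ))
}

test_that("buildLdPairs enumerates informative pairs within loci only", {
  ld <- buildLdPairs(.ldAln())
  p <- ldPairs(ld)
  # informative sites: 2 (C/G 5-3), 4 (A/T 5-3), 5 (G/T 5-3); singleton at 1
  expect_identical(nrow(p), 3L)
  expect_identical(p$pos_i, c(2L, 2L, 4L))
  expect_identical(p$pos_j, c(4L, 5L, 5L))
  expect_identical(p$distance_bp, c(2L, 3L, 1L))
  # sites 2 and 4 are perfectly correlated
  expect_equal(p$r2[1], 1, tolerance = 1e-12)
  expect_equal(p$dprime[1], 1, tolerance = 1e-12)
  info <- attr(ld, "info")
  expect_identical(info$n_informative, 3L)
  expect_identical(info$n_pairs_expected, 3)
})

test_that("haplotype counts are computed on jointly called individuals", {
  aln <- LocusAlignment("m", c(
    s1 = "AG", s2 = "AG", s3 = "AT", s4 = "CT", s5 = "CT", s6 = "NT",
    s7 = "CG", s8 = "AG"
  ))
  p <- ldPairs(buildLdPairs(aln))
  expect_identical(nrow(p), 1L)
  expect_identical(p$n11 + p$n12 + p$n21 + p$n22, 7L)
  expect_identical(p$miss_i, 1L)
  expect_identical(p$miss_j, 0L)
})

test_that("pairs that degenerate after joint-missing removal are dropped and logged", {
  # site 1 informative over all 6; the subset jointly called with site 2
  # leaves site 1 monomorphic
  aln <- LocusAlignment("m", c(
    s1 = "AG", s2 = "AG", s3 = "AT", s4 = "AT", s5 = "CN", s6 = "CN"
  ))
  ld <- buildLdPairs(aln, minHaplotypes = 4L)
  expect_identical(nrow(ldPairs(ld)), 0L)
  dr <- ld@dropped
  expect_identical(nrow(dr), 1L)
  expect_match(dr$reason, "monomorphic margin")
})

test_that("Bonferroni scope changes the significance denominator", {
  la <- .ldAln()
  lb <- LocusAlignment("ld2", sequences(la))
  global <- ldPairs(buildLdPairs(list(la, lb), correctionScope = "global"))
  per <- ldPairs(buildLdPairs(list(la, lb), correctionScope = "per_locus"))
  # same p-values, different thresholds: global denominator 6, per-locus 3
  expect_identical(global$p_value, per$p_value)
  expect_identical(per$significant, per$p_value < 0.05 / 3)
  expect_identical(global$significant, global$p_value < 0.05 / 6)
})

test_that("population-scoped LD subsets and reclassifies", {
  la <- .ldAln()
  pm <- PopulationMap(data.frame(
    individual_id = paste0("s", 1:8),
    population_id = c(rep("A", 6), "B", "B")
  ))
  ld <- buildLdPairs(list(la), pm, population = "A")
  p <- ldPairs(ld)
  expect_true(all(p$population_id == "A"))
  expect_true(all(p$n11 + p$n12 + p$n21 + p$n22 <= 6))
  expect_error(buildLdPairs(list(la), population = "A"), "popmap")
})

test_that("ldSummary reports per-locus rows plus a totals row", {
  ld <- buildLdPairs(.ldAln())
  s <- ldSummary(ld, minPairs = 2L)
  expect_identical(nrow(s), 2L)
  expect_identical(s$locus_id, c("ld", "all_loci"))
  expect_identical(s$n_pairs, c(3L, 3L))
  expect_equal(s$mean_r2[1], mean(ldPairs(ld)$r2), tolerance = 1e-12)
  # below the pair floor the mean is suppressed
  s10 <- ldSummary(ld, minPairs = 10L)
  expect_true(is.na(s10$mean_r2[1]))
})

test_that("pruning removes one member of each offending pair", {
  ld <- buildLdPairs(.ldAln(), alpha = 0.9, correctionScope = "per_locus")
  p <- ldPairs(ld)
  # force the perfectly linked pair to be offending
  expect_true(any(p$significant & p$r2 > 0.2))
  pr <- pruneLinkedSnps(ld, thresholdR2 = 0.2)
  expect_true(nrow(pr$removed) >= 1)
  left <- pr$retained
  # no offending pair survives among retained SNPs
  surv <- p[p$significant & p$r2 > 0.2, ]
  for (i in seq_len(nrow(surv))) {
    both <- c(surv$pos_i[i], surv$pos_j[i]) %in%
      left$position[left$locus_id == surv$locus_id[i]]
    expect_false(all(both))
  }
  # nothing to prune -> everything retained
  ld2 <- buildLdPairs(.ldAln(), alpha = 1e-9)
  pr2 <- pruneLinkedSnps(ld2)
  expect_identical(nrow(pr2$removed), 0L)
  expect_identical(nrow(pr2$retained), 3L)
})
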