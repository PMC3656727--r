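.resamplePopmap <- function(aln, pop = "P1") {
  PopulationMap(data.frame(
    individual_id = names(sequences(aln)),
    population_id = pop, stringsAsFactors = FALSE
  ))
}

test_that("k equal to the population size reproduces the full estimate exactly", {
  aln <- tinyAlignment()
  pm <- .resamplePopmap(aln)
  rs <- resampleStatistics(aln, pm, "P1", k = 6L, B = 20L, seed = 1L)
  expect_equal(rs$mean_d, rs$full_d, tolerance = 1e-12)
  expect_identical(rs$min_d, rs$max_d)
  expect_equal(rs$mean_pi, rs$full_pi, tolerance = 1e-12)
  expect_identical(rs$n_excluded_d, 0L)
  expect_equal(rs$full_d, tinyOracle$d, tolerance = 1e-10)
})

test_that("resampling is deterministic under a fixed seed", {
  aln <- tinyAlignment()
  pm <- .resamplePopmap(aln)
  r1 <- resampleStatistics(aln, pm, "P1", k = 4L, B = 30L, seed = 9L)
  r2 <- resampleStatistics(aln, pm, "P1", k = 4L, B = 30L, seed = 9L)
  expect_identical(r1, r2)
  r3 <- resampleStatistics(aln, pm, "P1", k = 4L, B = 30L, seed = 10L)
  expect_false(identical(r1$d, r3$d))
})

test_that("summary bounds bracket the mean and exclusions are counted", {
  aln <- tinyAlignment()
  pm <- .resamplePopmap(aln)
  rs <- resampleStatistics(aln, pm, "P1", k = 4L, B = 50L, seed = 2L)
  expect_true(rs$min_d <= rs$mean_d && rs$mean_d <= rs$max_d)
  expect_true(rs$min_pi <= rs$mean_pi && rs$mean_pi <= rs$max_pi)
  expect_identical(rs$n_excluded_d, sum(is.na(rs$d)))
  expect_true(sum(!is.na(rs$d)) <= rs$B)
})

test_that("undersized populations error and tiny subsamples warn", {
  aln <- tinyAlignment()
  pm <- .resamplePopmap(aln)
  expect_error(
    resampleStatistics(aln, pm, "P1", k = 7L, B = 5L),
    "cannot subsample"
  )
  expect_warning(
    resampleStatistics(aln, pm, "P1", k = 3L, B = 5L, seed = 1L),
    "unstable"
  )
})

test_that("monomorphic draws are excluded from the D summary, not imputed", {
  # only one variable site, carried by a single sequence: draws without s2
  # have S = 0
  aln <- LocusAlignment("m", c(
    s1 = "AAAA", s2 = "ATAA", s3 = "AAAA", s4 = "AAAA",
    s5 = "AAAA", s6 = "AAAA"
  ))
  pm <- .resamplePopmap(aln)
  rs <- resampleStatistics(aln, pm, "P1", k = 4L, B = 40L, seed = 3L)
  expect_true(rs$n_excluded_d > 0)
  expect_identical(rs$n_excluded_d + sum(!is.na(rs$d)), 40L)
})

test_that("resampleStudy flags undersized populations and attaches replicates", {
  aln <- tinyAlignment()
  pm <- PopulationMap(data.frame(
    individual_id = paste0("s", 1:6),
    population_id = c("A", "A", "A", "A", "B", "B")
  ))
  tab <- resampleStudy(list(aln), pm, populationIds = c("A", "B"),
    k = 4L, B = 10L, seed = 1L)
  expect_identical(nrow(tab), 2L)
  expect_true(tab$computed[tab$population_id == "A"])
  expect_false(tab$computed[tab$population_id == "B"])
  reps <- attr(tab, "replicates")
  expect_identical(nrow(reps), 10L)
  expect_true(all(reps$population_id == "A"))
})

test_that("joint draws reuse one subsample across loci within a replicate", {
  # two identical loci: joint resampling must give identical replicate
  # series at both loci
  a1 <- tinyAlignment()
  a2 <- LocusAlignment("tiny2", sequences(tinyAlignment()))
  pm <- .resamplePopmap(a1)
  tab <- resampleStudy(list(a1, a2), pm, populationIds = "P1",
    k = 4L, B = 15L, seed = 4L, joint = TRUE)
  reps <- attr(tab, "replicates")
  d1 <- reps$d[reps$locus_id == "tiny"]
  d2 <- reps$d[reps$locus_id == "tiny2"]
  expect_identical(d1, d2)
  # independent mode redraws per locus
  tab2 <- resampleStudy(list(a1, a2), pm, populationIds = "P1",
    k = 4L, B = 15L, seed = 4L, joint = FALSE)
  reps2 <- attr(tab2, "replicates")
  expect_false(identical(
    reps2$d[reps2$locus_id == "tiny"],
    reps2$d[reps2$locus_id == "tiny2"]
  ))
})

test_that("latitude trend table aggregates per population with a rank statistic", {
  aln <- tinyAlignment()
  pm <- PopulationMap(
    data.frame(
      individual_id = paste0("s", 1:6),
      population_id = c("A", "A", "A", "B", "B", "B")
    ),
    data.frame(
      population_id = c("A", "B"), name = c("A", "B"),
      latitude = c(59, 66), longitude = c(12, 20), n_sampled = c(3L, 3L)
    )
  )
  summ <- suppressWarnings(summarizeLoci(list(aln), pm, scope = "population"))
  tab <- latitudeTrendTable(summ, pm)
  expect_identical(tab$population_id, c("A", "B"))
  expect_identical(tab$latitude, c(59, 66))
  # fewer than 3 populations -> no trend statistic
  expect_null(attr(tab, "spearman"))
  # identical populations -> identical mean D
  a_dup <- LocusAlignment("dup", c(
    x1 = "ACGTACGTAC", x2 = "ACCTACGTAA", x3 = "ACGTACGAAC",
    y1 = "ACGTACGTAC", y2 = "ACCTACGTAA", y3 = "ACGTACGAAC"
  ))
  pm3 <- PopulationMap(data.frame(
    individual_id = c("x1", "x2", "x3", "y1", "y2", "y3"),
    population_id = c("X", "X", "X", "Y", "Y", "Y")
  ))
  summ3 <- suppressWarnings(
    summarizeLoci(list(a_dup), pm3, scope = "population")
  )
  tab3 <- latitudeTrendTable(summ3, pm3)
  expect_equal(tab3$mean_d[1], tab3$mean_d[2], tolerance = 1e-12)
})
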