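#' r2 and D' from a 2x2 haplotype count table
#'
#' For haploid (phased) data the haplotype table at two biallelic sites is
#' observed directly. With `pA`, `pB` the marginal frequencies of the
#' first allele at each site and `p11` the frequency of the (1,1)
#' haplotype, `D = p11 - pA*pB`, `r2 = D^2 / (pA*(1-pA)*pB*(1-pB))` and
#' `D' = |D| / Dmax`, where `Dmax = min(pA*(1-pB), (1-pA)*pB)` when
#' `D > 0` and `min(pA*pB, (1-pA)*(1-pB))` when `D < 0` (`D' = 0` at
#' `D = 0`). Both statistics are symmetric in site order and invariant
#' under allele relabelling at either site.
#'
#' @param n11,n12,n21,n22 haplotype counts: allele index at site 1 x allele
#'   index at site 2, over individuals called at both sites.
#' @return List with `r2`, `dprime`, `d`.
#' @examples
#' ldPairStats(6, 2, 2, 6) # r2 = 0.25, D' = 0.5
#' @export
ldPairStats <- function(n11, n12, n21, n22) {
  m <- n11 + n12 + n21 + n22
  pA <- (n11 + n12) / m
  pB <- (n11 + n21) / m
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    stop("monomorphic margin: LD undefined for this pair")
  }
  D <- n11 / m - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  dmax <- if (D > 0) {
    min(pA * (1 - pB), (1 - pA) * pB)
  } else if (D < 0) {
    min(pA * pB, (1 - pA) * (1 - pB))
  } else {
    1 # D == 0 -> D' = 0 regardless
  }
  list(r2 = r2, dprime = abs(D) / dmax, d = D)
}

#' Two-sided exact test for a 2x2 haplotype table
#'
#' Fisher's exact test: with margins fixed, sums the hypergeometric
#' probabilities of all tables no more probable than the observed one
#' (probabilities within a relative 1e-7 of the observed are counted as
#' ties, the standard guard against floating-point noise). A table with
#' any zero margin is degenerate: `p = 1` by convention.
#'
#' @inheritParams ldPairStats
#' @return p-value in (0, 1].
#' @examples
#' ldExactTest(5, 0, 0, 5) # 2/choose(10, 5) = 0.00794
#' @export
ldExactTest <- function(n11, n12, n21, n22) {
  n <- n11 + n12 + n21 + n22
  r <- n11 + n12
  cc <- n11 + n21
  if (r == 0 || cc == 0 || r == n || cc == n) {
    return(1)
  }
  lo <- max(0L, r + cc - n)
  hi <- min(r, cc)
  k <- lo:hi
  probs <- dhyper(k, cc, n - cc, r)
  p_obs <- dhyper(n11, cc, n - cc, r)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Build all within-locus LD pairs over parsimony-informative sites
#'
#' Enumerates every pair of analyzed parsimony-informative biallelic sites
#' within each locus (loci are unlinked genes, so between-locus pairs are
#' never formed), computes `r2`, `D'` and the exact-test p-value on the
#' individuals called at both sites (pairwise deletion; at least
#' `minHaplotypes` complete haplotypes required), and applies a Bonferroni
#' correction at level `alpha`. With `correctionScope = "global"` the
#' denominator is the total number of tested pairs across all loci in the
#' analysis (one experiment-wide family); with `"per_locus"` each locus is
#' its own family. Pairs whose margins become monomorphic after
#' joint-missing removal, or with too few complete haplotypes, are dropped
#' and logged. When `population` is given the alignments are subset to
#' that population's individuals and sites are re-classified within it.
#'
#' @param alignments list of [LocusAlignment-class] objects.
#' @param popmap optional [PopulationMap-class] (required with `population`).
#' @param population optional population id for a within-population analysis.
#' @param missingPolicy site policy (default `"pairwise_available"`, using
#'   the full range of read lengths).
#' @param correctionScope `"global"` or `"per_locus"`.
#' @param alpha family-wise level (default 0.05).
#' @param minHaplotypes minimum complete haplotypes per pair (default 4).
#' @return An [LDPairSet-class].
#' @export
buildLdPairs <- function(alignments, popmap = NULL, population = NULL,
                         missingPolicy = "pairwise_available",
                         correctionScope = c("global", "per_locus"),
                         alpha = 0.05, minHaplotypes = 4L) {
  correctionScope <- match.arg(correctionScope)
  if (is(alignments, "LocusAlignment")) alignments <- list(alignments)
  pair_rows <- list()
  drop_rows <- list()
  info_rows <- list()
  for (aln in alignments) {
    aln <- dropEmptySequences(aln)
    if (!is.null(population)) {
      if (is.null(popmap)) stop("population-scoped LD requires a popmap")
      ids <- names(sequences(aln))
      members <- ids[populationOf(popmap, ids) == population]
      if (length(members) < minHaplotypes) next
      aln <- subsetAlignment(aln, members)
    }
    sites <- classifySites(aln, missingPolicy)
    st <- siteData(sites)
    am <- alleleMatrix(aln, sites, informativeOnly = TRUE)
    k <- ncol(am)
    info_rows[[length(info_rows) + 1L]] <- data.frame(
      locus_id = locusId(aln),
      population_id = if (is.null(population)) NA_character_ else population,
      n_informative = k, n_pairs_expected = choose(k, 2),
      stringsAsFactors = FALSE
    )
    if (k < 2L) next
    pos <- as.integer(colnames(am))
    miss <- colSums(is.na(am))
    for (i in seq_len(k - 1L)) {
      xi <- am[, i]
      for (j in (i + 1L):k) {
        xj <- am[, j]
        ok <- !is.na(xi) & !is.na(xj)
        n11 <- sum(xi[ok] == 0L & xj[ok] == 0L)
        n12 <- sum(xi[ok] == 0L & xj[ok] == 1L)
        n21 <- sum(xi[ok] == 1L & xj[ok] == 0L)
        n22 <- sum(xi[ok] == 1L & xj[ok] == 1L)
        m <- n11 + n12 + n21 + n22
        reason <- NULL
        if (m < minHaplotypes) {
          reason <- "fewer complete haplotypes than required"
        } else if ((n11 + n12) %in% c(0L, m) || (n11 + n21) %in% c(0L, m)) {
          reason <- "monomorphic margin after joint-missing removal"
        }
        if (!is.null(reason)) {
          drop_rows[[length(drop_rows) + 1L]] <- data.frame(
            locus_id = locusId(aln),
            population_id = if (is.null(population)) NA_character_ else population,
            pos_i = pos[i], pos_j = pos[j], n_complete = m, reason = reason,
            stringsAsFactors = FALSE
          )
          next
        }
        ld <- ldPairStats(n11, n12, n21, n22)
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          locus_id = locusId(aln),
          population_id = if (is.null(population)) NA_character_ else population,
          pos_i = pos[i], pos_j = pos[j],
          distance_bp = abs(pos[j] - pos[i]),
          n11 = n11, n12 = n12, n21 = n21, n22 = n22,
          r2 = ld$r2, dprime = ld$dprime,
          p_value = ldExactTest(n11, n12, n21, n22),
          miss_i = as.integer(miss[i]), miss_j = as.integer(miss[j]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  pairs <- if (length(pair_rows)) {
    do.call(rbind, pair_rows)
  } else {
    data.frame(
      locus_id = character(), population_id = character(),
      pos_i = integer(), pos_j = integer(), distance_bp = integer(),
      n11 = integer(), n12 = integer(), n21 = integer(), n22 = integer(),
      r2 = numeric(), dprime = numeric(), p_value = numeric(),
      miss_i = integer(), miss_j = integer(), stringsAsFactors = FALSE
    )
  }
  if (nrow(pairs)) {
    denom <- if (correctionScope == "global") {
      nrow(pairs)
    } else {
      stats::ave(pairs$p_value, pairs$locus_id, FUN = length)
    }
    pairs$significant <- pairs$p_value < alpha / denom
  } else {
    pairs$significant <- logical(0)
  }
  dropped <- if (length(drop_rows)) {
    do.call(rbind, drop_rows)
  } else {
    data.frame(
      locus_id = character(), population_id = character(),
      pos_i = integer(), pos_j = integer(), n_complete = integer(),
      reason = character(), stringsAsFactors = FALSE
    )
  }
  out <- new("LDPairSet",
    pairs = pairs, dropped = dropped,
    correctionScope = correctionScope, alpha = alpha
  )
  attr(out, "info") <- do.call(rbind, info_rows)
  out
}

#' Per-locus LD summary table
#'
#' Mirrors the usual per-gene LD report: number of informative sites,
#' number of pairwise comparisons, percent significant after correction,
#' and mean r2 over tested pairs. Loci with fewer comparisons than
#' `minPairs` get `NA` mean r2 (too few pairs for a meaningful mean).
#'
#' @param ldset an [LDPairSet-class] from [buildLdPairs()].
#' @param minPairs minimum comparisons for reporting mean r2 (default 10).
#' @return data.frame with one row per locus plus an `all_loci` totals row.
#' @export
ldSummary <- function(ldset, minPairs = 10L) {
  p <- ldPairs(ldset)
  info <- attr(ldset, "info")
  rows <- lapply(seq_len(nrow(info)), function(i) {
    sel <- p$locus_id == info$locus_id[i] &
      (is.na(info$population_id[i]) | p$population_id %in% info$population_id[i])
    pp <- p[sel, , drop = FALSE]
    data.frame(
      locus_id = info$locus_id[i],
      population_id = info$population_id[i],
      n_informative = info$n_informative[i],
      n_pairs = nrow(pp),
      pct_significant = if (nrow(pp)) 100 * mean(pp$significant) else NA_real_,
      mean_r2 = if (nrow(pp) >= minPairs) mean(pp$r2) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  tot <- data.frame(
    locus_id = "all_loci", population_id = NA_character_,
    n_informative = sum(info$n_informative),
    n_pairs = nrow(p),
    pct_significant = if (nrow(p)) 100 * mean(p$significant) else NA_real_,
    mean_r2 = if (nrow(p)) mean(p$r2) else NA_real_,
    stringsAsFactors = FALSE
  )
  rbind(do.call(rbind, rows), tot)
}

#' Greedy LD-based SNP pruning
#'
#' Removes SNPs until no remaining pair is both significant after
#' correction and above the r2 threshold, the preprocessing used before
#' model-based clustering of near-panmictic data. From each offending pair
#' (scanned in locus/position order) the member with the higher missing
#' count is removed; ties remove the higher position. The greedy rule is
#' deterministic plumbing: any rule breaking all offending pairs is
#' admissible.
#'
#' @param ldset an [LDPairSet-class].
#' @param thresholdR2 prune pairs with significant r2 above this (default 0.2).
#' @return List with `retained` (data.frame `locus_id`, `position` of SNPs
#'   kept among those appearing in tested pairs) and `removed`
#'   (data.frame with the removal log).
#' @export
pruneLinkedSnps <- function(ldset, thresholdR2 = 0.2) {
  p <- ldPairs(ldset)
  key <- function(locus, pos, popid) paste(locus, popid, pos, sep = "\r")
  p$ki <- key(p$locus_id, p$pos_i, p$population_id)
  p$kj <- key(p$locus_id, p$pos_j, p$population_id)
  all_snps <- unique(data.frame(
    locus_id = c(p$locus_id, p$locus_id),
    population_id = c(p$population_id, p$population_id),
    position = c(p$pos_i, p$pos_j),
    k = c(p$ki, p$kj), stringsAsFactors = FALSE
  ))
  offending <- p[p$significant & p$r2 > thresholdR2, , drop = FALSE]
  offending <- offending[order(
    offending$locus_id, offending$pos_i, offending$pos_j
  ), , drop = FALSE]
  removed <- character()
  log_rows <- list()
  while (nrow(offending)) {
    row <- offending[1L, ]
    victim <- if (row$miss_i > row$miss_j) {
      list(k = row$ki, pos = row$pos_i)
    } else if (row$miss_j > row$miss_i) {
      list(k = row$kj, pos = row$pos_j)
    } else {
      list(k = row$kj, pos = row$pos_j) # tie -> higher position
    }
    removed <- c(removed, victim$k)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      locus_id = row$locus_id, position = victim$pos,
      partner = if (victim$pos == row$pos_j) row$pos_i else row$pos_j,
      r2 = row$r2, p_value = row$p_value, stringsAsFactors = FALSE
    )
    offending <- offending[offending$ki != victim$k & offending$kj != victim$k, ,
      drop = FALSE
    ]
  }
  retained <- all_snps[!all_snps$k %in% removed, c("locus_id", "population_id", "position")]
  rownames(retained) <- NULL
  list(
    retained = retained,
    removed = if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(
        locus_id = character(), position = integer(), partner = integer(),
        r2 = numeric(), p_value = numeric(), stringsAsFactors = FALSE
      )
  )
}
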