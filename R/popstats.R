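#' Watterson's estimate of theta per site
#'
#' `S / (a1 * L)` with `a1 = sum(1/i, i = 1..n-1)`: the segregating-sites
#' estimator of theta = 4*Ne*mu, per base pair.
#'
#' @param S number of segregating sites.
#' @param n haploid sample size (>= 2).
#' @param L number of sites analyzed (>= 1).
#' @return Per-site theta estimate.
#' @examples
#' wattersonTheta(3, 2, 100) # a1 = 1 -> 0.03
#' @export
wattersonTheta <- function(S, n, L) {
  if (n < 2) stop("wattersonTheta needs at least 2 sequences")
  stopifnot(L >= 1, S >= 0)
  S / (sum(1 / seq_len(n - 1)) * L)
}

#' Constants of Tajima's D for a sample size
#'
#' The harmonic-sum constants `a1, a2, b1, b2, c1, c2, e1, e2` entering the
#' variance normalization of Tajima's D.
#'
#' @param n haploid sample size (>= 3; below 4 the statistic is unstable).
#' @return Named list of the eight constants.
#' @export
tajimaConstants <- function(n) {
  stopifnot(n >= 3)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D with beta-approximation significance
#'
#' `D = (piTotal - S/a1) / sqrt(e1*S + e2*S*(S-1))`, the normalized
#' difference between the mean-pairwise-difference and segregating-sites
#' estimators of theta. Negative values indicate an excess of rare variants
#' (e.g. population expansion), positive values an excess of
#' intermediate-frequency variants. Significance uses the scaled
#' beta-distribution approximation of the null density of D between its
#' attainable bounds, the approach standard in sequence-analysis software;
#' an optional coalescent-simulated null is available via
#' [tajimaSimulatedPvalue()].
#'
#' @param S number of segregating sites.
#' @param n haploid sample size (a warning is emitted below 4).
#' @param piTotal mean number of pairwise differences per sequence pair
#'   (summed over sites, not per site).
#' @param alpha significance level (default 0.05, two-sided).
#' @return List with `d`, `p_value`, `significant`. When `S = 0` the
#'   statistic is undefined: `d` and `p_value` are `NA` and `significant`
#'   is `FALSE`.
#' @examples
#' cs <- tajimaConstants(10)
#' tajimasD(5, 10, 5 / cs$a1) # piTotal == S/a1 -> D = 0
#' @export
tajimasD <- function(S, n, piTotal, alpha = 0.05) {
  if (S < 1) {
    return(list(d = NA_real_, p_value = NA_real_, significant = FALSE))
  }
  if (n < 4) warning("Tajima's D is unstable for n < 4")
  cs <- tajimaConstants(n)
  d <- (piTotal - S / cs$a1) / sqrt(cs$e1 * S + cs$e2 * S * (S - 1))
  p <- tajimaBetaPvalue(d, n)
  list(d = d, p_value = p, significant = !is.na(p) && p < alpha)
}

#' Two-sided beta-approximation p-value for Tajima's D
#'
#' Under the approximation, D follows a generalized beta density on its
#' attainable range `[Dmin, Dmax]` with mean 0 and variance 1, where
#' `Dmin = (2/n - 1/a1)/sqrt(e2)` (all singletons) and
#' `Dmax = (n/(2(n-1)) - 1/a1)/sqrt(e2)` for even n
#' (`((n+1)/(2n) - 1/a1)/sqrt(e2)` for odd n; balanced frequencies).
#'
#' @param d observed D value.
#' @param n haploid sample size.
#' @return Two-sided p-value in (0, 1]; `NA` when the approximation is
#'   ill-defined for this n.
#' @export
tajimaBetaPvalue <- function(d, n) {
  if (is.na(d)) {
    return(NA_real_)
  }
  cs <- tajimaConstants(n)
  dmin <- (2 / n - 1 / cs$a1) / sqrt(cs$e2)
  dmax <- if (n %% 2 == 0) {
    (n / (2 * (n - 1)) - 1 / cs$a1) / sqrt(cs$e2)
  } else {
    ((n + 1) / (2 * n) - 1 / cs$a1) / sqrt(cs$e2)
  }
  ab <- dmin * dmax
  shape_a <- -(1 + ab) * dmax / (dmax - dmin)
  shape_b <- (1 + ab) * dmin / (dmax - dmin)
  if (is.na(shape_a) || is.na(shape_b) || shape_a <= 0 || shape_b <= 0) {
    return(NA_real_)
  }
  if (d <= dmin) {
    return(.Machine$double.eps)
  }
  if (d >= dmax) {
    return(.Machine$double.eps)
  }
  x <- (d - dmin) / (dmax - dmin)
  cdf <- stats::pbeta(x, shape_b, shape_a)
  min(1, 2 * min(cdf, 1 - cdf))
}

#' Coalescent-simulated p-value for Tajima's D
#'
#' Simulates the null distribution of D under the standard neutral model
#' conditioned approximately on theta (fixed-theta coalescent replicates)
#' and returns the two-sided empirical p-value.
#'
#' @param d observed D.
#' @param n haploid sample size.
#' @param thetaLocus locus-wide theta for the null simulations.
#' @param reps number of replicates.
#' @param seed RNG seed.
#' @return Empirical two-sided p-value.
#' @export
tajimaSimulatedPvalue <- function(d, n, thetaLocus, reps = 1000, seed = 1) {
  if (is.na(d)) {
    return(NA_real_)
  }
  set.seed(seed)
  null_d <- vapply(seq_len(reps), function(i) {
    muts <- simulateAncestry(n, thetaLocus, rho = 0)
    S <- length(muts$carriers)
    if (S == 0) {
      return(NA_real_)
    }
    k <- vapply(muts$carriers, length, 1L)
    piTotal <- sum(2 * k * (n - k) / (n * (n - 1)))
    cs <- tajimaConstants(n)
    (piTotal - S / cs$a1) / sqrt(cs$e1 * S + cs$e2 * S * (S - 1))
  }, 1)
  null_d <- null_d[!is.na(null_d)]
  (1 + sum(abs(null_d) >= abs(d))) / (1 + length(null_d))
}

#' Per-site nucleotide diversity from a site table
#'
#' Mean pairwise difference per analyzed site. Per site with `c` called
#' sequences and minor count `m` the contribution is `2*m*(c-m)/(c*(c-1))`
#' (the unbiased `c/(c-1)` heterozygosity correction); under
#' `complete_deletion` (`c = n` everywhere) this equals the brute-force
#' average over all `choose(n, 2)` sequence pairs exactly.
#'
#' @param sites a [SiteTable-class].
#' @return List with `pi` (per site), `pi_total` (summed over sites, i.e.
#'   mean pairwise differences per sequence pair), `L` (analyzed sites),
#'   `S` (analyzed segregating sites).
#' @export
nucleotideDiversity <- function(sites) {
  st <- siteData(sites)
  an <- st[st$analyzed, , drop = FALSE]
  L <- nrow(an)
  bi <- an[an$klass == "biallelic_snp", , drop = FALSE]
  if (nrow(bi)) {
    c_called <- bi$count1 + bi$count2
    h <- 2 * bi$count1 * bi$count2 / (c_called * (c_called - 1))
    pi_total <- sum(h)
  } else {
    pi_total <- 0
  }
  list(
    pi = if (L > 0) pi_total / L else 0,
    pi_total = pi_total, L = L, S = nrow(bi)
  )
}

#' Haplotype count and diversity
#'
#' Haplotypes are distinct strings over the analyzed segregating sites.
#' Sequences carrying missing data at any of those sites have an undefined
#' haplotype and are excluded from the computation (their number is
#' reported). `Hd = (n/(n-1)) * (1 - sum(p_k^2))`.
#'
#' @param aln a [LocusAlignment-class].
#' @param sites the matching [SiteTable-class].
#' @return List with `H`, `Hd`, `n_used`, `n_excluded`.
#' @export
haplotypeStats <- function(aln, sites) {
  st <- siteData(sites)
  seg <- st$position[st$analyzed & st$klass == "biallelic_snp"]
  m <- alignmentMatrix(aln)
  if (length(seg) == 0L) {
    return(list(H = 1L, Hd = 0, n_used = nrow(m), n_excluded = 0L))
  }
  sub <- m[, seg, drop = FALSE]
  ok <- rowSums(sub == "N" | sub == "-") == 0L
  sub <- sub[ok, , drop = FALSE]
  n <- nrow(sub)
  if (n < 2L) {
    return(list(H = NA_integer_, Hd = NA_real_, n_used = n, n_excluded = sum(!ok)))
  }
  hap <- apply(sub, 1L, paste, collapse = "")
  p <- table(hap) / n
  list(
    H = length(p),
    Hd = (n / (n - 1)) * (1 - sum(p^2)),
    n_used = n, n_excluded = sum(!ok)
  )
}

#' Per-locus (or per-population) diversity summary
#'
#' Assembles the standard summary row for a locus: sample size, analyzed
#' sites, segregating sites and singletons, haplotype count and diversity,
#' Watterson's theta and nucleotide diversity per site, and Tajima's D with
#' its beta-approximation significance. With `scope = "population"` the
#' alignment is subset per population and every statistic (including site
#' classification) is recomputed within the subset; populations with fewer
#' than 2 sequenced individuals are emitted with `computed = FALSE` and NA
#' statistics rather than dropped.
#'
#' Individuals with no called base at any position are dropped from the
#' locus before classification (their sequences carry no information and
#' would zero out the complete-deletion site set).
#'
#' @param aln a [LocusAlignment-class].
#' @param popmap a [PopulationMap-class]; required for population scope.
#' @param scope `"all"` (pooled) or `"population"`.
#' @param missingPolicy passed to [classifySites()].
#' @param alpha significance level for Tajima's D.
#' @return data.frame with columns `locus_id`, `population_id`, `n`, `L`,
#'   `S`, `singletons`, `H`, `Hd`, `theta_w`, `pi`, `tajimas_d`,
#'   `d_pvalue`, `d_significant`, `computed`.
#' @export
summarizeLocus <- function(aln, popmap = NULL, scope = c("all", "population"),
                           missingPolicy = "complete_deletion", alpha = 0.05) {
  scope <- match.arg(scope)
  aln <- dropEmptySequences(aln)
  if (scope == "all") {
    return(.summaryRow(aln, NA_character_, missingPolicy, alpha))
  }
  if (is.null(popmap)) stop("population scope requires a popmap")
  ids <- names(sequences(aln))
  pops <- populationOf(popmap, ids)
  rows <- lapply(unique(populations(popmap)$population_id), function(p) {
    members <- ids[pops == p]
    if (length(members) < 2L) {
      return(.naRow(locusId(aln), p, length(members)))
    }
    .summaryRow(subsetAlignment(aln, members), p, missingPolicy, alpha)
  })
  do.call(rbind, rows)
}

#' Summarize a list of loci
#'
#' @param alignments list of [LocusAlignment-class] objects.
#' @inheritParams summarizeLocus
#' @return Row-bound data.frame of [summarizeLocus()] results.
#' @export
summarizeLoci <- function(alignments, popmap = NULL, scope = "all",
                          missingPolicy = "complete_deletion", alpha = 0.05) {
  do.call(rbind, lapply(
    alignments, summarizeLocus,
    popmap = popmap,
    scope = scope, missingPolicy = missingPolicy, alpha = alpha
  ))
}

.summaryRow <- function(aln, population_id, missingPolicy, alpha) {
  n <- nSequences(aln)
  if (n < 2L) {
    return(.naRow(locusId(aln), population_id, n))
  }
  sites <- classifySites(aln, missingPolicy)
  st <- siteData(sites)
  div <- nucleotideDiversity(sites)
  hap <- haplotypeStats(aln, sites)
  an_bi <- st$analyzed & st$klass == "biallelic_snp"
  S <- sum(an_bi)
  singletons <- sum(st$is_singleton & st$analyzed)
  theta_w <- if (div$L > 0) wattersonTheta(S, n, div$L) else 0
  td <- tajimasD(S, n, div$pi_total, alpha = alpha)
  data.frame(
    locus_id = locusId(aln), population_id = population_id,
    n = n, L = div$L, S = S, singletons = singletons,
    H = hap$H, Hd = hap$Hd,
    theta_w = theta_w, pi = div$pi,
    tajimas_d = td$d, d_pvalue = td$p_value, d_significant = td$significant,
    computed = TRUE, stringsAsFactors = FALSE
  )
}

.naRow <- function(locus_id, population_id, n) {
  data.frame(
    locus_id = locus_id, population_id = population_id,
    n = n, L = NA_integer_, S = NA_integer_, singletons = NA_integer_,
    H = NA_integer_, Hd = NA_real_, theta_w = NA_real_, pi = NA_real_,
    tajimas_d = NA_real_, d_pvalue = NA_real_, d_significant = NA,
    computed = FALSE, stringsAsFactors = FALSE
  )
}

dropEmptySequences <- function(aln) {
  m <- alignmentMatrix(aln)
  called <- rowSums(m != "N" & m != "-") > 0L
  if (all(called)) {
    return(aln)
  }
  subsetAlignment(aln, rownames(m)[called])
}

#' Brute-force mean pairwise differences (reference implementation)
#'
#' Averages per-site differences over all sequence pairs directly,
#' restricted to analyzed columns and, per pair, to columns where both
#' sequences are called. Quadratic and slow; intended as an independent
#' check of [nucleotideDiversity()].
#'
#' @param aln a [LocusAlignment-class].
#' @param sites the matching [SiteTable-class].
#' @return List with `pi` (mean per-site rate over pairs) and `pi_total`
#'   (mean differences per pair, scaled to the analyzed length).
#' @export
pairwiseDifferences <- function(aln, sites) {
  st <- siteData(sites)
  keep <- st$position[st$analyzed]
  m <- alignmentMatrix(aln)[, keep, drop = FALSE]
  n <- nrow(m)
  stopifnot(n >= 2)
  rates <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "N" & m[i, ] != "-" & m[j, ] != "N" & m[j, ] != "-"
      if (!any(ok)) next
      rates <- c(rates, sum(m[i, ok] != m[j, ok]) / sum(ok))
    }
  }
  list(pi = mean(rates), pi_total = mean(rates) * length(keep))
}
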