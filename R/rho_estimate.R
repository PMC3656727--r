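#' Project a haplotype configuration to the lookup sample size
#'
#' A pair of sites with missing data is observed on `m < n` complete
#' haplotypes. To score it against a table built for `n`, the counts are
#' scaled by `n / m` - the configuration whose expected hypergeometric
#' down-sample to `m` haplotypes matches the observation - and rounded by
#' largest remainder so the projection sums exactly to `n` while keeping
#' every nonzero observed cell nonzero.
#'
#' @param counts integer vector `(n11, n10, n01, n00)` summing to `m`.
#' @param n target sample size (`>= m`).
#' @return Integer vector summing to `n`.
#' @keywords internal
.projectConfig <- function(counts, n) {
  m <- sum(counts)
  if (m == n) return(as.integer(counts))
  scaled <- counts * n / m
  base <- floor(scaled)
  base[counts > 0 & base == 0] <- 1L
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(scaled - base, decreasing = TRUE)
    for (i in ord) {
      if (short == 0) break
      base[i] <- base[i] + 1
      short <- short - 1
    }
  } else if (short < 0) {
    ord <- order(scaled - base)
    for (i in ord) {
      if (short == 0) break
      if (base[i] > 1 || (base[i] == 1 && counts[i] == 0)) {
        base[i] <- base[i] - 1
        short <- short + 1
      }
    }
  }
  as.integer(base)
}

#' Composite-likelihood estimate of the population recombination rate
#'
#' Sums two-locus log-likelihoods over all pairs of analyzed biallelic
#' SNPs, with the two-locus rate of a pair at candidate rate `c` (per kb)
#' taken as `c * distance_kb`, interpolated linearly on the lookup grid
#' (and held at the boundary value beyond it). The estimate is the
#' candidate maximizing the composite log-likelihood profile; ties go to
#' the smallest candidate. Pairs are reduced to haplotypes called at both
#' sites; pairs with fewer than 4 complete haplotypes or a monomorphic
#' margin after reduction are skipped, and pairs with fewer haplotypes
#' than the table's sample size are projected up (see internals). The
#' profile is flagged flat when its maximum is fewer than 2 log-units
#' above its value at the candidate-grid boundary farthest from the
#' maximizer.
#'
#' @param aln a [LocusAlignment-class].
#' @param sites a [SiteTable-class] for `aln` (pairwise-available policy
#'   recommended).
#' @param lookup a [LookupTable-class]; its sample size must be at least
#'   the number of sequences in `aln`.
#' @param candidates nonnegative candidate rates per kb (default 101
#'   points on `[0, max(rho_grid)]`).
#' @return List with `locus_id`, `computed`, `rho_per_kb`, `rho_per_site`,
#'   `rho_locus` (per-site rate times amplicon length), `profile`
#'   (data.frame of `rho_per_kb`, `log_composite_likelihood`),
#'   `flat_likelihood`, `n_snps`, `n_pairs_used`, `n_pairs_skipped`.
#'   When fewer than 2 usable SNPs remain, `computed` is `FALSE` and the
#'   rate fields are `NA` (not an error), mirroring loci reported blank.
#' @export
estimateRho <- function(aln, sites, lookup,
                        candidates = seq(0, max(lookup@rhoGrid),
                          length.out = 101
                        )) {
  stopifnot(is(aln, "LocusAlignment"), is(sites, "SiteTable"),
    is(lookup, "LookupTable"))
  stopifnot(all(candidates >= 0), !is.unsorted(candidates))
  if (nSequences(aln) > lookup@n) {
    stop(
      "lookup table sample size (", lookup@n, ") is smaller than the ",
      "alignment (", nSequences(aln), " sequences); rebuild the table"
    )
  }
  notComputed <- function(n_snps, skipped) list(
    locus_id = locusId(aln), computed = FALSE,
    rho_per_kb = NA_real_, rho_per_site = NA_real_, rho_locus = NA_real_,
    profile = NULL, flat_likelihood = NA,
    n_snps = n_snps, n_pairs_used = 0L, n_pairs_skipped = skipped
  )
  st <- siteData(sites)
  snp <- st[st$analyzed & st$klass == "biallelic_snp", , drop = FALSE]
  if (nrow(snp) < 2L) return(notComputed(nrow(snp), 0L))
  geno <- alleleMatrix(aln, sites, informativeOnly = FALSE)
  geno <- geno[, as.character(snp$position), drop = FALSE]
  pos <- snp$position
  nS <- length(pos)

  pairRows <- list()
  pairDist <- numeric(0)
  skipped <- 0L
  floorLL <- rep(log(1 / (lookup@nDraws + 1)), length(lookup@rhoGrid))
  for (i in seq_len(nS - 1L)) {
    xi <- geno[, i]
    for (j in (i + 1L):nS) {
      xj <- geno[, j]
      ok <- !is.na(xi) & !is.na(xj)
      m <- sum(ok)
      if (m < 4L) { skipped <- skipped + 1L; next }
      a <- xi[ok]; b <- xj[ok]
      if (sum(a) %in% c(0L, m) || sum(b) %in% c(0L, m)) {
        skipped <- skipped + 1L
        next
      }
      counts <- c(
        sum(a == 1 & b == 1), sum(a == 1 & b == 0),
        sum(a == 0 & b == 1), sum(a == 0 & b == 0)
      )
      code <- canonicalConfigCode(.projectConfig(counts, lookup@n), lookup@n)
      row <- match(code, lookup@configCode)
      ll <- if (is.na(row)) floorLL else lookup@logLik[row, ]
      pairRows[[length(pairRows) + 1L]] <- ll
      pairDist <- c(pairDist, abs(pos[j] - pos[i]))
    }
  }
  if (length(pairRows) < 1L) return(notComputed(nS, skipped))
  P <- do.call(rbind, pairRows)
  grid <- lookup@rhoGrid
  dkb <- pairDist / 1000
  npair <- nrow(P)
  profile <- vapply(candidates, function(cand) {
    rho_ij <- pmin(max(grid), pmax(min(grid), cand * dkb))
    idx <- findInterval(rho_ij, grid, all.inside = TRUE)
    w <- (rho_ij - grid[idx]) / (grid[idx + 1L] - grid[idx])
    sum((1 - w) * P[cbind(seq_len(npair), idx)] +
      w * P[cbind(seq_len(npair), idx + 1L)])
  }, 1)
  best <- which.max(profile) # which.max returns the first (smallest) tie
  far <- if (best - 1L >= length(candidates) - best) 1L else length(candidates)
  flat <- (profile[best] - profile[far]) < 2
  rho_kb <- candidates[best]
  list(
    locus_id = locusId(aln), computed = TRUE,
    rho_per_kb = rho_kb, rho_per_site = rho_kb / 1000,
    rho_locus = rho_kb / 1000 * ampliconLength(aln),
    profile = data.frame(
      rho_per_kb = candidates,
      log_composite_likelihood = profile
    ),
    flat_likelihood = flat,
    n_snps = nS, n_pairs_used = npair, n_pairs_skipped = skipped
  )
}

#' Ratio of recombination to mutation, rho/theta
#'
#' Quotient of the per-site composite-likelihood recombination rate and
#' per-site Watterson's theta from the same data. Undefined (NA, with
#' `defined = FALSE`) when theta is zero or either input was not computed.
#'
#' @param estimate result of [estimateRho()], or a per-site rho value.
#' @param thetaW per-site Watterson's theta, or a locus summary row (a
#'   one-row data.frame with a `theta_w` column, as produced by
#'   [summarizeLocus()]).
#' @return List with `rho_over_theta` and `defined`.
#' @export
rhoOverTheta <- function(estimate, thetaW) {
  rho <- if (is.list(estimate) && !is.data.frame(estimate)) {
    if (!isTRUE(estimate$computed)) NA_real_ else estimate$rho_per_site
  } else {
    as.numeric(estimate)
  }
  th <- if (is.data.frame(thetaW)) {
    stopifnot(nrow(thetaW) == 1L, "theta_w" %in% names(thetaW))
    thetaW$theta_w
  } else {
    as.numeric(thetaW)
  }
  if (is.na(rho) || is.na(th) || th <= 0) {
    return(list(rho_over_theta = NA_real_, defined = FALSE))
  }
  list(rho_over_theta = rho / th, defined = TRUE)
}
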