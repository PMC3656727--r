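#' Classify alignment columns
#'
#' Classifies every column of a haploid alignment into one of
#' `indel_column` (any retained sequence carries `-`: indels are excluded
#' wholesale from all analyses), `multiallelic` (three or more bases among
#' called sequences; excluded), `biallelic_snp`, or `monomorphic`.
#' Biallelic SNPs are flagged `is_singleton` (minor allele count 1) or
#' `is_parsimony_informative` (both allele counts >= 2). `N` is missing
#' data, not an indel.
#'
#' The `analyzed` flag encodes the missing-data policy:
#' * `complete_deletion` - a column enters the analysis only if it is not
#'   excluded and every sequence is called there (DnaSP-style restricted
#'   data set);
#' * `pairwise_available` - a column enters if it is not excluded and at
#'   least two sequences are called; per-site sample sizes (`n_called`)
#'   then differ across columns.
#'
#' @param aln a [LocusAlignment-class].
#' @param missingPolicy `"complete_deletion"` (default, used for diversity
#'   statistics) or `"pairwise_available"` (default for LD).
#' @return A [SiteTable-class]. Allele columns `allele1`/`allele2` hold the
#'   major/minor base of biallelic SNPs (alphabetic tie-break), with counts
#'   `count1` >= `count2`.
#' @examples
#' aln <- LocusAlignment("demo", c(a = "AAG", b = "AAG", c = "ACG"))
#' siteData(classifySites(aln))
#' @export
classifySites <- function(aln,
                          missingPolicy = c("complete_deletion", "pairwise_available")) {
  missingPolicy <- match.arg(missingPolicy)
  m <- alignmentMatrix(aln)
  n <- nrow(m)
  L <- ncol(m)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(
    bases,
    function(b) .colSums(m == b, n, L),
    numeric(L)
  )
  if (L == 1L) counts <- matrix(counts, nrow = 1L, dimnames = list(NULL, bases))
  gap <- .colSums(m == "-", n, L) > 0L
  n_called <- as.integer(rowSums(counts))
  n_alleles <- as.integer(rowSums(counts > 0L))

  klass <- rep("monomorphic", L)
  klass[n_alleles == 2L] <- "biallelic_snp"
  klass[n_alleles > 2L] <- "multiallelic"
  klass[gap] <- "indel_column"

  allele1 <- allele2 <- rep(NA_character_, L)
  count1 <- count2 <- rep(NA_integer_, L)
  bi <- which(klass == "biallelic_snp")
  if (length(bi)) {
    for (j in bi) {
      present <- which(counts[j, ] > 0L)
      cts <- counts[j, present]
      # major first; alphabetic tie-break keeps coding deterministic
      ord <- order(-cts, bases[present])
      allele1[j] <- bases[present][ord[1L]]
      allele2[j] <- bases[present][ord[2L]]
      count1[j] <- as.integer(cts[ord[1L]])
      count2[j] <- as.integer(cts[ord[2L]])
    }
  }
  is_singleton <- klass == "biallelic_snp" & !is.na(count2) & count2 == 1L
  is_informative <- klass == "biallelic_snp" & !is.na(count2) & count2 >= 2L

  excluded <- klass %in% c("multiallelic", "indel_column")
  analyzed <- !excluded & if (missingPolicy == "complete_deletion") {
    n_called == n
  } else {
    n_called >= 2L
  }

  sites <- data.frame(
    position = seq_len(L),
    n_called = n_called,
    klass = klass,
    allele1 = allele1, allele2 = allele2,
    count1 = count1, count2 = count2,
    is_singleton = is_singleton,
    is_parsimony_informative = is_informative,
    excluded = excluded,
    analyzed = analyzed,
    stringsAsFactors = FALSE
  )
  new("SiteTable",
    locusId = locusId(aln), sites = sites,
    policy = missingPolicy, nSeq = n
  )
}

#' Minimum minor allele frequency of a parsimony-informative site
#'
#' A parsimony-informative biallelic site needs both alleles in at least
#' two sequences, so its minor allele frequency is at least 2/n. Restricting
#' LD analyses to informative sites therefore imposes this MAF floor, which
#' rises as samples get smaller (0.02 at n = 97 vs 0.125 at n = 16) and
#' inflates within-population r2 relative to pooled estimates.
#'
#' @param n haploid sample size (>= 4 for an informative site to exist).
#' @return `2 / n`.
#' @export
minInformativeMaf <- function(n) {
  stopifnot(all(n >= 4))
  2 / n
}
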