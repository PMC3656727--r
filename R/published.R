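.extdata <- function(file) {
  path <- system.file("extdata", file, package = "haploLD")
  if (!nzchar(path)) stop("bundled table not found: ", file)
  read.table(path,
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    na.strings = "NA"
  )
}

#' Sampling design of the reference Norway spruce study
#'
#' Ten Scandinavian populations sampled along a latitudinal gradient
#' (58-67 degrees N): seven populations of 8 haploid megagametophyte
#' sequences and three densely sampled populations of 24, 128 individuals
#' in total.
#'
#' @return data.frame with columns `population_id`, `name`, `latitude`,
#'   `longitude`, `n_sampled`.
#' @export
studyDesignTable <- function() {
  .extdata("study_design.tsv")
}

#' Reference per-locus diversity summary
#'
#' Published diversity summary for 11 nuclear loci in the pooled Norway
#' spruce dataset: sample size, amplicon and sequenced lengths, site
#' counts, haplotype statistics, Watterson's theta and pi (both x 1000)
#' and Tajima's D. Useful as an arithmetic reference for report-shaped
#' outputs and for checking survey-level bookkeeping (e.g. column sums of
#' segregating sites and singletons).
#'
#' @return data.frame, one row per locus.
#' @export
publishedLocusSummary <- function() {
  .extdata("locus_summary.tsv")
}

#' Reference per-locus LD and recombination summary
#'
#' Published within-locus linkage disequilibrium and recombination
#' summary on the pooled dataset: parsimony-informative site counts,
#' pairwise comparisons, percent significant after Bonferroni-corrected
#' Fisher tests, mean r2, the distance at which fitted r2 falls below 0.2,
#' and composite-likelihood recombination rates (per locus, per site, and
#' relative to theta). The `all_loci` row is the pooled summary; the
#' locus with only 6 pairwise comparisons carries NA for mean r2 (too few
#' pairs).
#'
#' @return data.frame, one row per locus plus an `all_loci` row.
#' @export
publishedLdSummary <- function() {
  .extdata("ld_summary.tsv")
}
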