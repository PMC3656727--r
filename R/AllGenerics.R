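#' @import methods
#' @importFrom stats dhyper optimize rexp runif rbinom rpois setNames
#'   complete.cases cor pbeta
#' @importFrom utils read.table write.table head
#' @importFrom Rcpp sourceCpp
#' @useDynLib haploLD, .registration = TRUE
NULL

#' Locus identifier of an object
#'
#' @param x a [LocusAlignment-class] or [SiteTable-class] object.
#' @return A character scalar.
#' @export
setGeneric("locusId", function(x) standardGeneric("locusId"))

#' Aligned sequences of a locus
#'
#' @param x a [LocusAlignment-class] object.
#' @return A named [Biostrings::DNAStringSet] (one entry per individual).
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' Amplicon length in base pairs
#'
#' @param x a [LocusAlignment-class] object.
#' @return Integer scalar: the full amplicon span the alignment represents.
#' @export
setGeneric("ampliconLength", function(x) standardGeneric("ampliconLength"))

#' Sequenced intervals of an amplicon
#'
#' Paired-end Sanger designs sequence only the ends of each amplified
#' fragment; the interior is unsequenced. These intervals record which
#' alignment columns were actually read.
#'
#' @param x a [LocusAlignment-class] object.
#' @return An [IRanges::IRanges] of 1-based inclusive intervals.
#' @export
setGeneric("sequencedSegments", function(x) standardGeneric("sequencedSegments"))

#' Number of sequences (haploid individuals) in an alignment
#'
#' @param x a [LocusAlignment-class] object.
#' @return Integer scalar.
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' Individual-to-population assignments
#'
#' @param x a [PopulationMap-class] object.
#' @return A data.frame with columns `individual_id`, `population_id`.
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' Population metadata table
#'
#' @param x a [PopulationMap-class] object.
#' @return A data.frame with columns `population_id`, `name`, `latitude`,
#'   `longitude`, `n_sampled`.
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' Per-site classification table
#'
#' @param x a [SiteTable-class] object.
#' @return A data.frame with one row per alignment column.
#' @export
setGeneric("siteData", function(x) standardGeneric("siteData"))

#' Missing-data policy used to build an object
#'
#' @param x a [SiteTable-class] object.
#' @return `"complete_deletion"` or `"pairwise_available"`.
#' @export
setGeneric("missingPolicy", function(x) standardGeneric("missingPolicy"))

#' Pair-level linkage disequilibrium table
#'
#' @param x an [LDPairSet-class] object.
#' @return A data.frame with one row per within-locus site pair.
#' @export
setGeneric("ldPairs", function(x) standardGeneric("ldPairs"))
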