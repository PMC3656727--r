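#' LocusAlignment: a haploid multiple sequence alignment for one locus
#'
#' Container for the aligned haploid sequences of a single amplified locus.
#' Each record is one individual (in conifers, one megagametophyte, so
#' sequences are naturally phased). The alignment alphabet is
#' `A`, `C`, `G`, `T`, `N` (missing) and `-` (alignment gap). The amplicon
#' may be longer than the part actually sequenced; `sequencedSegments`
#' records the 1-based inclusive intervals covered by reads (ends-only
#' paired-end Sanger designs leave an internal unsequenced gap, which is
#' represented as `N` in all individuals).
#'
#' @slot locusId character scalar, the locus (gene) name.
#' @slot seqs named [Biostrings::DNAStringSet]; all entries equal width,
#'   names are unique individual identifiers.
#' @slot ampliconLength integer scalar, full amplicon span in bp
#'   (>= alignment width).
#' @slot sequencedSegments [IRanges::IRanges] of non-overlapping intervals
#'   within `[1, width]`.
#'
#' @seealso [readLocusAlignment()], [classifySites()], [subsetAlignment()]
#' @export
setClass("LocusAlignment",
  slots = c(
    locusId = "character",
    seqs = "DNAStringSet",
    ampliconLength = "integer",
    sequencedSegments = "IRanges"
  )
)

setValidity("LocusAlignment", function(object) {
  msg <- character()
  if (length(object@locusId) != 1L || is.na(object@locusId) || !nzchar(object@locusId)) {
    msg <- c(msg, "locusId must be a single non-empty string")
  }
  if (length(object@seqs) == 0L) {
    msg <- c(msg, "alignment contains no sequences")
  } else {
    w <- Biostrings::width(object@seqs)
    if (length(unique(w)) != 1L) {
      msg <- c(msg, "all sequences must have equal length")
    }
    nm <- names(object@seqs)
    if (is.null(nm) || anyNA(nm) || any(!nzchar(nm))) {
      msg <- c(msg, "every sequence must carry an individual_id name")
    } else if (anyDuplicated(nm)) {
      msg <- c(msg, "individual_id names must be unique within a locus")
    }
    if (length(object@ampliconLength) != 1L || is.na(object@ampliconLength) ||
        object@ampliconLength < w[1L]) {
      msg <- c(msg, "ampliconLength must be a single integer >= alignment width")
    }
    if (length(object@sequencedSegments) > 0L) {
      if (min(IRanges::start(object@sequencedSegments)) < 1L ||
          max(IRanges::end(object@sequencedSegments)) > w[1L]) {
        msg <- c(msg, "sequencedSegments must lie within [1, alignment width]")
      }
      if (!isDisjoint(object@sequencedSegments)) {
        msg <- c(msg, "sequencedSegments must be non-overlapping")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @importFrom IRanges isDisjoint
NULL

#' Construct a LocusAlignment
#'
#' @param locusId character scalar locus name.
#' @param sequences a named [Biostrings::DNAStringSet] or a named character
#'   vector of equal-length strings over `A,C,G,T,N,-`.
#' @param ampliconLength full amplicon length in bp; defaults to the
#'   alignment width.
#' @param sequencedSegments an [IRanges::IRanges] (or two-column matrix of
#'   start/end) of sequenced intervals; defaults to the whole alignment.
#' @return A [LocusAlignment-class] object.
#' @examples
#' aln <- LocusAlignment("locusA",
#'   c(ind1 = "ACGTACGTAC", ind2 = "ACGTACGTAC", ind3 = "ACCTACGTAC"))
#' nSequences(aln)
#' @export
LocusAlignment <- function(locusId, sequences, ampliconLength = NULL,
                           sequencedSegments = NULL) {
  if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  w <- if (length(sequences)) Biostrings::width(sequences)[1L] else 0L
  if (is.null(ampliconLength)) ampliconLength <- w
  if (is.null(sequencedSegments)) {
    sequencedSegments <- IRanges::IRanges(start = 1L, end = w)
  } else if (is.matrix(sequencedSegments)) {
    sequencedSegments <- IRanges::IRanges(
      start = as.integer(sequencedSegments[, 1L]),
      end = as.integer(sequencedSegments[, 2L])
    )
  }
  new("LocusAlignment",
    locusId = as.character(locusId), seqs = sequences,
    ampliconLength = as.integer(ampliconLength),
    sequencedSegments = sequencedSegments
  )
}

#' @rdname locusId
#' @export
setMethod("locusId", "LocusAlignment", function(x) x@locusId)

#' @rdname sequences
#' @export
setMethod("sequences", "LocusAlignment", function(x) x@seqs)

#' @rdname ampliconLength
#' @export
setMethod("ampliconLength", "LocusAlignment", function(x) x@ampliconLength)

#' @rdname sequencedSegments
#' @export
setMethod("sequencedSegments", "LocusAlignment", function(x) x@sequencedSegments)

#' @rdname nSequences
#' @export
setMethod("nSequences", "LocusAlignment", function(x) length(x@seqs))

setMethod("show", "LocusAlignment", function(object) {
  w <- if (length(object@seqs)) Biostrings::width(object@seqs)[1L] else 0L
  cat("LocusAlignment '", object@locusId, "': ", length(object@seqs),
    " haploid sequences x ", w, " bp (amplicon ", object@ampliconLength,
    " bp, ", sum(IRanges::width(object@sequencedSegments)),
    " bp in sequenced segments)\n",
    sep = ""
  )
})

#' PopulationMap: individual-to-population assignments with metadata
#'
#' @slot assign data.frame with columns `individual_id`, `population_id`.
#' @slot pops data.frame with columns `population_id`, `name`, `latitude`,
#'   `longitude`, `n_sampled`.
#' @seealso [readPopulationMap()]
#' @export
setClass("PopulationMap",
  slots = c(assign = "data.frame", pops = "data.frame")
)

setValidity("PopulationMap", function(object) {
  msg <- character()
  need_a <- c("individual_id", "population_id")
  need_p <- c("population_id", "name", "latitude", "longitude", "n_sampled")
  if (!all(need_a %in% names(object@assign))) {
    msg <- c(msg, "assignments need columns individual_id, population_id")
  } else {
    if (anyDuplicated(object@assign$individual_id)) {
      msg <- c(msg, "each individual maps to exactly one population")
    }
  }
  if (!all(need_p %in% names(object@pops))) {
    msg <- c(msg, paste("populations need columns", paste(need_p, collapse = ", ")))
  } else if (all(need_a %in% names(object@assign))) {
    if (!all(object@assign$population_id %in% object@pops$population_id)) {
      msg <- c(msg, "every assigned population_id must appear in the population table")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PopulationMap
#'
#' @param assignments data.frame (`individual_id`, `population_id`).
#' @param populations optional data.frame (`population_id`, `name`,
#'   `latitude`, `longitude`, `n_sampled`); derived from `assignments`
#'   (with NA coordinates) when omitted.
#' @return A [PopulationMap-class].
#' @export
PopulationMap <- function(assignments, populations = NULL) {
  assignments <- as.data.frame(assignments)
  assignments$individual_id <- as.character(assignments$individual_id)
  assignments$population_id <- as.character(assignments$population_id)
  if (is.null(populations)) {
    tab <- table(assignments$population_id)
    populations <- data.frame(
      population_id = names(tab), name = names(tab),
      latitude = NA_real_, longitude = NA_real_,
      n_sampled = as.integer(tab), stringsAsFactors = FALSE
    )
  }
  populations <- as.data.frame(populations)
  populations$population_id <- as.character(populations$population_id)
  new("PopulationMap", assign = assignments, pops = populations)
}

#' @rdname assignments
#' @export
setMethod("assignments", "PopulationMap", function(x) x@assign)

#' @rdname populations
#' @export
setMethod("populations", "PopulationMap", function(x) x@pops)

setMethod("show", "PopulationMap", function(object) {
  cat("PopulationMap: ", nrow(object@assign), " individuals in ",
    nrow(object@pops), " populations\n",
    sep = ""
  )
})

#' Population of given individuals
#'
#' @param popmap a [PopulationMap-class].
#' @param individuals character vector of individual ids.
#' @return Character vector of population ids (error on unknown individuals).
#' @export
populationOf <- function(popmap, individuals) {
  a <- assignments(popmap)
  idx <- match(individuals, a$individual_id)
  if (anyNA(idx)) {
    stop(
      "individuals absent from population map: ",
      paste(individuals[is.na(idx)], collapse = ", ")
    )
  }
  a$population_id[idx]
}

#' SiteTable: classified alignment columns for one locus
#'
#' One row per alignment column, with the observed allele counts, the
#' number of called (non-missing, non-gap) sequences, the column class
#' (`monomorphic`, `biallelic_snp`, `multiallelic`, `indel_column`),
#' singleton / parsimony-informative flags, and an `analyzed` flag derived
#' from the missing-data policy. Indel columns and multiallelic sites are
#' always excluded from analysis; under `complete_deletion` any column with
#' a missing base among the retained individuals is excluded too.
#'
#' @slot locusId character scalar.
#' @slot sites data.frame, one row per column (see [classifySites()]).
#' @slot policy missing-data policy the `analyzed` flag encodes.
#' @slot nSeq number of sequences classified.
#' @seealso [classifySites()]
#' @export
setClass("SiteTable",
  slots = c(
    locusId = "character",
    sites = "data.frame",
    policy = "character",
    nSeq = "integer"
  )
)

setValidity("SiteTable", function(object) {
  msg <- character()
  need <- c(
    "position", "n_called", "klass", "allele1", "allele2",
    "count1", "count2", "is_singleton", "is_parsimony_informative",
    "excluded", "analyzed"
  )
  if (!all(need %in% names(object@sites))) {
    msg <- c(msg, paste("sites table needs columns", paste(need, collapse = ", ")))
  } else {
    ok_klass <- c("monomorphic", "biallelic_snp", "multiallelic", "indel_column")
    if (!all(object@sites$klass %in% ok_klass)) {
      msg <- c(msg, "invalid site klass value")
    }
    bi <- object@sites$klass == "biallelic_snp"
    if (any(object@sites$is_singleton & !bi)) {
      msg <- c(msg, "is_singleton implies biallelic_snp")
    }
    if (any(object@sites$is_parsimony_informative & !bi)) {
      msg <- c(msg, "is_parsimony_informative implies biallelic_snp")
    }
  }
  if (!object@policy %in% c("complete_deletion", "pairwise_available")) {
    msg <- c(msg, "policy must be complete_deletion or pairwise_available")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname locusId
#' @export
setMethod("locusId", "SiteTable", function(x) x@locusId)

#' @rdname siteData
#' @export
setMethod("siteData", "SiteTable", function(x) x@sites)

#' @rdname missingPolicy
#' @export
setMethod("missingPolicy", "SiteTable", function(x) x@policy)

setMethod("show", "SiteTable", function(object) {
  s <- object@sites
  cat("SiteTable '", object@locusId, "' (", object@policy, "): ",
    nrow(s), " columns; ",
    sum(s$klass == "biallelic_snp" & s$analyzed), " analyzed biallelic SNPs (",
    sum(s$is_singleton & s$analyzed), " singletons, ",
    sum(s$is_parsimony_informative & s$analyzed), " parsimony-informative), ",
    sum(s$klass == "multiallelic"), " multiallelic, ",
    sum(s$klass == "indel_column"), " indel columns excluded\n",
    sep = ""
  )
})

#' LDPairSet: within-locus pairwise linkage disequilibrium results
#'
#' @slot pairs data.frame with one row per tested site pair: `locus_id`,
#'   `population_id` (NA when pooled), `pos_i`, `pos_j`, `distance_bp`,
#'   haplotype counts `n11`,`n12`,`n21`,`n22`, `r2`, `dprime`, `p_value`,
#'   `significant`, per-site missing counts `miss_i`,`miss_j`.
#' @slot dropped data.frame of pairs excluded before testing, with reasons.
#' @slot correctionScope `"global"` or `"per_locus"` Bonferroni scope.
#' @slot alpha family-wise significance level (default 0.05).
#' @seealso [buildLdPairs()], [pruneLinkedSnps()]
#' @export
setClass("LDPairSet",
  slots = c(
    pairs = "data.frame",
    dropped = "data.frame",
    correctionScope = "character",
    alpha = "numeric"
  )
)

#' @rdname ldPairs
#' @export
setMethod("ldPairs", "LDPairSet", function(x) x@pairs)

setMethod("show", "LDPairSet", function(object) {
  p <- object@pairs
  cat("LDPairSet: ", nrow(p), " pairs (", sum(p$significant),
    " significant, Bonferroni scope '", object@correctionScope,
    "', alpha = ", object@alpha, "); mean r2 = ",
    if (nrow(p)) round(mean(p$r2), 4) else NA, "\n",
    sep = ""
  )
})

#' LookupTable: Monte Carlo two-locus composite-likelihood lookup
#'
#' Log-likelihoods of 2x2 haplotype configurations at a grid of two-locus
#' scaled recombination rates, tabulated by coalescent simulation for a
#' fixed haploid sample size, in the small-theta (one mutation per site)
#' conditional limit. Configurations are stored under a canonical code
#' that folds allele relabelling at either site and site exchange.
#'
#' @slot n haploid sample size the table was built for.
#' @slot thetaPerSite nominal per-site theta the table mirrors (the
#'   conditional configuration distribution is computed in the small-theta
#'   limit, an excellent approximation at theta = 0.001).
#' @slot rhoGrid increasing nonnegative two-locus rho values, starting at 0.
#' @slot configCode integer canonical configuration codes (rows of logLik).
#' @slot logLik matrix of smoothed log-likelihoods, configurations x grid.
#' @slot nDraws total configuration draws tabulated per grid point.
#' @slot seed integer seed the table was built under.
#' @seealso [buildLookup()], [estimateRho()]
#' @export
setClass("LookupTable",
  slots = c(
    n = "integer", thetaPerSite = "numeric", rhoGrid = "numeric",
    configCode = "integer", logLik = "matrix", nDraws = "integer",
    seed = "integer"
  )
)

setValidity("LookupTable", function(object) {
  msg <- character()
  if (length(object@rhoGrid) < 2L || object@rhoGrid[1L] != 0 ||
      is.unsorted(object@rhoGrid, strictly = TRUE)) {
    msg <- c(msg, "rhoGrid must be strictly increasing and start at 0")
  }
  if (nrow(object@logLik) != length(object@configCode) ||
      ncol(object@logLik) != length(object@rhoGrid)) {
    msg <- c(msg, "logLik must be configurations x grid")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "LookupTable", function(object) {
  cat("LookupTable: n = ", object@n, ", theta/site = ", object@thetaPerSite,
    ", rho grid [", min(object@rhoGrid), ", ", max(object@rhoGrid), "] x ",
    length(object@rhoGrid), " points, ", length(object@configCode),
    " configurations (", object@nDraws, " draws/point, seed ",
    object@seed, ")\n",
    sep = ""
  )
})

#' DecayFit: fitted LD-decay curve
#'
#' Result of fitting either the Hill-Weir drift expectation of r2 against
#' physical distance (parameter: rho per bp) or the D'(t) = (1-r)^t decay
#' (parameter: t, generations since complete disequilibrium).
#'
#' @slot model `"hill_weir_r2"` or `"dprime_generations"`.
#' @slot param fitted nonnegative parameter (rho per bp, or t generations).
#' @slot n sample size entering the Hill-Weir expectation (NA for D').
#' @slot mapScale cM per Mb assumed when converting distance to
#'   recombination fraction (D' model; default 1).
#' @slot mapping `"linear"` or `"haldane"` distance-to-r mapping (D' model).
#' @slot rss residual sum of squares at the fitted parameter.
#' @slot nPairs number of pairs entering the fit.
#' @slot illConditioned TRUE when the design was degenerate (e.g. all
#'   distances equal) and the fit is returned with a warning.
#' @seealso [fitHillWeir()], [fitDprimeDecay()], [crossingDistance()]
#' @export
setClass("DecayFit",
  slots = c(
    model = "character", param = "numeric", n = "numeric",
    mapScale = "numeric", mapping = "character", rss = "numeric",
    nPairs = "integer", illConditioned = "logical"
  )
)

setMethod("show", "DecayFit", function(object) {
  lab <- if (object@model == "hill_weir_r2") "rho/bp" else "t (generations)"
  cat("DecayFit [", object@model, "]: ", lab, " = ",
    signif(object@param, 6), " (n = ", object@n, ", ", object@nPairs,
    " pairs, RSS = ", signif(object@rss, 6), ")\n",
    sep = ""
  )
})

#' SimTruth: generating parameters of a synthetic locus
#'
#' Records everything needed to reproduce a simulated locus and to test
#' parameter recovery: mutation and recombination rates, demography,
#' sampling design and the paired-end masking layout.
#'
#' @slot locusId character scalar.
#' @slot thetaPerSite per-site theta = 4*Ne*mu.
#' @slot rhoPerSite per-site rho = 4*Ne*r.
#' @slot locusLength locus length in bp.
#' @slot growthRate exponential growth rate (coalescent units of 2*Ne
#'   generations; 0 = constant size). May be one value per population when
#'   migration is 0.
#' @slot migrationRate scaled symmetric island migration rate 4*Ne*m
#'   (0 with one population).
#' @slot samplesPerPopulation integer vector of haploid sample sizes.
#' @slot maskLayout [IRanges::IRanges] of sequenced intervals.
#' @slot readJitter fraction by which individual read ends are randomly
#'   shortened (emulates per-individual read-length variation).
#' @slot seed integer seed.
#' @export
setClass("SimTruth",
  slots = c(
    locusId = "character", thetaPerSite = "numeric", rhoPerSite = "numeric",
    locusLength = "integer", growthRate = "numeric", migrationRate = "numeric",
    samplesPerPopulation = "integer", maskLayout = "IRanges",
    readJitter = "numeric", seed = "integer"
  )
)

setValidity("SimTruth", function(object) {
  msg <- character()
  if (object@thetaPerSite < 0 || object@rhoPerSite < 0 ||
      object@migrationRate < 0) {
    msg <- c(msg, "rates must be nonnegative")
  }
  if (any(object@growthRate < 0)) msg <- c(msg, "growthRate must be >= 0")
  npop <- length(object@samplesPerPopulation)
  if (sum(object@samplesPerPopulation) < 2L) {
    msg <- c(msg, "total sample size must be >= 2")
  }
  if (npop == 1L && object@migrationRate > 0) {
    msg <- c(msg, "migration with a single population is contradictory")
  }
  if (!length(object@growthRate) %in% c(1L, npop)) {
    msg <- c(msg, "growthRate must be scalar or one value per population")
  }
  if (length(object@growthRate) == npop && npop > 1L &&
      length(unique(object@growthRate)) > 1L && object@migrationRate > 0) {
    msg <- c(msg, "population-specific growth requires migrationRate = 0")
  }
  if (length(object@maskLayout) > 0L &&
      (min(IRanges::start(object@maskLayout)) < 1L ||
        max(IRanges::end(object@maskLayout)) > object@locusLength)) {
    msg <- c(msg, "mask intervals must lie within the locus")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth '", object@locusId, "': L = ", object@locusLength,
    " bp, theta/site = ", object@thetaPerSite, ", rho/site = ",
    object@rhoPerSite, ", growth = ",
    paste(object@growthRate, collapse = "/"), ", 4Nm = ",
    object@migrationRate, ", samples = ",
    paste(object@samplesPerPopulation, collapse = "+"),
    ", seed ", object@seed, "\n",
    sep = ""
  )
})
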