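#' Read a per-locus haploid alignment from multi-FASTA
#'
#' Reads one locus worth of aligned haploid sequences. Characters are
#' uppercased on load; IUPAC ambiguity codes other than `N` are mapped to
#' `N` (missing) with a warning, since base-quality filtering happens
#' upstream and residual ambiguity is treated conservatively as missing
#' data. Gaps (`-`) are kept and later force whole-column exclusion (indels
#' are excluded from all analyses).
#'
#' @param path multi-FASTA file, all records of equal length.
#' @param locusId locus name; defaults to the file name without extension.
#' @param ampliconLength,sequencedSegments see [LocusAlignment()].
#' @return A [LocusAlignment-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">i1", "ACGTACGTAC", ">i2", "acgtacgtac"), fa)
#' readLocusAlignment(fa, "demo")
#' @export
readLocusAlignment <- function(path, locusId = NULL, ampliconLength = NULL,
                               sequencedSegments = NULL) {
  if (is.null(locusId)) {
    locusId <- sub("\\.(fa|fasta|fas|txt)$", "", basename(path), ignore.case = TRUE)
  }
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty alignment file: ", path)
  chars <- toupper(as.character(raw))
  w <- nchar(chars)
  if (length(unique(w)) != 1L) {
    stop(
      "alignment records have unequal lengths in ", path, ": ",
      paste(unique(w), collapse = ", ")
    )
  }
  bad <- gsub("[ACGTN-]", "", chars)
  n_amb <- sum(nchar(bad))
  if (n_amb > 0L) {
    warning(
      n_amb, " ambiguity code(s) other than N in '", locusId,
      "' mapped to N"
    )
    chars <- vapply(chars, function(s) gsub("[^ACGTN-]", "N", s), "",
      USE.NAMES = FALSE
    )
  }
  names(chars) <- names(raw)
  LocusAlignment(locusId, Biostrings::DNAStringSet(chars),
    ampliconLength = ampliconLength, sequencedSegments = sequencedSegments
  )
}

#' Write a LocusAlignment to multi-FASTA
#'
#' @param aln a [LocusAlignment-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeLocusAlignment <- function(aln, path) {
  Biostrings::writeXStringSet(sequences(aln), path, width = 80L)
  invisible(path)
}

#' Subset an alignment to selected individuals
#'
#' @param aln a [LocusAlignment-class].
#' @param individuals character vector of individual ids (order kept).
#' @return A [LocusAlignment-class] with the same coordinates and segments.
#' @export
subsetAlignment <- function(aln, individuals) {
  s <- sequences(aln)
  miss <- setdiff(individuals, names(s))
  if (length(miss)) {
    stop("individuals not in alignment: ", paste(miss, collapse = ", "))
  }
  LocusAlignment(locusId(aln), s[individuals],
    ampliconLength = ampliconLength(aln),
    sequencedSegments = sequencedSegments(aln)
  )
}

#' Character matrix view of an alignment
#'
#' @param aln a [LocusAlignment-class].
#' @return Character matrix, individuals x columns.
#' @keywords internal
alignmentMatrix <- function(aln) {
  s <- as.character(sequences(aln))
  m <- matrix(unlist(strsplit(s, "", fixed = TRUE), use.names = FALSE),
    nrow = length(s), byrow = TRUE
  )
  rownames(m) <- names(sequences(aln))
  m
}

#' Read a population map from TSV
#'
#' The file must carry columns `individual_id`, `population_id` and may
#' carry `name`, `latitude`, `longitude` (decimal degrees). `n_sampled` is
#' derived from the assignment counts.
#'
#' @param path TSV file with a header line.
#' @return A [PopulationMap-class].
#' @export
readPopulationMap <- function(path) {
  d <- read.table(path,
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    colClasses = "character"
  )
  need <- c("individual_id", "population_id")
  if (!all(need %in% names(d))) {
    stop("population map must have columns individual_id, population_id")
  }
  tab <- table(d$population_id)
  pops <- data.frame(
    population_id = names(tab), stringsAsFactors = FALSE
  )
  for (col in c("name", "latitude", "longitude")) {
    if (col %in% names(d)) {
      pops[[col]] <- d[[col]][match(pops$population_id, d$population_id)]
    } else {
      pops[[col]] <- NA
    }
  }
  pops$latitude <- suppressWarnings(as.numeric(pops$latitude))
  pops$longitude <- suppressWarnings(as.numeric(pops$longitude))
  pops$name[is.na(pops$name)] <- pops$population_id[is.na(pops$name)]
  pops$n_sampled <- as.integer(tab[pops$population_id])
  PopulationMap(d[, c("individual_id", "population_id")], pops)
}

#' Write a population map to TSV
#'
#' @param popmap a [PopulationMap-class].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writePopulationMap <- function(popmap, path) {
  a <- assignments(popmap)
  p <- populations(popmap)
  idx <- match(a$population_id, p$population_id)
  out <- data.frame(
    individual_id = a$individual_id,
    population_id = a$population_id,
    name = p$name[idx],
    latitude = p$latitude[idx],
    longitude = p$longitude[idx],
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a site table to TSV
#'
#' @param sites a [SiteTable-class].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeSiteTable <- function(sites, path) {
  d <- siteData(sites)
  d <- cbind(locus_id = locusId(sites), d, stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' 0/1 allele matrix over biallelic SNPs
#'
#' Codes each analyzed biallelic SNP as 0 (major allele; alphabetic
#' tie-break) / 1 (minor allele) / NA (missing or gap).
#'
#' @param aln a [LocusAlignment-class].
#' @param sites the matching [SiteTable-class].
#' @param informativeOnly keep only parsimony-informative SNPs.
#' @return Integer matrix individuals x SNPs; column names are positions.
#' @export
alleleMatrix <- function(aln, sites, informativeOnly = FALSE) {
  st <- siteData(sites)
  keep <- st$klass == "biallelic_snp" & st$analyzed
  if (informativeOnly) keep <- keep & st$is_parsimony_informative
  st <- st[keep, , drop = FALSE]
  m <- alignmentMatrix(aln)
  out <- matrix(NA_integer_,
    nrow = nrow(m), ncol = nrow(st),
    dimnames = list(rownames(m), as.character(st$position))
  )
  for (j in seq_len(nrow(st))) {
    col <- m[, st$position[j]]
    out[col == st$allele1[j], j] <- 0L
    out[col == st$allele2[j], j] <- 1L
  }
  out
}

#' Write a STRUCTURE input file for haploid data
#'
#' One row per individual: label, integer population code, then one
#' integer-coded allele column per analyzed biallelic SNP across all loci
#' (1 = major allele, 2 = minor allele, -9 = missing). A two-line header
#' records the marker names (`locus:position`) and per-locus origin.
#'
#' @param alignments list of [LocusAlignment-class] objects.
#' @param sites list of matching [SiteTable-class] objects.
#' @param popmap a [PopulationMap-class] covering every individual.
#' @param path output file.
#' @param informativeOnly restrict to parsimony-informative SNPs.
#' @return Invisibly, the marker names written.
#' @export
writeStructureInput <- function(alignments, sites, popmap, path,
                                informativeOnly = FALSE) {
  stopifnot(length(alignments) == length(sites))
  inds <- sort(unique(unlist(lapply(alignments, function(a) names(sequences(a))))))
  pops <- populationOf(popmap, inds)
  popcode <- as.integer(factor(pops, levels = unique(populations(popmap)$population_id)))
  blocks <- list()
  markers <- character()
  for (i in seq_along(alignments)) {
    am <- alleleMatrix(alignments[[i]], sites[[i]], informativeOnly = informativeOnly)
    if (ncol(am) == 0L) next
    full <- matrix(NA_integer_, length(inds), ncol(am),
      dimnames = list(inds, NULL)
    )
    full[rownames(am), ] <- am
    blocks[[length(blocks) + 1L]] <- full
    markers <- c(markers, paste0(locusId(alignments[[i]]), ":", colnames(am)))
  }
  geno <- if (length(blocks)) do.call(cbind, blocks) else matrix(integer(), length(inds), 0L)
  coded <- geno + 1L
  coded[is.na(coded)] <- -9L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(markers, collapse = " "), con)
  for (i in seq_along(inds)) {
    writeLines(
      paste(c(inds[i], popcode[i], coded[i, ]), collapse = " "),
      con
    )
  }
  invisible(markers)
}

#' Write LDhat-style sites and locs files
#'
#' Emits `<prefix>.sites` (header `n S 1`, then FASTA-like 0/1-coded
#' haplotypes with `?` for missing) and `<prefix>.locs` (header
#' `S L_kb L`, then SNP positions in kb) for one locus.
#'
#' @param aln a [LocusAlignment-class].
#' @param sites the matching [SiteTable-class].
#' @param pathPrefix output path prefix.
#' @return Invisibly, the two file paths.
#' @export
writeLdhatInputs <- function(aln, sites, pathPrefix) {
  am <- alleleMatrix(aln, sites)
  if (ncol(am) == 0L) {
    warning("no biallelic SNPs in '", locusId(aln), "': empty LDhat output")
  }
  chr <- matrix("?", nrow(am), ncol(am))
  chr[which(am == 0L)] <- "0"
  chr[which(am == 1L)] <- "1"
  sites_path <- paste0(pathPrefix, ".sites")
  locs_path <- paste0(pathPrefix, ".locs")
  con <- file(sites_path, "w")
  writeLines(paste(nrow(am), ncol(am), 1L), con)
  for (i in seq_len(nrow(am))) {
    writeLines(paste0(">", rownames(am)[i]), con)
    writeLines(paste(chr[i, ], collapse = ""), con)
  }
  close(con)
  pos_kb <- as.numeric(colnames(am)) / 1000
  w <- Biostrings::width(sequences(aln))[1L]
  con <- file(locs_path, "w")
  writeLines(paste(ncol(am), format(w / 1000, nsmall = 3), "L"), con)
  writeLines(paste(sprintf("%.3f", pos_kb), collapse = " "), con)
  close(con)
  invisible(c(sites = sites_path, locs = locs_path))
}
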