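#' Hudson-style global FST per locus
#'
#' `FST = 1 - Hw/Hb`, where `Hw` is the mean within-population pairwise
#' diversity (averaged over populations with at least two sequences at the
#' locus) and `Hb` the mean pairwise diversity between sequences from
#' different populations. Pairwise diversities are per-site rates over the
#' analyzed columns where both sequences are called. Estimates can be
#' slightly negative by sampling noise and are reported as computed;
#' `Hb = 0` yields an undefined (NA) estimate.
#'
#' @param alignments list of [LocusAlignment-class] objects (or one).
#' @param popmap a [PopulationMap-class].
#' @param missingPolicy site policy for [classifySites()]; pairwise
#'   availability is the natural default since distances are pairwise.
#' @return data.frame with one row per locus: `locus_id`, `fst`,
#'   `n_populations`, `within_diversity`, `between_diversity`.
#' @export
globalFst <- function(alignments, popmap,
                      missingPolicy = "pairwise_available") {
  if (is(alignments, "LocusAlignment")) alignments <- list(alignments)
  rows <- lapply(alignments, function(aln) {
    aln <- dropEmptySequences(aln)
    sites <- classifySites(aln, missingPolicy)
    st <- siteData(sites)
    keep <- st$position[st$analyzed]
    m <- alignmentMatrix(aln)[, keep, drop = FALSE]
    code <- matrix(match(m, c("A", "C", "G", "T")), nrow = nrow(m))
    rownames(code) <- rownames(m)
    pops <- populationOf(popmap, rownames(code))
    use_pops <- names(which(table(pops) >= 2L))
    if (length(use_pops) < 2L) {
      stop(
        "globalFst needs >= 2 populations with >= 2 sequences each (locus ",
        locusId(aln), ")"
      )
    }
    sel <- pops %in% use_pops
    code <- code[sel, , drop = FALSE]
    pops <- pops[sel]
    n <- nrow(code)
    # per-pair per-site difference rates
    within <- stats::setNames(vector("list", length(use_pops)), use_pops)
    between <- c()
    for (i in seq_len(n - 1)) {
      xi <- code[i, ]
      for (j in (i + 1):n) {
        xj <- code[j, ]
        ok <- !is.na(xi) & !is.na(xj)
        nok <- sum(ok)
        if (nok == 0L) next
        rate <- sum(xi[ok] != xj[ok]) / nok
        if (pops[i] == pops[j]) {
          within[[pops[i]]] <- c(within[[pops[i]]], rate)
        } else {
          between <- c(between, rate)
        }
      }
    }
    hw <- mean(vapply(within, mean, 1))
    hb <- mean(between)
    fst <- if (is.na(hb) || hb == 0) NA_real_ else 1 - hw / hb
    data.frame(
      locus_id = locusId(aln), fst = fst,
      n_populations = length(use_pops),
      within_diversity = hw, between_diversity = hb,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
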