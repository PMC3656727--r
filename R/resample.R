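.popIndividuals <- function(aln, popmap, populationId) {
  ids <- names(sequences(aln))
  pops <- populationOf(popmap, ids)
  ids[pops == populationId]
}

.replicateStats <- function(aln, ids, alpha = 0.05) {
  sub <- subsetAlignment(aln, ids)
  sub <- dropEmptySequences(sub)
  sites <- classifySites(sub, "complete_deletion")
  dv <- nucleotideDiversity(sites)
  d <- if (dv$S >= 1 && nSequences(sub) >= 4) {
    tajimasD(dv$S, nSequences(sub), dv$pi_total, alpha = alpha)$d
  } else {
    NA_real_
  }
  pi <- if (dv$L > 0) dv$pi else NA_real_
  c(d = d, pi = pi, S = dv$S)
}

#' Subsampling sensitivity of Tajima's D and pi
#'
#' Draws `B` subsamples of `k` individuals without replacement from one
#' population at one locus; each draw re-classifies sites within the
#' subsample (complete deletion; a site segregating in the full sample may
#' be monomorphic in a draw) and recomputes Tajima's D and per-site pi.
#' Replicates with no segregating sites have undefined D and are excluded
#' from the D summary (their count is reported); pi is summarized over all
#' replicates.
#'
#' @param aln a [LocusAlignment-class].
#' @param popmap a [PopulationMap-class].
#' @param populationId population to resample.
#' @param k subsample size (default 8).
#' @param B number of replicates (default 100).
#' @param seed RNG seed, recorded in the output.
#' @return List with `locus_id`, `population_id`, `k`, `B`, `seed`,
#'   per-replicate vectors `d` and `pi`, `mean_d`, `min_d`, `max_d`,
#'   `mean_pi`, `min_pi`, `max_pi`, `n_excluded_d` (replicates with S = 0),
#'   and `full_d`, `full_pi` (full-population estimates).
#' @export
resampleStatistics <- function(aln, popmap, populationId, k = 8L, B = 100L,
                               seed = 1L) {
  stopifnot(is(aln, "LocusAlignment"), is(popmap, "PopulationMap"))
  ids <- .popIndividuals(aln, popmap, populationId)
  if (length(ids) < k) {
    stop(
      "population ", populationId, " has ", length(ids),
      " individuals at locus ", locusId(aln), "; cannot subsample k = ", k
    )
  }
  if (k < 4L) warning("Tajima's D is unstable for subsamples of fewer than 4")
  set.seed(seed)
  draws <- lapply(seq_len(B), function(b) sample(ids, k))
  .resampleFromDraws(aln, popmap, populationId, draws, k, B, seed)
}

.resampleFromDraws <- function(aln, popmap, populationId, draws, k, B, seed) {
  reps <- vapply(draws, function(ids) .replicateStats(aln, ids), c(0, 0, 0))
  d <- reps["d", ]
  pi <- reps["pi", ]
  d_ok <- d[!is.na(d)]
  full <- .replicateStats(aln, .popIndividuals(aln, popmap, populationId))
  list(
    locus_id = locusId(aln), population_id = populationId,
    k = as.integer(k), B = as.integer(B), seed = as.integer(seed),
    d = d, pi = pi,
    mean_d = if (length(d_ok)) mean(d_ok) else NA_real_,
    min_d = if (length(d_ok)) min(d_ok) else NA_real_,
    max_d = if (length(d_ok)) max(d_ok) else NA_real_,
    mean_pi = mean(pi, na.rm = TRUE),
    min_pi = suppressWarnings(min(pi, na.rm = TRUE)),
    max_pi = suppressWarnings(max(pi, na.rm = TRUE)),
    n_excluded_d = sum(is.na(d)),
    full_d = unname(full["d"]), full_pi = unname(full["pi"])
  )
}

#' Resample several loci and populations jointly
#'
#' Runs the subsampling experiment across loci and populations. By default
#' draws are joint: within a replicate the same `k` individuals are used
#' at every locus (one "resampled population" of trees); `joint = FALSE`
#' redraws independently per locus. Populations with fewer than `k`
#' sequenced individuals at a locus are skipped with a message in the
#' returned table (`computed = FALSE`).
#'
#' @param alignments list of [LocusAlignment-class] objects.
#' @param popmap a [PopulationMap-class].
#' @param populationIds populations to resample (default: all populations
#'   with at least `k` assigned individuals).
#' @param k,B,seed as in [resampleStatistics()].
#' @param joint logical; share draws across loci within a replicate.
#' @return data.frame with one row per locus x population: summary columns
#'   of [resampleStatistics()] plus `computed`; per-replicate values are
#'   attached as attribute `"replicates"` (a long data.frame).
#' @export
resampleStudy <- function(alignments, popmap, populationIds = NULL,
                          k = 8L, B = 100L, seed = 1L, joint = TRUE) {
  if (is(alignments, "LocusAlignment")) alignments <- list(alignments)
  if (is.null(populationIds)) {
    tab <- table(assignments(popmap)$population_id)
    populationIds <- names(tab)[tab >= k]
  }
  set.seed(seed)
  # joint draws: one set of individuals per population per replicate,
  # drawn from the individuals assigned to the population (an individual
  # missing entirely from some locus is dropped there by the per-locus
  # empty-sequence filter)
  joint_draws <- NULL
  if (joint) {
    a <- assignments(popmap)
    joint_draws <- lapply(populationIds, function(p) {
      ids <- a$individual_id[a$population_id == p]
      if (length(ids) < k) {
        return(NULL) # skipped below with computed = FALSE
      }
      lapply(seq_len(B), function(b) sample(ids, k))
    })
    names(joint_draws) <- populationIds
  }
  rows <- list()
  longs <- list()
  for (li in seq_along(alignments)) {
    aln <- alignments[[li]]
    for (p in populationIds) {
      ids <- .popIndividuals(aln, popmap, p)
      if (length(ids) < k) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus_id = locusId(aln), population_id = p, k = k, B = B,
          seed = seed, mean_d = NA_real_, min_d = NA_real_,
          max_d = NA_real_, mean_pi = NA_real_, min_pi = NA_real_,
          max_pi = NA_real_, n_excluded_d = NA_integer_,
          full_d = NA_real_, full_pi = NA_real_, computed = FALSE,
          stringsAsFactors = FALSE
        )
        next
      }
      res <- if (joint) {
        draws <- lapply(joint_draws[[p]], function(d) intersect(d, ids))
        if (any(vapply(draws, length, 1L) < k)) {
          # some drawn individuals unavailable at this locus: top up from
          # the remaining sequenced individuals of the population
          draws <- lapply(draws, function(d) {
            need <- k - length(d)
            if (need > 0) c(d, sample(setdiff(ids, d), need)) else d
          })
        }
        .resampleFromDraws(aln, popmap, p, draws, k, B, seed)
      } else {
        # independent mode: a distinct derived seed per locus x population
        resampleStatistics(aln, popmap, p, k = k, B = B,
          seed = seed + (li - 1L) * length(populationIds) +
            match(p, populationIds))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = res$locus_id, population_id = res$population_id,
        k = res$k, B = res$B, seed = res$seed,
        mean_d = res$mean_d, min_d = res$min_d, max_d = res$max_d,
        mean_pi = res$mean_pi, min_pi = res$min_pi, max_pi = res$max_pi,
        n_excluded_d = res$n_excluded_d,
        full_d = res$full_d, full_pi = res$full_pi, computed = TRUE,
        stringsAsFactors = FALSE
      )
      longs[[length(longs) + 1L]] <- data.frame(
        locus_id = res$locus_id, population_id = res$population_id,
        replicate = seq_len(B), d = res$d, pi = res$pi,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- if (length(longs)) do.call(rbind, longs) else NULL
  out
}

#' Mean Tajima's D per population against latitude
#'
#' One row per population with its latitude, the mean full-sample D across
#' loci, and (when a resampling table is supplied) the mean resampled D.
#' With at least 3 populations carrying latitudes, the Spearman rank
#' correlation of mean D with latitude is attached as attribute
#' `"spearman"`.
#'
#' @param summaries per-population locus summaries from
#'   [summarizeLoci()] with `scope = "population"`.
#' @param popmap a [PopulationMap-class] carrying latitudes.
#' @param resampled optional output of [resampleStudy()].
#' @return data.frame with columns `population_id`, `latitude`, `n_loci`,
#'   `mean_d`, and `mean_resampled_d` when available.
#' @export
latitudeTrendTable <- function(summaries, popmap, resampled = NULL) {
  s <- summaries[!is.na(summaries$population_id) & summaries$computed, ,
    drop = FALSE
  ]
  if (nrow(s) == 0L) stop("no computed per-population summaries supplied")
  pops <- populations(popmap)
  pop_ids <- sort(unique(s$population_id))
  rows <- lapply(pop_ids, function(p) {
    d <- s$tajimas_d[s$population_id == p]
    d <- d[!is.na(d)]
    rd <- NA_real_
    if (!is.null(resampled)) {
      rr <- resampled$mean_d[resampled$population_id == p & resampled$computed]
      rr <- rr[!is.na(rr)]
      if (length(rr)) rd <- mean(rr)
    }
    data.frame(
      population_id = p,
      latitude = pops$latitude[match(p, pops$population_id)],
      n_loci = length(d),
      mean_d = if (length(d)) mean(d) else NA_real_,
      mean_resampled_d = rd,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$latitude) & !is.na(out$mean_d)
  if (sum(ok) >= 3L) {
    attr(out, "spearman") <- stats::cor(
      out$latitude[ok], out$mean_d[ok],
      method = "spearman"
    )
  }
  out
}
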