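#' Construct a SimTruth
#'
#' @param locusId locus identifier.
#' @param thetaPerSite per-site scaled mutation rate 4*Ne*mu.
#' @param rhoPerSite per-site scaled recombination rate 4*Ne*r.
#' @param locusLength locus length in bp.
#' @param growthRate exponential growth rate in coalescent units (0 =
#'   constant size); may be one value per population when `migrationRate`
#'   is 0.
#' @param migrationRate symmetric island-model rate 4*Ne*m.
#' @param samplesPerPopulation integer vector of haploid sample sizes.
#' @param maskLayout [IRanges::IRanges] of sequenced windows (empty =
#'   fully sequenced).
#' @param readJitter fraction by which individual read ends are randomly
#'   shortened.
#' @param seed integer RNG seed.
#' @return A [SimTruth-class].
#' @export
SimTruth <- function(locusId, thetaPerSite, rhoPerSite = 0,
                     locusLength = 1000L, growthRate = 0,
                     migrationRate = 0, samplesPerPopulation = 10L,
                     maskLayout = IRanges::IRanges(), readJitter = 0,
                     seed = 1L) {
  new("SimTruth",
    locusId = as.character(locusId), thetaPerSite = thetaPerSite,
    rhoPerSite = rhoPerSite, locusLength = as.integer(locusLength),
    growthRate = growthRate, migrationRate = migrationRate,
    samplesPerPopulation = as.integer(samplesPerPopulation),
    maskLayout = maskLayout, readJitter = readJitter,
    seed = as.integer(seed)
  )
}

.mergeSegs <- function(sa, sb, n) {
  pts <- sort(unique(c(
    unlist(lapply(sa, function(s) c(s$l, s$r))),
    unlist(lapply(sb, function(s) c(s$l, s$r)))
  )))
  out <- list()
  for (i in seq_len(length(pts) - 1L)) {
    l <- pts[i]
    r <- pts[i + 1L]
    mid <- (l + r) / 2
    desc <- integer(0)
    for (s in sa) {
      if (s$l <= mid && mid < s$r) {
        desc <- s$desc
        break
      }
    }
    for (s in sb) {
      if (s$l <= mid && mid < s$r) {
        desc <- sort(unique(c(desc, s$desc)))
        break
      }
    }
    nd <- length(desc)
    if (nd == 0L || nd == n) next
    k <- length(out)
    if (k > 0L && out[[k]]$r == l && identical(out[[k]]$desc, desc)) {
      out[[k]]$r <- r
    } else {
      out[[k + 1L]] <- list(l = l, r = r, desc = desc)
    }
  }
  out
}

.segSpan <- function(segs) {
  lo <- min(vapply(segs, function(s) s$l, 1))
  hi <- max(vapply(segs, function(s) s$r, 1))
  c(lo, hi)
}

#' Coalescent genealogy with mutations for one ancestral process
#'
#' Simulates the ancestral recombination graph of a sample under the
#' neutral coalescent with (optional) recombination, exponential growth
#' and symmetric island migration, placing infinite-sites mutations with
#' rate theta/2 per lineage on the continuous locus `[0, 1)`. Time is in
#' units of 2*Ne generations; recombination occurs at rate rho/2 times the
#' ancestral span of a lineage; migration moves a lineage to a uniformly
#' chosen other population at rate migration/2; exponential growth
#' multiplies the coalescence intensity at time `t` by `exp(g*t)`. Sample
#' indices are `1..n` ordered by population block.
#'
#' Uses the session RNG; wrap in `set.seed()` for reproducibility.
#'
#' @param n total haploid sample size.
#' @param thetaLocus locus-wide theta (4*Ne*mu summed over the locus).
#' @param rho locus-wide scaled recombination rate.
#' @param samplesPerPopulation sample sizes per population (defaults to a
#'   single population of size `n`; must sum to `n`).
#' @param migrationRate island-model 4*Ne*m (required > 0 when more than
#'   one population is simulated jointly).
#' @param growthRate exponential growth rate (scalar, or one value per
#'   population).
#' @return List with `n`, `positions` (continuous in `[0, 1)`), `carriers`
#'   (list of integer vectors of sample indices carrying the derived
#'   allele), and `intervals` (two-column matrix of the ancestral segment
#'   each mutation fell on, used for collision redraws).
#' @export
simulateAncestry <- function(n, thetaLocus, rho = 0,
                             samplesPerPopulation = n, migrationRate = 0,
                             growthRate = 0) {
  samplesPerPopulation <- as.integer(samplesPerPopulation)
  stopifnot(
    n >= 2, sum(samplesPerPopulation) == n, thetaLocus >= 0, rho >= 0,
    all(growthRate >= 0), migrationRate >= 0
  )
  npop <- length(samplesPerPopulation)
  if (npop > 1L && migrationRate <= 0) {
    stop(
      "multiple populations with no migration never find a common ",
      "ancestor; simulate populations independently instead"
    )
  }
  g <- rep_len(growthRate, npop)
  pop_of <- rep(seq_len(npop), samplesPerPopulation)
  segs <- lapply(seq_len(n), function(i) list(list(l = 0, r = 1, desc = i)))
  pops <- pop_of
  # per-lineage caches, updated in place by each event
  spans <- rep(1, n)
  lens <- rep(1, n)
  t_now <- 0
  mut_pos <- numeric(0)
  mut_car <- list()
  mut_int <- NULL
  guard <- 0L

  .lineageStats <- function(s) {
    ls <- vapply(s, function(x) x$l, 1)
    rs <- vapply(s, function(x) x$r, 1)
    c(span = max(rs) - min(ls), len = sum(rs - ls))
  }

  while (length(segs) > 0L) {
    guard <- guard + 1L
    if (guard > 10000000L) stop("ancestral process failed to coalesce")
    k <- length(segs)
    kp <- tabulate(pops, npop)

    # candidate waiting times for each competing event type
    t_coal <- rep(Inf, npop)
    for (p in seq_len(npop)) {
      if (kp[p] < 2L) next
      base <- kp[p] * (kp[p] - 1) / 2
      E <- rexp(1)
      t_coal[p] <- if (g[p] == 0) {
        E / base
      } else {
        log(1 + g[p] * E / (base * exp(g[p] * t_now))) / g[p]
      }
    }
    rateR <- rho / 2 * sum(spans)
    t_rec <- if (rateR > 0) rexp(1) / rateR else Inf
    rateM <- if (npop > 1L) migrationRate / 2 * k else 0
    t_mig <- if (rateM > 0) rexp(1) / rateM else Inf

    dt <- min(c(t_coal, t_rec, t_mig))
    if (!is.finite(dt)) stop("ancestral process stalled: no possible events")
    t_now <- t_now + dt

    # mutations accrued on all current ancestral material during dt
    if (thetaLocus > 0) {
      n_mut <- rpois(1, thetaLocus / 2 * dt * sum(lens))
      if (n_mut > 0) {
        seg_list <- unlist(segs, recursive = FALSE)
        seg_len <- vapply(seg_list, function(s) s$r - s$l, 1)
        pick <- sample.int(length(seg_list), n_mut,
          replace = TRUE, prob = seg_len
        )
        for (m in pick) {
          s <- seg_list[[m]]
          mut_pos <- c(mut_pos, runif(1, s$l, s$r))
          mut_car[[length(mut_car) + 1L]] <- s$desc
          mut_int <- rbind(mut_int, c(s$l, s$r))
        }
      }
    }

    if (dt == t_rec) {
      i <- sample.int(k, 1L, prob = spans)
      lo <- min(vapply(segs[[i]], function(s) s$l, 1))
      hi <- max(vapply(segs[[i]], function(s) s$r, 1))
      u <- runif(1, lo, hi)
      left <- list()
      right <- list()
      for (s in segs[[i]]) {
        if (s$r <= u) {
          left[[length(left) + 1L]] <- s
        } else if (s$l >= u) {
          right[[length(right) + 1L]] <- s
        } else {
          left[[length(left) + 1L]] <- list(l = s$l, r = u, desc = s$desc)
          right[[length(right) + 1L]] <- list(l = u, r = s$r, desc = s$desc)
        }
      }
      segs[[i]] <- left
      segs[[k + 1L]] <- right
      pops[k + 1L] <- pops[i]
      st <- .lineageStats(left)
      spans[i] <- st["span"]
      lens[i] <- st["len"]
      st <- .lineageStats(right)
      spans[k + 1L] <- st["span"]
      lens[k + 1L] <- st["len"]
    } else if (dt == t_mig) {
      i <- sample.int(k, 1L)
      dest <- sample(setdiff(seq_len(npop), pops[i]), 1L)
      pops[i] <- dest
    } else {
      p <- which.min(t_coal)
      in_p <- which(pops == p)
      pair <- sort(in_p[sample.int(length(in_p), 2L)])
      i <- pair[1] # i < j, so deleting j below leaves index i valid
      j <- pair[2]
      merged <- .mergeSegs(segs[[i]], segs[[j]], n)
      drop <- j
      if (length(merged) == 0L) {
        drop <- c(i, j)
      } else {
        segs[[i]] <- merged
        st <- .lineageStats(merged)
        spans[i] <- st["span"]
        lens[i] <- st["len"]
      }
      segs <- segs[-drop]
      pops <- pops[-drop]
      spans <- spans[-drop]
      lens <- lens[-drop]
    }
  }
  if (is.null(mut_int)) mut_int <- matrix(numeric(0), 0, 2)
  list(n = n, positions = mut_pos, carriers = mut_car, intervals = mut_int)
}

# Assign continuous mutation positions to distinct integer sites on a grid
# of length L; a collision redraws the position within the mutation's own
# ancestral segment so the position-genealogy coupling is preserved.
.assignSites <- function(muts, L, taken = integer(0)) {
  n_mut <- length(muts$positions)
  sites <- integer(n_mut)
  used <- taken
  for (m in seq_len(n_mut)) {
    x <- muts$positions[m]
    site <- min(L, floor(x * L) + 1L)
    tries <- 0L
    while (site %in% used) {
      tries <- tries + 1L
      if (tries > 10000L) {
        stop("could not place ", n_mut, " mutations on ", L, " sites")
      }
      x <- runif(1, muts$intervals[m, 1], muts$intervals[m, 2])
      site <- min(L, floor(x * L) + 1L)
    }
    sites[m] <- site
    used <- c(used, site)
  }
  sites
}

.jitterWindow <- function(win_start, win_end, side, readJitter) {
  w <- win_end - win_start + 1L
  cut <- floor(runif(1, 0, readJitter) * w)
  if (side == "right") {
    c(win_start, win_end - cut)
  } else {
    c(win_start + cut, win_end)
  }
}

#' Simulate one locus alignment from generating truth
#'
#' Runs the coalescent of [simulateAncestry()] under the parameters in
#' `truth` and renders haploid sequences: the reference base is `A` at
#' every site and each mutation's derived allele is drawn uniformly from
#' `C/G/T` (infinite sites on an integer grid; position collisions are
#' redrawn). With several populations and `migrationRate = 0`, each
#' population is simulated as an independent coalescent (no shared
#' ancestry), which is how population-specific growth rates are honored.
#' Positions outside the sequenced windows of `maskLayout` are written as
#' `N`; within windows, each individual's read is independently shortened
#' by up to `readJitter` of the window length (odd-numbered windows are
#' read from the left and lose bases on the right, even-numbered windows
#' the reverse).
#'
#' @param truth a [SimTruth-class]; `truth@seed` fully determines the
#'   output.
#' @param populationIds optional population names (default `P1..Pk`).
#' @return List with `alignment` ([LocusAlignment-class]), `popmap`
#'   ([PopulationMap-class]), `truth`, and `siteTruth` (data.frame of
#'   simulated site positions, derived alleles and carrier counts).
#' @export
simulateLocus <- function(truth, populationIds = NULL) {
  stopifnot(is(truth, "SimTruth"))
  sizes <- truth@samplesPerPopulation
  npop <- length(sizes)
  n <- sum(sizes)
  L <- truth@locusLength
  if (n > 200 || L > 10000) {
    stop("simulation is desk-scale: n <= 200 and locus length <= 10 kb")
  }
  if (is.null(populationIds)) populationIds <- paste0("P", seq_len(npop))
  stopifnot(length(populationIds) == npop)
  set.seed(truth@seed)
  g <- rep_len(truth@growthRate, npop)

  site_pos <- integer(0)
  site_derived <- character(0)
  site_carriers <- list()
  independent <- npop > 1L && truth@migrationRate == 0
  blocks <- if (independent) seq_len(npop) else 1L
  offset <- 0L
  for (b in blocks) {
    if (independent) {
      muts <- simulateAncestry(sizes[b], truth@thetaPerSite * L,
        rho = truth@rhoPerSite * L, growthRate = g[b]
      )
    } else {
      muts <- simulateAncestry(n, truth@thetaPerSite * L,
        rho = truth@rhoPerSite * L, samplesPerPopulation = sizes,
        migrationRate = truth@migrationRate, growthRate = g
      )
    }
    new_sites <- .assignSites(muts, L, taken = site_pos)
    site_pos <- c(site_pos, new_sites)
    site_derived <- c(
      site_derived,
      sample(c("C", "G", "T"), length(new_sites), replace = TRUE)
    )
    site_carriers <- c(
      site_carriers,
      lapply(muts$carriers, function(d) d + offset)
    )
    if (independent) offset <- offset + sizes[b]
  }

  seqm <- matrix("A", n, L)
  for (m in seq_along(site_pos)) {
    seqm[site_carriers[[m]], site_pos[m]] <- site_derived[m]
  }

  windows <- truth@maskLayout
  if (length(windows) > 0L) {
    ws <- IRanges::start(windows)
    we <- IRanges::end(windows)
    ord <- order(ws)
    ws <- ws[ord]
    we <- we[ord]
    for (i in seq_len(n)) {
      called <- rep(FALSE, L)
      for (w in seq_along(ws)) {
        side <- if (w %% 2L == 1L) "right" else "left"
        jw <- .jitterWindow(ws[w], we[w], side, truth@readJitter)
        if (jw[2] >= jw[1]) called[jw[1]:jw[2]] <- TRUE
      }
      seqm[i, !called] <- "N"
    }
  }

  ind_ids <- sprintf(
    "%s_i%02d", rep(populationIds, sizes),
    unlist(lapply(sizes, seq_len))
  )
  seqs <- apply(seqm, 1, paste0, collapse = "")
  names(seqs) <- ind_ids
  aln <- LocusAlignment(truth@locusId, seqs,
    ampliconLength = L,
    sequencedSegments = if (length(windows) > 0L) windows else NULL
  )
  popmap <- PopulationMap(data.frame(
    individual_id = ind_ids,
    population_id = rep(populationIds, sizes),
    stringsAsFactors = FALSE
  ))
  ord <- order(site_pos)
  siteTruth <- data.frame(
    position = site_pos[ord],
    derived = site_derived[ord],
    n_carriers = vapply(site_carriers, length, 1L)[ord]
  )
  list(alignment = aln, popmap = popmap, truth = truth, siteTruth = siteTruth)
}

#' Default multi-locus study configuration
#'
#' Describes the synthetic study: 11 nuclear loci of 1.5-7.3 kb amplified
#' in 10 populations sampled along a latitudinal gradient (7 populations
#' of 8 and 3 densely sampled populations of 24, 128 haploid sequences in
#' total), with only the two ends of each amplicon sequenced (about 29% of
#' the amplicon on average) and per-individual read-length jitter.
#'
#' Two demographic scenarios are provided. `"panmictic"` (the default)
#' uses a single exponentially growing species connected by strong
#' migration (4Nm = 50), the regime of a widespread outcrossing conifer:
#' weak structure and an excess of rare variants. `"gradient"` switches to
#' independent populations whose growth rate declines from south to north,
#' producing a cline of Tajima's D against latitude. The default
#' `thetaPerSite` of 0.0032 is calibrated so that the observed per-site
#' Watterson estimate under the default demography is about 0.005 (island
#' structure inflates, and growth deflates, observed diversity relative to
#' the per-deme scaled mutation rate; the net factor was measured once by
#' simulation and frozen).
#'
#' @param scenario `"panmictic"` or `"gradient"`.
#' @param seed master seed; per-locus seeds are derived from it.
#' @param thetaPerSite scaled per-site mutation rate.
#' @param rhoPerSite scaled per-site recombination rate (default twice
#'   theta).
#' @param growthRate exponential growth rate (scalar; under `"gradient"`
#'   this is the southernmost rate, declining linearly to 0 at the
#'   northern end).
#' @param migrationRate island-model 4Nm for the `"panmictic"` scenario.
#' @param readJitter per-read length jitter fraction.
#' @return A list of class `haploLDConfig`.
#' @export
studyConfig <- function(scenario = c("panmictic", "gradient"), seed = 1L,
                        thetaPerSite = 0.0032, rhoPerSite = 2 * thetaPerSite,
                        growthRate = 10, migrationRate = 50,
                        readJitter = 0.25) {
  scenario <- match.arg(scenario)
  nLoci <- 11L
  ampliconLengths <- c(
    4681L, 1585L, 2970L, 4328L, 2742L, 4126L,
    7271L, 1859L, 4411L, 3189L, 4107L
  )
  sequencedBp <- c(
    457L, 1028L, 2449L, 1597L, 748L, 742L,
    1796L, 986L, 470L, 605L, 803L
  )
  sizes <- c(8L, 8L, 24L, 8L, 24L, 8L, 8L, 8L, 8L, 24L)
  latitudes <- round(seq(58, 67, length.out = 10), 1)
  popIds <- sprintf("P%02d", seq_along(sizes))
  growth <- if (scenario == "gradient") {
    seq(growthRate, 0, length.out = length(sizes))
  } else {
    growthRate
  }
  structure(list(
    scenario = scenario,
    nLoci = nLoci,
    locusIds = sprintf("locus%02d", seq_len(nLoci)),
    ampliconLengths = ampliconLengths,
    sequencedBp = sequencedBp,
    populationIds = popIds,
    populationSizes = sizes,
    latitudes = latitudes,
    thetaPerSite = thetaPerSite,
    rhoPerSite = rhoPerSite,
    growthRate = growth,
    migrationRate = if (scenario == "gradient") 0 else migrationRate,
    readJitter = readJitter,
    seed = as.integer(seed)
  ), class = "haploLDConfig")
}

#' Sequenced-end mask layout for an amplicon
#'
#' Splits a total sequenced length into two windows anchored at the two
#' ends of the amplicon (paired end-sequencing of a long amplicon).
#'
#' @param ampliconLength amplicon length in bp.
#' @param sequencedBp total sequenced bases (`<= ampliconLength`).
#' @return An [IRanges::IRanges] of one or two sequenced windows.
#' @export
endMaskLayout <- function(ampliconLength, sequencedBp) {
  stopifnot(sequencedBp >= 1, sequencedBp <= ampliconLength)
  left <- as.integer(ceiling(sequencedBp / 2))
  right <- as.integer(sequencedBp - left)
  if (right == 0L || left + right >= ampliconLength) {
    return(IRanges::IRanges(start = 1L, end = as.integer(sequencedBp)))
  }
  IRanges::IRanges(
    start = c(1L, ampliconLength - right + 1L),
    end = c(left, as.integer(ampliconLength))
  )
}

#' Simulate a full multi-locus study
#'
#' Draws independent loci under one shared demographic truth from a
#' [studyConfig()] configuration: same individuals and populations across
#' loci, per-locus seeds derived from the master seed.
#'
#' @param config a `haploLDConfig` from [studyConfig()].
#' @return List with `alignments` (list of [LocusAlignment-class]),
#'   `popmap` ([PopulationMap-class] with latitudes), `truths` (list of
#'   [SimTruth-class]), and `config`.
#' @export
simulateStudy <- function(config = studyConfig()) {
  stopifnot(inherits(config, "haploLDConfig"))
  set.seed(config$seed)
  locus_seeds <- sample.int(100000000L, config$nLoci)
  alignments <- vector("list", config$nLoci)
  truths <- vector("list", config$nLoci)
  popmap <- NULL
  for (i in seq_len(config$nLoci)) {
    truth <- SimTruth(
      locusId = config$locusIds[i],
      thetaPerSite = config$thetaPerSite,
      rhoPerSite = config$rhoPerSite,
      locusLength = config$ampliconLengths[i],
      growthRate = config$growthRate,
      migrationRate = config$migrationRate,
      samplesPerPopulation = config$populationSizes,
      maskLayout = endMaskLayout(
        config$ampliconLengths[i], config$sequencedBp[i]
      ),
      readJitter = config$readJitter,
      seed = locus_seeds[i]
    )
    sim <- simulateLocus(truth, populationIds = config$populationIds)
    alignments[[i]] <- sim$alignment
    truths[[i]] <- truth
    popmap <- sim$popmap
  }
  pops <- populations(popmap)
  pops$latitude <- config$latitudes[
    match(pops$population_id, config$populationIds)
  ]
  popmap <- PopulationMap(assignments(popmap), pops)
  names(alignments) <- config$locusIds
  names(truths) <- config$locusIds
  list(
    alignments = alignments, popmap = popmap, truths = truths,
    config = config
  )
}

#' Write a simulated study to disk
#'
#' Emits one FASTA per locus, `popmap.tsv`, a `truth.json` with every
#' generating parameter, and `config.txt` (plain key-value lines).
#'
#' @param study result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimResult <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (aln in study$alignments) {
    writeLocusAlignment(aln, file.path(dir, paste0(locusId(aln), ".fasta")))
  }
  writePopulationMap(study$popmap, file.path(dir, "popmap.tsv"))
  truth_list <- lapply(study$truths, function(tr) list(
    locus_id = tr@locusId,
    theta_per_site = tr@thetaPerSite,
    rho_per_site = tr@rhoPerSite,
    locus_length_bp = tr@locusLength,
    growth_rate = tr@growthRate,
    migration_rate = tr@migrationRate,
    samples_per_population = tr@samplesPerPopulation,
    sequenced_windows = if (length(tr@maskLayout)) {
      data.frame(
        start = IRanges::start(tr@maskLayout),
        end = IRanges::end(tr@maskLayout)
      )
    } else {
      NULL
    },
    read_jitter = tr@readJitter,
    seed = tr@seed
  ))
  jsonlite::write_json(
    list(master_seed = study$config$seed, loci = truth_list),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  cfg <- study$config
  keyvals <- vapply(names(cfg), function(k) {
    paste(k, paste(cfg[[k]], collapse = ","), sep = "=")
  }, "")
  writeLines(keyvals, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Read a study configuration from a key-value text file
#'
#' Parses the `config.txt` dialect written by [writeSimResult()] back into
#' a `haploLDConfig`, so a simulated study can be regenerated from its
#' output directory.
#'
#' @param path config file.
#' @return A list of class `haploLDConfig`.
#' @export
readStudyConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(vapply(kv, length, 1L) != 2L)
  if (length(bad)) {
    stop("config parse error at line ", bad[1], " of ", path,
      ": expected key=value")
  }
  vals <- lapply(kv, function(x) strsplit(x[2], ",", fixed = TRUE)[[1]])
  names(vals) <- vapply(kv, `[[`, "", 1L)
  num <- function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) stop("config parse error: non-numeric value ", x[1])
    v
  }
  structure(list(
    scenario = vals$scenario,
    nLoci = as.integer(num(vals$nLoci)),
    locusIds = vals$locusIds,
    ampliconLengths = as.integer(num(vals$ampliconLengths)),
    sequencedBp = as.integer(num(vals$sequencedBp)),
    populationIds = vals$populationIds,
    populationSizes = as.integer(num(vals$populationSizes)),
    latitudes = num(vals$latitudes),
    thetaPerSite = num(vals$thetaPerSite),
    rhoPerSite = num(vals$rhoPerSite),
    growthRate = num(vals$growthRate),
    migrationRate = num(vals$migrationRate),
    readJitter = num(vals$readJitter),
    seed = as.integer(num(vals$seed))
  ), class = "haploLDConfig")
}
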