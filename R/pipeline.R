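#' Build and validate a run configuration
#'
#' Collects every knob of the full analysis in one validated object; the
#' configuration (and its hash) is echoed into every output, so a report
#' bundle is reproducible from its manifest alone.
#'
#' @param inputDir directory containing one FASTA per locus plus
#'   `popmap.tsv` (the layout written by [writeSimResult()]).
#' @param outDir output directory for the report bundle.
#' @param missingPolicy site policy for diversity summaries.
#' @param ldMissingPolicy site policy for LD (pairwise availability).
#' @param correctionScope Bonferroni scope, `"global"` or `"per_locus"`.
#' @param alpha significance level.
#' @param decayThreshold r2 threshold for the decay crossing distance.
#' @param mapScales cM-per-Mb scales for the D' decay fit.
#' @param resampleK,resampleB subsample size and replicate count.
#' @param densePopMinN minimum population sample size for
#'   population-scoped analyses (smaller populations are flagged, not
#'   dropped).
#' @param lookupPath optional likelihood file from [writeLookupTable()];
#'   when `NULL` a table is simulated per required sample size.
#' @param rhoGridMax,rhoNSims,rhoMutDraws lookup-build parameters used
#'   when `lookupPath` is `NULL`.
#' @param seed master seed for every stochastic stage.
#' @return A list of class `haploLDRunConfig`.
#' @export
runConfig <- function(inputDir, outDir,
                      missingPolicy = "complete_deletion",
                      ldMissingPolicy = "pairwise_available",
                      correctionScope = "global", alpha = 0.05,
                      decayThreshold = 0.2, mapScales = c(1, 10, 20),
                      resampleK = 8L, resampleB = 100L,
                      densePopMinN = 11L, lookupPath = NULL,
                      rhoGridMax = 100, rhoNSims = 3000L,
                      rhoMutDraws = 4L, seed = 1L) {
  stopifnot(
    dir.exists(inputDir),
    missingPolicy %in% c("complete_deletion", "pairwise_available"),
    ldMissingPolicy %in% c("complete_deletion", "pairwise_available"),
    correctionScope %in% c("global", "per_locus"),
    alpha > 0, alpha < 1, decayThreshold > 0, all(mapScales > 0),
    resampleK >= 2, resampleB >= 1, densePopMinN >= 2,
    rhoGridMax > 0, rhoNSims >= 100, rhoMutDraws >= 1
  )
  if (!is.null(lookupPath) && !file.exists(lookupPath)) {
    stop("lookupPath does not exist: ", lookupPath)
  }
  structure(list(
    inputDir = inputDir, outDir = outDir,
    missingPolicy = missingPolicy, ldMissingPolicy = ldMissingPolicy,
    correctionScope = correctionScope, alpha = alpha,
    decayThreshold = decayThreshold, mapScales = mapScales,
    resampleK = as.integer(resampleK), resampleB = as.integer(resampleB),
    densePopMinN = as.integer(densePopMinN), lookupPath = lookupPath,
    rhoGridMax = rhoGridMax, rhoNSims = as.integer(rhoNSims),
    rhoMutDraws = as.integer(rhoMutDraws), seed = as.integer(seed)
  ), class = "haploLDRunConfig")
}

#' Hash of a run configuration
#'
#' MD5 of the deparsed configuration; changing any field changes the hash.
#'
#' @param config a `haploLDRunConfig` (paths are excluded from the hash so
#'   the same analysis on relocated inputs is recognizable).
#' @return Character MD5 hash.
#' @export
configHash <- function(config) {
  c2 <- unclass(config)
  c2$inputDir <- NULL
  c2$outDir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(c2), tmp)
  unname(tools::md5sum(tmp))
}

.writeReportTsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the inputs of a run (FASTA set plus population map)
#'
#' @param inputDir directory with `*.fasta` files and `popmap.tsv`.
#' @return List with `alignments` and `popmap`.
#' @export
readStudyInputs <- function(inputDir) {
  fastas <- sort(list.files(inputDir, "\\.fasta$", full.names = TRUE))
  if (length(fastas) == 0L) stop("no .fasta files in ", inputDir)
  pm_path <- file.path(inputDir, "popmap.tsv")
  if (!file.exists(pm_path)) stop("missing popmap.tsv in ", inputDir)
  alignments <- lapply(fastas, function(f) {
    readLocusAlignment(f, locusId = sub("\\.fasta$", "", basename(f)))
  })
  names(alignments) <- vapply(alignments, locusId, "")
  list(alignments = alignments, popmap = readPopulationMap(pm_path))
}

.displayDiversity <- function(div) {
  out <- div
  out$theta_w <- signif(div$theta_w * 1000, 2)
  out$pi <- signif(div$pi * 1000, 2)
  names(out)[names(out) == "theta_w"] <- "theta_w_x1000"
  names(out)[names(out) == "pi"] <- "pi_x1000"
  out
}

.decayRow <- function(fit, scope, threshold) {
  cross <- crossingDistance(fit, threshold = threshold)
  data.frame(
    scope = scope, model = fit@model, parameter = fit@param,
    n = fit@n, map_scale = fit@mapScale, mapping = fit@mapping,
    rss = fit@rss, n_pairs = fit@nPairs,
    ill_conditioned = fit@illConditioned,
    crossing_bp = cross$bp, crossing_status = cross$status,
    stringsAsFactors = FALSE
  )
}

#' Run the full analysis and write a report bundle
#'
#' Orchestrates every analysis stage on a directory of per-locus FASTA
#' alignments: pooled and per-population diversity summaries, within-locus
#' LD with multiple-test correction, r2 and D' decay fits with crossing
#' distances, composite-likelihood recombination rates, global FST, the
#' subsampling experiment in densely sampled populations, and the
#' latitude trend table. All outputs are TSV (raw full precision, plus a
#' display-scaled diversity report) under `config$outDir`, together with a
#' JSON manifest recording the configuration, its hash, package and R
#' versions, seeds and per-stage status. A failed stage is recorded in the
#' manifest and the run continues; the returned bundle carries
#' `complete = FALSE` in that case.
#'
#' Pooled recombination rates are estimated only when the pooled sample
#' size is within the lookup-table range (100); per-population estimates
#' are always attempted for dense populations.
#'
#' @param config a `haploLDRunConfig` from [runConfig()].
#' @return The report bundle (named list of tables and fits, plus
#'   `manifest`), invisibly.
#' @export
runFullAnalysis <- function(config) {
  stopifnot(inherits(config, "haploLDRunConfig"))
  if (!dir.exists(config$outDir)) dir.create(config$outDir, recursive = TRUE)
  hash <- configHash(config)
  stages <- list()
  bundle <- list()
  outputs <- character()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      message("stage '", name, "' failed: ", conditionMessage(res))
      stages[[name]] <<- list(status = "failed",
        error = conditionMessage(res))
      NULL
    } else {
      stages[[name]] <<- list(status = "ok")
      res
    }
  }
  emit <- function(df, file) {
    path <- file.path(config$outDir, file)
    .writeReportTsv(df, path, hash)
    outputs <<- c(outputs, file)
  }

  inputs <- stage("read_inputs", readStudyInputs(config$inputDir))
  if (is.null(inputs)) {
    manifest <- list(
      config = unclass(config), config_hash = hash,
      package_version = as.character(utils::packageVersion("haploLD")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      stages = stages, outputs = outputs, complete = FALSE
    )
    jsonlite::write_json(manifest,
      file.path(config$outDir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
    )
    return(invisible(list(manifest = manifest)))
  }
  alignments <- inputs$alignments
  popmap <- inputs$popmap
  pop_sizes <- table(assignments(popmap)$population_id)
  dense <- names(pop_sizes)[pop_sizes >= config$densePopMinN]

  bundle$diversity_pooled <- stage("diversity_pooled", summarizeLoci(
    alignments, popmap,
    scope = "all",
    missingPolicy = config$missingPolicy, alpha = config$alpha
  ))
  bundle$diversity_population <- stage("diversity_population", {
    d <- summarizeLoci(alignments, popmap,
      scope = "population",
      missingPolicy = config$missingPolicy, alpha = config$alpha
    )
    d$dense <- d$population_id %in% dense
    d
  })
  if (!is.null(bundle$diversity_pooled)) {
    emit(bundle$diversity_pooled, "diversity_pooled.tsv")
    emit(.displayDiversity(bundle$diversity_pooled), "diversity_report.tsv")
  }
  if (!is.null(bundle$diversity_population)) {
    emit(bundle$diversity_population, "diversity_population.tsv")
  }

  bundle$ld_pooled <- stage("ld_pooled", buildLdPairs(
    alignments, popmap,
    missingPolicy = config$ldMissingPolicy,
    correctionScope = config$correctionScope, alpha = config$alpha
  ))
  if (!is.null(bundle$ld_pooled)) {
    emit(ldPairs(bundle$ld_pooled), "ld_pairs_pooled.tsv")
    bundle$ld_summary_pooled <- ldSummary(bundle$ld_pooled)
    emit(bundle$ld_summary_pooled, "ld_summary_pooled.tsv")
  }
  bundle$ld_population <- stage("ld_population", {
    sets <- lapply(dense, function(p) buildLdPairs(
      alignments, popmap,
      population = p,
      missingPolicy = config$ldMissingPolicy,
      correctionScope = config$correctionScope, alpha = config$alpha
    ))
    names(sets) <- dense
    sets
  })
  if (!is.null(bundle$ld_population) && length(bundle$ld_population)) {
    pp <- do.call(rbind, lapply(bundle$ld_population, ldPairs))
    emit(pp, "ld_pairs_population.tsv")
    ps <- do.call(rbind, lapply(dense, function(p) {
      s <- ldSummary(bundle$ld_population[[p]])
      cbind(population_id = p, s, stringsAsFactors = FALSE)
    }))
    emit(ps, "ld_summary_population.tsv")
  }

  bundle$decay <- stage("decay", {
    rows <- list()
    fits <- list()
    if (!is.null(bundle$ld_pooled) && nrow(ldPairs(bundle$ld_pooled)) >= 5) {
      f <- fitHillWeir(bundle$ld_pooled)
      fits$pooled_r2 <- f
      rows[[length(rows) + 1L]] <- .decayRow(f, "pooled",
        config$decayThreshold)
      for (ms in config$mapScales) {
        fd <- fitDprimeDecay(bundle$ld_pooled, mapScale = ms)
        fits[[paste0("pooled_dprime_", ms)]] <- fd
        rows[[length(rows) + 1L]] <- .decayRow(fd, "pooled",
          config$decayThreshold)
      }
    }
    for (p in names(bundle$ld_population)) {
      lp <- bundle$ld_population[[p]]
      if (nrow(ldPairs(lp)) < 5) next
      f <- fitHillWeir(lp)
      fits[[paste0(p, "_r2")]] <- f
      rows[[length(rows) + 1L]] <- .decayRow(f, p, config$decayThreshold)
    }
    list(table = do.call(rbind, rows), fits = fits)
  })
  if (!is.null(bundle$decay) && !is.null(bundle$decay$table)) {
    emit(bundle$decay$table, "decay_fits.tsv")
  }

  bundle$rho <- stage("rho", {
    need_n <- sort(unique(c(
      vapply(dense, function(p) as.integer(pop_sizes[[p]]), 1L),
      if (length(alignments) &&
        nSequences(alignments[[1]]) <= 100) nSequences(alignments[[1]])
    )))
    lookups <- list()
    for (nn in need_n) {
      lookups[[as.character(nn)]] <- if (!is.null(config$lookupPath)) {
        lk <- readLookupTable(config$lookupPath)
        if (lk@n != nn) {
          stop("lookup file is for n = ", lk@n, ", need n = ", nn)
        }
        lk
      } else {
        buildLookup(nn,
          rhoGrid = seq(0, config$rhoGridMax, length.out = 21),
          nSims = config$rhoNSims, mutDraws = config$rhoMutDraws,
          seed = config$seed
        )
      }
    }
    rows <- list()
    for (aln in alignments) {
      scopes <- c(
        if (nSequences(aln) <= 100) list(list(id = "pooled", aln = aln)),
        lapply(dense, function(p) {
          ids <- assignments(popmap)
          keep <- ids$individual_id[ids$population_id == p]
          list(id = p, aln = subsetAlignment(
            aln, intersect(names(sequences(aln)), keep)
          ))
        })
      )
      for (sc in scopes) {
        a <- dropEmptySequences(sc$aln)
        key <- as.character(nSequences(a))
        if (!key %in% names(lookups)) {
          lookups[[key]] <- buildLookup(nSequences(a),
            rhoGrid = seq(0, config$rhoGridMax, length.out = 21),
            nSims = config$rhoNSims, mutDraws = config$rhoMutDraws,
            seed = config$seed
          )
        }
        sites <- classifySites(a, "pairwise_available")
        est <- estimateRho(a, sites, lookups[[key]])
        summ <- summarizeLocus(a, alpha = config$alpha)
        rt <- rhoOverTheta(est, summ$theta_w)
        rows[[length(rows) + 1L]] <- data.frame(
          locus_id = locusId(aln), scope = sc$id,
          computed = est$computed, rho_per_kb = est$rho_per_kb,
          rho_per_site = est$rho_per_site, rho_locus = est$rho_locus,
          rho_over_theta = rt$rho_over_theta,
          flat_likelihood = est$flat_likelihood,
          n_snps = est$n_snps, n_pairs_used = est$n_pairs_used,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
  if (!is.null(bundle$rho)) emit(bundle$rho, "rho_estimates.tsv")

  bundle$fst <- stage("fst", globalFst(alignments, popmap))
  if (!is.null(bundle$fst)) emit(bundle$fst, "fst.tsv")

  bundle$resample <- stage("resample", resampleStudy(
    alignments, popmap,
    populationIds = dense, k = config$resampleK,
    B = config$resampleB, seed = config$seed
  ))
  if (!is.null(bundle$resample)) {
    emit(bundle$resample, "resample_summary.tsv")
    reps <- attr(bundle$resample, "replicates")
    if (!is.null(reps)) emit(reps, "resample_replicates.tsv")
  }

  bundle$latitude_trend <- stage("latitude_trend", latitudeTrendTable(
    bundle$diversity_population, popmap,
    resampled = bundle$resample
  ))
  if (!is.null(bundle$latitude_trend)) {
    emit(bundle$latitude_trend, "latitude_trend.tsv")
  }

  complete <- all(vapply(stages, function(s) s$status == "ok", TRUE))
  manifest <- list(
    config = unclass(config), config_hash = hash,
    package_version = as.character(utils::packageVersion("haploLD")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, stages = stages, outputs = outputs,
    complete = complete
  )
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  bundle$manifest <- manifest
  invisible(bundle)
}

.cliUsage <- function() {
  paste(
    "usage: haploLD <subcommand> [options]",
    "",
    "subcommands:",
    "  stats     --in DIR --out DIR            diversity summaries",
    "  ld        --in DIR --out DIR            LD pair table + summary",
    "  decay     --in DIR --out DIR [--map-scale X]  decay fits",
    "  rho       --in DIR --out DIR [--seed N] recombination rates",
    "  resample  --in DIR --out DIR [--seed N] subsampling experiment",
    "  fst       --in DIR --out DIR            global FST",
    "  prune     --in DIR --out DIR            LD-pruned SNP set",
    "  simulate  --out DIR [--seed N] [--scenario S]  synthetic study",
    "  run       --in DIR --out DIR [--seed N] full analysis",
    sep = "\n"
  )
}

.cliParse <- function(args, allowed) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      return(list(error = paste("unexpected argument:", a)))
    }
    key <- substring(a, 3L)
    if (!key %in% allowed) return(list(error = paste("unknown flag:", a)))
    if (i == length(args)) return(list(error = paste(a, "needs a value")))
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' Maps subcommands 1:1 onto package entry points; intended to be called
#' from a thin Rscript wrapper (see `system.file("scripts", "haploLD.R",
#' package = "haploLD")`). Logs to stderr; returns an exit status (0 on
#' success, 2 on usage errors, 1 on runtime failure) instead of quitting,
#' so it is testable in-process.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit status.
#' @export
haploLDCli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L) {
    message(.cliUsage())
    return(2L)
  }
  sub <- argv[1]
  known <- c(
    "stats", "ld", "decay", "rho", "resample", "fst", "prune",
    "simulate", "run"
  )
  if (!sub %in% known) {
    message("unknown subcommand: ", sub, "\n", .cliUsage())
    return(2L)
  }
  opts <- .cliParse(argv[-1], c(
    "in", "out", "seed", "map-scale", "scenario", "k", "B", "alpha"
  ))
  if (!is.null(opts$error)) {
    message(opts$error, "\n", .cliUsage())
    return(2L)
  }
  seed <- if (is.null(opts$seed)) 1L else as.integer(opts$seed)
  if (is.null(opts$out)) {
    message("--out is required\n", .cliUsage())
    return(2L)
  }
  needs_in <- sub != "simulate"
  if (needs_in && is.null(opts[["in"]])) {
    message("--in is required for '", sub, "'\n", .cliUsage())
    return(2L)
  }
  status <- tryCatch({
    if (sub == "simulate") {
      scen <- if (is.null(opts$scenario)) "panmictic" else opts$scenario
      study <- simulateStudy(studyConfig(scenario = scen, seed = seed))
      writeSimResult(study, opts$out)
      message("wrote simulated study to ", opts$out)
      return(0L)
    }
    cfg <- runConfig(
      inputDir = opts[["in"]], outDir = opts$out, seed = seed,
      mapScales = if (is.null(opts[["map-scale"]])) c(1, 10, 20) else
        as.numeric(opts[["map-scale"]]),
      resampleK = if (is.null(opts$k)) 8L else as.integer(opts$k),
      resampleB = if (is.null(opts$B)) 100L else as.integer(opts$B),
      alpha = if (is.null(opts$alpha)) 0.05 else as.numeric(opts$alpha)
    )
    hash <- configHash(cfg)
    inputs <- readStudyInputs(cfg$inputDir)
    if (!dir.exists(cfg$outDir)) dir.create(cfg$outDir, recursive = TRUE)
    if (sub == "run") {
      bundle <- runFullAnalysis(cfg)
      if (!isTRUE(bundle$manifest$complete)) return(1L)
      return(0L)
    }
    if (sub == "stats") {
      div <- summarizeLoci(inputs$alignments, inputs$popmap,
        scope = "all", missingPolicy = cfg$missingPolicy, alpha = cfg$alpha)
      .writeReportTsv(div, file.path(cfg$outDir, "diversity_pooled.tsv"),
        hash)
    } else if (sub == "ld" || sub == "prune") {
      ldset <- buildLdPairs(inputs$alignments, inputs$popmap,
        missingPolicy = cfg$ldMissingPolicy,
        correctionScope = cfg$correctionScope, alpha = cfg$alpha)
      if (sub == "ld") {
        .writeReportTsv(ldPairs(ldset),
          file.path(cfg$outDir, "ld_pairs_pooled.tsv"), hash)
        .writeReportTsv(ldSummary(ldset),
          file.path(cfg$outDir, "ld_summary_pooled.tsv"), hash)
      } else {
        pr <- pruneLinkedSnps(ldset)
        .writeReportTsv(pr$retained,
          file.path(cfg$outDir, "pruned_snps.tsv"), hash)
        .writeReportTsv(pr$removed,
          file.path(cfg$outDir, "pruned_removed.tsv"), hash)
      }
    } else if (sub == "decay") {
      ldset <- buildLdPairs(inputs$alignments, inputs$popmap,
        missingPolicy = cfg$ldMissingPolicy,
        correctionScope = cfg$correctionScope, alpha = cfg$alpha)
      rows <- list(.decayRow(fitHillWeir(ldset), "pooled",
        cfg$decayThreshold))
      for (ms in cfg$mapScales) {
        rows[[length(rows) + 1L]] <- .decayRow(
          fitDprimeDecay(ldset, mapScale = ms), "pooled",
          cfg$decayThreshold
        )
      }
      .writeReportTsv(do.call(rbind, rows),
        file.path(cfg$outDir, "decay_fits.tsv"), hash)
    } else if (sub == "rho") {
      rows <- list()
      lookups <- list()
      for (aln in inputs$alignments) {
        a <- dropEmptySequences(aln)
        if (nSequences(a) > 100) {
          message("skipping ", locusId(aln), ": n > 100")
          next
        }
        key <- as.character(nSequences(a))
        if (!key %in% names(lookups)) {
          lookups[[key]] <- buildLookup(nSequences(a),
            rhoGrid = seq(0, cfg$rhoGridMax, length.out = 21),
            nSims = cfg$rhoNSims, mutDraws = cfg$rhoMutDraws, seed = seed
          )
        }
        sites <- classifySites(a, "pairwise_available")
        est <- estimateRho(a, sites, lookups[[key]])
        rows[[length(rows) + 1L]] <- data.frame(
          locus_id = locusId(aln), computed = est$computed,
          rho_per_kb = est$rho_per_kb, rho_per_site = est$rho_per_site,
          rho_locus = est$rho_locus,
          flat_likelihood = est$flat_likelihood,
          stringsAsFactors = FALSE
        )
      }
      .writeReportTsv(do.call(rbind, rows),
        file.path(cfg$outDir, "rho_estimates.tsv"), hash)
    } else if (sub == "resample") {
      rs <- resampleStudy(inputs$alignments, inputs$popmap,
        k = cfg$resampleK, B = cfg$resampleB, seed = seed)
      .writeReportTsv(rs, file.path(cfg$outDir, "resample_summary.tsv"),
        hash)
    } else if (sub == "fst") {
      .writeReportTsv(globalFst(inputs$alignments, inputs$popmap),
        file.path(cfg$outDir, "fst.tsv"), hash)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}
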