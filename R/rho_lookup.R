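#' Canonical code of a 2x2 haplotype configuration
#'
#' Two-locus composite likelihoods do not depend on which allele is
#' labelled first at either site, nor on the order of the two sites, so
#' configurations are stored under the lexicographically smallest of the
#' eight equivalent count vectors, encoded in base `n + 1`.
#'
#' @param cfg integer matrix (or vector) with columns `n11,n10,n01,n00`
#'   summing to `n` per row.
#' @param n haploid sample size.
#' @return Integer vector of canonical codes.
#' @keywords internal
canonicalConfigCode <- function(cfg, n) {
  if (is.null(dim(cfg))) cfg <- matrix(cfg, nrow = 1L)
  a <- cfg[, 1L]; b <- cfg[, 2L]; c <- cfg[, 3L]; d <- cfg[, 4L]
  enc <- function(x, y, z, w) ((x * (n + 1) + y) * (n + 1) + z) * (n + 1) + w
  as.integer(pmin(
    enc(a, b, c, d), enc(c, d, a, b), enc(b, a, d, c), enc(d, c, b, a),
    enc(a, c, b, d), enc(b, d, a, c), enc(c, a, d, b), enc(d, b, c, a)
  ))
}

.decodeConfig <- function(code, n) {
  w <- code %% (n + 1); code <- code %/% (n + 1)
  z <- code %% (n + 1); code <- code %/% (n + 1)
  y <- code %% (n + 1); x <- code %/% (n + 1)
  cbind(n11 = x, n10 = y, n01 = z, n00 = w)
}

#' Build a two-locus composite-likelihood lookup table
#'
#' Tabulates, by coalescent simulation, the probability of each 2x2
#' haplotype configuration at a pair of segregating sites, for every value
#' on a grid of two-locus scaled recombination rates. Mutations are placed
#' uniformly by branch length on each marginal genealogy, i.e. the table is
#' the small-theta limit of conditioning on both sites segregating - an
#' excellent approximation at the conventional theta = 0.001 per site,
#' where double mutations are negligible. Add-one smoothing
#' (`(count + 1) / (nDraws + 1)`) prevents minus-infinity composite
#' log-likelihoods for configurations never observed at some grid value;
#' the same constant enters every grid point, so rate comparisons are
#' unaffected.
#'
#' @param n haploid sample size (2..100).
#' @param thetaPerSite nominal per-site theta recorded in the table
#'   (default 0.001).
#' @param rhoGrid increasing nonnegative grid of two-locus rho values
#'   starting at 0 (default 21 points on `[0, 100]`).
#' @param nSims coalescent genealogies simulated per grid point.
#' @param mutDraws conditional mutation placements per genealogy (draws are
#'   correlated within a genealogy but unbiased; they amortize the
#'   genealogy cost).
#' @param seed RNG seed; identical seeds give identical tables.
#' @return A [LookupTable-class].
#' @export
buildLookup <- function(n, thetaPerSite = 0.001,
                        rhoGrid = seq(0, 100, length.out = 21),
                        nSims = 20000L, mutDraws = 4L, seed = 1L) {
  stopifnot(n >= 2, n <= 100, length(rhoGrid) >= 2, rhoGrid[1] == 0)
  if (is.unsorted(rhoGrid, strictly = TRUE)) stop("rhoGrid must be increasing")
  if (length(rhoGrid) > 101L) stop("rhoGrid longer than 101 points")
  set.seed(seed)
  nDraws <- as.integer(nSims) * as.integer(mutDraws)
  counts <- list()
  for (g in seq_along(rhoGrid)) {
    cfg <- .twoLocusConfigs(as.integer(n), rhoGrid[g], as.integer(nSims),
      as.integer(mutDraws))
    code <- canonicalConfigCode(cfg, n)
    counts[[g]] <- table(code)
    if (sum(counts[[g]]) != nDraws) {
      stop("lookup cell at rho = ", rhoGrid[g], " lost simulations")
    }
  }
  codes <- sort(unique(as.integer(unlist(lapply(counts, names)))))
  ll <- matrix(0, length(codes), length(rhoGrid))
  for (g in seq_along(rhoGrid)) {
    cnt <- integer(length(codes))
    idx <- match(as.integer(names(counts[[g]])), codes)
    cnt[idx] <- as.integer(counts[[g]])
    ll[, g] <- log((cnt + 1) / (nDraws + 1))
  }
  new("LookupTable",
    n = as.integer(n), thetaPerSite = thetaPerSite,
    rhoGrid = as.numeric(rhoGrid), configCode = codes, logLik = ll,
    nDraws = nDraws, seed = as.integer(seed)
  )
}

#' Write a lookup table to a text likelihood file
#'
#' The dialect follows the layout of composite-likelihood lookup files:
#' a header with the sample size, theta, grid and provenance, then one row
#' per haplotype configuration (`n11 n10 n01 n00 : log-likelihood at each
#' grid point`). The format is documented fully in the file header itself.
#'
#' @param table a [LookupTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeLookupTable <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("haploLD two-locus likelihood table v1", con)
  writeLines(paste("n", table@n), con)
  writeLines(paste("theta_per_site", format(table@thetaPerSite, digits = 17)), con)
  writeLines(paste("n_draws", table@nDraws), con)
  writeLines(paste("seed", table@seed), con)
  writeLines(paste(
    "rho_grid",
    paste(format(table@rhoGrid, digits = 17), collapse = " ")
  ), con)
  writeLines(paste("n_configs", length(table@configCode)), con)
  cfg <- .decodeConfig(table@configCode, table@n)
  for (i in seq_along(table@configCode)) {
    writeLines(paste(
      paste(cfg[i, ], collapse = " "), ":",
      paste(format(table@logLik[i, ], digits = 17), collapse = " ")
    ), con)
  }
  invisible(path)
}

#' Read a lookup table from a text likelihood file
#'
#' Parses the dialect written by [writeLookupTable()]. Parse failures
#' report the offending line number. If `thetaPerSite` is supplied and
#' disagrees with the file header, a warning is emitted and the header
#' value wins.
#'
#' @param path likelihood file.
#' @param thetaPerSite optional expected theta for validation.
#' @return A [LookupTable-class].
#' @export
readLookupTable <- function(path, thetaPerSite = NULL) {
  lines <- readLines(path)
  fail <- function(i, why) {
    stop("lookup parse error at line ", i, " of ", path, ": ", why)
  }
  if (length(lines) < 7L) fail(length(lines), "file truncated")
  if (!startsWith(lines[1L], "haploLD two-locus likelihood table")) {
    fail(1L, "unrecognized header")
  }
  getField <- function(i, key, n_values = 1L) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(parts) < 1L + n_values || parts[1L] != key) {
      fail(i, paste("expected", key))
    }
    vals <- suppressWarnings(as.numeric(parts[-1L]))
    if (anyNA(vals)) fail(i, paste("non-numeric", key))
    vals
  }
  n <- as.integer(getField(2L, "n"))
  theta <- getField(3L, "theta_per_site")
  nDraws <- as.integer(getField(4L, "n_draws"))
  seed <- as.integer(getField(5L, "seed"))
  grid_parts <- strsplit(trimws(lines[6L]), "\\s+")[[1L]]
  if (grid_parts[1L] != "rho_grid") fail(6L, "expected rho_grid")
  grid <- as.numeric(grid_parts[-1L])
  if (anyNA(grid)) fail(6L, "non-numeric rho_grid")
  n_cfg <- as.integer(getField(7L, "n_configs"))
  if (length(lines) < 7L + n_cfg) {
    fail(length(lines), paste("file truncated:", n_cfg, "configurations expected"))
  }
  codes <- integer(n_cfg)
  ll <- matrix(NA_real_, n_cfg, length(grid))
  for (i in seq_len(n_cfg)) {
    ln <- 7L + i
    parts <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    sep <- which(parts == ":")
    if (length(sep) != 1L || sep != 5L) fail(ln, "expected 'n11 n10 n01 n00 : ...'")
    cfg <- suppressWarnings(as.integer(parts[1:4]))
    vals <- suppressWarnings(as.numeric(parts[-(1:5)]))
    if (anyNA(cfg) || anyNA(vals) || length(vals) != length(grid)) {
      fail(ln, "malformed configuration row")
    }
    codes[i] <- canonicalConfigCode(cfg, n)
    ll[i, ] <- vals
  }
  if (!is.null(thetaPerSite) && !isTRUE(all.equal(theta, thetaPerSite))) {
    warning(
      "lookup header theta_per_site (", theta, ") differs from configured (",
      thetaPerSite, "); header wins"
    )
  }
  ord <- order(codes)
  new("LookupTable",
    n = n, thetaPerSite = theta, rhoGrid = grid,
    configCode = codes[ord], logLik = ll[ord, , drop = FALSE],
    nDraws = nDraws, seed = seed
  )
}
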