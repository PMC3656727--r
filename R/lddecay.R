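#' Drift expectation of r2 at scaled recombination C
#'
#' The sample-size-adjusted expectation of r2 between two biallelic sites
#' separated by scaled recombination `C = rho_bp * distance`:
#' `E[r2] = (10+C)/((2+C)(11+C)) * (1 + (3+C)(12+12C+C^2)/(n(2+C)(11+C)))`.
#' Strictly decreasing in `C`; tends to `10/22` as `C -> 0, n -> Inf` and
#' to 0 as `C -> Inf`.
#'
#' @param C nonnegative scaled recombination (vectorized).
#' @param n haploid sample size (>= 2).
#' @return Expected r2, same length as `C`.
#' @export
expectedR2 <- function(C, n) {
  stopifnot(all(C >= 0), n >= 2)
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

.pairsInput <- function(pairs) {
  if (is(pairs, "LDPairSet")) ldPairs(pairs) else as.data.frame(pairs)
}

.fitScalar <- function(grid, rss_fun) {
  # deterministic multi-start: evaluate a fixed grid, refine the best
  # bracket with golden-section; the returned value never exceeds the best
  # grid point.
  rss <- vapply(grid, rss_fun, 1)
  b <- which.min(rss)
  lo <- grid[max(1L, b - 1L)]
  hi <- grid[min(length(grid), b + 1L)]
  best <- list(par = grid[b], rss = rss[b])
  if (hi > lo) {
    # optimize()'s default tol is absolute and far too coarse for small
    # rates; scale it to the bracket so recovery is sharp at any magnitude
    opt <- optimize(rss_fun, lower = lo, upper = hi,
      tol = max(1e-12, 1e-9 * hi))
    if (opt$objective < best$rss) best <- list(par = opt$minimum, rss = opt$objective)
  }
  best
}

#' Fit the Hill-Weir r2 decay curve
#'
#' Unweighted nonlinear least squares of observed pairwise r2 against
#' physical distance, fitting a single nonnegative `rho_bp` in
#' `E[r2](rho_bp * d, n)` (see [expectedR2()]). All pairs enter unbinned.
#' Optimization evaluates a fixed log-spaced grid of starting values and
#' refines the best bracket, so the fit is deterministic.
#'
#' @param pairs an [LDPairSet-class] or data.frame with columns
#'   `distance_bp` and `r2`.
#' @param n sample size for the expectation; by default the mean number of
#'   complete haplotypes per pair (recorded in the fit).
#' @return A [DecayFit-class] with `model = "hill_weir_r2"`.
#' @export
fitHillWeir <- function(pairs, n = NULL) {
  p <- .pairsInput(pairs)
  if (nrow(p) < 5L) stop("need at least 5 pairs to fit the decay curve")
  if (any(p$distance_bp <= 0)) stop("pair distances must be positive")
  if (is.null(n)) {
    if (!all(c("n11", "n12", "n21", "n22") %in% names(p))) {
      stop("supply n explicitly when pairs carry no haplotype counts")
    }
    n <- mean(p$n11 + p$n12 + p$n21 + p$n22)
  }
  ill <- length(unique(p$distance_bp)) == 1L
  if (ill) {
    warning("all pair distances are equal: the decay fit is ill-conditioned")
  }
  d <- p$distance_bp
  r2 <- p$r2
  rss_fun <- function(rho_bp) sum((r2 - expectedR2(rho_bp * d, n))^2)
  grid <- c(0, 10^seq(-9, 1, length.out = 41))
  best <- .fitScalar(grid, rss_fun)
  new("DecayFit",
    model = "hill_weir_r2", param = best$par, n = n,
    mapScale = NA_real_, mapping = NA_character_, rss = best$rss,
    nPairs = nrow(p), illConditioned = ill
  )
}

#' Distance-to-recombination-fraction mapping
#'
#' Converts physical distance to a recombination fraction under an assumed
#' map scale (`mapScale` cM per Mb; 1 by default, i.e. 1 cM = 1 Mb).
#' `"linear"` caps `r` at 0.5; `"haldane"` applies the Haldane map
#' function (differences are negligible at kb scales).
#'
#' @param d distance in bp (vectorized).
#' @param mapScale cM per Mb.
#' @param mapping `"linear"` or `"haldane"`.
#' @return Recombination fraction in `[0, 0.5]`.
#' @export
recombinationFraction <- function(d, mapScale = 1,
                                  mapping = c("linear", "haldane")) {
  mapping <- match.arg(mapping)
  morgans <- mapScale * d / 1e8 # d/1e6 Mb * mapScale cM/Mb / 100
  if (mapping == "linear") pmin(0.5, morgans) else 0.5 * (1 - exp(-2 * morgans))
}

#' Fit the D'(t) = (1 - r)^t decay
#'
#' Least-squares fit of the number of generations `t` since complete
#' disequilibrium, with the recombination fraction between a pair of SNPs
#' obtained from their physical distance via [recombinationFraction()].
#' The default assumes 1 cM = 1 Mb; alternative map scales (e.g. 0.5, 10,
#' 20 cM/Mb) rescale the fitted `t` inversely at small `r`.
#'
#' @param pairs an [LDPairSet-class] or data.frame with columns
#'   `distance_bp` and `dprime`.
#' @param mapScale cM per Mb (default 1).
#' @param mapping distance-to-r mapping (default `"linear"`).
#' @return A [DecayFit-class] with `model = "dprime_generations"`.
#' @export
fitDprimeDecay <- function(pairs, mapScale = 1, mapping = "linear") {
  p <- .pairsInput(pairs)
  if (nrow(p) < 5L) stop("need at least 5 pairs to fit the decay curve")
  r <- recombinationFraction(p$distance_bp, mapScale, mapping)
  dp <- p$dprime
  if (all(dp == 1)) {
    return(new("DecayFit",
      model = "dprime_generations", param = 0, n = NA_real_,
      mapScale = mapScale, mapping = mapping, rss = 0,
      nPairs = nrow(p), illConditioned = FALSE
    ))
  }
  rss_fun <- function(t) sum((dp - (1 - r)^t)^2)
  grid <- c(0, 10^seq(-2, 7, length.out = 46))
  best <- .fitScalar(grid, rss_fun)
  new("DecayFit",
    model = "dprime_generations", param = best$par, n = NA_real_,
    mapScale = mapScale, mapping = mapping, rss = best$rss,
    nPairs = nrow(p), illConditioned = FALSE
  )
}

#' Predicted LD at given distances from a fitted decay curve
#'
#' @param fit a [DecayFit-class].
#' @param d distances in bp (vectorized).
#' @return Predicted r2 or D' values.
#' @export
predictDecay <- function(fit, d) {
  if (fit@model == "hill_weir_r2") {
    expectedR2(fit@param * d, fit@n)
  } else {
    (1 - recombinationFraction(d, fit@mapScale, fit@mapping))^fit@param
  }
}

#' Distance at which a fitted decay curve crosses a threshold
#'
#' Smallest integer distance `d >= 1` at which the fitted curve falls
#' below `threshold`, found by doubling bracket plus integer bisection
#' (the fitted curves are monotone non-increasing in distance). A curve
#' already below the threshold at `d = 1` reports 0 bp
#' (status `"below_at_origin"`); a curve that never falls below it within
#' `dMax` reports `Inf` (status `"never_reached"`).
#'
#' @param fit a [DecayFit-class].
#' @param threshold LD threshold (default 0.2).
#' @param dMax search limit in bp (default 1e9).
#' @return List with `bp` (integer distance, 0, or Inf) and `status`
#'   (`"ok"`, `"below_at_origin"`, `"never_reached"`).
#' @export
crossingDistance <- function(fit, threshold = 0.2, dMax = 1e9) {
  if (predictDecay(fit, 1) < threshold) {
    return(list(bp = 0, status = "below_at_origin"))
  }
  hi <- 1
  while (predictDecay(fit, hi) >= threshold) {
    hi <- hi * 2
    if (hi > dMax) {
      return(list(bp = Inf, status = "never_reached"))
    }
  }
  lo <- hi / 2 # >= threshold here
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (predictDecay(fit, mid) < threshold) hi <- mid else lo <- mid
  }
  list(bp = hi, status = "ok")
}
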