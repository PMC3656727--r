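# Independent reference implementations used to check package results.
# These deliberately avoid the package's own code paths.

# Two-sided Fisher exact p by direct enumeration with log-gamma arithmetic.
oracleFisherP <- function(n11, n12, n21, n22) {
  n <- n11 + n12 + n21 + n22
  r <- n11 + n12
  cc <- n11 + n21
  if (r == 0 || cc == 0 || r == n || cc == n) {
    return(1)
  }
  lp <- function(k) {
    lchoose(cc, k) + lchoose(n - cc, r - k) - lchoose(n, r)
  }
  ks <- max(0, r + cc - n):min(r, cc)
  probs <- exp(vapply(ks, lp, 1))
  p_obs <- exp(lp(n11))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# r2 and D' straight from the definitions.
oracleLd <- function(n11, n12, n21, n22) {
  m <- n11 + n12 + n21 + n22
  pA <- (n11 + n12) / m
  pB <- (n11 + n21) / m
  D <- n11 / m - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  dmax <- if (D > 0) {
    min(pA * (1 - pB), (1 - pA) * pB)
  } else if (D < 0) {
    min(pA * pB, (1 - pA) * (1 - pB))
  } else {
    1
  }
  list(r2 = r2, dprime = abs(D) / dmax)
}

# Mean pairwise per-site difference by brute force over all sequence pairs
# (complete-deletion columns only).
oraclePi <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  called <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, called, drop = FALSE]
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) tot <- tot + sum(m[i, ] != m[j, ])
  }
  list(pi_total = tot / choose(n, 2), L = ncol(m))
}

# A small fully-called alignment with hand-checkable properties:
# sites 3 (G4/C2, informative), 5 (A5/T1, singleton), 8 (T5/A1, singleton),
# 10 (C4/A2, informative); haplotype multiset {2, 2, 1, 1}.
tinyAlignment <- function() {
  LocusAlignment("tiny", c(
    s1 = "ACGTACGTAC", s2 = "ACGTACGTAC", s3 = "ACCTACGTAA",
    s4 = "ACCTACGTAA", s5 = "ACGTACGAAC", s6 = "ACGTTCGTAC"
  ))
}

# Frozen oracle values for tinyAlignment (computed independently with
# scipy/python from the closed-form definitions).
tinyOracle <- list(
  S = 4L,
  pi_total = 52 / 30,
  a1 = 2.283333333333333,
  theta_locus = 1.7518248175182483,
  d = -0.0572222934960183,
  d_beta_p = 0.9633499876293579,
  H = 4L,
  Hd = 0.8666666666666667
)

# Frozen Fisher p-values (scipy.stats.fisher_exact, two-sided).
frozenFisher <- list(
  list(tab = c(10, 2, 3, 9), p = 0.012278137799742322),
  list(tab = c(8, 1, 2, 7), p = 0.015220074043603456),
  list(tab = c(5, 5, 5, 5), p = 1.0)
)

# Frozen LD statistics for table (10, 2, 3, 9).
frozenLd <- list(r2 = 0.3426573426573428, dprime = 0.6363636363636365)

# One shared lookup table per sample size, built once per test run.
.lookupCache <- new.env(parent = emptyenv())
cachedLookup <- function(n, nSims = 2500L) {
  key <- paste0("n", n)
  if (is.null(.lookupCache[[key]])) {
    .lookupCache[[key]] <- buildLookup(n,
      rhoGrid = seq(0, 100, length.out = 21),
      nSims = nSims, mutDraws = 4L, seed = 99L
    )
  }
  .lookupCache[[key]]
}

# Independent coalescent replicates (S, pi_total, D) at n = 50,
# theta_locus = 10 from an established external simulator, frozen as a
# fixture for the distributional cross-check.
oracleCoalescentReplicates <- function() {
  read.table(test_path("fixtures", "coalescent_oracle_n50_theta10.tsv"),
    header = TRUE, sep = "\t"
  )
}

# Tajima's D from raw mutation records of simulateAncestry, using only
# closed-form constants (no package site-classification machinery).
dFromAncestry <- function(muts) {
  n <- muts$n
  S <- length(muts$carriers)
  if (S == 0) {
    return(NA_real_)
  }
  k <- vapply(muts$carriers, length, 1L)
  pit <- sum(2 * k * (n - k) / (n * (n - 1)))
  cs <- tajimaConstants(n)
  (pit - S / cs$a1) / sqrt(cs$e1 * S + cs$e2 * S * (S - 1))
}
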