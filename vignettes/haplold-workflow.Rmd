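---
title: "Analyzing haploid multilocus alignments with haploLD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing haploid multilocus alignments with haploLD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploLD)
```

haploLD analyzes phased haploid sequence alignments — one recombinant
haplotype per sampled individual, as obtained from conifer
megagametophytes. This vignette walks through the full workflow on
simulated data: site classification, diversity statistics, linkage
disequilibrium (LD), LD decay, composite-likelihood estimation of the
population recombination rate, subsampling sensitivity, and the
one-call pipeline.

## Data model

A `LocusAlignment` holds equal-length haploid sequences for one locus;
a `PopulationMap` assigns individuals to populations and optionally
carries coordinates. Alignments are read from FASTA
(`readLocusAlignment`), population maps from TSV
(`readPopulationMap`). Ambiguity codes other than `N` are converted to
`N` with a warning.

```{r simulate}
truth <- SimTruth("demo", thetaPerSite = 0.005, rhoPerSite = 0.01,
  locusLength = 2000L, samplesPerPopulation = 24L,
  growthRate = 2, seed = 42L)
sim <- simulateLocus(truth)
aln <- sim$alignment
aln
```

## Site classification and missing-data policies

Every downstream statistic starts from `classifySites`, which excludes
alignment columns containing gaps or more than two bases and flags the
rest as monomorphic, singleton or parsimony-informative. Two policies
govern missing data:

* `complete_deletion` — a column with any `N` is dropped for all
  sequence-level statistics (the conservative classical convention);
* `pairwise_available` — each column is analyzed over the sequences
  actually called there (appropriate for LD, where each pair of sites
  uses the jointly-called haplotypes).

```{r sites}
sites <- classifySites(aln, "pairwise_available")
head(siteData(sites))
```

## Diversity statistics

`summarizeLocus` computes the number of segregating sites S,
singletons, Watterson's θ per site, nucleotide diversity π, haplotype
number and diversity, and Tajima's D. Significance of D uses the
beta-distribution approximation of its null density
(`tajimaBetaPvalue`); a coalescent-simulated alternative is available
as `tajimaSimulatedPvalue`.

```{r diversity}
summarizeLocus(aln)
```

Per-population tables (and Hudson-style global F~ST~ via `globalFst`)
require a `PopulationMap`; populations with fewer than 4 sequences are
reported with `computed = FALSE` rather than silently dropped.

## Linkage disequilibrium

`buildLdPairs` evaluates every pair of parsimony-informative sites
within each locus: r², D′, and a two-sided Fisher exact test on the
2×2 haplotype table, using the jointly-called haplotypes per pair
(pairs with fewer than 4 are dropped and logged). Bonferroni
correction is applied globally or per locus.

```{r ld}
ld <- buildLdPairs(list(aln), list(sites))
ldSummary(ld)
```

`pruneLinkedSnps` greedily thins sites until no significant pair
remains, preferring to remove the site with more missing data (then
the downstream one).

## LD decay with distance

`fitHillWeir` fits the Hill–Weir sampling expectation of r² as a
function of C = ρ·distance for sample size n. Note its large-distance
asymptote is 1/n (the sampling floor), not 0. `fitDprimeDecay` fits
the recurrence D′(t) = (1 − r)^t, converting distance to recombination
fraction through a configurable map scale (cM per Mb).
`crossingDistance` reports where a fitted curve first drops below a
threshold, with explicit `below_at_origin` / `never_reached`
conventions.

```{r decay}
fit <- fitHillWeir(ld)
fit
crossingDistance(fit, 0.2)
```

## Population recombination rate

`buildLookup` tabulates Monte Carlo two-locus likelihoods on a ρ grid
for a fixed sample size; `estimateRho` projects each informative pair
onto the table's sample size and maximizes the composite likelihood
over the grid (with interpolation), returning ρ per kb, per site, per
locus and the full profile. Tables round-trip through a plain-text
format (`writeLookupTable` / `readLookupTable`) so an expensive table
is built once and reused.

```{r rho}
lk <- buildLookup(24, nSims = 1000L, seed = 7L)
est <- estimateRho(aln, sites, lk)
c(rho_per_kb = est$rho_per_kb, flat = est$flat_likelihood)
rhoOverTheta(est, summarizeLocus(aln)$theta_w)
```

## The simulator and the default study design

`simulateAncestry` is a coalescent simulator with recombination,
exponential growth and island migration; `simulateLocus` adds
mutations and emulates a paired-end amplicon design by masking
everything outside windows at the two amplicon ends
(`endMaskLayout`), with per-individual read-length jitter.
`studyConfig()` encodes a range-wide 11-locus, 128-tree,
10-population design; its default mutation parameter was calibrated
once so that the realized per-site Watterson's θ of simulated loci
matches the empirical value of ≈ 0.005, and is frozen at
`thetaPerSite = 0.0032`. `simulateStudy` + `writeSimResult` produce a
complete on-disk input bundle (FASTA, population map, truth JSON,
config).

## Subsampling sensitivity

`resampleStatistics` redraws k individuals without replacement B times
and recomputes D and π within each draw; draws that are monomorphic
have undefined D and are excluded with a count. `resampleStudy` shares
draws across loci by default (one "resampled population" of trees per
replicate), and `latitudeTrendTable` aggregates mean D per population
against latitude with a Spearman rank correlation.

## Pipeline

`runFullAnalysis(runConfig(inputDir, outDir, seed))` runs the whole
analysis on a directory of FASTA files plus `popmap.tsv`: pooled and
per-population diversity, LD and its summary, decay fits, ρ (pooled
only when n ≤ 100), F~ST~, resampling and the latitude trend. Every
output TSV carries a `# config_hash:` header (an MD5 of the settings,
ignoring paths) and a `manifest.json` records the run. The same
functionality is available from the shell through
`inst/scripts/haploLD.R`.

## Reference tables

Summary tables from a published Norway spruce diversity survey are
shipped as plain-text fixtures and accessible via
`publishedLocusSummary()`, `publishedLdSummary()` and
`studyDesignTable()`; they anchor the test suite's arithmetic checks
and the default simulation design.

```{r published}
head(publishedLocusSummary())
```
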