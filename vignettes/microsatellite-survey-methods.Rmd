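---
title: "Methods: microsatellite surveys and the phylogenetic breakdown of coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsatellite surveys and the phylogenetic breakdown of coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrphylo)
```

## The problem

Eukaryote genomes carry tandem repeats of 1-6 bp motifs (microsatellites,
SSRs) at densities far above random expectation. Whether the amount and
composition of this repeat fraction carries phylogenetic signal — whether
related species resemble each other — can be asked with a genome *snapshot*:
a few Mb to ~100 Mb of single-end shotgun reads per species gives a
near-random sample of each genome without the assembly biases that drop
repetitive regions. `ssrphylo` implements that survey design end to end:
scan reads for perfect repeat tracks, reduce each species to a coverage and
composition profile, and test autocorrelation of coverage across the clades
of a dated phylogeny.

## Repeat detection model

A *track* is a maximal perfect tandem array of a primitive unit of length
$u \in \{1,\dots,6\}$: no extension left or right preserves the period, the
unit is not itself a repetition of a shorter unit, and any non-ACGT symbol
breaks the array. Qualification thresholds are counted in *full* units:

* homopolymers ($u = 1$): at least 12 repetitions,
* di- to hexanucleotides ($u = 2..6$): at least 5 repetitions.

A partial final unit (e.g. the trailing `A` of `ACACACACACA`) extends the
reported track and its base count but never contributes to qualification;
`scan_config(count_partial_units = FALSE)` switches to whole-unit base
counting, since survey literature is split on this convention and the raw
scripts behind published tables rarely say which was used. Either convention
is applied uniformly, so cross-species comparisons are unaffected.

Motif classes are named by the alphabetical minimum over all circular
permutations of the unit and of its reverse complement (`AAC` stands for
`AAC, ACA, CAA, TTG, TGT, GTT`), with A < C < G < T. Primitivity plus
canonical naming yields exactly 2, 4, 10, 33, 102 and 350 classes at unit
lengths 1-6; these counts are asserted against an independent orbit-closure
enumeration in the test suite.

One geometric subtlety: two maximal arrays of the same period but different
motifs can abut and share up to $u-1$ boundary bases
(`ATATATA|CACAC` shares one base). We report both arrays in full rather than
inventing a precedence rule; such junctions are rare in practice and the
alternative (trimming) would make reported tracks non-maximal. Tracks of
*different* unit lengths may also overlap and are each reported in full,
since homopolymers are tallied separately and overlapping qualifying di-hexa
arrays are rare.

The scanner compares the byte sequence with itself at lag $u$ and takes
run-length encodings, which is $O(6n)$ in vectorised R; at snapshot scale
(~100 Mb) this removes any need for compiled code. Its reference is a naive
per-start extension oracle, with equivalence checked on thousands of random
repeat-enriched sequences.

## Coverage and composition

For a species with $B$ sequenced bases, *microsatellite coverage* is
(bases in di-hexa tracks)$/B \times 10^6$ — bases per Mb, with Mb $= 10^6$
exactly and no rounding. Homopolymer coverage is carried separately
everywhere and only enters a total via an explicit
`include_homopolymers = TRUE`, because the 12-repetition homopolymer cutoff
is not commensurable with the 5-repetition microsatellite cutoff.
Composition is reported two ways: by unit length (share of each $u$ in the
combined repeat bases, including homopolymers) and by motif within a unit
length (each motif's bases over all bases of that unit length). GC content
is computed over all bases, including repeat tracks — whether published GC
values excluded repeat tracks is typically unstated, and at observed repeat
densities the difference is far below the precision of any comparison made
with it.

## Phylogenetic autocorrelation

Given an ultrametric tree with branch lengths in My (leaves at age 0 within
a relative tolerance of $10^{-6}$), species are pooled, for each cutoff age
$t$, into the *largest* clades whose MRCA is strictly younger than $t$
("younger than" is strict; a leaf whose parent is at or above the cutoff
is a singleton clade). On log-transformed coverage $x$ we compute Moran's

$$I = \frac{n}{W_0} \, \frac{\sum_{i \ne j} w_{ij}(x_i-\bar x)(x_j-\bar x)}
      {\sum_i (x_i-\bar x)^2},$$

with binary same-clade weights, each nonzero row rescaled to sum 1 and
$W_0$ the total weight. Under the randomisation null $E[I] = -1/(n-1)$; the
variance uses the kurtosis-robust (randomisation) moments, and the p-value
is two-sided Gaussian. Singleton-clade rows stay all-zero and enter only
through the denominator, keeping $n$ equal to the species count used in
$E[I]$. The correlogram evaluates $I$ at cutoffs 50 My and multiples of
100 My by default, reporting undefined cutoffs (all-singleton partitions,
zero variance) as `NA` rows rather than dropping them.

Numerical choices worth recording:

* **Log base.** The natural log is used; since $I$ is invariant to affine
  changes of the trait, the base is observationally irrelevant (asserted as
  a property test).
* **Null variant.** Published surveys rarely state whether the normality or
  randomisation variance was used; we use randomisation and arbitrate with a
  permutation oracle (10,000 shuffles), which agrees with the Gaussian
  p-value to well within 0.03 in our tests. Exact third-decimal
  reproduction of a published $I$'s p-value can still depend on the
  original software's weight normalisation.
* **Group tests.** The Wilcoxon rank-sum statistic is
  $W = \#\{x_i > y_j\} + \tfrac12\#\{x_i = y_j\}$, which depends on which
  group is named first; both orientations are reported
  ($W_{xy} + W_{yx} = n_1 n_2$). Spearman's $\rho$ is the Pearson
  correlation of mid-ranks with a t-approximate p-value.

## What the simulator emulates — and what it does not

`simulate_reads()` produces 454-scale reads (truncated Gaussian lengths,
default $350 \pm 100$ bp, floor 50 bp — the scale, not the error model, of
that platform) with i.i.d. background bases at a chosen GC and planted
perfect arrays recorded in a truth table. The i.i.d. background keeps the
chance rate of qualifying arrays analytically small, so planted coverage is
recoverable within tight bounds; it deliberately does *not* emulate real
repeat landscapes, homopolymer sequencing error, transposable-element
structure, or compound/interrupted repeats. A green recovery test therefore
establishes scanner correctness, not realism of the background.

`simulate_yule_tree()` (pure birth, rescaled to an exact root age) and
`simulate_trait()` (Brownian motion with per-branch variance
$\sigma^2 \times$ length, or white noise) provide the statistical structure
the correlogram assumes: similarity decaying with divergence time under BM,
none under white noise. Defaults used in the property suite — 40 leaves,
root age 900 My, cutoffs 50 then 100..900 My, 100 replicates — mirror a
deep animal-phylogeny survey at desk scale.

One expectation commonly held for correlograms does **not** transfer to
this pooling scheme, and we record it as a known limitation rather than
hiding it: with *cumulative* same-clade weights, a Brownian trait keeps a
positive mean $I$ even at the deepest cutoff (~+0.16 at the root age in the
default suite), because the root's child clades retain distinct Brownian
means and $I$ is scale-invariant. The familiar "autocorrelation turns
negative at large distances" behaviour belongs to distance-*class* weights
(pairs within a divergence band). Empirical surveys that observe deep-cutoff
breakdown are therefore seeing faster-than-BM signal decay, not a BM
artefact; the corresponding deep-cutoff assertion in the acceptance suite is
deliberately left failing with this analysis.

## Design decisions on the open points

* Non-primitive input to `canonical_motif()` is reduced to its primitive
  root (`ACAC` → `AC`) instead of erroring, which makes "canonical motifs
  are always primitive" an invariant the scanner can rely on.
* The profile CSV mirrors the survey-supplement layout (species, free-text
  taxonomy columns, total length, GC, one column per canonical motif,
  ordered by unit length then alphabetically); a `col_map` override names
  foreign columns instead of guessing them, and motif-like headers that are
  not canonical names are rejected by name.
* Run configuration files are JSON (not TOML): no TOML parser is available
  in the supported dependency set, and JSON round-trips through `jsonlite`
  losslessly, including the run manifests written beside simulator outputs.
* Taxonomy labels are opaque strings; no taxonomy-database validation is
  attempted (it would add a network dependency).

## Limitations

* Only perfect repeats are modelled; degenerate/compound microsatellites
  and quality/adapter handling are out of scope (inputs are assumed
  post-platform-filtering).
* The reader loads read sets into memory; at the tens-of-Mb snapshot scale
  this is comfortable, but the design would need chunked streaming for
  whole-genome resequencing inputs.
* Statistics on published survey tables require the table itself; the
  package ships only synthetic stand-ins (clearly labelled) and the
  machinery to analyse the real file when supplied.
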