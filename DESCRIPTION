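Package: ssrphylo
Title: Microsatellite Surveys from Genome Shotgun Reads with Phylogenetic
    Autocorrelation
Version: 0.1.0
Authors@R:
    person("ssrphylo", "developers", email = "ssrphylo@example.org",
           role = c("aut", "cre"))
Description: Detects perfect microsatellite (SSR) tracks of unit length 1-6
    in genome shotgun reads, names motifs canonically (alphabetical minimum
    over circular permutations and reverse complements), aggregates
    per-species coverage and composition profiles, and tests phylogenetic
    autocorrelation of coverage with Moran's I correlograms over clade
    partitions of an ultrametric tree at divergence-time cutoffs, plus
    Wilcoxon rank-sum group comparisons and Spearman correlations with GC
    content.  Includes a seeded simulator for 454-style reads with planted
    repeat tracks and for ultrametric trees with Brownian-motion or
    white-noise traits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
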