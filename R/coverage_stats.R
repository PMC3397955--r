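# Per-species aggregation: coverage per Mb, composition by unit length,
# motif proportions within a unit length, GC content.
#
# Convention inherited from the survey design: "microsatellite coverage"
# means bases in di- to hexanucleotide tracks per Mb of sequence;
# homopolymer tracks (>= 12 bases) are tallied separately and only enter a
# total when explicitly requested.

new_species_profile <- function(species_id, taxonomy, total_bases,
                                gc_fraction, bases_by_motif) {
  structure(list(species_id = species_id,
                 taxonomy = taxonomy,
                 total_bases = total_bases,
                 gc_fraction = gc_fraction,
                 bases_by_motif = bases_by_motif),
            class = "species_profile")
}

#' Build a per-species microsatellite profile
#'
#' Sums track base counts by canonical motif over the full registry of
#' canonical classes (unit lengths 1-6), alongside sequence totals.
#'
#' @param tracks Track data frame as returned by [scan_sequence()] /
#'   [scan_reads()].
#' @param total_bases Total number of sequenced bases for the species.
#' @param gc_count Number of G/C bases in the sequences.
#' @param species_id Species name.
#' @param taxonomy Optional named character vector of taxonomic labels
#'   (e.g. `c(phylum = "Chordata", class = "Aves")`); stored verbatim.
#' @return An object of class `species_profile` with fields `species_id`,
#'   `taxonomy`, `total_bases`, `gc_fraction` and `bases_by_motif` (named
#'   numeric over every canonical motif class).
#' @examples
#' sc <- scan_reads(c(r1 = paste0(strrep("AC", 8), strrep("G", 30))))
#' p <- build_profile(sc$tracks, sc$total_bases, sc$gc_count, "demo sp.")
#' total_coverage(p)
#' @export
build_profile <- function(tracks, total_bases, gc_count, species_id,
                          taxonomy = character()) {
  if (!is.numeric(total_bases) || length(total_bases) != 1L ||
      total_bases <= 0)
    stop("total_bases must be a single positive number", call. = FALSE)
  classes <- all_motif_classes(1:6)
  bases <- stats::setNames(numeric(length(classes)), classes)
  if (nrow(tracks)) {
    bad <- setdiff(unique(tracks$canonical_motif), classes)
    if (length(bad))
      stop("unknown canonical motif(s) in tracks: ",
           paste(bad, collapse = ", "), call. = FALSE)
    sums <- tapply(tracks$track_len, tracks$canonical_motif, sum)
    bases[names(sums)] <- as.numeric(sums)
  }
  new_species_profile(species_id, taxonomy, as.numeric(total_bases),
                      gc_count / total_bases, bases)
}

#' @export
print.species_profile <- function(x, ...) {
  cat("species_profile:", x$species_id, "\n")
  if (length(x$taxonomy))
    cat("  taxonomy:", paste(x$taxonomy, collapse = " / "), "\n")
  cat(sprintf("  total bases: %s  GC: %.3f\n",
              format(x$total_bases, big.mark = ","), x$gc_fraction))
  cat(sprintf("  microsatellite coverage (di-hexa): %.1f bases/Mb\n",
              total_coverage(x)))
  cat(sprintf("  homopolymer coverage: %.1f bases/Mb\n",
              homopolymer_coverage(x)))
  invisible(x)
}

.unit_lengths_of <- function(p) nchar(names(p$bases_by_motif))

#' Total microsatellite coverage in bases per Mb
#'
#' Bases in di- to hexanucleotide tracks per Mb of sequence.  Homopolymer
#' tracks are excluded unless `include_homopolymers = TRUE`.
#'
#' @param p A `species_profile`.
#' @param include_homopolymers Logical; include mononucleotide tracks.
#' @return Coverage in bases per Mb (Mb = 1e6 bases exactly), unrounded.
#' @export
total_coverage <- function(p, include_homopolymers = FALSE) {
  stopifnot(inherits(p, "species_profile"))
  keep <- if (include_homopolymers) TRUE else .unit_lengths_of(p) >= 2L
  sum(p$bases_by_motif[keep]) / p$total_bases * 1e6
}

#' Homopolymer coverage in bases per Mb
#'
#' @inheritParams total_coverage
#' @return Coverage of mononucleotide tracks in bases per Mb.
#' @export
homopolymer_coverage <- function(p) {
  stopifnot(inherits(p, "species_profile"))
  sum(p$bases_by_motif[.unit_lengths_of(p) == 1L]) / p$total_bases * 1e6
}

#' Composition by repeat unit length
#'
#' Share of each unit length (1-6) in the combined microsatellite plus
#' homopolymer base count.
#'
#' @inheritParams total_coverage
#' @return Named numeric vector of proportions (names "1".."6"), summing to
#'   1; empty (with a warning) when the profile has no repeat bases at all.
#' @export
composition_by_unit_length <- function(p) {
  stopifnot(inherits(p, "species_profile"))
  tot <- sum(p$bases_by_motif)
  if (tot == 0) {
    warning("profile has no microsatellite or homopolymer bases",
            call. = FALSE)
    return(stats::setNames(numeric(0), character(0)))
  }
  by_u <- tapply(p$bases_by_motif, .unit_lengths_of(p), sum)
  stats::setNames(as.numeric(by_u) / tot, names(by_u))
}

#' Motif proportions within one unit length
#'
#' Each motif's coverage divided by the coverage of all microsatellites of
#' the same unit length.
#'
#' @inheritParams total_coverage
#' @param k Unit length, 1-6.
#' @return Named numeric vector over all canonical classes of length `k`,
#'   summing to 1; empty (with a warning) when that unit length has no
#'   bases.
#' @export
motif_proportions <- function(p, k) {
  stopifnot(inherits(p, "species_profile"))
  sel <- p$bases_by_motif[.unit_lengths_of(p) == as.integer(k)]
  if (length(sel) == 0L)
    stop("unit length k must be between 1 and 6", call. = FALSE)
  tot <- sum(sel)
  if (tot == 0) {
    warning("no bases at unit length ", k, call. = FALSE)
    return(stats::setNames(numeric(0), character(0)))
  }
  sel / tot
}

#' GC proportion
#'
#' @param gc_count Number of G/C bases.
#' @param total_acgt_bases Number of A/C/G/T bases.
#' @return `gc_count / total_acgt_bases`.
#' @export
gc_percent <- function(gc_count, total_acgt_bases) {
  if (!is.numeric(total_acgt_bases) || length(total_acgt_bases) != 1L ||
      total_acgt_bases <= 0)
    stop("total_acgt_bases must be positive", call. = FALSE)
  gc_count / total_acgt_bases
}
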