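# Canonical naming of microsatellite repeat units.
#
# A repeat unit of length k (1-6) is identified with every circular
# permutation of itself and of its reverse complement; the class is named by
# the alphabetically smallest member (A < C < G < T).  Only primitive units
# (not a whole-number repetition of a shorter unit) name classes, so e.g.
# "AA" is a homopolymer, not a dinucleotide, and "ACAC" is the dinucleotide
# AC.

# cache for per-k class enumerations and the primitive-kmer -> canonical map
.motif_cache <- new.env(parent = emptyenv())

.validate_motif <- function(m, max_len = 6L) {
  if (!is.character(m) || length(m) == 0L)
    stop("motif must be a non-empty character vector", call. = FALSE)
  m <- toupper(m)
  n <- nchar(m)
  if (any(n == 0L) || any(n > max_len))
    stop("motif length must be between 1 and ", max_len, call. = FALSE)
  if (any(grepl("[^ACGT]", m)))
    stop("invalid alphabet: motifs must contain only A, C, G, T", call. = FALSE)
  m
}

#' Reverse complement of a repeat motif
#'
#' Watson-Crick complement, reversed.  Vectorised over `m`.
#'
#' @param m Character vector of motifs over the alphabet A/C/G/T
#'   (case-insensitive), each 1-6 bases long.
#' @return Character vector of reverse complements, upper case.
#' @examples
#' reverse_complement(c("TTG", "AT", "ACG"))
#' @export
reverse_complement <- function(m) {
  m <- .validate_motif(m)
  comp <- chartr("ACGT", "TGCA", m)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

.rotations <- function(s) {
  n <- nchar(s)
  if (n == 1L) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  vapply(seq_len(n), function(i)
    paste(ch[c(seq(i, n), seq_len(i - 1L))], collapse = ""), character(1))
}

#' Is a motif primitive?
#'
#' A motif is primitive when it is not a whole-number (>1) tandem repetition
#' of any shorter prefix, e.g. `"AAC"` is primitive but `"ACAC"` and
#' `"AAAAAA"` are not.  Only primitive motifs name microsatellite classes.
#'
#' @inheritParams reverse_complement
#' @return Logical vector.
#' @examples
#' is_primitive(c("ACAC", "AAC", "AAAAAA"))
#' @export
is_primitive <- function(m) {
  m <- .validate_motif(m)
  vapply(m, function(s) .primitive_root(s) == s, logical(1), USE.NAMES = FALSE)
}

# smallest d dividing nchar(s) such that s is the d-prefix repeated
.primitive_root <- function(s) {
  n <- nchar(s)
  for (d in seq_len(n)) {
    if (n %% d != 0L) next
    if (strrep(substr(s, 1L, d), n %/% d) == s) return(substr(s, 1L, d))
  }
  s
}

#' Canonical name of a repeat motif class
#'
#' Returns the alphabetically smallest string among all circular permutations
#' of the motif and of its reverse complement, so that every member of a
#' repeat class maps to the same name (e.g. AAC stands for AAC, ACA, CAA,
#' TTG, TGT and GTT).  Non-primitive input is first reduced to its primitive
#' root (`"ACAC"` is treated as `"AC"`).
#'
#' @inheritParams reverse_complement
#' @return Character vector of canonical motif names.
#' @examples
#' canonical_motif(c("TTG", "CAA", "GT", "ACAC"))
#' @export
canonical_motif <- function(m) {
  m <- .validate_motif(m)
  vapply(m, function(s) {
    s <- .primitive_root(s)
    min(c(.rotations(s), .rotations(reverse_complement(s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Enumerate canonical motif classes of one unit length
#'
#' All canonical names of primitive repeat units of length `k`, sorted
#' alphabetically.  Class counts are fixed by combinatorics: 2, 4, 10, 33,
#' 102 and 350 for k = 1..6 (mononucleotide classes are the A/T and C/G
#' homopolymers; the four dinucleotide classes are AC, AG, AT, CG).
#'
#' @param k Integer unit length, 1-6.
#' @return Sorted character vector of canonical motif names.
#' @examples
#' motif_classes(2)
#' length(motif_classes(3))
#' @export
motif_classes <- function(k) {
  if (length(k) != 1L || is.na(k) || k != as.integer(k) || k < 1 || k > 6)
    stop("unit length k must be a single integer between 1 and 6", call. = FALSE)
  key <- paste0("classes", k)
  if (!is.null(.motif_cache[[key]])) return(.motif_cache[[key]])
  lk <- .canonical_lookup(as.integer(k))
  cls <- sort(unique(unname(lk)))
  .motif_cache[[key]] <- cls
  cls
}

#' All canonical motif classes for a set of unit lengths
#'
#' @param unit_lengths Integer vector of unit lengths (subset of 1-6).
#' @return Character vector ordered by unit length, then alphabetically.
#' @export
all_motif_classes <- function(unit_lengths = 1:6) {
  unlist(lapply(sort(unique(as.integer(unit_lengths))), motif_classes),
         use.names = FALSE)
}

# named map: every primitive k-mer -> canonical name (non-primitive absent)
.canonical_lookup <- function(k) {
  key <- paste0("lookup", k)
  if (!is.null(.motif_cache[[key]])) return(.motif_cache[[key]])
  bases <- c("A", "C", "G", "T")
  kmers <- do.call(paste0, expand.grid(rep(list(bases), k),
                                       stringsAsFactors = FALSE))
  prim <- kmers[vapply(kmers, function(s) .primitive_root(s) == s, logical(1))]
  lk <- canonical_motif(prim)
  names(lk) <- prim
  .motif_cache[[key]] <- lk
  lk
}
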