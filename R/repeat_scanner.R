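# Detection of maximal perfect tandem repeat tracks in reads.
#
# For each unit length u the scanner compares the sequence with itself
# shifted by u bases; maximal runs of equality are perfect arrays of period
# u, extended by the partial final unit.  A run is reported only when its
# repeat unit is primitive (so a (AC)n array is a dinucleotide, never a
# tetranucleotide) and when it contains at least the configured number of
# full units: 12 for homopolymers, 5 for di- to hexanucleotide motifs.

.default_min_repetitions <- c(`1` = 12L, `2` = 5L, `3` = 5L, `4` = 5L,
                              `5` = 5L, `6` = 5L)

#' Scanner configuration
#'
#' @param min_repetitions Named integer vector mapping unit length (as name)
#'   to the minimum number of full repeat units a track must contain.
#'   Defaults to 12 for homopolymers and 5 for unit lengths 2-6.
#' @param unit_lengths Integer vector of unit lengths to scan, subset of 1-6.
#' @param count_partial_units Logical; when `TRUE` (default) a partial final
#'   unit extends the reported track and its base count (qualification always
#'   uses full units only).  When `FALSE` tracks are truncated to whole units.
#' @return An object of class `scan_config`.
#' @examples
#' scan_config()
#' scan_config(min_repetitions = c(`2` = 7), unit_lengths = 2)
#' @export
scan_config <- function(min_repetitions = NULL, unit_lengths = 1:6,
                        count_partial_units = TRUE) {
  mr <- .default_min_repetitions
  if (!is.null(min_repetitions)) {
    if (is.null(names(min_repetitions)) || any(names(min_repetitions) == ""))
      stop("min_repetitions must be named by unit length", call. = FALSE)
    mr[names(min_repetitions)] <- as.integer(min_repetitions)
  }
  unit_lengths <- sort(unique(as.integer(unit_lengths)))
  if (length(unit_lengths) == 0L || any(!unit_lengths %in% 1:6))
    stop("unit_lengths must be a non-empty subset of 1:6", call. = FALSE)
  if (any(is.na(mr)) || any(mr < 2L))
    stop("all minimum repetition thresholds must be integers >= 2",
         call. = FALSE)
  structure(list(min_repetitions = mr, unit_lengths = unit_lengths,
                 count_partial_units = isTRUE(count_partial_units)),
            class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat("scan_config: unit lengths", paste(x$unit_lengths, collapse = ","),
      "| min repetitions",
      paste(sprintf("%s:%d", names(x$min_repetitions), x$min_repetitions),
            collapse = " "),
      "| partial final units", ifelse(x$count_partial_units, "counted",
                                      "dropped"), "\n")
  invisible(x)
}

.empty_tracks <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             unit_length = integer(), canonical_motif = character(),
             n_full_units = integer(), track_len = integer(),
             stringsAsFactors = FALSE)
}

#' Scan one sequence for perfect microsatellite tracks
#'
#' Reports every maximal perfect tandem array whose primitive repeat unit has
#' length in `cfg$unit_lengths` and which reaches the configured minimum
#' number of full repetitions.  Any non-ACGT character (e.g. N) breaks
#' tracks.  Coordinates are 0-based, half-open.
#'
#' @param seq_id Identifier attached to reported tracks.
#' @param seq A single sequence string (case-insensitive).
#' @param cfg A [scan_config()] object.
#' @return A data frame with columns `seq_id`, `start`, `end`,
#'   `unit_length`, `canonical_motif`, `n_full_units`, `track_len`,
#'   sorted by `start` then `unit_length`.
#' @examples
#' scan_sequence("r1", "TTGTTGTTGTTGTTG", scan_config())
#' @export
scan_sequence <- function(seq_id, seq, cfg = scan_config()) {
  if (!inherits(cfg, "scan_config")) stop("cfg must be a scan_config object",
                                          call. = FALSE)
  if (length(seq) != 1L || !is.character(seq))
    stop("seq must be a single character string", call. = FALSE)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L) return(.empty_tracks())
  s <- charToRaw(seq)
  ok <- s %in% charToRaw("ACGT")
  out <- vector("list", length(cfg$unit_lengths))
  for (j in seq_along(cfg$unit_lengths)) {
    u <- cfg$unit_lengths[j]
    minrep <- cfg$min_repetitions[[as.character(u)]]
    if (n < minrep * u) next
    idx <- seq_len(n - u)
    m <- (s[idx] == s[idx + u]) & ok[idx] & ok[idx + u]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= (minrep - 1L) * u
    if (!any(keep)) next
    a <- starts[keep]                       # 1-based start of the array
    L <- r$lengths[keep]
    track_len <- L + u
    unit <- substring(seq, a, a + u - 1L)
    canon <- unname(.canonical_lookup(u)[unit])
    prim <- !is.na(canon)                   # non-primitive unit: reported at
    if (!any(prim)) next                    # its true (shorter) period only
    a <- a[prim]; track_len <- track_len[prim]; canon <- canon[prim]
    nfu <- track_len %/% u
    if (!cfg$count_partial_units) track_len <- nfu * u
    out[[j]] <- data.frame(seq_id = seq_id, start = a - 1L,
                           end = a - 1L + track_len,
                           unit_length = u, canonical_motif = canon,
                           n_full_units = nfu, track_len = track_len,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(.empty_tracks())
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$unit_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan a set of reads
#'
#' Applies [scan_sequence()] to every read and accumulates sequence totals.
#'
#' @param reads Either a named character vector of sequences (names are read
#'   ids) or a path to a FASTA/FASTQ file (optionally gzipped), read with
#'   [read_sequences()].
#' @param cfg A [scan_config()] object.
#' @return A list with elements `tracks` (combined track data frame),
#'   `total_bases` (sum of read lengths) and `gc_count` (number of G/C
#'   bases).
#' @examples
#' scan_reads(c(r1 = strrep("A", 12), r2 = strrep("C", 12)))
#' @export
scan_reads <- function(reads, cfg = scan_config()) {
  if (is.character(reads) && length(reads) == 1L && is.null(names(reads)) &&
      file.exists(reads))
    reads <- read_sequences(reads)
  if (length(reads) == 0L)
    return(list(tracks = .empty_tracks(), total_bases = 0L, gc_count = 0L))
  if (is.null(names(reads)) || any(names(reads) == ""))
    stop("reads must be named by sequence id", call. = FALSE)
  total <- 0
  gc <- 0
  gcset <- charToRaw("GCgc")
  tracks <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    sq <- reads[[i]]
    res <- tryCatch(scan_sequence(names(reads)[i], sq, cfg), error = function(e) {
      warning("skipping unreadable record '", names(reads)[i], "': ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(res)) next
    total <- total + nchar(sq)
    gc <- gc + sum(charToRaw(sq) %in% gcset)
    tracks[[i]] <- res
  }
  tracks <- tracks[!vapply(tracks, is.null, logical(1))]
  tr <- if (length(tracks)) do.call(rbind, tracks) else .empty_tracks()
  rownames(tr) <- NULL
  list(tracks = tr, total_bases = as.integer(total), gc_count = as.integer(gc))
}
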