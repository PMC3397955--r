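# File formats: FASTA/FASTQ reads (via Biostrings, gzip transparent),
# BED-like track TSV, per-species profile CSV mirroring the survey's
# supplementary table layout, newick trees (via ape), JSON run configs.

#' Read sequences from FASTA or FASTQ
#'
#' Format is guessed from the file extension unless given.  Identifiers are
#' taken verbatim up to the first whitespace.  Gzipped files are handled
#' transparently.
#'
#' @param path Path to a FASTA or FASTQ file (optionally `.gz`).
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return Named character vector of upper-case sequences.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  ss <- Biostrings::readDNAStringSet(path, format = format)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a track table (BED-like TSV)
#'
#' Tab-separated with a header comment declaring the 0-based half-open
#' coordinate convention.
#'
#' @param tracks Track data frame from [scan_sequence()] / [scan_reads()].
#' @param path Output path.
#' @export
write_tracks_tsv <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ssrphylo tracks; coordinates 0-based, half-open", con)
  utils::write.table(tracks, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a track table written by [write_tracks_tsv()]
#'
#' @param path Path to the TSV.
#' @return Track data frame.
#' @export
read_tracks_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = c(seq_id = "character",
                                         canonical_motif = "character"))
  need <- c("seq_id", "start", "end", "unit_length", "canonical_motif",
            "n_full_units", "track_len")
  if (!all(need %in% names(tr)))
    stop("track file missing column(s): ",
         paste(setdiff(need, names(tr)), collapse = ", "), call. = FALSE)
  tr
}

#' Write species profiles to CSV
#'
#' One row per species: `species`, any taxonomy columns, `total_bases`,
#' `gc_fraction`, then one column per canonical motif ordered by unit
#' length and alphabetically.
#'
#' @param profiles A `species_profile` or list of them.
#' @param path Output path.
#' @export
write_profiles_csv <- function(profiles, path) {
  if (inherits(profiles, "species_profile")) profiles <- list(profiles)
  tax_names <- unique(unlist(lapply(profiles, function(p) names(p$taxonomy))))
  classes <- all_motif_classes(1:6)
  rows <- lapply(profiles, function(p) {
    tax <- stats::setNames(rep(NA_character_, length(tax_names)), tax_names)
    tax[names(p$taxonomy)] <- p$taxonomy
    c(list(species = p$species_id), as.list(tax),
      list(total_bases = p$total_bases, gc_fraction = p$gc_fraction),
      as.list(p$bases_by_motif[classes]))
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# role -> default column name candidates (case-insensitive match)
.profile_col_candidates <- list(
  species = c("species", "species_name", "species.name"),
  total_bases = c("total_bases", "total_length", "total.length",
                  "total_length_of_454_sequences", "total length"),
  gc_fraction = c("gc_fraction", "gc_proportion", "gc", "gc.proportion",
                  "gc%", "gc_percent"))

#' Read species profiles from CSV
#'
#' Accepts files written by [write_profiles_csv()] and, via `col_map`,
#' survey tables in the published supplementary layout (species, taxonomy
#' columns, total 454 sequence length, GC proportion, one column of
#' microsatellite base counts per canonical motif).
#'
#' Columns whose header is a valid A/C/G/T string of length 1-6 must be
#' canonical motif names; a non-canonical motif header (e.g. `TTG`) is
#' rejected with a named error.  All other columns besides the mapped ones
#' are kept as taxonomy labels.
#'
#' @param path Path to the CSV.
#' @param col_map Optional named character vector overriding the column
#'   names used for roles `species`, `total_bases` and `gc_fraction`.
#' @return List of `species_profile` objects.
#' @export
read_profiles_csv <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(df)
  resolve <- function(role) {
    if (!is.null(col_map) && role %in% names(col_map)) {
      if (!col_map[[role]] %in% nm)
        stop("mapped column '", col_map[[role]], "' for role '", role,
             "' not present", call. = FALSE)
      return(col_map[[role]])
    }
    hit <- nm[tolower(nm) %in% .profile_col_candidates[[role]]]
    if (length(hit) == 0L)
      stop("schema error: no column found for '", role,
           "' (use col_map to name it)", call. = FALSE)
    hit[1L]
  }
  sp_col <- resolve("species")
  tot_col <- resolve("total_bases")
  gc_col <- resolve("gc_fraction")
  motif_like <- grepl("^[ACGTacgt]{1,6}$", nm)
  motif_like[nm %in% c(sp_col, tot_col, gc_col)] <- FALSE
  classes <- all_motif_classes(1:6)
  bad <- nm[motif_like & !(toupper(nm) %in% classes)]
  if (length(bad))
    stop("unknown motif column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  motif_cols <- nm[motif_like]
  tax_cols <- setdiff(nm, c(sp_col, tot_col, gc_col, motif_cols))
  lapply(seq_len(nrow(df)), function(i) {
    counts <- stats::setNames(numeric(length(classes)), classes)
    if (length(motif_cols)) {
      v <- as.numeric(df[i, motif_cols])
      v[is.na(v)] <- 0
      if (any(v < 0))
        stop("validation error: negative count for species '",
             df[i, sp_col], "'", call. = FALSE)
      counts[toupper(motif_cols)] <- v
    }
    tot <- as.numeric(df[i, tot_col])
    if (is.na(tot) || tot <= 0)
      stop("validation error: non-positive total length for species '",
           df[i, sp_col], "'", call. = FALSE)
    new_species_profile(
      species_id = as.character(df[i, sp_col]),
      taxonomy = stats::setNames(as.character(unlist(df[i, tax_cols])),
                                 tax_cols),
      total_bases = tot,
      gc_fraction = as.numeric(df[i, gc_col]),
      bases_by_motif = counts)
  })
}

#' Write simulated reads to FASTA
#'
#' A JSON manifest (seed and full configuration) is written next to the
#' FASTA so a run can be reproduced from its outputs.
#'
#' @param reads Named character vector of sequences.
#' @param path Output FASTA path (`.gz` for gzip).
#' @param manifest Optional list (e.g. a `read_sim_config`) recorded as
#'   `<path>.manifest.json`.
#' @export
write_reads_fasta <- function(reads, path, manifest = NULL) {
  ss <- Biostrings::DNAStringSet(reads)
  names(ss) <- names(reads)
  Biostrings::writeXStringSet(ss, path,
                              compress = grepl("\\.gz$", path))
  if (!is.null(manifest))
    jsonlite::write_json(unclass(manifest), paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  invisible(path)
}

#' Read an ultrametric newick tree
#'
#' @param path Path to a newick file with branch lengths in My.
#' @param tol Relative ultrametricity tolerance.
#' @return A `phylo` tree, validated to be ultrametric.
#' @export
read_ultrametric_newick <- function(path, tol = 1e-6) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path, call. = FALSE)
  .node_ages(tr, tol)   # validates branch lengths + ultrametricity
  tr
}
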