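# Seeded simulators: 454-style shotgun reads with planted perfect repeat
# tracks (plus a truth table), and ultrametric pure-birth trees with traits
# evolved under Brownian motion or white noise.
#
# The read background is i.i.d. bases at a set GC level, so the chance
# repeat rate is analytically small; planted tracks are the signal the
# scanner must recover.  Read lengths emulate 454 shotgun data in scale
# only (truncated Gaussian, default 350 +/- 100, floor 50).

#' Read-simulation configuration
#'
#' @param n_reads Number of reads.
#' @param read_length_mean,read_length_sd Read length distribution in bases
#'   (truncated Gaussian).
#' @param min_read_length Lower truncation for read lengths.
#' @param gc_background Background GC proportion, in (0,1).
#' @param planted_tracks Data frame with columns `motif` (canonical,
#'   primitive), `n_units` (full repetitions per track) and `count` (number
#'   of tracks to plant), or `NULL` for none.
#' @param seed Integer seed; every simulation is deterministic given it.
#' @return An object of class `read_sim_config`.
#' @export
read_sim_config <- function(n_reads = 1000L, read_length_mean = 350,
                            read_length_sd = 100, min_read_length = 50,
                            gc_background = 0.4, planted_tracks = NULL,
                            seed = 1L) {
  if (n_reads < 1L) stop("n_reads must be positive", call. = FALSE)
  if (gc_background <= 0 || gc_background >= 1)
    stop("gc_background must be in (0,1)", call. = FALSE)
  if (!is.null(planted_tracks)) {
    stopifnot(is.data.frame(planted_tracks),
              all(c("motif", "n_units", "count") %in% names(planted_tracks)))
    if (any(planted_tracks$n_units < 2) || any(planted_tracks$count < 1))
      stop("planted track counts and repetitions must be positive",
           call. = FALSE)
    if (!all(planted_tracks$motif == canonical_motif(planted_tracks$motif)))
      stop("planted motifs must be canonical primitive motifs", call. = FALSE)
  }
  structure(list(n_reads = as.integer(n_reads),
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd,
                 min_read_length = min_read_length,
                 gc_background = gc_background,
                 planted_tracks = planted_tracks,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Simulate 454-style reads with planted repeat tracks
#'
#' Background bases are i.i.d. with the configured GC; each planted track
#' (a perfect tandem array `strrep(motif, n_units)`) overwrites a uniformly
#' chosen window of a read, avoiding overlap with previously planted tracks
#' in the same read.  Deterministic given `cfg$seed`.
#'
#' @param cfg A [read_sim_config()].
#' @param max_tries Bounded retries per track before a generation error.
#' @return List with `reads` (named character vector) and `truth` (data
#'   frame `seq_id`, `start`, `end`, `motif`, `n_units`; 0-based half-open
#'   coordinates).
#' @examples
#' cfg <- read_sim_config(n_reads = 20, seed = 7,
#'   planted_tracks = data.frame(motif = "AC", n_units = 8, count = 5))
#' sim <- simulate_reads(cfg)
#' head(sim$truth)
#' @export
simulate_reads <- function(cfg, max_tries = 1000L) {
  stopifnot(inherits(cfg, "read_sim_config"))
  set.seed(cfg$seed)
  lens <- pmax(cfg$min_read_length,
               round(stats::rnorm(cfg$n_reads, cfg$read_length_mean,
                                  cfg$read_length_sd)))
  pr <- c(A = (1 - cfg$gc_background) / 2, C = cfg$gc_background / 2,
          G = cfg$gc_background / 2, T = (1 - cfg$gc_background) / 2)
  reads <- vapply(lens, function(L)
    paste(sample(names(pr), L, replace = TRUE, prob = pr), collapse = ""),
    character(1))
  names(reads) <- sprintf("read_%05d", seq_len(cfg$n_reads))
  truth <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      n_units = integer(), stringsAsFactors = FALSE)
  if (!is.null(cfg$planted_tracks)) {
    occupied <- vector("list", cfg$n_reads)   # planted intervals per read
    for (i in seq_len(nrow(cfg$planted_tracks))) {
      motif <- cfg$planted_tracks$motif[i]
      n_units <- cfg$planted_tracks$n_units[i]
      track <- strrep(motif, n_units)
      tl <- nchar(track)
      for (k in seq_len(cfg$planted_tracks$count[i])) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          r <- sample.int(cfg$n_reads, 1L)
          if (lens[r] < tl + 2L) next
          a <- sample.int(lens[r] - tl + 1L, 1L)     # 1-based start
          iv <- c(a - nchar(motif), a + tl - 1L + nchar(motif))
          clash <- any(vapply(occupied[[r]], function(o)
            iv[1] <= o[2] && o[1] <= iv[2], logical(1)))
          if (clash) next
          substr(reads[r], a, a + tl - 1L) <- track
          occupied[[r]] <- c(occupied[[r]], list(c(a, a + tl - 1L)))
          truth <- rbind(truth, data.frame(
            seq_id = names(reads)[r], start = a - 1L, end = a - 1L + tl,
            motif = motif, n_units = n_units, stringsAsFactors = FALSE))
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place planted track ", motif, "x", n_units,
               " after ", max_tries, " tries", call. = FALSE)
      }
    }
    truth <- truth[order(truth$seq_id, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
  }
  list(reads = reads, truth = truth)
}

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' A pure-birth topology whose node depths are rescaled so the root age is
#' exactly `root_age_mya`.
#'
#' @param n_leaves Number of leaves (>= 3).
#' @param root_age_mya Root age in millions of years.
#' @param seed Optional integer seed.
#' @return An ultrametric `phylo` tree with tip labels `s1..sn`.
#' @export
simulate_yule_tree <- function(n_leaves, root_age_mya, seed = NULL) {
  if (n_leaves < 3L) stop("n_leaves must be at least 3", call. = FALSE)
  if (root_age_mya <= 0) stop("root_age_mya must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_leaves, birth = 1, death = 0)
  tr$tip.label <- paste0("s", seq_len(n_leaves))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (root_age_mya / depth)
  tr
}

#' Simulate a leaf trait on a tree
#'
#' `model = "brownian"`: independent Gaussian increments per branch with
#' variance `sigma2 * branch length`, accumulated root to tip from
#' `root_value`.  `model = "white_noise"`: i.i.d. Gaussian
#' (`root_value`, `sigma2`) at the leaves, ignoring the tree.
#'
#' @param tree A `phylo` tree.
#' @param model `"brownian"` or `"white_noise"`.
#' @param sigma2 Brownian variance rate per My, or the white-noise variance.
#' @param root_value Trait value at the root / the white-noise mean.
#' @param seed Optional integer seed.
#' @return Named numeric vector over tip labels.
#' @export
simulate_trait <- function(tree, model = c("brownian", "white_noise"),
                           sigma2 = 1, root_value = 0, seed = NULL) {
  model <- match.arg(model)
  if (sigma2 < 0) stop("sigma2 must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  if (model == "white_noise")
    return(stats::setNames(stats::rnorm(ntip, root_value, sqrt(sigma2)),
                           tree$tip.label))
  tr <- stats::reorder(tree, "cladewise")   # parents precede children
  x <- numeric(ntip + tr$Nnode)
  x[ntip + 1L] <- root_value
  inc <- stats::rnorm(nrow(tr$edge), 0, sqrt(sigma2 * tr$edge.length))
  for (e in seq_len(nrow(tr$edge)))
    x[tr$edge[e, 2L]] <- x[tr$edge[e, 1L]] + inc[e]
  stats::setNames(x[seq_len(ntip)], tr$tip.label)
}
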