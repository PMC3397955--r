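# Independent oracles used to freeze expected values.  They share no code
# with the package internals: canonical naming is done by orbit closure,
# primitivity by the string-doubling trick, scanning by per-start extension,
# and Wilcoxon's W by pair enumeration.

oracle_rc <- function(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")

# non-primitive iff s occurs inside (s+s) at a non-trivial offset
oracle_is_primitive <- function(s) {
  n <- nchar(s)
  if (n == 1L) return(TRUE)
  inner <- substr(strrep(s, 2L), 2L, 2L * n - 1L)
  regexpr(s, inner, fixed = TRUE) < 0L
}

# BFS closure under rotate-by-one and reverse complement; class name = min
oracle_canonical <- function(m) {
  rot1 <- function(s) paste0(substr(s, 2L, nchar(s)), substr(s, 1L, 1L))
  seen <- character()
  frontier <- m
  while (length(frontier)) {
    seen <- union(seen, frontier)
    nxt <- unique(c(vapply(frontier, rot1, character(1)),
                    vapply(frontier, oracle_rc, character(1))))
    frontier <- setdiff(nxt, seen)
  }
  min(seen)
}

# number of classes of primitive k-mers under the orbit closure
oracle_class_set <- function(k) {
  kmers <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                       stringsAsFactors = FALSE))
  prim <- kmers[vapply(kmers, oracle_is_primitive, logical(1))]
  sort(unique(vapply(prim, oracle_canonical, character(1))))
}

# naive scanner: tests every (start, unit length) pair for a maximal
# perfect array meeting the thresholds
oracle_scan <- function(seq_id, seq, cfg = scan_config()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  ok <- ch %in% c("A", "C", "G", "T")
  rows <- list()
  for (u in cfg$unit_lengths) {
    minrep <- cfg$min_repetitions[[as.character(u)]]
    if (n < u + 1L) next
    for (a in seq_len(n - u)) {
      if (!(ok[a] && ok[a + u] && ch[a] == ch[a + u])) next
      left_ext <- a > 1L && a - 1L + u <= n && ok[a - 1L] && ok[a - 1L + u] &&
        ch[a - 1L] == ch[a - 1L + u]
      if (left_ext) next                     # not a run start
      b <- a
      while (b <= n - u && ok[b] && ok[b + u] && ch[b] == ch[b + u])
        b <- b + 1L
      track_len <- (b - a) + u
      nf <- track_len %/% u
      if (nf < minrep) next
      unit <- paste(ch[a:(a + u - 1L)], collapse = "")
      if (!oracle_is_primitive(unit)) next
      if (!cfg$count_partial_units) track_len <- nf * u
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = seq_id, start = a - 1L, end = a - 1L + track_len,
        unit_length = u, canonical_motif = oracle_canonical(unit),
        n_full_units = nf, track_len = track_len, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(ssrphylo:::.empty_tracks())
  res <- do.call(rbind, rows)
  res <- res[order(res$start, res$unit_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# W = #{x_i > y_j} + 0.5 #{x_i == y_j}
oracle_wilcoxon_W <- function(x, y)
  sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))

# random sequence enriched in tandem repeats so scanner tests bite
random_repeatish_dna <- function(len, p_insert = 0.15) {
  bases <- c("A", "C", "G", "T")
  s <- paste(sample(bases, len, replace = TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  n_ins <- stats::rpois(1, p_insert * len / 60)
  for (i in seq_len(n_ins)) {
    u <- sample(1:6, 1)
    motif <- paste(sample(bases, u, replace = TRUE), collapse = "")
    reps <- sample(3:15, 1)
    arr <- strrep(motif, reps)
    if (nchar(arr) >= nchar(s)) next
    at <- sample.int(nchar(s) - nchar(arr), 1)
    substr(s, at, at + nchar(arr) - 1L) <- arr
  }
  s
}

# permutation p-value oracle for Moran's I
oracle_perm_moran_p <- function(values, part, B = 10000L) {
  obs <- morans_i(values, part)
  sp <- names(part$clade_of)
  x <- values[sp]
  stat <- function(v) {
    names(v) <- sp
    morans_i(v, part)$I
  }
  ref <- abs(obs$I - obs$expected_I)
  hits <- 0L
  for (b in seq_len(B)) {
    ib <- stat(sample(x))
    if (abs(ib - obs$expected_I) >= ref - 1e-12) hits <- hits + 1L
  }
  (hits + 1L) / (B + 1L)
}

# small survey table (labelled synthetic) exercising the Dataset-S1-style
# reader/analysis path: two taxonomic groups with distinct coverage levels
make_synthetic_survey <- function(n_per_group = 10L, seed = 42L) {
  set.seed(seed)
  profs <- list()
  for (g in c("groupA", "groupB")) {
    mu <- if (g == "groupA") 2000 else 400       # bases of AC per Mb scale
    for (i in seq_len(n_per_group)) {
      total <- round(stats::runif(1, 2e6, 8e6))
      gc <- stats::runif(1, 0.33, 0.46)
      counts <- c(
        A = stats::rpois(1, 3e-4 * total), C = stats::rpois(1, 5e-5 * total),
        AC = stats::rpois(1, mu / 1e6 * total * 0.5),
        AG = stats::rpois(1, mu / 1e6 * total * 0.2),
        AT = stats::rpois(1, mu / 1e6 * total * 0.3),
        AAT = stats::rpois(1, mu / 1e6 * total * 0.15),
        AAAT = stats::rpois(1, mu / 1e6 * total * 0.08))
      tracks <- data.frame(
        seq_id = "pooled", start = 0L, end = 0L,
        unit_length = nchar(names(counts)),
        canonical_motif = names(counts),
        n_full_units = 0L, track_len = as.integer(counts),
        stringsAsFactors = FALSE)
      profs[[length(profs) + 1L]] <- build_profile(
        tracks, total, round(gc * total),
        species_id = sprintf("%s_sp%02d", g, i),
        taxonomy = c(phylum = g))
    }
  }
  profs
}
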