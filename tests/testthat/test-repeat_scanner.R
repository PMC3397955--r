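test_that("scan_config validates thresholds and unit lengths", {
  cfg <- scan_config()
  expect_identical(unname(cfg$min_repetitions),
                   c(12L, rep(5L, 5)))
  expect_error(scan_config(min_repetitions = c(`2` = 1)), ">= 2")
  expect_error(scan_config(unit_lengths = c(0, 7)), "subset")
  expect_error(scan_config(min_repetitions = 5), "named")
})

test_that("scanner reproduces the threshold examples", {
  cfg <- scan_config()
  # (TTG)x5: one trinucleotide track, canonical AAC
  tr <- scan_sequence("r1", "TTGTTGTTGTTGTTG", cfg)
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$unit_length, 3L)
  expect_identical(tr$canonical_motif, "AAC")
  expect_identical(c(tr$start, tr$end, tr$n_full_units), c(0L, 15L, 5L))
  # homopolymer threshold is 12
  expect_identical(nrow(scan_sequence("r1", strrep("A", 11), cfg)), 0L)
  a12 <- scan_sequence("r1", strrep("A", 12), cfg)
  expect_identical(a12$track_len, 12L)
  expect_identical(a12$canonical_motif, "A")
  # partial final unit counts toward track_len, not qualification
  expect_identical(nrow(scan_sequence("r1", "ACACACACA", cfg)), 0L)
  ac <- scan_sequence("r1", "ACACACACACA", cfg)
  expect_identical(c(ac$unit_length, ac$track_len, ac$n_full_units),
                   c(2L, 11L, 5L))
  # whole-units-only convention truncates the partial unit
  ac2 <- scan_sequence("r1", "ACACACACACA",
                       scan_config(count_partial_units = FALSE))
  expect_identical(c(ac2$track_len, ac2$end), c(10L, 10L))
  # non-primitive units are never reported as separate tracks
  at <- scan_sequence("r1", "ATATATATATAT", cfg)
  expect_identical(nrow(at), 1L)
  expect_identical(at$unit_length, 2L)
  # empty sequence, invalid config
  expect_identical(nrow(scan_sequence("r1", "", cfg)), 0L)
  expect_error(scan_sequence("r1", "ACGT", cfg = list()), "scan_config")
})

test_that("N and lowercase handling", {
  cfg <- scan_config()
  # N breaks an otherwise qualifying homopolymer
  expect_identical(nrow(scan_sequence("r", paste0(strrep("A", 8), "N",
                                                  strrep("A", 8)), cfg)), 0L)
  expect_identical(scan_sequence("r", strrep("a", 12), cfg)$track_len, 12L)
})

test_that("scanner equals the naive per-start oracle on random sequences", {
  set.seed(101)
  cfg <- scan_config()
  for (i in 1:150) {
    s <- random_repeatish_dna(sample(80:2000, 1))
    if (i %% 10 == 0) {   # sprinkle Ns
      pos <- sample(nchar(s), 3)
      for (p in pos) substr(s, p, p) <- "N"
    }
    expect_identical(scan_sequence("q", s, cfg), oracle_scan("q", s, cfg),
                     info = paste("iter", i))
  }
})

test_that("strand symmetry: classes and lengths are strand-invariant", {
  set.seed(102)
  cfg <- scan_config()
  for (i in 1:40) {
    s <- random_repeatish_dna(sample(200:1500, 1))
    fwd <- scan_sequence("q", s, cfg)
    rev <- scan_sequence("q", oracle_rc(s), cfg)
    key <- function(d) sort(paste(d$canonical_motif, d$track_len))
    expect_identical(key(fwd), key(rev))
    # coordinates mirrored
    n <- nchar(s)
    expect_setequal(paste(fwd$start, fwd$end),
                    paste(n - rev$end, n - rev$start))
  }
})

test_that("same-unit-length tracks only touch at array junctions (< u)", {
  set.seed(103)
  cfg <- scan_config()
  for (i in 1:30) {
    tr <- scan_sequence("q", random_repeatish_dna(1500), cfg)
    for (u in unique(tr$unit_length)) {
      d <- tr[tr$unit_length == u, ]
      if (nrow(d) < 2) next
      d <- d[order(d$start), ]
      overlap <- utils::head(d$end, -1) - utils::tail(d$start, -1)
      expect_true(all(overlap < u))
    }
  }
})

test_that("scan_reads aggregates totals and is order-invariant", {
  res <- scan_reads(c(r1 = strrep("A", 12), r2 = strrep("C", 12)))
  expect_identical(nrow(res$tracks), 2L)
  expect_identical(res$total_bases, 24L)
  expect_identical(res$gc_count, 12L)
  empty <- scan_reads(character(0))
  expect_identical(empty$total_bases, 0L)
  expect_identical(nrow(empty$tracks), 0L)
  set.seed(104)
  reads <- vapply(1:20, function(i) random_repeatish_dna(400), character(1))
  names(reads) <- paste0("r", 1:20)
  a <- scan_reads(reads)
  b <- scan_reads(rev(reads))
  expect_identical(a$total_bases, b$total_bases)
  expect_identical(a$gc_count, b$gc_count)
  key <- function(d) sort(paste(d$seq_id, d$start, d$end, d$canonical_motif))
  expect_identical(key(a$tracks), key(b$tracks))
  # determinism
  expect_identical(a, scan_reads(reads))
})
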