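test_that("a perfect planted array is called exactly, with clean flanks", {
  set.seed(7)
  flank_l <- random_dna(60)
  flank_r <- random_dna(60)
  # phase-breaking junctions so the planted edges are the array edges
  seq <- paste0(substr(flank_l, 1, 59), "T", strrep("GAAA", 16),
                "C", substr(flank_r, 2, 60))
  res <- find_tandem_repeats(seq, repeat_scan_params(min_period = 4,
                                                     max_period = 5,
                                                     min_copy_number = 12,
                                                     min_match_pct = 90))
  expect_equal(nrow(res), 1L)
  expect_equal(res$start, 60L)
  expect_equal(res$end, 124L)
  expect_equal(res$period, 4L)
  expect_equal(res$copy_number, 16)
  expect_equal(res$match_pct, 100)
  expect_equal(res$indel_pct, 0)
  expect_equal(res$unit, "GAAA")
  expect_equal(res$longest_perfect_run, 16L)
})

test_that("shuffled sequence without a planted array yields no calls", {
  set.seed(1)
  seq <- paste(sample(rep(c("A", "C", "G", "T"), 100)), collapse = "")
  params <- repeat_scan_params(min_period = 4, max_period = 5,
                               min_copy_number = 12, min_match_pct = 90)
  expect_identical(nrow(find_tandem_repeats(seq, params)), 0L)
  # confirmed by the perfect-run oracle: nothing close to 12 copies exists
  expect_identical(nrow(oracle_perfect_runs(seq, 4, 5, 12)), 0L)
})

test_that("a single-base interruption gives one merged imperfect call", {
  seq <- paste0(strrep("GAAA", 6), "C", strrep("GAAA", 6))
  res <- find_tandem_repeats(seq, repeat_scan_params(min_copy_number = 12,
                                                     min_match_pct = 90))
  expect_equal(nrow(res), 1L)
  expect_equal(res$copy_number, 49 / 4)
  expect_equal(res$longest_perfect_run, 6L)
  # match percentage pinned to an exhaustive tandem-alignment oracle
  orc <- oracle_tandem_alignment(seq, "GAAA")
  expect_equal(res$match_pct, orc$match_pct, tolerance = 1e-12)
  expect_equal(res$score, orc$score)
  expect_equal(orc$match_pct, 100 * 48 / 49)  # 48 matches, 1 inserted base
})

test_that("wraparound alignment agrees with the exhaustive oracle on small cases", {
  cases <- list(
    list(seq = strrep("GAAA", 4), unit = "GAAA"),
    list(seq = paste0(strrep("GAAA", 3), "GA"), unit = "GAAA"),      # partial unit
    list(seq = paste0(strrep("CAG", 5), "T", strrep("CAG", 4)), unit = "CAG"),
    list(seq = paste0("GAAA", "GATA", strrep("GAAA", 3)), unit = "GAAA") # mismatch
  )
  for (cs in cases) {
    got <- wraparound_align(cs$seq, cs$unit)
    orc <- oracle_tandem_alignment(cs$seq, cs$unit)
    expect_equal(got$score, orc$score, info = cs$seq)
    expect_equal(got$match_pct, orc$match_pct, tolerance = 1e-12,
                 info = cs$seq)
  }
})

test_that("perfect arrays across periods match the brute-force scanner", {
  set.seed(42)
  for (unit in c("AC", "CAG", "GAAA", "ATCGG")) {
    p <- nchar(unit)
    seq <- paste0("T", strrep(unit, 13), "T", random_dna(40))
    res <- find_tandem_repeats(seq, repeat_scan_params(min_period = p,
                                                       max_period = p,
                                                       min_copy_number = 12,
                                                       min_match_pct = 90))
    orc <- oracle_perfect_runs(seq, p, p, 12)
    expect_equal(nrow(res), 1L, info = unit)
    expect_equal(res$start, orc$start[1], info = unit)
    expect_equal(res$end, orc$end[1], info = unit)
    expect_equal(res$copy_number, orc$copies[1], info = unit)
    expect_equal(res$match_pct, 100, info = unit)
  }
})

test_that("raising thresholds never adds repeats (monotonicity)", {
  set.seed(11)
  for (i in 1:5) {
    seq <- paste0(random_dna(80), strrep("GAAA", sample(10:14, 1)),
                  random_dna(30), strrep("TTAGG", 13), random_dna(50))
    key <- function(df) paste(df$start, df$end, df$unit)
    base <- find_tandem_repeats(seq, repeat_scan_params(
      min_period = 4, max_period = 5, min_copy_number = 8, min_match_pct = 80))
    for (mc in c(10, 12, 14)) {
      tighter <- find_tandem_repeats(seq, repeat_scan_params(
        min_period = 4, max_period = 5, min_copy_number = mc,
        min_match_pct = 80))
      expect_true(all(key(tighter) %in% key(base)))
    }
    for (mp in c(90, 95, 99)) {
      tighter <- find_tandem_repeats(seq, repeat_scan_params(
        min_period = 4, max_period = 5, min_copy_number = 8,
        min_match_pct = mp))
      expect_true(all(key(tighter) %in% key(base)))
    }
  }
})

test_that("reported unit is stable under entry phase and strand mirroring", {
  params <- repeat_scan_params(min_copy_number = 10, min_match_pct = 90)
  # enter the same array at all four phases: same canonical unit
  units <- vapply(c("GAAA", "AAAG", "AAGA", "AGAA"), function(rot) {
    seq <- paste0("T", substr(rot, 1, 2), strrep(rot, 12), "C")
    res <- find_tandem_repeats(seq, params)
    res$unit[1]
  }, character(1))
  expect_true(all(units == "GAAA"))

  # reverse complement mirrors the interval
  set.seed(3)
  seq <- paste0(random_dna(50), "T", strrep("GAAA", 14), "C", random_dna(50))
  L <- nchar(seq)
  fwd <- find_tandem_repeats(seq, params)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rev <- find_tandem_repeats(rc, params)
  expect_equal(nrow(fwd), nrow(rev))
  expect_setequal(paste(L - fwd$end, L - fwd$start), paste(rev$start, rev$end))
})

test_that("input validation and N handling behave as specified", {
  expect_identical(nrow(find_tandem_repeats("")), 0L)
  expect_error(find_tandem_repeats("ACGTXACGT"), "offset 4")
  # an N splits the candidate region: no repeat spans it
  seq <- paste0(strrep("GAAA", 7), "N", strrep("GAAA", 7))
  res <- find_tandem_repeats(seq, repeat_scan_params(min_copy_number = 5,
                                                     min_match_pct = 80))
  expect_equal(nrow(res), 2L)
  expect_true(all(res$copy_number == 7))
})

test_that("uninterrupted unit counting enumerates runs at any phase", {
  expect_identical(count_uninterrupted_units("GAAAGAAAGAAA", "GAAA"), 3L)
  expect_identical(count_uninterrupted_units("GAAAGAAAGAACGAAAGAAA", "GAAA"), 2L)
  expect_identical(count_uninterrupted_units("CCCC", "GAAA"), 0L)
  expect_error(count_uninterrupted_units("GAAA", ""), "non-empty")
  # human-reference-like fixture: 16 perfect units inside flanks
  fixture <- paste0("TTGCA", strrep("GAAA", 16), "CTGGA")
  expect_identical(count_uninterrupted_units(fixture, "GAAA"), 16L)
})

test_that("canonical units collapse rotations and honor the override table", {
  expect_identical(canonical_unit("AAAG"), "GAAA")
  expect_identical(canonical_unit("CAG"), "CAG")
  expect_identical(canonical_unit("agc"), "CAG")
  rots <- c("GAAA", "AAAG", "AAGA", "AGAA")
  expect_true(all(vapply(rots, canonical_unit, character(1)) == "GAAA"))
  # without overrides the representative is the lexicographic minimum
  expect_identical(canonical_unit("GAAA", overrides = NULL), "AAAG")
  expect_error(canonical_unit(""), "non-empty")
})

test_that("FASTA records are scanned independently", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chrA", paste0("T", strrep("GAAA", 13), "C"),
               ">chrB", paste0("T", strrep("CAGT", 13), "C")), fa)
  res <- find_tandem_repeats_fasta(fa, repeat_scan_params(
    min_copy_number = 12, min_match_pct = 90))
  expect_equal(res$chrom, c("chrA", "chrB"))
  expect_equal(res$unit, c("GAAA", "AGTC"))  # AGTC: canonical rotation of CAGT
})
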