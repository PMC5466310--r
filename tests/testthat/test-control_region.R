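test_that("find_motif reports exact, possibly overlapping occurrences", {
  hits <- find_motif("GGATAGATTT", "ATAGA")
  expect_equal(nrow(hits), 1L)
  expect_equal(c(hits$start, hits$end), c(3L, 7L))
  expect_equal(nrow(find_motif("GGGGGG", "ATAGA")), 0L)
  # overlapping occurrences are all reported
  expect_equal(find_motif("ATATATA", "ATA")$start, c(1L, 3L, 5L))
  expect_error(find_motif("ACGT", "ATN"), "ambiguous")
  expect_error(find_motif("ACGT", "AT"), "shorter")
})

test_that("reverse-strand hits mirror forward hits", {
  set.seed(29)
  for (k in 1:10) {
    region <- random_dna(60)
    motif <- random_dna(4, c("A", "T", "G"))
    both <- find_motif(region, motif, both_strands = TRUE)
    rhits <- both[both$strand == "R", ]
    fw_on_rc <- find_motif(revcomp(region), motif)
    n <- nchar(region)
    expect_setequal(rhits$start, n - fw_on_rc$end + 1L)
    # hit invariant: the slice on the reported strand equals the motif
    for (i in seq_len(nrow(both))) {
      slice <- substring(region, both$start[i], both$end[i])
      if (both$strand[i] == "R") slice <- revcomp(slice)
      expect_equal(slice, motif)
    }
  }
})

test_that("the ATAGA/poly-T element detector honors its threshold", {
  region <- paste0("GGCC", "ATAGA", strrep("T", 17), "ACGT")
  el <- find_ataga_polyT(region)
  expect_equal(el$polyT$copies, 17)
  expect_equal(el$polyT$start, 10L)
  expect_equal(el$offset, 0L)
  # short run below threshold
  expect_null(find_ataga_polyT("CCATAGATTTCC", min_len = 10))
  # threshold 0 degenerates to plain motif finding
  el0 <- find_ataga_polyT("CCATAGACCC", min_len = 0)
  expect_equal(el0$motif$start, find_motif("CCATAGACCC", "ATAGA")$start)
  # small offset between motif and run is tolerated
  el2 <- find_ataga_polyT(paste0("ATAGA", "CA", strrep("T", 12)),
                          offset_max = 2)
  expect_equal(el2$offset, 2L)
  expect_equal(el2$polyT$copies, 12)
})

test_that("longest_homopolymer matches substring enumeration", {
  hit <- longest_homopolymer("TTTATTTT", "T")
  expect_equal(c(hit$start, hit$end, hit$copies), c(5, 8, 4))
  expect_equal(longest_homopolymer(strrep("A", 30), "A")$copies, 30)
  expect_equal(nrow(longest_homopolymer("CCCC", "A")), 0L)
  set.seed(31)
  for (k in 1:30) {
    s <- random_dna(30, c("A", "T"))
    want <- oracle_longest_run(s, "T")
    got <- longest_homopolymer(s, "T")
    if (want$len == 0) expect_equal(nrow(got), 0L)
    else {
      expect_equal(got$copies, want$len)
      expect_equal(got$start, want$start)
    }
  }
})

test_that("microsatellite detection matches its documented examples", {
  ms <- find_microsatellites(strrep("AT", 9), unit_sizes = 1:4)
  expect_equal(nrow(ms), 1L)
  expect_equal(ms$unit, "AT")
  expect_equal(ms$copies, 9)
  expect_equal(ms$kind, "microsatellite")
  # 2.5 copies is below the threshold of 3
  expect_equal(nrow(find_microsatellites("ATATA", unit_sizes = 2)), 0L)
  expect_error(find_microsatellites("AT", min_copies = 2), "min_copies")
})

test_that("repeat detectors equal exhaustive enumeration on random strings", {
  set.seed(37)
  for (k in 1:40) {
    s <- random_dna(sample(4:12, 1))
    got <- find_microsatellites(s, unit_sizes = 1:3, min_copies = 3)
    want <- oracle_repeats(s, 1:3, 3)
    expect_equal(got[, c("unit", "unit_size", "copies", "start", "end")],
                 want[, c("unit", "unit_size", "copies", "start", "end")],
                 info = s)
  }
})

test_that("tandem repeat detection suppresses nested reports", {
  tr <- find_tandem_repeats("ACGACGACG", 1, 3)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$unit, "ACG")
  expect_equal(tr$copies, 3)
  expect_equal(tr$kind, "tandem")
  tr5 <- find_tandem_repeats(strrep("ACGTT", 4), 1, 5)
  expect_equal(nrow(tr5), 1L)
  expect_equal(tr5$unit_size, 5L)
  expect_equal(c(tr5$start, tr5$end), c(1L, 20L))
  expect_warning(find_tandem_repeats("ACGT", 1, 10), "clamped")
  # every reported hit re-slices to its unit (self-verification)
  set.seed(43)
  for (k in 1:10) {
    s <- random_dna(30, c("A", "T", "G"))
    tr <- find_tandem_repeats(s, 1, 4)
    for (i in seq_len(nrow(tr))) {
      span <- substring(s, tr$start[i], tr$end[i])
      rep_full <- strrep(tr$unit_observed[i], ceiling(tr$copies[i]))
      expect_equal(span, substring(rep_full, 1, nchar(span)))
    }
  }
})

test_that("spacer_motif_report recovers the generator's planted elements", {
  gen <- generate_mitogenome(genome_spec(seed = 3))
  ok <- check_plant_and_recover(gen)
  expect_true(all(ok), info = paste(names(ok)[!ok], collapse = ", "))
  hits <- spacer_motif_report(gen$genome)
  expect_true(any(hits$region == "spacer:trnS2(UCN)-nad1" &
                    hits$motif == "ATACTAA"))
  # exactly one ATAGA in the scrubbed control region
  expect_equal(sum(hits$kind == "motif" & hits$motif == "ATAGA"), 1L)
  expect_error(spacer_motif_report(fixture_genome()), "sequence")
})
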