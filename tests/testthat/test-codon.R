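test_that("translate_mt implements the invertebrate mitochondrial code", {
  expect_equal(translate_mt("ATGAAATAA"), "MK")
  expect_equal(translate_mt("ATGAGAAGG"), "MSS")   # AGA/AGG are Ser
  expect_equal(translate_mt("ATGTGA"), "MW")        # TGA is Trp
  expect_equal(translate_mt("ATAAAA"), "MK")        # ATA initiator -> Met
  expect_equal(substring(translate_mt("CGAAAA"), 1, 1), "R")  # nonstandard kept
  expect_error(translate_mt("ATGTAAAAA"), "internal stop.*2")
  expect_error(translate_mt("ATGA"), "multiple of 3")
  expect_error(translate_mt("AT"), "shorter")
  expect_error(translate_mt("ATGNNN"), "non-ACGT")
})

test_that("incomplete termini are completed by the polyadenylation model", {
  expect_equal(translate_mt("ATGAAAT", complete_stop = TRUE), "MK")
  expect_equal(translate_mt("ATGAAATA", complete_stop = TRUE), "MK")
  # a trailing base that cannot polyadenylate to a stop is an error
  expect_error(translate_mt("ATGAAAC", complete_stop = TRUE),
               "does not complete")
})

test_that("translate_mt agrees with the Biostrings table-5 oracle", {
  code5 <- Biostrings::getGeneticCode("5")
  nonstop <- names(code5)[code5 != "*"]
  set.seed(13)
  for (k in 1:200) {
    codons <- c("ATG", sample(nonstop, sample(1:30, 1), replace = TRUE))
    cds <- paste(codons, collapse = "")
    want <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds), genetic.code = code5))
    expect_equal(translate_mt(cds), want)
  }
})

test_that("start/stop classification reproduces the printed tallies", {
  g <- fixture_genome()
  tal <- start_stop_tally(g)
  expect_equal(as.integer(tal$start_tally[c("ATA", "ATT", "ATG", "ATC", "CCA")]),
               c(1L, 2L, 7L, 2L, 1L))
  expect_setequal(tal$incomplete_T_genes, c("cox1", "cox2", "nad5", "nad4"))
  cox1 <- Filter(function(r) r$name == "cox1", g$records)[[1]]
  expect_equal(classify_start_stop(g, cox1)$start_class, "nonstandard")
  expect_error(classify_start_stop(g, g$records[[1]]), "not a protein")
})

test_that("stop classes cover complete, incomplete_T and incomplete_TA", {
  s <- paste0("ATG", "AAA", "TAG")
  g <- toy_genome(paste0(s, "G"),
                  list(gene_record("toy", "PCG", "F", 1, 9,
                                   start_codon = "ATG", stop_codon = "TAG")))
  call <- classify_start_stop(g, g$records[[1]])
  expect_equal(call$stop_class, "complete")
  gT <- toy_genome("ATGAAATGG",
                   list(gene_record("toy", "PCG", "F", 1, 7,
                                    start_codon = "ATG", stop_codon = "T")))
  expect_equal(classify_start_stop(gT, gT$records[[1]])$stop_class,
               "incomplete_T")
  gTA <- toy_genome("ATGAAATAG",
                    list(gene_record("toy", "PCG", "F", 1, 8,
                                     start_codon = "ATG", stop_codon = "TA")))
  expect_equal(classify_start_stop(gTA, gTA$records[[1]])$stop_class,
               "incomplete_TA")
})

test_that("codon_usage counts and rates are exact on small inputs", {
  u <- codon_usage(c("ATGAAA", "ATGAAA"))
  expect_equal(unname(u$counts["ATG"]), 2L)
  expect_equal(unname(u$counts["AAA"]), 2L)
  expect_equal(unname(u$per_thousand["ATG"]), 500)
  expect_equal(u$n_codons, 4L)
  # terminal stops and incomplete termini are excluded
  u2 <- codon_usage(c("ATGAAATAA", "ATGAAAT"))
  expect_equal(u2$n_codons, 4L)
  expect_equal(sum(u2$counts[c("TAA", "TAG")]), 0L)
  expect_error(codon_usage(character()), "empty")
})

test_that("per-thousand sums to 1000 and RSCU family means are 1", {
  nonstop <- codon_family_table()
  nonstop <- nonstop$codon[nonstop$family != "Stop"]
  set.seed(17)
  for (k in 1:10) {
    cds <- vapply(1:5, function(i)
      paste(sample(nonstop, 50, replace = TRUE), collapse = ""),
      character(1))
    u <- rscu(codon_usage(cds))
    expect_lt(abs(sum(u$per_thousand) - 1000), 0.01)
    fams <- split(names(u$rscu), u$family[names(u$rscu)])
    for (f in fams) expect_lt(abs(mean(u$rscu[f]) - 1), 1e-9)
    expect_equal(sum(u$counts), u$n_codons)
    # scale invariance: doubling every sequence leaves RSCU unchanged
    u2 <- rscu(codon_usage(c(cds, cds)))
    expect_equal(u2$rscu, u$rscu)
  }
})

test_that("RSCU closed forms and the missing-codon set are right", {
  u <- rscu(codon_usage(c("GCA", "GCC", "GCG", "GCT")))
  expect_equal(unname(u$rscu[c("GCA", "GCC", "GCG", "GCT")]),
               c(1, 1, 1, 1))
  u2 <- rscu(codon_usage(c("AAA", "AAA", "AAA", "AAG")))
  expect_equal(unname(u2$rscu["AAA"]), 1.5)
  expect_equal(unname(u2$rscu["AAG"]), 0.5)
  # GCG never used -> reported missing (the "codon not present" figure annotation)
  u3 <- codon_usage(c("GCAGCCGCT"))
  expect_true("GCG" %in% u3$missing)
  expect_false("GCA" %in% u3$missing)
})

test_that("generator codon bias is recovered from synthetic PCGs", {
  gen <- generate_mitogenome(genome_spec(seed = 5))
  g <- gen$genome
  fpcg <- Filter(function(r) r$feature_class == "PCG" && r$strand == "F",
                 g$records)
  cds <- lapply(fpcg, function(r) extract_feature_sequence(g, r))
  u <- codon_usage(cds)
  bias <- genome_spec(seed = 5)$codon_bias
  expected <- 1000 * bias / sum(bias)
  top <- names(sort(expected, decreasing = TRUE))[1:5]
  for (cd in top)
    expect_lt(abs(u$per_thousand[[cd]] - expected[[cd]]), 20)
  expect_gt(stats::cor(as.numeric(u$per_thousand[names(expected)]),
                       as.numeric(expected)), 0.98)
})
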