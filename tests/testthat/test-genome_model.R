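test_that("the annotation fixture parses into the expected genome", {
  g <- fixture_genome()
  expect_s3_class(g, "annotated_genome")
  expect_length(g$records, 38L)
  cls <- table(vapply(g$records, `[[`, character(1), "feature_class"))
  expect_equal(as.integer(cls[c("PCG", "tRNA", "rRNA", "control_region")]),
               c(13L, 22L, 2L, 1L))
  expect_equal(g$length, 15247L)
  # printed order preserved
  expect_equal(g$records[[1]]$name, "trnM")
  expect_equal(g$records[[38]]$name, "AT_rich_region")
  expect_null(g$sequence)
})

test_that("annotation tables round-trip through write/read", {
  g <- fixture_genome()
  tmp <- tempfile(fileext = ".tsv")
  write_annotation_table(g, tmp)
  g2 <- read_annotation_table(tmp, identifier = g$identifier)
  expect_equal(g2$records, g$records)
  expect_equal(g2$length, g$length)
  # idempotent a second time round
  tmp2 <- tempfile(fileext = ".tsv")
  write_annotation_table(g2, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("degenerate and wrapping annotation tables are handled", {
  hdr <- "Gene\tDirection\tStart\tEnd\tSize\tAnticodon\tStartCodon\tStopCodon\tIntergenicNucleotides"
  empty <- tempfile(); writeLines(hdr, empty)
  g0 <- read_annotation_table(empty)
  expect_length(g0$records, 0L)
  expect_equal(g0$length, 0L)

  toy <- tempfile()
  writeLines(c(hdr,
               "geneA\tF\t3\t8\t6\t-\tATG\tTAA\t1",
               "geneB\tR\t10\t2\t5\t-\t-\t-\t0",
               "geneC\tF\t4\t9\t6\t-\t-\t-\t-"), toy)
  g <- read_annotation_table(toy)
  expect_true(g$records[[2]]$wraps)
  expect_false(g$records[[1]]$wraps)
  tmp <- tempfile()
  write_annotation_table(g, tmp)
  expect_equal(read_annotation_table(tmp)$records, g$records)

  bad <- tempfile()
  writeLines(c(hdr, "geneA\tF\txx\t8\t6\t-\tATG\tTAA\t1"), bad)
  expect_error(read_annotation_table(bad), "malformed.*row 1")
  bad2 <- tempfile()
  writeLines(c(hdr, "geneA\tZ\t1\t8\t8\t-\tATG\tTAA\t1"), bad2)
  expect_error(read_annotation_table(bad2), "strand")
})

test_that("gene_length handles plain, single-base and wrapping features", {
  r <- function(s, e) gene_record("x", "rRNA", "F", s, e)
  expect_equal(gene_length(r(1476, 3004), 15247), 1529L)
  expect_equal(gene_length(r(5, 5), 15247), 1L)
  # positions 15246,15247,1,2,3 counted by enumeration
  expect_equal(gene_length(r(15246, 3), 15247), 5L)
  expect_error(gene_length(r(5, 20), 10), "out of range")
})

test_that("extract_feature_sequence is circular- and strand-aware", {
  seqc <- "ACGTACGTGG"
  gF <- gene_record("f", "rRNA", "F", 1, 3)
  gR <- gene_record("r", "rRNA", "R", 1, 3)
  gW <- gene_record("w", "rRNA", "F", 9, 2)
  g <- toy_genome(seqc, list(gF, gR, gW))
  expect_equal(extract_feature_sequence(g, gF), "ACG")
  expect_equal(extract_feature_sequence(g, gR), revcomp("ACG"))
  # wrapping slice equals tail+head concatenation (rotation oracle)
  expect_equal(extract_feature_sequence(g, gW),
               paste0(substring(seqc, 9, 10), substring(seqc, 1, 2)))
  # brute-force rotation oracle over random circles
  set.seed(41)
  for (k in 1:10) {
    s <- random_dna(30)
    st <- sample(30, 1); en <- sample(30, 1)
    rec <- gene_record("z", "rRNA", "F", st, en)
    rotated <- paste0(substring(s, st, 30), substring(s, 1, st - 1))
    want <- substring(rotated, 1, gene_length(rec, 30))
    expect_equal(extract_feature_sequence(toy_genome(s, list(rec)), rec),
                 want)
  }
  # reverse complement is an involution on extracted slices
  expect_equal(revcomp(revcomp(extract_feature_sequence(g, gW))),
               extract_feature_sequence(g, gW))
  expect_error(extract_feature_sequence(fixture_genome(), gF),
               "table-only")
})

test_that("FASTA round-trips and normalizes case", {
  tmp <- tempfile(fileext = ".fasta")
  write_fasta("taxonX", "acgtACGTnn", tmp)
  fa <- read_fasta(tmp)
  expect_equal(fa$identifier, "taxonX")
  expect_equal(fa$sequence, "ACGTACGTNN")
  long <- random_dna(200)
  write_fasta("y", long, tmp)
  expect_equal(read_fasta(tmp)$sequence, long)
  expect_equal(nchar(readLines(tmp)[2]), 70L)
})

test_that("GenBank round-trips the synthetic genome", {
  gen <- generate_mitogenome(genome_spec(seed = 11))
  tmp <- tempfile(fileext = ".gb")
  write_genbank(gen$genome, tmp)
  g2 <- read_genbank(tmp)
  expect_equal(length(g2$records), length(gen$genome$records))
  expect_equal(g2$length, gen$genome$length)
  expect_equal(g2$sequence, gen$genome$sequence)
  expect_equal(g2$records, gen$genome$records)
})

test_that("a hand-built GenBank with a complement CDS parses", {
  lines <- c(
    "LOCUS       mini 100 bp    DNA     circular INV 01-JAN-2026",
    "FEATURES             Location/Qualifiers",
    "     source          1..100",
    "     CDS             complement(10..30)",
    "                     /gene=\"toygene\"",
    "                     /note=\"start_codon:ATG;stop_codon:TAA\"",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtac", 4), collapse = " ")),
    "//")
  tmp <- tempfile(); writeLines(lines, tmp)
  g <- read_genbank(tmp)
  expect_equal(g$length, 100L)
  expect_length(g$records, 1L)
  r <- g$records[[1]]
  expect_equal(r$strand, "R")
  expect_equal(c(r$start, r$end), c(10L, 30L))
  expect_equal(r$feature_class, "PCG")
  expect_equal(r$name, "toygene")
  nolocus <- tempfile(); writeLines("FEATURES", nolocus)
  expect_error(read_genbank(nolocus), "LOCUS")
})

test_that("consistency report flags the published table's mismatches", {
  rep <- consistency_report(fixture_genome())
  expect_equal(rep$gene[rep$kind == "size"], c("cox3", "rrnS"))
  expect_equal(rep$computed[rep$kind == "size"], c(797L, 779L))
  ig <- rep[rep$kind == "intergenic", ]
  expect_equal(ig$gene, c("trnQ", "trnW", "nad5", "trnH"))
  expect_equal(ig$printed, c(55L, 2L, 0L, 24L))
  expect_equal(ig$computed, c(53L, -8L, 15L, 10L))
})
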