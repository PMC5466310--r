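test_that("build_supermatrix concatenates aligned PCGs", {
  cl <- generate_clade(clade_spec(seed = 2))
  sm <- build_supermatrix(cl$genomes)
  expect_equal(sm$width, 13L * 240L)
  expect_equal(nrow(sm$partition), 13L)
  expect_equal(sm$partition$end[13], sm$width)
  expect_true(all(nchar(sm$seqs) == sm$width))
  # permutation invariance modulo row order
  sm2 <- build_supermatrix(rev(cl$genomes))
  expect_equal(sm2$seqs[sm$taxa], sm$seqs)
  # single taxon still builds
  expect_equal(length(build_supermatrix(cl$genomes[1])$taxa), 1L)
  # missing gene is a named error
  broken <- cl$genomes[[1]]
  broken$records <- broken$records[-1]
  expect_error(build_supermatrix(list(broken, cl$genomes[[2]])),
               "lacks gene")
})

test_that("p and K2P distances match closed forms and the ape oracle", {
  mk_sm <- function(seqs) {
    genomes <- lapply(names(seqs), function(nm)
      annotated_genome(nm, list(gene_record("g1", "PCG", "F", 1,
                                            nchar(seqs[[nm]]),
                                            start_codon = "ATG")),
                       sequence = seqs[[nm]]))
    build_supermatrix(genomes, gene_order = "g1")
  }
  sm <- mk_sm(c(a = "AAAA", b = "AAAG"))
  expect_equal(pairwise_distance(sm, "p")["a", "b"], 0.25)
  expect_equal(pairwise_distance(sm, "K2P")["a", "b"], -0.5 * log(0.5),
               tolerance = 1e-12)
  smid <- mk_sm(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(pairwise_distance(smid, "p")["a", "b"], 0)
  # ambiguity codes are excluded pairwise
  smn <- mk_sm(c(a = "ACGTN", b = "ACGAA"))
  expect_equal(pairwise_distance(smn, "p")["a", "b"], 0.25)
  expect_error(pairwise_distance(mk_sm(c(a = "NNN", b = "AAA")), "p"),
               "zero comparable")
  # related random alignments (~15% divergence) against ape::dist.dna
  set.seed(47)
  for (k in 1:5) {
    base <- strsplit(random_dna(300), "")[[1]]
    seqs <- stats::setNames(
      vapply(1:4, function(i) {
        mut <- base
        at <- sample(300, 45)
        mut[at] <- sample(c("A", "C", "G", "T"), 45, replace = TRUE)
        paste(mut, collapse = "")
      }, character(1)),
      paste0("t", 1:4))
    sm <- mk_sm(seqs)
    bin <- ape::as.DNAbin(t(sapply(seqs, function(s)
      strsplit(tolower(s), "")[[1]])))
    expect_equal(unname(pairwise_distance(sm, "p")[lower.tri(diag(4))]),
                 unname(as.vector(ape::dist.dna(bin, "raw"))),
                 tolerance = 1e-12)
    expect_equal(unname(pairwise_distance(sm, "K2P")[lower.tri(diag(4))]),
                 unname(as.vector(ape::dist.dna(bin, "K80"))),
                 tolerance = 1e-10)
  }
})

test_that("neighbor joining recovers additive matrices exactly", {
  for (k in 1:20) {
    oa <- oracle_additive_matrix(sample(4:10, 1), seed = 100 + k)
    tr <- neighbor_joining(oa$d)
    expect_equal(rf_distance(tr, oa$tree), 0L, info = paste("seed", k))
    # branch lengths are recovered too (additive => exact)
    expect_equal(sort(tr$edge.length), sort(oa$tree$edge.length),
                 tolerance = 1e-6)
  }
})

test_that("3-taxon and tied matrices are handled deterministically", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_equal(ape::Ntip(tr), 3L)
  el <- stats::setNames(tr$edge.length,
                        tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el[c("a", "b", "c")]), c(0, 2, 3))
  star <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(star) <- 0
  t1 <- neighbor_joining(star)
  t2 <- neighbor_joining(star)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_error(neighbor_joining(star[1:2, 1:2]), "three")
})

test_that("outgroup rooting demands a split", {
  oa <- oracle_additive_matrix(6, seed = 55)
  tr <- neighbor_joining(oa$d)
  out1 <- tr$tip.label[1]
  rooted <- root_with_outgroup(tr, out1)
  expect_true(ape::is.rooted(rooted))
  # a scattered pair is typically not a split
  pairs <- utils::combn(tr$tip.label, 2, simplify = FALSE)
  bad <- Filter(function(p) !ape::is.monophyletic(tr, p), pairs)
  if (length(bad))
    expect_error(root_with_outgroup(tr, bad[[1]]), "not a split")
  expect_error(root_with_outgroup(tr, "nonexistent"), "not in tree")
})

test_that("bootstrap support is reproducible and sane", {
  cl <- generate_clade(clade_spec(seed = 9))
  sm <- build_supermatrix(cl$genomes)
  t1 <- bootstrap_support(sm, reps = 1, seed = 4)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
  t2 <- bootstrap_support(sm, reps = 25, seed = 4)
  t3 <- bootstrap_support(sm, reps = 25, seed = 4)
  expect_equal(ape::write.tree(t2), ape::write.tree(t3))
  # two clearly separated clades get >= 95% support
  big <- clade_spec(tree = "((A:0.05,B:0.05):0.3,(C:0.05,D:0.05):0.3);",
                    seed = 12)
  smb <- build_supermatrix(generate_clade(big)$genomes)
  tb <- bootstrap_support(smb, reps = 100, seed = 6)
  supb <- suppressWarnings(as.numeric(tb$node.label))
  expect_true(all(supb[!is.na(supb)] >= 95))
  # support values survive taxon-order permutation
  smp <- build_supermatrix(rev(generate_clade(big)$genomes))
  tp <- bootstrap_support(smp, reps = 100, seed = 6)
  expect_setequal(tb$node.label, tp$node.label)
})

test_that("Newick I/O round-trips, including support labels", {
  tmp <- tempfile(fileext = ".nwk")
  t3 <- neighbor_joining(matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
                                dimnames = list(c("a", "b", "c"),
                                                c("a", "b", "c"))))
  write_newick(t3, tmp)
  expect_equal(ape::write.tree(read_newick(tmp)), ape::write.tree(t3))
  oa <- oracle_additive_matrix(5, seed = 77)
  t5 <- neighbor_joining(oa$d)
  # unrooted 5-taxon tree keeps its trifurcating root through I/O
  write_newick(t5, tmp)
  back <- read_newick(tmp)
  expect_false(ape::is.rooted(back))
  expect_equal(rf_distance(back, t5), 0L)
  cl <- generate_clade(clade_spec(seed = 3))
  tb <- bootstrap_support(build_supermatrix(cl$genomes), reps = 10,
                          seed = 2)
  write_newick(tb, tmp)
  expect_equal(read_newick(tmp)$node.label, tb$node.label)
  badf <- tempfile(); writeLines("((a,b", badf)
  suppressWarnings(expect_error(read_newick(badf), "alformed|arse"))
})

test_that("rf_distance agrees with the phangorn oracle", {
  skip_if_not_installed("phangorn")
  set.seed(59)
  for (k in 1:10) {
    a <- ape::unroot(ape::rtree(7))
    b <- ape::unroot(ape::rtree(7, tip.label = a$tip.label))
    expect_equal(rf_distance(a, b),
                 as.integer(phangorn::RF.dist(a, b)))
  }
})

test_that("distances grow with simulated divergence", {
  mean_p <- vapply(c(0.5, 1, 2), function(scale) {
    sp <- clade_spec(tree = sprintf(
      "((A:%f,B:%f):%f,(C:%f,D:%f):%f);",
      0.1 * scale, 0.1 * scale, 0.05 * scale,
      0.1 * scale, 0.1 * scale, 0.05 * scale), seed = 21)
    d <- pairwise_distance(build_supermatrix(generate_clade(sp)$genomes),
                           "p")
    mean(d[lower.tri(d)])
  }, numeric(1))
  expect_true(all(diff(mean_p) > 0))
})
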