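# Concatenated-PCG supermatrix, p / Kimura-two-parameter distances,
# canonical neighbor joining with deterministic tie-breaking, and
# column-bootstrap support. Trees are ape "phylo" objects throughout;
# Newick I/O is delegated to ape.

#' Build a concatenated supermatrix from annotated genomes
#'
#' Extracts each gene of `gene_order` from every genome and
#' concatenates the (pre-aligned, equal-length per gene) sequences.
#' Alignment itself is out of scope: per-gene lengths must already
#' agree across taxa.
#'
#' @param genomes List of [annotated_genome()] objects with sequence.
#' @param gene_order Genes to concatenate, in order (default: the 13
#'   PCGs in lepidopteran genome order).
#' @return An object of class `supermatrix`: list with `taxa`, `seqs`
#'   (named character vector), `partition` (gene -> column range) and
#'   `width`.
#' @export
build_supermatrix <- function(genomes, gene_order = mt_pcg_names) {
  taxa <- vapply(genomes, `[[`, character(1), "identifier")
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  per_gene <- lapply(gene_order, function(g) {
    vapply(genomes, function(gen) {
      rec <- tryCatch(.find_record(gen, g), error = function(e)
        stop("taxon '", gen$identifier, "' lacks gene '", g, "'"))
      extract_feature_sequence(gen, rec)
    }, character(1))
  })
  names(per_gene) <- gene_order
  lens <- vapply(per_gene, function(s) {
    u <- unique(nchar(s))
    if (length(u) != 1L)
      stop("gene '", names(which.max(table(nchar(s)))),
           "' has unequal lengths across taxa; align the genes externally")
    u
  }, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  seqs <- stats::setNames(
    vapply(seq_along(taxa), function(i)
      paste(vapply(per_gene, `[[`, character(1), i), collapse = ""),
      character(1)), taxa)
  structure(list(taxa = taxa, seqs = seqs,
                 partition = data.frame(gene = gene_order, start = starts,
                                        end = ends, stringsAsFactors = FALSE),
                 width = sum(lens)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns (%d genes)\n",
              length(x$taxa), x$width, nrow(x$partition)))
  invisible(x)
}

.char_matrix <- function(sm) {
  do.call(rbind, strsplit(toupper(unname(sm$seqs)), "", fixed = TRUE))
}

.transitions <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)

#' Pairwise distances from a supermatrix
#'
#' `model = "p"`: mismatch proportion. `model = "K2P"`: Kimura
#' two-parameter distance `-1/2 log((1 - 2P - Q) sqrt(1 - 2Q))` with
#' `P`/`Q` the transition/transversion proportions. Columns holding a
#' gap or ambiguity code in either member of a pair are excluded
#' pairwise (pairwise deletion).
#'
#' @param sm A [build_supermatrix()] result with >= 2 taxa.
#' @param model `"p"` or `"K2P"`.
#' @return Symmetric numeric matrix with taxon dimnames and zero
#'   diagonal.
#' @export
pairwise_distance <- function(sm, model = c("K2P", "p")) {
  model <- match.arg(model)
  if (length(sm$taxa) < 2L) stop("need at least two taxa")
  m <- .char_matrix(sm)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(sm$taxa, sm$taxa))
  acgt <- c("A", "C", "G", "T")
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] %in% acgt & m[j, ] %in% acgt
    nv <- sum(ok)
    if (!nv) stop("zero comparable columns between '", sm$taxa[i],
                  "' and '", sm$taxa[j], "'")
    a <- m[i, ok]; b <- m[j, ok]
    diff <- a != b
    if (model == "p") {
      val <- sum(diff) / nv
    } else {
      pair <- paste0(a[diff], b[diff])
      P <- sum(pair %in% names(.transitions)) / nv
      Q <- (sum(diff) - sum(pair %in% names(.transitions))) / nv
      arg1 <- 1 - 2 * P - Q
      arg2 <- 1 - 2 * Q
      if (arg1 <= 0 || arg2 <= 0)
        stop("K2P distance undefined (saturated) for pair '",
             sm$taxa[i], "'/'", sm$taxa[j], "'")
      val <- -0.5 * log(arg1 * sqrt(arg2))
    }
    d[i, j] <- d[j, i] <- val
  }
  d
}

.nj_fmt <- function(x) sprintf("%.10g", x)

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei neighbor joining on a symmetric distance
#' matrix. Exact ties on the Q criterion are broken by the
#' lexicographically smallest pair of cluster labels (a cluster is
#' labelled by its alphabetically first member taxon), so the result is
#' deterministic. Negative branch lengths are clamped to zero with the
#' deficit moved to the sibling edge. The returned tree is unrooted
#' (trifurcating root node).
#'
#' @param d Symmetric numeric matrix with taxon dimnames (>= 3 taxa).
#' @return An [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  taxa <- rownames(d)
  if (is.null(taxa)) stop("distance matrix needs taxon dimnames")
  if (nrow(d) < 3L) stop("need at least three taxa")
  frag <- taxa
  rep_lab <- taxa
  D <- d
  clamp2 <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    c(li, lj)
  }
  while (length(frag) > 3L) {
    n <- length(frag)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij)
      paste(sort(c(rep_lab[ij[1]], rep_lab[ij[2]])), collapse = "\r"))
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    l <- clamp2(li, lj)
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], .nj_fmt(l[1]),
                        frag[j], .nj_fmt(l[2]))
    new_rep <- min(rep_lab[i], rep_lab[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    rep_lab <- c(rep_lab[keep], new_rep)
    D <- D2
  }
  la <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], .nj_fmt(la),
                 frag[2], .nj_fmt(lb), frag[3], .nj_fmt(lc))
  ape::read.tree(text = nwk)
}

#' Root a tree on the edge separating an outgroup
#'
#' @param tree An [ape::phylo] tree.
#' @param taxa Outgroup tip labels; must form a split of the tree.
#' @return The rooted tree.
#' @export
root_with_outgroup <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("outgroup taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(taxa) > 1L && !ape::is.monophyletic(tree, taxa))
    stop("outgroup {", paste(taxa, collapse = ", "),
         "} is not a split of the tree")
  ape::root(tree, outgroup = taxa, resolve.root = TRUE)
}

# Non-trivial bipartitions of an unrooted tree: named character vector
# (internal node id -> canonical key). The canonical side is the one
# NOT containing the alphabetically first taxon.
.tree_bipartitions <- function(tree) {
  nt <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", nt + tr$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  all_taxa <- sort(tree$tip.label)
  anchor <- all_taxa[1]
  root <- nt + 1L
  internals <- setdiff(unique(tr$edge[, 2]), seq_len(nt))
  keys <- vapply(internals, function(nd) {
    side <- sort(desc[[nd]])
    if (anchor %in% side) side <- setdiff(all_taxa, side)
    if (length(side) < 2L || length(side) > nt - 2L) return(NA_character_)
    paste(side, collapse = "|")
  }, character(1))
  stats::setNames(keys, internals)
}

.resample_supermatrix <- function(sm, cols) {
  m <- .char_matrix(sm)[, cols, drop = FALSE]
  sm2 <- sm
  sm2$seqs <- stats::setNames(apply(m, 1L, paste, collapse = ""), sm$taxa)
  sm2$width <- length(cols)
  sm2
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement `reps` times, rebuilds
#' the NJ tree per replicate and reports, for every internal edge of
#' the full-data tree, the percentage of replicates containing the same
#' bipartition. Reproducible for a given `seed`.
#'
#' @param sm A [build_supermatrix()] result (>= 4 taxa for non-trivial
#'   support).
#' @param model Distance model, see [pairwise_distance()].
#' @param reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return The full-data NJ tree with `node.label` holding integer
#'   support percentages (root label empty).
#' @export
bootstrap_support <- function(sm, model = "K2P", reps = 100L, seed = 1L) {
  stopifnot(reps >= 1L)
  ref <- neighbor_joining(pairwise_distance(sm, model))
  ref_parts <- .tree_bipartitions(ref)
  counts <- stats::setNames(numeric(length(ref_parts)), names(ref_parts))
  set.seed(seed)
  for (b in seq_len(reps)) {
    cols <- sample.int(sm$width, sm$width, replace = TRUE)
    bt <- tryCatch(
      neighbor_joining(pairwise_distance(.resample_supermatrix(sm, cols),
                                         model)),
      error = function(e) NULL)
    if (is.null(bt)) next
    bk <- .tree_bipartitions(bt)
    counts <- counts + (ref_parts %in% bk[!is.na(bk)])
  }
  nt <- length(ref$tip.label)
  labels <- character(ref$Nnode)
  for (k in seq_along(ref_parts)) {
    nd <- as.integer(names(ref_parts)[k])
    labels[nd - nt] <- if (is.na(ref_parts[k])) "" else
      as.character(round(100 * counts[k] / reps))
  }
  ref$node.label <- labels
  ref
}

#' Write / read Newick trees
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()];
#' `read_newick(write_newick(tree))` is the identity on the canonical
#' form.
#'
#' @param tree An [ape::phylo] tree.
#' @param path File path.
#' @return `write_newick`: `path` invisibly; `read_newick`: a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e)
    stop("malformed Newick in '", path, "': ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick in '", path, "'")
  tr
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Counted directly over the symmetric difference of the non-trivial
#' bipartition sets.
#'
#' @param a,b [ape::phylo] trees on the same tip set.
#' @return Integer RF distance.
#' @export
rf_distance <- function(a, b) {
  pa <- .tree_bipartitions(a); pa <- pa[!is.na(pa)]
  pb <- .tree_bipartitions(b); pb <- pb[!is.na(pb)]
  length(setdiff(pa, pb)) + length(setdiff(pb, pa))
}
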